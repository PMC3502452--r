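test_that("a single non-branching path reassembles the source sequence", {
  s <- "ACGGTCCAT"
  reads <- substring(s, 1:5, 5:9)
  ctg <- assemble(reads, k_asm = 5, min_node_coverage = 1, min_contig_length = 5)
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$sequence %in% c(s, reverse_complement(s)))
})

test_that("disjoint loci assemble into one contig each", {
  withr::with_seed(51, {
    l1 <- random_seq(200)
    l2 <- random_seq(200)
    reads <- c(substring(l1, seq(1, 150, 7), seq(51, 200, 7)),
               substring(l2, seq(1, 150, 7), seq(51, 200, 7)))
    ctg <- assemble(reads, k_asm = 21, min_node_coverage = 2, min_contig_length = 80)
    expect_equal(nrow(ctg), 2L)
    for (s in ctg$sequence) {
      expect_true(stringi::stri_detect_fixed(l1, s) | stringi::stri_detect_fixed(l2, s) |
                    stringi::stri_detect_fixed(reverse_complement(l1), s) |
                    stringi::stri_detect_fixed(reverse_complement(l2), s))
    }
  })
})

test_that("error-free tiling reads reproduce the source exactly when coverage is met", {
  withr::with_seed(52, {
    for (rep in 1:5) {
      s <- random_seq(300)
      starts <- seq(1, 250, by = 5)
      reads <- substring(s, starts, starts + 50)
      ctg <- assemble(reads, k_asm = 21, min_node_coverage = 2, min_contig_length = 80)
      expect_equal(nrow(ctg), 1L)
      expect_true(ctg$sequence %in% c(NA, s, reverse_complement(s)) |
                    stringi::stri_detect_fixed(s, ctg$sequence) |
                    stringi::stri_detect_fixed(reverse_complement(s), ctg$sequence))
      # all emitted k-mers meet the coverage floor
      expect_true(all(ctg$mean_kmer_coverage >= 2))
    }
  })
})

test_that("assembly is deterministic and orientation-canonical", {
  withr::with_seed(53, {
    s <- random_seq(250)
    starts <- seq(1, 200, by = 4)
    reads <- substring(s, starts, starts + 50)
    a <- assemble(reads, k_asm = 15, min_node_coverage = 2, min_contig_length = 60)
    b <- assemble(rev(reads), k_asm = 15, min_node_coverage = 2, min_contig_length = 60)
    expect_equal(a, b)
    expect_true(all(a$sequence <= reverse_complement(a$sequence)))
  })
})

test_that("all reads shorter than k_asm yield an empty result with a warning", {
  expect_warning(ctg <- assemble(c("ACGT", "GGTT"), k_asm = 7), "shorter")
  expect_equal(nrow(ctg), 0L)
})

test_that("around one isolated SNP at 20x, a single short contig carrying the variant emerges", {
  clade <- balanced_clade(seed = 55, n_snps = 2)
  ev <- clade$ev
  k <- 21
  tables <- lapply(names(ev$genomes), function(g) {
    count_kmers(simulate_reads(ev$genomes[[g]], error_rate = 0, seed = 56 + match(g, names(ev$genomes)),
                               genome_id = g),
                k = k, threshold = 3, genome_id = g)
  })
  p <- build_tip_and_shared(tables)
  g <- "B"
  reads <- simulate_reads(ev$genomes[[g]], error_rate = 0, seed = 56 + 2, genome_id = g)
  led <- ev$ledger[ev$ledger$node == g, ]
  for (r in seq_len(nrow(led))) {
    # select reads for just this variant's k-mers
    ctx <- led$after_context[r]
    var_kmers <- canonicalize(kmer_windows(ctx, k))
    tipset <- intersect(var_kmers, p$tips$kmer[p$tips$genome_id == g])
    sel <- select_reads(reads, tipset, k = k)
    ctg <- assemble(sel, k_asm = k, min_node_coverage = 2, min_contig_length = 80,
                    genome_id = g)
    expect_equal(nrow(ctg), 1L)
    # single-feature footprint: at most 2 * read length - 1, and contains the alt context
    expect_lte(ctg$length, 2L * 51L - 1L)
    expect_gte(ctg$length, 80L)
    expect_true(stringi::stri_detect_fixed(ctg$sequence, ctx) ||
                  stringi::stri_detect_fixed(reverse_complement(ctg$sequence), ctx))
  }
})

test_that("variants closer than twice the read length merge into fewer, longer contigs", {
  withr::with_seed(57, {
    base <- random_seq(1200)
    mut <- function(s, pos) {
      old <- substr(s, pos, pos)
      substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
      s
    }
    read_len <- 51L
    mk_reads <- function(s) {
      starts <- seq(1, nchar(s) - read_len + 1, by = 2)
      substring(s, starts, starts + read_len - 1L)
    }
    count_contigs <- function(positions) {
      alt <- Reduce(mut, positions, accumulate = FALSE, init = base)
      reads_alt <- mk_reads(alt)
      ref_tab <- count_kmers(mk_reads(base), k = 21, threshold = 1)
      alt_tab <- count_kmers(reads_alt, k = 21, threshold = 1)
      tips <- setdiff(alt_tab$kmer, ref_tab$kmer)
      sel <- select_reads(tibble::tibble(id = as.character(seq_along(reads_alt)),
                                         sequence = reads_alt), tips, k = 21)
      nrow(assemble(sel, k_asm = 21, min_node_coverage = 2, min_contig_length = 80))
    }
    far <- count_contigs(c(300, 700))   # separation >> 2 * read length
    near <- count_contigs(c(500, 560))  # separation < 2 * read length
    expect_equal(far, 2L)
    expect_lte(near, far)
    expect_equal(near, 1L)
  })
})

test_that("branch pruning removes weak error paths but keeps balanced junctions intact", {
  withr::with_seed(58, {
    s <- random_seq(240)
    starts <- seq(1, 190, by = 3)
    good <- substring(s, starts, starts + 50)
    err_read <- good[30]
    substr(err_read, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(err_read, 25, 25))[1]
    reads <- c(good, err_read, err_read) # recurrent error passes the coverage floor
    with_prune <- assemble(reads, k_asm = 21, min_node_coverage = 2,
                           min_contig_length = 80, branch_ratio = 3)
    expect_equal(nrow(with_prune), 1L)
    expect_true(stringi::stri_detect_fixed(s, with_prune$sequence) ||
                  stringi::stri_detect_fixed(reverse_complement(s), with_prune$sequence))
    no_prune <- assemble(reads, k_asm = 21, min_node_coverage = 2,
                         min_contig_length = 20, branch_ratio = Inf)
    expect_gt(nrow(no_prune), 1L) # bubble splits the unitig instead
  })
})
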