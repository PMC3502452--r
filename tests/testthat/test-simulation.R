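test_that("quadripartite construction: lengths, derived IRB, determinism", {
  g <- make_genome(2000, 600, 700, seed = 71)
  expect_equal(nchar(g$sequence), 2000 + 600 + 2 * 700)
  ira <- substr(g$sequence, 2001, 2700)
  irb <- substr(g$sequence, 3301, 4000)
  expect_equal(irb, reverse_complement(ira))
  expect_equal(make_genome(2000, 600, 700, seed = 71)$sequence, g$sequence)
  expect_false(make_genome(2000, 600, 700, seed = 72)$sequence == g$sequence)
})

test_that("IR duplication removes its length from k-mer diversity; no IR gives the 1:1 regime", {
  k <- 21
  g <- make_genome(5000, 1400, 1800, seed = 73)
  G <- nchar(g$sequence)
  d <- distinct_kmer_count(count_kmers(g$sequence, k = k, threshold = 1))
  expected <- (G - 1800) - (k - 1)
  expect_lte(abs(d - expected), 2 * (k - 1))
  g0 <- make_genome(5000, 1400, 0, seed = 74)
  d0 <- distinct_kmer_count(count_kmers(g0$sequence, k = k, threshold = 1))
  expect_equal(d0, nchar(g0$sequence) - k + 1)
})

test_that("variants apply correctly and invert cleanly", {
  g <- make_genome(500, 200, 100, seed = 75)
  snp <- apply_variant(g, "snp", 250, seed = 76)
  d <- mapply(function(a, b) a != b,
              strsplit(g$sequence, "")[[1]], strsplit(snp$genome$sequence, "")[[1]])
  expect_equal(sum(d), 1L)
  ins <- apply_variant(g, "insertion", 250, i = 5, seed = 77)
  expect_equal(nchar(ins$genome$sequence), nchar(g$sequence) + 5)
  del <- apply_variant(ins$genome, "deletion", 250, i = 5)
  expect_equal(del$genome$sequence, g$sequence)
  expect_equal(del$entry$ref_allele, ins$entry$alt_allele)
  tr <- apply_variant(g, "translocation", 100, seg_len = 40, dest = 400, seed = 78)
  expect_equal(nchar(tr$genome$sequence), nchar(g$sequence))
  expect_false(tr$genome$sequence == g$sequence)
  expect_error(apply_variant(g, "snp", 10000), "range")
  expect_error(apply_variant(g, "deletion", 890, i = 50), "fit")
})

test_that("zero rates leave all leaves identical and tip sets empty", {
  root <- make_genome(1500, 400, 400, seed = 79)
  ev <- evolve_on_tree(root, "((A:1,B:1):1,(C:1,D:1):1);", n_snps = 0, seed = 80)
  expect_equal(nrow(ev$ledger), 0L)
  for (g in ev$genomes) expect_equal(g$sequence, root$sequence)
  tabs <- lapply(names(ev$genomes), function(g) {
    count_kmers(ev$genomes[[g]]$sequence, k = 21, threshold = 1, genome_id = g)
  })
  p <- build_tip_and_shared(tabs)
  expect_equal(nrow(p$tips), 0L)
})

test_that("one interior SNP on a terminal branch creates exactly k new tip k-mers", {
  root <- make_genome(3000, 800, 0, seed = 81, circular = FALSE)
  k <- 21
  ev <- evolve_on_tree(root, "(A:1,B:1);", n_snps = c(A = 1), seed = 82)
  tabs <- lapply(names(ev$genomes), function(g) {
    count_kmers(ev$genomes[[g]]$sequence, k = k, threshold = 1, genome_id = g)
  })
  p <- build_tip_and_shared(tabs)
  tipA <- p$tips$kmer[p$tips$genome_id == "A"]
  tipB <- p$tips$kmer[p$tips$genome_id == "B"]
  expect_equal(length(tipA), k)       # the k windows covering the new allele
  expect_equal(length(tipB), k)       # the k replaced windows stay unique to B
  ctx <- ev$ledger$after_context[1]
  expect_true(all(tipA %in% canonicalize(kmer_windows(ctx, k))))
})

test_that("a variant on an internal branch lands in the descendant pair's exclusive group", {
  root <- make_genome(4000, 1000, 0, seed = 83, circular = FALSE)
  k <- 21
  ev <- evolve_on_tree(root, "((A:1,B:1)ab:1,(C:1,D:1)cd:1);",
                       n_snps = c(ab = 1), seed = 84)
  tabs <- lapply(names(ev$genomes), function(g) {
    count_kmers(ev$genomes[[g]]$sequence, k = k, threshold = 1, genome_id = g)
  })
  p <- build_tip_and_shared(tabs)
  excl <- extract_group(p$shared, tabs, c("A", "B"), "exclusive")
  expect_equal(length(excl), k)
  expect_equal(nrow(p$tips), 0L)
})

test_that("ledger replay reproduces every leaf exactly", {
  root <- make_genome(6000, 1500, 1200, seed = 85)
  ev <- evolve_on_tree(root, "((A:1,B:1):1,(C:1,D:1):1);",
                       n_snps = 4, n_insertions = 2, n_deletions = 2, seed = 86)
  expect_equal(nrow(ev$ledger), 8L * 6L)
  for (leaf in names(ev$genomes)) {
    expect_equal(replay_ledger(root, ev, leaf), ev$genomes[[leaf]]$sequence)
  }
})

test_that("read counts, error-free substring property, and determinism", {
  g <- make_genome(5000, 1400, 1800, seed = 87) # 10 kb
  reads <- simulate_reads(g, read_len = 51, coverage = 20, error_rate = 0,
                          seed = 88, genome_id = "g")
  expect_equal(nrow(reads), 2L * round(10000 * 20 / (2 * 51)))
  expect_lte(abs(sum(nchar(reads$sequence)) / 10000 - 20), 0.2) # coverage conservation
  pad <- paste0(g$sequence, substr(g$sequence, 1, 500))
  idx <- sample(nrow(reads), 50)
  ok <- vapply(reads$sequence[idx], function(s) {
    stringi::stri_detect_fixed(pad, s) || stringi::stri_detect_fixed(pad, reverse_complement(s))
  }, logical(1))
  expect_true(all(ok))
  again <- simulate_reads(g, read_len = 51, coverage = 20, error_rate = 0,
                          seed = 88, genome_id = "g")
  expect_equal(again, reads)
  expect_error(simulate_reads(g, read_len = 51, insert_mean = 40), "insert_mean")
})

test_that("substitution errors are calibrated to the requested rate", {
  g <- make_genome(5000, 1400, 1800, seed = 89)
  reads <- simulate_reads(g, read_len = 51, coverage = 20, error_rate = 0.05,
                          seed = 90, genome_id = "g")
  truth <- simulate_reads(g, read_len = 51, coverage = 20, error_rate = 0,
                          seed = 90, genome_id = "g")
  expect_equal(truth$id, reads$id) # same fragments, same layout
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$sequence, truth$sequence))
  n <- sum(nchar(reads$sequence))
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(mism, ci[1])
  expect_lte(mism, ci[2])
})

test_that("variant loci respect spacing, including across inverted-repeat mirrors", {
  root <- make_genome(5000, 1400, 1800, seed = 91)
  ev <- evolve_on_tree(root, "(A:1,B:1);", n_snps = 15, min_spacing = 120, seed = 92)
  pos <- ev$ledger$root_pos
  mir <- kmercomp:::ir_mirror(root, pos)
  all_pos <- c(pos, mir[!is.na(mir)])
  d <- as.matrix(dist(all_pos))
  diag(d) <- NA
  # mirrored coordinates of IR variants count as the same locus
  mirrored_self <- abs(outer(pos, mir, "-")) == 0
  expect_gte(min(d[d > 0], na.rm = TRUE), 120)
})
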