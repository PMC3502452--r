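# build small k-mer tables directly from synthetic per-genome k-mer sets
tables_from_sets <- function(sets, k = 3) {
  lapply(names(sets), function(g) {
    kms <- sort(sets[[g]], method = "radix")
    kmercomp:::new_kmer_table(tibble::tibble(kmer = kms, count = rep(3L, length(kms))),
                              genome_id = g, k = k, threshold = 1L)
  })
}

# map arbitrary symbolic ids to valid canonical 3-mers
km <- function(...) {
  pool <- c("AAA", "AAC", "AAG", "AAT", "ACA", "ACC", "ACG", "ACT",
            "AGA", "AGC", "AGG", "ATA", "ATC", "ATG", "CAA", "CAC",
            "CAG", "CTC", "CCA", "CCC", "CCG", "CGA", "CGC", "CTA",
            "GAA", "GAC", "GCA", "GGA", "GTA", "TAA")
  pool[c(...)]
}

test_that("tip/shared split matches the definitional example", {
  sets <- list(A = km(1, 2), B = km(2, 3), C = km(2, 4))
  p <- build_tip_and_shared(tables_from_sets(sets))
  expect_equal(p$tips$kmer[p$tips$genome_id == "A"], km(1))
  expect_equal(p$tips$kmer[p$tips$genome_id == "B"], km(3))
  expect_equal(p$tips$kmer[p$tips$genome_id == "C"], km(4))
  expect_equal(p$shared$kmer, km(2))
  expect_equal(p$shared$group_key, "A+B+C")
  expect_true(check_partition_law(p, tables_from_sets(sets)))
})

test_that("identical tables produce no tips and a full shared table", {
  sets <- list(A = km(1), B = km(1))
  p <- build_tip_and_shared(tables_from_sets(sets))
  expect_equal(nrow(p$tips), 0L)
  expect_equal(p$shared$group_key, "A+B")
})

test_that("mismatched k or duplicate genome ids are rejected", {
  a <- count_kmers("ACGTACG", k = 3, threshold = 1, genome_id = "A")
  b <- count_kmers("ACGTACG", k = 5, threshold = 1, genome_id = "B")
  expect_error(build_tip_and_shared(list(a, b)), "same k")
  a2 <- count_kmers("ACGTACG", k = 3, threshold = 1, genome_id = "A")
  expect_error(build_tip_and_shared(list(a, a2)), "duplicate")
})

test_that("exclusive and inclusive extraction match hand set algebra", {
  sets <- list(A = km(5, 6), B = km(5, 6, 7), C = km(6))
  tabs <- tables_from_sets(sets)
  p <- build_tip_and_shared(tabs)
  expect_equal(extract_group(p$shared, tabs, c("A", "B"), "exclusive"), km(5))
  expect_equal(extract_group(p$shared, tabs, c("A", "B"), "inclusive"),
               sort(km(5, 6), method = "radix"))
  expect_equal(extract_group(p$shared, tabs, c("A", "B", "C"), "exclusive"), km(6))
  expect_error(extract_group(p$shared, tabs, c("A", "Z"), "exclusive"), "unknown")
})

test_that("partition law and both extraction modes agree with the brute-force oracle", {
  withr::with_seed(21, {
    pool <- unique(oracle_canonical(vapply(1:400, function(i) random_seq(5), character(1))))
    for (rep in 1:30) {
      n_g <- sample(2:8, 1)
      ids <- LETTERS[seq_len(n_g)]
      sets <- setNames(lapply(ids, function(g) {
        sample(pool, sample(5:40, 1))
      }), ids)
      tabs <- tables_from_sets(sets, k = 5)
      p <- build_tip_and_shared(tabs)
      expect_true(check_partition_law(p, tabs))
      o <- oracle_tips_shared(sets)
      for (g in ids) {
        expect_setequal(p$tips$kmer[p$tips$genome_id == g], o$tips[[g]])
      }
      # exclusive groups partition the shared table
      expect_equal(sum(group_sharing_counts(p$shared)$n_kmers), nrow(p$shared))
      grp <- sample(ids, if (n_g == 2) 2 else sample(2:n_g, 1))
      excl <- extract_group(p$shared, tabs, grp, "exclusive")
      incl <- extract_group(p$shared, tabs, grp, "inclusive")
      expect_setequal(excl, oracle_exclusive(sets, grp))
      expect_setequal(incl, oracle_inclusive(sets, grp))
      expect_true(all(excl %in% incl))
    }
  })
})

test_that("inclusive extraction is antitone and composes by intersection", {
  withr::with_seed(22, {
    pool <- unique(oracle_canonical(vapply(1:300, function(i) random_seq(5), character(1))))
    sets <- setNames(lapply(1:4, function(i) sample(pool, 60)), LETTERS[1:4])
    tabs <- tables_from_sets(sets, k = 5)
    p <- build_tip_and_shared(tabs)
    iab <- extract_group(p$shared, tabs, c("A", "B"), "inclusive")
    ibc <- extract_group(p$shared, tabs, c("B", "C"), "inclusive")
    iabc <- extract_group(p$shared, tabs, c("A", "B", "C"), "inclusive")
    expect_setequal(iabc, intersect(iab, ibc))
    expect_true(all(iabc %in% iab))
  })
})

test_that("group sharing counts tally memberships and filter as expected", {
  sets <- list(A = km(10, 11, 12), B = km(10, 11, 13), C = km(11))
  p <- build_tip_and_shared(tables_from_sets(sets))
  gc <- group_sharing_counts(p$shared)
  expect_equal(gc$n_kmers[gc$group_key == "A+B"], 1L)
  expect_equal(gc$n_kmers[gc$group_key == "A+B+C"], 1L)
  expect_equal(sum(gc$n_kmers), nrow(p$shared))
  empty <- p$shared[0, ]
  expect_equal(nrow(group_sharing_counts(empty)), 0L)
})

test_that("congruent group enumeration: worked examples and deduplication", {
  tx <- tibble::tibble(
    genome_id = c("A", "B", "C", "D"),
    lineage = list(c("root", "X"), c("root", "X"), c("root", "Y"), c("root", "Y"))
  )
  g <- enumerate_congruent_groups(tx)
  expect_setequal(g$group_key, c("A+B", "C+D", "A+B+C+D"))
  # unsampled genome shrinks the leaf sets
  g2 <- enumerate_congruent_groups(tx, sampled = c("A", "B", "D"))
  expect_setequal(g2$group_key, c("A+B", "A+B+D"))
  # all genomes in one genus: every taxon collapses to the same set
  tx3 <- tibble::tibble(genome_id = c("A", "B"),
                        lineage = list(c("r", "f", "g"), c("r", "f", "g")))
  expect_equal(enumerate_congruent_groups(tx3)$group_key, "A+B")
})
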