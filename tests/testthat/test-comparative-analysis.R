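test_that("variant k-mer span laws at k = 17 reproduce the closed forms", {
  expect_equal(variant_kmer_span("snp", 17), 17L)
  expect_equal(variant_kmer_span("junction", 17), 16L)
  expect_equal(variant_kmer_span("insertion", 17, i = 3), 19L)
  expect_equal(variant_kmer_span("deletion", 17, i = 3), 16L)
  expect_error(variant_kmer_span("insertion", 17), "i >= 1")
  expect_error(variant_kmer_span("snp", 16), "odd")
})

test_that("span formulas agree with the brute-force window oracle across k and i", {
  withr::with_seed(101, {
    for (k in seq(11, 31, by = 2)) {
      cx <- make_contexts("snp", k)
      expect_equal(oracle_span(cx$ref, cx$alt, k), variant_kmer_span("snp", k))
      cx <- make_contexts("junction", k)
      expect_equal(oracle_span(cx$ref, cx$alt, k), variant_kmer_span("junction", k))
      for (i in 1:10) {
        cx <- make_contexts("insertion", k, i = i)
        expect_equal(oracle_span(cx$ref, cx$alt, k), variant_kmer_span("insertion", k, i = i))
        cx <- make_contexts("deletion", k, i = i)
        expect_equal(oracle_span(cx$ref, cx$alt, k), variant_kmer_span("deletion", k, i = i))
      }
    }
  })
})

test_that("coverage profiles have the expected peak, plateau, and conservation", {
  withr::with_seed(102, {
    k <- 17
    cx <- make_contexts("snp", k)
    pr <- variant_coverage_profile(cx$ref, cx$alt, k)
    expect_equal(max(pr$coverage), k)
    expect_equal(plateau_width(pr), 1L)
    expect_equal(sum(pr$coverage), variant_kmer_span("snp", k) * k)

    cx <- make_contexts("junction", k)
    pj <- variant_coverage_profile(cx$ref, cx$alt, k)
    expect_equal(max(pj$coverage), k - 1L)
    expect_equal(plateau_width(pj), 2L)
    expect_equal(sum(pj$coverage), variant_kmer_span("junction", k) * k)

    for (i in c(1, 4, 9)) {
      cx <- make_contexts("insertion", k, i = i)
      pi <- variant_coverage_profile(cx$ref, cx$alt, k)
      expect_equal(max(pi$coverage), k)
      expect_equal(plateau_width(pi), i)
      expect_equal(sum(pi$coverage), variant_kmer_span("insertion", k, i = i) * k)
    }
  })
})

test_that("short flanks and identical contexts are rejected", {
  withr::with_seed(103, {
    k <- 11
    left <- random_seq(5) # too short to bound the variant
    ref <- paste0(left, "A", random_seq(40))
    alt <- ref
    substr(alt, 6, 6) <- "C"
    expect_error(variant_coverage_profile(ref, alt, k), "flank")
    expect_error(variant_coverage_profile(ref, ref, k), "identical")
  })
})

test_that("regression recovers exact coefficients on noiseless points", {
  pts <- tibble::tibble(genome_size = seq(60000, 200000, length.out = 10),
                        distinct_kmers = 1801 + 0.82 * seq(60000, 200000, length.out = 10),
                        has_ir = TRUE)
  fit <- diversity_regression(pts)
  expect_equal(fit$slope, 0.82, tolerance = 1e-10)
  expect_equal(fit$intercept, 1801, tolerance = 1e-6)
  expect_error(diversity_regression(dplyr::mutate(pts, has_ir = FALSE)), "two IR-flagged")
  g <- suppressWarnings(glance(fit)) # lm warns on an exactly perfect fit
  expect_equal(g$slope, fit$slope)
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  expect_equal(nrow(augment(fit)), 10L)
})

test_that("regression is invariant to point order and consistent under unit rescaling", {
  withr::with_seed(104, {
    pts <- tibble::tibble(genome_size = runif(15, 6e4, 2e5))
    pts$distinct_kmers <- 1801 + 0.82 * pts$genome_size + rnorm(15, 0, 500)
    pts$has_ir <- TRUE
    f1 <- diversity_regression(pts)
    f2 <- diversity_regression(pts[sample(15), ])
    expect_equal(f1$slope, f2$slope)
    kb <- dplyr::mutate(pts, genome_size = genome_size / 1000,
                        distinct_kmers = distinct_kmers / 1000)
    f3 <- diversity_regression(kb)
    expect_equal(f3$slope, f1$slope, tolerance = 1e-8)
    expect_equal(f3$intercept, f1$intercept / 1000, tolerance = 1e-6)
  })
})

test_that("synthetic genomes with 18% IR duplication sit on the 0.82-slope line", {
  k <- 21
  pts <- purrr::map_dfr(1:12, function(i) {
    scale <- 0.5 + 0.12 * i # genome sizes ~56-107 kb at fixed 18% duplication
    g <- make_genome(round(50000 * scale), round(14000 * scale), round(18000 * scale),
                     seed = 200 + i)
    tibble::tibble(genome_size = nchar(g$sequence),
                   distinct_kmers = distinct_kmer_count(count_kmers(g$sequence, k = k, threshold = 1)),
                   has_ir = TRUE)
  })
  fit <- diversity_regression(pts)
  expect_gte(fit$slope, 0.80)
  expect_lte(fit$slope, 0.84)
})
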