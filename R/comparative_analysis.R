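#' Number of informative k-mers spanning a variant
#'
#' Closed-form footprint of an isolated variant in non-repetitive context:
#' a single-nucleotide change appears in exactly `k` k-mers (every window
#' covering the changed base); a novel junction (translocation or inversion
#' breakpoint) appears in `k - 1` (every window containing at least one
#' base from each side); an insertion of length `i` appears in `k + i - 1`
#' (every window containing at least one inserted base). A deletion is the
#' mirror image: the genome carrying the deletion gains `k - 1` junction
#' k-mers while the genome retaining the sequence holds the `k + i - 1`
#' insertion-side k-mers.
#'
#' @param vtype One of `"snp"`, `"junction"`, `"insertion"`, `"deletion"`.
#' @param k Odd word size.
#' @param i Insertion/deletion length (required for `"insertion"` and
#'   `"deletion"`).
#' @return Integer k-mer count.
#' @examples
#' variant_kmer_span("snp", 17)        # 17
#' variant_kmer_span("junction", 17)   # 16
#' variant_kmer_span("insertion", 17, i = 3) # 19
#' @export
variant_kmer_span <- function(vtype, k, i = NULL) {
  k <- check_odd_k(k)
  vtype <- match.arg(vtype, c("snp", "junction", "translocation", "insertion", "deletion"))
  switch(vtype,
    snp = k,
    junction = ,
    translocation = ,
    deletion = k - 1L,
    insertion = {
      if (is.null(i) || i < 1) abort("insertion span needs i >= 1")
      k + as.integer(i) - 1L
    }
  )
}

#' Empirical per-base coverage of variant-spanning k-mers
#'
#' Enumerates every k-window of the variant-carrying sequence that is
#' absent (canonically) from the reference sequence(s), and accumulates how
#' many such informative k-mers cover each base. For an isolated SNP the
#' profile peaks at `k` on the single changed base; a novel junction shows
#' a two-base plateau at `k - 1`; an insertion of length `i` shows a
#' plateau of height `k` across the `i` inserted bases. Total coverage
#' always equals `span * k` for interior variants (each informative k-mer
#' covers k bases).
#'
#' @param ref_context Character vector of reference sequence(s) — for a
#'   junction, supply both original regions.
#' @param alt_context The variant-carrying sequence; flanks around the
#'   variant must be at least `k` bases (so a shared window bounds the
#'   variant on both sides) or the profile would be truncated by edge
#'   effects (error).
#' @param k Odd word size.
#' @return A `coverage_profile`: tibble with `position` (1-based on
#'   `alt_context`) and `coverage`, plus attribute `k`.
#' @export
variant_coverage_profile <- function(ref_context, alt_context, k) {
  k <- check_odd_k(k)
  stopifnot(length(alt_context) == 1L)
  alt_context <- toupper(alt_context)
  ref_context <- toupper(ref_context)
  L <- nchar(alt_context)
  if (L < k) abort("alt context shorter than k")
  ref_set <- unique(canonicalize(kmer_windows(ref_context, k)))
  starts <- seq_len(L - k + 1L)
  win <- substring(alt_context, starts, starts + k - 1L)
  novel <- !(canonicalize(win) %in% ref_set)
  if (!any(novel)) abort("no informative k-mers: contexts are identical under canonical comparison")
  first_n <- which(novel)[1L]; last_n <- tail(which(novel), 1L)
  if (first_n == 1L || last_n == length(starts)) {
    abort("flanks around the variant are shorter than k - 1 bases; edge effects would distort the profile")
  }
  cov <- integer(L)
  for (s in starts[novel]) cov[s:(s + k - 1L)] <- cov[s:(s + k - 1L)] + 1L
  structure(tibble(position = seq_len(L), coverage = cov),
            k = k, n_informative = sum(novel),
            class = c("coverage_profile", class(tibble())))
}

#' Width of the maximum-coverage plateau
#'
#' Longest run of consecutive positions attaining the profile maximum:
#' 1 for a SNP, 2 for a junction, i for an insertion of length i.
#'
#' @param profile A `coverage_profile` ([variant_coverage_profile()]) or a
#'   numeric coverage vector.
#' @return Integer plateau width.
#' @export
plateau_width <- function(profile) {
  cov <- if (is.data.frame(profile)) profile$coverage else profile
  if (length(cov) == 0L) abort("empty coverage profile")
  at_max <- cov == max(cov)
  r <- rle(at_max)
  max(r$lengths[r$values])
}

#' Regress k-mer diversity on genome size
#'
#' Ordinary least squares of distinct canonical k-mer count on genome size,
#' fitted over the genomes flagged as carrying an inverted repeat. Genomes
#' without an IR sit on the 1:1 line (diversity ~ size); IR-bearing genomes
#' fall on a line whose slope is one minus the duplicated fraction — a
#' conserved ~18% duplication yields a slope near 0.82. Deviations from the
#' fit are reported for every point (including non-IR genomes) so outliers
#' with unusual duplication structure stand out.
#'
#' @param points Tibble/data.frame with columns `genome_size` (bases) and
#'   `distinct_kmers`, optionally `genome_id`.
#' @param has_ir Logical vector flagging the IR-bearing genomes the line is
#'   fitted to (at least two); defaults to a `has_ir` column of `points`.
#' @return A `diversity_fit` object with [tidy()], [glance()], [augment()]
#'   and [autoplot()] methods.
#' @export
diversity_regression <- function(points, has_ir = points$has_ir) {
  if (is.null(has_ir)) abort("has_ir flags are required (which genomes carry an inverted repeat?)")
  has_ir <- as.logical(has_ir)
  stopifnot(length(has_ir) == nrow(points))
  if (sum(has_ir) < 2L) abort("need at least two IR-flagged points to fit a line")
  fit <- lm(distinct_kmers ~ genome_size, data = points[has_ir, , drop = FALSE])
  pts <- as_tibble(points)
  pts$has_ir <- has_ir
  pts$fitted <- predict(fit, newdata = pts)
  pts$deviation <- pts$distinct_kmers - pts$fitted
  structure(list(fit = fit, points = pts,
                 slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
                 n_points = sum(has_ir)),
            class = "diversity_fit")
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat(sprintf("k-mer diversity ~ genome size (OLS over %d IR-bearing genomes):\n", x$n_points))
  cat(sprintf("  distinct_kmers = %.0f + %.3f * genome_size\n", x$intercept, x$slope))
  invisible(x)
}

#' @rdname diversity_regression
#' @param x A `diversity_fit`.
#' @param ... Unused.
#' @method tidy diversity_fit
#' @export
tidy.diversity_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "genome_size"),
         estimate = unname(s[, 1L]), std_error = unname(s[, 2L]),
         statistic = unname(s[, 3L]), p_value = unname(s[, 4L]))
}

#' @rdname diversity_regression
#' @method glance diversity_fit
#' @export
glance.diversity_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = s$r.squared, sigma = s$sigma, n_points = x$n_points)
}

#' @rdname diversity_regression
#' @method augment diversity_fit
#' @export
augment.diversity_fit <- function(x, ...) x$points
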