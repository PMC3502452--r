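#' Recruit the reads carrying any k-mer of a target set
#'
#' A read is selected iff at least one of its length-k windows (canonical
#' form, windows containing `N` skipped) belongs to `kmers`. Matching is
#' strand-insensitive because both the set and the windows are canonical.
#' Input order is preserved and no read is reported twice. With
#' `rescue_mates = TRUE` the mate of every selected read (same `pair_id`,
#' other `mate`) is added and flagged `mate_rescued` — off by default, since
#' recruitment by k-mer content alone is the conservative definition; mates
#' mostly improve contiguity.
#'
#' @param reads Reads tibble (`id`, `sequence`, optionally `quality`,
#'   `pair_id`, `mate`).
#' @param kmers Character vector of canonical k-mers, all of length `k`.
#' @param k Word size; defaults to the k-mer length in `kmers`.
#' @param rescue_mates Add mates of selected reads (needs `pair_id`/`mate`).
#' @return The selected subset of `reads` with a logical `mate_rescued`
#'   column; attribute `n_too_short` counts reads shorter than k (never
#'   selected).
#' @examples
#' reads <- tibble::tibble(id = c("r1", "r2", "r3"),
#'                         sequence = c("TTTTT", "TACGT", "CCGTA"))
#' select_reads(reads, "ACG", k = 3)
#' @export
select_reads <- function(reads, kmers, k = NULL, rescue_mates = FALSE) {
  kmers <- as.character(kmers)
  if (is.null(k)) {
    if (length(kmers) == 0L) abort("k must be given when the k-mer set is empty")
    k <- nchar(kmers[1L])
  }
  k <- check_odd_k(k)
  if (length(kmers) && any(nchar(kmers) != k)) abort("k-mers must all have length k")
  hit <- logical(nrow(reads))
  if (length(kmers) && nrow(reads)) {
    seqs <- toupper(reads$sequence)
    lens <- nchar(seqs)
    n_short <- sum(lens < k)
    undecided <- which(lens >= k)
    off <- 1L
    while (length(undecided) > 0L && off <= max(lens[undecided]) - k + 1L) {
      cand <- undecided[lens[undecided] >= off + k - 1L]
      w <- substr(seqs[cand], off, off + k - 1L)
      ok <- !stringi::stri_detect_fixed(w, "N")
      m <- logical(length(w))
      m[ok] <- canonicalize_safe(w[ok]) %in% kmers
      hit[cand[m]] <- TRUE
      undecided <- setdiff(undecided, cand[m]) # first hit wins
      off <- off + 1L
    }
  } else {
    n_short <- if (nrow(reads)) sum(nchar(reads$sequence) < k) else 0L
  }
  out <- reads[hit, , drop = FALSE]
  out$mate_rescued <- FALSE
  if (rescue_mates && nrow(out) && all(c("pair_id", "mate") %in% names(reads))) {
    mate_key <- paste(reads$pair_id, 3L - reads$mate)
    sel_key <- paste(out$pair_id, out$mate)
    add <- reads[mate_key %in% sel_key & !hit, , drop = FALSE]
    if (nrow(add)) {
      add$mate_rescued <- TRUE
      out <- bind_rows(out, add)
      out <- out[order(match(out$id, reads$id)), , drop = FALSE]
    }
  }
  if (n_short > 0L) {
    warn(sprintf("%d read(s) shorter than k = %d were never selected", n_short, k))
  }
  structure(as_tibble(out), n_too_short = n_short)
}

# canonicalize without re-validating (selection loops call this per offset
# on windows already screened for N)
canonicalize_safe <- function(w) {
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", w))
  ifelse(w <= rc, w, rc)
}
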