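# Internal helpers shared across modules.

# C-locale (radix) sort: the on-disk sortedness contract must not depend on
# the user's collation locale.
sort_c <- function(x) sort(x, method = "radix")

is_sorted_strict <- function(x) {
  if (length(x) < 2L) return(TRUE)
  identical(x, sort_c(x)) && !anyDuplicated(x)
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringi::stri_detect_regex(x, pat)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T%s} (first offender: %s)",
      what, if (allow_n) ",N" else "", x[which(bad)[1L]]
    ))
  }
  invisible(x)
}

#' Serialize a set of genome ids as a deterministic group key
#'
#' Group keys identify a subset of genomes; they are always the sorted
#' member ids joined by `"+"` so that the same set of genomes yields the
#' same key regardless of input order.
#'
#' @param members Character vector of genome ids (non-empty).
#' @return A single string, e.g. `"A+C"`.
#' @examples
#' group_key(c("C", "A"))
#' @export
group_key <- function(members) {
  if (length(members) < 1L) abort("a group key needs at least one member")
  paste(sort_c(unique(as.character(members))), collapse = "+")
}

#' Split a group key back into its member ids
#'
#' @param key A group key string as produced by [group_key()].
#' @return Character vector of member genome ids.
#' @export
group_members <- function(key) {
  stopifnot(length(key) == 1L)
  stringi::stri_split_fixed(key, "+")[[1]]
}

# Extract all length-k windows of each sequence as one character vector.
# Windows containing N are dropped. Returns character(0) if nothing fits.
kmer_windows <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character(0))
  out <- vector("list", max(nchar(seqs)) - k + 1L)
  lens <- nchar(seqs)
  for (off in seq_len(max(lens) - k + 1L)) {
    keep <- lens >= off + k - 1L
    out[[off]] <- substr(seqs[keep], off, off + k - 1L)
  }
  w <- unlist(out, use.names = FALSE)
  if (length(w)) w <- w[!stringi::stri_detect_fixed(w, "N")]
  w
}

new_seed <- function(seed, salt) {
  # derive a stream-specific seed below 2^31 from a user seed and a label
  (as.integer(seed) + sum(utf8ToInt(salt)) * 1009L) %% 2147483647L
}
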