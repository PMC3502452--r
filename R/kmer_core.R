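#' Reverse complement of DNA sequences
#'
#' Vectorized over sequences; `N` is its own complement. Applying it twice
#' returns the input.
#'
#' @param seq Character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return Character vector of the same lengths.
#' @examples
#' reverse_complement(c("ACGT", "AAC"))
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq, allow_n = TRUE)
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' Canonical form of k-mers
#'
#' A k-mer and its reverse complement are equated by keeping whichever of
#' the pair comes first alphabetically (A < C < G < T). All tables and sets
#' in the package store k-mers in canonical form, which makes every
#' comparison strand-insensitive. Only defined for odd k: an even-length
#' k-mer can equal its own reverse complement, making "first alphabetically"
#' ambiguous as a strand marker.
#'
#' @param kmer Character vector of equal-length DNA words with no `N`.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize("CGT") # revcomp ACG sorts first
#' @export
canonicalize <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  if (any(stringi::stri_detect_fixed(kmer, "N"))) {
    abort("cannot canonicalize a k-mer containing N; skip such windows")
  }
  assert_dna(kmer, allow_n = FALSE, what = "k-mer")
  len <- unique(nchar(kmer))
  if (length(len) != 1L) abort("k-mers must all have the same length")
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", kmer))
  # byte-wise comparison; for uppercase ACGT this is the alphabetical order
  # in every locale
  ifelse(kmer <= rc, kmer, rc)
}

check_odd_k <- function(k) {
  if (k < 3L || k %% 2L == 0L) {
    abort("k must be odd and >= 3: even k allows reverse-complement palindromic k-mers with no strict canonical form")
  }
  invisible(as.integer(k))
}

new_kmer_table <- function(entries, genome_id, k, threshold) {
  structure(
    entries,
    genome_id = genome_id, k = as.integer(k), threshold = as.integer(threshold),
    class = c("kmer_tbl", class(tibble()))
  )
}

#' Accessors for k-mer table metadata
#'
#' A k-mer table is a tibble with columns `kmer` and `count` plus the
#' attributes `genome_id`, `k` and `threshold`.
#'
#' @param table A k-mer table from [count_kmers()] or [read_kmer_table()].
#' @return The stored metadata value.
#' @export
kmer_k <- function(table) attr(table, "k")

#' @rdname kmer_k
#' @export
kmer_genome <- function(table) attr(table, "genome_id")

#' @rdname kmer_k
#' @export
kmer_threshold <- function(table) attr(table, "threshold")

#' Count canonical k-mers of one genome's sequences or reads
#'
#' Every length-k window (skipping windows that contain `N`) contributes one
#' occurrence to its canonical form, so the frequency of a k-mer is the sum
#' of its occurrences in both orientations. After counting, entries below
#' `threshold` are dropped: at ~20x coverage a threshold of three removes
#' most k-mers created by random sequencing error while keeping genuine
#' genomic k-mers, whose expected multiplicity is far higher.
#'
#' @param x A character vector of sequences, a reads/sequences tibble with a
#'   `sequence` column, or a genome model from [make_genome()].
#' @param k Odd word size (default 21).
#' @param threshold Minimum retained frequency (default 3). Use 1 to keep
#'   everything, e.g. when counting a finished genome sequence.
#' @param genome_id Identifier stored with the table.
#' @param circular If `TRUE`, the first k-1 bases of each sequence are
#'   appended before counting so windows spanning the origin of a circular
#'   molecule are included.
#' @return A sorted k-mer table (tibble: `kmer`, `count`) with attributes
#'   `genome_id`, `k`, `threshold`.
#' @examples
#' count_kmers("ACGTACGT", k = 3, threshold = 1, genome_id = "demo")
#' @export
count_kmers <- function(x, k = 21, threshold = 3, genome_id = "genome",
                        circular = FALSE) {
  k <- check_odd_k(k)
  threshold <- as.integer(threshold)
  stopifnot(threshold >= 0L)
  seqs <- as_sequences(x)
  assert_dna(seqs, allow_n = TRUE)
  n_short <- sum(nchar(seqs) < k)
  if (n_short > 0L) {
    warn(sprintf("%d sequence(s) shorter than k = %d contribute no k-mers", n_short, k))
  }
  if (circular) {
    long <- nchar(seqs) >= k
    seqs[long] <- paste0(seqs[long], substr(seqs[long], 1L, k - 1L))
  }
  w <- kmer_windows(seqs, k)
  if (length(w) == 0L) {
    return(new_kmer_table(tibble(kmer = character(0), count = integer(0)),
                          genome_id, k, threshold))
  }
  canon <- canonicalize(w)
  tab <- table_counts(canon)
  tab <- tab[tab$count >= threshold, , drop = FALSE]
  tab <- tab[order(tab$kmer, method = "radix"), ]
  new_kmer_table(as_tibble(tab), genome_id, k, threshold)
}

# fast exact counting of a character vector -> data.frame(kmer, count)
table_counts <- function(x) {
  ux <- unique(x)
  idx <- match(x, ux)
  data.frame(kmer = ux, count = tabulate(idx, nbins = length(ux)),
             stringsAsFactors = FALSE)
}

as_sequences <- function(x) {
  if (inherits(x, "genome_model")) return(x$sequence)
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x)) abort("data frame input needs a 'sequence' column")
    return(toupper(x$sequence))
  }
  if (is.character(x)) return(toupper(x))
  abort("cannot interpret input as DNA sequences")
}

#' Number of distinct k-mers in a table
#'
#' The table's key count — the "k-mer diversity" of a genome. For a
#' repeat-free linear sequence of length G this equals G - k + 1; sequence
#' duplicated in inverted repeats adds (almost) no new canonical k-mers, so
#' diversity measures the single-copy fraction of a genome.
#'
#' @inheritParams kmer_k
#' @return Integer count of distinct canonical k-mers.
#' @export
distinct_kmer_count <- function(table) nrow(table)

#' One-row summary of a k-mer frequency spectrum
#'
#' Mean and maximum frequency and their ratio. A large max/mean ratio
#' signals proliferation of short repeats (on the scale of k); large
#' duplications instead inflate genome size without super-abundant k-mers.
#'
#' @inheritParams kmer_k
#' @return Tibble with `mean_count`, `max_count`, `max_mean_ratio`.
#' @export
frequency_spectrum_summary <- function(table) {
  if (nrow(table) == 0L) abort("empty k-mer table has no frequency spectrum")
  m <- mean(table$count)
  mx <- max(table$count)
  tibble(mean_count = m, max_count = mx, max_mean_ratio = mx / m)
}
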