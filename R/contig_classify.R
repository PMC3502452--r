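#' Classify contigs into single-feature, long, and other
#'
#' Two biologically meaningful classes: "single_feature" contigs are about
#' twice the read length — the footprint of one isolated variant after
#' low-coverage end trimming (~90-110 bp with 51 bp reads) — and "long"
#' contigs are the longest `long_fraction` (default 5%) of contigs within
#' each taxonomic class, flagging local hot-spots of variation where
#' individual variant footprints merged. "long" takes precedence (with one
#' contig in a class, `ceiling(0.05 * 1) = 1` makes it long); remaining
#' contigs at most `2 * read_length + single_feature_slack` bases are
#' "single_feature"; the rest are "other".
#'
#' @param contigs Contig tibble ([assemble()]).
#' @param read_length Read length of the underlying data, in bases.
#' @param class_of_genome Optional named character vector mapping
#'   `genome_id` to a taxonomic class; unmapped genomes (or `NULL`) fall in
#'   one class `"all"`.
#' @param long_fraction Fraction of contigs labelled long per class.
#' @param single_feature_slack Bases over `2 * read_length` still accepted
#'   as a single feature (default 10).
#' @return `contigs` with added `class` and `label` columns; attribute
#'   `cutoffs` holds a tibble of per-class long-length cutoffs.
#' @export
classify_contigs <- function(contigs, read_length, class_of_genome = NULL,
                             long_fraction = 0.05, single_feature_slack = 10) {
  if (nrow(contigs) == 0L) {
    out <- contigs
    out$class <- character(0)
    out$label <- character(0)
    attr(out, "cutoffs") <- tibble(class = character(0), n = integer(0),
                                   n_long = integer(0), long_cutoff = integer(0))
    return(out)
  }
  cls <- if (is.null(class_of_genome)) rep("all", nrow(contigs)) else {
    unname(class_of_genome[contigs$genome_id])
  }
  if (anyNA(cls)) abort("every contig's genome needs a class label")
  contigs$class <- cls
  contigs$label <- "other"
  cutoffs <- list()
  for (cl in sort_c(unique(cls))) {
    idx <- which(cls == cl)
    n_long <- ceiling(long_fraction * length(idx))
    o <- idx[order(-contigs$length[idx], contigs$sequence[idx], method = "radix")]
    long_idx <- o[seq_len(n_long)]
    contigs$label[long_idx] <- "long"
    cutoffs[[cl]] <- tibble(class = cl, n = length(idx), n_long = n_long,
                            long_cutoff = min(contigs$length[long_idx]))
  }
  sf <- contigs$label != "long" &
    contigs$length <= 2L * read_length + single_feature_slack
  contigs$label[sf] <- "single_feature"
  attr(contigs, "cutoffs") <- bind_rows(cutoffs)
  contigs
}

#' Validate contigs against their true source genome
#'
#' For each contig, reports whether it occurs verbatim in the reference (on
#' either strand) and its best local-alignment percent identity (matches /
#' alignment columns, both strands tried). With simulated data the source
#' genome is known exactly, so this measures assembly accuracy directly.
#'
#' @param contigs Contig tibble ([assemble()]).
#' @param reference The source genome: a [make_genome()] object, a
#'   single sequence string, or a one-row tibble with a `sequence` column.
#' @param circular Treat the reference as a circular molecule: the first
#'   bases are appended before matching, so contigs spanning the origin
#'   validate correctly. Defaults to the genome model's own flag.
#' @return Tibble `contig_id`, `length`, `identity` (percent), `exact`.
#' @seealso [summarize_validation()]
#' @export
validate_contigs <- function(contigs, reference, circular = NULL) {
  refseq <- as_sequences(reference)
  stopifnot(length(refseq) == 1L)
  if (is.null(circular)) {
    circular <- if (inherits(reference, "genome_model")) reference$circular else FALSE
  }
  if (circular && nrow(contigs) > 0L) {
    pad <- min(nchar(refseq), max(nchar(contigs$sequence)) - 1L)
    if (pad > 0L) refseq <- paste0(refseq, substr(refseq, 1L, pad))
  }
  rc_ref <- reverse_complement(refseq)
  if (nrow(contigs) == 0L) {
    return(tibble(contig_id = character(0), length = integer(0),
                  identity = numeric(0), exact = logical(0)))
  }
  exact <- stringi::stri_detect_fixed(refseq, contigs$sequence) |
    stringi::stri_detect_fixed(rc_ref, contigs$sequence)
  identity <- rep(100, nrow(contigs))
  todo <- which(!exact)
  if (length(todo)) {
    subj_f <- Biostrings::DNAString(refseq)
    subj_r <- Biostrings::DNAString(rc_ref)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
    for (i in todo) {
      pat <- Biostrings::DNAString(contigs$sequence[i])
      best <- NULL
      for (subj in list(subj_f, subj_r)) {
        aln <- Biostrings::pairwiseAlignment(pat, subj, type = "local",
                                             substitutionMatrix = mat,
                                             gapOpening = 4, gapExtension = 2)
        if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) best <- aln
      }
      identity[i] <- 100 * Biostrings::nmatch(best) / Biostrings::nchar(best)
    }
  }
  tibble(contig_id = contigs$contig_id, length = contigs$length,
         identity = identity, exact = exact)
}

#' Aggregate a contig validation report
#'
#' @param report Output of [validate_contigs()] (reports for several
#'   genomes may be row-bound first).
#' @return One-row tibble: `n_contigs`, `fraction_exact`, `min_identity`,
#'   `mean_identity`.
#' @export
summarize_validation <- function(report) {
  if (nrow(report) == 0L) {
    return(tibble(n_contigs = 0L, fraction_exact = NA_real_,
                  min_identity = NA_real_, mean_identity = NA_real_))
  }
  tibble(n_contigs = nrow(report),
         fraction_exact = mean(report$exact),
         min_identity = min(report$identity),
         mean_identity = mean(report$identity))
}
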