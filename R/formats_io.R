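#' Read a FASTA file into a tibble
#'
#' Sequences are upper-cased; the id is the header token before the first
#' whitespace, the remainder is kept in `description`. Ambiguity codes other
#' than `N` are rejected — the k-mer alphabet is \{A,C,G,T\} and `N` windows
#' are skipped downstream.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return Tibble with columns `id`, `description`, `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(tibble(id = character(0), description = character(0), sequence = character(0)))
  }
  if (!startsWith(lines[nonempty[1L]], ">")) {
    abort(sprintf("malformed FASTA header at line %d: expected '>'", nonempty[1L]))
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    abort(sprintf("record '%s' has an empty sequence", ids[empty[1L]]))
  }
  assert_dna(seqs, allow_n = TRUE)
  tibble(id = unname(ids), description = unname(desc), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `id` and `sequence` (optional `description`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  hdr <- x$id
  if ("description" %in% names(x)) {
    hdr <- ifelse(nzchar(x$description), paste(hdr, x$description), hdr)
  }
  s <- Biostrings::BStringSet(setNames(x$sequence, hdr))
  Biostrings::writeXStringSet(s, path, format = "fasta", width = width)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Plain 4-line-per-record FASTQ with Sanger-offset qualities. Reading and
#' writing round-trip `(id, sequence, quality)` exactly.
#'
#' @param path File path.
#' @return `read_fastq()`: tibble with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  n <- length(lines)
  if (n == 0L) return(tibble(id = character(0), sequence = character(0), quality = character(0)))
  if (n %% 4L != 0L) abort("truncated FASTQ: line count is not a multiple of 4")
  at <- lines[seq(1L, n, by = 4L)]
  sq <- toupper(lines[seq(2L, n, by = 4L)])
  plus <- lines[seq(3L, n, by = 4L)]
  qu <- lines[seq(4L, n, by = 4L)]
  if (!all(startsWith(at, "@"))) {
    bad <- which(!startsWith(at, "@"))[1L]
    abort(sprintf("malformed FASTQ header at line %d", (bad - 1L) * 4L + 1L))
  }
  if (!all(startsWith(plus, "+"))) abort("malformed FASTQ: missing '+' separator line")
  ids <- sub("\\s.*$", "", substring(at, 2L))
  mism <- which(nchar(sq) != nchar(qu))
  if (length(mism)) {
    abort(sprintf("record '%s': quality length differs from sequence length", ids[mism[1L]]))
  }
  assert_dna(sq, allow_n = TRUE)
  tibble(id = ids, sequence = sq, quality = qu)
}

#' @rdname read_fastq
#' @param x Tibble with `id`, `sequence` and optionally `quality` (a
#'   constant high quality is filled in when absent).
#' @return `write_fastq()`: `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- x$quality
  if (is.null(qual)) qual <- strrep("I", nchar(x$sequence))
  bad <- which(nchar(qual) != nchar(x$sequence))
  if (length(bad)) {
    abort(sprintf("record '%s': quality length differs from sequence length", x$id[bad[1L]]))
  }
  out <- character(4L * nrow(x))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", x$id)
  out[seq(2L, length(out), by = 4L)] <- x$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read / write k-mer frequency tables
#'
#' The on-disk format is a diffable TSV: one comment header
#' `#<genome_id>\tk=<k>\tthreshold=<t>` followed by `kmer<TAB>count` lines in
#' strict ascending alphabetical order. Sortedness is a format guarantee —
#' it is what allows shared tables to be built by single-pass merging — so
#' reading an out-of-order file is an error, not a silent re-sort.
#'
#' @param table A k-mer table ([count_kmers()]).
#' @param path File path.
#' @return `read_kmer_table()`: the k-mer table; `write_kmer_table()`:
#'   `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\tk=%d\tthreshold=%d",
                     kmer_genome(table), kmer_k(table), kmer_threshold(table)), con)
  if (nrow(table)) {
    writeLines(paste0(table$kmer, "\t", table$count), con)
  }
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#")) {
    abort("k-mer table must start with a '#' header line")
  }
  hdr <- stringi::stri_split_fixed(sub("^#", "", lines[1L]), "\t")[[1]]
  if (length(hdr) != 3L || !grepl("^k=\\d+$", hdr[2L]) || !grepl("^threshold=\\d+$", hdr[3L])) {
    abort("malformed k-mer table header; expected '#genome\\tk=K\\tthreshold=T'")
  }
  genome_id <- hdr[1L]
  k <- as.integer(sub("k=", "", hdr[2L]))
  threshold <- as.integer(sub("threshold=", "", hdr[3L]))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(new_kmer_table(tibble(kmer = character(0), count = integer(0)),
                          genome_id, k, threshold))
  }
  parts <- stringi::stri_split_fixed(body, "\t", simplify = TRUE)
  if (ncol(parts) != 2L) abort("malformed k-mer table line: expected kmer<TAB>count")
  kmers <- parts[, 1L]
  counts <- as.integer(parts[, 2L])
  if (!is_sorted_strict(kmers)) abort("table not sorted: k-mers must be unique and in ascending order")
  if (any(nchar(kmers) != k)) abort(sprintf("k-mer length differs from header k = %d", k))
  if (any(counts < threshold)) abort("count below the table's threshold")
  new_kmer_table(tibble(kmer = kmers, count = counts), genome_id, k, threshold)
}

#' Read a taxonomy table
#'
#' TSV with two columns: genome id and its lineage as semicolon-joined taxon
#' names ordered root to tip. All genomes are expected to share the root
#' taxon; duplicate genome ids are an error.
#'
#' @param path File path.
#' @return Tibble with `genome_id` and list-column `lineage`.
#' @export
read_taxonomy <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#",
                    col.names = c("genome_id", "lineage"))
  as_taxonomy(tibble(genome_id = as.character(raw$genome_id),
                     lineage = stringi::stri_split_fixed(as.character(raw$lineage), ";")))
}

as_taxonomy <- function(tbl) {
  if (anyDuplicated(tbl$genome_id)) {
    abort(sprintf("duplicate genome_id in taxonomy: '%s'",
                  tbl$genome_id[duplicated(tbl$genome_id)][1L]))
  }
  tbl$lineage <- map(tbl$lineage, ~ trimws(.x))
  if (any(lengths(tbl$lineage) == 0L) || any(map_chr(tbl$lineage, 1) == "")) {
    abort("every lineage must be non-empty")
  }
  roots <- unique(map_chr(tbl$lineage, 1))
  if (length(roots) > 1L) {
    abort(sprintf("all lineages must share one root taxon (found: %s)",
                  paste(roots, collapse = ", ")))
  }
  tbl
}

#' @rdname read_taxonomy
#' @param x Tibble with `genome_id` and `lineage` (list of character vectors
#'   or semicolon-joined strings).
#' @param path Output path.
#' @export
write_taxonomy <- function(x, path) {
  lin <- if (is.list(x$lineage)) map_chr(x$lineage, paste, collapse = ";") else x$lineage
  write.table(data.frame(x$genome_id, lin), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
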