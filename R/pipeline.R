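#' Assemble a pipeline configuration
#'
#' Bundles and validates every knob of the end-to-end run. Either supply
#' per-genome reads (named list of read tibbles, FASTQ paths work through
#' [read_fastq()]) or genome models/sequences from which reads are
#' simulated. All randomness flows from `seed`, so a config runs to
#' byte-identical outputs every time.
#'
#' @param genomes Named list of `genome_model`s or sequence strings (truth;
#'   enables simulation and contig validation).
#' @param reads Named list of read tibbles, one per genome id; simulated
#'   from `genomes` when omitted.
#' @param k,threshold Counting word size (odd) and frequency threshold.
#' @param groups Group-selection policy: `"observed"` (every exclusive
#'   membership with at least `min_group_kmers` k-mers), `"congruent"`
#'   (taxonomically congruent groups from `taxonomy`), `"none"`, or an
#'   explicit character vector of `"+"`-joined group keys.
#' @param taxonomy Taxonomy tibble (required for `groups = "congruent"`).
#' @param mode Group k-mer semantics, `"exclusive"` or `"inclusive"`.
#' @param min_group_kmers Minimum shared k-mers for an observed group.
#' @param exclude_universal Drop the group containing every genome in
#'   observed mode: its k-mers are the unpartitioned conserved backbone and
#'   recruiting them amounts to whole-genome assembly, outside the
#'   localized scope.
#' @param read_len,coverage,error_rate,paired,insert_mean,insert_sd Read
#'   simulation settings (see [simulate_reads()]).
#' @param k_asm,min_node_coverage,min_contig_length Assembly settings (see
#'   [assemble()]); `k_asm` defaults to [choose_assembly_k()] — the largest
#'   odd word size (at most `k`) whose expected error-free k-mer coverage
#'   under the configured read length, fold coverage and error rate is at
#'   least 8, so unitigs are not broken by random coverage dropouts. With
#'   error-free data this is simply `k`.
#' @param rescue_mates Recruit mates of selected reads ([select_reads()]).
#' @param polish Consensus-polish contigs against the genome's full read
#'   set ([polish_contigs()]); a no-op on error-free data.
#' @param validate Align contigs back to their source genome when the truth
#'   is available ([validate_contigs()]).
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when set, tables, contig FASTA and a
#'   manifest are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes = NULL, reads = NULL, k = 21, threshold = 3,
                            groups = "observed", taxonomy = NULL,
                            mode = c("exclusive", "inclusive"),
                            min_group_kmers = 100, exclude_universal = TRUE,
                            read_len = 51, coverage = 20, error_rate = 0.05,
                            paired = TRUE, insert_mean = 300, insert_sd = 30,
                            k_asm = NULL, min_node_coverage = 2,
                            min_contig_length = 80, rescue_mates = FALSE,
                            polish = TRUE, validate = TRUE, seed = 1,
                            out_dir = NULL) {
  check_odd_k(k)
  mode <- match.arg(mode)
  if (is.null(genomes) && is.null(reads)) abort("supply genomes and/or reads")
  if (is.null(reads) && is.null(names(genomes))) abort("genomes must be named")
  if (!is.null(reads) && is.null(names(reads))) abort("reads must be named")
  if (identical(groups, "congruent") && is.null(taxonomy)) {
    abort("groups = 'congruent' needs a taxonomy")
  }
  structure(list(
    genomes = genomes, reads = reads, k = as.integer(k),
    threshold = as.integer(threshold), groups = groups, taxonomy = taxonomy,
    mode = mode, min_group_kmers = min_group_kmers,
    exclude_universal = exclude_universal, read_len = as.integer(read_len),
    coverage = coverage, error_rate = error_rate, paired = paired,
    insert_mean = insert_mean, insert_sd = insert_sd,
    k_asm = as.integer(k_asm %||% choose_assembly_k(k, read_len, coverage, error_rate)),
    min_node_coverage = min_node_coverage,
    min_contig_length = min_contig_length, rescue_mates = rescue_mates,
    polish = polish, validate = validate, seed = as.integer(seed),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the reference-free pipeline end to end
#'
#' Executes count -> tip/shared partition -> group extraction -> read
#' recruitment -> localized assembly (-> validation against the truth when
#' available), collecting per-stage counts and a manifest. Deterministic:
#' rerunning the same config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `tables` (per-genome k-mer tables),
#'   `partition`, `group_keys`, `contigs` (all tip and group contigs, one
#'   tibble), `validation` (per-contig identity report or NULL), `log`
#'   (stage counts), `manifest`, and the `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  log <- list()
  note <- function(stage, item, n) log[[length(log) + 1L]] <<- tibble(stage = stage, item = item, n = n)

  genome_seqs <- if (!is.null(cfg$genomes)) map(cfg$genomes, as_sequences) else NULL
  genome_ids <- names(cfg$reads %||% cfg$genomes)

  reads <- cfg$reads
  if (is.null(reads)) {
    reads <- imap(cfg$genomes, function(g, id) {
      simulate_reads(g, read_len = cfg$read_len, coverage = cfg$coverage,
                     error_rate = cfg$error_rate, paired = cfg$paired,
                     insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd,
                     genome_id = id, seed = new_seed(cfg$seed, paste0("reads:", id)))
    })
  }
  for (id in genome_ids) note("simulate/input", id, nrow(reads[[id]]))

  tables <- imap(reads, function(r, id) {
    count_kmers(r, k = cfg$k, threshold = cfg$threshold, genome_id = id)
  })
  for (id in genome_ids) note("count", id, nrow(tables[[id]]))

  partition <- build_tip_and_shared(unname(tables))
  note("filter", "tip_kmers", nrow(partition$tips))
  note("filter", "shared_kmers", nrow(partition$shared))

  group_keys <- pipeline_group_keys(cfg, partition, genome_ids)
  note("group", "groups", length(group_keys))

  # canonical windows of each genome's reads are reused across every target
  # k-mer set, so recruitment scans each read set once
  windex <- map(reads, ~ window_index(.x$sequence, cfg$k))

  contigs <- list()
  for (id in genome_ids) {
    tip_set <- partition$tips$kmer[partition$tips$genome_id == id]
    sel <- reads[[id]][recruit(windex[[id]], tip_set), , drop = FALSE]
    note("select", paste0("tip:", id), nrow(sel))
    ctg <- assemble(sel, k_asm = cfg$k_asm,
                    min_node_coverage = cfg$min_node_coverage,
                    min_contig_length = cfg$min_contig_length,
                    genome_id = id, group_key = id)
    ctg$kind <- "tip"
    contigs[[paste0("tip:", id)]] <- ctg
  }
  for (key in group_keys) {
    kms <- extract_group(partition$shared, unname(tables), key, mode = cfg$mode)
    for (id in group_members(key)) {
      sel <- reads[[id]][recruit(windex[[id]], kms), , drop = FALSE]
      ctg <- assemble(sel, k_asm = cfg$k_asm,
                      min_node_coverage = cfg$min_node_coverage,
                      min_contig_length = cfg$min_contig_length,
                      genome_id = id, group_key = key)
      ctg$kind <- "group"
      contigs[[paste0(key, ":", id)]] <- ctg
    }
  }
  contigs <- bind_rows(contigs)
  note("assemble", "contigs", nrow(contigs))

  if (cfg$polish && nrow(contigs)) {
    n_pol <- 0L
    for (id in genome_ids) {
      idx <- which(contigs$genome_id == id)
      if (length(idx) == 0L) next
      # anchor at the assembly word size: with errors, short words give
      # far more reads a clean anchor, so true bases out-vote recurrent
      # miscalls at contested columns
      wx <- if (cfg$k_asm == cfg$k) windex[[id]] else
        window_index(toupper(reads[[id]]$sequence), cfg$k_asm)
      pol <- polish_with_index(contigs[idx, , drop = FALSE],
                               toupper(reads[[id]]$sequence),
                               wx, cfg$k_asm,
                               trim_depth = max(3, ceiling(cfg$coverage / 3)))
      contigs$sequence[idx] <- pol$sequence
      n_pol <- n_pol + (attr(pol, "polished_bases") %||% 0L)
    }
    contigs$length <- nchar(contigs$sequence)
    contigs <- contigs[contigs$length >= cfg$min_contig_length, , drop = FALSE]
    note("polish", "bases_corrected", n_pol)
    note("polish", "contigs_kept", nrow(contigs))
  }

  validation <- NULL
  if (cfg$validate && !is.null(genome_seqs) && nrow(contigs)) {
    validation <- bind_rows(map(genome_ids, function(id) {
      sub <- contigs[contigs$genome_id == id, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      rep <- validate_contigs(sub, cfg$genomes[[id]])
      rep$genome_id <- id
      rep$kind <- sub$kind
      rep
    }))
    note("validate", "aligned_contigs", nrow(validation))
  }

  result <- structure(list(
    config = cfg, tables = tables, partition = partition,
    group_keys = group_keys, contigs = contigs, validation = validation,
    log = bind_rows(log)
  ), class = "pipeline_result")
  result$manifest <- write_pipeline_outputs(result, cfg$out_dir)
  result
}

#' Pick an assembly word size from the sequencing conditions
#'
#' A de Bruijn node only enters the graph if sampled without error at least
#' `min_node_coverage` times. The expected error-free k-mer coverage is
#' `coverage * (read_len - k + 1) / read_len * (1 - error_rate)^k`, and
#' treating per-node sampling as Poisson, the word size must keep the
#' dropout probability `P(X < min_node_coverage)` at or below
#' `max_dropout`, or unitigs break at random coverage holes. Larger words
#' are otherwise better (fewer chance (k-1)-mer collisions between
#' unrelated loci in a pooled read subset), so this returns the largest
#' odd `k_asm <= k_max` meeting the dropout bound, never below 11. With
#' error-free reads at 20x this returns `k_max` unchanged; at a 5% error
#' rate with 51 bp reads it steps down to 15.
#'
#' @param k_max Upper bound (the pipeline counting k).
#' @param read_len,coverage,error_rate Sequencing conditions.
#' @param min_node_coverage Assembly coverage floor (see [assemble()]).
#' @param max_dropout Tolerated per-node dropout probability (default 1%,
#'   about one unitig break per hundred graph nodes).
#' @return An odd integer word size.
#' @export
choose_assembly_k <- function(k_max, read_len, coverage, error_rate,
                              min_node_coverage = 2, max_dropout = 0.01) {
  eff <- function(k) coverage * (read_len - k + 1) / read_len * (1 - error_rate)^k
  for (k in rev(seq(11L, check_odd_k(k_max), by = 2L))) {
    if (stats::ppois(min_node_coverage - 1, eff(k)) <= max_dropout) return(k)
  }
  11L
}

pipeline_group_keys <- function(cfg, partition, genome_ids) {
  if (identical(cfg$groups, "none")) return(character(0))
  if (identical(cfg$groups, "congruent")) {
    cg <- enumerate_congruent_groups(cfg$taxonomy, sampled = genome_ids)
    return(cg$group_key)
  }
  if (identical(cfg$groups, "observed")) {
    gc <- group_sharing_counts(partition$shared)
    gc <- gc[gc$n_kmers >= cfg$min_group_kmers, , drop = FALSE]
    if (cfg$exclude_universal) {
      gc <- gc[gc$n_members < length(genome_ids), , drop = FALSE]
    }
    return(sort_c(gc$group_key))
  }
  keys <- map_chr(cfg$groups, ~ group_key(group_members(.x)))
  unknown <- setdiff(unlist(map(keys, group_members)), genome_ids)
  if (length(unknown)) abort(sprintf("group lists unknown genome: %s", unknown[1L]))
  sort_c(keys)
}

# one-off canonical window index of a read set: read number, window start
# (1-based), canonical word, and whether the window was already canonical
# ("forward") in the read
window_index <- function(seqs, k) {
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  per_off <- list()
  max_off <- max(c(0L, lens - k + 1L))
  for (off in seq_len(max_off)) {
    idx <- which(lens >= off + k - 1L)
    w <- substr(seqs[idx], off, off + k - 1L)
    ok <- !stringi::stri_detect_fixed(w, "N")
    w <- w[ok]
    canon <- canonicalize_safe(w)
    per_off[[off]] <- list(read = idx[ok], pos = rep.int(off, sum(ok)),
                           canon = canon, fwd = w == canon)
  }
  list(read = unlist(map(per_off, "read"), use.names = FALSE),
       pos = unlist(map(per_off, "pos"), use.names = FALSE),
       canon = unlist(map(per_off, "canon"), use.names = FALSE),
       fwd = unlist(map(per_off, "fwd"), use.names = FALSE),
       n_reads = length(seqs))
}

recruit <- function(windex, kmer_set) {
  if (length(kmer_set) == 0L) return(logical(windex$n_reads))
  hit <- logical(windex$n_reads)
  hit[unique(windex$read[windex$canon %in% kmer_set])] <- TRUE
  hit
}

write_pipeline_outputs <- function(result, out_dir) {
  cfg <- result$config
  rows <- list(tibble(artifact = "contigs", n = nrow(result$contigs),
                      path = NA_character_, md5 = NA_character_))
  if (is.null(out_dir)) {
    man <- bind_rows(rows)
    return(man)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(artifact, n, path) {
    rows[[length(rows) + 1L]] <<- tibble(
      artifact = artifact, n = n, path = path,
      md5 = unname(tools::md5sum(path)))
  }
  for (id in names(result$tables)) {
    p <- file.path(out_dir, paste0(id, ".k", cfg$k, ".tsv"))
    write_kmer_table(result$tables[[id]], p)
    add(paste0("kmer_table:", id), nrow(result$tables[[id]]), p)
  }
  if (nrow(result$contigs)) {
    p <- file.path(out_dir, "contigs.fasta")
    write_fasta(tibble(id = result$contigs$contig_id,
                       sequence = result$contigs$sequence), p)
    add("contigs", nrow(result$contigs), p)
  }
  if (!is.null(result$validation)) {
    p <- file.path(out_dir, "validation.tsv")
    write.table(result$validation, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add("validation", nrow(result$validation), p)
  }
  p <- file.path(out_dir, "run_log.tsv")
  write.table(result$log, p, sep = "\t", quote = FALSE, row.names = FALSE)
  add("log", nrow(result$log), p)
  man <- bind_rows(rows)
  mp <- file.path(out_dir, "manifest.tsv")
  hdr <- sprintf("# k=%d threshold=%d k_asm=%d seed=%d", cfg$k, cfg$threshold,
                 cfg$k_asm, cfg$seed)
  writeLines(c(hdr, paste(names(man), collapse = "\t"),
               do.call(paste, c(man, sep = "\t"))), mp)
  man
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("reference-free pipeline run\n")
  cat(sprintf("  genomes: %d; k = %d, threshold = %d, seed = %d\n",
              length(x$tables), x$config$k, x$config$threshold, x$config$seed))
  cat(sprintf("  tip k-mers: %d; shared k-mers: %d; groups assembled: %d\n",
              nrow(x$partition$tips), nrow(x$partition$shared), length(x$group_keys)))
  cat(sprintf("  contigs: %d", nrow(x$contigs)))
  if (!is.null(x$validation)) {
    s <- summarize_validation(x$validation)
    cat(sprintf(" (%.1f%% exact, min identity %.1f%%)",
                100 * s$fraction_exact, s$min_identity))
  }
  cat("\n")
  invisible(x)
}
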