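#' Partition k-mers into per-genome tip sets and a shared membership table
#'
#' A k-mer observed in exactly one genome's table is a "tip" k-mer of that
#' genome — variation unique to it. A k-mer observed in two or more genomes
#' goes to the shared table together with its exact membership (the set of
#' genomes containing it). Tip sets and shared keys partition the union of
#' all input tables' k-mers.
#'
#' @param tables List of k-mer tables ([count_kmers()]), one per genome,
#'   all with the same k and distinct genome ids.
#' @return List with elements
#'   * `tips`: tibble `genome_id`, `kmer`, `count` (the count in that genome),
#'   * `shared`: tibble `kmer`, `group_key`, `n_members`, sorted by k-mer,
#'   and attribute `k`.
#' @examples
#' a <- count_kmers("AAACGTACGTC", k = 3, threshold = 1, genome_id = "A")
#' b <- count_kmers("TTACGTACGTC", k = 3, threshold = 1, genome_id = "B")
#' build_tip_and_shared(list(a, b))
#' @export
build_tip_and_shared <- function(tables) {
  if (length(tables) < 2L) abort("need at least two genome tables")
  ks <- map_int(tables, kmer_k)
  if (length(unique(ks)) != 1L) abort("all tables must share the same k")
  ids <- map_chr(tables, kmer_genome)
  if (anyDuplicated(ids)) abort("duplicate genome_id across tables")
  long <- bind_rows(map(tables, ~ tibble(genome_id = kmer_genome(.x),
                                         kmer = .x$kmer, count = .x$count)))
  long <- long[order(long$kmer, long$genome_id, method = "radix"), ]
  occ <- tabulate(match(long$kmer, unique(long$kmer)))
  n_members <- rep.int(occ, occ)
  tips <- long[n_members == 1L, ]
  sh <- long[n_members > 1L, ]
  if (nrow(sh)) {
    shared <- sh |>
      group_by(.data$kmer) |>
      summarise(group_key = paste(.data$genome_id, collapse = "+"),
                n_members = dplyr::n(), .groups = "drop") |>
      arrange(.data$kmer)
  } else {
    shared <- tibble(kmer = character(0), group_key = character(0), n_members = integer(0))
  }
  structure(list(tips = as_tibble(tips), shared = shared),
            k = unname(ks[1L]), class = "kmer_partition")
}

#' @export
print.kmer_partition <- function(x, ...) {
  cat(sprintf("k-mer partition (k = %d): %d tip k-mers across %d genomes; %d shared k-mers in %d groups\n",
              attr(x, "k"), nrow(x$tips), length(unique(x$tips$genome_id)),
              nrow(x$shared), length(unique(x$shared$group_key))))
  invisible(x)
}

#' Extract the k-mer set of one group of genomes
#'
#' Two intersection semantics are supported. `"exclusive"` returns k-mers
#' whose membership is exactly the group: present in every member and
#' absent from all other genomes. `"inclusive"` returns k-mers present in
#' every member regardless of the other genomes — the plain intersection of
#' the member tables, which assumes no knowledge about non-members.
#' Exclusive sets partition the shared table; inclusive sets are antitone
#' (a larger group has a smaller inclusive set) and `exclusive(G)` is
#' always a subset of `inclusive(G)`.
#'
#' @param shared The `shared` tibble from [build_tip_and_shared()] (used in
#'   exclusive mode).
#' @param tables The original per-genome k-mer tables (used in inclusive
#'   mode; pass the same list given to [build_tip_and_shared()]).
#' @param group Character vector of member genome ids, or a `"+"`-joined
#'   group key; at least two members.
#' @param mode `"exclusive"` or `"inclusive"`.
#' @return Sorted character vector of canonical k-mers.
#' @export
extract_group <- function(shared, tables, group, mode = c("exclusive", "inclusive")) {
  mode <- match.arg(mode)
  if (length(group) == 1L && grepl("+", group, fixed = TRUE)) group <- group_members(group)
  group <- unique(as.character(group))
  ids <- map_chr(tables, kmer_genome)
  unknown <- setdiff(group, ids)
  if (length(unknown)) abort(sprintf("unknown genome in group: %s", unknown[1L]))
  if (length(group) < 2L) abort("a group needs at least two members")
  if (mode == "exclusive") {
    key <- group_key(group)
    sort_c(shared$kmer[shared$group_key == key])
  } else {
    sets <- map(tables[match(group, ids)], ~ .x$kmer)
    sort_c(Reduce(intersect, sets))
  }
}

#' Tally how many k-mers each observed group shares
#'
#' Counts the shared table's k-mers by exact membership. Filtering the
#' result (e.g. groups sharing at least 1000 k-mers) separates signal from
#' the homoplasy noise of k-mers shared by arbitrary genome subsets.
#'
#' @param shared The `shared` tibble from [build_tip_and_shared()].
#' @return Tibble `group_key`, `n_members`, `n_kmers`, sorted by decreasing
#'   `n_kmers` then key.
#' @export
group_sharing_counts <- function(shared) {
  if (nrow(shared) == 0L) {
    return(tibble(group_key = character(0), n_members = integer(0), n_kmers = integer(0)))
  }
  shared |>
    group_by(.data$group_key, .data$n_members) |>
    summarise(n_kmers = dplyr::n(), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_kmers), .data$group_key)
}

#' Enumerate taxonomically congruent groups
#'
#' A congruent group is the set of sampled genomes descending from one
#' taxonomy node: for every taxon name occurring in any lineage, take the
#' sampled genomes whose lineage contains it, keep sets with at least two
#' members, and deduplicate identical sets (nested taxa with the same
#' sampled leaves collapse to one group). The root taxon yields the group
#' of all sampled genomes.
#'
#' @param taxonomy Taxonomy tibble ([read_taxonomy()]).
#' @param sampled Genome ids to restrict to (default: all in the taxonomy).
#' @return Tibble `group_key`, `n_members`, `taxa` (the taxon names mapping
#'   to that leaf set, `;`-joined), sorted by key.
#' @export
enumerate_congruent_groups <- function(taxonomy, sampled = taxonomy$genome_id) {
  unknown <- setdiff(sampled, taxonomy$genome_id)
  if (length(unknown)) abort(sprintf("sampled genome not in taxonomy: %s", unknown[1L]))
  tx <- taxonomy[taxonomy$genome_id %in% sampled, ]
  if (nrow(tx) == 0L) {
    return(tibble(group_key = character(0), n_members = integer(0), taxa = character(0)))
  }
  long <- tibble(
    genome_id = rep.int(tx$genome_id, lengths(tx$lineage)),
    taxon = unlist(tx$lineage, use.names = FALSE)
  ) |> distinct()
  per_taxon <- long |>
    group_by(.data$taxon) |>
    summarise(group_key = group_key(.data$genome_id),
              n_members = length(unique(.data$genome_id)), .groups = "drop") |>
    filter(.data$n_members >= 2L)
  per_taxon |>
    group_by(.data$group_key, .data$n_members) |>
    summarise(taxa = paste(sort_c(.data$taxon), collapse = ";"), .groups = "drop") |>
    arrange(.data$group_key)
}

#' Check the tip/shared partition law
#'
#' For every genome g, its tip k-mers plus the shared k-mers whose
#' membership contains g must equal the keys of g's table, with no overlap.
#' Used as an internal consistency check; returns `TRUE` or aborts.
#'
#' @param partition Result of [build_tip_and_shared()].
#' @param tables The input tables.
#' @return `TRUE` invisibly if the law holds.
#' @export
check_partition_law <- function(partition, tables) {
  for (tb in tables) {
    g <- kmer_genome(tb)
    tip_g <- partition$tips$kmer[partition$tips$genome_id == g]
    in_shared <- map_chr(stringi::stri_split_fixed(partition$shared$group_key, "+"),
                         ~ if (g %in% .x) "yes" else "no") == "yes"
    shared_g <- partition$shared$kmer[in_shared]
    if (length(intersect(tip_g, shared_g))) abort("tip and shared sets overlap")
    if (!setequal(c(tip_g, shared_g), tb$kmer)) abort("partition law violated")
  }
  invisible(TRUE)
}
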