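#' Assemble a recruited read subset into localized de novo contigs
#'
#' Builds a de Bruijn graph at word size `k_asm` over the reads' k-mers and
#' emits maximal unambiguous paths (unitigs) as contigs. Both orientations
#' of every k-mer are nodes (coverage is counted on the canonical form), so
#' assembly is strand-insensitive; each unitig is reported once, in its
#' canonical orientation (the lexicographically smaller of the sequence and
#' its reverse complement). Nodes with coverage below `min_node_coverage`
#' are removed before path extraction — this both suppresses residual
#' sequencing-error k-mers inside a subset and trims the low-coverage
#' contig ends covered by a single read, which is why contigs built around
#' one isolated variant come out slightly shorter than twice the read
#' length. At branch nodes the unitig simply stops: no greedy extension, no
#' bubble popping — recruited subsets are locally simple, and a bubble
#' surfaces as two contigs rather than an arbitrary choice.
#'
#' @param reads Reads tibble (e.g. from [select_reads()]), or a character
#'   vector of sequences.
#' @param k_asm Odd assembly word size (default 21; usually the pipeline k).
#' @param min_node_coverage Minimum canonical k-mer multiplicity for a node
#'   to enter the graph (default 2).
#' @param min_contig_length Shortest contig reported, in bases (default 80).
#' @param branch_ratio Relative-coverage branch pruning: at a junction, a
#'   branch whose coverage times `branch_ratio` is still no more than the
#'   strongest sibling branch is treated as a sequencing-error path and
#'   removed (default 3; `Inf` disables). Recurrent errors — the same
#'   miscall in two or three reads — survive the absolute coverage floor
#'   but sit far below the genuine path's coverage, and without pruning
#'   each one would break the unitig. Genuine alternative paths have
#'   comparable coverage and are never pruned; they still stop the unitig.
#' @param genome_id,group_key Provenance carried into the output.
#' @return Tibble of contigs: `contig_id`, `genome_id`, `group_key`,
#'   `sequence`, `length`, `mean_kmer_coverage`, ordered deterministically.
#' @examples
#' reads <- substring("ACGGTCCAT", 1:5, 5:9) # five tiling 5-mers
#' assemble(reads, k_asm = 4 + 1, min_node_coverage = 1, min_contig_length = 5)
#' @export
assemble <- function(reads, k_asm = 21, min_node_coverage = 2,
                     min_contig_length = 80, branch_ratio = 3,
                     genome_id = "genome", group_key = "tip") {
  k_asm <- check_odd_k(k_asm)
  seqs <- as_sequences(reads)
  if (length(seqs) == 0L || all(nchar(seqs) < k_asm)) {
    if (length(seqs)) warn(sprintf("all reads shorter than k_asm = %d; nothing to assemble", k_asm))
    return(empty_contigs())
  }
  w <- kmer_windows(toupper(seqs), k_asm)
  if (length(w) == 0L) return(empty_contigs())
  cov_tab <- table_counts(canonicalize(w))
  cov_tab <- cov_tab[cov_tab$count >= min_node_coverage, , drop = FALSE]
  if (nrow(cov_tab) == 0L) return(empty_contigs())

  # doubled-strand node set, deterministic order
  fw <- cov_tab$kmer
  rv <- stringi::stri_reverse(chartr("ACGT", "TGCA", fw))
  nodes <- c(fw, rv)
  covg <- c(cov_tab$count, cov_tab$count)
  ord <- order(nodes, method = "radix")
  nodes <- nodes[ord]; covg <- covg[ord]

  if (is.finite(branch_ratio)) {
    keep <- prune_weak_branches(nodes, covg, k_asm, branch_ratio)
    nodes <- nodes[keep]; covg <- covg[keep]
    if (length(nodes) == 0L) return(empty_contigs())
  }

  paths <- unitig_paths(nodes, k_asm)
  contigs <- map_chr(paths, function(p) {
    paste0(nodes[p[1L]], paste(substr(nodes[p[-1L]], k_asm, k_asm), collapse = ""))
  })
  mean_cov <- map_dbl(paths, ~ mean(covg[.x]))

  # read-coherence check: every junction between consecutive graph nodes
  # must be witnessed by a (k+1)-mer occurring in some read, otherwise two
  # unrelated loci that happen to share a (k-1)-mer are joined into a
  # chimera; unsupported junctions split the contig
  support <- unique(canonicalize(kmer_windows(toupper(seqs), k_asm + 1L)))
  if (length(support)) {
    pieces <- split_unsupported(contigs, mean_cov, support, k_asm)
    contigs <- pieces$sequence
    mean_cov <- pieces$mean_cov
  }
  rc <- reverse_complement(contigs)
  canon_seq <- ifelse(contigs <= rc, contigs, rc)
  keep <- !duplicated(canon_seq)
  out <- tibble(
    genome_id = genome_id, group_key = group_key,
    sequence = canon_seq[keep],
    length = nchar(canon_seq[keep]),
    mean_kmer_coverage = mean_cov[keep]
  )
  out <- out[out$length >= min_contig_length, , drop = FALSE]
  out <- out[order(-out$length, out$sequence, method = "radix"), ]
  out$contig_id <- sprintf("%s|%s|contig_%d", out$genome_id, out$group_key,
                           seq_len(nrow(out)))
  out[, c("contig_id", "genome_id", "group_key", "sequence", "length",
          "mean_kmer_coverage")]
}

empty_contigs <- function() {
  tibble(contig_id = character(0), genome_id = character(0),
         group_key = character(0), sequence = character(0),
         length = integer(0), mean_kmer_coverage = numeric(0))
}

# Split contigs wherever the junction between consecutive k-mers lacks a
# supporting (k+1)-mer from the reads. One vectorized membership test
# covers all contigs.
split_unsupported <- function(contigs, mean_cov, support, k) {
  L <- nchar(contigs)
  n_win <- pmax(0L, L - k)
  ci <- rep.int(seq_along(contigs), n_win)
  starts <- sequence(n_win)
  if (length(starts)) {
    w <- substring(contigs[ci], starts, starts + k)
    rcw <- stringi::stri_reverse(chartr("ACGT", "TGCA", w))
    ok <- ifelse(w <= rcw, w, rcw) %in% support
  } else {
    ok <- logical(0)
  }
  bad <- unique(ci[!ok])
  if (length(bad) == 0L) return(list(sequence = contigs, mean_cov = mean_cov))
  out_seq <- as.list(contigs)
  out_cov <- as.list(mean_cov)
  cut_by <- split(starts[!ok], ci[!ok])
  for (i in bad) {
    # an unsupported junction j separates node j (ending at j+k-1) from
    # node j+1 (starting at j+1); the flanking segments keep both nodes
    cuts <- cut_by[[as.character(i)]]
    seg_start <- c(1L, cuts + 1L)
    seg_end <- c(cuts + k - 1L, L[i])
    out_seq[[i]] <- substring(contigs[i], seg_start, seg_end)
    out_cov[[i]] <- rep(mean_cov[i], length(seg_start))
  }
  list(sequence = unlist(out_seq, use.names = FALSE),
       mean_cov = unlist(out_cov, use.names = FALSE))
}

# Relative-coverage branch pruning on the doubled node set. Nodes sharing a
# (k-1)-prefix compete as outgoing branches of one junction; a node whose
# coverage * ratio <= the strongest competitor's coverage is dropped,
# together with its reverse-complement partner (keeping the graph
# strand-symmetric; suffix-side junctions are the prefix junctions of the
# partners, so one rule covers both). Iterated to a fixed point.
prune_weak_branches <- function(nodes, covg, k, ratio) {
  keep <- rep(TRUE, length(nodes))
  partner <- match(stringi::stri_reverse(chartr("ACGT", "TGCA", nodes)), nodes)
  repeat {
    idx <- which(keep)
    pref <- substr(nodes[idx], 1L, k - 1L)
    grp <- match(pref, unique(pref))
    best <- vapply(split(covg[idx], grp), max, numeric(1))
    weak <- idx[covg[idx] * ratio <= best[as.character(grp)]]
    if (length(weak) == 0L) break
    keep[weak] <- FALSE
    keep[partner[weak]] <- FALSE
  }
  keep
}

# Maximal non-branching chains over a doubled k-mer node set.
# An edge u->v exists when suffix(u) == prefix(v); it is unitig-internal
# when it is u's only out-edge and v's only in-edge.
unitig_paths <- function(nodes, k) {
  n <- length(nodes)
  pref <- substr(nodes, 1L, k - 1L)
  suf <- substr(nodes, 2L, k)
  upref <- unique(pref)
  usuf <- unique(suf)
  pref_count <- tabulate(match(pref, upref), nbins = length(upref))
  suf_count <- tabulate(match(suf, usuf), nbins = length(usuf))
  first_with_pref <- match(upref, pref)
  first_with_suf <- match(usuf, suf)

  m_out <- match(suf, upref)           # which prefix group my suffix feeds
  out_deg <- ifelse(is.na(m_out), 0L, pref_count[m_out])
  succ <- ifelse(out_deg == 1L, first_with_pref[m_out], NA_integer_)
  m_in <- match(pref, usuf)            # which suffix group feeds my prefix
  in_deg <- ifelse(is.na(m_in), 0L, suf_count[m_in])
  pred <- ifelse(in_deg == 1L, first_with_suf[m_in], NA_integer_)

  nxt <- rep(NA_integer_, n)
  ok <- !is.na(succ) & in_deg[ifelse(is.na(succ), 1L, succ)] == 1L
  # exclude self-loops (k-mer of a single repeated base)
  ok <- ok & succ != seq_len(n)
  nxt[ok] <- succ[ok]
  has_internal_in <- rep(FALSE, n)
  has_internal_in[nxt[!is.na(nxt)]] <- TRUE

  visited <- logical(n)
  paths <- list()
  walk <- function(start) {
    p <- integer(0)
    u <- start
    while (!is.na(u) && !visited[u]) {
      visited[u] <<- TRUE
      p[length(p) + 1L] <- u
      u <- nxt[u]
    }
    p
  }
  for (u in which(!has_internal_in)) {
    if (!visited[u]) paths[[length(paths) + 1L]] <- walk(u)
  }
  # pure cycles have no chain start; break each at its smallest node
  for (u in which(!visited)) {
    if (!visited[u]) paths[[length(paths) + 1L]] <- walk(u)
  }
  paths
}
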