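#' Build a synthetic quadripartite genome
#'
#' Emulates the circular chloroplast architecture: a large single-copy
#' region (LSC), inverted repeat A, a small single-copy region (SSC), and
#' inverted repeat B, with IRB exactly the reverse complement of IRA. The
#' single-copy regions and IRA are uniform random DNA; IRB is derived, so
#' the duplicated fraction of the genome is `ir_len / total` and the
#' distinct canonical k-mer count is close to `(total - ir_len) - (k - 1)`
#' (the second IR copy contributes only a handful of junction k-mers).
#' Defaults give a 100 kb genome with the ~18% duplication typical of
#' chloroplasts.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bases.
#' @param seed Optional integer seed (deterministic output per seed).
#' @param circular Mark the molecule circular (reads may span the origin).
#' @return A `genome_model`: list with `sequence`, the region lengths, a
#'   `regions` tibble (0-based half-open coordinates), and `circular`.
#' @examples
#' g <- make_genome(2000, 600, 700, seed = 1)
#' nchar(g$sequence)
#' @export
make_genome <- function(lsc_len = 50000, ssc_len = 14000, ir_len = 18000,
                        seed = NULL, circular = TRUE) {
  stopifnot(lsc_len >= 0, ssc_len >= 0, ir_len >= 0)
  gen <- function() {
    lsc <- random_dna(lsc_len)
    ira <- random_dna(ir_len)
    ssc <- random_dna(ssc_len)
    irb <- if (ir_len > 0) reverse_complement(ira) else ""
    seqn <- paste0(lsc, ira, ssc, irb)
    bounds <- cumsum(c(lsc_len, ir_len, ssc_len, ir_len))
    structure(list(
      sequence = seqn, lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
      circular = circular,
      regions = tibble(region = c("LSC", "IRA", "SSC", "IRB"),
                       start = c(0L, bounds[1:3]), end = bounds)
    ), class = "genome_model")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# tips keep their labels; internal nodes use their newick label when given,
# otherwise node_<i>
tree_node_names <- function(tree) {
  nl <- tree$node.label %||% character(0)
  internal <- paste0("node_", seq_len(ape::Nnode(tree)))
  if (length(nl)) {
    keep <- nzchar(nl) & !is.na(nl)
    internal[keep] <- nl[keep]
  }
  c(tree$tip.label, internal)
}

# Mirror coordinate of a position lying in either inverted-repeat copy:
# the two copies are the same sequence, so a locus in IRA and its mirror in
# IRB are the same place in sequence space. NA outside the IRs.
ir_mirror <- function(genome, pos) {
  if (!inherits(genome, "genome_model") || genome$ir_len == 0L) {
    return(rep(NA_integer_, length(pos)))
  }
  ira0 <- genome$lsc_len
  irb0 <- genome$lsc_len + genome$ir_len + genome$ssc_len
  out <- rep(NA_integer_, length(pos))
  in_a <- pos >= ira0 & pos < ira0 + genome$ir_len
  in_b <- pos >= irb0 & pos < irb0 + genome$ir_len
  out[in_a] <- irb0 + (genome$ir_len - 1L) - (pos[in_a] - ira0)
  out[in_b] <- ira0 + (genome$ir_len - 1L) - (pos[in_b] - irb0)
  out
}

# Draw N positions pairwise separated by >= min_spacing in sequence space:
# besides linear distance, a position inside one IR copy also blocks the
# mirror locus in the other copy (identical sequence would otherwise merge
# the two variants' recruited reads into one chimeric contig).
draw_spaced_positions <- function(genome, N, min_spacing, margin) {
  G <- nchar(as_sequences(genome))
  slack <- (G - 2 * margin) - (N - 1) * min_spacing
  if (slack <= 0) abort("genome too small for this many spaced variants")
  pos <- margin + (seq_len(N) - 1L) * min_spacing + round(sort(runif(N, 0, slack)))
  ok_at <- function(cand, others) {
    blk <- c(others, ir_mirror(genome, others))
    all(abs(cand - blk) >= min_spacing, na.rm = TRUE)
  }
  for (iter in seq_len(10L * N + 100L)) {
    d <- outer(pos, c(pos, ir_mirror(genome, pos)), function(a, b) abs(a - b))
    d[cbind(seq_len(N), seq_len(N))] <- NA # a position vs itself
    conflict <- which(apply(d, 1L, function(r) any(r < min_spacing, na.rm = TRUE)))
    if (length(conflict) == 0L) return(sort(pos))
    j <- conflict[length(conflict)] # redraw one; recheck on the next pass
    placed <- FALSE
    for (try in 1:500) {
      cand <- round(runif(1, margin, G - margin))
      if (ok_at(cand, pos[-j])) {
        pos[j] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  abort("could not place variants with the requested spacing; reduce their number or the spacing")
}

random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("synthetic quadripartite genome: %d bp (LSC %d + IR %d x2 + SSC %d)%s\n",
              nchar(x$sequence), x$lsc_len, x$ir_len, x$ssc_len,
              if (x$circular) ", circular" else ""))
  invisible(x)
}

#' Apply one variant to a genome and record it
#'
#' Supported types: `"snp"` (substitute one base for a different one),
#' `"insertion"` (insert `i` random or given bases before `position`),
#' `"deletion"` (remove `i` bases at `position`), and `"translocation"`
#' (excise `seg_len` bases at `position` and reinsert them before `dest`,
#' creating novel junctions). Coordinates are 0-based; intervals half-open.
#' The returned ledger entry stores the local sequence context before and
#' after the edit, which downstream tests use as ground truth: a recovered
#' contig must contain the "after" context.
#'
#' @param genome A `genome_model` or a plain sequence string.
#' @param vtype One of `"snp"`, `"insertion"`, `"deletion"`,
#'   `"translocation"`.
#' @param position 0-based offset of the edit.
#' @param i Length of the inserted/deleted stretch (indels only).
#' @param seg_len,dest Translocation segment length and destination offset
#'   (on the genome after excision).
#' @param alt Optional explicit substituted/inserted bases; random if
#'   omitted.
#' @param context_flank Bases of flanking context recorded in the ledger.
#' @param seed Optional integer seed.
#' @return List with `genome` (same class as input) and `entry` (one-row
#'   ledger tibble).
#' @export
apply_variant <- function(genome, vtype, position, i = NULL, seg_len = NULL,
                          dest = NULL, alt = NULL, context_flank = 20,
                          seed = NULL) {
  run <- function() {
    seqn <- as_sequences(genome)
    G <- nchar(seqn)
    vtype <- match.arg(vtype, c("snp", "insertion", "deletion", "translocation"))
    if (position < 0 || position >= G) abort("variant position out of range")
    p1 <- position + 1L # 1-based
    before_context <- substr(seqn, max(1L, p1 - context_flank), min(G, p1 + context_flank))
    ref_allele <- alt_allele <- NA_character_
    if (vtype == "snp") {
      ref_allele <- substr(seqn, p1, p1)
      alt_allele <- if (!is.null(alt)) alt else sample(setdiff(c("A", "C", "G", "T"), ref_allele), 1L)
      if (alt_allele == ref_allele) abort("snp must change the base")
      new <- paste0(substr(seqn, 1L, p1 - 1L), alt_allele, substr(seqn, p1 + 1L, G))
    } else if (vtype == "insertion") {
      if (is.null(i) || is.na(i) || i < 1) abort("insertion needs i >= 1")
      alt_allele <- if (!is.null(alt)) alt else random_dna(i)
      new <- paste0(substr(seqn, 1L, p1 - 1L), alt_allele, substr(seqn, p1, G))
    } else if (vtype == "deletion") {
      if (is.null(i) || is.na(i) || i < 1) abort("deletion needs i >= 1")
      if (position + i > G) abort("deletion does not fit in the genome")
      ref_allele <- substr(seqn, p1, p1 + i - 1L)
      new <- paste0(substr(seqn, 1L, p1 - 1L), substr(seqn, p1 + i, G))
    } else {
      if (is.null(seg_len) || is.null(dest)) abort("translocation needs seg_len and dest")
      if (position + seg_len > G) abort("segment does not fit in the genome")
      seg <- substr(seqn, p1, p1 + seg_len - 1L)
      rest <- paste0(substr(seqn, 1L, p1 - 1L), substr(seqn, p1 + seg_len, G))
      if (dest < 0 || dest > nchar(rest)) abort("translocation destination out of range")
      new <- paste0(substr(rest, 1L, dest), seg, substr(rest, dest + 1L, nchar(rest)))
      ref_allele <- seg
    }
    ctr <- if (vtype == "translocation") dest else position
    span <- switch(vtype, snp = 1L, deletion = 1L,
                   insertion = as.integer(i), translocation = as.integer(seg_len))
    after_context <- substr(new, max(1L, ctr + 1L - context_flank),
                            min(nchar(new), ctr + span + context_flank))
    out_genome <- genome
    if (inherits(genome, "genome_model")) out_genome$sequence <- new else out_genome <- new
    list(
      genome = out_genome,
      entry = tibble(vtype = vtype, position = as.integer(position),
                     i = as.integer(i %||% NA_integer_),
                     seg_len = as.integer(seg_len %||% NA_integer_),
                     dest = as.integer(dest %||% NA_integer_),
                     ref_allele = ref_allele, alt_allele = alt_allele,
                     before_context = before_context, after_context = after_context,
                     length_change = nchar(new) - G)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Evolve a root genome along a phylogeny with a ground-truth ledger
#'
#' Plants substitutions and indels on every branch of a tree and returns the
#' leaf genomes together with a complete variant ledger. Variant loci are
#' drawn once, genome-wide, with a minimum pairwise spacing (default 120 bp,
#' comfortably more than twice a 51 bp read), so every planted variant is
#' isolated: its recruited reads cannot overlap another variant's, and each
#' variant is expected to surface in exactly one localized contig.
#' Translocations are not drawn here (they break the coordinate bookkeeping
#' that guarantees isolation); use [apply_variant()] directly for those.
#'
#' @param root Root `genome_model` ([make_genome()]).
#' @param tree An `ape` `phylo` object or a newick string.
#' @param n_snps,n_insertions,n_deletions Variants per branch: a single
#'   number (every branch) or a vector named by child node/tip label.
#' @param indel_len Inclusive range of indel lengths to draw from.
#' @param min_spacing Minimum distance between any two variant loci (root
#'   coordinates).
#' @param context_flank Context width recorded in the ledger.
#' @param seed Optional integer seed.
#' @return List: `genomes` (named list of leaf `genome_model`s), `ledger`
#'   (tibble with one row per planted variant: `node`, `branch`, `vtype`,
#'   `root_pos`, `position`, alleles, contexts, `apply_order`), `tree`.
#' @export
evolve_on_tree <- function(root, tree, n_snps = 0, n_insertions = 0,
                           n_deletions = 0, indel_len = c(1L, 10L),
                           min_spacing = 120, context_flank = 20, seed = NULL) {
  run <- function() {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (is.null(tree)) abort("malformed newick tree")
    if (anyDuplicated(tree$tip.label)) abort("tree leaves must be uniquely named")
    node_name <- tree_node_names(tree)
    edges <- tree$edge # parent, child (ape numbering)
    child_names <- node_name[edges[, 2L]]
    per_branch <- function(x) {
      if (!is.null(names(x))) {
        v <- rep(0L, nrow(edges))
        hit <- match(names(x), child_names)
        if (anyNA(hit)) abort("branch counts named after unknown node")
        v[hit] <- as.integer(x)
        v
      } else rep(as.integer(x), nrow(edges))
    }
    ns <- per_branch(n_snps); ni <- per_branch(n_insertions); nd <- per_branch(n_deletions)
    plan <- tibble(
      edge = rep(seq_len(nrow(edges)), ns + ni + nd),
      vtype = unlist(map(seq_len(nrow(edges)), function(e) {
        c(rep("snp", ns[e]), rep("insertion", ni[e]), rep("deletion", nd[e]))
      }), use.names = FALSE)
    )
    G0 <- nchar(root$sequence)
    N <- nrow(plan)
    if (N > 0L) {
      margin <- max(min_spacing, context_flank + max(indel_len) + 1L)
      pos <- draw_spaced_positions(root, N, min_spacing, margin)
      plan$root_pos <- pos[sample.int(N)] # random locus-to-branch assignment
      lens <- seq(indel_len[1L], indel_len[2L])
      plan$i <- ifelse(plan$vtype == "snp", NA_integer_,
                       lens[sample.int(length(lens), N, replace = TRUE)])
    } else {
      plan$root_pos <- integer(0)
      plan$i <- integer(0)
    }
    # preorder traversal applying each branch's variants to its parent genome
    tree_cw <- stats::reorder(tree, "cladewise") # parent edges precede child edges
    edge_order <- match(paste(tree_cw$edge[, 1L], tree_cw$edge[, 2L]),
                        paste(edges[, 1L], edges[, 2L]))
    root_id <- length(tree$tip.label) + 1L
    genomes <- list(); shifts <- list()
    genomes[[root_id]] <- root
    shifts[[root_id]] <- tibble(root_pos = integer(0), delta = integer(0))
    ledger <- list()
    order_ct <- 0L
    for (e in edge_order) {
      parent <- edges[e, 1L]; child <- edges[e, 2L]
      g <- genomes[[parent]]
      sh <- shifts[[parent]]
      rows <- plan[plan$edge == e, , drop = FALSE]
      rows <- rows[order(rows$root_pos), , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        rp <- rows$root_pos[r]
        cur <- rp + sum(sh$delta[sh$root_pos < rp])
        res <- apply_variant(g, rows$vtype[r], cur, i = rows$i[r],
                             context_flank = context_flank)
        g <- res$genome
        order_ct <- order_ct + 1L
        entry <- res$entry
        entry$node <- node_name[child]
        entry$branch <- paste0(node_name[parent], "->", node_name[child])
        entry$root_pos <- rp
        entry$apply_order <- order_ct
        ledger[[order_ct]] <- entry
        sh <- bind_rows(sh, tibble(root_pos = rp, delta = entry$length_change))
      }
      genomes[[child]] <- g
      shifts[[child]] <- sh
    }
    leaf_ids <- seq_along(tree$tip.label)
    led <- if (length(ledger)) bind_rows(ledger) else
      tibble(vtype = character(0), position = integer(0), node = character(0),
             branch = character(0), root_pos = integer(0), apply_order = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             before_context = character(0), after_context = character(0),
             i = integer(0), seg_len = integer(0), dest = integer(0),
             length_change = integer(0))
    list(genomes = setNames(genomes[leaf_ids], tree$tip.label),
         ledger = led, tree = tree)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Replay a ledger to reproduce a leaf genome
#'
#' Applies the recorded edits for the branches on the root-to-leaf path, in
#' recorded order, using the recorded positions and alleles. Replaying must
#' reproduce the simulated leaf exactly — the round-trip check that makes
#' the ledger trustworthy as ground truth.
#'
#' @param root The root `genome_model` given to [evolve_on_tree()].
#' @param evolved Result of [evolve_on_tree()].
#' @param leaf Leaf (tip) label.
#' @return The reconstructed leaf sequence (character scalar).
#' @export
replay_ledger <- function(root, evolved, leaf) {
  tree <- evolved$tree
  node_name <- tree_node_names(tree)
  leaf_id <- match(leaf, tree$tip.label)
  if (is.na(leaf_id)) abort("unknown leaf")
  # collect path node names from leaf up to root
  path <- character(0)
  cur <- leaf_id
  repeat {
    path <- c(path, node_name[cur])
    parent <- tree$edge[tree$edge[, 2L] == cur, 1L]
    if (length(parent) == 0L) break
    cur <- parent
  }
  rows <- evolved$ledger[evolved$ledger$node %in% path, , drop = FALSE]
  rows <- rows[order(rows$apply_order), , drop = FALSE]
  seqn <- root$sequence
  for (r in seq_len(nrow(rows))) {
    res <- apply_variant(seqn, rows$vtype[r], rows$position[r], i = rows$i[r],
                         alt = rows$alt_allele[r])
    seqn <- res$genome
  }
  seqn
}

#' Simulate short reads from a genome
#'
#' Uniform fragment starts (wrapping the origin when the molecule is
#' circular), optional paired-end layout, and an independent per-base
#' substitution error model: each base is replaced by a uniformly random
#' different base with probability `error_rate`. Reverse-strand reads are
#' emitted as reverse complements. Qualities are constant — nothing
#' downstream consumes them. Read count is `round(G * coverage /
#' read_len)` (half as many fragments when paired), so total sequenced
#' bases match the requested coverage to within one read.
#'
#' @param genome `genome_model` or sequence string.
#' @param read_len Read length in bases (default 51).
#' @param coverage Fold coverage (default 20).
#' @param error_rate Per-base substitution probability (default 0.05; the
#'   error model used for the "with error" condition).
#' @param paired Emit read pairs from fragment ends (default TRUE).
#' @param insert_mean,insert_sd Fragment length distribution (paired mode).
#' @param genome_id Prefix for read ids.
#' @param seed Optional integer seed.
#' @return Reads tibble: `id`, `sequence`, `quality`, `pair_id`, `mate`,
#'   plus provenance columns `frag_start` (0-based), `frag_len`, `strand`
#'   used by recovery and calibration tests.
#' @export
simulate_reads <- function(genome, read_len = 51, coverage = 20,
                           error_rate = 0.05, paired = TRUE,
                           insert_mean = 300, insert_sd = 30,
                           genome_id = "genome", seed = NULL) {
  run <- function() {
    seqn <- as_sequences(genome)
    circular <- if (inherits(genome, "genome_model")) genome$circular else FALSE
    G <- nchar(seqn)
    stopifnot(error_rate >= 0, error_rate < 1, read_len >= 1)
    if (G < read_len) abort("genome shorter than the read length")
    if (paired && insert_mean < read_len) abort("insert_mean must be at least read_len in paired mode")
    if (paired) {
      n_frag <- max(1L, round(G * coverage / (2 * read_len)))
      frag_len <- pmin(pmax(round(rnorm(n_frag, insert_mean, insert_sd)), read_len), G)
    } else {
      n_frag <- max(1L, round(G * coverage / read_len))
      frag_len <- rep(read_len, n_frag)
    }
    pad <- paste0(seqn, substr(seqn, 1L, max(frag_len)))
    if (circular) {
      start <- sample.int(G, n_frag, replace = TRUE) # 1-based, may wrap
    } else {
      start <- map_int(frag_len, ~ sample.int(G - .x + 1L, 1L))
    }
    frags <- substring(pad, start, start + frag_len - 1L)
    strand <- sample(c("+", "-"), n_frag, replace = TRUE)
    neg <- strand == "-"
    frags[neg] <- reverse_complement(frags[neg])
    if (paired) {
      r1 <- substr(frags, 1L, read_len)
      r2 <- reverse_complement(substring(frags, frag_len - read_len + 1L, frag_len))
      reads <- tibble(
        id = c(sprintf("%s_f%d/1", genome_id, seq_len(n_frag)),
               sprintf("%s_f%d/2", genome_id, seq_len(n_frag))),
        sequence = c(r1, r2),
        pair_id = rep(sprintf("%s_f%d", genome_id, seq_len(n_frag)), 2L),
        mate = rep(c(1L, 2L), each = n_frag),
        frag_start = rep(start - 1L, 2L),
        frag_len = rep(frag_len, 2L),
        strand = rep(strand, 2L)
      )
    } else {
      reads <- tibble(
        id = sprintf("%s_f%d/1", genome_id, seq_len(n_frag)),
        sequence = frags,
        pair_id = sprintf("%s_f%d", genome_id, seq_len(n_frag)),
        mate = 1L,
        frag_start = start - 1L, frag_len = frag_len, strand = strand
      )
    }
    if (error_rate > 0) {
      reads$sequence <- add_substitution_errors(reads$sequence, error_rate)
    }
    reads$quality <- strrep("I", nchar(reads$sequence))
    reads[, c("id", "sequence", "quality", "pair_id", "mate",
              "frag_start", "frag_len", "strand")]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# substitute each base with prob p to a uniformly random different base
add_substitution_errors <- function(seqs, p) {
  L <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), L, p)
  idx <- which(n_err > 0L)
  if (length(idx) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  seqs[idx] <- map_chr(idx, function(j) {
    ch <- stringi::stri_sub(seqs[j], seq_len(L[j]), length = 1L)
    pos <- sample.int(L[j], n_err[j])
    ch[pos] <- map_chr(ch[pos], ~ sample(setdiff(bases, .x), 1L))
    paste(ch, collapse = "")
  })
  seqs
}
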