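#' Polish contigs by per-base read consensus
#'
#' A unitig can carry a sequencing error when a recurrent miscall bridges a
#' coverage hole in the true path — the k-mer evidence is missing there,
#' but the base-level evidence is not: the genome's full read set covers
#' every locus at the sequencing depth, and at moderate error rates the
#' correct base always dominates a column vote. Because the error model is
#' substitution-only, a read aligns to a contig at a fixed offset, found
#' from any shared canonical k-mer (no gapped alignment); reads whose
#' overlap disagrees with the contig at more than `max_mismatch_frac` of
#' positions (anchored by chance, e.g. across an inverted-repeat boundary)
#' are excluded from the vote. A base is rewritten only on a supermajority
#' (at least `min_majority` of at least `min_votes` votes): inside an
#' inverted repeat the two copies' reads can contest a column that
#' genuinely differs between copies at roughly even odds, and an even
#' split must never overwrite the assembled base.
#'
#' @param contigs Contig tibble ([assemble()]).
#' @param reads The genome's full read tibble (not just the recruited
#'   subset).
#' @param k Anchor word size (the pipeline counting k).
#' @param max_mismatch_frac Drop read-contig alignments more discordant
#'   than this (default 0.2, four times the strongest error model used).
#' @param min_votes Minimum column depth before a base may change.
#' @param min_majority Vote fraction the winning base needs before it
#'   replaces the assembled base (default 2/3).
#' @param trim_ends Also trim contig ends back to the outermost column with
#'   a confident consensus (a clear majority of at least `trim_depth`
#'   votes). Assembly errors concentrate at unitig ends — an end extended
#'   through a coverage hole by a recurrent miscall is supported by only
#'   those few erroneous reads — so thinly supported end columns are
#'   removed rather than guessed at.
#' @param trim_depth Column depth required for a confident end (default
#'   `min_votes`; the pipeline passes a quarter of the expected read
#'   coverage, so a handful of recurrent-error reads can never prop up a
#'   contig end on their own).
#' @return `contigs` with polished sequences (and lengths updated when ends
#'   were trimmed); a `polished_bases` attribute counts rewritten positions.
#' @export
polish_contigs <- function(contigs, reads, k = 21, max_mismatch_frac = 0.2,
                           min_votes = 3, trim_ends = TRUE,
                           trim_depth = min_votes, min_majority = 2 / 3) {
  if (nrow(contigs) == 0L) return(contigs)
  windex <- window_index(as_sequences(reads), k)
  polish_with_index(contigs, as_sequences(reads), windex, k,
                    max_mismatch_frac, min_votes, trim_ends, trim_depth,
                    min_majority)
}

polish_with_index <- function(contigs, read_seqs, windex, k,
                              max_mismatch_frac = 0.2, min_votes = 3,
                              trim_ends = TRUE, trim_depth = min_votes,
                              min_majority = 2 / 3) {
  seqs <- contigs$sequence
  clen <- nchar(seqs)
  # dictionary of contig k-mers: canonical word -> (contig, position, strand)
  starts <- map(clen, ~ seq_len(max(0L, .x - k + 1L)))
  ci <- rep.int(seq_along(seqs), lengths(starts))
  cpos <- unlist(starts, use.names = FALSE)
  if (length(cpos) == 0L) return(contigs)
  cw <- substr(rep(seqs, lengths(starts)), cpos, cpos + k - 1L)
  ccanon <- canonicalize_safe(cw)
  cfwd <- cw == ccanon

  # many-to-many anchor join: a k-mer occurring in several contigs
  # (overlapping loci) must anchor its reads to each of them
  hit <- which(windex$canon %in% ccanon)
  if (length(hit) == 0L) return(contigs)
  wdf <- tibble(rd = windex$read[hit], rpos = windex$pos[hit],
                rfwd = windex$fwd[hit], canon = windex$canon[hit])
  cdf <- tibble(tci = ci, tcpos = cpos, tcfwd = cfwd, canon = ccanon)
  j <- dplyr::inner_join(wdf, cdf, by = "canon",
                         relationship = "many-to-many")
  rd <- j$rd; rpos <- j$rpos; rfwd <- j$rfwd
  tci <- j$tci; tcpos <- j$tcpos; tcfwd <- j$tcfwd
  L <- nchar(read_seqs)[rd]
  same <- rfwd == tcfwd
  # forward alignment: read position rpos sits at contig position tcpos;
  # reverse: the window lands at rc-read position L - rpos - k + 2
  offset <- ifelse(same, tcpos - rpos, tcpos - (L - rpos - k + 2L))
  key <- paste(rd, tci, sep = "_")
  first <- !duplicated(key)
  al <- tibble(read = rd[first], contig = tci[first], offset = offset[first],
               reverse = !same[first], read_len = L[first])

  oriented <- read_seqs[al$read]
  oriented[al$reverse] <- reverse_complement(oriented[al$reverse])
  # expand to per-base votes, clipped to the contig
  reps <- al$read_len
  pair <- rep(seq_len(nrow(al)), reps)
  read_off <- sequence(reps)
  pos <- al$offset[pair] + read_off
  base <- unlist(strsplit(oriented, ""), use.names = FALSE)
  keep <- pos >= 1L & pos <= clen[al$contig[pair]]
  pair <- pair[keep]; pos <- pos[keep]; base <- base[keep]
  cg <- al$contig[pair]
  cur <- substr(rep(seqs[cg], 1L), pos, pos) # current contig base per vote
  mism <- base != cur
  # per-pair discordance filter
  n_tot <- tabulate(pair, nbins = nrow(al))
  n_mm <- tabulate(pair[mism], nbins = nrow(al))
  bad_pair <- n_tot > 0L & n_mm / pmax(n_tot, 1L) > max_mismatch_frac
  ok <- !bad_pair[pair]
  pair <- pair[ok]; pos <- pos[ok]; base <- base[ok]; cg <- cg[ok]

  bi <- match(base, c("A", "C", "G", "T"))
  valid <- !is.na(bi)
  code <- (cumsum(c(0L, clen))[cg[valid]] + pos[valid] - 1L) * 4L + bi[valid]
  votes <- tabulate(code, nbins = 4L * sum(clen))
  vm <- matrix(votes, nrow = 4L)
  tot <- colSums(vm)
  win <- max.col(t(vm), ties.method = "first")
  win_n <- vm[cbind(win, seq_along(tot))]
  vm2 <- vm
  vm2[cbind(win, seq_along(tot))] <- -1L
  second_n <- vm2[cbind(max.col(t(vm2), ties.method = "first"), seq_along(tot))]
  all_pos <- sequence(clen)
  all_cg <- rep.int(seq_along(seqs), clen)
  cur_all <- substr(rep(seqs, clen), all_pos, all_pos)
  new_base <- c("A", "C", "G", "T")[win]
  # the supermajority is judged against the runner-up, not the total:
  # scattered third-base noise must not shield a genuine correction, while
  # an even two-way contest (the inverted-repeat case) still never flips
  change <- tot >= min_votes & win_n >= min_majority * (win_n + second_n) &
    new_base != cur_all
  n_changed <- sum(change)
  if (n_changed > 0L) {
    for (j in which(change)) {
      i <- all_cg[j]
      substr(seqs[i], all_pos[j], all_pos[j]) <- new_base[j]
    }
  }
  if (trim_ends) {
    # a confident column has both depth and a supermajority; ends are cut
    # back to the first run of k confident columns so a contested column
    # near an end cannot survive behind a lone supported one
    confident <- tot >= trim_depth & win_n >= min_majority * tot
    for (i in seq_along(seqs)) {
      conf_i <- confident[all_cg == i]
      need <- min(k, clen[i])
      r <- rle(conf_i)
      ends_r <- cumsum(r$lengths)
      starts_r <- ends_r - r$lengths + 1L
      good <- which(r$values & r$lengths >= need)
      if (length(good) == 0L) {
        seqs[i] <- ""
        next
      }
      lo <- starts_r[good[1L]]
      hi <- ends_r[good[length(good)]]
      if (lo > 1L || hi < clen[i]) seqs[i] <- substr(seqs[i], lo, hi)
    }
  }
  contigs$sequence <- seqs
  if ("length" %in% names(contigs)) contigs$length <- nchar(seqs)
  attr(contigs, "polished_bases") <- n_changed
  contigs
}
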