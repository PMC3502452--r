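# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (character-by-character), so
# they share no code path with the package implementation.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# enumerate all k-windows of a sequence (no canonicalization, keeps N)
oracle_windows <- function(s, k) {
  if (nchar(s) < k) return(character(0))
  vapply(seq_len(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1), character(1))
}

# brute-force canonical k-mer counting over a set of sequences
oracle_count <- function(seqs, k, threshold = 1) {
  w <- unlist(lapply(seqs, oracle_windows, k = k))
  w <- w[!grepl("N", w, fixed = TRUE)]
  tab <- table(oracle_canonical(w))
  tab <- tab[tab >= threshold]
  tab <- tab[order(names(tab), method = "radix")]
  data.frame(kmer = names(tab), count = as.integer(tab), stringsAsFactors = FALSE)
}

# brute-force count of k-windows of alt absent from ref (canonical sets)
oracle_span <- function(ref, alt, k) {
  ref_set <- unique(oracle_canonical(unlist(lapply(ref, oracle_windows, k = k))))
  alt_win <- oracle_canonical(oracle_windows(alt, k))
  sum(!(alt_win %in% ref_set))
}

# direct set-algebra oracle over a named list of k-mer sets
oracle_tips_shared <- function(sets) {
  all_k <- unique(unlist(sets))
  membership <- lapply(all_k, function(km) names(sets)[vapply(sets, function(s) km %in% s, logical(1))])
  names(membership) <- all_k
  tips <- lapply(names(sets), function(g) {
    names(Filter(function(m) identical(m, g), membership))
  })
  names(tips) <- names(sets)
  shared <- Filter(function(m) length(m) >= 2, membership)
  list(tips = tips, shared = shared)
}

oracle_exclusive <- function(sets, group) {
  os <- oracle_tips_shared(sets)
  names(Filter(function(m) setequal(m, group), os$shared))
}

oracle_inclusive <- function(sets, group) {
  Reduce(intersect, sets[group])
}

# ref/alt context pairs with non-repetitive flanks around a single variant.
# The closed-form span counts assume a fully novel variant, so the bases
# abutting an edit must differ from the reference continuation — otherwise
# the boundary windows coincide with reference windows and the brute-force
# count drops below the formula.
make_contexts <- function(vtype, k, i = NULL, flank = 60) {
  other_than <- function(...) sample(setdiff(c("A", "C", "G", "T"), c(...)), 1)
  set_char <- function(s, pos, ch) { substr(s, pos, pos) <- ch; s }
  novel_fill <- function(n, right1, leftF) {
    s <- random_seq(n)
    if (n == 1) return(other_than(right1, leftF))
    s <- set_char(s, 1, other_than(right1))
    set_char(s, n, other_than(leftF))
  }
  left <- random_seq(flank)
  right <- random_seq(flank)
  if (vtype == "snp") {
    mid <- random_seq(1)
    list(ref = paste0(left, mid, right), alt = paste0(left, other_than(mid), right))
  } else if (vtype == "insertion") {
    ins <- novel_fill(i, substr(right, 1, 1), substr(left, flank, flank))
    list(ref = paste0(left, right), alt = paste0(left, ins, right))
  } else if (vtype == "deletion") {
    del <- novel_fill(i, substr(right, 1, 1), substr(left, flank, flank))
    list(ref = paste0(left, del, right), alt = paste0(left, right))
  } else { # junction: two reference regions, alt joins left of one to right of other
    left2 <- random_seq(flank)
    right2 <- random_seq(flank)
    left2 <- set_char(left2, flank, other_than(substr(left, flank, flank)))
    right2 <- set_char(right2, 1, other_than(substr(right, 1, 1)))
    list(ref = c(paste0(left, right), paste0(left2, right2)),
         alt = paste0(left, right2))
  }
}

# strip a k-mer table to its bare columns for comparison with oracles
plain_counts <- function(tbl) {
  data.frame(kmer = tbl$kmer, count = as.integer(tbl$count), stringsAsFactors = FALSE)
}

random_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# small shared fixture: a 4-leaf evolved clade used by several test files
balanced_clade <- function(seed = 42, n_snps = 8,
                           lsc = 6000, ssc = 1500, ir = 1500) {
  root <- make_genome(lsc, ssc, ir, seed = seed)
  ev <- evolve_on_tree(root, "((A:1,B:1):1,(C:1,D:1):1);",
                       n_snps = n_snps, seed = seed + 1)
  list(root = root, ev = ev)
}
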