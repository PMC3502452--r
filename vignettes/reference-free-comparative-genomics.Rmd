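---
title: "Reference-free comparative genomics with canonical k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free comparative genomics with canonical k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmercomp)
```

## The method

Comparative questions rarely need whole assembled genomes: most of the
informative signal is concentrated in the small fraction of sequence that
differs between the genomes under comparison. kmercomp compares many
genomes directly from unassembled short reads in four steps:

1. **Count.** Each genome's reads become a table of canonical k-mers
   (default k = 21) with frequencies. A k-mer and its reverse complement
   are equated by keeping the alphabetically smaller of the pair, so all
   downstream comparisons are strand-insensitive. A frequency threshold
   (default 3) removes most k-mers created by sequencing error: at ~20x
   coverage a genuine genomic k-mer is seen ~12 times while an error k-mer
   is usually seen once or twice.
2. **Partition.** K-mers observed in exactly one genome are that genome's
   *tip* k-mers — variation unique to it. K-mers observed in two or more
   genomes enter a shared table together with their exact membership (the
   set of genomes containing them). Group k-mer sets are extracted either
   *exclusively* (membership equals the group exactly) or *inclusively*
   (present in all members, regardless of the rest).
3. **Select.** For each target k-mer set, the reads containing at least
   one of its k-mers are recruited, per genome. Around an isolated
   variant this captures precisely the reads overlapping it, because every
   read covering a substituted base contains at least one of its k
   variant-spanning k-mers.
4. **Assemble.** Each small read subset is assembled independently into
   localized de novo contigs with a de Bruijn unitig assembler, then
   polished against the genome's full read set and validated against the
   truth when it is known (simulations).

The footprint of a variant in k-mer space has a closed form in
non-repetitive context: a substitution appears in exactly $k$ k-mers, a
novel junction (translocation or inversion breakpoint) in $k-1$, and an
insertion of length $i$ in $k+i-1$. The per-base coverage profile of these
informative k-mers peaks at $k$ on a substituted base, shows a two-base
plateau at a junction, and a plateau of height $k$ across an insertion.
`variant_kmer_span()` and `variant_coverage_profile()` implement these and
are checked against brute-force window enumeration.

K-mer diversity itself is informative before any assembly: for a genome
with little internal repetition, distinct canonical k-mers ≈ genome length
− duplicated length. Chloroplast genomes carry a large inverted repeat
(IR) duplicating ~18% of the molecule, so IR-bearing plastomes fall on a
line of slope ≈ 0.82 in the diversity-versus-size plane while IR-less ones
track the 1:1 line; `diversity_regression()` fits that line and reports
per-genome deviations so unusual duplication structure stands out.

## The simulator as ground truth

`make_genome()` builds a circular quadripartite genome (LSC + IRA + SSC +
IRB, with IRB the exact reverse complement of IRA; defaults 50 kb + 18 kb
+ 14 kb + 18 kb = 100 kb at the ~18% duplication typical of chloroplasts).
`evolve_on_tree()` plants substitutions and indels on each branch of a
phylogeny and records every edit in a ledger whose replay reproduces each
leaf exactly; `simulate_reads()` generates 51 bp paired reads at 20x with
an independent per-base substitution error model (default 5%). These
defaults are the simulated-sequencing conditions the analyses are
validated under; the error rate is a parameter because published work with
this design has used both 3% and 5%.

Variant loci are drawn once, genome-wide, with a minimum pairwise spacing
(default 120 bp, more than twice the read length), so every variant is
*isolated*: its recruited reads cannot overlap another variant's and each
variant is expected in exactly one contig. Spacing is enforced in
*sequence space*: a locus inside one IR copy is mirrored into the other
copy before distances are checked, because the two copies are the same
sequence — two variants at mirror positions would otherwise share flanking
k-mers and merge into a single chimeric contig through no fault of the
assembler.

What the simulator does *not* emulate: indel sequencing errors, quality
ramps, GC or amplification bias, heteroplasmy, and structural variation
beyond single translocations. Passing tests therefore demonstrate
correctness of the method's logic under a clean substitution-error model,
not performance on any particular instrument's error profile.

## Assembly and polishing choices

The assembler builds a doubled-strand de Bruijn graph (every k-mer and its
reverse complement are nodes; coverage is counted canonically) and emits
maximal unambiguous paths, deduplicated by canonical orientation. Nodes
below `min_node_coverage` (default 2) are removed first — this is what
trims single-read contig ends, which is why a contig centred on one
isolated variant comes out slightly shorter than twice the read length
(~90–110 bp with 51 bp reads). At genuine branch points the unitig stops;
there is no greedy extension.

Three further choices matter under sequencing error, where a *recurrent*
miscall (the same wrong base in two or three reads) passes the absolute
coverage floor:

* **Assembly word size.** A node survives only if sampled error-free at
  least `min_node_coverage` times. The expected error-free k-mer coverage
  is $C\,(L-k+1)/L\,(1-e)^k$; `choose_assembly_k()` picks the largest odd
  word (up to the counting k) that keeps the Poisson dropout probability
  per node at or below 1%. With error-free reads this is k itself; at a 5%
  error rate with 51 bp reads it steps down to 15. Smaller words would
  invite chance (k−1)-mer collisions between unrelated loci pooled in one
  read subset, so the largest word meeting the dropout bound is used.
* **Branch pruning.** At a junction, a branch at least `branch_ratio`
  (default 3) times weaker than its strongest sibling is treated as an
  error path and removed (together with its reverse-complement twin, so
  the graph stays strand-symmetric). Genuine alternative paths have
  comparable coverage and still stop the unitig.
* **Read coherence.** Two unrelated loci pooled into one read subset can
  share a (k−1)-mer by chance, which would join them into a chimera. Every
  junction between consecutive contig k-mers must therefore be witnessed
  by a (k+1)-mer that actually occurs in a read; contigs are split at
  unsupported junctions.
* **Consensus polishing.** A recurrent miscall can still bridge a
  coverage hole in the true path; the k-mer evidence is missing there but
  the base-level evidence is not. `polish_contigs()` anchors the genome's
  *full* read set to each contig by shared k-mers (offsets are exact
  because the error model is substitution-only), filters alignments more
  than 20% discordant (chance anchors, reads from the other IR copy
  crossing a boundary), and rewrites a base only when the winning base
  holds a 2/3 supermajority over the runner-up among at least 3 votes —
  judged against the runner-up so scattered third-base noise cannot shield
  a correction. The supermajority matters inside inverted repeats, where
  reads from the two copies can contest a column at even odds and an even
  split must never overwrite the assembled base. Finally, contig ends
  are trimmed back to the first run of k columns that are *confident* —
  supermajority support at depth of at least a third of the expected
  coverage, more than any plausible recurrent-error multiplicity — so an
  end extended through a coverage hole by a few erroneous reads is removed
  rather than guessed at.

Validation (`validate_contigs()`) measures best local-alignment identity
(matches / alignment columns, both strands) with an exact-substring fast
path, and treats circular genomes correctly by padding the origin. The
problem sizes used throughout the tests — 4 genomes of 100 kb, ~50
variants per terminal branch, 3 seeded replicates per error condition —
keep a full validation run in the low minutes on one core while matching
the genome architecture the method targets.

## Group selection in the pipeline

`run_pipeline()` assembles tip contigs for every genome and group contigs
for a configurable set of groups: an explicit list, the taxonomically
congruent groups of a supplied taxonomy (every taxon's sampled-descendant
set with ≥ 2 members, deduplicated — nested taxa with identical sampled
leaves collapse), or, by default, every *observed* exclusive membership
carrying at least `min_group_kmers` k-mers. In observed mode the group
containing all genomes is excluded: its k-mers are the unpartitioned
conserved backbone, and recruiting them would amount to whole-genome
assembly, outside the localized scope of the method (in broad real
panels that group is tiny anyway — deeply divergent genomes share almost
no exact k-mers).

With sequencing error, observed memberships also include *dropout* groups:
a conserved k-mer that fell below the frequency threshold in some genomes
appears exclusive to the rest. Their contigs are ordinary conserved
sequence and validate cleanly; they inflate group counts but not error
rates. Filtering on `min_group_kmers` (default 100) keeps the group list
dominated by genuine shared variation.

## Degenerate inputs and numerical conventions

* k must be odd everywhere: an even-length word can equal its own reverse
  complement, which would make the canonical choice ambiguous.
* Windows containing `N` are skipped; other ambiguity codes are rejected.
* Ledger coordinates are 0-based with half-open intervals; genome region
  tables use the same convention.
* All tables are sorted with byte-order (C-locale) collation, and
  sortedness is a guarantee of the on-disk k-mer table format — reading an
  out-of-order table is an error, never a silent re-sort.
* Every random step takes an explicit seed, and `run_pipeline()` derives
  per-stage seeds from one master seed, so a configuration reruns to
  byte-identical outputs.

## Known limitations

* The assembler targets small localized read subsets; it is not a
  whole-genome assembler and has no paired-end scaffolding.
* Polishing relies on the substitution-only error model for exact-offset
  anchoring; indel-rich reads would need gapped alignment.
* Span formulas assume non-repetitive flanks; in repetitive context the
  brute-force window count (which the package also provides) is the ground
  truth, and collisions can only reduce the count.
* Reproducing published full-panel figures (the 174-genome regression
  constants, panel-wide group counts) requires the original genome set and
  its taxonomy table, which are not bundled; the operations to recompute
  them are all exported.
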