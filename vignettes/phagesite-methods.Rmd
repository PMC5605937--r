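---
title: "phagesite: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagesite: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phagesite)
```

# The assay and its computational model

Temperate phages integrate into the host chromosome by integrase-mediated
site-specific recombination. Essentially all events use the canonical
attachment site (attB), but the integrase also acts, at roughly
100-1000-fold lower frequency, on *secondary* sites that resemble the att
core sequence. A junction-enrichment library reads out these events
directly: genomic DNA from infected cells is fragmented, and nested PCR with
a biotinylated phage-specific primer selects fragments containing the
host-phage junction. After sequencing, read 1 of an informative pair is

```
[45-nt constant phage anchor][7-nt strand-exchange overlap][host flank ...]
```

and read 2 is the reverse complement of the distal fragment end. The 7-nt
overlap is the region physically exchanged during recombination: its
sequence is identical in attP and the target, so it cannot be attributed to
phage or host and is trimmed before mapping. The coordinate we call *the
site* is the first base of that overlap on the integration strand.

`phagesite` implements the full analysis as composable stages (filter, map,
call, motif, guides) plus a simulator that generates libraries with a known
ground truth, so that each stage's contract is testable end to end.

# Filtering cascade

Order of operations per read pair (all defaults are the published assay
thresholds):

1. exact substring search for the 45-nt anchor in read 1 — a single
   mismatch disqualifies the pair (`no_anchor`). First occurrence wins on
   the (astronomically unlikely) event of two occurrences. Bases 5' of the
   anchor are primer/adapter slop and are discarded with it.
2. 3' quality trimming of the remnant: iteratively drop the terminal base
   while its Phred score is `< qmin` (10) **or** the current mean is
   `< qavg` (15). The published description fixes both thresholds but not
   the exact algorithm (single pass vs. iterative); we chose the iterative
   rule because it is the weakest rule that guarantees both exit conditions
   (terminal >= qmin, mean >= qavg) on the retained prefix. A remnant
   trimmed to nothing is `low_quality`.
3. removal of the first 7 (`overlap_trim`) bases — the strand-exchange
   region.
4. length gates: host remnant >= 16 nt and read 2 at least 20 nt, of which
   exactly the 5' 20-nt prefix is used (`too_short` otherwise). Read 2 is
   deliberately not quality-trimmed: the upstream description applies the
   quality rule in the read-1 context only, and specifies read 2 purely as
   its 20-base 5' prefix.

With a 2x75 bp run this yields remnants of 16-23 nt (75 - 45 - 7 = 23 when
nothing is quality-trimmed).

# Mapping

Queries are 16-23 nt (read 1) and 20 nt (read 2) under a >= 95% identity
contract, so at most `floor(L * 0.05)` = 0 or 1 substitutions are
admissible and *no indel can survive the cutoff* at these lengths; the
aligner is therefore ungapped by construction, and identity is defined over
query length. The implementation is seed-and-extend in C++:

* candidate generation uses internal 8-mer seeds with pigeonhole chunking —
  the query is split into `m + 1` contiguous chunks (`m` = tolerated
  mismatches); any admissible hit leaves one chunk exact, whose leading
  8-mer is then an exact seed. A single fixed 12-mer seed would provably
  miss 1-mismatch hits on 20-23-mers (a mismatch at query positions 9-12
  intersects every 12-window), which is why the exported `build_index()`
  k=12 table is a lookup/diagnostic contract rather than the mapper's
  internal seed. The chunked 8-mer scheme is lossless for the m <= 1 domain;
  identities below ~0.9 on short queries would need m >= 2 and are outside
  the guarantee (the tests pin the default contract against a brute-force
  full scan).
* extension is a full-length comparison with early bailout; N in the genome
  counts as a mismatch (conservative).
* `ref_start` is the forward-genome coordinate of the query's *5'-most*
  base — the right end of the aligned interval for minus-strand hits. This
  makes the junction inference symmetric: site = `ref_start - 7` (+) or
  `ref_start + 7` (-).
* pair concordance requires opposite strands in forward-reverse orientation
  with fragment span <= `max_insert` (1000 nt, circular-aware). `unique`
  means exactly one concordant pairing maximises summed identity; ties are
  `ambiguous` and are *discarded* from site calling — repeats (e.g. rRNA
  operons) must not spawn phantom sites. The upstream method does not state
  its multi-mapper policy; discarding is our conservative substitute and is
  counted in the run summary.

The genome is treated as circular by default: subsequence extraction,
mapping, span arithmetic and window extraction all wrap modulo the genome
length, so sites near the origin coordinate are handled exactly.

# Site calling

Junctions sharing (position, strand) merge into one site; the merge
tolerance defaults to 0 nt because the 7-nt trim already normalises the
junction register and the assay reports discrete unique sites (tolerance is
configurable for error-tolerant runs; with tolerance > 0 the representative
coordinate is the member with most reads, leftmost on ties, and clusters do
not wrap across the origin). `detection_frequency` is the number of
replicates contributing >= `min_reads` reads (default 1 — the upstream
method applies no per-site depth filter). attB is supplied by the caller
(or auto-detected as the single highest-read site); sites within +/-10 nt
of it are flagged attB, and

```
ratio_secondary_to_attB = secondary reads / attB reads
```

is the headline statistic. In the simulator the attB-vs-secondary choice is
made per read with probability `f/(1+f)`, which makes the *ratio* estimator
target `f` exactly.

Gene-context categories: a site inside any CDS span is `within_gene`;
otherwise the nearest gene (by distance to its closer boundary) decides
`upstream`/`downstream` in the gene's own orientation within `near_window`
(500 nt — a typical bacterial promoter/terminator scale, our choice since
the upstream work defines the categories but no distance cap), else
`intergenic_far`. Coding regions default to CDS features; rRNA features are
retained separately because integrations in rRNA operons are the known
repeat-ambiguity failure mode.

# Motif analysis

29-base windows (labels -14..+14, 0 = first overlap base) are read on the
integration strand; the published motif labels positions -10..+6 without
fixing the full register, so we centre symmetrically on label 0 and keep the
offsets configurable. Windows containing N are excluded from matrix
building and score as NA. The matrix uses pseudocount 1 per base and
log2-odds against the genome base composition (neither is stated upstream;
both are standard PSSM practice). Information content is
`2 + sum_b f log2 f` bits on the pseudocounted frequencies, so an invariant
column scores 2 bits only at pseudocount 0; the degenerate `0 log 0` term
is defined as 0.

The genome scan scores every window start on *both* strands (integration
shows no strand bias, and whether the published scan used one or two
strands is unstated; two-strand is our default), reporting the mean as the
genome baseline, the full histogram, and the top-scoring windows *not* in
the catalog — the "high score but never detected" set. Relative site
scores subtract the catalog mean, so their catalog-wide mean is 0 by
construction and ranking is unchanged.

# Guide design

For a chosen site, every 20-nt protospacer with NGG immediately 3' (either
strand) whose protospacer+PAM interval lies within +/-30 nt of the site is
enumerated. Integration splits the host sequence at the overlap region and
both resulting junctions retain the overlap itself, so a protospacer is
destroyed in lysogens only if it has at least one base strictly on each
side of the 7-nt overlap — this interval reading of "spans the junction" is
slightly stricter than a midpoint reading and is the biologically correct
disruption criterion. The uniqueness screen counts genome-wide occurrences
(both strands, NGG-adjacent) at up to 2 mismatches — no threshold is stated
upstream; 2 is conservative for a *selection*, where an undetected
off-target kills the cells one wants to keep. Accepted guides are ranked by
distance of the predicted blunt cut (between protospacer bases 17/18, 3 bp
5' of the PAM) to the overlap midpoint; ranking is cosmetic, acceptance is
not.

# The simulator: what it emulates, and what it does not

Defaults describe the assay's stated world: E. coli-like GC (0.508), one
attB plus `n_secondary_sites` secondary sites sampled around a generating
matrix whose constrained positions (T at -1,-2,-3,-5,-6; C at -7,-10; A at
+5,+6; conservation 0.9) mirror the published motif, 8 replicates of 2x75
pairs, secondary read fraction 0.51%, per-cycle mean Phred decaying 38 to
28 (sd 3), substitution errors at 1e-3 on host-derived bases, 5%
anchor-free background pairs, and 1% of junction reads carrying an anchor
mutation (these must fail the filter). Site placement samples uniformly
over non-overlapping window configurations (order-statistics spacing) —
equivalent in distribution to rejection sampling but feasible at high site
counts. Insert sizes are Gaussian (mean 300, sd 50, clamped so read 2 stays
fully host-derived), matching tagmentation-scale fragments.

Deliberately not modelled: PCR duplicates, indel errors, tagmentation
insertion bias, per-cell co-infection structure (the read-level
secondary/attB split suffices for every statistic the pipeline computes),
and calibrated per-site read-depth distributions (the upstream work reports
none, so secondary reads are allocated multinomially, uniform by default
with optional per-site weights). A green simulation test therefore
establishes algorithmic correctness on the stated read anatomy — not
robustness to library artefacts the simulator does not produce. Sites whose
realised read allocation is zero cannot be called; exact-recovery tests
compare against the manifest's *realised* counts, which at the acceptance
scale (>= 15 expected reads/site) leaves dropout probability ~1e-7.

With the default quality profile no base approaches the Q10/Q15 trim
thresholds, so in the error-free acceptance setting no junction read is
quality-trimmed and per-replicate counts can match the manifest exactly;
the trimming code is exercised by dedicated fixtures with degraded
profiles.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive internally (the R/Bioconductor
  convention); only BED output converts to 0-based half-open.
* Frequencies rows are checked to sum to 1 within 1e-9; the relative-score
  centring identity holds to 1e-9.
* Identity tolerance: `m = floor(L (1 - min_identity) + 1e-9)` so that a
  19/20 hit is *retained* at the 0.95 cutoff (the >= is inclusive) and a
  15/16 hit is rejected — the arithmetic the cutoff forces.
* Empty inputs flow through: empty FASTQ pairs give an empty stream, an
  empty catalog writes a header-only TSV and empty BED, an empty annotation
  categorises everything `intergenic_far` with a warning, a replicate of 0
  reads writes valid empty FASTQ.
* One global seed fans out additively to fixed per-stage streams (genome,
  planting, library), so stages are individually reproducible and FASTQ
  output is byte-identical for a fixed seed.

# Known limitations

* The mapper's losslessness argument is tied to the 16-23-nt / >= 0.95
  domain; much longer queries or much lower cutoffs would need a different
  seed plan.
* Merge tolerance 0 means a systematic +/-1 register error in real data
  would split sites; the tolerance knob exists but its clustering is greedy
  and linear, not circular.
* The guide screen counts substitution-only off-targets; bulged (indel)
  off-targets and efficiency scoring are out of scope.
* Multi-chromosome genomes are not supported (first FASTA record only,
  with a warning).
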