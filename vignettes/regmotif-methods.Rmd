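---
title: "Methods: network construction, motif enrichment and tissue conservation"
author: "regmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, motif enrichment and tissue conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmotif)
```

This vignette is the package's own account of what it computes and why
its defaults are what they are. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The model

The object of study is a directed, weighted gene regulatory network with
two edge classes. A *transcriptional* edge TF → gene means the TF has
binding evidence in the gene's promoter region; its weight is the number
of supporting binding sites. A *posttranscriptional* edge miRNA ⊣ gene
comes from a curated target table; miRNA action is assumed repressive,
TF action may be activating or repressing — the motifs analysed here are
purely topological.

Four motif classes built on TF autoregulation are enumerated:

* **M1**: A→A (the minimal negative-feedback oscillator topology);
* **M2**: A→A, A→m, m⊣A (TF–miRNA dual feedback, the HES1/miR-9
  circuit topology);
* **M3**: A→A, A⇄B with B non-autoregulatory (amplified feedback);
* **M4**: A→A, B→B, A⇄B (dual TF feedback).

## 2. Network construction

**CRM filter.** Binding sites that do not overlap a cis-regulatory
module by at least one base pair are removed as likely non-specific
binding. Coordinates are uniformly 0-based half-open (BED convention);
GFF3 input is converted on read and back on write, so abutting intervals
never count as overlapping. Removed peaks are retained for comparison
against candidate regulatory elements
(`intersect_candidate_elements()`).

**TSS assignment.** Each peak is represented by its integer midpoint
`floor((start + end)/2)` — the paper trail behind such pipelines rarely
states whether midpoint, summit, or any-overlap was used; the midpoint
is symmetric and deterministic, and the reference point is a documented
config choice. A TSS is eligible when its strand-oriented window
contains the midpoint: `[TSS − 50000, TSS + 10000)` on the + strand and
the mirror image on the − strand ("upstream"/"downstream" are
strand-relative). Among eligible TSSs the nearest wins; an exact
distance tie between genes goes to the lexicographically smallest
`gene_id` and is reported via a message, so assignment is deterministic
and auditable. Peaks without an eligible TSS are counted as
`n_outside_window`.

**Host inheritance.** A majority of human miRNAs are intragenic, and a
large fraction share their host's transcriptional control. Each miRNA
whose locus overlaps a transcript span inherits a *copy* of every
assignment to the host gene, while assignments to its own TSS are kept;
after collapsing, the TF → miRNA edge weight is the sum of direct and
inherited support. When several transcripts overlap a locus, the host
with the largest overlap is chosen (ties lexicographic).

**Collapse.** One edge per (TF, target gene) across all of the gene's
TSSs; the weight is the number of supporting assignments, so weights sum
to the number of assignments — an invariant the tests enforce.

**Mean filter.** More binding sites at a TSS region are better evidence
of regulation, so for each TF only targets with at least the TF's
average site count are kept. The threshold is made robust in three
steps: compute the per-TF mean and *sample* (n−1) SD of edge weights;
exclude weights more than `outlier_sd` (default 2, two-sided) SDs from
the mean — exclusion affects *only* the threshold, excluded edges remain
eligible for keeping; recompute the mean over the remaining weights and
keep every edge with weight ≥ that mean, compared exactly as real
numbers (no rounding). Sidedness is configurable because the filter's
description in the literature ("> 2 SD of the mean") does not state it;
the symmetric default is the conservative reading. A TF with one edge
keeps it; zero SD skips outlier exclusion. Worked fixtures: weights
{1,2,3,10} give threshold 4 and keep only the 10; weights {1×10, 200}
exclude 200 as an outlier, set the threshold to 1, and keep all 11
edges, the outlier included.

**Trimmed network.** Feedback motifs only involve regulators, so motif
search and randomisation run on the sub-network of edges whose target is
itself a TF (a transcriptional source anywhere in the data) or a miRNA.
Trimming is idempotent.

## 3. Motif counting conventions

Two conventions are genuinely open and are exposed as flags rather than
guessed silently:

* **M3 vs M4 disjointness.** By default an M3 partner must *not*
  autoregulate, so M3 and M4 are disjoint classes matching their
  distinct circuit diagrams; `allow_autoreg_partner = TRUE` reproduces
  the inclusive convention in which every mutual pair with an
  autoregulatory member counts as M3.
* **M4 order.** A dual-feedback circuit is one biological object, so
  unordered pairs are counted once by default; `ordered = TRUE` counts
  both directions.

Every finder is validated against an independently written brute-force
enumerator over all node tuples (100 random networks per run of the
suite), and the containments M2-TFs ⊆ M1-TFs, M4-TFs ⊆ M1-TFs and the
M3/M4 disjointness are asserted as properties.

Autoregulatory and non-autoregulatory TFs are compared
(`degree_comparison()`) on out-degree per target biotype and miRNA
in-degree with two-sided Wilcoxon rank-sum tests: exact when the smaller
group has ≤ 8 observations and there are no ties, otherwise the normal
approximation with tie correction.

## 4. The rewiring null model

Enrichment is assessed against degree-preserving edge rewiring. Edge
classes are randomised independently — a miRNA must never acquire a
transcriptional target. For each class, `ceiling(1.1 × class size)`
swaps are *attempted*: an attempt draws two distinct eligible edges
(a→b, c→d) and proposes (a→d, c→b). Attempts that would duplicate an
existing edge, leave the drawn pair unchanged, or — in locked mode —
create a self-loop are discarded *without retry*; the discarded attempt
still consumes budget. This "attempts, not successes" reading matches a
description in which bad swaps "were discarded" with no mention of
retrying. Sources never change, so per-node in/out degrees within each
class are preserved exactly.

* **Unlocked** mode rewires everything; self-loops may form or vanish.
  This is the null for M1 — the autoregulation count must be free to
  vary.
* **Locked** mode excludes existing self-loops from the eligible pool
  and rejects swaps that would create one, so the self-loop set is
  exactly invariant. It is the null for M2–M4, whose enrichment is
  conditional on the autoregulation backbone (otherwise M1 enrichment
  alone would make every autoregulation-containing motif look
  enriched).

With `r = #{null counts ≥ observed}` (inclusive) among `n` replicates,
`p = (r + 1)/(n + 1)`; the smallest attainable p with 1,000 replicates
is 1/1001 ≈ 0.001. The z-score uses the sample SD of the null counts
and is reported as missing when that SD is zero. Replicate seeds are
derived deterministically from the master seed
(`seed_i = (seed × 69069 + i × 1234567) mod (2^31 − 1)`), so a summary
is bit-reproducible from `(network, config)`. The swap loop is
implemented in C++ (via Rcpp) using R's RNG stream.

## 5. Calibration

Applying the enrichment test to a network drawn from its own null should
give approximately uniform p-values. Two discreteness effects matter and
drove the design of the calibration check in the test suite:

* The motif count is an integer; with the inclusive `≥` convention,
  ties between the observed and null counts push p upward
  (super-uniformity). The distortion scales with the tie probability,
  i.e. inversely with the null count's spread, so calibration is
  checked on a network dense enough that the null M1 count has mean
  ≈ 27 and SD ≈ 4 (70 TFs, TF–TF edge density 0.4).
* A single 1.1×E pass is a *step* of a Markov chain, not an independent
  draw from its stationary distribution. Starting from a network far
  from stationarity (e.g. one with planted enrichment), one step is not
  enough to forget the start. The calibration check therefore pre-mixes
  the base network (30×E attempts) and uses a mixing-adequate budget
  (8×E, at which the measured lag-1 autocorrelation of the count is
  ≈ 0) for both the "observed" draws and the null replicates.

Under those conditions a Kolmogorov–Smirnov test of 200 p-values against
the uniform distribution is not rejected at α = 0.01 in the suite. At
default settings on a strongly non-null network the same machinery
detects planted autoregulation at `p ≤ 0.05` with 200 replicates, while
degree-matched controls drawn from the null are non-significant in at
least 9 of 10 runs.

## 6. Tissue analysis

Datasets (experiment / cell-type labels) are mapped to tissues by an
input table; the full construction pipeline is rerun inside each tissue,
*including recomputation of the mean-filter thresholds* — "recalculated
as above" is read literally, since a TF's binding depth differs between
tissues. miRNA target edges carry no tissue information and are appended
unchanged to every tissue network.

A TF "has data" in a tissue when at least one of its peaks from that
tissue survives CRM filtering — presence of evidence, not survival of
the mean filter. Conservation for a TF with data in ≥ 2 tissues is
`100 × (tissues containing the motif) / (tissues with data)`; TFs with
data in a single tissue are discounted. Three levels are scored: the
self-loop (M1), TF participation in any M2 (M2_tf), and each exact
(TF, miRNA) pair (M2_full).

Tissue similarity uses the standard Jaccard index
`|E₁ ∩ E₂| / |E₁ ∪ E₂|` over transcriptional edges keyed by
(source, target). The phrase "edges unique to each network" sometimes
used for this quantity conflicts with the standard definition; the
standard intersection-over-union is implemented.

When an M2 pair present somewhere is absent from another data-bearing
tissue, the absence is attributed to the missing edge: the self-loop
(`lost_autoregulation`), the TF→miRNA edge
(`missing_tf_mirna_regulation`), or both. The miRNA⊣TF edge can never
be the cause, because posttranscriptional edges are tissue-invariant.
Frequencies are reported relative to all pair × data-tissue
combinations.

## 7. The synthetic-data generator

`simulate_regulatory_data()` emulates the *structure* of the real
inputs, with planted ground truth for recovery scoring:

* **True network.** Each TF autoregulates with probability 0.56 and, if
  autoregulatory, enters a reciprocal miRNA feedback loop with
  probability 0.89 — the observed rates in large human TF compendia.
  Additional Poisson numbers of protein-coding, lincRNA, TF and miRNA
  targets, explicit reciprocal TF pairs (seeding M3/M4), and sparse
  miRNA target sets complete the truth. Planted motif lists are
  enumerated from the true edges.
* **Genome layout.** Genes sit on 200 kb-spaced slots (100 per
  chromosome), so 60 kb promoter windows of neighbouring genes never
  overlap and closest-TSS assignment of true peaks is unambiguous by
  construction. 68% of miRNAs are intragenic, placed 15 kb into a host
  transcript — outside the host's own assignment window — with direct
  miRNA peaks placed strand-downstream of the miRNA TSS, so host and
  miRNA peaks provably assign to their intended targets on both
  strands. 20% of genes get a second TSS 200 bp away to exercise
  gene-level collapse across TSSs.
* **Peaks.** Each true transcriptional edge receives
  `max(1, NB(mean 6, size 5))` peaks — overdispersed, as binding-site
  counts are — placed in the target's window; each TF also gets ~40
  Poisson background peaks of weight ~1 on random promoters, plus ~5%
  of that number in gene-free gaps (outside every window). This
  separation of weight scales is what gives the mean filter its job:
  thresholds land between the background (≈1) and true (≈6) weights.
* **CRMs.** 98.6% of peaks (allocated exactly, not Bernoulli) are
  placed inside CRM zones covering 80% of each promoter region;
  out-of-CRM peaks are placed with a margin so they cannot touch a CRM
  interval, making the in/out labels exact.
* **Tissues.** Each TF has 2 datasets assigned to random tissues
  (default 4), and peaks carry their dataset's tissue.

The same seed yields byte-identical bundles. What the generator does
*not* emulate: sequence content, realistic chromatin domains or peak
shape, correlated TF binding within CRMs beyond co-location, ambiguous
promoter windows (available only via tight gene spacing in custom
configs), tissue-specific miRNA expression, and the heavy right tail of
real per-TF dataset counts. Passing recovery tests therefore show the
pipeline's logic is correct under the stated data model, not that real
ReMap-scale data would yield the same precision.

## 8. Problem sizes and numerical choices

The suite runs at deliberate desk scale: default bundles of ~40 TFs /
~370 genes / ~4,000 peaks (seconds per build), 100 oracle-checked random
networks of ≤ 40 nodes, 20-seed rewiring invariant checks, 200-replicate
calibration and planted-enrichment experiments. End-to-end recovery of
planted M1/M2 instances is asserted at recall and precision ≥ 0.8; at
the default conditions the realised values are typically ≥ 0.9, with
losses dominated by true edges whose negative-binomial peak count lands
at 1, below the TF's mean-filter threshold.

Degenerate inputs are defined behaviour: empty CRM sets remove every
peak; a TF with a single edge keeps it; zero-variance null counts yield
a missing z with a warning; edge classes with fewer than two eligible
edges are returned unchanged with a warning; empty networks produce
empty-but-typed tibbles throughout.

## 9. Known limitations

* Enhancer–gene links beyond the fixed promoter window are out of
  scope; distal regulation is deliberately excluded and quantified only
  via the candidate-element overlap report.
* Motifs are topological; edge sign is not modelled, so only a subset
  of found instances can actually oscillate.
* The empirical p-value is bounded below by 1/(n+1); claims beyond that
  resolution require more replicates.
* The swap-budget reading ("attempts, not successes") makes the
  effective amount of randomisation depend on network density; the
  calibration analysis above is the guard rail.
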