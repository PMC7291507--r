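---
title: "Bi-level regulated proteins and interolog networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-level regulated proteins and interolog networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilevelppi)
```

## The problem

Cyanobacteria such as *Arthrospira platensis* respond to growth-temperature
stress on two levels at once: protein abundance changes (transcription and
translation) and reversible phosphorylation of serine, threonine and
tyrosine residues (signalling, often through two-component histidine
kinases). Proteins regulated on *both* levels — differentially expressed
*and* detected as phosphorylated — are prime candidates for the switching
points of the stress-response cascade; we call them **bi-level regulated
proteins**. Because protein–protein interaction (PPI) data rarely exist for
the organism under study, interactions are borrowed from a better-studied
template species: if two template proteins interact and both have orthologs
in the query species, the ortholog pair is inferred to interact (an
**interolog**).

`bilevelppi` implements that whole chain as small composable stages: signal
filtering and differential testing of three-condition label-free
intensities, phosphopeptide parsing and per-protein site aggregation,
bi-level intersection and reporting, reciprocal-best-hit (RBH) orthology
with Markov clustering, interolog network transfer, and a condition-overlay
network rendering. A synthetic-data generator with planted ground truth
makes every stage testable offline.

## Quantitative proteome stage

The substrate is an `abundance_matrix`: protein × (condition, replicate)
intensities in arbitrary MS units with a per-measurement noise estimate.
The design has three conditions — `LOW` (22 °C), `OPT` (35 °C), `HIGH`
(40 °C) — with three biological replicates each.

**Signal filter.** Intensities strictly below `noise_multiplier × noise`
(default 3×) are set missing; equality is kept. The filter is idempotent
and the number of removed values is logged.

**Differential test.** For each stress condition against the optimum the
fold-change is the ratio of *linear* mean intensities, while the p-value
comes from a two-sided pooled-variance (Student) t-test on *log2*
intensities. Testing in log space is the standard for multiplicative MS
noise; reporting fold-changes on linear means keeps the familiar scale.
Both cut-offs are inclusive: `UP` needs fold-change ≥ 1.5 **and** p ≤ 0.05;
`DOWN` needs fold-change ≤ 1/1.5 and p ≤ 0.05. A protein needs at least two
present replicates per condition to be testable; there is no imputation.
No multiple-testing correction is applied on the headline path (raw
p ≤ 0.05); Benjamini–Hochberg is available via `thresholds(adjust_p =
TRUE)`. A one-group t-test against zero and a three-condition one-way ANOVA
are exposed as reported statistics only; calls always derive from the two
pairwise contrasts.

**Regulation classes.** The pair of calls (LOW contrast, HIGH contrast)
maps deterministically onto nine classes (`UP_UP`, `DOWN_DOWN`,
`UP22_DOWN40`, `DOWN22_UP40`, the four single-condition classes, `NONE`).
`NOT_SIGNIFICANT` and `UNTESTABLE` are treated alike here: both mean "not
regulated in that contrast".

**Clustering.** Expression profiles (per-condition mean log2 intensity) are
clustered by average-linkage agglomeration on Euclidean distances — the
usual companion of an expression heatmap — and can be written as a Newick
dendrogram whose branch lengths are merge heights.

## Phosphoproteome stage

Phosphopeptide evidence uses the lowercase convention: `TIVyKGMVR` with
label `Y237y` means tyrosine 237 (1-based protein coordinate) was
phosphorylated. Parsing cross-validates the number and residue identity of
lowercase marks against the labels; positions are *not* validated against a
protein sequence because peptide start coordinates are not part of the
evidence. Stringency tiers are a metadata filter on the identification's
mass tolerances: the high tier keeps |precursor| ≤ 20 ppm and |product| ≤
50 ppm, the low tier ≤ 50/≤ 100 ppm, so the high-tier set is always nested
in the low-tier set.

Aggregation deduplicates sites by (residue, position) with a union of
detection conditions, counts distinct pS/pT/pY, and counts unique
phosphopeptides by the exact case-sensitive modified string. (In the
packaged worked example the published "unique" column evidently counted
distinct unmodified base sequences instead; we keep the modified-string
rule and do not assert that column.)

## Bi-level intersection

A protein is a bi-level *candidate* when it has phosphosite evidence and a
computed fold-change in at least one contrast; it is *reported* when some
contrast is significant at ≥ 1.5-fold — i.e. its call is `UP` or `DOWN`.
This two-tier rule reproduces the published narrowing from 40 candidates to
31 reported proteins without further guidance. Report rows are ordered by
accession and the totals row is a plain column sum; both are invariant
under permutation of the input rows. The packaged transcription of the
published table (31 proteins, 70 peptide rows) reproduces the printed site
totals exactly: pS = 30, pT = 36, pY = 15, total = 81.

## Orthology stage

BLAST is replaced by exact Smith–Waterman local alignment with affine gaps
(BLOSUM62, gap open 11, extend 1; a length-*g* gap costs `11 + g`), which
is affordable and fully deterministic at desk-scale proteome sizes. Bit
scores and e-values use the Karlin–Altschul form with the published
ungapped BLOSUM62 constants (λ = 0.3176, K = 0.134) and search space
m × n per pair:

\[ \mathrm{bits} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
   E = mn\, 2^{-\mathrm{bits}} . \]

A reciprocal best hit requires each protein to be the other's
highest-scoring hit with both e-values **strictly** below 1 × 10⁻¹⁰; score
ties break to the lexicographically smallest accession, everywhere, for
determinism.

Ortholog groups come from Markov clustering (MCL) of the similarity graph
weighted by −log10 e-value: self-loops are set to each node's maximum
incident weight, the column-stochastic matrix is alternately squared
(expansion) and taken element-wise to the `inflation` power (default 1.5,
the classic OrthoMCL default) with column renormalisation, entries below
`tol = 1e-6` pruned, until stable (`max_iter = 100`; non-convergence
returns the current partition with a warning). Clusters are the connected
components of the limit matrix's support; every node is assigned exactly
once. One practical note: with this self-loop rule, very large inflation
drives every node towards being its own attractor, so the partition
refines towards singletons rather than towards strongest-edge forest
components; the suite asserts the refinement behaviour and checks the
partition against an independent dense reference loop at the default
inflation.

Group confirmation by domain architecture is a multiset Jaccard similarity
of caller-supplied domain tokens: a group is confirmed when every member
pair reaches ≥ 0.5, unknown (`NA`, distinct from `FALSE`) when fewer than
two members have architectures. The 0.5 threshold is this package's
operationalisation of "similar domain structure"; HMM scanning is out of
scope.

## Interolog network stage

Template edges are directed bait → prey. For a template edge (b, p) every
query pair (B, P) with B in b's group and P in p's group is emitted — the
full Cartesian product for many-to-many groups — each carrying provenance
(template edge plus both group ids). Edges with an unmapped endpoint go to
a skip log; with a perfect 1:1 map the number of inferred edges equals the
number of mappable template edges.

Node decoration follows the condition-overlay legend: bi-level proteins are
six-sector circles (upper three sectors = quantitative-proteome detection,
lower three = phospho detection, each ordered HIGH, OPT, LOW left to
right), differentially expressed proteins are grey-bordered rectangles with
temperature strips, everything else a black-bordered diamond. Circle
borders are cyan at ≥ 1.5-fold significant regulation and pink below. Edges
between two circles are green, circle–rectangle edges purple, the rest
neutral; classification ignores edge direction, as does neighbourhood
extraction (`extract_subnetwork`, a breadth-first ball of configurable
radius). Exports: SIF (edges plus isolated-node lines), GraphML with all
typed attributes (round-trips through igraph), and SVG 1.1 with a
deterministic force-directed layout — a fixed seed gives byte-identical
files. Unmapped proteins are drawn as isolated nodes by default
(`include_isolated`).

## Synthetic data: what it emulates, and what it does not

`sim_config()` defaults encode the study design: 3 conditions × 3
biological replicates; log-normal intensities (replicate sd 0.2 log2 units,
the typical label-free spread) around per-protein baselines; 10% of
proteins planted as differentially expressed per contrast with |log2 FC|
drawn from [log2 1.5, 2]; 2% of measurements planted below the 3×-noise
floor; 20% of proteins carrying 1–3 phosphosites whose tryptic fragments
(K/R cleavage, ≤ 2 missed cleavages) are emitted with per-condition
detection probability 0.8; a template proteome of 80 proteins with 80%
planted 1:1 orthologs at 5% residue divergence and background amino-acid
frequencies matching a fixed composition table; and a 60-edge bait → prey
template network. One seed drives everything through a fixed sub-seed
splitting scheme, so identical seeds give byte-identical datasets.

The generator does **not** emulate: peptide-level quantification, retention
time or spectral features, structured missingness beyond the noise floor,
paralog families or domain shuffling, or site-localisation ambiguity.
Passing tests therefore demonstrate the correctness of the pipeline's
logic and statistics under a clean generative model, not robustness to
every artefact of real LC-MS/MS data.

Two deliberate calibration notes. First, recovery at the planted design
point |log2 FC| = log2 1.5 is intrinsically capped: an `UP`/`DOWN` call
requires the *observed* fold-change to reach the inclusive 1.5 cut-off, and
an effect planted exactly at the cut-off falls below it in about half of
replicate draws, so call sensitivity sits near 0.5 regardless of test
power. `evaluate_recovery()` therefore reports both the full-call
sensitivity and a significance-only sensitivity (correct direction at
p ≤ 0.05, around 0.76–0.82 at these settings) so the two effects are
separable. Second, the near-noiseless end-to-end check plants effects from
log2 1.6 upward: the degenerate limit is meant to exercise set logic
(every planted bi-level protein must be reported), which requires effects
strictly inside the reporting region rather than on its boundary.

## Numerical and policy choices

* Thresholds: signal filter strict (`< 3×noise` removed), p and
  fold-change cut-offs inclusive, RBH e-value strict — matching the
  wording each rule comes from.
* Pooled-variance (Student) t rather than Welch; with three replicates per
  group the pooled form is the conventional choice. Zero pooled variance
  degenerates to p = 1 (equal means) or p = 0.
* Fold-changes with a non-positive optimal mean are `UNTESTABLE` with a
  reason rather than infinite.
* All orderings (report rows, RBH ties, MCL group ids, transfer output)
  are lexicographic, so every artefact is reproducible byte for byte.
* Percentages in site-type ratios are rounded to one decimal; their sum is
  allowed the usual rounding slack (99.7–100.3).
* Local-alignment scores are floored at zero (the empty alignment), the
  Smith–Waterman convention.

## Problem sizes used by the checks

The shipped test-and-acceptance workloads use desk-scale sizes chosen to
exercise every code path: 500 proteins for the differential-expression
design point, 100 planted ortholog pairs (proteins of 80–160 residues) for
RBH recall, 30–40 proteins/edges for transfer and end-to-end checks, and
random graphs of ≤ 10 nodes against the dense MCL reference. The packaged
worked example is the published 31-protein table itself.

## Known limitations

* The dataset-level headline counts of the original study (hundreds of
  identified and differentially expressed proteins) require the raw MS
  data from its external repository and are out of scope; the package
  reproduces the in-table worked example and recovery on planted truth.
* E-values use ungapped Karlin–Altschul constants with gapped alignments —
  the standard quick approximation, adequate for thresholding at 1e-10 but
  not a replacement for full BLAST statistics.
* Stringency filtering is a post-search metadata filter; it cannot re-run
  the spectral search.
* Positions in site labels are trusted as protein coordinates; without the
  full protein sequence for each row they cannot be re-derived.
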