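---
title: "Sign-consistency assessment of regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-consistency assessment of regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnsign)
```

# The question

A curated gene regulatory network (GRN) asserts, for each edge, that a
transcription factor (TF) activates or represses a target gene (TG). If
those assertions describe reality, they should leave a footprint in
expression data: when a TF goes up in some condition, its activated targets
should tend up and its repressed targets down. `grnsign` quantifies how
often a signed, directed GRN agrees with a compendium of expression
contrasts, and — because raw counts of contradictions are meaningless
without a baseline — compares the observed disagreement against two
randomized null models.

# The model

## Contrasts and labels

Expression enters as a gene × sample matrix spanning several datasets
(studies/platforms). Two normalization stages are in scope:

* **Quantile normalization**, per dataset: every sample of a dataset is
  forced onto the common distribution given by the row-wise means of the
  column-sorted matrix, ties receiving the mean of the reference values at
  their rank positions. This is delegated to `limma::normalizeQuantiles()`,
  the standard implementation of exactly this rule.
* **z-scoring**, per gene within each dataset, with the sample (n−1)
  standard deviation; constant segments map to 0. This removes per-dataset
  location/scale per gene so heterogeneous datasets can be pooled on one
  scale.

A *contrast* compares a case sample group against a reference group from
the same dataset: `Δ[g, c] = mean(case) − mean(reference)`. The sign
convention "positive = up in the case" is configurable, and every
downstream count is invariant to a global flip.

Contrasts are discretized into ternary labels with a single global
threshold `t`:
`label = sign(Δ)` if `|Δ| > t`, else `0` (unchanged). The inequality is
strict, so a value exactly at the threshold is unchanged; this makes the
monotonicity of labelling in `t` exact. `t` is not chosen by hand: it is
calibrated so that a target fraction `f` of all pooled gene × contrast
values is called deregulated — `t` is the `(1 − f)` quantile (linear
interpolation, R type 7) of the pooled `|Δ|` multiset. The default
`f = 0.5` assumes about half of all contrast values reflect real up- or
downregulation; `f = 1/3` and `f = 2/3` are the conventional sensitivity
settings. Pooling over all genes and contrasts is one of three readings of
"a fraction f of the contrasts" (the others being per-gene or per-column
calibration); it is adopted because it is the only one that yields a single
scalar threshold for the whole compendium, matching the use of one global
threshold throughout.

## The conservative sign-consistency rule

For an edge `u → v` with sign `s ∈ {+1, −1}` and a contrast with labels
`L(u)`, `L(v)`:

* **inconsistent** iff `L(u) ≠ 0`, `L(v) ≠ 0` and `L(v) ≠ s·L(u)`;
* **consistent** iff `L(u) ≠ 0`, `L(v) ≠ 0` and `L(v) = s·L(u)`;
* **indeterminate** otherwise.

The rule is *conservative*: an unchanged endpoint never counts as evidence
against an edge, because regulation may simply not be active in that
condition, and a changed target under an unchanged regulator may be
explained by other regulators. Only definite sign contradictions count.
Each edge is assessed independently; no AND/OR logic combines multiple
regulators of one target. Instead, the report splits all counts by role
(activation/repression) and by single-regulator targets — the subset where
no other regulator can excuse a contradiction.

Aggregates follow the three summary formulas: the **global inconsistency
load** (total inconsistent (edge, contrast) cases), **mEdge** (sum of
per-edge inconsistency counts divided by the number of assessed edges
`nPairs`), and per-category mean correlations **mc** (sum of per-pair
correlations divided by the number of pairs). Edges whose regulator or
target lacks expression data are excluded from `nPairs` rather than counted
as consistent, and reported as dropped.

## Null models

Two empirical baselines, 200 iterations each by default:

* **Profile shuffle** — permute which gene identity owns which expression
  row, keep the topology. Implemented as a row permutation of the label
  matrix, which is exactly equivalent to shuffling the contrast rows and
  relabelling with the original threshold; the threshold is *not*
  recalibrated per iteration (the pooled `|Δ|` multiset is permutation
  invariant, so recalibration would be a no-op anyway).
* **Edge shuffle** — degree-preserving rewiring by double edge swaps:
  replace `(a→x, b→y)` with `(a→y, b→x)`, rejecting swaps that would
  duplicate an existing pair or create a new self-loop. The default burn-in
  is 10 × |edges| accepted swaps, the standard prescription for
  degree-preserving randomization. Signs (and weights) stay attached to the
  regulator's edge slot, preserving each TF's activation/repression
  out-profile — the stricter choice, since only degree preservation is
  essential; an attempt budget guards degenerate topologies (e.g. a
  single-TF star, where every swap is a no-op).

`mGlobal` is the exact arithmetic mean of the per-iteration loads. The
observed load is located in the null by a midrank percentile. Per-iteration
seeds derive from one master seed through a reproducible stream, so null
distributions are bit-reproducible.

## Group comparisons

Perturbed contrasts (stress, knockout, double knockout, overexpression) are
compared with unperturbed (baseline-vs-baseline) contrasts on two
per-contrast statistics: inconsistency load and deregulated-gene count. The
Mann–Whitney U test is computed from midranked rank sums; for combined
n ≤ 16 the two-sided p comes from exact enumeration of all
`choose(n1+n2, n1)` assignments (counting arrangements at least as far from
`n1·n2/2` as observed, which handles ties exactly), above that from the
normal approximation with tie-corrected variance and continuity correction.
The exact-with-ties branch is implemented in the package because
`stats::wilcox.test` falls back to the approximation whenever ties occur;
`wilcox.test` still serves as an independent cross-check in the tests.

# The synthetic world

Real compendia of this kind are assembled from public repositories and
curated network databases; the package instead ships a generator whose
output has known ground truth, so every claim the analysis makes can be
verified mechanically.

## Network generation

TFs are assigned to layers (default 2); each deeper TF is regulated by one
shallower TF, and each target gene draws `1 + Binomial(3, (d−1)/3)`
regulators uniformly from the TF set (default mean in-degree `d = 1.5`).
The result is a DAG. Weights are uniform on `[0.5, 1.5]`.

Signs default to **coherent mode**: each node gets a latent polarity
`p ∈ {±1}` and each edge's sign is `p_u · p_v`. Every directed path between
two genes then carries the same product of signs, so the contributions of
all paths from a perturbed gene to any descendant agree in sign — a
single-gene perturbation world is *exactly* sign-consistent in the
noiseless limit. With independent Bernoulli signs (available as
`coherent_signs = FALSE`) two paths can contradict each other at a shared
descendant and the noiseless load need not be zero; that mode emulates
curated networks, which carry no such guarantee. The polarity probability
is solved from the requested activation fraction
(`q² + (1−q)² = af`, feasible for `af ≥ 0.5`; default 0.6).

A degree template (an existing network) can be supplied instead; its
topology is copied verbatim with fresh signs and weights — an in-silico
twin of an experimental topology, matching how in-silico benchmarks are
modelled on curated networks.

## Expression simulation

Steady-state log-scale expression is linear-Gaussian, computed in
topological order:

```
x_v = basal_v + offset_{v,dataset} + Σ_u  s(u→v) · w(u→v) · x_u + ε,
ε ~ N(0, σ²)
```

with `σ = 0.3` by default. A nonlinear ODE simulator would add realism the
analysis never consumes; the linear form preserves exactly what matters —
sign-faithful propagation plus noise — and stays closed-form testable.
Cyclic networks are supported only through opt-in damped fixed-point
iteration (damping 0.5, tolerance 1e−8, max 500 iterations), so the
default acyclic generator always has a well-defined steady state.

Condition semantics:

* **knockout / double knockout** clamp the biological signal of the
  affected gene(s) at −2 (z-units) before propagation; **overexpression**
  clamps at +2. Measurement noise still applies to clamped genes — a
  knockout sample is still a noisy measurement. The ±2 magnitude
  comfortably exceeds calibrated thresholds and is configurable.
* **stress** shifts the basal level of a random 20% of genes by ±1.5 with
  an independent random sign per gene. Because the shifts act on genes
  directly rather than through the network, stress contrasts carry no
  noiseless-consistency guarantee even in coherent-sign worlds — which is
  deliberate: it keeps decoupled negative controls honest (a
  polarity-aligned stress would fabricate network-free sign agreement).
* **wildtype** groups are unclamped; extra wild-type case groups yield the
  unperturbed contrasts.

The schedule is split across datasets (default 3) with independent
per-gene basal offsets per dataset, so per-dataset z-scoring has real work
to do. Per-dataset defaults: one wild-type reference (4 replicates), two
knockouts, one overexpression, one stress, two extra wild-type groups
(3 replicates each) — 66 samples, 18 contrasts (12 perturbed). Knockout
and overexpression always hit TFs, where a perturbation can propagate.
An optional per-condition noise multiplier (default 1) models noisier
perturbation experiments; the perturbed-vs-unperturbed analyses use 2,
since in an exactly consistent world larger *effects* alone only add
consistent cases.

The **ground truth** is the label sign of the σ = 0 system, computed by
re-propagating every condition with the same design draws and zero noise;
with σ = 0 and any threshold below the smallest nonzero noiseless `|Δ|`,
the pipeline reproduces it entry for entry.

`decouple()` regenerates expression with all weights set to 0 — the same
experimental design with network-independent expression — as the negative
control: its observed load should be a typical draw from both nulls.

# What the tests do and do not show

The test suite verifies, among others: exhaustive-enumeration agreement of
all inconsistency counts on 1000 random instances; exact noiseless
ground-truth recovery over 20 seeds; exact structural contracts of both
nulls (degree profile, sign multiset, node set, row multiset,
bit-reproducibility) over 200 rewiring iterations of a 50-edge network;
that a GRN-driven world's load falls below the 5th percentile of both
200-iteration nulls in ≥19/20 seeds while a decoupled world sits inside
the central 90% in ≥17/20; correlation sign separation
(activation mc > 0.3, repression mc < −0.3 at 66 samples, collapsing below
0.1 in magnitude after shuffling); threshold calibration against the
standard-normal quantile on 10⁵ draws; and exact Mann–Whitney agreement
with full-permutation enumeration for all splits with combined n ≤ 8. The
problem sizes (30 genes, ~33 edges, 18–60 contrasts, 200 null iterations)
were chosen as the smallest worlds in which every effect of interest is
unambiguous; all results above are properties of those generated
conditions.

What passing does *not* show: that any curated network is consistent with
any real compendium. The generator's expression is linear, homoskedastic
within a condition, and free of batch artefacts beyond per-dataset offsets;
real microarray/RNA-seq compendia violate all three, and a curated GRN has
no reason to be sign-coherent along paths. The package measures
consistency; it does not certify it.

# Numerical and degenerate-input choices

* Duplicate edges with the same sign deduplicate silently; conflicting
  signs abort by default or are quarantined (and reported) under a
  permissive flag — the sign model is undefined for dual-role edges.
* Gene identifiers are opaque, case-sensitive strings; no locus-tag
  normalization, to avoid silent mis-joins between files.
* Self-loops are retained and assessed; bacterial autoregulation is common.
* Operon maps are carried as annotation; assessment is always per gene
  (the least lossy reading of per-"TG/operon" reporting).
* Constant expression rows z-score to 0 and are skipped (and counted) in
  correlations; a category with no valid pair reports `mc` as undefined
  (`NA`), never 0.
* Missing values fail loudly by default; per-gene-per-dataset mean
  imputation is opt-in.
* All-zero contrast matrices calibrate to `t = 0` with achieved fraction 0.
* Boundary `|Δ| = t` labels as unchanged (strict inequality).
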