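---
title: "Methods: qPCR normalization, correlation sets and ABCDE conformance"
author: "spikeMADS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR normalization, correlation sets and ABCDE conformance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeMADS)
```

# Scope

spikeMADS implements a transcript-profiling workflow for developmental
RT-qPCR panels, of the kind used to follow MADS-box transcription-factor
expression through cereal inflorescence development: raw quantification
cycles (Cq) are normalized against a reference-gene panel, assays covered
by an overlapping antisense transcript are corrected by subtraction, the
normalized time-course profiles are grouped into co-expression sets by a
Pearson threshold rule, and the floral-organ panel is scored against the
ABCDE model of floral organ identity.  A synthetic-data generator with
known ground truth makes the whole chain testable without laboratory data.

# The measurement model

A reaction with amplification efficiency $E$ (fold change per cycle,
default $E = 2$) relates transcript quantity $x$ to the quantification
cycle by $x \propto E^{-Cq}$.  The generator's forward model anchors
relative expression $1.0$ at `baseCq` (default 22 cycles, an arbitrary
anchor that cancels in normalization):

$$Cq = \mathrm{baseCq} - \log_2 x + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_\mathrm{rep}),$$

with three technical replicates per reaction
($\sigma_\mathrm{rep} = 0.15$ cycles by default, a typical technical
spread).  Expression below a floor of $2^{-15}$ of the gene's maximum is
emitted as a missing Cq — a reaction with no amplification — which
exercises the missing-data path downstream: a missing Cq contributes
relative quantity 0, and no imputation is attempted, because undetectable
transcript is a biological observation, not a missing measurement.

# Reference-gene selection and normalization

"Best matching" references are chosen by a geNorm-style average pairwise
variation: for candidate $i$, the score is the mean over the other
candidates $j$ of $\mathrm{sd}_c\!\left(Cq_i(c) - Cq_j(c)\right)$ across
conditions.  Two candidates that track each other perfectly have constant
difference and contribute 0; the candidate least coherent with the rest
scores worst.  The alternative — ranking by raw Cq variance — was
rejected because it conflates abundance changes with instability.  The
$k = 3$ lowest-scoring candidates (ties broken lexicographically) are
retained; the default panel carries four candidates of which one is
destabilized, and the scoring must rank it last.

Stage and organ samples are normalized as separate batches, and the
references are re-scored and re-selected per batch, since a candidate
stable through a developmental time course need not be stable across
dissected organs.  Per replicate and condition, the normalization factor
is the arithmetic mean of the reference relative quantities ("average
expression" read literally; a geometric-mean switch is available in
`normParams()`), the normalized value is $E^{-Cq}$ divided by that
factor, and replicates are normalized individually before being
aggregated into a mean and standard deviation — the error bars reflect
the spread of the plotted, normalized values.  Normalization is invariant
to any per-condition Cq shift applied to all assays, because the factor
cancels it.

## Antisense-overlap correction

When a gene's genomic span is fully covered by a transcript from the
opposite strand, every primer pair for the target also amplifies the
antisense background.  Given a background-only assay, the corrected
profile is $\max(0, Q_\mathrm{obs} - Q_\mathrm{bg})$ per condition, with
replicate standard deviations propagated in quadrature.  The result is
clipped at 0 because negative expression is physically meaningless.  At
zero measurement noise the correction recovers the generator's true
target profile exactly (to floating-point error), which the tests assert
at $10^{-9}$ relative tolerance.

# The correlation-set rule

Co-expression is quantified by the Pearson correlation of per-gene mean
profiles over the time-course conditions only; the organ panel never
enters set assignment.  Undetected stages enter as 0, matching the
profiles as plotted.  Zero-variance profiles have undefined correlation;
these are stored as missing and can never exceed a threshold.

A correlation set is defined by the rule "every member has $r > \tau$
with at least $m$ other members" ($\tau = 0.9$ strict, $m = 2$).  The
word *members* is read as membership-consistent: partners must themselves
belong to the set, which makes a set a connected component of the
$m$-core of the graph with edges wherever $r > \tau$.  The $m$-core —
iterated deletion of nodes with fewer than $m$ qualifying partners — is
the unique maximal solution and is independent of deletion order, which
the tests verify by exhaustive enumeration of deletion orders on small
graphs.  The looser reading ($\ge m$ partners among all genes) remains
available via `setRuleParams(partnerScope = "all")`.  Components smaller
than `minSetSize = 3` are discarded.  Recovered sets are labelled
`set_1 ... set_K` by ascending mean peak stage, so the earliest-expressed
set is always `set_1`.

## The pseudoset

The pseudoset — a looser group whose members are co-expressed but fail
the strict rule — has no formal published definition ("not as closely
correlated"), so a concrete one is adopted here: among genes left
unassigned, edges are drawn at a secondary threshold $\tau_2 = 0.75$, and
the largest connected component with at least 3 genes (ties broken by
earliest mean peak stage) is the pseudoset.  There is no guarantee that
this choice of $\tau_2$ reproduces any particular published membership;
it is a package design decision, exposed in `setRuleParams()`.

## Hierarchical-clustering cross-check

As an independent look at the grouping, per-gene z-scored time-course
profiles are clustered with Euclidean distance and complete linkage and
the tree is cut at $k$ clusters.  The cross-check
(`crossCheckClustering()`) compares cluster labels with set labels by
adjusted Rand index **on the genes the set rule grouped** (sets plus
pseudoset): ungrouped genes carry no grouping for the two methods to
agree on, and because their z-scored profiles are pure noise they act as
distance outliers that consume clusters without testing anything about
the grouping.  Clustering over all genes is still available directly via
`hierarchicalCluster()`.  Zero-variance genes cannot be z-scored and are
excluded with a warning.

# The synthetic study

The generator emulates a developmental profiling study: 26 target assays
plus 4 reference candidates over the 11 sampled Waddington stages (W1 to
W10.5, the last 3 days post-pollination) and 5 floral organs, 3 technical
replicates each.  Group temporal templates, evaluated on the numeric
stage values:

* **set1** (3 genes, emulating SVP-like floral repressors):
  exponential decline from W1 with half-life 0.5 stage units.
* **set2** (6 genes, floral-organ builders): logistic rise with onset
  near W3.5 (midpoint 5.5, width 0.9), multiplied by a sharp
  post-pollination drop (factor 0.12 after W9.75), so the peak is W9.5.
* **set3** (7 genes, carpel/ovule program): late logistic rise (midpoint
  9, width 0.8), still rising at W10.5.
* **pseudoset** (6 genes): a shared broad bump centred at W2.5 (width
  1.0) on a raised baseline, plus fixed per-gene profile distortions that
  are mutually orthogonal and orthogonal to the bump, with their
  amplitude set so that the noise-free correlation between any two
  members equals a configurable cohesion (default 0.83 — between
  $\tau_2$ and $\tau$).  Unstructured per-gene jitter alone cannot hold
  all 15 pairwise correlations inside the (0.75, 0.9] band across seeds;
  the structured construction makes "loosely co-expressed" a controlled
  property rather than a lucky draw.
* **ungrouped** (3 erratic low-abundance genes plus the antisense kinase
  assay): mutually independent lognormal noise profiles.  The component
  along the pseudoset's shared trend is projected out (and the profile
  re-shifted positive, which Pearson correlation ignores), so that these
  genes are exactly uncorrelated with that trend in truth and act as true
  negatives; without the projection, an erratic 11-point profile crosses
  $r = 0.75$ with some pseudoset member by chance in roughly 7% of
  seeds.

Set members share their template up to a per-gene positive scale
(lognormal, sd 0.3) and multiplicative stage-wise jitter (sd 0.05 for
sets, 0.08 for the pseudoset).  One optional stressor — a late second
expression peak on the first set1 gene, emulating a floral repressor
resurging in the stamens — is off by default because a strong resurgence
breaks that gene's correlation with its set; it can be enabled via
`simConfig(resurgenceEnabled = TRUE)` to study exactly that failure mode.

The reference panel has three stable candidates (between-condition Cq sd
0.15 cycles) and one destabilized candidate (sd 1.2 cycles) that the
stability scoring must exclude.  The overlap pair wires one set2 gene
("PI1") to the kinase background assay ("KIN1"): the PI1 reactions
measure target plus background, and KIN1 is also measured alone.

Organ profiles are drawn from the expectation row of each gene's ABCDE
class (weight 1 on expected organs) with multiplicative lognormal noise
(sd 0.2); non-ABCDE genes get a broad flat profile.  One deviation is
injected by default — C-class weight 0.5 in the lodicules — so the
conformance reporter always has both conforming and deviating genes to
flag.

## What the generator does and does not emulate

It reproduces the *structure* the analysis relies on: log-scale
measurement noise, technical replicates, detection dropout, a destabilized
reference, an antisense-covered assay, and groups whose internal
correlation brackets the rule thresholds.  It does not simulate
amplification curves, melt curves, primer-efficiency differences between
assays, inter-plate calibration, biological replicates, or the mixture of
developmental ages present in a real shoot-apex sample.  Passing tests
therefore show that the pipeline implements its rules correctly and
recovers structure under realistic noise — not that any particular real
dataset would partition the same way.

# Profile summaries and ABCDE conformance

`peakStage()` is the stage of maximum mean expression (earliest stage on
ties); `onsetStage()` is the earliest stage reaching a fraction $f = 0.1$
of the profile maximum.  Both are invariant under positive rescaling, and
onset is non-decreasing in $f$.  All-zero profiles report `"none"`.

`callExpressedOrgans()` binarizes the organ panel at 0.1 of the gene's
organ maximum — a pragmatic cutoff, since published descriptions of
"expressed in organ X" never state one; conformance verdicts may shift
for genes near the threshold.  `classifyABCDE()` compares calls with the
class expectation under the whorl logic (lemma/palea = whorl 1, lodicule
= 2, stamen = 3, carpel = 4): A in whorls 1–2, B in 2–3, C in 3–4, D in
the carpel sample, E everywhere.  By default the E class is split into
its two SEPALLATA subclades — E-LOFSEP expected in lemma and palea,
E-SEP3 in lodicule, stamen and carpel — reflecting the outer/inner-whorl
division of labour observed in grasses; `abcdeExpectation(splitE =
FALSE)` restores the classic undivided E row.  Lemma and palea are not
distinguished in the expectations.  A verdict is `conforming` iff no
organ is unexpectedly called and none expectedly absent; it depends only
on the call sets, never on magnitudes.  Genes outside the model
(`"other"`) are reported descriptively with verdict `n/a`.

# Numerical choices and degenerate inputs

* Thresholds are strict (`>`), so $r = \tau$ exactly is not an edge.
* Correlations are computed on replicate means; undefined correlations
  (zero variance) are missing, never edges.
* Ties: reference selection and set labelling break ties by gene name;
  peak and onset by earliest stage; pseudoset candidates by size then
  earliest mean peak.
* A gene undetected in all replicates of a condition has mean 0 and
  sd 0; subtraction clips at 0.
* Problem sizes used by the test-suite calibration checks: 100–200 seeds
  of the default 30-assay study, chosen to estimate the >= 95% recovery
  and tightness rates with adequate margin while keeping the suite quick.

# Known limitations

* The pseudoset definition ($\tau_2$, largest component) is one of many
  defensible readings of "less cohesive group"; memberships near the
  threshold are sensitive to it.
* The organ-call cutoff (0.1 of organ maximum) is arbitrary in the same
  way; verdicts are only as sharp as the binarization.
* Correlation on 11 stages has wide sampling error; with real data,
  genes with erratic low-abundance profiles may attach to groups by
  chance, as the generator's ungrouped genes demonstrate when the
  decorrelation is disabled.
* Amplification efficiency is fixed at 2.0 for all assays; per-assay
  efficiencies from dilution series are out of scope.

# Session info

```{r}
sessionInfo()
```
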