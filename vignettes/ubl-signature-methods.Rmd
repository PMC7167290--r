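---
title: "Discovering and scoring UbL-conjugation signatures of AML chemoresistance"
author: "UbLsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and scoring UbL-conjugation signatures of AML chemoresistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(UbLsig)
```

## The problem

Acute myeloid leukemia (AML) patients receive an induction chemotherapy of
an anthracycline (daunorubicin, DNR) plus cytarabine (Ara-C), yet 20--30%
do not respond, and no rapid prognostic assay exists at diagnosis.
Dysregulated ubiquitin-family (UbL) conjugation -- ubiquitylation and
SUMOylation -- is a candidate readout of chemoresistance: if an E1/E2/E3
cascade is over- or under-active in resistant cells, the in vitro
modification level of its substrates changes. UbLsig implements the
analysis chain for an assay family that measures exactly this: protein
arrays incubated with cell extracts under conjugation-permissive
conditions, with N-ethylmaleimide (NEM)-treated extracts (all E1/E2
activity blocked) as the no-conjugation background, and a miniaturized
multiplexed bead assay for clinical-scale follow-up.

The package covers: GPR scan parsing; preprocessing (background
correction, duplicate-spot averaging, within-experiment quantile
normalization, cross-experiment batch adjustment); two-stage calling
(robustly modified proteins against NEM controls, then differentially
modified proteins between resistant and parental lines, globally and per
cell line x drug); signature merging; a genetic-algorithm (GA) +
linear-discriminant (LDA) score of chemoresistance; and bead-assay
quantification. A synthetic-data module generates the full study design
with planted ground truth, so every stage is testable without the
original scans (which were never deposited).

## The simulated study

The generator mirrors the discovery design: 3 independent experiments,
each probing HL-60 and U937 as parental, Ara-C-resistant (ARA-R) and
DNR-resistant (DNR-R) sublines plus 2 NEM controls -- 24 two-channel
arrays, each protein spotted in duplicate. The signal model, on the log2
scale, is

```
log2 intensity = baseline + modification effect + differential effect
                 + batch offset + spot noise
```

with the linear-scale value emitted as `2^(log2) + scanner background`.
The per-protein baseline is Normal(9, 1) -- a multiplicative biology term
representing protein-dependent nonspecific binding, present in every
array including NEM controls. Modified proteins gain the modification
effect (default 2.0 log2 units) only in conjugation-permissive arrays;
differential proteins additionally shift by +/- 1.0 log2 units in the
resistant conditions in scope. Batch offsets are Normal(0, 0.5 log2);
duplicate-spot noise is lognormal with CV 0.15; scanner background is
100 +/- 20 a.u. The spot-level noise and background magnitudes are free
parameters of the simulation (the real scans' values are unknown), chosen
once at plausible scanner scales. Default fractions: 10% of proteins
ubiquitylated and 4% SUMOylated (echoing the ~11% ubiquitylated /
~1% SUMOylated split seen on real arrays, with the SUMO set enlarged
enough that recovery statistics are estimable at the default 1,000
proteins -- the real arrays carry >9,000); 10% of each modified set is
differential.

Every stochastic component draws from its own stream derived by hashing
the master seed with a component label (`deriveSeed()`), so output is
bitwise reproducible across platforms and adding arrays or experiments
never perturbs existing draws.

What the simulator does *not* model: spatial artefacts (gradients,
scratches, print-tip effects), enzyme kinetics, saturation, or
correlated substrate families. Passing recovery tests therefore shows
the statistical chain is sound under the stated noise model, not that it
is robust to every failure mode of real scans.

```{r sim, eval = FALSE}
cfg <- simulationConfig(n_proteins = 1000, rng_seed = 1)
sim <- simulateProtoarrayStudy(cfg, dir = "scans")
x <- assembleMatrix(sim$spots, sim$meta)
x <- preprocessChain(x)
```

## Preprocessing

The four steps re-implement the standard protein-array chain:

* **Background correction**: `max(F - B, floor)` per spot, floor 1 a.u.
  so log transforms stay defined.
* **Duplicate averaging**: arithmetic mean of the (at most two) duplicate
  spots; a single surviving duplicate passes through; both missing stays
  missing. More than two sub-rows is treated as a grid violation.
* **Quantile normalization**, within experiment: every array in a group
  is mapped onto the group's mean-of-sorted-values reference. Ties
  receive the mean of the reference values at their rank positions;
  missing values are excluded from the reference and stay missing. The
  implementation agrees with `limma::normalizeQuantiles(ties = TRUE)`
  exactly on complete data (verified in the tests) and is idempotent.
* **Batch adjustment**, across experiments: the default maps each
  batch's pooled log2 median onto the global log2 median -- a monotone,
  rank-preserving, idempotent multiplicative correction. The original
  analysis delegated this step to a package whose internal method is not
  described, so exact equivalence cannot be asserted; an empirical-Bayes
  location/scale alternative (ComBat via \pkg{sva}) is available with
  `batch.method = "eb_location_scale"`.

One consequence worth knowing: quantile normalization pools NEM-control
arrays into the same reference as permissive arrays, which compresses the
upper tail where modified proteins live by 1--2%. This is inherent to
normalizing heterogeneous arrays together (as the assay's standard chain
does) and slightly lowers modification-calling sensitivity near the
intensity floor (see "Detection floor" below).

## Two-stage calling

**Stage 1 -- modified vs NEM.** Per (protein, modifier), intensities on
the 18 permissive arrays are compared with the NEM controls, averaged
within each experiment (one control replicate per experiment). A protein
is called modified when *both* the Welch t test and the
Wilcoxon--Mann--Whitney test give two-sided p < 0.05, the permissive mean
exceeds 800 a.u. (the assay's arbitrary intensity floor), and the
permissive mean exceeds the control mean. The dual parametric +
non-parametric gate guards against the very unequal variances of
permissive vs inhibited conditions.

**Stage 2 -- differential.** For called proteins, each resistant array is
ratioed against the parental array of the same cell line *and the same
experiment* -- pairing within experiment cancels batch effects by
construction. Tests run on log2 ratios against 0 (the raw-vs-log choice
is not documented for the original analysis; log is symmetric in up/down
and is the default here), with the geometric mean as the ratio summary.
The pooled ("global") analysis calls a protein when both the Wilcoxon
signed-rank and the one-sample t test give p < 0.05 and the
geometric-mean ratio is > 1.25 or < 0.8. The per cell line x drug
("separated") analysis has only 3 ratios per comparison, so it uses the
one-sample t test alone with wider gates (> 1.5 or < 0.66). The
signature is the per-modifier union of both analyses; proteins carrying
both modifiers count once in the distinct-protein total. No
multiple-testing correction is applied by default, matching the raw
p < 0.05 convention of the assay; Benjamini--Hochberg is available via
`bhCorrect = TRUE`.

### Detection floor

Under the default simulation conditions the 800 a.u. floor is an
explicit sensitivity ceiling: a planted modified protein needs
`baseline + 2 > log2(800) ~ 9.64`, which a Normal(9, 1) baseline fails
with probability ~9%. Together with the quantile-normalization
compression this caps modification-calling sensitivity at ~0.89--0.91
against the full planted truth, with an essentially zero false-call rate;
the misses are proteins whose absolute signal is below the detection
floor by construction, not test failures. Differential recovery
(sensitivity ~0.85, FDR ~0.04 at the defaults) is measured against the
planted differential set, and inherits the same floor on its modified
parents.

## Statistical tests

The Welch/one-sample/paired t tests, the Wilcoxon--Mann--Whitney test and
the Wilcoxon signed-rank test are implemented in the package and verified
against closed forms and exact enumeration. Small samples use exact
permutation nulls: all `choose(n+m, n)` labelings for the rank-sum test
(tie-free pooled data, n+m <= 16) and all `2^n` sign patterns for the
signed rank (n <= 20, computed by convolution so midranks from ties are
honoured). Larger samples use tie-corrected normal approximations with
continuity correction; at the switch-over sizes these agree with the
exact enumeration to within 0.01. Two-sided exact p-values use the
classical doubled-tail convention, capped at 1. Zero differences are
dropped before ranking (Wilcoxon's original convention). Degenerate
zero-variance t inputs return p = 1 (equal means) or p = 0 (unequal) by
convention. Exact null distributions are memoised per sample size, which
keeps 10,000-replicate calibration runs fast.

## The UbL score

The 23 signature proteins retained for scoring expand to 30 variables
(7 SUMO-only + 9 Ub-only + 7 proteins counted for both modifiers); in
general `expandVariables()` creates one variable per (protein, modifier)
flag. The decision rule is two-class LDA: coefficients
`solve(Sigma, mu_R - mu_S)` over the pooled within-class covariance,
posterior of resistance from the logistic form, and a strict 50% rule --
below 0.5 sensitive, above 0.5 resistant, exactly 0.5 indeterminate (the
rule is defined only by strict inequalities). Because the variable count
can approach the sample count, the pooled covariance is shrunk toward its
diagonal; `shrinkage = "auto"` uses an analytic (Schafer--Strimmer-type)
estimate of the off-diagonal shrinkage intensity.

Variable selection is a binary-chromosome GA (tournament selection,
uniform crossover, bit-flip mutation, elitism) with fitness

```
fitness(S) = cvAccuracy(S) - lambda * |S| / n_variables
```

The original study's custom fitness function is not published; this
cross-validated-accuracy-minus-parsimony form implements its stated goal
of a parsimonious predictive model and is pluggable. The GA is run
`nRuns` times (default 40) with the mutation rate jittered per run and,
for the repeated-split CV scheme, freshly drawn folds per run. The
re-drawn folds matter: with a fixed deterministic fitness every run
converges into the same overfit landscape, whereas run-to-run variation
decorrelates spurious selections so that the *selection frequency* --
the fraction of runs whose best subset contains a variable -- concentrates
on genuinely predictive variables. Variables are ranked by that
frequency (ties broken by marginal single-variable CV accuracy, then
lexicographically) and cut into nested subsets of sizes 4, 7, 11, 17 and
all-selected by default; only the second cut (7 variables, the size the
discovery study found optimal) is anchored by the assay, the others are
uncalibrated defaults. Each subset's cross-validated accuracy is
compared and ties go to the smaller subset.

Numerical/design choices that matter in practice, all set from
identifiability reasoning on simulated cohorts: sparse chromosome
initialization (inclusion probability 0.3) suits selection problems where
the good subsets are small; with repeated-split fitness at p ~ n a
parsimony weight near 0.3 is needed for the penalty to outrank CV noise
(the package default stays at 0.05); and a validation cohort of 30
samples per class is the scale at which a planted 7-variable rule with
Bayes accuracy 0.95 becomes identifiable at all -- at 15 per class some
planted variables realize near-zero in-sample effects and even ranking
by the true marginal t statistics recovers only ~6.3 of 7. The
validation suite uses 12-variable instances (exhaustive search over all
4,095 subsets as the oracle) and 3--10 simulated cohorts; GA fitness
evaluations are memoised per subset, so repeated runs cost little beyond
the first.

```{r score, eval = FALSE}
train <- simulateScoreCohort(nPerClass = 30, seed = 1)
sols <- gaSelect(train$X, gaConfig(nRuns = 16, lambda = 0.3,
                                   cvScheme = list(type = "split",
                                                   train_frac = 0.75,
                                                   n_rep = 4)))
ns <- buildNestedSubsets(sols, X = train$X)
ev <- evaluateSubsets(train$X, ns)
model <- ldaFit(VariableMatrix(train$X@X[, ns$subsets[[attr(ev, "best")]]],
                               sampleLabels(train$X)))
```

## Bead assay

The multiplexed follow-up assay couples signature proteins to color-coded
beads; flow-cytometry events carry two classification channels (bead
color = biomarker identity) and two reporter channels (ubiquitin via
anti-Flag, SUMO-1 via anti-SUMO-1). The chain is: nearest-centroid
region assignment (centroids supplied or estimated by seeded k-means;
events beyond a robust distance gate -- median + 5 MAD by default -- are
left unassigned), median fluorescence intensity (MFI) per (sample,
region, reporter) with the midpoint convention for even counts and a
minimum of 30 events per region, NEM-control subtraction with a 1 a.u.
floor (ratios whose parental denominator sits at the floor are flagged
unstable), resistant/parental ratios, and group comparisons (paired t
for cell-line ratios, Welch for responder vs refractory patients).

Patient flagging -- "high ubiquitylation on at least one biomarker" --
was never defined numerically by the assay's developers; the package
uses an explicit stand-in: biomarker MFI above the responder-group
mean + k SD (k = 2 by default, configurable). The exact-recovery
exact-recovery check in the test suite runs at k = 3, where the expected number of chance
flags in a 39-patient cohort is negligible (at k = 2 the ~2.3% Gaussian
tail makes roughly one chance flag likely, so "exact" recovery would
test the rule's tail probability rather than the pipeline).

## Problem sizes and limitations

The test suite and the reproduction script use 1,000-protein arrays over the 24-array
design (20 seeds for recovery), 12-variable GA instances for the
exhaustive comparison, 30-per-class scoring cohorts, and bead cohorts of
39 patients with 200 events per bead region -- sizes chosen so the whole
validation runs comfortably on a laptop while keeping every statistical
property estimable.

Known limitations: identity-level reproduction of the published protein
lists (988/83 modified, the 122-protein signature, the 16/18 and 4/4
predictions) is impossible because the raw scans were not deposited --
the package validates the *procedure* on planted truth instead; the
batch-adjustment step cannot be proven equivalent to the original
unpublished implementation; sidedness of the original tests is assumed
two-sided; and how patient arrays were normalized relative to cell-line
training data is undocumented -- the package applies the same
preprocessing chain to both.
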