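# UbLsig

Discovery and scoring of ubiquitin/SUMO-conjugation ("UbL") signatures of
acute myeloid leukemia (AML) chemoresistance from two-channel protein-array
experiments, with a multiplexed bead-assay quantification module for
clinical-scale follow-up.

## What it does

AML induction therapy (daunorubicin + cytarabine) fails in 20–30% of
patients, and no rapid assay predicts response at diagnosis. Changes in the
activity of ubiquitin/SUMO E1–E2–E3 conjugation cascades are a candidate
readout: incubating protein arrays with cell extracts under
conjugation-permissive conditions measures, per spotted protein, how much
ubiquitin or SUMO-1 the extract's enzymes attach to it. Extracts treated
with N-ethylmaleimide (NEM, which inactivates all E1/E2 enzymes) define the
no-conjugation background. UbLsig implements the complete analysis:

1. **Array I/O** — GPR (GenePix Results) parsing into a
   `SummarizedExperiment`-based `UbLArraySet` (one intensity matrix per
   modifier channel, duplicate spots as sub-rows).
2. **Preprocessing** — background correction (`max(F − B, floor)`),
   duplicate-spot averaging, within-experiment quantile normalization,
   cross-experiment batch adjustment (log2 median-centering; ComBat-style
   empirical Bayes optional).
3. **Modification calling** — per (protein, modifier), permissive arrays vs
   NEM controls with *both* Welch and Wilcoxon–Mann–Whitney tests at
   p < 0.05 plus an 800 a.u. mean-intensity floor.
4. **Differential calling** — resistant/parental ratios paired within
   experiment and cell line; pooled analysis (signed-rank + one-sample t,
   geometric-mean ratio > 1.25 or < 0.8) and per cell-line × drug analysis
   (one-sample t, ratio > 1.5 or < 0.66); union of both = the signature.
5. **UbL score** — variables expanded per (protein, modifier); binary-
   chromosome genetic algorithm run repeatedly with per-run settings,
   selection-frequency ranking, nested subsets (second subset = top 7);
   linear discriminant score `α·R₁ + … + ω·Rₙ` with shrunk pooled
   covariance; probability of resistance with a strict 50% rule.
6. **Bead assay** — event-level gating to bead regions, median fluorescence
   (MFI), NEM-background subtraction, resistant/parental ratios, Welch /
   paired comparisons, and per-patient high-modification flags.
7. **Synthetic data** — a first-class simulator of the 3-experiment ×
   (2 cell lines × 3 conditions + 2 NEM controls) = 24-array design and of
   bead-event tables, with planted ground truth, so every stage is testable
   (the original raw scans were never deposited).

The statistical tests (Welch/one-sample/paired t, exact and approximate
Mann–Whitney and Wilcoxon signed-rank) are implemented in-package and
verified against closed forms and exact enumeration.

## Worked example

```r
library(UbLsig)

cfg <- simulationConfig(n_proteins = 1000, rng_seed = 1)
sim <- simulateProtoarrayStudy(cfg)
x   <- preprocessChain(assembleMatrix(sim$spots, sim$meta))
x
#> UbLArraySet (protein level): 1000 row(s) x 24 array(s)
#>   modifiers: SUMO1, ubiquitin
#>   experiments: exp1, exp2, exp3; NEM controls: 6
#>   transforms: correctBackground -> averageDuplicates -> quantileNormalize -> batchAdjust

calls <- callModified(x)            # dual-test + 800 a.u. floor
sum(calls$called)
#> [1] 127

rat <- computeRatios(x, calls)
sig <- mergeSignature(callDifferentialGlobal(rat),
                      callDifferentialSeparated(rat))
signatureCounts(sig)
#> $SUMO1
#> [1] 3
#> $ubiquitin
#> [1] 9
#> $distinct_proteins
#> [1] 12
```

127 of the 140 planted modified (protein, modifier) pairs pass the
modification filter (the planted set includes proteins whose absolute
signal sits below the 800 a.u. detection floor by construction), and all
12 signature entries are planted differential proteins (12 of 14 planted
recovered, zero false calls at these settings). Scoring a labeled cohort:

```r
train <- simulateScoreCohort(nPerClass = 30, seed = 1)   # planted 7-variable rule
sols  <- gaSelect(train$X, gaConfig(nRuns = 16, lambda = 0.3,
                                    cvScheme = list(type = "split",
                                                    train_frac = 0.75,
                                                    n_rep = 4),
                                    shrinkage = 0.25, seed = 1))
ns  <- buildNestedSubsets(sols, X = train$X)
ev  <- evaluateSubsets(train$X, ns)
fit <- ldaFit(VariableMatrix(train$X@X[, ns$subsets[[attr(ev, "best")]]],
                             sampleLabels(train$X)))
classifySample(fit, train$X@X[1, names(coef(fit))])
#>    sample probability_resistant     class
#> 1 sample1            0.00719668 sensitive
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ubl-pipeline.R` (subcommands `simulate`, `discover`, `score`,
`bead`).

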