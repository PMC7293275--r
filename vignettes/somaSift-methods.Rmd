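---
title: "somaSift: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somaSift: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somaSift implements the computational path from annotated tumor-only
whole-exome variant calls in benign tissue to somatic risk readouts: hard
filters, somatic-versus-germline classification, platform concordance,
mutational-signature discovery and association, case-control enrichment,
copy-number deletion association, and protein-domain burden risk modeling.
Because the motivating study data (benign breast biopsies from a 135-case /
69-control cohort) are protected, the package ships a fully seeded
synthetic-data generator that reproduces the *statistical structure* of
such a cohort and supplies planted ground truth for recovery tests. This
vignette documents the models, every tunable parameter that matters, the
numerical choices, and what the synthetic experiments do and do not show.

## The synthetic cohort generator

`simulateVariantCohort()` draws, for each of `nCases + nControls` samples
(defaults 135/69):

* **Germline variants** from a cohort-shared pool of polymorphic sites
  (default 600) with population allele frequencies from Beta(0.6, 1.6).
  Carrier status follows Hardy-Weinberg sampling at each site's frequency;
  heterozygous carriers receive a true VAF from a Beta with mode 0.5
  (concentration 100, SD ≈ 0.05), homozygous carriers from a Beta with
  mode 0.97. This produces the characteristic bimodal germline VAF
  histogram near 0.5 and 1.0.
* **Somatic SNVs** (default 180 per sample, matching ≈36,800 substitutions
  over 204 samples) with true VAF from a Beta with mean 0.232 and first
  shape 2.5, which places >95% of its mass below 0.6. The study-scale
  generative targets — mean VAF 0.232 and mean depth 99 — are the
  documented study conditions; the Beta/negative-binomial shapes are our
  choices, since only means are reported. Depth is negative binomial
  (mean 99, size 8), and the observed VAF is `rbinom(depth, trueVAF)/depth`,
  so depth-dependent measurement noise is built in.
* **Trinucleotide channels** for each somatic SNV are drawn from the
  sample's signature mixture `w %*% H0` (below), so variant tables, mutation
  catalogs, and exposures are generated by one coherent model. Half of the
  SNVs are presented on the purine strand to exercise the folding code.
* **Class-dependent annotations**: population frequency (somatic ≈ 0,
  germline common), dbSNP-common flag, somatic-catalog counts, six
  pathogenicity scores with a weak class shift and ~5% missingness,
  variant-class distributions (germline ≈ 66% silent, somatic ≈ 37%,
  mirroring the silent/non-silent contrast expected between the two
  classes), and a PIK3CA p.H1047R hotspot planted at 28% in PDWA versus 5%
  in NP histology.

All generators are pure functions of `(config, seed)`: the RNG state is
scoped and restored, and identical configurations produce byte-identical
outputs.

### Planted signatures and exposures

`defaultSignatures()` provides three 96-channel stand-ins: an aging-like
process (70% of mass on N[C>T]G, the 5-methylcytosine deamination motif),
a mismatch-repair-like process (broad C>T with a C>A component), and an
oxidation-like "O/TN" process (60% of mass on T>G with T[T>G]C the single
largest channel). Two design points deserve emphasis:

* **Sparse supports.** Each stand-in is zero outside a few substitution
  classes, as curated signatures essentially are. This is not cosmetic: a
  planted factorization with strictly positive profiles is not identifiable
  by NMF (rotations of the flat background reconstruct the data equally
  well), so noise-free recovery tests would be meaningless.
* **Dispersed exposures.** Per-sample exposure weights are
  Dirichlet(2, 1.2, 0.8). The low total concentration gives minor
  signatures a coefficient of variation near 0.7 — the strongly skewed
  activity pattern seen in real cohorts, where individual samples are
  dominated by single processes (e.g. mismatch-repair-deficient samples).
  Under weakly dispersed exposures the residual-sum-of-squares curve of
  the factorization has no usable elbow at the true rank, because each
  additional rank absorbs multinomial noise worth more than the weakest
  signature's structure; rank selection from an RSS inflection presumes
  realistic exposure heterogeneity.

TNBC-flagged samples (a `tnbcFraction` = 0.17 subset of cases) have their
O/TN weight multiplied by `exp(tnbcOtnShift)` (default shift 1) before
renormalization — the planted effect the exposure-association analysis is
asked to recover.

### CNV and burden fixtures

`simulateCnvSegments()` emits SEG-convention segments for a CNV-profiled
subset (default 26 samples, the matched-germline subset size): neutral
segments with log2 ratios N(0, 0.05) and, for planted deletion carriers,
focal segments at N(-1, 0.15) covering MLH3 (or PMS2). Deletion carriers
are planted as an exact count, `round(deletionRate * n)`, rather than
per-sample Bernoulli draws, so the fixture's group sizes — and therefore
the power of the downstream Welch test — are stable across seeds. The MMR
exposure baseline is Gamma(shape 9) around the mean attributed MMR count
(CV = 1/3): the fixture emulates a mutational process that is active in
every sample at moderate dispersion, and the planted shift is
`deletionMmrShift` (default 2) population SDs.

`simulateDomainBurdenCohort()` draws per-domain baseline rates from
Gamma(0.4, 20) over 1966 domains (most domains are rarely hit; expected
total ≈ 40 domain-annotated mutations per sample), sets informative
domains (default five) to rate 0.8, and assigns case labels from a
logistic model in which each informative-domain mutation contributes its
configured log-odds (default 1.0); the intercept is calibrated by root
finding so the expected case fraction equals 135/204.

## Hard filters

`buildPon()` implements the conventional panel-of-normals rule: a site
enters the blacklist when observed in at least 2 distinct normals
(`minNormals = 2`), and `applyPon()` removes exact
(chrom, pos, ref, alt) matches — no position-only matching.
`filterDepth()` removes records below 20 total reads; the boundary is
inclusive (depth 20 is retained). Both filters commute and are
property-tested against set-algebra oracles.

## The somatic/germline classifier

`deriveTruthLabels()` reproduces the labeling scheme available when a
matched normal exists: tumor-only calls overlapping the germline call set
are labeled germline, those overlapping the paired somatic call set are
labeled somatic, and calls in neither or both are excluded (counts
reported). `assembleFeatures()` builds the 31-column schema: VAF, three
depth columns, cohort recurrence (distinct carriers of the identical
site), population frequency, dbSNP-common flag, somatic-catalog presence
and count, six pathogenicity/conservation scores, an 8-level
variant-class one-hot, a 6-level pyrimidine base-change one-hot, a
GC-context flag and a homopolymer flag. The exact feature list of the
original analysis is not public; this schema covers the named feature
groups and is declared in one place so real annotations can be mapped in.
Missing numeric scores are imputed with the column median (0.5 when a
column is entirely missing) — a deterministic policy chosen because the
original imputation rule is unstated.

`trainModels()` evaluates seven families — penalized logistic regression
(glmnet), linear SVM, random forest, gradient-boosted trees (xgboost),
k-nearest neighbors, RBF SVM, and a single-hidden-layer perceptron
(nnet) — each over a small fixed grid (≤ 6 points) scored by mean F1
(somatic positive) under stratified five-fold cross-validation on a
stratified 80/20 train/test split; the split fraction is our choice, as
the original is unstated. The best grid point per family is refit and
compared on the held-out split, and the best family is returned with its
standardizer and schema. The perceptron grid uses hidden widths
{8, 16, 32} with at most 150 BFGS iterations: nnet trains full-batch, so
cost grows linearly with width, and for a 31-feature input widths beyond
32 buy no measurable F1 on this problem while multiplying runtime.
Class imbalance is handled by stratification only; every stochastic fit
is seeded, so the whole selection is reproducible from one integer.

## Concordance with genotyping arrays

`overlapRate()` compares platforms over the sites present on both, keyed
by (sample, chrom, pos, ref, alt): the rate is the fraction with
`|AF_wes - AF_array| <= allowance`, with an inclusive boundary (an
allowance of 25% admits a discrepancy of exactly 0.25; inclusivity is our
decision). Sites absent from one platform are excluded from the
denominator. `allowanceSweep()` evaluates a sorted allowance grid, pooled
across samples by default with a per-sample breakdown attached, and is
monotone by construction of the comparison.

## Signature discovery

`buildCatalog()` folds purine-presented substitutions to the reverse
complement and bins SNVs into the 96 pyrimidine-centered channels in
standard order (C>A, C>G, C>T, T>A, T>C, T>G, each with 16 alphabetical
flank contexts). Non-SNVs and records whose context middle base disagrees
with the reference are skipped and counted.

`extractSignatures()` is multiplicative-update NMF under Frobenius loss:
best of `restarts` (default 30) seeded random initializations, at most
2000 iterations, stopping when the relative loss decrease over a 10-step
block falls below `tol` = 1e-6. The objective is non-increasing under
these updates. H rows are normalized to sum 1 with W rescaled so `W %*% H`
is unchanged; W entries are therefore attributed mutation counts.
Associations use these attributed counts, standardized (per-sample
proportions are a supported alternative; the original scaling is
unstated).

`selectRank()` operationalizes "the first inflection of the RSS curve" as
the interior candidate k maximizing the discrete second difference
`RSS(k-1) - 2 RSS(k) + RSS(k+1)`, ties breaking toward the smaller rank;
a degenerate all-equal RSS curve returns the smallest candidate with a
warning. Rank selection uses lighter NMF settings (5 restarts, 500
iterations) than final extraction, since only the RSS trend is needed.

`matchSignatures()` assigns extracted to reference signatures by optimal
bipartite matching on cosine similarity (assignment policy is ours; only
pairwise scores are reported in the motivating work) and flags assigned
similarities below 0.8 as "uncatalogued" — the mechanism by which a novel
planted signature is detected.

## Association tests

`associateExposure()` fits a logistic regression of a binary outcome on
the standardized exposure, optionally adjusted for age, menopausal
status, and histology class, reporting the Wald estimate, 95% CI, and
two-sided p. Perfect separation (non-convergence, |estimate| > 15, or
SE > 100) is reported as such with a ridge-penalized fallback estimate
and no p-value. `exposureGroupTest()` is a two-sided Welch test with
per-group means and t-based 95% CIs; it backs
`deletionSignatureAssociation()`. The statistical test behind the
original deletion association is unstated; Welch is our choice.

## Enrichment and FDR

`perGeneCaseControl()` fits, per gene, a logistic regression of
case/control on mutation status and takes the Wald p; whenever the 2x2
table has a zero cell or the fit separates, a two-sided exact
(Fisher) test replaces it — the original's degenerate-case handling is
unstated. Results carry group fractions, direction, log10 p, BH q
(`bhFdr()` wraps the step-up adjustment), and length-adjusted rates
(mutations per sample per kb) from a supplied gene-length table.
`subgroupEnrichment()` applies the same machinery at gene or
(gene, protein-change) hotspot level, dropping silent variants by
default ("non-silent" = missense, nonsense, frameshift, stop-gain,
splice; the original contrasts silent/non-silent without an explicit
list). `serThrAccounting()` parses `p.S100T`-style changes and counts
serine/threonine gains and losses, a Ser-to-Thr change counting as both a
loss and a gain.

## CNV deletion calls

`callGeneDeletion()` calls a gene deleted when at least `minOverlap`
(default 0.5) of its interval is covered by segments with log2 ratio at
or below `log2Threshold` (default -0.3); both defaults are ours, as no
deletion criterion is stated in the motivating work, and both are
arguments. Segments are reduced per sample before coverage is computed,
making calls invariant to segment ordering and to splitting contiguous
equal-ratio segments. Coordinates are 1-based inclusive (SEG convention).

## Burden risk model

`aggregateDomainBurden()` counts each sample's somatic mutations per
annotated protein domain (multi-domain variants count once per domain).
`bootstrapAuc()` repeats (default 10 times): stratified 7:3 split,
L1-penalized logistic fit on the training split with the penalty chosen
by internal 5-fold cross-validation over a 30-point log-spaced grid in
[1e-3, 1], and AUC on the test split. The report carries per-run AUCs,
their mean, and a 95% percentile interval across runs (the original CI
construction over 10 runs is unstated). Columns are standardized inside
the penalized fit by default; a raw-count mode and clinical-covariate
augmentation are available. Degenerate splits with a single-class test
set are redrawn and counted.

## Problem sizes used by the test suite

The recovery experiments run at the study's generative scale — 204
samples at 180 SNVs per sample for signatures (20 seeds), n = 204 for
exposure association (100 planted + 500 null seeds), 6,000 labeled
variants from the 26-sample matched-normal subset for the classifier,
n = 26 for the CNV association (100 seeds), and 204 x 1966 burden
matrices (20 planted cohorts) — sizes we consider sufficient for stable
property checks at desk scale. The exact-test oracle is verified by full
enumeration over all 2x2 tables with group sizes up to 30.

## What passing tests do and do not show

The synthetic generator reproduces marginal VAF/depth structure,
class-dependent annotation shifts, cohort recurrence, planted signatures,
and planted effect sizes. It does not emulate FFPE deamination damage,
alignment or caller artifacts, linkage between neighboring sites,
realistic annotation correlations, or the partial overlap of real
signature profiles (e.g. curated aging and MMR signatures are
substantially more collinear than our stand-ins). Classifier F1 near 1.0
on synthetic data therefore demonstrates correctness of the selection
machinery, not expected field performance; the motivating study reports
F1 = 0.96 on matched-normal truth data, and no synthetic result here
should be read as reproducing it. Similarly, the cohort table of the
motivating work reports slightly different PDWA/NP counts (75/115) than
its text (76/119); the simulator follows the text.
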