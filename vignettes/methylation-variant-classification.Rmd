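---
title: "Classifying BRCA1 variants from tumor DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying BRCA1 variants from tumor DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclass)
```

## The problem

Clinical sequencing of *BRCA1* regularly turns up variants of uncertain
significance (VUS): missense changes, small in-frame indels, and intronic
substitutions whose effect on cancer risk is unknown. The multifactorial
likelihood framework classifies such variants by Bayesian updating: a prior
probability of pathogenicity derived from sequence bioinformatics is
multiplied (on the odds scale) by likelihood ratios from independent data
sources, and the posterior probability maps onto the five-tier IARC scale
(Class 1, not pathogenic, below 0.001, through Class 5, pathogenic, above
0.99).

Tumors arising in carriers of pathogenic *BRCA1* mutations have a DNA
methylation profile distinguishable from that of *BRCA1*-wild-type familial
("BRCAx") tumors. `methclass` turns that observation into an evidence
channel: it screens methylation array probes for mutation-associated
signal, validates candidate markers, fits a logistic model that converts a
tumor's marker methylation into a probability of the carrier's variant
being pathogenic, and feeds the resulting likelihood ratios into the
multifactorial posterior.

The dominant obstacle is confounding. Estrogen-receptor (ER) status drives
breast-tumor methylation far more strongly than *BRCA1* status does — in
genome-scale screens, ER-associated probes outnumber mutation-associated
probes by orders of magnitude — and ER status is itself strongly
associated with *BRCA1* mutation status. A marker that merely reads out ER
status would double-count evidence already captured by pathology likelihood
ratios. Much of the pipeline exists to detect and remove such markers.

## Pipeline and models

### Quality control

Samples are screened on array control metrics: a sample fails when any
metric lies more than 3 standard deviations from that metric's mean across
samples (`sample_qc()`). Probes are screened on detection p-values: a probe
is discarded when it fails (p ≥ 0.05) in strictly more than 20% of samples
(`probe_qc()`). The boundary case — failing in exactly 20% — is retained.
The per-call detection threshold of 0.05 is the platform convention and is
exposed as an argument.

### Probe screen

`wilcoxon_screen()` runs a two-sided Wilcoxon rank-sum test per probe for
three contrasts: mutation status (BRCA1 vs BRCAx, known-status samples
only), ER status, and grade dichotomized as grades 1–2 vs grade 3. Samples
missing a label are dropped from the affected contrast only. The null
distribution is exact whenever the smaller group has at most 8 samples and
the data are tie-free; otherwise a normal approximation with tie and
continuity corrections is used. p-values are adjusted per contrast by
Benjamini–Hochberg step-up (`bh_fdr()`, delegating to
`stats::p.adjust`).

Candidate markers are probes significant (q < 0.05) in the mutation
contrast but in neither the ER nor the grade contrast (`venn_unique()`),
then filtered to an absolute median methylation difference of at least 5%
(`effect_size_filter()`; a probe exactly at 5% is retained, since only
differences *less than* 5% are excluded). A locus whose targeted CpG
carries a SNP is tested for genotype-by-group association with a Pearson
chi-squared test without continuity correction (`snp_confound_test()`) and
excluded at p < 0.05: allele-frequency differences between groups would
masquerade as differential methylation.

### Consensus clustering

`consensus_cluster()` repeatedly applies k-means (k = 2, Euclidean
distance on beta values) to randomly subsampled sample sets and records,
per sample pair, the fraction of co-subsampled runs in which the two
samples co-clustered; the final partition is an average-linkage
hierarchical cut of one minus the consensus matrix. Defaults are 100
resamples at an 80% subsampling fraction with 10 k-means restarts per
resample — conventional consensus-clustering settings, all exposed as
arguments. Each cluster is labelled BRCA1-like or BRCAx-like by majority
vote of its known-status members (`call_test_samples()`); ties make a
cluster ambiguous, and clusters without known-status members leave their
test tumors uncalled.

### Marker validation

Cross-platform agreement between array beta values and pyrosequencing
percent methylation is measured by the intraclass correlation
(`icc_array_vs_pyro()`). The two-way, single-measure, absolute-agreement
form ICC(A,1) is the default because a systematic scale shift between the
two platforms *should* count against agreement; consistency and one-way
forms are selectable. Pyrosequencing percentages are divided by 100 first
so both raters share a scale. Inter-locus redundancy is measured by
pairwise squared Pearson correlation on pairwise-complete observations
(`pairwise_r2()`).

`independence_glm()` fits three nested logistic regressions — mutation ~
methylation, + ER, + ER + grade — on complete cases only and reports Wald
p-values. The signature of a confounded marker is methylation significant
marginally but not once ER enters the model. Whether methylation enters as
raw percent or rescaled is immaterial for these p-values, so raw percent
is used. Perfect separation is detected from the fitted probabilities
(any fitted value within 1e-8 of 0 or 1), flagged, and the affected
p-values reported as missing; the threshold is deliberately looser than
`glm`'s own end-of-fit check, which does not trigger when iteration stops
early.

### Prediction model

Marker values from known-status tumors are standardized to z-scores using
training means and standard deviations (`zscore_transform()`), and a
maximum-likelihood logistic regression predicts pathogenicity
(`fit_logistic()`). The reference statistics are stored in the fitted
model, so test tumors are standardized against the training distribution
— never their own — which prevents leakage. Markers measurable in too few
tumors are dropped greedily, most-missing first, until every class keeps
at least 5 complete cases (mirroring the removal of a marker that could
not be assayed in enough tumors); the floor is configurable. Under perfect
separation the fit falls back to a lightly ridge-penalized Newton solver
(penalty 0.01 on slopes only) with a warning, keeping coefficients finite.

Performance is estimated by leave-one-out cross-validation (`loocv()`) at
a 0.5 threshold, with PPV and NPV from the standard confusion-matrix
definitions. The z references are recomputed inside every fold by default
(`refit_reference = FALSE` disables this); the alternative—standardizing
folds against full-cohort references—leaks a small amount of held-out
information and is retained only for comparison. Predicted probabilities
are clamped to [1e-12, 1 − 1e-12] so downstream likelihood ratios are
finite.

### Likelihood ratios, priors, posterior, classes

A tumor's probability p becomes a likelihood ratio p/(1 − p)
(`prob_to_lr()`). Only tumors from different individuals are independent,
so `combine_lrs()` multiplies one contribution per individual; when an
individual contributed several tumors the within-individual reducer
(default: geometric mean) yields that contribution, and the range of
combined LRs over single-tumor choices is reported alongside. The
geometric mean was chosen because it is the symmetric, order-free reducer
on the odds scale; published tables in this setting report ranges rather
than naming a reducer, which is why the range is always carried.

The bioinformatic prior (`combined_prior()`) is an explicit override if
present, otherwise the maximum of the missense prior and any splicing
priors. Splicing priors come from calibrated maximum-entropy splice-site
scores: raw scores are standardized against the mean and standard
deviation of wild-type junction scores (`mes_zscore()`), and banded
probabilities apply only when the variant changes the score in the
damaging direction (`splicing_prior()`): for native donors, z < −2 gives
0.97 and −2 ≤ z < 0 gives 0.34; for native acceptors, z < −1.5 gives 0.97
and −1.5 ≤ z < 0.5 gives 0.34; for de novo donors (score-increasing
variants), z > 0 gives 0.64 and −2 ≤ z ≤ 0 gives 0.30. These banded
values are used verbatim; the underlying calibration data are not public,
so the bands are inputs, not estimates.

`posterior_probability()` forms posterior odds = prior odds × LR and
converts back to a probability. `iarc_class()` maps the posterior to the
five-tier scale with edges resolved as: 0.001, 0.05 and 0.95 belong to the
higher class, 0.99 to Class 4 (Class 5 requires strictly more than 0.99).
The published interval notation leaves edges ambiguous; these choices are
centralized in one function and exercised by a grid test that checks the
bands partition (0, 1).

`enigma_guard()` implements the consortium evidence guard: a final Class 1
or 2 requires a combined LR below 0.5, a final Class 4 or 5 a combined LR
above 2.0; otherwise the variant is demoted to Class 3. The guard is off
by default because the methylation-only classification column it would
police is conventionally reported unguarded (a published example assigns
Class 4 at LR 1.43, which the guard would demote); both behaviors are one
flag apart.

## The synthetic cohort generator

No patient data ship with the package; every quantitative claim is
exercised on cohorts from `generate_cohort()`, which emulates the
statistical structure the analysis assumes:

* **Beta values** are drawn from beta distributions parameterized by
  (mean, concentration). Planted effects shift the mean additively and the
  mean is clipped to (0.02, 0.98), which keeps [0, 1] support without
  re-deriving shape parameters. The default concentration of 50 gives a
  per-probe standard deviation of roughly 0.07 at intermediate
  methylation, comparable to array noise in FFPE material.
* **Planted structure**: a small set of mutation-associated probes with
  absolute effects drawn from 0.05–0.30 (the screen's own floor and the
  published effect ceiling), a much larger ER-associated set (default 300
  of 2000, mirroring ER's dominance), very few grade probes, and
  optionally probes carrying both mutation and ER effects (declared
  overlap).
* **Confounding** enters only through the label association: pathogenic
  tumors are ER-negative with elevated log-odds (default 2, which at
  realistic sample sizes reproduces the strong ER-mutation association
  seen in familial cohorts). Methylation effects themselves are additive,
  so any ER signal at a mutation probe in a confounded cohort is genuine
  label-induced confounding, not a generator artifact.
* **The SNP-confounded locus**: one mutation probe's measured signal is
  scaled by C-allele dosage at a CG>TG SNP (minor allele frequency 0.2 in
  wild-type samples, lower in pathogenic samples), so the T allele is
  overrepresented in the BRCAx group and the genotype test excludes the
  locus.
* **Pyrosequencing** values are 100 × beta plus Gaussian noise (default sd
  3 percentage points), clipped to [0, 100], with per-locus missingness
  drawn uniformly from 30–75% and applied completely at random. The
  agreement between platforms in real data varies widely between assays
  and no dropout mechanism has been characterized, so noise and dropout
  are free parameters rather than fitted ones.
* **Grade** is simulated as an independent binary (40% high grade);
  detection p-values plant failing probes that exceed the 20% failure
  rule by construction.

What the generator does **not** emulate: probe-type chemistry and its
normalization, batch effects, spatially correlated CpG blocks,
non-random assay dropout, and tumor-microenvironment covariates. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative assumptions, not field performance on arrays.

## Benchmark conditions and numerical choices

The test suite's recovery benchmark runs the full screen on a cohort of
25 + 25 known-status tumors, 2000 probes, 20 planted mutation probes at
effects of 0.15–0.30, 300 ER probes, and 10 overlap probes, with *no*
ER-mutation label confounding, and requires at least 80% of pure mutation
probes in the final panel with zero leakage of ER-only probes. The choice
to benchmark recovery without label confounding is deliberate: simulation
during design showed that at 25 samples per group even moderate label
confounding occasionally produces near-collinear ER and mutation labels,
in which case the Venn step correctly removes most mutation probes — the
same attrition the genome-wide screen exhibits on real cohorts, where
hundreds of mutation-associated probes reduce to a couple of dozen
ER-independent ones. That behavior is a property of the design under
confounding, not an implementation defect, and it is exercised separately
through the label-association and independence-glm tests; the recovery
benchmark instead isolates the screen's sensitivity and the Venn step's
specificity through planted overlap.

Other numerical choices worth recording:

* Exact rank-sum null only for tie-free data with the smaller group ≤ 8;
  beyond that the normal approximation with continuity correction is
  standard and accurate.
* BH q-values are mapped back to input order by stable sort (ties broken
  by input index).
* Consensus entries for sample pairs never co-subsampled (possible only
  at very low resample counts) default to 0; with the default 100
  resamples at 80% every pair is observed with overwhelming probability.
* k-means resamples that fail to produce k clusters are redrawn up to 10
  times before the run aborts; all-identical samples abort immediately as
  degenerate.
* Problem sizes throughout the suite (2000-probe screens, 50-cohort null
  calibration, n = 400 coefficient recovery, 100-resample clustering) were
  chosen so the full suite and the acceptance script each complete in
  well under a minute on a single core while keeping every stochastic
  assertion comfortably inside its tolerance across seeds.

## Limitations

* The splicing-prior bands are fixed constants taken from an external
  calibration; the package cannot re-derive them, and raw splice-site
  scores must be computed upstream.
* Segregation, co-occurrence, family-history and pathology likelihood
  ratios are accepted as numeric inputs (`extra_lrs`) and multiplied in;
  their derivation is out of scope.
* The within-individual LR reducer is a modelling convention. The
  reported min/max range across single-tumor choices should accompany any
  classification based on non-independent tumors.
* Complete-case logistic fits discard tumors with missing covariates;
  with heavy pyrosequencing dropout the effective sample size for the
  three-way independence model can be half the cohort, and its power is
  correspondingly limited.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- default_pipeline_config(outdir = "run1", seed = 1)
report <- run_pipeline(cfg)
report
```

The run writes every artifact (beta matrix, sample sheet, per-contrast
screen tables, selection JSON, consensus matrix, model JSON, predictions,
classification table, and an md5 manifest) into `outdir`, and the printed
report gives the stage counts: samples and probes passing QC, probes
significant per contrast, panel size after the Venn and effect-size steps,
markers retained in the model, LOOCV accuracy, and the per-variant
posterior table.
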