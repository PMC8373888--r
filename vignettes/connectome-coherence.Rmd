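---
title: "Connectome construction and coherence analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome construction and coherence analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncoh)
```

## The scientific problem

Diffuse glioma is increasingly understood as a whole-brain disease: beyond
the visible lesion, tumor cells migrate along white-matter tracts and the
lesion perturbs both structural and functional brain networks at a distance.
`conncoh` implements a cohort-level analysis of this systemic impact. It
takes *parcellated derivatives* — the outputs of standard diffusion and
resting-state fMRI preprocessing — and asks two questions:

1. **Group differences**: do glioma patients (split by IDH mutation status,
   which separates prognostically distinct tumor types) differ from healthy
   controls in ipsilesional, contralesional and interhemispheric structural
   and functional connectivity?
2. **Connectomic coherence**: within each group, how strongly do the
   hemispheric summaries of one connectivity measure co-vary across
   subjects ("intramodal" partial correlations), and do structural and
   functional measures co-vary with each other ("intermodal")? Loss of
   intramodal coherence is read as large-scale connectomic disorganization.

The package does not touch raw images. Tractography, registration, free-water
correction, nuisance regression and parcellation are upstream, published-tool
stages; `conncoh` consumes their per-subject outputs (or synthetic stand-ins).

## Data model

Per subject, over an atlas of $R$ regions (default $R = 246$, odd ids left
hemisphere, even ids right — the convention of the packaged 246-region
atlas table):

* a symmetric streamline count matrix $N$ ($N_{ij}$ = streamlines connecting
  regions $i$ and $j$; zero diagonal),
* a symmetric per-edge mean fractional anisotropy matrix, defined only where
  $N_{ij} > 0$,
* a $T \times R$ regional BOLD time-series table (default $T = 300$).

Three modality matrices are derived:

* **Edge weight (EW)**: $EW_{ij} = N_{ij} / \tfrac{1}{2}(S_i + S_j)$ with
  region strength $S_i = \sum_k N_{ik}$. Since $S_i, S_j \ge N_{ij}$, every
  edge weight lies in $[0, 1]$; the measure is invariant to uniform count
  scaling, which removes the arbitrary total-streamline scale of
  probabilistic tractography.
* **FA**: the per-edge mean FA, validated and carried as-is (missing where
  no streamline connects the pair).
* **FC**: zero-lag Pearson correlation between regional time series,
  Fisher-z transformed ($z = \operatorname{atanh} r$). "Cross-correlated" is
  implemented at lag zero, the standard resting-state convention implied by
  the Fisher-z step. $r$ is clamped to $\pm(1 - 10^{-12})$ before `atanh` so
  degenerate (collinear) series cannot poison compartment means; clamps are
  reported. Regions with constant signal yield missing rows with a warning.

**Edge mask.** Only region pairs connected by at least one streamline in
*every* control subject are analysis-eligible. The mask is built from
controls only and applied to all subjects and all three modalities. The DMN
analysis applies the same per-edge rule to the DMN-restricted count
matrices, which is identical to restricting the whole-brain mask.

**Hemispheric summaries.** Each masked matrix is reduced to unweighted means
over the intra-left, intra-right and interhemispheric edge sets. Edges
inside the mask but missing for one subject (FA of an absent connection)
are omitted from that subject's mean with a reduced contributing-edge
count; an entirely empty compartment is an error, never a silent gap. For
patients the left/right means are relabelled to ipsi-/contralesional by
lesion side; for controls the mean of left and right serves as the healthy
baseline for both slots. This yields 9 variables per subject:
$\{EW, FA, FC\} \times \{\text{ipsi}, \text{contra}, \text{inter}\}$.

**Outlier correction.** Within each group and variable, values deviating
strictly more than 2.5 sample standard deviations from the group mean are
replaced by the most extreme remaining non-outlier value in the same
direction (a nearest-rank winsorization). The source protocol specifies
replacement by the "worst" group-specific score without defining "worst";
the winsorization reading is a documented package choice, applied in a
single pass with statistics from the uncorrected data.

## Inference

* **Three one-way MANOVAs** (ipsilesional, contralesional,
  interhemispheric), each with DVs $(EW, FA, FC)$ and group
  (control/IDHmut/IDHwt) as factor. The statistic is **Pillai's trace**
  $V = \operatorname{tr}\!\left(H (H + E)^{-1}\right)$ with the standard F
  approximation; for the study's shape ($g = 3$, $p = 3$, $N = 56$) the
  approximation gives $F(6, 104)$, which identifies Pillai (Wilks/Rao would
  give a denominator df of 102). Wilks' $\Lambda$ is carried as a clearly
  labelled secondary statistic. Univariate follow-ups and pooled-error
  Bonferroni post-hoc t-tests (the classical SPSS-style post-hoc: pooled
  within-group error variance on $N - g$ df, raw p times the number of
  pairs, capped at 1) are computed unconditionally but flagged `gated` by
  the omnibus outcome, so reports can reproduce hierarchical reporting
  without hiding results.
* **Coherence profiles.** Per group, all 36 pairwise partial correlations
  among the 9 variables, controlling for age (residual-on-covariates
  definition; $df = n - 2 - k$, two-sided t test). Pairs sharing a modality
  are intramodal (3 per modality), the rest intermodal. Significance uses
  the Bonferroni threshold $\alpha / 9 = 0.0056$ (reported as 0.006),
  matching the nine-variable family; the family size is a parameter. For
  controls the profile uses the raw left/right means by default (their
  natural labels), with the baseline-averaged variables available as an
  option; both feed the same machinery.
* **Dissociation summary.** Counts of significant intramodal pairs split
  into structural (EW--EW, FA--FA; 6 pairs) and functional (FC--FC; 3
  pairs), plus intermodal counts — the reportable form of the
  structural/functional coherence dissociation.

## The synthetic cohort generator

The clinical derivatives the pipeline was designed for are not public, so
the generator is a first-class module that emulates them with plantable
effects. Defaults are the study conditions: 27 controls, 15 IDH-mutant and
14 IDH-wildtype patients; ages normal $46 \pm 14$, $37 \pm 11$ and
$65 \pm 8$ years truncated to $[18, 80)$; left-lesion probabilities 10/15
and 9/14; male probabilities 17/27, 11/15, 6/14; $R = 246$; $T = 300$.

Per subject the generator draws three *mutually independent* standard-normal
latent factors, one per modality. Compartment targets are

$$v_{m,c} = \mu_{m,c} + \delta_{m,c}(\text{group, lesion side})
  + \sigma_m\left(\sqrt{\lambda_m}\, g_m + \sqrt{1 - \lambda_m}\,\eta_{m,c}\right),$$

so that two compartments of one modality correlate at $\lambda_m$ across
subjects while different modalities are uncorrelated by construction —
mirroring the observed pattern of strong intramodal and absent intermodal
correlations. $\lambda$ is therefore parameterized as the *target
inter-compartment correlation* (the factor weight is $\sqrt{\lambda}$);
with the default $\lambda = 0.8$ the realized intramodal correlations sit
in the 0.7–0.9 range reported for healthy controls. Patient groups default
to $\lambda_{SC} = 0$ (structural coherence abolished) and
$\lambda_{FC} = 0.8$ (functional coherence preserved).

Planted group effects (defaults): interhemispheric EW reduced by 15% in
both patient groups; ipsilesional FA lowered by 0.03 in IDH-wildtype;
contralesional FA raised by 0.03 in IDH-mutant. Between-subject scales:
$\sigma_{EW} = 8\%$ (relative), $\sigma_{FA} = 0.02$, $\sigma_{FC} = 0.05$
(Fisher-z). Baselines: FA 0.45 intra / 0.50 inter (callosal fibers are
highly anisotropic), FC $z$ 0.30 intra / 0.15 inter; the EW baseline is
the template's own expected compartment means (about 0.06 intra / 0.05
inter), since EW levels are a property of the wiring, not a free dial.

**Count realization.** A deterministic wiring template connects
same-hemisphere regions within 5 hemisphere-index steps (about 600 edges
per hemisphere at $R = 246$) and three of every four homotopic pairs (93
interhemispheric edges), at Poisson rates 40 and 30; all remaining pairs
carry a diffuse background rate of 1. The background serves two purposes:
it gives region strengths a component untouched by compartment-wise rate
scaling — without it, intrahemispheric edge-weight targets would be
unreachable because EW is scale-invariant — and its edges practically never
survive the all-controls mask ($P \approx (1 - e^{-1})^{27} < 10^{-4}$),
reproducing the sparse surviving-edge structure of real control cohorts.
Per-compartment rate scales are calibrated to each subject's EW targets by
a deterministic fixed point on expected values (30 iterations, scales
clamped to $[0.02, 50]$); empirical recovery error of compartment means is
below 1% bias with ~3% subject-level spread.

**FA realization.** Each connected edge draws FA from a normal centred on
its compartment target (SD 0.08), truncated to $(0,1)$ by rejection;
missing exactly where counts are zero.

**Time-series realization.** An exact two-hemisphere factor construction:
each hemisphere has a common factor, partially shared across hemispheres,
so within-left, within-right and cross-hemisphere correlations equal
$\tanh$ of the targets. This is $O(TR)$ per subject and exact; positive
definiteness requires $r_{inter}^2 \le r_L r_R$, and infeasible targets are
repaired by shrinking the interhemispheric correlation with a warning
(rare at the defaults, where the intra-minus-inter margin is wide).
Correlations are clamped to $[0, 0.95]$; negative compartment targets are
not representable and are floored at independence.

**Seeding.** A master seed draws the demographics and spawns one derived
seed per subject, so cohorts are bit-reproducible and subjects mutually
independent.

## What the simulations show — and what they cannot

The generator reproduces the *mechanisms* the analysis is sensitive to:
compartment-level mean shifts, within-modality latent coherence, Poisson
count noise, finite-T correlation noise, edge-level FA noise, and the
group demographics. It deliberately omits spatial structure (no tumor
geometry, no distance-dependent wiring beyond the template, no regional
heterogeneity of FC), scanner and motion artifacts, neurovascular
uncoupling, and any age effect on connectivity (age is drawn with the
study's group-specific distributions but does not enter the connectivity
model, so age-partialling is exercised but not stressed). Passing recovery
tests therefore demonstrates that the pipeline detects the planted
cohort-level effects at realistic sizes — not that it would behave
identically on clinical data with spatially structured lesions.

Three simulation suites back the package:

* **Calibration** (no planted effects, equal $\lambda$ everywhere, reduced
  size $R = 40$, $T = 120$ for throughput): across 2,000 cohorts the
  interhemispheric MANOVA and a null intermodal partial correlation reject
  at 5.9% and 4.6% at $\alpha = 0.05$ — inside the binomial 99% band.
* **Effect recovery** (50 default-size cohorts): the ipsilesional FA and
  interhemispheric EW univariate effects are detected in every seed.
* **Dissociation recovery**: in ≥ 90% of seeds the control profile shows
  significant structural *and* functional intramodal pairs while both
  patient groups show zero significant structural pairs with functional
  coherence preserved.

These problem sizes (2,000 reduced replicates; 50 and 20 full cohorts in
the test suite and reproduction script) keep the suites proportionate while
leaving the binomial margins meaningful.

## Numerical and design choices

* **Pillai by hand, ANOVA by `stats`.** The multivariate statistic is
  computed from explicit SSCP matrices (and unit-tested against
  `stats::manova` as an independent oracle); univariate ANOVA, chi-square
  and t-distribution tails go through base R.
* **Degenerate inputs.** Isolated regions (zero strength) get zero edge
  weight with a warning; constant time series yield missing FC rows;
  rank-deficient covariates and zero residual variance are errors; a
  compartment with no contributing edges aborts the run naming modality
  and compartment.
* **Outlier rule edge cases.** Values at exactly the threshold are retained
  ("more than" is strict); a zero-variance group has no outliers;
  replacement values never extend the observed range.
* **Control coherence labels.** Controls have no lesion side, so their
  profile correlates the raw left/right means by default; the
  baseline-averaged alternative is one switch away. The choice matters
  little in simulation (left and right share the same latent structure).
* **Determinism.** The analysis path contains no randomness; machine
  outputs (CSV/JSON) are stably ordered, so re-running on the same inputs
  reproduces identical files.

## Known limitations

* The hemisphere coding assumes the odd/even id convention unless the atlas
  table says otherwise; atlases with interleaved schemes must supply their
  own `hemisphere` column.
* The generator's EW lever saturates when a compartment target demands more
  than the template-to-background strength ratio allows (beyond roughly
  ±50% at the defaults); the calibration clamps rather than fails, so
  extreme custom effect sizes are realized only approximately.
* Small groups (< 6 subjects) are excluded from coherence profiling; the
  MANOVA requires every group to exceed the number of DVs.
* p-values are exact under the usual normality assumptions; the pipeline
  applies no permutation or rank-based alternatives.
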