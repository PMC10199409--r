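---
title: "Network-level RSA of person-knowledge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-level RSA of person-knowledge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrsa)
```

## The analysis in brief

Network-level representational similarity analysis (NetRSA) asks how a
*network* of brain regions organises cognition, rather than how voxel
patterns within one region do. The unit of observation is the mean
(baseline-subtracted) beta estimate of each region of interest (ROI) for
each task. With 21 person-selective ROIs and ten person-knowledge tasks,
every subject contributes an ROI x task response matrix. Two similarity
structures are derived from it:

- **cognitive taxonomy** — correlate task columns across ROIs: tasks that
  recruit the network in the same graded way are similar;
- **regional taxonomy** — correlate ROI rows across tasks: regions with the
  same cognitive tuning profile are similar.

Dissimilarity is `1 - Pearson r`, giving entries in [0, 2]. Similarity is
computed *per subject* and averaged across subjects only for clustering and
display; inference always operates on the per-subject values. The group
matrices are clustered with Ward linkage and embedded with classical
(Torgerson) MDS. Hypotheses enter as model RDMs — binary partition models
(0 within a group, 1 between) or empirical matrices from an independent
experiment — and are evaluated by correlating each subject's observed
lower-triangle with the model's, followed by one-sample or paired t-tests
on the resulting per-subject r values.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without any
data download. It emulates the *statistical structure the analysis
assumes*, not fMRI physics:

```
beta(s, roi, cond) = baseline + signal_strength * latent(group(roi), cond)
                     + Normal(0, noise_sd)
```

- The **latent tuning** is a 3 x 3 ROI-group by macro-domain matrix drawn
  once from a standard normal with a fixed internal seed, shared by all
  ROIs of a group. Drawing it per group (rather than per ROI) guarantees
  planted block structure in *both* RDM orientations at once. Using a fixed
  internal seed makes the planted geometry identical across user seeds, so
  recovery properties are stable study-to-study; the user's seed drives
  jitter, subject noise, voxel noise and RT streams through a documented
  offset rule (`sub-seed = (seed + 1000003 * stream) mod (2^31 - 1)`).
- The three **task macro-domains** are memories (episodic + biographical),
  traits (social + physical) and nominal, matching the three families of
  cortical signature the task battery probes. The default **ROI partition**
  mirrors the tripartite subsystem structure of face-cued person-knowledge:
  an internalised/default-mode group (precuneus, vmPFC, dmPFC, ATL, AG), a
  perceptual-prefrontal group (core face regions with IFG and OFC) and an
  anterior-ventral group (ATFP, amygdala).
- **Within-domain jitter** (default 0.1, relative to `signal_strength`)
  makes the two tasks of each knowledge domain similar but not identical:
  the pair shares a domain-level offset, plus a half-sized task-level
  offset, so dendrograms show tight task pairs nested inside macro-domain
  blocks — the qualitative signature of the real data.
- **Control conditions** (two 1-back matching tasks) carry baseline and
  noise but no task signal, so subtracting the famous-name 1-back baseline
  removes them exactly in the noiseless case.
- Defaults: 24 subjects (the study's final sample), `signal_strength = 1`,
  `noise_sd = 0.4` and `baseline_mean = 0.5` — beta magnitudes and a
  signal-to-noise regime giving group-level model-fit effect sizes of
  order d ≈ 1–2, the range reported for this kind of analysis.

Noise is independent Gaussian across ROIs and conditions. The covariance of
subject noise across regions is not constrained by anything the study
reports, so none is modelled; this is the main respect in which passing
tests do *not* certify behaviour on real data, where regional noise is
spatially and physiologically correlated. Scanner physics, motion and
slice-timing are out of scope by design.

The voxel-level generator places isotropic Gaussian blobs (FWHM 12 mm) at
the 21 printed MNI peaks with per-condition amplitudes taken from the same
latent model, plus a localiser statistic map that is suprathreshold at the
peaks. It exists to exercise sphere construction, conjunction and
extraction end-to-end on a 3 mm grid.

## GLM stage

The paper's estimation stage is reproduced at its statistical core:
boxcars at a fine internal step (0.1 s — events of 0.5 s are much shorter
than the 2.5 s TR), convolved with a canonical double-gamma HRF (delays
6/16 s, dispersions 1/1, peak:undershoot 6, unit-peak normalised — the
conventional defaults, since no HRF parameters are printed), sampled at
volume times, with six unconvolved motion regressors and per-run
intercepts. Instruction screens are left unmodelled (the description of the
design does not state they were regressors); drift regressors are off by
default for the same reason. Estimation is plain OLS with a hard rank
check — a collinear column is an error naming the column, never a silent
drop.

## Numerical choices

- **Ward convention.** `hclust`'s `"ward.D2"` (Lance–Williams on squared
  dissimilarities, heights on the original scale) is the default, the
  convention of the common MATLAB/statistical implementations of Ward
  (1963); `"ward.D"` is available behind a flag because the original
  convention cannot be ruled out. Both are checked against a naive
  O(n³) Lance–Williams oracle in the tests. Ties in agglomeration are
  measure-zero for correlation distances of continuous data; `hclust`'s
  deterministic ordering is used as-is.
- **MDS.** Classical (Torgerson) scaling: deterministic, no initialisation
  or stress minimisation. Correlation distances are generally
  non-Euclidean, so negative eigenvalues can appear; they are truncated to
  zero with a warning and reported in the embedding object.
- **Model-fit convention.** Observed *dissimilarities* are correlated with
  model *dissimilarities* (0 within group, 1 between). Correlating
  similarities instead only flips the sign of r.
- **t-tests on raw r.** Group tests operate on the per-subject r values
  directly; a Fisher-z option exists but is off by default, matching the
  one-r-value-per-subject testing convention. Zero-variance samples raise
  an explicit degenerate-variance error. `paired_t(a, b)` is implemented as
  `one_sample_t(a - b)`, making the paired/one-sample identity exact by
  construction.
- **Power.** `power_mde()` root-finds the smallest d with
  `P(T > t_crit) >= power` under a noncentral t with `df = n - 1` and
  noncentrality `d * sqrt(n)`. The exact root for n = 24, one-tailed
  alpha = .05, power = .80 is d = 0.5232. The two-decimal quote is taken
  *conservatively* (`d_2dp = 0.53`): the smallest two-decimal effect size
  whose power actually reaches the target (0.52 gives power .798). Rounding
  down would claim a sensitivity the design does not have. Only the
  one-tailed convention yields a minimal detectable effect of about half a
  standard deviation for this sample size; the two-tailed value is 0.60.
- **Sphere geometry.** MNI mm peaks are mapped through the grid affine;
  distance is measured centre-to-centre in mm and the boundary is
  inclusive (`<= radius`), which reproduces the 81-voxel full sphere for a
  7.5 mm radius on a 3 mm isotropic lattice — consistent with the largest
  printed ROI size. The 1 mm functional slice gap is ignored for synthetic
  grids: the printed ROI sizes are consistent with an isotropic lattice and
  the localiser grid is not specified.
- **Baseline.** The famous-name 1-back condition (not monuments) is
  subtracted, isolating knowledge access from name reading per se.

## Open design points and how they were resolved

- **ROI table oddities.** The printed table lists identical coordinates for
  right FFA and right IFG, and OFC/ATFP x-signs inconsistent with their
  hemisphere labels. The table is loaded verbatim and the loader warns;
  silently "fixing" printed coordinates would manufacture data.
- **Grouping-contrast models.** The biographical-with-episodic versus
  biographical-with-nominal contrast is modelled with the contrasted pair
  of domains merged into one cluster and every other task a singleton
  (between-group dissimilarity 1); only the contrasted grouping is
  specified by the hypothesis, so the neutral singleton treatment avoids
  asserting structure the contrast is not about. The models are
  configurable.
- **Region sets.** Core = OFA, FFA, pSTS (six ROIs); extended = the
  remaining fifteen. The tripartite I/E/C regional model (internalised =
  precuneus, vmPFC, dmPFC, ATL, AG; control = IFG, OFC; ventromedial =
  ATFP, amygdala) ships as a JSON configuration file, not code, so
  alternative memberships can be supplied.
- **Empirical cross-modal models.** In the pipeline, the "face experiment"
  patterns are an independent synthetic replicate (20 subjects, shifted
  seed) averaged across its subjects — the group-average-model convention —
  standing in for an empirical model from a separate cohort.
- **RT control.** The analysis accepts any number of subjects with RT data
  and records the n used, since inferential dfs in such controls can
  legitimately differ from the full sample (missing behavioural data).

## Problem sizes and what the tests show

The test suite runs entirely on synthetic data at desk scale: null
calibration uses 1000 simulated 24-subject datasets (the one-sample
model-fit test's type-I error must sit inside the binomial 95% interval
around .05); planted-structure recovery uses 100 seeds of noiseless data
(adjusted Rand index must be exactly 1 at k = 3); Ward linkage is checked
against the naive oracle on 100 random matrices up to size 7; the power
computation is checked against 50,000-replicate Monte-Carlo simulations of
raw one-sample experiments. These sizes give Monte-Carlo error well below
each test's tolerance. Passing them certifies the machinery — the
estimators, the clustering, the calibration of the inference — under the
generator's assumptions; it does not certify robustness to correlated
regional noise, preprocessing artefacts or hemodynamic model mismatch in
real data.

## Worked example

```{r example}
cfg <- synthetic_config(n_subjects = 8, noise_sd = 0.15, seed = 3)
sim <- generate_subject_betas(cfg)
fit <- netrsa(sim$betas)
summary(fit)

tasks <- person_knowledge_tasks()
macro <- partition_model(tasks$task,
                         structure(tasks$macro_domain, names = tasks$task))
mf <- fit_model_per_subject(fit$task_rdms, macro, "macro_domain")
test_model_fit(mf)

power_mde(n = 24)
```

## Known limitations

- Independent noise across ROIs (see above): real inter-regional noise
  correlations will inflate the similarity of co-fluctuating regions.
- The GLM stage has no autocorrelation model (no prewhitening); its OLS
  betas are unbiased but their standard errors are not used anywhere.
- Classical MDS on non-Euclidean correlation distances discards negative
  eigenvalues; embedded distances are then a lower-rank approximation.
- Partition model RDMs are binary; graded theoretical models must be
  supplied as empirical-style matrices.
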