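---
title: "Methods: simulating and analysing auditory-oddball fMRI with oddbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing auditory-oddball fMRI with oddbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddbold)
```

## The scientific problem

Stimulus-specific adaptation (SSA) — a reduced response to a repeated
standard sound with a preserved response to a rare deviant — admits two
competing explanations. Under *habituation*, neurons simply fatigue with
repetition and recover for any new stimulus. Under *prediction error*,
responses scale with how unexpected each sound is given the listener's
internal model. Ordinary oddball paradigms confound the two, because the
deviant is simultaneously rare and unexpected.

The paradigm implemented here breaks the confound with an abstract rule.
Every trial is a sequence of eight sounds: seven repetitions of a standard
and one deviant that occurs at position 4, 5 or 6 with equal prior
probability, and listeners know this. Expectation therefore follows a
hazard rate that is independent of local stimulus statistics:

* a deviant at position 4 is heard with probability $1/3$;
* if it did not occur there, a deviant at position 5 has probability $1/2$;
* if it occurred at neither, position 6 holds it with certainty.

A standard heard at position 4 or 5 has the complementary probability
($2/3$, $1/2$), and positions 2, 3, 7 and 8 are fully predictable. The
first sound is assigned probability $1/2$, since either member of the
current standard/deviant pairing can open a trial. `predictability()`
implements this hazard; `h2_amplitudes()` is the same function expressed
as a per-position amplitude vector.

The two hypotheses become two amplitude models over the eight positions:

* **h1 (habituation):** the $k$-th standard (counting standards only)
  carries $1/k$ before the deviant and $1/(k-1)$ after it (a one-step
  recovery); the first standard and the deviant carry 1. We follow the
  tabulated vectors, in which post-deviant amplitudes continue the decay
  with a one-step recovery, rather than the looser phrase "position within
  the sequence": the two disagree for post-deviant standards and the table
  is authoritative.
* **h2 (prediction error):** every sound carries its hazard-rate
  probability; the vectors for deviant positions 5 and 6 coincide, because
  position 6 is determined once positions 4 and 5 have passed.

## Design generation

`build_run()` produces one run of 6 blocks x 10 trials. Deviant positions
occur exactly 20 times each and the six standard/deviant pairings (three
pure tones at 1455/1500/1600 Hz, or three FM-sweeps with spans 80/100/-80
Hz) are each used 10 times, with pairing-by-position cells balanced as
evenly as the integers allow (3 or 4). The permutation is rejection-sampled
until no deviant position repeats more than 3 times in a row — a constraint
the original experiments do not state; we chose it to avoid long runs of
identical expectations.

Inter-trial intervals target a Gaussian deviant-to-deviant separation
(mean 5 s, sd 1 s): each gap is solved from a drawn separation minus the
trial span (5.3 s at the 50 ms sound / 700 ms ISI timing) and the
within-trial offsets of the two flanking deviants, then clipped to
[1.5 s, 11 s]. Because the trial span exceeds the target mean, the lower
clip binds frequently and the realised separations sit above 5 s for many
position transitions; this is a property of the published timing itself,
not of the implementation. Null events (silent gaps of one trial length)
are interspersed at a configurable rate, default 10% of trial slots; the
original rate is unstated.

## BOLD simulation

`simulate_run()` turns a schedule into analysis-ready voxel time series on
a labelled grid (`make_roi_grid()`; the default carves eight blocks named
after the bilateral auditory fields Te1.0, Te1.1, Te1.2 and Te3 out of a
20 x 20 x 10 grid). Each ROI's voxels share an evoked component: per sound
an event of amplitude

$$\text{baseline} + \text{slope\_sign} \times \text{gain} \times f(a),$$

with $f(a) = a$ for h1 and $f(a) = 1 - a$ (surprise) for h2 — BOLD is
assumed to increase with unexpectedness; the model comparison is invariant
to this affine choice. Events are convolved with a canonical double-gamma
HRF (peak ~5 s, undershoot ~15 s, unit peak) on a 50 ms microtime grid and
sampled at the TR (defaults 1.6 s for the pure-tone arm, 1.9 s for the
sweep arm).

Noise is AR(1) (coefficient 0.3) plus a slow sinusoidal drift (60 s
period, random phase) plus white noise, in variance proportions
0.5/0.2/0.3, jointly scaled so the temporal SNR (mean over temporal sd)
hits its target — 50 or 30, matching the 7 T and 3 T arms. The original
study does not describe a generative noise model; this is a standard fMRI
approximation. The default gain of 2 against a baseline of 100 corresponds
to a 2% peak signal change, a typical auditory-cortex evoked amplitude at
high field. What the simulator deliberately omits: motion, distortion,
slice-timing effects, physiological cycles, spatial noise correlations and
between-voxel response heterogeneity. Passing tests therefore demonstrate
the correctness and calibration of the analysis chain on idealised data,
not robustness to real-data artefacts.

## First-level GLM

`build_design_matrix()` builds the six task regressors (std0, std1, std2,
dev4, dev5, dev6). std1 and std2 additionally carry a linear parametric
modulator — the within-trial index of the repeated standard, z-standardized
across the run's events before convolution — so that slow within-trial
changes in the standard response are absorbed without committing to a
recovery size. Condition estimates are read from the unmodulated
main-effect columns. Nuisance columns are an intercept, a linear trend and
a discrete-cosine high-pass set up to 1/120 Hz, standing in for the
physiological and motion regressors that are out of scope here. Fitting is
ordinary least squares (`fit_glm()`); the group-level tests downstream are
nonparametric across participants, so serial-correlation prewhitening is
not needed for their validity. Betas are z-standardized per participant x
run x ROI slice (`standardize_betas()`) before second-level analysis.

## SSA detection and quantification

`voxelwise_contrast_test()` computes, per voxel, right-tailed rank-sum
tests across participants (betas first averaged across runs): adaptation
is $\mathrm{std0} > 0.5\,\mathrm{std1} + 0.5\,\mathrm{std2}$ (repetition
suppression) and deviant detection is
$\mathrm{dev4} > 0.5\,\mathrm{std1} + 0.5\,\mathrm{std2}$ (neuronal
mismatch; dev4 because abstract expectation affects it least). The exact
rank-sum null is used whenever the samples are tie-free, otherwise a
tie-corrected normal approximation. Treating participants as the unpaired
sampling unit is our reading of the group-level test; the alternative
(pairing by participant) is not what a rank-sum test implies.

`ssa_conjunction()` forms $P_{SSA} = \max(P_{adaptation},
P_{deviant})$ — a conjunction requiring both effects — applies
Benjamini-Hochberg across all ROI voxels jointly at $\alpha = 0.05$
(per-ROI FDR is available as an option), and reports peak-level
family-wise corrected p-values: Bonferroni by the ROI's voxel count, then
Holm across the eight ROIs. We fixed the Holm family at the ROIs of one
contrast map; the total-comparison count in the source is ambiguous
(possibly 16 = 8 ROIs x 2 contrasts), and the choice only rescales the
peak p-values monotonically. `extract_clusters()` labels connected
components within each ROI under 26-connectivity, with cluster peaks at
the smallest $P_{SSA}$ (ties broken by lowest linear voxel index).

`ssai_map()` computes the SSA index per voxel: dev4, std1 and std2 values
pooled across participants and runs are min-max normalized to $[0, 1]$,
averaged per condition, and combined into
$\mathrm{SSAi} = (d - 0.5 s_1 - 0.5 s_2) / (d + 0.5 s_1 + 0.5 s_2) \in
[-1, 1]$. The normalization scope (pooled across the three conditions and
all participants x runs within voxel) is our resolution of an ambiguity;
pooling guarantees the three condition means share a scale.

## Predictability statistics

Within significant SSA ROIs, `pairwise_tests()` runs Wilcoxon signed-rank
contrasts on per-participant condition means: the ordered deviant
contrasts (dev4 > dev5 > dev6), the effect-size contrasts std0 > std2 and
dev4 > std2, and the two-sided dev6 vs std2 — under prediction error a
fully predictable deviant should be indistinguishable from the equally
predictable post-deviant standards. Zero differences are dropped; the
exact null is used for n <= 25 tie-free samples. Holm correction accepts
an explicit family size (30 and 48 in the two original arms).

`fit_lmm()` estimates `beta ~ 1 + predictability + (1 + predictability |
run) + (1 + predictability | participant)` (plus a session term when
present) by REML with Satterthwaite degrees of freedom, predictability
coded 1/3, 1/2, 1. Observations are voxel x run level deviant betas,
following the very large degrees of freedom reported for the original
group models; singular fits are flagged, never dropped.
`spearman_predictability()` gives the per-participant rank correlation
between predictability and run-averaged deviant betas; with many voxels
tied at three predictability levels, the large-sample approximation is
used.

## Bayesian model comparison

`model_design()` builds, per model, a single amplitude regressor: event
impulses weighted by the model's per-position amplitudes, z-standardized
per run before convolution. Because the amplitudes are centred, the mean
response common to all sounds is carried by a shared unmodulated
all-sounds regressor — the zeroth-order term that always accompanies a
parametric modulation — identical across the two designs, as are the
intercept, trend and cosine columns. Without that shared column the
common sound response is absorbed asymmetrically and biases the
comparison; with it, model recovery is symmetric under profile swap
(tested).

`log_evidence()` is the closed-form marginal likelihood of the linear
model under a conjugate normal-inverse-gamma prior: a unit-information
g-prior ($g = n$) on the centred non-constant columns, a flat prior on the
intercept (integrated analytically on centred data), and
$\sigma^2 \sim \mathrm{IG}(1/2, \mathrm{var}(y)/2)$. Scaling the prior to
the data variance and flattening the intercept make evidence *differences*
invariant to affine transformations of the series, so the comparison does
not depend on arbitrary signal units. The original analysis used a
variational Bayesian estimator with unreported priors; only the relative
comparison under matched priors is meaningful, and an independent
quadrature oracle (coefficients integrated via the Gaussian convolution
identity, the rest numerically) guards the closed form to 1e-6 in the
tests.

Group aggregation (`group_maps()`) produces both the fixed-effects Bayes
factor $K_{h2/h1} = \exp\big(\sum_s \Delta \log E_s\big)$ per voxel (what
the Bayes-factor maps display) and random-effects Bayesian model selection
(`rfx_bms()`): a variational Dirichlet posterior over model frequencies
(prior $\alpha_0 = 1$ per model, convergence tolerance 1e-6), with
expected posterior probabilities $r_k = \alpha_k / \sum \alpha$ and
exceedance probabilities from seeded Dirichlet draws (default $10^6$). A
voxel "favors" h2 when its RFX posterior exceeds 0.5; per-ROI summaries
report the fraction of such voxels and the median $K$.

## Numerical choices and degenerate inputs

* Convolution on a 50 ms microtime grid, sampled at volume times (sound
  duration is far below the TR).
* Rank-sum: exact via the Wilcoxon distribution for tie-free samples below
  size 50; tie-corrected, continuity-corrected normal otherwise.
* Zero-variance standardization slices, constant Spearman inputs and
  zero-denominator SSAi voxels raise errors or are flagged undefined — they
  are never silently imputed.
* Cluster peak ties break to the lowest linear voxel index, making maps
  deterministic.
* `rfx_bms()` refuses non-finite evidences; `fit_glm()` and
  `log_evidence()` refuse rank-deficient designs.
* All randomness flows through explicit seeds; the pipeline fans one
  master seed into per-subject, per-run child seeds, so a report is
  reproducible from its JSON config alone.

## Known limitations

The classical deviant-position analysis is not fully immune to
habituation: the linear modulator only approximates the $1/k$ decay of the
adapted standards, so on purely habituation-generated data a small
negative pseudo-slope of deviant beta on predictability survives the
first level (about a tenth of the gain per unit predictability in
noiseless simulation). The Bayesian model comparison is the analysis that
disambiguates the hypotheses — it recovers h1 and h2 symmetrically in the
swap test — and this is mirrored in what the package's acceptance suite
asserts: a strong negative slope under h2, a much attenuated one under h1,
and symmetric model recovery.

Problem sizes used by the test suite were chosen to exercise the study
conditions at desk scale: the error-control simulation uses 19 simulated
participants and 800 voxels over 200 replicates; recovery cohorts use 10
subjects x 2 runs x 200 signal voxels; the full-pipeline tests run 6
subjects on a 10 x 10 x 4 grid. The cohort sizes of the original arms (19
and 18 participants, 4 and 8-9 runs) are the package defaults in
`pipeline_config()`.
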