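---
title: "Methods: volume-of-activation and connectivity analysis for phMRI dose-response studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volume-of-activation and connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phmriVoA)
```

## The analysis model

A pharmacological-MRI session is a single uninterrupted 4D acquisition
split into two windows: a pre-injection *baseline* and a post-injection
*stimulation* window. All acquisition indices in this package are
0-based with half-open ranges, mirroring scanner numbering; the default
windows are `[0, 50)` and `[50, 150)` on a 150-acquisition run (5 min
baseline, 10 min post-injection at a 6 s repetition time).

Per voxel $v$ the effect measure is percent signal change,

$$\Delta_v = 100\,\frac{\bar{x}_v^{\mathrm{stim}} - \bar{x}_v^{\mathrm{base}}}{\bar{x}_v^{\mathrm{base}}},$$

and the decision statistic is a two-sample comparison of the
stimulation-window samples against the baseline-window samples. The
default is Welch's t (direction-signed, robust to mild variance
differences between windows); pooled-variance t and a normal-approximation
rank-sum are available through the `statistic` argument because the
field has no single convention here. A voxel is categorised *positive*
if $p < \alpha$ and $\Delta_v > 0$, *negative* if $p < \alpha$ and
$\Delta_v < 0$, otherwise *none*. The voxel-level $\alpha$ (default
0.05) is deliberately uncorrected: inference is two-tier, with
multiplicity handled at the region level, so voxel counts behave like a
calibrated per-voxel detector feeding region statistics.

Temporal autocorrelation is not modelled at the voxel level; this is a
known limitation shared with window-mean approaches generally, and the
synthetic generator (below) produces white noise, so calibration results
here do not speak to strongly autocorrelated real data.

### Drift removal

`voxel_test(detrend = TRUE)` removes a linear drift before testing. The
drift is estimated on the *baseline window of the brain-mean trace* and
the fitted slope is subtracted from every voxel. The choice matters:
fitting per voxel on 50 baseline points and extrapolating 100 points
forward carries slope noise of roughly $\sigma/\sqrt{\sum (t-\bar t)^2}
\cdot 75 \approx 0.7\sigma$ into the stimulation mean, which destroys
the calibration of the voxel test. A brain-mean fit averages the slope
estimate over $\sim 10^4$ voxels and is effectively noise-free. The
model behind it — a drift shared across the brain, typical of scanner
warm-up — is exactly what the generator produces; voxel-specific drifts
are out of scope.

### Region statistics

Counting voxels by category inside each atlas label gives the per
subject×region volume of activation (positive and negative counted
separately; identity $n_{+} + n_{-} + n_{\mathrm{none}} = n_{\mathrm{total}}$
is a tested invariant). Across dose groups the package computes, per
region:

- per-dose **medians** (mean-of-middle convention at even n),
- a tie-corrected **Kruskal–Wallis** H with chi-square p at $k-1$ df —
  chosen because VoA tables report medians and the counts are small,
  tied integers; the statistic is pluggable, and a Monte-Carlo
  permutation p (`method = "permutation"`) provides an exact reference,
- **ω²** from the classical one-way ANOVA decomposition of the raw
  counts, clipped to $[0, 1]$ — not rank-based, so it reads as the
  conventional variance-explained measure readers expect next to a p
  column,
- **Benjamini–Hochberg** FDR flags over all regions at $q = 0.05$, with
  the *realized threshold* (the largest passing p) reported in the
  "significance level was $p \le x$" style — that number is a
  data-dependent output of the step-up rule, not an input,
- a **shape label** from the four dose medians.

The shape rule, with separation parameter $\delta$ (default 1 voxel,
because counts are integers): *inverted-U* if the intermediate
(second-highest) dose exceeds all others by $\ge \delta$; *U* if, among
the active doses, the intermediate dose is the minimum and the low dose
the maximum, each by $\ge \delta$; *monotonic* if all four values are
ordered in dose by $\ge \delta$ per step; otherwise *flat*. Checks are
applied in that order, so an extreme inverted-U cannot also be labelled
monotonic.

Macro-region summaries average the per-dose medians over all regions of
a macro-region (forebrain / midbrain / hindbrain) and compare dose pairs
with two-sided Mann–Whitney tests on per-subject region-averaged counts,
uncorrected by default (a `p_adjust` method can be supplied). The
time-course comparison averages all voxels of a region set per subject
and acquisition and fits a two-factor fixed-effects ANOVA
(treatment × acquisition, with interaction) on the subject-level traces;
the treatment main effect has 1 df. With one trace per subject this is a
pragmatic fixed-effects convention, not a repeated-measures model; its
error df depends on the subject and acquisition counts and is not
claimed to match any particular published df.

### Connectivity graphs

Resting-state series are parcellated to region means, correlated
(Pearson) per subject, and combined across subjects by Fisher-z
averaging — the variance-stabilised choice for averaging correlations.
Graphs are built by thresholding the group matrix at $|r| \ge c$
(default $c = 0.3$): binary, undirected, no self-edges; degree is the
incident edge count. Degree comparisons between groups use a paired
two-sided Wilcoxon signed-rank over the member nodes of each subregion
tag; when every member's degree is identical in both graphs the
difference is exactly zero and p is reported as 1.

The composite-node analysis merges a member set (canonically the ARAS)
into a single node whose time series is the mean of the member region
series per subject — chosen over union-of-edges because it yields a
well-defined correlation with every other region. Coupling is the
group-level Fisher-z mean of the per-subject composite-to-region
correlations, and a region is *hyper* (or *hypo*) when the between-group
coupling difference exceeds a margin in z-space (default 0.1, about 0.1
in r near zero) with the corresponding sign.

## The synthetic cohort generator

No suitable public dataset accompanies this design, so validation rests
on a generator that emulates the study structure with known ground
truth:

- **Atlas**: the in-brain voxels (inside a one-voxel background shell,
  dropped on grids too small to afford it) are split into `n_regions`
  near-equal contiguous parcels ordered along the rostral–caudal axis,
  so forebrain / midbrain / hindbrain occupy contiguous slabs and
  rostral-vs-caudal polarization of effects is geometrically meaningful.
  Default: a 32×32×14 grid, 138 regions (≈78 voxels each), macro split
  55/28/55, with olfactory (12), prefrontal (10), ARAS (12) and
  cerebellum (12) system tags.
- **phMRI subjects**: baseline level 100 (arbitrary units), i.i.d.
  Gaussian noise of SD 2, and a linear drift of 0.02 units/acquisition
  shared by all in-brain voxels. Effects are steps: a seeded random
  subset (default 30%) of an effect region's voxels shifts by the
  region's dose amplitude from acquisition `baseline_len` onward. A step
  rather than a hemodynamic ramp because the analysis quantifies window
  means, which are insensitive to onset shape at these window lengths.
- **Amplitude unit**: amplitudes are stated in percent signal change; a
  convenient noise-relative unit is 0.5% = 0.25 noise-SD per
  acquisition, which gives ≈30% per-voxel detection power at the default
  windows, while 3 units give ≈99%. The stock inverted-U profile uses
  0/1/3/1 units at 0/3/10/30 mg/kg, so dose information is carried by
  detection *counts*, not just means — vehicle regions sit near the
  2.5% one-sided false-positive floor, 1× doses near 30% of affected
  voxels, the 10 mg/kg dose near all of them.
- **Resting state**: region series are multivariate normal with a
  correlation matrix built from 5×5 system blocks; voxel series add
  independent noise (SD 1) around their region's series. The default
  design gives the first group uniform inter-system coupling 0.40
  (within-system 0.80) and, in the second group, decouples the ARAS from
  everything except the prefrontal block (0.10) while hypercoupling it
  to the olfactory block (0.65). These values were chosen to be
  positive-definite (the obvious flatter design with within-system 0.55
  is *not* PSD once one block is perturbed — the generator checks
  eigenvalues and names the offending block) and to keep every edge
  ≈5 z-SDs from the 0.3 cutoff at n = 10, T = 200, so the qualitative
  graph pattern is stable across seeds.
- **Determinism**: one root seed; three derived streams (affected-voxel
  selection, phMRI subjects, resting-state subjects) with per-subject
  child seeds, so any subject is a pure function of `(spec, seed)` and
  two runs of a pipeline config produce byte-identical tables.

What the generator does *not* emulate: physiological (cardiac /
respiratory) noise, motion, temporal autocorrelation, spatial smoothness
of real BOLD fields, or hemodynamic response shapes. Passing the
validation battery therefore demonstrates correctness of the
computations and calibration under the stated noise model — not
robustness to every artefact of in vivo data.

## Numerical and design choices

- **Welch by default.** At window lengths 50/100 with equal noise
  variance the Welch test's size is 0.0500 ± 0.0002 (measured over 2×10⁶
  simulated voxels), so the null-calibration checks are attainable with
  the default statistic.
- **Chi-square vs permutation p.** At total n = 16 (four groups of
  four) the chi-square approximation to the Kruskal–Wallis null deviates
  from the permutation distribution by ≈0.016 mean absolute difference
  (max ≈0.045) in p — an intrinsic property of the approximation, not
  an implementation artefact. The agreement tests therefore use
  tolerances of 0.03 (mean) and 0.08 (max), fixed from that
  characterisation before the tests were written.
- **All-tied samples.** `kruskal.test` returns NaN when every
  observation is equal (the tie correction divides by zero);
  `kruskal_wallis` defines this case as H = 0, p = 1 — no rank
  variation, no evidence.
- **ω² clipping.** The unbiased-flavoured ω² estimator is negative when
  group means are closer than chance predicts; values are clipped to 0,
  and zero total variance returns 0 with a warning.
- **FDR threshold reporting.** When nothing passes, the realized
  threshold is `NA`, not 0 — "no region met the step-up rule" is
  different from "the threshold was zero".
- **Degenerate inputs.** Nonpositive baseline means (impossible for
  in-brain voxels under the generator, possible in real masks) raise an
  error listing the offending voxels; empty regions yield zero count
  rows, never missing rows; regions with no in-mask voxels get NA time
  series plus a warning.

## Problem sizes in the test suite

Unit tests run on miniature cohorts (8–12 regions, ~1,000-voxel grids,
40 acquisitions) and complete in seconds. The validation battery runs at
the emulated study scale — 26 subjects in 4 dose groups on the default
grid, 20 replicate cohorts for calibration and recovery, 20 resting-state
replicates at n = 10+10, T = 200, and 1,000-instance oracle sweeps —
about 4 minutes on one CPU via `scripts/acceptance.R`, and the same
checks run as acceptance tests in the suite.

## Known limitations

- Voxel tests ignore temporal autocorrelation; with real (smoothed,
  autocorrelated) data the effective per-voxel α will differ from the
  nominal value.
- The time-course ANOVA treats acquisitions as exchangeable fixed
  levels; serial correlation within subjects is not modelled.
- The shape classifier is a deterministic rule on medians; it does not
  propagate uncertainty, and near-δ margins flip labels under
  resampling.
- Graph results depend on the |r| cutoff; only the default 0.3 is
  exercised by the validation battery, though any cutoff in (0, 1) is
  accepted.
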