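---
title: "Source-space oscillatory coupling: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space oscillatory coupling: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megcoupling)
```

## The analysis problem

Multi-trial MEG experiments that contrast a baseline fixation window with a
post-cue window often ask three questions at the source level: (i) where
does band-limited oscillatory power change between conditions, (ii) does the
phase of a slow rhythm at a seed region become more tightly coupled to the
phase of the same rhythm elsewhere, and (iii) does the phase of the slow
rhythm at the seed modulate the amplitude of a fast rhythm elsewhere.
`megcoupling` implements this chain end to end — LCMV beamforming,
band-limited power contrasts, seed-based phase coupling (PLV, PLI),
theta-phase/gamma-amplitude coupling (a double-Hilbert envelope-phase PLV),
trial-covariate residualization, and cluster-level permutation statistics —
together with a synthetic-data generator that plants every one of these
effects with known parameters. Because real recordings of this kind are
rarely shareable, the package is validated by parameter recovery on
synthetic studies rather than against archived data.

The emulated design: 17 subjects, 36 retrieval trials per subject, sensor
data sampled at 480 Hz. Each trial contains a 1-s baseline fixation window
(the final second before cue onset, `[-1, 0)` s) and a 1-s cue window
(`[0.5, 1.5)` s after cue onset). The analysis bands are theta (4–8 Hz),
low gamma (30–45 Hz) and high gamma (65–85 Hz). Statistical maps live on a
10-mm source grid in MNI-like mm coordinates.

## Models and statistics

### LCMV scalar beamformer

For voxel $n$ with (scalar, fixed-orientation) lead field $l_n$ and sensor
covariance $C$, the spatial filter is

$$ w_n = \frac{C_r^{-1} l_n}{l_n^\top C_r^{-1} l_n},
   \qquad C_r = C + \lambda\,\overline{\mathrm{diag}(C)}\, I $$

which passes its own source with unit gain ($w_n^\top l_n = 1$) and
minimizes output variance. The covariance is estimated from the
concatenated baseline and cue windows of all trials — a *common* filter, so
condition differences cannot be artifacts of condition-specific weights.
Band power at each voxel is the mean squared band-passed virtual-electrode
signal per window, normalized by the projected sensor white-noise power
$\sigma^2 w_n^\top w_n$ (the neural-activity-index convention), which
removes the beamformer's depth-dependent noise amplification and makes the
contrast invariant to global sensor gain. Defaults: regularization fraction
$\lambda = 0.05$ of the mean sensor variance; $\sigma^2$ defaults to the
smallest covariance eigenvalue. Both are conventional, deliberately mild
choices; neither is critical on the synthetic studies, and both are
exposed as arguments.

### Phase coupling metrics

Instantaneous phase $\phi(t, n)$ comes from the Hilbert transform
(analytic signal) of the theta-band-filtered virtual electrode. For a seed
$s$ and target $n$ over the $T$ samples of one window,

$$ \mathrm{PLV} = \Bigl| \tfrac{1}{T} \sum_t e^{i(\phi(t,n) - \phi(t,s))}
   \Bigr|, \qquad
   \mathrm{PLI} = \Bigl| \tfrac{1}{T} \sum_t \mathrm{sign}\,
   \mathrm{wrap}(\phi(t,n) - \phi(t,s)) \Bigr|. $$

PLV is the resultant vector length of the phase differences (1 = perfectly
consistent relation). PLI takes only the sign of the wrapped difference, so
instantaneous (zero-lag) mixing of a common source — volume conduction and
beamformer leakage — contributes symmetric phase differences around zero
and cancels; only a consistent *lagged* relation survives. `sign(0)`
contributes 0; exact zeros occur only on degenerate inputs. Phases are
wrapped to $(-\pi, \pi]$ throughout.

Both statistics are computed within each trial's baseline window and cue
window separately, and per-trial values averaged within condition before
entering the second level. The sample PLV over a finite window is
positively biased (about $1/\sqrt{T_{\mathrm{eff}}}$ under independence);
we do not correct this, because both conditions use identical window
lengths and the bias cancels in the contrast — any residual SNR-dependent
bias is what the confound regression is for.

### Theta-phase/gamma-amplitude coupling

The PAC metric band-passes the target series in the gamma band, extracts
its analytic amplitude (envelope), band-passes that envelope in the theta
band, applies the Hilbert transform a second time to obtain the envelope's
instantaneous phase, and computes the PLV between that phase and the seed's
theta phase. The seed phase is the seed voxel's theta-band analytic phase.
The envelope's theta-band filtering removes its DC component; no further
detrending is applied. Filtering and both Hilbert transforms always operate
on the full epoch, with the analysis window cropped last, so that both
filtering passes see adequate context.

### Confound residualization

Trial-to-trial eye-movement activity and SNR (power) changes can masquerade
as power or coupling effects. For each subject, per-trial measures across
all 72 trial windows (36 baseline + 36 cue, pooled over conditions) are
residualized by OLS against normalized covariates (mean 0, sd 1, sample-sd
denominator): eye-movement variance alone for power maps; eye variance,
seed theta power, and per-voxel source power (theta for phase coupling,
gamma for PAC) for coupling maps. Condition is deliberately **not** a
regressor — including it would absorb the effect of interest; the condition
contrast of the residuals is what proceeds to the group stage. Per-voxel
regressions share the eye/seed columns, so the implementation projects
those out once and handles the per-voxel source-power column as a rank-1
update (Frisch–Waugh); the result is numerically identical to per-voxel
OLS. At the seed voxel, source power duplicates seed power and drops out
automatically. Elsewhere a rank-deficient design is an error naming the
collinear columns.

### Group statistics

Per-subject difference maps (cue − baseline) enter a one-sample t test,
$t = \bar d / (s_d / \sqrt{n})$, $df = n - 1$, with Z equivalents matched
by upper-tail probability and clipped at $|Z| = 8$. Supra-threshold voxels
(one-sided $p < 0.001$ by default, matching the directional contrast) are
clustered under 6-connectivity (faces only) on the grid and clusters below
the minimum extent (10 voxels at full scale) discarded. Family-wise error
over clusters is controlled by sign-flip permutation: under the one-sample
null the subject maps are symmetric about zero, so randomly flipping each
subject's sign generates the null distribution of the maximum cluster
extent, and each observed cluster gets
$p_{\mathrm{FWE}} = (1 + \#\{\text{null max extent} \ge \text{observed}\})
/ (n_{\mathrm{perm}} + 1)$. This replaces parametric random-field cluster
correction: it is distribution-free, exactly implementable, and appropriate
for a one-sample design. Sign flips leave per-voxel sums of squares
unchanged, so the permuted t maps cost one matrix product each.

Each subject's seed voxel is the one with the greatest theta power increase
within 20 mm of the group peak, accommodating between-subject variability
in frontal-midline source location; ties break by distance, then index.
Voxels within the search radius of the group peak are flagged
`seed_adjacent` in coupling outputs, since effects that close to the seed
are hard to interpret.

## The synthetic generator

`sim_config()` fixes the experimental constants (17 subjects, 36 trials,
480 Hz, the three bands, 1-s windows) and the planted effects. Per subject,
each trial is a lead-field mixture of three dipole-like scalar sources on
the grid plus an eye-artifact component and white sensor noise:

* **Seed source** — a wandering-frequency theta oscillation (instantaneous
  frequency is an Ornstein–Uhlenbeck process inside 4–8 Hz, so phase
  decorrelates across trials) whose amplitude rises by
  $\sqrt{\texttt{power\_ratio}}$ inside the cue window (raised-cosine ramps,
  100 ms). Default power ratio 2.
* **Coupled source** — the seed's theta phase plus a constant lag
  (default $\pi/4$) plus von Mises jitter whose concentration $\kappa$
  switches from `kappa_baseline` (0.8) to `kappa_cue` (1.6) inside the cue
  window. Jitter is drawn once per theta cycle and interpolated through
  unit vectors, so it survives band-pass filtering while its per-cycle
  concentration matches the requested $\kappa$; the expected PLV of the
  planted pair is the Bessel ratio $I_1(\kappa)/I_0(\kappa)$
  (0.37 → 0.54 at the defaults).
* **PAC source** — a high-gamma carrier whose amplitude follows
  $1 + m\cos\phi_\theta$ with the *seed's* theta phase; $m$ rises from 0.2
  to 0.7 in the cue window, and the carrier amplitude scales by
  `gamma_power_ratio` (1.5, emulating a perceptual gamma response).
* **Eye artifact** — a slow (OU, $\tau = 150$ ms) time course with a fixed
  frontal-inferior topography, scaled per trial by a variance drawn
  uniformly from `artifact_variance_range`; its realized per-window
  variance is recorded as the eye covariate (the generator supplies the
  covariate directly — isolating ocular components from real sensor data
  is out of scope). `artifact_condition_gain` optionally couples the
  artifact to condition to exercise the regression control.
* **Noise and variability** — broadband source noise, white sensor noise,
  and log-normal per-trial per-window source gains (`trial_gain_sd` = 0.2)
  providing the within-condition power variability that the confound
  regression needs to estimate its slopes.

Lead fields are smooth synthetic ones: sensors on a hemispherical cap,
Gaussian distance falloff (30 mm width) with a mild fixed asymmetry,
columns unit-normalized. Neighbouring voxels therefore mix strongly, which
is what makes the PLI volume-conduction tests meaningful. Each subject's
true seed source is displaced uniformly within 20 mm of the group reference
voxel, emulating between-subject variance in source location. Per-subject
RNG streams are derived deterministically from `(rng_seed, subject_id)`, so
regeneration is bit-reproducible.

Source depth and SNR are not part of the fixed study conditions, so those
defaults are this package's own choices, made once to keep desk-scale
parameter recovery feasible and documented here: unit source amplitude
against sensor noise SD 0.3 gives an in-band (4–8 Hz) SNR of roughly 10 at
the reconstructed seed, and the planted coupling step $\kappa$ 0.8 → 1.6
is a moderate-to-strong effect that the 17 × 36 geometry can detect
reliably. Coupling effects in real MEG data of this kind are far smaller
(a few percent of PLV); what the synthetic studies validate is the
*machinery* — localization, bias cancellation, confound control, error
control — not the claim that effects of that real-world size would be
recovered.

### What the generator does not emulate

No realistic head model or Maxwell physics (lead fields are synthetic
Gaussians), no vendor sensor formats, no ICA — the artifact covariate is
known by construction. Sources are scalar; free-orientation optimization is
out of scope. Passing tests therefore demonstrate correctness of the
statistics and pipeline on data whose generative model is known, not
robustness to coregistration error, forward-model misspecification, or
artifact-isolation failure on real recordings.

## Numerical choices

* **Filtering** — 4th-order Butterworth band-pass applied forward and
  backward (zero phase, squared magnitude response). The operator is
  applied spectrally: odd-reflection padding of about three cycles of the
  band's low edge, multiplication of the FFT by $|H(\omega)|^2$, inverse
  FFT — identical to the time-domain forward-backward pass away from the
  padded-out edges (the suite checks this agreement) and fast enough to
  filter a whole epoch set in one vectorized call. A time-domain
  `stats::filter()`-based path is kept for cross-validation.
* **Edge handling** — epochs span `[-1.5, 2)` s by default so that every
  analysis window has at least 0.5 s of context; filtering and Hilbert
  transforms always run on the full epoch, windows are cropped last.
  Windows are half-open `[t0, t1)` at sample resolution, times rounded to
  the nearest sample: at 480 Hz the cue window is exactly samples
  240–719 after onset, 480 samples per window.
* **Band power** — mean squared band-passed signal over the window (a unit
  in-band sinusoid has power 0.5); stated once here, used everywhere.
* **Degenerate inputs** — constant covariates, rank-deficient designs,
  asymmetric or non-PSD covariances, out-of-grid indices, too-short epochs
  and empty seed neighbourhoods are errors; zero-variance voxels in the
  group t map are masked with a warning rather than silently dropped.
* **Ties** — seed selection breaks ties by distance then voxel index;
  cluster labels are deterministic (BFS order).

## Validation strategy and problem sizes

The test suite validates each statistic against an independent oracle
(brute-force resultant length, sign mean, textbook t, constrained
optimization for the minimum-variance property, the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$ for von Mises phase jitter), then validates the
pipeline by parameter recovery and calibration:

* metric oracles on 1000 random phase pairs (equality to $10^{-12}$);
* Monte-Carlo convergence of sample PLV to the Bessel ratio at $n = 10^5$;
* zero-lag mixtures: PLV contrast inflated, PLI pipeline null in ≥ 95 % of
  100 runs;
* planted-coupling recovery at the full study geometry (17 subjects ×
  36 trials, 1-s windows, 480 Hz) over 50 replicates, with the planted
  cluster recovered at FWE 0.05 in ≥ 80 % and the cue-ward PLV increase
  positive in ≥ 14/17 subjects on average;
* PAC monotonicity in modulation depth and a trial-shuffling surrogate
  null for $m = 0$;
* confound control: a pure SNR-change scenario is significant raw and null
  after residualization, a genuine-coupling scenario survives;
* type-I calibration of the voxel threshold and a one-sided
  Kolmogorov–Smirnov check that permutation FWE p-values are
  uniform-or-conservative under the null;
* the beamformer contract: unit gain to $10^{-6}$, the planted 2× power
  ratio recovered within 15 %, argmax localization within 10 mm in ≥ 90 %
  of subjects.

Replicated experiments keep the subject/trial geometry of the emulated
study but run on reduced grids (27–48 voxels), fewer sensors (16–24) and
shorter epochs (`[-1.25, 1.75)` s), with the cluster extent threshold
scaled to the grid (4–5 voxels on a 27–48-voxel grid versus 10 on a
whole-brain grid) and 99–499 permutations. These sizes are the package's
own choices for replicated validation runs; single analyses use the full
defaults. `scripts/acceptance.R` re-runs the complete pipeline on a fresh
default-conditions study and writes the recovered quantities as JSON.

## Known limitations

* The PLI's finite-sample bias is SNR-dependent through the
  autocorrelation of the sign sequence; in high-SNR zero-lag scenarios the
  PLI contrast is only asymptotically null. The cluster threshold and
  permutation control keep the realized false-positive rate nominal, which
  is what the volume-conduction criterion checks.
* Cycle-level interpolation of the planted von Mises jitter slightly
  smooths it, so the *measured* PLV at the coupled voxel sits above the
  Bessel ratio of the planted $\kappa$; condition ordering and contrasts
  are unaffected, which is why recovery is asserted on contrasts, not on
  absolute levels.
* The envelope of a wandering gamma carrier loses modulation sidebands at
  the analysis-band edges, attenuating recovered PAC depth by roughly 10 %
  at the defaults; the depth sweep is therefore asserted as monotone
  rather than as an unbiased estimate of $m$.
* `residualize()` removes only *linear* covariate effects, as in the
  control analyses it reproduces; a strongly nonlinear SNR–PLV relation
  would leave a residue.
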