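---
title: "fusmap: models and methods for functional ultrasound analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fusmap: models and methods for functional ultrasound analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fusmap)
```

## The measurement model

Functional ultrasound (fUS) imaging estimates cerebral blood volume (CBV)
from ultrafast plane-wave Doppler acquisitions. Once per second a block of
300 complex compound frames is acquired at 500 Hz. In each voxel the
slow-time signal $s(t)$ is a mixture of three components:

* **tissue clutter** — high-energy, spatially coherent, slow (< 5 Hz):
  breathing and tissue pulsatility move large image regions together;
* **blood signal** — a complex exponential at the Doppler frequency
  $f_D = 2 v f_0 / c$ for axial velocity $v$, carrier $f_0$ and speed of
  sound $c$, with power proportional to the local blood volume;
* **thermal noise** — white and complex.

The analysis chain is: (1) remove clutter with a spatio-temporal SVD
filter, (2) optionally restrict the Doppler band to slow axial flow,
(3) integrate power over the block, and (4) normalize to percent change
(%CBV) against a pre-stimulus baseline.

### SVD clutter filtering

`svdClutterFilter()` reshapes a block into its space $\times$ time
Casorati matrix, removes the leading singular components and
reconstructs. Because tissue motion is spatially coherent it concentrates
in the first few singular vectors, while blood signal — decorrelated
across voxels — spreads over the tail of the spectrum. The number of
removed components is a fixed configuration choice (default 1), with an
optional energy-fraction rule; a fixed rank keeps every result exactly
reproducible.

The synthetic generator (`makeFrameBlock()`) makes this separation
analytically exact: its tissue term is *rank-1 by construction* (one
shared slow sinusoid scaled by a smooth spatial profile), so removing one
singular component annihilates it completely. This turns the clutter
filter's central claim into a testable identity — the residual power of a
tissue + blood mixture must equal the power of the separately generated
blood-only block (the suite requires agreement within 5% at a 100:1
tissue-to-blood amplitude ratio) — rather than an approximate
plausibility check. Real clutter is only approximately low-rank; the
generator does not emulate rank-2+ tissue motion, and nothing here
validates rank selection on real data.

### Velocity band selection

`velocityBandFilter()` converts a maximum axial speed into a Doppler
cutoff $f_c = 2 v_{max} f_0 / c$ (3.1 mm/s at 15 MHz in soft tissue gives
about 60.4 Hz) and applies a fifth-order low-pass Butterworth filter to
each voxel's complex slow-time signal, forward and backward so the filter
is zero-phase and the power estimate is not shifted in time. Two
numerical points are deliberate:

* the *discrete* filter obtained by the bilinear transform follows the
  prewarped magnitude
  $|H(f)|^2 = 1/(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2n})$, which
  approaches the textbook analog response $1/(1+(f/f_c)^{2n})$ only well
  below the Nyquist frequency — the tests assert the exact discrete form;
* the complex signal is filtered symmetrically in frequency, so the sign
  of the axial velocity (flow direction) is not resolved; the band is a
  speed band, not a velocity band.

The speed of sound is taken as 1540 m/s, the standard soft-tissue value.

### Power and %CBV

`powerDoppler()` is the mean of $|s(t)|^2$ over the block's 300 samples —
the discrete power integral — and is proportional to CBV.
`percentCBV()` computes $100\,(PD(t) - B)/B$ with $B$ the mean power over
a baseline window; the baseline mean of the result is zero per voxel by
construction, and voxels with non-positive baseline are flagged and set
to `NA` rather than silently producing infinities. The default baseline
is the 10 s pre-stimulus silence of each trial (per-trial, not global:
session-long baselines drift).

## Trial structure and hemodynamics

The tone-mapping protocol (`trialProtocol()`) is 10 s of silence, 3 s of
pure tone, 8 s of return to baseline, with a uniform 1–3 s jitter between
trials; five tones log-spaced from 602 Hz to 19234 Hz, 10 trials each, in
random order. Acquisition is synchronized with trial starts, so the
generator rounds each inter-trial gap to the 1 Hz sampling grid; this
keeps the noise-free forward model exactly invertible through epoching
(the round-trip tests require equality to 1e-9).

The hemodynamic impulse response (`gammaHRF()`) is a unit-peak gamma
kernel, shape 3 and peak at 2 s at 1 Hz sampling, truncated at 8 s. The
shape is a modelling choice — the response-window convention (below) only
requires that the stimulus-convolved response is near its peak 3–5 s
after onset, which this kernel satisfies. Truncation at 8 s (where the
kernel has decayed to 4% of peak) guarantees that a trial's response,
whose convolved support ends 10 s after onset, can never leak into the
next trial's pre-onset baseline (earliest possible at 12 s under minimum
jitter). Voxel responses scale the stimulus-convolved kernel by a
Gaussian tuning curve $A \exp(-(i - c)^2 / 2w^2)$ on the log-frequency
index grid, with per-voxel amplitude $A$ (around 20 %CBV for responsive
ferret cortex), center $c$ and width $w$ in frequency steps.

Window conventions are inclusive on the 1 Hz grid: "3 to 5 s" means the
samples at 3, 4 and 5 s, "4 to 5 s" the samples at 4 and 5 s, and
"3 to 6 s" the samples at 3–6 s (stimulation experiments).

## Response statistics

`epochTrials()` re-references each trial to its onset and subtracts the
trial's own pre-onset mean. `windowedResponse()` averages the 3–5 s
post-onset samples into one scalar per trial and voxel (4–5 s for
decoding). `tuningStats()` computes per voxel the mean tuning curve, its
standard error *across trials*, the best frequency (argmax), a one-way
ANOVA across the five frequencies, and — after a significant ANOVA at
p < 1e-3 — pairwise Wilcoxon rank-sum post-hoc tests. The mass-univariate
ANOVA is computed in closed form (vectorized sums of squares) and is
checked against `stats::aov` in the tests; its type-I error is verified
to match the nominal level on null data.

`meanHemodynamicResponse()` averages the peristimulus time course of all
voxels whose windowed response has a z-score (mean over sem across
trials) above 3, normalized to unit peak — the fUS analogue of an
empirical HRF. `glmFIR()` estimates per-voxel impulse responses to each
frequency without assuming a response shape: one indicator column per
frequency and post-onset lag (0–8 s by default) plus an intercept, solved
by least squares. Jittered inter-stimulus intervals (the rapid protocol
uses 2 s tones with 4–6 s intervals) make the design full rank; a
rank-deficient design is rejected with its condition number rather than
silently regularized. On noise-free data the estimator inverts the
forward model exactly, and its error scales as $1/\sqrt{n}$ in the trial
count — both tested.

`stimRoiResponse()` summarizes stimulation-evoked responses (3–6 s
window) per condition as mean ± 2 sem with a two-sided Wilcoxon
signed-rank test against zero. The choice of the signed-rank test is
ours: it matches the nonparametric choices made elsewhere in the chain.

## Tonotopic map post-processing

`displayMask()` keeps a voxel for display iff its peak tuning response
reaches 15 %CBV and its best-frequency time course correlates with the
structure's mean hemodynamic response (Pearson, p < 1e-3, over the
0–8 s post-onset window — the correlation window is our choice).
`smoothMaps()` smooths best-frequency values with a 3×3×1 Gaussian
(sd 0.5 voxel) renormalized over defined voxels, and cleans the mask with
a 3×3×3 median filter (majority of the 27-neighbourhood, replicate
padding at borders) that removes isolated voxels. Smoothed BF values are
kept as interpolated non-integer values for display; they are ordinal
positions on the log-frequency grid, not frequencies. `surfaceView()`
projects the masked BF volume onto the surface by averaging 5–10 voxels
below a manually delimited surface; surface normals are approximated by
the vertical axis, which is exact for the flat synthetic geometry and an
approximation on curved cortex. `makeLayeredCortex()` splits the
surface-to-depth span into ten equal bands the same way. `matchPlane()`
repositions a recording plane in a reference vascular stack by
normalized cross-correlation, breaking ties toward the lowest slice index
with an explicit flag.

## Multivoxel decoding

`looOvoDecode()` performs K-class classification with one-vs-one linear
boundaries and leave-one-out cross-validation over *balanced folds*: each
fold holds out one trial per class, so every pairwise boundary trains on
equal class counts (9 vs 9 in the 10-trial design). This fold design is
deliberate. With a single-trial holdout the held-out trial's class trains
on one fewer trial than its opponent; since the expected squared norm of
a class mean grows as $1/n$, the midpoint threshold is then biased
against the true class, and chance-level accuracy falls measurably below
$1/K$ (we measure 0.163 instead of 0.2 in the 5-class design). Balanced
folds remove the bias exactly: permuted-label accuracy averages 0.198 ±
0.004 over 300 runs. The pairwise boundary is the mean-difference
hyperplane through the midpoint of the class means — the simplest
"linear boundary" — and the majority vote over the ten pairs decides the
class, ties broken uniformly at random under the caller's seed.

`fisherDecode()` replaces the mean-difference direction with
$\hat\Sigma^{-1}(\mu_a - \mu_b)$, where $\hat\Sigma$ is the pooled
within-class covariance of the training trials, regularized as
$(1-\lambda)\hat\Sigma + \lambda\,\mathrm{diag}(\hat\Sigma)$. With 10
trials per class the unregularized estimate is singular whenever voxels
outnumber trials, so $\lambda = 0.1$ is the default (a 75-trial design
supports smaller $\lambda$); $\lambda = 1$ is the diagonal-covariance
decoder, and at $\lambda = 0$ predictions are invariant to any invertible
linear map of the voxels. The per-fold covariance is obtained by exact
rank-one downdates of the pooled scatter and verified against naive
recomputation in the tests.

`buildPseudopopulation()` concatenates, per pseudo-trial, one randomly
drawn class-matched trial from each slice (without replacement within a
shuffle), preserving per-slice class means exactly.
`permutationTest()` builds the chance distribution from label-shuffled
re-runs (100 by default); significance is exceedance of the null's 95th
percentile and the p-value is floored at 1/n~perm~. One property of
permutation nulls is worth knowing: shuffling labels preserves each
permuted class's composition of any latent clusters in the data, so on
strongly clustered responses the null mean sits somewhat above $1/K$
while remaining a valid null; on label-independent responses it is $1/K$
exactly (both behaviours are tested). `depthDecoding()` equalizes voxel
counts across cortical depths (random subsample to the minimum per
subject), decodes per depth and subject, and tests the depth effect with
a classical one-way repeated-measures ANOVA (condition tested against
the subject × condition interaction, no sphericity correction).

## Functional spatial resolution

To ask at what distance two voxels carry independent information,
`pairAnova()` runs a balanced two-factor fixed-effects ANOVA (voxel ×
frequency) on the windowed tuning responses of every voxel pair inside a
contour drawn around a sharp functional transition. A significant voxel
main effect marks the pair dissimilar in overall *responsiveness*; a
significant voxel × frequency interaction marks it dissimilar in
*tuning* independently of responsiveness. `dissimilarityCurves()` bins
the dissimilar fractions by the rounded Euclidean inter-voxel distance
(half-up rounding; the distance rule is interpreted as the evident
Euclidean intent), `nullCurves()` rebuilds the curves under 50 global
randomizations of the scalar responses over all voxels, trials and
frequencies, and `functionalResolution()` reads off the shortest
distance at which the observed fraction exceeds the null's 95th
percentile, in micrometres at the 100 µm voxel pitch.

The two-way ANOVA is computed from closed-form sums of squares on
per-voxel sufficient statistics, which is what makes the roughly one
million pair tests of a full analysis (all pairs × 51 curve passes × 25
generator seeds) run in seconds; it agrees with `stats::aov` to 1e-9 on
random balanced designs. Degenerate noise-free inputs are defined
explicitly: zero error with zero effect gives F = 0 (identical voxels
are never dissimilar), zero error with a non-zero effect gives
F = ∞.

The synthetic transition patches (`makeTransitionPatch()`) state their
conditions exactly: the responsiveness patch is a 10 × 4 grid whose
columns peak at 20/14/8/2 %CBV across all frequencies with 2 %CBV trial
noise; the tuning patch is a 4 × 12 grid with Gaussian tuning of width
one frequency step whose center advances by 1/3 step per column at
20 %CBV amplitude and 4 %CBV trial noise; 10 trials per frequency in
both. Under these conditions the responsiveness criterion resolves at
the voxel size (100 µm). The tuning criterion *also* resolves at 100 µm:
a 1/3-step tuning shift at this amplitude-to-noise ratio gives the
interaction test roughly 80% power per adjacent pair, so the observed
dissimilar fraction at distance 1 (~0.5) clears the randomization null
(~0.09) for every seed. A coarser tuning resolution, as reported for
awake-animal recordings, requires either smoother underlying tonotopy or
lower effective response SNR than this generator produces; the
generator's conditions are stated, fixed, and not adjusted to produce
any particular readout. This is the main respect in which passing the
synthetic suite does not certify behaviour on real data, where tonotopic
smoothness, vascular point-spread and correlated physiological noise all
reduce pairwise discriminability.

## Problem sizes, determinism and degenerate inputs

* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; the same seed reproduces results bit-for-bit.
* The test suite uses reduced but honest problem sizes (e.g. 400
  permuted-label decoding runs, 9 generator seeds per resolution
  analysis, 1500-voxel null calibrations); the acceptance script runs
  the full sizes (1000 runs, 25 seeds).
* Ties: `matchPlane()` prefers the lowest slice index and sets a flag;
  decoder vote ties are uniform random under the seed; the distance
  rounding is half-up.
* Error paths are explicit: invalid configurations, crossing cortex
  curves, out-of-range clutter ranks, cutoffs at or above Nyquist,
  truncated trials (dropped with a count), empty response windows,
  rank-deficient FIR designs, unbalanced ANOVA cells, singular
  covariances at zero shrinkage, and depths without voxels.

## Known limitations

No beamforming or plane-wave compounding (the chain starts at beamformed
frame blocks); no speckle or point-spread modelling; physiological noise
beyond the rank-1 tissue term and white Gaussian noise is not emulated;
3-D tomographic reconstruction and cross-modality registration are out
of scope. Manual delineations (contours, surfaces, masks) are inputs,
not reproduced.
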