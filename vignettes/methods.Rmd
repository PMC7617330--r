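---
title: "Models and methods behind epimech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epimech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic-data tests do and do
not establish about real microscopy data.

## Cell-cycle phase model and the FUCCI4 generator

A cell's cycle is modeled as consecutive phases G0/G1 → S → G2 → M with
independent random durations. G0 and G1 are reported jointly: the FUCCI4
reporter set cannot separate them. Phase boundaries are *onsets*: completion
of division (start of Cdt1 reporter accumulation), start of Cdt1 degradation
(S onset, with a simultaneous geminin rise), start of SLBP degradation (G2
onset), and nuclear envelope breakdown (NEB, flagged by histone H1
condensation). Durations are differences of those onsets, so they inherit the
10-min acquisition grid (`dt = 1/6` h): boundaries snap to the grid and
durations are multiples of `dt`.

**Duration distributions.** For the low-density condition the G2 cohort
summaries are over-determined for a two-parameter family: mean 3.0 h, SD
0.8 h, *and* a 99th percentile of 4.5 h. A lognormal matched to the mean and
SD puts q99 at 5.33 h, which is inconsistent with the third summary, so the
low-density G2 uses a (left-skewed) skew-normal calibrated to all three
numbers; the calibration is exact at the CDF level (`dist_skewnormal`)
and reduces to solving one equation for the shape parameter. G0/G1 and S have
no published cohort values at these densities, so they keep the simpler
lognormal family with placeholder means of 8 ± 2 h and 7 ± 1.5 h — consistent
with an 18–19 h MDCK cycle, configurable, and never asserted against external
numbers.

The high-density G2 distribution is a two-component mixture: with probability
$1-p$ a low-density-like draw and with probability $p$ a *prolonged* draw
supported on (4.5, 10] h (scaled Beta, concentration 4). Two calibration
equations fix the free parameters: $P(G2 > 4.5) = (1-p)\cdot0.01 + p = 0.458$
gives $p = 0.4525$, and matching the overall mean 4.6 h puts the prolonged
component mean at 6.54 h. The published overall SD (1.5 h) cannot be matched
simultaneously — any mixture with these component means and weights has SD
≥ 1.86 h — so the mean and the prolonged fraction, the two quantities the
analysis relies on, take precedence.

**Reporter kinetics.** Channels follow exponential rise/decay with
per-channel rate constants (amplitude 1000 a.u.): fast rises (12 h⁻¹) for the
degradation-defined reporters so their plateau is established well before the
onset that matters, a slower geminin rise (2 h⁻¹) because its onset *is* the
detected event, and a binary-like H1 channel (base 60, condensed 1200).
Noise is multiplicative Gaussian (`noise_sd = 0.1` by default), which makes
log intensities homoskedastic — the property the change-point fit exploits.
Noiseless fixtures are therefore *exactly* consistent with the caller's
model, which is what makes zero-boundary-error tests meaningful.

**What the generator does not emulate:** photobleaching, segmentation/
tracking errors, cell death and extrusion, correlated (heritable) durations
between phases or between sibling cells, and intensity cross-talk. Passing
recovery tests show the caller is correct *under its stated noise model*,
not that it is robust to all failure modes of live-cell tracking.

## Phase calling by change-point detection

Degradation onsets are found by an exhaustive two-segment least-squares fit
in log space over the admissible window: a flat plateau up to candidate
frame $c$ and a linear decline (exponential decay) after it, with the decline
slope clamped ≤ 0 and the fit truncated once the smoothed signal has fallen
3.5 nats below its running peak (beyond that the exponential model is
indistinguishable from background, and floored logs would otherwise distort
the fit). The candidate minimizing the total SSE is the onset. On noiseless
traces the objective is zero exactly at the true boundary and positive
elsewhere, so the caller is exact there; under multiplicative noise the
log-space fit is an ordinary homoskedastic regression and the estimator is
unbiased, which the cohort tests confirm (mean called G2 within 0.1 h of the
cohort truth at the default noise). A sliding "sustained decline below 90 %
of the running peak" rule was considered and rejected: at the default noise
level it false-triggers on plateau fluctuations with appreciable
probability, biasing called G2 durations upward.

The geminin rise (S-onset cross-check) uses a threshold rule — the last
baseline frame before the smoothed signal stays above baseline + 25 % of its
dynamic range for 3 consecutive frames — and the S onset is the *earlier* of
the Cdt1-decline and geminin-rise estimates, flagged `ambiguous` when they
disagree by more than 1 h. Traces whose initial or terminal H1-high run is
missing are `censored`; affected phase durations are reported `NA`, and added
noise can only move calls toward `censored`/`ambiguous`, never the reverse.

Cohort statistics follow experiment-level practice: per-phase means and SDs
are computed on the means of independent (pseudo-)experiments, the
prolonged-G2 threshold is the empirical 99th percentile of the reference
cohort's complete G2 durations, and G2 occupancy at a snapshot counts cells
whose called G2 interval spans the snapshot among cells in cycle there.

## PIV

Single-pass direct cross-correlation on 24 × 24 px windows with 50 %
overlap. The correlator is *normalized* (template window against a
search area of ± half a window, NCC computed via FFT with running sums):
normalization removes the loss-of-pairs bias toward zero displacement that
plain correlation of co-located windows suffers, and it makes a perfect
integer match detectable (NCC = 1), in which case sub-pixel refinement is
skipped — integer translations and identical images are recovered exactly.
Sub-pixel refinement is the standard 3-point Gaussian fit per axis (falling
back to parabolic when a neighbor is non-positive); ties at the integer peak
break toward the smaller displacement. Windows touching the image border are
dropped; vectors larger than 5 px/frame are flagged excluded and carry no
value in any downstream mean. Measured sub-pixel accuracy on smooth synthetic
shear flows is ~0.1 px RMS with bias < 0.01 px.

## Finite-thickness traction force microscopy

The substrate is a linear elastic layer of thickness $h$ bonded to rigid
glass, loaded by in-plane surface tractions with zero normal surface stress.
Per wavevector the surface response splits into a transverse (anti-plane)
compliance with closed form $\tanh(kh)/(\mu k)$ and a longitudinal
(plane-strain) compliance computed *exactly* by solving the
constant-coefficient Navier boundary-value problem through the thickness —
a 4 × 4 matrix exponential per distinct $kh$, with bonded-base and
free-normal-stress boundary conditions. This avoids hand-transcribing a long
closed-form layer tensor; the solver is validated against two independent
limits: the Boussinesq half-space tensor
($Q_L = (1-\nu)/(\mu k)$, $Q_T = 1/(\mu k)$) as $kh \to \infty$, and the
thin-layer shear-lag limit $u = T h/\mu$ as $kh \to 0$. For $kh > 8$ the
Boussinesq forms are used directly (the layer correction decays like
$e^{-2kh} < 10^{-7}$ there, and the fundamental-matrix solve would otherwise
lose precision to its $e^{kh}$ growing modes).

Defaults: $E = 12600$ Pa (a 12.6 kPa silicone gel), $\nu = 0.49$
(near-incompressible silicone; the ratio is not measurable from these data
and is configurable). The zero-frequency mode (rigid motion) is removed on
both directions of the transform. Both operators are strictly periodic on
the given grid by default (`pad = FALSE`), which makes the inverse the exact
inverse of the forward — the round-trip identity holds to float precision.
Optional 2× zero-padding is available for measured fields whose islands
approach the field of view; it was *not* made the default because forward
and inverse must share one operator for the round trip to be exact.

**Regularization.** Inversion applies a per-mode Tikhonov filter
$Q/(Q^2+\lambda^2 Q_{\max}^2)$ with dimensionless $\lambda$. The classical
L-curve is implemented but degenerate here: the discrete operator is only
mildly ill-conditioned (condition ~ the ratio of Nyquist to fundamental
wavenumber), so the solution norm stays bounded as $\lambda \to 0$ and the
log–log curve has no sharp corner. Spectral generalized cross-validation
(`gcv_lambda`) is therefore the automatic choice; on synthetic noisy scenes
it lands within a factor ~2 of the oracle-optimal error. With displacement
noise of 1 % of the maximum (≈3 % of the RMS), the recovered-traction
relative L2 error has a floor of roughly 4–8× the relative data noise —
~15–20 % for smooth dipole fields, ~25 % for the discontinuous strip whose
edges cost extra under any spectral filter. This floor is a property of the
inverse problem at that SNR, not of the implementation; sub-10 % recovery
requires proportionally cleaner displacement data.

## Monolayer stress microscopy

The monolayer is treated as a thin elastic sheet in mechanical equilibrium
with the traction it exerts on the substrate: $\partial_j (\sigma h)_{ij} =
T_i$ (sign convention: $T$ is the cell-on-substrate traction; tension is
positive, pinned by the strip oracle below). The balance is closed with
plane-stress compatibility at monolayer Poisson ratio $\nu_m = 0.5$ (the
standard assumption; configurable) and stress-free conditions on the
footprint's free edges. Discretization: each masked traction pixel is one
bilinear (Q4) plane-stress finite element carrying its traction as a
distributed load; free edges are natural boundary conditions, so arbitrary
(including annular) footprints need no special casing, and disconnected
components are solved independently. The sheet modulus cancels from the
recovered stress; only $\nu_m$ enters, and statically determinate 1-D
geometries are $\nu_m$-independent. Rigid-body modes are pinned at two
nodes; with force-balanced loads the pinned reactions are numerically zero.
A net-force imbalance above tolerance is removed by subtracting the mean
traction, with a warning.

The reported `residual` is the assembled equilibrium residual
$\|Kv - F\|/\|F\|$ — the discrete divergence operator *of the
discretization* — and is at solver precision (~1e-12). A naive
central-difference divergence of the recovered stress cannot be small at a
load discontinuity (the strip midline), where one-cell quadrature error is
unavoidable; on smooth scenes the central-difference divergence reproduces
the input traction to < 1 % relative L2, which is tested separately.

The canonical oracle: a 200 µm × 10 µm strip under uniform ±100 Pa inward
traction has a triangular tension profile, zero at the free edges, peak
tr(σ)·h = 100 Pa × 100 µm = 10 mN/m at the midline, and mask average half
the peak. The narrow (bar-like) geometry is what makes the 1-D quadrature
exact; wider strips acquire genuine 2-D Poisson-coupling corrections near
their lateral edges. "Average normal tension" defaults to the *sum*
convention tr(σ)·h (matching the usual axis label); the /2 (mean normal
tension) convention is available behind a flag.

## FRET quantification

Each channel is background-subtracted (scalar background; estimated as the
modal rounded intensity when not supplied — the off-contact background
dominates the histogram), Gaussian-smoothed with radius 1 px, and thresholded
at 4 % of the 12-bit range (the midpoint of the conventional 3–5 % band;
configurable across that band, and the contact-mean sensitivity to the sweep
is bounded and tested). The index $I_{EYFP}/(I_{mTFP}+I_{EYFP})$ is computed
where both smoothed channels clear the threshold. Contacts are segmented on
the smoothed acceptor channel by Otsu threshold and connected-component
labeling, dropping components under 20 px; morphological thinning was
dropped as unnecessary for ridge-like junction geometry. Because background
removal precedes smoothing, edge blending attenuates both channels by the
same factor and the ratio is preserved — noiseless scenes are recovered to
float precision, not merely to a tolerance. No bleed-through or spectral
unmixing correction is attempted: the index is the ratio formula, nothing
more, and absolute calibration to force is out of scope.

## Wound response model

The monolayer is an asynchronous population: cycle ages at $t=0$ follow the
exponential-growth age distribution $f(a) \propto 2^{-a/T_c}$, and each cell
renews with its own drawn durations, so the baseline NEB rate is stationary.
Wounding at $t_w$ releases exactly the cells sitting in a *prolonged* G2 at
$t_w$: their NEB is rescheduled to $t_w$ + `release_delay` plus a small
lognormal entry lag (0.35 ± 0.25 h) when that is earlier than their natural
NEB, modeling rapid Wee1 degradation followed by a variable mitotic-entry
lag. With no prolonged pool the time course is flat by construction; with
one, the burst peaks in the window 1–2 h post wound and the rate returns to
baseline as the pool is exhausted — both are tested against 3-SD bands on the
pre-wound windows.

## Statistics layer

All group tests act on experiment means. The ratio paired t test is the
paired t on natural-log-transformed means (testing mean ratio 1). Two
degenerate paired cases are distinguished: identical pairs return statistic
0, p = 1 (no effect, no evidence), while constant nonzero (log-)differences
— zero variance with nonzero mean — are flagged `degenerate` with `NA`
statistics rather than returning `NaN`. Type-I error of both paired tests is
calibrated by Monte Carlo at n = 4 pairs (10,000 null replicates in the
acceptance suite) against the [0.04, 0.06] band. Density classes follow the
published ranges with the gaps (< 1000, 2200–2600 cells/mm²) explicitly
`unclassified`.

## Problem sizes and reproducibility

The test and acceptance workloads are sized for a laptop-class single core:
cohorts of 300 cells (≈120 frames each) for phase-recovery statistics,
10,000-cell draws only for distribution-level Monte Carlo, 64²–128² grids
for TFM/MSM, 128²–192² images for PIV and FRET, and 2,000-cell wound
simulations. Every generator takes an explicit integer seed and is
bit-reproducible given it; analysis drivers and the acceptance script derive
all randomness from their seed arguments.

## Known limitations

* The phase caller is validated against its own generative model; real
  traces violate it in ways listed above (tracking errors, bleaching).
* TFM assumes linear elasticity, in-plane tractions and a laterally infinite
  (periodic) substrate; finite islands near the field edge need the padding
  option and ideally apodization of measured displacements.
* MSM inherits the standard monolayer-stress assumptions (thin elastic
  sheet, uniform $\nu_m$, stress-free edges); for recessed or annular masks
  the stress-free condition on *all* free boundaries makes the solution
  unique but physically approximate if the inner rim actually carries load.
* The wound model releases only prolonged-G2 cells with a fixed delay; it
  does not model the motility increase or the graded tension field behind
  the wound edge.
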