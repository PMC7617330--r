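# epimech

Quantitative machinery for studying how epithelial cell density and
intercellular mechanics control cell-cycle progression in monolayers.
Epithelia adapt their division rate to local cell density: dense (but still
cycling) monolayers accumulate a pool of cells halted in G2 phase that divide
within 1–2 h of wounding, and the underlying signal is mechanical — tension
sensed at E-cadherin junctions. Testing that picture quantitatively requires
several independent measurement pipelines, which this package implements as
reusable, tested R components:

* **FUCCI4 phase-length calling** — per-cell four-channel reporter traces
  (Cdt1, SLBP, geminin fragments, histone H1) are segmented into G0/G1, S,
  G2 and M by change-point detection. Phase boundaries follow the reporter
  logic: G0/G1 runs from completion of division to the onset of Cdt1
  degradation, S to the onset of SLBP degradation, and G2 to nuclear
  envelope breakdown (NEB, the terminal H1 condensation event). Degradation
  onsets are located by an exhaustive two-segment fit (flat plateau +
  exponential decline) in log-intensity space.
* **PIV motility** — single-pass direct cross-correlation particle image
  velocimetry (24 × 24 px windows, 50 % overlap, normalized correlation with
  3-point Gaussian sub-pixel fit, vectors > 5 px/frame excluded).
* **Traction force microscopy** — forward and inverse Fourier-space TFM on a
  gel of finite thickness *h* bonded to glass: per wavevector **k** the
  surface displacement is `u(k) = Q(k; E, nu, h) t(k)`, with the transverse
  compliance `tanh(kh)/(mu k)` in closed form and the longitudinal
  compliance obtained exactly from the plane-strain elastic layer
  boundary-value problem (Boussinesq limit `(1 - nu)/(mu k)` as `kh -> inf`).
  Inversion is Tikhonov-regularized with automatic (GCV) parameter choice.
* **Monolayer stress microscopy** — recovery of the in-sheet line-tension
  tensor σ·h (N/m) from the traction field via the 2-D force balance
  `div(sigma h) = T`, closed with plane-stress compatibility and stress-free
  monolayer edges (bilinear finite elements on the traction grid).
* **FRET tension-sensor quantification** — background subtraction, Gaussian
  smoothing (radius 1 px), thresholding at 4 % of the 12-bit range, pixel
  index `I_EYFP / (I_mTFP + I_EYFP)`, and per-contact means over
  acceptor-segmented cell–cell junctions.
* **Cohort statistics** — co-stain normalization and rescaling to the
  control-condition median, paired and ratio-paired t tests / Mann-Whitney /
  Pearson on experiment means, density classification (low 1000–2200,
  high 2600–4500, CIP > 4500 cells/mm²), and mitotic-fraction time courses.

Because raw imaging data of this kind are not publicly deposited, every
pipeline stage is paired with a **synthetic-data generator** that emulates
the statistical structure of the real data with exact ground truth: FUCCI4
trace cohorts (including the high-density bimodal G2 mixture), advected
speckle pairs for PIV, traction scenes with force-balanced loads and their
exact forward displacements, FRET scenes with prescribed contact indices,
and asynchronous wound/mitosis event streams. The generators define the
study conditions; the analysis modules are scored against their truth.

## Worked example

Simulate a dense-monolayer FUCCI4 cohort, call phases, and summarize:

```r
library(epimech)

low  <- generate_fucci_cohort(fucci_preset("low_density"),  300, seed = 101)
high <- generate_fucci_cohort(fucci_preset("high_density"), 300, seed = 102)
calls_low  <- detect_events_cohort(low$traces)
calls_high <- detect_events_cohort(high$traces)
cohort_stats(calls_high, reference_calls = calls_low)
```

```
<cohort_phase_stats>  n = 300 complete cells
  g0g1  mean  7.99 h  sd(exp) 0.28 h
  s     mean  6.90 h  sd(exp) 0.12 h
  g2    mean  4.70 h  sd(exp) 0.14 h
  G2 q99 reference: 4.50 h   prolonged fraction: 47.7%
```

The dense cohort's mean G2 is ~1.6 h longer than the low-density cohort's
(3.09 h under the same seeds), and ~48 % of its cells exceed the low-density
99th percentile (4.50 h) — the prolonged-G2 pool. Mechanics of a contractile
island on a 12.6 kPa gel:

```r
gel <- gel_spec(E = 12600, nu = 0.49, thickness = 60)
sc  <- generate_traction_scene("contractile_strip", 100, gel,
                               grid = list(n = 128, spacing = 2),
                               strip_frac = 200 / 256, strip_aspect = 0.05)
st  <- recover_stress(sc$scene$traction, sc$scene$mask, nu_m = 0.5)
tension_summary(st)$average_normal_tension
#> [1] 5.000006
```

For a 200 µm strip under uniform 100 Pa inward traction the tension profile
is triangular with peak tr(σ)·h = 10 mN/m at the midline and mask average
5 mN/m, matching the 1-D force-balance quadrature.

The numbered drivers in `analysis/` run the full workflow (simulate → call
phases → PIV motility–density correlation → TFM/MSM force recovery → FRET
density series → wound response) and write their tables under `results/`.

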