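---
title: "Models and methods behind vitriqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vitriqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitriqc)
```

`vitriqc` analyzes the three bench measurements commonly used to qualify a
purified membrane-protein sample before cryo-EM grids are attempted:
nanoDSF (thermal stability), dynamic light scattering (dispersity), and
mass photometry (mass distribution and oligomeric state).  This vignette
records the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate — i.e. the package's reasoning, in one place.

## Mass photometry: left-truncated Gaussian mixtures

A mass photometer converts the interferometric contrast of single
macromolecules landing on a coverslip into mass.  Below a detection limit
*t* (≈30 kDa for typical instruments) landing events produce no usable
contrast, so an event histogram is empty below *t* and any population
near *t* appears clipped.  Fitting plain Gaussians there biases means up
and widths down; `fit_truncated_mixture()` therefore models the expected
count of component *k* in bin $[l, u)$ as

$$E = N_k\,\frac{\Phi\!\left(\frac{u-\mu_k}{\sigma_k}\right) -
       \Phi\!\left(\frac{\max(l,t)-\mu_k}{\sigma_k}\right)}
      {1 - \Phi\!\left(\frac{t-\mu_k}{\sigma_k}\right)},$$

exactly zero for bins entirely below *t*, and minimizes the squared
count residuals over all $(\mu_k, \sigma_k, N_k)$ with $\sigma_k > 0$,
$N_k \ge 0$.

Design choices worth stating:

* **Renormalization.**  Dividing by the visible tail makes $N_k$ the
  expected number of *observable* events, so component fractions are
  well defined.  The alternative — zeroing the model below *t* without
  renormalizing, so $N_k$ counts the full, partly invisible population —
  is available via `renormalize = FALSE`; which convention an
  instrument's own software uses is generally undocumented, so both are
  provided and the interpretable one is the default.
* **Bin expectations via the CDF**, not density × width: exact for wide
  bins at negligible cost.
* **Optimizer.**  Bounded Levenberg–Marquardt (`minpack.lm`), cost
  tolerance $10^{-10}$, no randomness.  Narrow populations spanning only
  a couple of bins admit a degenerate local minimum in which a component
  collapses onto a single bin ($\sigma \to 0$); the fit therefore runs a
  deterministic multi-start — the supplied widths, widths re-estimated
  from the local histogram second moment, and halved widths — and keeps
  the lowest residual.  Non-convergence is flagged, never silent.
* **Tie-break.**  Two components whose fitted means land within one bin
  width are indistinguishable on that histogram; they are merged
  (count-weighted) with a warning rather than reported as a split peak.
* **Defaults.**  Histogram bin width 10 kDa over [0, 2000) kDa;
  truncation 30 kDa; all per-instrument overridable.  Peak detection
  smooths counts with a 5-bin moving average and seeds
  $\sigma^0 = \max(15\ \text{kDa},\ 0.08\,\mu^0)$ — a mass-proportional
  resolution floor chosen so that peaks ~4 bin widths apart (the closest
  pair the package is expected to separate, ~106 vs ~274 kDa) get
  distinct seeds.  Automatic guesses are starting points, not answers;
  crowded histograms warrant user-supplied guesses.
* **Unbinding events** (negative values) are excluded from mass
  histograms but counted in `qc_event_count()`, along with the
  3000-count regular-field-of-view ceiling and a 100-count floor.

Calibration (`fit_calibration()`) is ordinary least squares of known
mass on mean contrast, free intercept by default (`force_origin`
optional, since the line's parameterization is an instrument convention
rather than physics), declared valid when the largest per-standard
relative error is below 5%.

## nanoDSF: derivative melting temperatures and the 1% onset

The F350/F330 intrinsic-fluorescence ratio tracks tryptophan solvent
exposure along a 20–90 °C ramp.  `find_transitions()` reports extrema of
the smoothed first derivative — both signs, since ratio transitions can
rise or fall; the classical "minimum of the first derivative" is the
falling case.  Numerical choices:

* **Derivative estimation** uses a Savitzky–Golay cubic filter, default
  window 21 points (~2 °C on the usual 0.1 °C grid).  The window must sit
  well below the >5 °C width of a protein unfolding transition yet
  average enough points that counting noise does not dominate the
  derivative; at realistic 0.1% fluorescence noise an 11-point window
  lets noise maxima outgrow genuine transitions, while 21 points keeps
  the noiseless extremum within one grid step of the true midpoint
  (regression-tested at windows 5–21).
* **Localization.**  The reported temperature is the centroid of the
  derivative peak above its half height — averaging tens of grid points
  instead of trusting the single noisiest one.  The filter's leading and
  trailing half-window, where one-sided fitting produces artifacts, is
  excluded from peak detection.
* **Prominence floor**: by default the larger of 10% of the biggest
  derivative magnitude and 12× the derivative noise (from the median
  absolute point-to-point difference).  A straight line yields an empty
  result, not an error.
* **Aggregation onset** (`find_aggregation_onset()`): baseline = median
  of the first 10% of points, plateau = maximum of the smoothed trace,
  onset = first crossing of 1% of the amplitude, linearly interpolated
  between grid points.  The crossing is evaluated on the *smoothed*
  trace — on raw counts, baseline noise of a few tenths of a percent
  would regularly fake the 1% crossing degrees too early.  No onset is
  reported when the total rise is below 5 baseline standard deviations.
  Whether an instrument defines its onset on raw or normalized
  scattering is not documented anywhere we know of; this normalization
  is the package's own and is affine-invariant by construction.
* A labelled buffer blank can be subtracted point-by-point
  (`subtract_blank()`); initial fluorescence is checked against the
  2000–15000 count acquisition window.

## DLS: cumulants and regularized inversion

With scattering vector $q = (4\pi n/\lambda)\sin(\theta/2)$, a diffusing
species decays at $\Gamma = q^2 D$, and Stokes–Einstein gives
$R_h = k_B T/(6\pi\eta D)$.  Defaults describe a red-laser instrument
measuring aqueous samples: λ = 658 nm, θ = 90°, n = 1.330, T = 298.15 K,
η = 8.872×10⁻⁴ Pa·s — all configurable; $k_B$ = 1.380649×10⁻²³ J/K.

`fit_cumulants()` fits the standard second-order expansion; a negative
second cumulant (possible in noise) is clipped to zero with a warning.
Cumulant results are wrecked by traces of aggregate, which is exactly why
the distribution route exists alongside.

`fit_size_distribution()` inverts the Laplace-like problem on a default
100-point log grid over 0.1–1000 nm: non-negative weights minimizing
$\|Kw - g_1\|^2 + \lambda\|Lw\|^2$ with a second-difference penalty,
solved exactly by NNLS.  Two numerical points matter:

* $g_1$ is taken as the *signed* square root of $(g_2 - B)/\beta$.  The
  unsigned root would rectify baseline noise into a spurious slow tail
  that NNLS dutifully fits with 100–1000 nm ghost components.  Rows are
  weighted by $\sqrt{|z|}$ (the inverse standard deviation of the
  transformed noise), making the solve first-order equivalent to least
  squares on $g_2$ itself.  $B$ and $\beta$ start from the tail mean and
  dynamic range and are refreshed by a linear fit between NNLS solves
  (3 alternations).
* **Regularization** is fixed at `alpha = 0.01` relative to the data
  scale ($\lambda = \alpha^2\|K\|_F^2/\|L\|_F^2$).  The value is chosen
  as the largest that still resolves species whose radii differ by a
  factor of 3 at 10⁻³ noise — the canonical resolution limit of DLS —
  while keeping single-species recoveries within one grid cell; a 10×
  stronger penalty merges such pairs into one broad peak.  No automatic
  L-curve/GCV selection in this version (known limitation).

Reweighting uses the compact-sphere Rayleigh convention — intensity ∝
mass·R³, mass ∝ number·R³ — giving exactly invertible maps between the
three weightings.  Vendor software's exact "mass-weighted" transform is
undocumented; this convention is declared rather than guessed, and kept
strictly separate from the empirical radius–mass power law
($M \approx 3.56\,R_h^{2.32}$ in kDa/nm, fitted by log–log OLS to five
built-in anchor pairs spanning 0.9–21.5 nm from detergent- and
amphipol-solubilized preparations).  The power law describes compact
detergent/protein particles, not elongated or disordered ones.

`detect_aggregation()` flags a sample when >5% of scattered intensity
sits above 100 nm; from a correlogram, a two-exponential fit that cuts
the single-decay residual by ≥20% with a slow radius above the cutoff
corroborates the call (a heuristic, documented as such).

## Synthetic data: what is and is not emulated

The generators produce data with exactly known ground truth, which is
what every recovery test and the acceptance analyses run on:

* `gen_mp_events()` — Gaussian mass populations truncated by
  rejection-with-redraw (keeping component counts exact, rather than
  discarding events and randomizing counts), optional uniform background
  and sign-flipped unbinding draws.
* `gen_dsf_ramp()` — two-state van 't Hoff unfolding
  ($K = e^{-(\Delta H/R)(1/T - 1/T_m)}$, default ΔH = 400 kJ/mol, a
  typical mid-size-protein cooperativity) mixing linear native/unfolded
  ratio baselines; flat F330 channel at 8000 counts; logistic
  scattering; relative Gaussian noise (default 0.1%) on both
  fluorescence channels, additive noise on scattering.
* `gen_correlogram()` — mixtures pushed through the package's own
  forward model `dls_g2_model()` (so the zero-noise generator output is
  reproduced exactly by the fit's model at the true weights), intensity
  weights ∝ mass·R³, additive τ-independent Gaussian noise.

Same seed, same bits; every generator's output round-trips through the
matching reader.  What these generators do **not** emulate: shot noise
and its τ-dependence in correlograms, instrument drift and focus
wander, detergent-micelle exchange kinetics, temperature-dependent
baseline curvature beyond linear, or correlated noise between
fluorescence channels.  Passing recovery tests therefore demonstrate the
*estimators* are correct and calibrated under clean, known conditions —
not that real instrument quirks are handled; real data should still be
inspected.

Problem sizes used throughout the tests and the acceptance analyses —
8000–9000 events per mass-photometry panel, 701-point thermal ramps,
200-lag correlograms — match routine single acquisitions and keep the
full suite under a minute.

## The decision tree

`evaluate_decision_tree()` walks the bench order (nanoDSF → DLS → MP),
grades each supplied technique pass/warn/fail with numeric evidence, and
recommends the earliest failing stage's remedy: buffer/detergent
optimization for instability, re-purification/reconstitution for
aggregation or a wrong mass distribution.  All numeric thresholds are
this package's own defaults, stated in `qc_thresholds()` (minimum Tm
45 °C, PDI ≤ 0.3, ≤5% intensity above 100 nm, 10% mass tolerance, ≥50%
target-species fraction, 100–3000 events) — the published decision
scheme names no numbers, so these are declared rather than inferred.
Two asymmetries are deliberate:

* A fitted mass component *above* the expected mass is a warning, not a
  failure: detergent-solubilized membrane proteins run heavy by a
  micelle's worth of mass, and that pattern is informative rather than
  disqualifying.
* A proceed recommendation can never coexist with any failing verdict
  (tested as an invariant), and tightening any threshold can only
  worsen a verdict (monotonicity, also tested).  The pipeline proceeds
  to negative staining first; `negative_stain_ok = TRUE` records that
  staining has been cleared and upgrades the recommendation to cryo-EM
  grid preparation, since nothing in the three biophysical measurements
  alone can certify grid behavior.

## Known limitations

Fixed rather than data-driven DLS regularization; semi-quantitative
radii for anything polydisperse (an intrinsic DLS limitation); no
thermodynamic (ΔG, ΔH) fitting of melting curves — only derivative and
onset analysis; the radius–mass law is only as good as its compact-
particle assumption; and the synthetic noise models are stand-ins, as
described above.
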