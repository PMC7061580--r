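---
title: "lcnose: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lcnose: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnose)
```

# The measurement being modeled

A liquid-crystal (LC) hybrid-gel film sits between a light-emitting diode
and a photodiode, sandwiched by polarizers crossed at 90 degrees.  At rest
the radially aligned LC droplets rotate polarized light, part of which
therefore reaches the photodiode.  A volatile organic compound (VOC)
partitioning into the film disrupts the LC alignment, less light crosses
the analyzer, and — because the photodiode circuit inverts — the recorded
signal **rises**.  Pumps alternate VOC-laden and clean air, so an assay is
a train of exposure/recovery cycles; with the default schedule, 45 cycles
of 5 s exposure + 15 s recovery at 90 Hz, i.e. a 15-minute, 81,000-sample
trace per assay, acquired in duplicate for each of 11 solvent headspaces
and each of four film thicknesses (15, 30, 60, 90 um nominal).

The package implements that pipeline end to end; since no public
recordings exist, a synthetic-data module stands in for the instrument.

# The forward model (synthetic data)

Each cycle is

$$ s(t) = b + r(t) + \varepsilon_t, \qquad \varepsilon_t \sim
\mathcal N(0, \sigma^2) \ \text{i.i.d.} $$

where \(b\) is the film's resting baseline plus accumulated drift, and the
response \(r(t)\) rises along a saturating logistic during exposure and
decays exponentially during recovery:

$$ r(t) = A_{\mathrm{eff}} \frac{\sigma_k(t) - \sigma_k(0)}{1 -
\sigma_k(0)}, \quad \sigma_k(t) = \frac{1}{1 + e^{-k (t - t_0)}}, \quad
t_0 = \frac{\log 99}{k} $$

for \(t\) in the exposure window, and
\(r(t) = r(t_{\mathrm{exp}})\, e^{-d (t - t_{\mathrm{exp}})}\) afterwards.
The choices embedded here:

* **Logistic rise, exponential recovery.**  The classification stage fits
  cycles to a logistic anyway (features 10–12), so the generator uses the
  same family; first-order decay is the simplest recovery that makes the
  rise/decay-ratio feature well posed.
* **Onset normalization.**  The midpoint \(t_0 = \log(99)/k\) puts the raw
  logistic at 1% of \(A\) at cycle start; the shift-and-rescale then pins
  \(r(0) = 0\) exactly, so the pre-exposure window really is baseline and
  the long-exposure plateau is exactly \(A_{\mathrm{eff}}\).
* **Positive polarity.**  Exposure deflects the signal upward, consistent
  with the inverted photodiode circuit described above.
* **Effective amplitude** \(A_{\mathrm{eff}} = A \times\) (active-area
  fraction): a film transduces in proportion to its birefringent area.
* **Drift.**  The baseline of cycle \(k\) is offset by
  \((k-1)\cdot\texttt{matrix\_shift}\): protic/hydrogen-bonding solvents
  slowly reorganize the gelatin matrix, which we model as linear per-cycle
  accumulation.  Aprotic solvents have `matrix_shift = 0`.
* **Noise.**  Additive i.i.d. Gaussian, `noise_sd = 1.5` intensity units
  for every VOC — there is no published noise model for this instrument,
  so the simplest testable choice is used.

## The stated world: default parameter values

The 11 kinetic profiles (`default_voc_library()`) are inventions
constrained to be pairwise well separated: amplitudes 45–130 units, rise
rates 1.1–3.0 /s, decay rates 0.5–1.8 /s, with every profile pair more
than 10% apart in at least one parameter (asserted by a test) while the
per-sample noise is 1.5 units.  A seed jitters all parameters by up to
±2% multiplicatively, so different seeds give numerically different but
equally separable libraries; the jitter can never erode the 10% margin.

The film set (`default_film_set()`) uses measured thicknesses 27, 36, 44
and 62 um for the four nominal thicknesses — thin films deposit 1.2–1.8x
thicker than nominal and thick films thinner, which these values follow —
with baselines 820/760/690/580 units (strictly decreasing in thickness)
and active-area fractions 0.35/0.50/0.62/0.78 (strictly increasing).  The
monotone trends are the physically documented behaviour; the numeric
levels are simulator choices, not measurements, and are asserted only as
trends.

## What the generator does and does not emulate

It reproduces the acquisition geometry (schedule, sampling rate, class
structure, duplicates), thickness-dependent baseline and response scaling,
VOC-specific kinetics, drift and sensor noise.  It does **not** emulate
droplet-scale optics, VOC partition equilibria, concentration dependence
(the headspace concentration is not a simulator variable), pump
transients, temperature effects, or inter-assay film aging.  Consequently
a green classification test establishes that the pipeline is correct and
that the classifier recovers the separability built into the stated world
— it does not certify the instrument accuracies reported for real films,
which were computed on recordings that were never deposited.

# Preprocessing

Traces are smoothed **before** cycle division (the stated processing
order) with a normalized sliding-window convolution, default window 100
points (1.1 s at 90 Hz).  The window shape is Hanning by default with
rectangular available: the upstream tooling names only "a smooth filter",
so the shape is configurable and both kernels are unit-sum.  Edges use
reflective padding (mirror about the edge sample, edge excluded) so output
length equals input length and constants are fixed points; the window is
anchored with `floor((w-1)/2)` samples of left context.  Hann windows of
length ≤ 2 are identically zero and silently degenerate to rectangular.

Cycle division is fixed-schedule slicing at multiples of
`cycle_samples = round((exposure_s + recovery_s) * sampling_hz)` — the
acquisition is pump-clocked, so event detection would add failure modes
without information.  A trailing partial cycle is dropped with a warning;
a trace shorter than one cycle is an error.  The per-cycle baseline is the
mean of the first 0.5 s (`round(0.5 * sampling_hz)` samples), a window
that lies before any appreciable response under the stated schedule.

# The 12 features

Features 1–9 are morphological; the identity of the original nine was
never published, so this set is a documented concrete choice spanning
amplitude, timing, area and derivative morphology (see
`?morphological_features`).  Numerical conventions: derivatives are
central differences with one-sided ends; areas are trapezoidal on the
baseline-subtracted cycle; `argmax`/`argmin` take the earliest index on
ties; divisors (`baseline` in f1, `|f5|` in f9) are floored at `1e-8`.

Features 10–12 are \((A, k, t_0)\) from a least-squares logistic fit to
the baseline-subtracted **exposure segment** (exactly three features are
specified, so the baseline is removed rather than fitted as a fourth
parameter; fitting the full cycle would mix recovery kinetics into the
rise parameters).  Initialization: \(A_0 = \max y\), \(t_{0,0}\) = time of
half-maximum, \(k_0 = 4/t_{\mathrm{exp}}\); the solver is bounded
Gauss–Newton (`nls`, port algorithm, \(A \ge 0\), \(k > 0\), ≤ 200
iterations).  A degenerate (non-positive) segment returns \(A = 0\) and a
non-converged fit returns the initialization values — both flagged via
`converged = FALSE`, never an exception, so one bad cycle cannot abort an
assay.

# Classification

Per film thickness (each thickness is analyzed independently): an RBF
kernel SVM, \(C = 100\), \(\gamma = 0.1\), one-vs-one with majority
voting, evaluated by stratified 10-fold cross-validation so every cycle is
predicted exactly once by a model that never saw it.

* **Own SMO solver.**  No SVM package is available in the target
  environment, so the binary C-SVC is solved in compiled code by
  sequential minimal optimization with maximal-violating-pair selection,
  stopping tolerance `1e-3` on the KKT violation.  It was validated
  against an independent reference SVM implementation; the reference
  decision values are frozen in the test suite.
* **Standardization.**  Features are z-scored with statistics computed on
  each fold's training rows only — \(\gamma = 0.1\) presupposes
  commensurate feature scales, and computing the statistics per training
  fold keeps the held-out fold unseen.  Constant features pass through
  unscaled.  A config flag disables standardization.
* **Fold assignment** is deterministic given the seed: within each class,
  indices are shuffled and dealt round-robin.  Cycles are treated as
  independent samples (the stated analysis unit); `groups` carries
  replicate ids for anyone wanting grouped CV.
* **Vote ties** go to the earlier class in the level order, which follows
  the standard solvent listing.
* **Reporting.**  Confusion matrices are row-normalized (rows = true VOC;
  the diagonal is per-VOC recall, called "accuracy" in this field).
  Overall accuracy is pooled (micro) across folds; the fold-averaged
  variant is also emitted because the published headline figures do not
  say which was used.  Precision is reported both macro-averaged
  (unweighted over classes; never-predicted classes contribute 0 and are
  flagged) and micro (= pooled accuracy), for the same reason.

# Film optics

* `corrected_thickness(x, tilt)` implements the tilted-stage correction
  \(x / \cos(90° - \text{tilt})\), evaluated in degrees (the source
  formula is written in degrees); default tilt 75°.
* `mean_gray_value` averages pixels whose **centers** fall inside the
  circular mask — a deterministic, oracle-friendly membership rule; no
  birefringence threshold is applied before averaging because none was
  ever published, so the raw mean is reported.
* `optical_response_timeseries` converts an image stack into a
  `signal_trace`, making the POM-video analysis route feed the same
  preprocessing and feature code as the photodiode route.
* Image I/O is plain-text PGM (P2); any reader that produces a numeric
  matrix can feed the module.  Color conversion, if needed, is the
  caller's responsibility (an unweighted channel mean is the documented
  convention).

# Numerical and testing choices

* All simulation functions take explicit seeds, use a locally scoped RNG
  (the caller's `.Random.seed` is restored) and derive per-trace seeds
  from the master seed, so any single trace is reproducible in isolation
  and full reruns are byte-identical.
* Oracle tests compare smoothing, derivatives, areas and gray values
  against brute-force reimplementations at `1e-12` relative error;
  logistic fits are cross-checked against a coarse grid search (closed
  form for \(A\) given \((k, t_0)\)) that the fit must never lose to.
* The acceptance suite runs the **full default experiment** (88 traces,
  3,960 cycles) twice to verify determinism and the ≥ 0.95 pooled CV
  accuracy per thickness — a property of the simulator's separability
  margin, explicitly not a reproduction of the published 97–99%
  instrument accuracies.  The permutation-null check subsamples 20
  cycles/class so the label-free CV remains affordable; its accuracy must
  fall in the central 99% binomial band around 1/11.

# Known limitations

* The morphological feature set is a reasoned reconstruction, not the
  original (unpublished) one; transfer of trained models to real
  recordings is untested and untestable until recordings are deposited.
* The SMO solver targets small per-fold problems (hundreds of rows); it
  precomputes the kernel matrix and would need caching for datasets
  orders of magnitude larger.
* The simulator's noise is white; real photodiode traces likely carry
  1/f and pump-synchronous components, which would lower CV accuracy.
* Concentration, temperature and humidity are outside the model.
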