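---
title: "Modelling and fitting substrate-water exchange kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting substrate-water exchange kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmims)
library(ggplot2)
```

## The measurement and the model

Photosystem II oxidizes two bound substrate "water" molecules at the
Mn₄CaO₅ cluster of the oxygen-evolving complex. The two substrates are
kinetically distinct: a fast-exchanging water W_f and a slow-exchanging
water W_s, with first-order exchange rate constants `k_f` and `k_s`
against the bulk. Time-resolved membrane-inlet mass spectrometry (TR-MIMS)
probes them by rapidly raising the ¹⁸O enrichment of the medium (an
H₂¹⁸O injection of a few milliseconds) and measuring, after turnover
flashes, how the ¹⁸O label appears in the evolved O₂ — as the
single-labeled isotopologue ¹⁸O¹⁶O at m/z 34 and the double-labeled
¹⁸O¹⁸O at m/z 36.

Because each O₂ takes one oxygen from each substrate site, the two mass
channels carry different information. Double labeling requires exchange of
the slow substrate, so the m/z 36 signal rises monophasically:

$$y_{36}(t) = 1 - e^{-k_s t}.$$

Single labeling happens as soon as *either* site has exchanged, so the
m/z 34 signal is biphasic:

$$y_{34}(t) = a\,\bigl(1 - b\,e^{-k_f t}\bigr) + (1-a)\,\bigl(1 - e^{-k_s t}\bigr),$$

with two dimensionless amplitude factors:

* **`a`, the fast-phase amplitude** (`fast_fraction_a()`). When only the
  fast site has exchanged, the product draws one oxygen at the final
  enrichment α_f and one still at the initial enrichment α_i. The
  single-labeled fraction of that mixed state, relative to the fully
  exchanged state where both sites sit at α_f, is
  $$a = \frac{\alpha_f(1-\alpha_i) + (1-\alpha_f)\,\alpha_i}
             {2\,\alpha_f(1-\alpha_f)}.$$
  At the typical study conditions — α_f ≈ 13 % after injection, α_i ≈
  0.07 % before — this gives `a` ≈ 0.577: barely more than half of the
  m/z 34 rise reports fast exchange. The package also ships the
  brute-force isotopologue enumeration (`isotopologue_fractions()`) from
  which this closed form follows; the equality of the two routes is a
  property test.

* **`b`, the inter-flash correction** (`interflash_b()`). S₂-state
  measurements use flash trains at 100 Hz, so each cycle the centres dwell
  ~10 ms in S₃, where W_f already exchanges at the S₃-state rate
  `k_f_s3`. The unexchanged fraction surviving one dwell is
  $$b = e^{-k_f^{S3}\,t^{S3}},$$
  which scales the fast-phase amplitude (the signal starts at
  `a(1 − b)` instead of 0). For S₃-state measurements `b` is exactly 1.
  One printed form of this correction has a positive exponent, which
  would give `b` > 1 and violate its meaning as an amplitude-reduction
  factor; this package adopts the decaying convention, exposed as
  `interflash_b(convention =)` so the alternative remains inspectable.
  A single dwell is applied, not a compounded one per Kok cycle, matching
  the one-interval timing of the flash protocol.

## The synthetic-data generator

Raw TR-MIMS instrument traces are rarely published, so every stage of the
pipeline is exercised against `simulate_mims()`, which forward-simulates
traces with known ground truth plus the artifact structure the analysis
must tolerate:

* a **step enrichment rise** at the injection trigger, optionally
  convolved with a first-order mixing response (`mixing_tau`; 6 ms is a
  realistic value for a fast injection, 0 is the default so that the fit
  model and generator agree exactly);
* a **residual-O₂ step**: the injected water carries dissolved O₂ that
  appears as an additive offset on both channels from the injection
  onward;
* **homoscedastic Gaussian detector noise** per channel. The true noise
  structure of an isotope-ratio MS detector is not reported in the
  literature we model; independent Gaussian noise is an assumption, and
  passing recovery tests therefore demonstrate statistical correctness
  under that assumption, not robustness to drift, flicker noise or
  heteroscedasticity of a real instrument;
* a sampling grid (`mims_time_grid()`) that is logarithmic from 2 ms to
  20 s after injection (dense where a ~100 s⁻¹ fast phase lives, sparse
  across a ~1 s⁻¹ slow tail) with 10 pre-injection baseline points. The
  defaults — 120 post-injection points, noise SD of 1 % of a unit
  plateau — are the conditions used throughout the test suite and the
  acceptance script.

Seeding is explicit and local: the same seed gives a bit-identical trace
and the ambient RNG stream is untouched. `simulate_fluorescence()` plays
the same role for the fluorescence pipeline, on the standard logarithmic
measuring-flash grid (8 flashes per decade, 150 µs–100 s).

## Preprocessing and the global fit

`preprocess_mims()` subtracts the pre-injection baseline per channel,
removes the residual-O₂ step, and re-zeroes time at injection. In `"auto"`
mode the step is estimated as the discontinuity between the last
pre-injection and first post-injection samples; this attributes any
genuine labeling signal in the first sample to the artifact, so auto mode
is only appropriate when the first post-injection sample is early relative
to `1/k_f` — otherwise pass the amplitude explicitly. Channels stay in raw
units: the fit carries per-channel positive scale factors rather than
normalizing by a noisy endpoint, which would bias `k_s`.

`fit_exchange()` minimizes the joint sum of squared residuals of both
channels with `k_s` shared — the m/z 36 channel anchors the slow rate so
the m/z 34 channel can resolve the fast one. Choices that matter:

* **Parameterization.** Rates are fit as `log k_s` and
  `log(k_f − k_s)`, enforcing positivity and the ordering `k_f > k_s`
  structurally; scales are fit on the log scale; when `a` is freed
  (default is fixed from the enrichment) it is logit-bounded in (0, 1).
  Rates are bounded to [10⁻⁶, 10⁶] s⁻¹.
* **Initialization.** A two-segment log-linear heuristic: the late-time
  slope of `log(1 − y₃₆/plateau)` seeds `k_s`; after removing the
  implied slow component from the m/z 34 channel, the early-time decay
  seeds `k_f`. If the heuristic fails (few usable points, inverted
  slopes) a coarse log-spaced grid over `k_s` and the rate ratio, with
  scales solved linearly, takes over.
* **Optimization.** Levenberg–Marquardt with an analytic Jacobian,
  followed by a few Gauss–Newton polish steps on the analytic gradient.
  The polish matters for the package's reproducibility contracts: a
  finite-difference LM stops when the SSR change reaches rounding noise,
  which locates the optimum only to ~10⁻⁹ relative; the gradient root is
  sharper, and with it rate estimates are invariant under joint channel
  rescaling to machine precision.
* **Degeneracy.** If the fitted contrast `k_f/k_s` falls below 2 the two
  phases are not meaningfully separated; the fit warns and attaches a
  monophasic (single shared rate) comparison fit, but never silently
  swaps models.
* **Weighting.** Uniform by default; inverse-variance weighting from the
  pre-injection noise estimates is available but changes nothing under
  the generator's equal-noise channels.

## Uncertainties: jackknife

`jackknife_errors()` implements a delete-one jackknife over time points,
removing the *i*-th sample from both channels simultaneously so that every
replicate retains the shared-`k_s` global structure, refitting each
replicate warm-started from the base estimates, and applying the standard
jackknife variance formula. The deletion unit is a design choice: deleting
single paired time points is the most fine-grained scheme that respects
the two-channel coupling; a block variant (`block =`) is available for
serially correlated residuals. The replicate distribution is retained for
diagnostic plotting (`autoplot(fit, type = "jackknife")`). The test suite
checks the jackknife against the textbook leave-one-out enumeration
exactly, and against the Monte-Carlo spread of independent noisy
realizations within a factor of two.

## The fluorescence pipeline

Flash-induced variable fluorescence relaxes as charge recombination
proceeds; with electron transfer to the Q_B site blocked, the decay over
150 µs–100 s is well described by a non-decaying offset plus three
exponential components. `normalize_fv()` maps raw yield to
$(F - F_0)/(F_{max} - F_0)$ — note the variable part of the signal is
normalized, so the result is 0 at the dark level and 1 at the maximum —
and `fit_fluor_decay()` estimates

$$F_V^{norm}(t) = A_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + A_3 e^{-t/\tau_3}.$$

The model is a plain sum of exponentials: the actinic flash (~30 µs) is
over before the first measuring point at 150 µs, so no instrument-response
convolution is applied. Time-constant ordering τ₁ < τ₂ < τ₃ is enforced by
parameterizing the gaps; candidate τ triplets spread over the sampled
decades seed the fit, with the amplitudes — linear given the τs — solved
by least squares. Residuals are computed on the natural signal with
uniform weight per point; the logarithmic grid already concentrates
points where the fast components live, so no per-decade reweighting is
applied.

Reported quantities follow the conventions of the field's result tables:

* both time constants τ and half-times t½ = τ·ln 2 are reported, since
  "half-time" and "τ" are often conflated in published tables;
* amplitude percentages are computed over the decaying total
  A₁ + A₂ + A₃, with A₀ reported separately. Published WT percentages
  that sum to ~98 % are consistent with a small excluded offset, but this
  is the package's convention, not a claim about any specific table;
* parameter uncertainties are square roots of the diagonal of the
  Gauss–Newton covariance at the optimum (with a delta-method transform
  for the amplitude percentages).

Adjacent time constants closer than 3× — or a component whose amplitude
collapses to below half a percent — trigger a degeneracy warning and a
stored single-exponential comparison fit.

## Numerical and degenerate-input policy

* Exponentials are evaluated directly; rates are bounded in fitting
  contexts, and the equal-rate limit `k_f → k_s` is handled by the
  `k_f = k_s + exp(u)` parameterization (exact equality is a boundary,
  approached but never crossed).
* Enrichments α_f ∈ {0, 1} are rejected at construction with the
  offending field named; α_i = α_f is rejected as contrast-free
  (`fast_fraction_a` → 1 in the limit).
* The first-order mixing convolution uses the closed form
  `(e^{-t/τ} − e^{-kt})/(kτ − 1)` with the `kτ = 1` limit
  `t e^{-kt}/τ` substituted inside a small guard band.
* All writers emit locale-independent full-precision text; repeated runs
  with the same inputs are byte-identical (no timestamps in outputs).

## Problem sizes used in the checks

The recovery experiments in the test suite and acceptance script use the
generator defaults: 120 post-injection points per channel, 1 % noise, 50
Monte-Carlo seeds for recovery medians, 100 seeds for Monte-Carlo spread
and for the WT-vs-mutant ordering power, and 48-point logarithmic grids
for the fluorescence fits. These sizes give stable medians while keeping a
full run in the tens of seconds on a laptop.

## A worked example

```{r example, fig.width = 6, fig.height = 3.5}
enr <- enrichment_spec(alpha_f = 0.13, alpha_i = 0.0007)
proto <- flash_protocol("S2", k_f_s3 = 29)

trace <- simulate_mims(exchange_params(k_f = 111, k_s = 0.93), enr, proto,
                       noise_sigma = 0.01, residual_o2_step = 0.03, seed = 1)
fit <- preprocess_mims(trace, residual = 0.03) |>
  fit_exchange(enr, proto) |>
  jackknife_errors()
tidy(fit)
autoplot(fit)
```

```{r fluor, fig.width = 6, fig.height = 3.5}
truth <- fluor_decay_params(A0 = 0.02, A1 = 0.07, A2 = 0.37, A3 = 0.54,
                            tau1 = 3.5e-3, tau2 = 0.289, tau3 = 1.5)
ffit <- simulate_fluorescence(truth, noise_sigma = 0.01, seed = 2) |>
  fit_fluor_decay()
ffit$components
```

## Known limitations

* The generator's Gaussian, drift-free noise is the weakest link between
  passing tests and real instrument data; systematic baseline drift or
  consumption at the membrane inlet would require preprocessing beyond
  the step-and-baseline model.
* The `"auto"` residual-O₂ estimator is biased whenever the first
  post-injection sample carries genuine labeling signal; it is provided
  because it matches common practice, but explicit amplitudes are safer.
* `k_f^{S3}` for the S₂-state correction must come from a companion
  S₃ measurement; it is never estimated jointly, and errors in it
  propagate directly into the fast-phase amplitude.
* Kok-cycle population effects (misses, double hits) and S-state mixing
  are outside the model; the single-dwell `b` factor is the only
  flash-protocol correction applied.
```
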