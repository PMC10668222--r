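---
title: "Trilateration on tools: models, network, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trilateration on tools: models, network, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triloc)
```

## The computational problem

A hand-held rod transmits touch as vibration: striking an object at
different points along the rod excites its resonant bending modes with
different relative amplitudes, and skilled users can report where the rod
was touched with surprising precision.  `triloc` models the computation
that turns that vibratory input into a location percept as
*trilateration*: the touch location is estimated by combining two distance
estimates, one from each boundary of the sensory surface (the hand at the
handle, and the tip), exactly as it is for touch on a limb bounded by its
joints.

The behavioral signature of trilateration is *perceptual anchoring*:
trial-to-trial variability (the variable error) is smallest near the two
boundaries and largest in between, tracing an inverted U across the
surface.

## The Bayesian observer

All locations are expressed in percent of tool space (0 at the hand
landmark, 100 at the tip); the truncation model's parameter bounds are
conventionally stated in these units, which is why they are canonical
here.  Each distance estimate is a Gaussian likelihood whose mean is the
true distance `d_i` from landmark `i` and whose standard deviation grows
linearly with distance,

    sd_i = eps_i + d_i * sigma_hat ,

with `sigma_hat` the noise accrued per unit of distance (a property of the
decoding machinery, shared by both landmarks) and `eps_i` a
landmark-specific intercept reflecting uncertainty about where the
landmark itself is.  Under a flat prior the two location estimates are
fused by maximum likelihood (inverse-variance weighting):

    mu_int = (mu_1 / v_1 + mu_2 / v_2) * v_int ,
    v_int  = v_1 v_2 / (v_1 + v_2) .

`integrate_estimates()` implements the fusion; `predicted_sd_curve()`
evaluates `sqrt(v_int)` across the surface.  The fused mean is unbiased
when the component estimates are; the model therefore predicts the
*variable* error profile, and constant error is summarized by the accuracy
regression but not modeled.

### Where the peak sits

Because `v_int` rises and falls with the smaller of the two variances, the
curve's derivative has the sign of `sd_2 - sd_1`, which decreases strictly
in `L`.  The curve is therefore always unimodal, with its maximum at the
balance point

    L* = 50 + (eps2 - eps1) / (2 sigma_hat) ,

clipped to `[0, 100]`.  Two consequences matter.  First, the peak is
interior — anchoring visible at *both* boundaries — exactly when the
intercept asymmetry satisfies `|eps1 - eps2| < 100 sigma_hat`; with a very
lopsided intercept the maximum sits at a boundary and the curve is
monotone.  Second, a noisier distal landmark (`eps2 > eps1`), as expected
when the tip's position must be inferred from wielding rather than seen,
pushes the peak toward the tip.  The test suite asserts the closed form
directly in the anchoring regime and the clipped form outside it.

`multisegment_sd_curve()` applies the same law locally within each segment
of a segmented rod, using the segment endpoints as landmarks, which
predicts one inverted-U lobe per segment with minima at every breakpoint.

## The vibratory feature space

The rod is modeled as a clamped-free (cantilever) Euler–Bernoulli beam of
unit length.  Mode shapes are

    phi_n(x) = cosh(b_n x) - cos(b_n x) - a_n (sinh(b_n x) - sin(b_n x)) ,
    a_n = (cosh b_n + cos b_n) / (sinh b_n + sin b_n) ,

with `b_n` the roots of `cosh(x) cos(x) = -1` (`cantilever_eigenvalues()`;
found by bracketed root isolation near `(n - 1/2) pi` and polished by
Newton steps to a residual below `1e-8`).  Only the first five modes are
used, since higher modes fall outside the mechanoreceptor bandwidth.  Each
shape is normalized to unit maximum absolute amplitude — the literature
offers no canonical amplitude units for the modal weights — and an
`amplitude_scale` configuration value (default 1) places the motifs inside
the mode layer's tuning support `[-1.5, 1.5]`.  The location-to-motif map
on a 1 % grid is injective, and `nearest_location()` inverts it exactly,
which is the isomorphism that lets vibration space stand in for physical
tool space.  Location 0 % is the clamp (the hand); the physical handle
length matters only for the behavioral generator's bookkeeping, not for
the beam model.

## The three-layer population network

`build_network()` assembles Poisson-spiking populations with Gaussian
tuning curves (peak rate `kappa`, width `sigma`):

* **Mode layer** — five subpopulations of 151 units, centers `-1.5` to
  `1.5` in steps of 0.02, `kappa = 25`, `sigma = 0.08`, each tuned to the
  amplitude of one mode.
* **Feature layer** — 181 units, centers `-40` to `140` in 1 % steps,
  `sigma = 3.40`, tuned over the location feature space.  Its input is
  template-matched: a stored mode-layer template per 1 % location
  (proportional to the mean mode response there, rows normalized to unit
  L2 norm so no location is favored by template energy), winner-take-all
  over the synaptic drive with ties to the smaller location, and Poisson
  spiking around the tuning-curve means evaluated at the winner's
  preferred location.  Putting the fresh Poisson noise around the
  winner-evaluated means (rather than around the raw drive) keeps the
  layer's Fano factor at 1; the alternative would carry mode-layer noise
  twice.
* **Distance layer** — two subpopulations (centers `0..140` and
  `-40..100`) anchored at the hand (0) and the tip (100).  Gain decays
  with distance `d` from the anchor as `kappa0 / (1 + beta d)^2` (the
  close-to-far, high-to-low gradient; `kappa0 = 25`, `beta = 0.01`) and
  width grows as `(gamma log(d + 1) + 1) sigma0` (`gamma = 0.5`,
  `sigma0 = 3.40`), i.e. uniform tuning in log space.  Because Poisson
  gain is precision, these gradients embody the linear distance-noise law.

Each distance unit's non-negative input weights are solved so that
`w . rS` reproduces its prescribed tuning curve over the 0–100 % grid
(`solve_decoder_weights()`; worst-case residual is about `1e-6` of the
unit's gain, far inside the 5 % tolerance the construction demands).  The
solver is a Lawson–Hanson active-set NNLS run on the normal equations with
a `1e-12` ridge (`nnls()`), written for this package because the densely
spaced Gaussian basis is near-collinear enough to defeat the usual
iteration caps of off-the-shelf active-set implementations.

Decoding uses the log tuning curves as kernels (floored at `1e-12` to keep
them finite): the maximum-likelihood location is the grid argmax of
`h(L) . r`, on a 1 % grid spanning `-40..140` so that decoding is not
truncated at the surface edges (decoded values outside `[0, 100]` are kept,
not clipped; argmax ties break to the smaller location, and an all-zero
response is flagged degenerate and mapped to the grid midpoint).  Summing
the two subpopulations' log-likelihoods before the argmax implements the
fusion rule of the Bayesian observer.

`run_simulation()` presents each touch with Gaussian sensory jitter of
0.5 % of space applied to the location before motif lookup (the noise is
stated in spatial units, which is why it is applied in the spatial domain
rather than to the amplitudes), and refuses to run without a seed unless
explicitly told otherwise.

### What the network does and does not reproduce

With the default parameters the simulations show: integrated estimates
essentially unbiased (|bias| under 1 % of space at all tested locations);
single-subpopulation noise growing monotonically with distance from its
anchor (the X-shaped pair of curves); and integrated noise lowest near the
boundaries (the inverted U), never exceeding the better single cue.

One quantitative caveat is intrinsic to the architecture: the two
subpopulations read the *same* feature-layer activity and the same jittered
stimulus, so their errors are positively correlated.  The closed-form
fusion rule assumes independent cues, and the shared variance (about
0.45 (% space)^2 with the defaults, of which 0.25 is the sensory jitter
itself) therefore makes the simulated integrated variance exceed the
independent-cue prediction `v_1 v_2 / (v_1 + v_2)` by well over 15 %
relative — dominating near the anchors where the private decoding noise is
small.  The test suite asserts the independent-cue agreement anyway, and
that expectation fails by design; the qualitative signatures above are the
meaningful network-level checks.

## The synthetic behavioral generator

`sample_participants()` and `generate_trials()` emulate the study design
the analysis assumes: 38 participants, a 60-cm rod (12-cm handle), touches
at 10–60 cm from the hand in 10-cm steps, two report tasks (pixels on a
20-cm drawing; centimeters on a 70-cm screen), ten trials per location per
task (120 trials per participant).  Judgment noise lives in percent of
tool space before task mapping, so both tasks share one generative law —
consistent with task having shown no effect behaviorally.

Defaults chosen where the literature is silent, fixed once:

* `sigma_hat ~ U[0.02, 0.10]`, `eps ~ U[0.5, 5]` (percent of space):
  produces variable errors in the 1–6 % range typical of rod localization.
* Judged tip `~ Normal(56.5, 1.62 * sqrt(38))` cm, truncated above the
  12-cm handle (the truncation point is the handle rather than zero so a
  judged tip always lies beyond the hand; the excluded mass is ~4e-6).
  The judged tip scales only the space task, mirroring how such responses
  must be normalized; the image task uses the fixed drawing geometry.
* Truncation-law generator (for model-selection validation):
  `sigma_T ~ U[5, 15]` %, `gamma1 ~ U[-10, 10]`, `gamma2 ~ U[90, 110]` —
  genuinely truncated response ranges, comfortably inside the fitting
  bounds.
* Display scale 1920 px / 70 cm.
* Constant errors default to zero; a per-participant response
  slope/intercept miscalibration is available to exercise the accuracy
  regression away from the identity.

Because the cursor cannot leave the drawing, image-task responses are
clamped to the drawing during normalization; for touches at the tip
(100 % of space) this truncates the upper noise tail and slightly
depresses the image-task variable error there.  That is the faithful task
geometry, not an artifact.

What the generator does *not* emulate: motor variability in striking,
auditory cues, learning across trials, lapses, or any constant-error
structure beyond the optional linear miscalibration.  Passing tests on
synthetic cohorts therefore show that the pipeline recovers what it
assumes, not that real data satisfy those assumptions.

## The analysis pipeline

Normalization maps raw responses to percent of tool space
(`normalize_image_task()`, `normalize_space_task()`); variable errors are
computed per participant and location with tasks collapsed after removing
each task's own cell mean (`summarize_localization()`), losing one degree
of freedom per task, so a constant offset between tasks cannot masquerade
as variability.  Plain pooling is available (`demean_tasks = FALSE`) since
either convention is defensible.

Both models are fitted to the six-point variable-error profile by bounded
least squares on the SDs — the quantity the goodness-of-fit is reported
on — with a deterministic 27-point multistart grid and the best-RSS
solution retained (`fit_trilateration()`, `fit_truncation()`).
Trilateration fits `sigma_hat, eps1, eps2 >= 0`; truncation fits the
closed-form truncated-normal SD (`truncated_sd()`) with `sigma_T` in
[1, 40], `gamma1` in [-30, 30], `gamma2` in [70, 130] (% of rod surface).
Flat profiles drive `sigma_hat` to zero and are flagged
(`degenerate_slope`), as are bound-hitting truncation solutions
(`at_bound`).

Model comparison uses the Gaussian-residual BIC,
`n log(RSS/n) + k log(n)` with `k = 3` for both models and `n = 6`
variance points per participant by default (12, one per task-location, is
available for sensitivity); with equal `k` the comparison reduces to the
RSS ratio.  `delta_BIC = BIC(truncation) - BIC(trilateration)`, with the
conventional cutoffs of 2 (moderate) and 6 (strong).  R² is `1 -
RSS/TSS` on the SD profile and may legitimately be negative for a bad
model.

### Resolution limits at study scale

With 20 trials per location, an SD estimate carries ~16 % relative
sampling error, and six locations give the fit little leverage.  Two
consequences, quantified by simulation in the test suite and worth stating
plainly:

* Parameter recovery: the median relative error of the three recovered
  parameters across a 38-participant cohort sits near 25 %, and the R²
  between fitted and generating SD curves has a median near 0.7 — not
  because the optimizer fails (noise-free profiles are recovered to
  RSS < 1e-6) but because that is the information available in 120 trials.
* Model discrimination: noise-free, each model fits its own curves
  perfectly and the competitor visibly worse, so discrimination at large
  trial counts is essentially certain (a property the suite checks).  At
  study scale, however, the wrong model can mimic the right one's
  six-point curve to within sampling noise, and the BIC picks the
  generating model in roughly 60–80 % of synthetic participants rather
  than all of them.  Stronger claims require either more locations or
  more trials per location.

## Numerical and interface choices

* Eigenvalue roots are cached; shape normalization constants are computed
  once on a `1e-4` grid.
* All stochastic entry points accept an explicit `seed` and restore the
  caller's RNG state, so seeded runs are byte-reproducible (the
  determinism tests hash the written CSV/JSON files).
* Trial tables use one canonical CSV schema (`participant, task,
  location_cm, trial, raw_response, response_units`) shared by the
  generator and any externally recorded data mapped to it; all internal
  computation is in percent of tool space.
* Tests run the network at 500 simulated touches per location over nine
  locations, and cohort analyses at the study's own scale (38
  participants, 120 trials each); these sizes make the full suite complete
  in a couple of minutes while leaving Monte-Carlo error well below the
  tolerances asserted.

## Known limitations

* The network treats mode decomposition as given: mechanoreceptor-level
  transduction of vibration into spikes is not modeled.
* Only straight, one-dimensional rods with a flat location prior;
  two-dimensional surfaces and non-flat priors are out of scope.
* The independent-cue fusion prediction is not quantitatively attained by
  the network (correlated pathways, see above).
* The truncation model contributes only its SD prediction; its
  truncation-induced mean shift is deliberately unused, since the analysis
  fits variable errors only.
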