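---
title: "Methods: testing trait proxies of striatal dopamine synthesis capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing trait proxies of striatal dopamine synthesis capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopaproxy)
```

## The scientific question

Striatal dopamine synthesis capacity — how readily presynaptic neurons
convert DOPA into dopamine — is measured with dynamic [18F]-FDOPA PET, an
expensive and invasive procedure. A long-standing hope is that cheap
"off-the-shelf" trait measures track it well enough to serve as proxies:
working-memory span tests (Digit Span, Listening Span), trait impulsivity
(BIS-11), spontaneous eye-blink rate (sEBR) from EOG, and reward
sensitivity (BAS). Testing that claim requires the full chain implemented
here: quantify the PET signal, extract the trait measures, and then ask —
with calibrated frequentist, Bayesian, predictive, and power machinery —
whether any association exists, and whether its *absence* is supported by
evidence rather than merely unproven.

Every stage is exercised end-to-end on synthetic cohorts with known ground
truth, so the pipeline's calibration claims are themselves tested.

## PET quantification: reference-region Patlak analysis

For a tracer that is irreversibly trapped (FDOPA decarboxylated to
fluorodopamine in striatum), the Gjedde–Patlak transform linearizes the
kinetics. Using cerebellar grey matter — effectively devoid of specific
trapping — as the reference region with activity $C_{ref}(t)$, each frame
maps to

$$x(t) = \frac{\int_0^t C_{ref}(\tau)\,d\tau}{C_{ref}(t)}, \qquad
  y(t) = \frac{C_T(t)}{C_{ref}(t)},$$

and after the reversible compartments equilibrate the points fall on a
line whose slope is the influx rate $k_i^{cer}$ (min$^{-1}$), the index of
dopamine synthesis capacity. `patlak_fit()` performs unweighted OLS on all
frames whose **mid-time** is at or after $t^* = 24$ min of the 24-frame,
89-min acquisition (4×1, 3×2, 3×3, 14×5-min frames).

Numerical choices, all of which matter at the 1–3% level:

* frame values are treated as *within-frame averages*, so the running
  integral uses the piecewise-constant rule (each completed frame
  contributes `activity × duration`); a trapezoid-on-mid-times variant is
  available;
* the frame mid-time anchors both the Patlak abscissa and the $t^*$
  selection (inclusive), the symmetric choice within a frame;
* frames with reference activity at or below a floor (`eps`) are dropped
  and reported, and fewer than three usable frames is an error;
* fitting is unweighted: no frame-duration weighting is applied.

The simulator (`simulate_pet_study()`) provides the ground truth: an
irreversible two-tissue target ($K_1, k_2, k_3$), a one-tissue reference
($K_{1r}, k_{2r}$), zero blood volume, and a gamma-variate plasma input
$C_p(t) = A\,t\,e^{-t/\tau}$ (the simplest single-peak form; multiexponential
inputs are deliberately out of scope). With zero blood volume the late-time
slope has the closed form

$$k_i^{cer} = \frac{K_1\,k_3\,k_{2r}}{(k_2 + k_3)\,K_{1r}},$$

which anchors the recovery tests. Defaults ($K_1 = K_{1r} = 0.03$,
$k_2 = 0.057$, $k_3 = 0.01$, $k_{2r} = 0.1$ min$^{-1}$) put the asymptote at
$\approx 0.0149$ min$^{-1}$, the scale of striatal FDOPA influx, and keep
the 24–89 min window inside the linear regime: the noise-free fit recovers
the asymptote within 2%, with the residual linearization error shrinking as
$t^*$ grows. Frame noise is zero-mean Gaussian with
SD $\propto \sqrt{\text{activity}/\text{duration}}$ — the standard count-
statistics approximation, not a scanner model. Because the reference curve
sits in the denominator of both Patlak coordinates, frame noise induces a
ratio bias that is *quadratic* in the noise scale; the unbiasedness test
therefore runs at a small noise scale where linearization holds, and larger
noise should be expected to bias $k_i^{cer}$ slightly upward.

## Blink-rate extraction

The vEOG pipeline mirrors standard practice: a zero-phase (forward–
backward) 4th-order Butterworth band-pass between 0.5 and 20 Hz, then
rectification. A blink is a voltage rise — sliding-window max minus min
over 400 ms — exceeding a 100 µV threshold (per-participant overrides
supported, since published thresholds are set individually). Two
implementation details replace manual curation: threshold crossings use
hysteresis (the rise must fall back below half the threshold before a new
event can trigger), and crossings closer than one window are merged. On
synthetic traces with raised-cosine blink pulses at SNR ≥ 10 the detector
recovers the embedded count exactly across 100 seeded recordings; real
EOG, with saccade artefacts, drifting baselines, and blink-amplitude
variability, is harder — the hEOG artefact hook flags suspect windows but
full artefact review is out of scope.

## Correlation inference

Associations between each trait and each ROI's $k_i^{cer}$ (caudate
nucleus, putamen, nucleus accumbens) are tested one-sidedly for a
*positive* correlation — the direction every proxy hypothesis predicts —
via the $t$ transform of the Pearson coefficient, with Holm–Bonferroni
control across the three-ROI family and pairwise deletion of missing
values (per-measure Ns differ).

The Bayesian side quantifies evidence *for absence*. The Bayes factor

$$\mathrm{BF}_{01} = \frac{f(r \mid \rho = 0, n)}
  {\int f(r \mid \rho, n)\, \pi(\rho)\, d\rho}$$

uses the exact sampling density of the Pearson correlation under bivariate
normality (Hotelling's hypergeometric form, evaluated in log space with a
direct series for $_2F_1$), not a Fisher-z approximation. The prior
$\pi$ is the stretched Beta$(1/w, 1/w)$ on $(-1, 1)$, truncated and
renormalized to the hypothesis interval: $(0, 1)$ for the directional
test, $(-1, 1)$ for the non-directional one; $w = 1$ is the flat prior
used for the headline numbers, and `bf_robustness_curve()` sweeps
$w \in (0, 2]$. Two structural facts are worth knowing when reading such
curves: at $r = 0$ the directional and non-directional Bayes factors
coincide exactly (the sampling density is even in $\rho$), and as
$w \to 0$ the prior SD shrinks like $\sqrt{w/2}$, so BF$_{01} \to 1$ at
root speed in the width — a "strong prior" of width 0.01 still has SD
$\approx 0.07$ and is far from a point null. The density itself is
validated against a Monte-Carlo oracle (binned distribution of sample
correlations from $2\times10^5$ simulated datasets), and the quadrature
against an independent Gauss–Legendre rule.

"Summary mode" (`corr_test_summary()`) reproduces a published table from
printed $(r, n)$ pairs alone; with 2–3-decimal inputs, reproduced
$p$-values carry that rounding (within about 0.005) and Bayes factors
within a few percent.

## Predictive modelling

In-sample significance does not imply predictive value, so each trait is
also scored by repeated $k$-fold cross-validation (defaults $k = 10$, 100
repeats) of the simple regression of $k_i^{cer}$ on the trait. Per repeat
the out-of-fold predictions are pooled and scored once:

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad
\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i (y_i - \hat y_i)^2},$$

with means and standard errors (SD/$\sqrt{\text{repeats}}$) across
repeats; pooling per repeat is what makes "one accuracy value per repeat"
— and one prediction-error dot per participant per repeat — well defined.
Out-of-sample $R^2$ of a useless predictor is *negative* in expectation
(the training fit spends a degree of freedom on noise), which is why an
all-negative $R^2$ column is the signature of absent predictive power
rather than an anomaly.

The permutation null shuffles the outcome, leaves the predictor intact,
and re-runs the cross-validation — one repeat per permutation, since the
null needs one draw per permutation and 5000 × 100 repeats would buy
nothing but runtime. The permutation $p$ is the literal proportion of
permutations at least as accurate as observed (ties inclusive; a
$(b+1)/(B+1)$ smoothed variant is available). Boundary cases follow from
the definition: a model beating all permutations has $p = 0$, and a
constant predictor under leave-one-out folds produces permutation-
invariant accuracy, hence all ties and $p = 1$. Calibration (uniform $p$
under the null) and sensitivity (a true $\rho = 0.6$ detected essentially
always) are both tested.

## Power analysis

`power_one_sided_r()` implements two conventions, and the distinction is
the kind of thing that silently produces off-by-a-few discrepancies in
published sample-size statements:

* `method = "gpower"` (default): the noncentral-$t$ formulation of the
  G*Power exact correlation module — noncentrality
  $\rho\sqrt{n}/\sqrt{1-\rho^2}$ at $n - 2$ degrees of freedom. This is
  the convention behind widely used software, and it reproduces published
  G*Power sensitivity numbers digit-for-digit (detectable $\rho$ of
  0.29/0.25 at $n = 94$ for power 0.9/0.8; required $n$ of 614/850 for
  $\rho = 0.1$).
* `method = "exact-r"`: direct integration of the exact sampling density
  of $r$ above the critical correlation. This is the true bivariate-normal
  rejection rate — it matches Monte-Carlo simulation within Monte-Carlo
  error — and runs up to about one percentage point below the
  noncentral-$t$ convention at these sample sizes (e.g. power 0.889 rather
  than 0.900 at $\rho = 0.29$, $n = 94$; detectable $\rho$ 0.296 rather
  than 0.291). The quadrature integrates over whichever side of the
  critical point excludes the density's sharp mode, so root-finding stays
  stable out to $\rho$ near 1.

Both are exposed because they answer different questions: "gpower"
reproduces the published design computation; "exact-r" states the actual
operating characteristic. The Fisher-z approximation (detectable
$\rho \approx 0.30$, required $n \approx 617$) is implemented only inside a
test as a sanity bracket. Effect-size conversions use
$d = 2r/\sqrt{1-r^2}$.

`subsample_variability()` resamples subsets *with replacement* (as such
analyses are typically described, even near the full sample size) and
reports percentile bounds of $r$ per size — plain percentile intervals,
not BCa, since the target is a descriptive spread. At the null the size-15
central 95% interval spans about $\pm 0.51$, the closed-form null quantile
$t_{0.975,13}/\sqrt{13 + t^2_{0.975,13}}$: a vivid reminder that $n = 15$
correlations of $\pm 0.5$ are compatible with no effect at all.

## The synthetic cohort generator

`simulate_cohort()` draws from a Gaussian copula: latent multivariate
normal with unit variances, the trait–ROI correlations set by `rho_true`
(all zero by default — the null cohort), traits mutually independent at
the latent level, and the three ROI influx rates correlated at
0.751/0.649/0.787 (the strong inter-striatal structure typical of such
data). Each latent coordinate is pushed through a monotone transform to
its marginal. With Gaussian marginals the copula correlation *is* the
Pearson correlation, which the recovery tests exploit; discretized or
clipped marginals preserve rank correlations asymptotically.

Marginal defaults are chosen once for plausibility, not estimated from any
dataset: Digit Span $\mathcal N(16, 4^2)$ on a 0.5 grid; Listening Span on
the half-point grid 2–7; BIS-11 $\mathcal N(62, 8^2)$ clipped to
[30, 120]; sEBR log-normal with median 17 blinks/min (sdlog 0.5); BAS
$\mathcal N(40, 5^2)$ clipped to [17, 68]; and $k_i^{cer}$
$\mathcal N(0.015, 0.00222^2)$ min$^{-1}$, the SD set so the IQR is
$\approx 0.003$ min$^{-1}$ (IQR $= 1.349\,\sigma$), matching the dispersion
scale of striatal FDOPA data. Per-ROI means are configurable, and should
be treated as free parameters. Missingness is expressed as per-trait
completeness *proportions* (BIS-11 66/94, sEBR 92/94) so it scales with
cohort size; at the default $n = 94$ it reproduces per-measure Ns of
66 and 92 exactly.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: item-level questionnaire response processes,
non-normal trait dependence (tail dependence, heteroscedastic coupling),
scanner image formation and motion, plasma-input multiexponential tails,
and EOG artefact structure. The generator's job is ground truth for the
statistical machinery, not realism for its own sake.

## Determinism and problem sizes

Every stochastic entry point takes a seed, and identical seeds give
bit-identical outputs (tables, traces, CV results); `run_all()` derives a
deterministic sub-seed per trait × ROI so the report directory is
byte-reproducible. The test suite runs its heavier calibration checks at
sizes chosen to keep the whole suite near half a minute while leaving the
Monte-Carlo error well below the asserted margins: 200 replicates for
null-CV sign and permutation-uniformity checks, 100 replicates at
$B = 500$ permutations for signal detection, $2\times10^5$ draws for the
density and power oracles, and 100 seeded EOG fixtures. The analysis
scripts under `analysis/` run the cross-validation at 20 repeats and 500
permutations; the full-scale 100 × 5000 configuration is a `cv_config()`
call away and changes only runtime.

## Known limitations

* The Patlak stage assumes no tracer washout from the trapped compartment;
  extended models with a loss term (relevant for long FDOPA scans) are out
  of scope, as is any image-space preprocessing.
* The blink detector's merge rule caps detectable blink rates near one
  event per 400 ms window; clustered micro-blinks will undercount.
* The exact-density Bayes factor assumes bivariate normality; rank-based
  alternatives are not provided.
* Voxel-wise inference (beyond ROI means of a supplied $k_i$ map) is not
  implemented.
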