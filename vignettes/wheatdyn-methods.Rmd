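---
title: "Models and methods behind wheatdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheatdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatdyn)
```

## The accumulation model

Per-stem dry-matter accumulation (DMA) and nitrogen accumulation (NA) in
winter wheat follow a sigmoidal time course: negligible build-up through
autumn and winter, a fast near-linear phase through stem elongation and
flowering, and saturation at maturity. `wheatdyn` models both with the
three-parameter logistic curve

$$W(t) = \frac{W_{max}}{1 + a\,e^{-kt}},$$

where $t$ is days after sowing, $W_{max}$ the asymptotic per-stem
accumulation, $a > 0$ a dimensionless shape constant and $k > 0$ the
relative rate constant (d⁻¹). The model assumes a single monotone
accumulation wave per season — no mid-season biomass loss, no double
sigmoid — which matches stage-sampled trial means well (published $R^2$ for
such trials are 0.98–0.999).

**Units.** DMA is carried in g stem⁻¹. NA is carried in **mg stem⁻¹**:
nitrogen asymptotes of 44–54 per stem are only plausible in milligrams, and
treating them as such makes the nitrogen rates (≈ 0.8–1.4 per day) directly
comparable with how such tables are printed. The unit is a label on
`logistic_params()`; no numeric conversion is applied.

**Time origin.** $t$ counts days after *sowing* (day 0 = sowing). Inflection
times of 120–160 d against a ~200–240 d season are consistent with
sowing-based counting; an emergence-based origin would shift every time by a
constant the data cannot identify. Users who prefer an emergence origin can
shift their input times before fitting.

## Characteristic values of the fast phase

Setting the second derivative of $W$ to zero gives the inflection
$T_m = \ln(a)/k$, where the rate peaks at $V_m = kW_{max}/4$ and
$W = W_{max}/2$. The roots of the *third* derivative bound the fast
accumulation phase:

$$T_1 = \frac{1}{k}\ln\frac{a}{2+\sqrt3},\qquad
  T_2 = \frac{1}{k}\ln\frac{a}{2-\sqrt3},$$

with $W(T_1) = W_{max}/(3+\sqrt3)$ and $W(T_2) = W_{max}/(3-\sqrt3)$. Note
the shape constant sits in the *numerator* inside the logarithm: the
variant with $a$ in the denominator, which sometimes appears in print,
yields negative times whenever $a \gg 1$ and cannot reproduce any published
characteristic-value table. Useful identities, all tested exactly:

* the duration $T = T_2 - T_1 = 2\ln(2+\sqrt3)/k$ depends on $k$ only;
* the mean phase rate $V_t = (W_2 - W_1)/T = W_{max}/(\sqrt3\,T)$;
* $V_m / V_t = \tfrac{\sqrt3}{2}\ln(2+\sqrt3) \approx 1.1405$ for every
  parameter triple.

`growth_eigenvalues()` implements the closed forms; the test suite verifies
them against symbolic-differentiation root finding (1 000 random triples,
agreement to 10⁻⁶ d) and against a published 16-curve table at printed
precision. `growth_eigenvalues()` refuses $a \le 2-\sqrt3$, where the phase
onset would precede the curve's origin of curvature.

## Fitting

`fit_logistic()` minimises squared residuals over $(W_{max}, a, k)$ with all
parameters bounded positive, via Levenberg–Marquardt (`minpack.lm::nlsLM`,
`ftol = ptol = 1e-12`, 200 iterations). Replicates are averaged to per-time
means first — stage-sampled trials fit treatment means, and the replicate
spread belongs to the yield analysis, not the curve. Four distinct times are
the minimum for three free parameters.

Starting values come from `logistic_init()`: with a provisional asymptote
$W_{max}^0 = 1.05\max(w)$, the model linearises to
$\ln(W_{max}^0/w - 1) = \ln a - kt$, solved by ordinary least squares. The
initialiser is deterministic, so fits are bit-reproducible; no random
restarts are used. The 1.05 inflation keeps the transform defined at the
largest observation but distorts the linearisation when sampling reaches
deep saturation, so the starting $k$ can be ~20 % off there — good enough,
in every case we generate, for the bounded optimiser to reach the global
least-squares solution, which is what the recovery tests assert.

Non-convergence is a *result*, not an exception: the fit returns
`converged = FALSE` with a warning, and `fit_growth_table()` flags the
treatment in its `note` column while the remaining treatments proceed.

## Thermal time and phenology conventions

* Accumulated temperature is $\sum \max(\bar T_d - T_{base}, 0)$ over
  calendar days, **both endpoints included**; for additivity checks a split
  day belongs to the later interval. The default base is 0 °C, which
  reproduces the magnitude of published whole-season sums for this crop and
  region; it is an argument everywhere.
* The wintering onset is the first day of the first run of ≥ 3 consecutive
  days with mean temperature below 10 °C. The pre-winter thermal sum runs
  from sowing up to the day *before* the onset (the onset day is already
  cold), and is 0 when sowing itself falls inside a cold run.
* Sowing-date deltas (flowering advance, growth-duration reduction,
  pre-winter thermal reduction) are computed **within each season first and
  then averaged across seasons**. With the bundled trial tables this
  convention reproduces the published 4.0/7.5/11.5 d flowering advances and
  the 18 d duration reduction exactly, and the published 21/37/51 %
  thermal reductions within one integer point (the raw 8-day-delay mean is
  20.4 %); both raw and rounded values are returned.

## Yield statistics

Yield loss is $(Y_{ns} - Y)/Y_{ns} \times 100$ relative to the
normal-sowing yield; advantages are per-season ratios averaged across
seasons. Pearson correlations use the two-sided $t$ test on $n-2$ df; note
that at $n = 4$ even $r = -0.94$ has $p = 0.058$, so a two-sided convention
can disagree with a published one-sided star at the margin.

The per-day loss rate deliberately returns **three labelled regression
variants** (pooled OLS, per-season OLS then mean, pooled through-origin)
rather than one number: on treatment means these give ≈ 1.18, 1.18 and
1.18 %/day across both seasons (0.98 through-origin on the first season
alone), and no convention recovers a single published headline rate from
means alone — replicate-level data would be needed. Presenting one number
would imply a precision the inputs cannot support.

The ratio regressions fit grain yield on the mature-to-jointing
accumulation ratio per season, then solve each line for the ratio at the
target yield (default 6 000 kg ha⁻¹) and average the per-season solutions.
Solving per season first (rather than pooling and solving once) is the
convention that matches how multi-season thresholds are reported; the pooled
alternative is a one-liner on the returned per-season table.

## The synthetic experiment generator

`make_experiment()` builds a complete trial — weather, phenology, growth
observations, replicate yields — with every generating value recorded, so
each analysis stage can be checked against known truth.

* **Weather** is a sinusoid with AR(1) daily noise:
  $\bar T_d = \mu - A\cos(2\pi(d - d_{trough})/365.25) + \varepsilon_d$,
  defaults $\mu = 18$ °C, $A = 9.6$ °C, trough 15 January, stationary noise
  sd 1.5 °C, lag-1 coefficient 0.6. These values were chosen once to give a
  late-October sowing at ≈ 14–16 °C, a deterministic 10 °C crossing in
  early December (so the wintering onset falls after the latest sowing) and
  pre-winter thermal sums of roughly 300–620 °C·d across the four sowing
  dates — the magnitudes seen in real trials of this design. One weather
  realisation is shared by all sowing dates in a season, as in the field,
  which is what forces the pre-winter thermal time to fall monotonically
  with sowing delay.
* **Phenology** places each stage where the degree-day sum from that
  sowing date crosses a configured threshold (defaults: seedling 250,
  tillering 500, jointing 1 430, booting 1 580, flowering 1 700, maturity
  2 350 °C·d), so a sowing-date shift propagates into phenology through
  thermal time rather than through fixed calendar offsets. The wintering
  date additionally follows the cold-run rule.
* **Growth truth** is sampled per treatment and variable from envelopes
  typical of published coefficient tables ($W_{max}$ 3–4 g stem⁻¹ for DMA,
  44–55 mg stem⁻¹ for NA; $k$ 0.07–0.134 and 0.072–0.111 d⁻¹). The shape
  constant is derived as $a = e^{kT_m}$ from a sampled inflection time
  ($T_m$ 130–160 d for DMA, 120–145 d for NA), which guarantees every
  sampled curve inflects inside the season — sampling $a$ directly on a log
  scale does not. Observations are the true curve at the six stage days
  times log-normal noise $e^{\varepsilon}$, $\varepsilon \sim N(0, 0.05^2)$
  by default; multiplicative noise respects positivity and the
  orders-of-magnitude spread between seedling and maturity values.
* **Yields** are linear in the true DMA mature/jointing ratio with additive
  Gaussian noise (sd 200 kg ha⁻¹, three replicates); the default per-season
  slopes and intercepts are the published trial lines, so the generator's
  zero-noise threshold solution is a known closed-form number.

**What the generator does not emulate** — and hence what passing tests do
not show about field data: no vernalisation or photoperiod control of
development (stage placement is pure thermal time, so synthetic sowing-date
effects on phenology are milder than real ones); a winter milder than a
continental one (default cold periods run ≈ 30–80 days against the 77–89
days a real season shows, because a sinusoidal trough has no flat cold
plateau); no replicate structure in the growth observations; no spatial or
management variation in yields beyond i.i.d. noise.

A finding worth knowing: with the generator's *stage-clustered* sampling
(two early near-zero points and four points packed around the rise), the
median relative error of $k$ at 5 % noise is ≈ 15–18 % — the clustering
genuinely weakens rate identifiability. The recovery benchmark in the test
suite therefore uses six samples spread across the curve (days 20–190 for a
$T_m \approx 135$ d truth), where the median error is ≈ 9 %. Trial designs
that can afford an extra mid-rise sampling date buy a visibly better-
determined rate constant.

## Problem sizes and numerical choices

The test suite fits ~220 curves in total: the oracle-equivalence property
uses 1 000 random parameter triples against symbolic-derivative root
finding, the recovery benchmark 200 noisy six-point replicates under a fixed
seed, the threshold-bias check 500 replicate yield draws. Zero-noise
end-to-end closure (fits, thermal summaries, ratio thresholds all equal to
generating values) runs on a full two-season experiment. Tolerances: 10⁻⁶
relative for noise-free recovery, 10⁻⁶ d for root agreement, 10⁻¹² for
algebraic identities, printed precision (±0.15 d, ±0.015 rate) against the
bundled published tables, which is the rounding floor of four-decimal
printed coefficients.

## Interface notes

`wheatdyn` is an analysis library, not a shell tool: `run_pipeline()`,
`eigenvalue_table()` (a coefficients-only entry point that needs no raw
growth data), `make_experiment()`/`write_experiment()` and
`render_table()`/`write_report()` are the orchestration surface, and
`scripts/acceptance.R` shows them composed into a reproducible run.

## Known limitations

Only the logistic family is implemented — no Gompertz or Richards
alternatives, and no per-area (population-level) accumulation. Fits consume
per-time means by default; replicate-level fitting is possible by passing
replicate rows directly but is not the tested path. The ANOVA/LSD
multiple-comparison letters that usually accompany such trials are out of
scope, as is any process-based crop simulation.
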