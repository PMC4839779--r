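---
title: "Modelling price-volume agreements with an exponential decay in patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling price-volume agreements with an exponential decay in patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pricevolume)
```

## The problem

When a drug is cost-effective per patient but its eligible population is
very large, the nationwide budget impact (NWBI) — full price times
candidate population — can be unsustainable even though no single treatment
decision is wrong. The canonical case is the direct-acting antivirals for
hepatitis C: at roughly 35,000 EUR per course and a million candidate
patients in a country like Italy, the undiscounted impact is 35 billion EUR.
Price-volume agreements resolve this by contracting the per-patient price
downward as cumulative volume grows. Historically the schedules have been
negotiated ad hoc; this package provides a minimal parametric model that
makes them comparable and designable.

## The model and its assumptions

The per-patient price is modelled as first-order exponential decay in the
cumulative number of treated patients $N$:

$$\mathrm{PRICE}(N) = f\mathrm{PRICE}\cdot e^{-kN},$$

with $f\mathrm{PRICE} > 0$ the launch (full) price and $k \ge 0$ the decay
constant in patients$^{-1}$. The form is borrowed directly from
pharmacokinetics with patients in place of time, which brings along the
half-life idea: the **price-halving population**

$$\mathrm{PHP} = \frac{c}{k}$$

is the number of patients over which the price halves, where $c$ is the
halving constant. Assumptions worth being explicit about:

- the decay is smooth and continuous in patients, whereas real contracts are
  stepped; `tier_schedule()` converts the curve into expenditure-conserving
  bands when a stepped schedule is needed;
- the x-axis is cumulative patients, not calendar time — there is no
  discounting, inflation, or uptake dynamics;
- a single national market; cross-country adaptation would need refitting;
- the relationship between budget impact and negotiated decay is clearly
  multi-factorial; the nomogram (below) deliberately uses NWBI as the single
  predictor and should be read as suggestive, not prescriptive.

## Parameters and defaults

- `half_life_const` ($c$): defaults to **0.693**, the convention used in the
  worked national agreements this package reproduces; with it,
  $\mathrm{PRICE}(\mathrm{PHP})/f\mathrm{PRICE} = e^{-0.693} \approx
  0.50005$. Passing `log(2)` gives exact halving. The 0.693 default is kept
  so that refitting the shipped fixtures reproduces their published PHP
  values (41,878 and 18,579 patients) to the patient.
- `decay_k`: patients$^{-1}$. $k = 0$ is a legitimate flat-price
  (no-discount) agreement with infinite PHP, represented by `Inf` rather
  than an error.
- `n_treated`: accepted as real-valued, since volumes are often prorated
  from dispensed units (e.g. vials ÷ vials-per-course).
- Money is real-valued EUR throughout; rounding to whole euros or whole
  patients happens only at presentation.

## Fitting

With two points the model is exactly determined:
$k = (\ln p_1 - \ln p_2)/(n_2 - n_1)$, anchored at $f\mathrm{PRICE} = p_1$
when $n_1 = 0$ (the usual case, launch prices being public) and
back-extrapolated otherwise. All arithmetic is done at full floating
precision: the published 4-decimal logarithms behind the worked constants
are display rounding, and reproducing the published PHPs requires the
unrounded $k$.

With more than two points, `fit_log_linear()` runs ordinary least squares of
$\ln(\text{price})$ on $n$ (`stats::lm`), optionally with the intercept
fixed at a known launch price. The exactly-two-point case is routed through
the closed form so it agrees with `fit_two_points()` bit for bit. A fitted
*rising* price (negative $k$), which noise can produce, is returned flagged
(`rising_price` attribute) with a warning rather than clamped or rejected —
the caller decides; `fit_two_points()`, where noise is no excuse, rejects it
outright.

## Expenditure

Total expenditure over $n$ patients is the area under the price-volume
curve. Two routes are provided and cross-checked in the tests:

- analytic: $f\mathrm{PRICE}\,(1 - e^{-kn})/k$ (exact integral; $f\mathrm{PRICE}\cdot n$ for $k=0$);
- composite trapezoidal rule (via `pracma::trapz`) on a uniform grid with
  the final partial panel handled exactly. Since the integrand is convex the
  trapezoid total always bounds the analytic one from above, converging at
  $O(\text{step}^2)$; the default step is `max(1, n/1e5)` and is always
  reported, never silent.

The average cost per patient, $(f\mathrm{PRICE} -
\mathrm{PRICE}(n))/(kn)$, is algebraically the analytic total over $n$; the
package computes both and asserts their identity to $10^{-12}$ relative.
For the shipped fixtures these averages are 7,705 EUR (ranibizumab over
20,000 patients) and 14,968 EUR (sofosbuvir over 60,000); the populations
anchoring them are the volumes at which the discounted prices were reported.

`solve_decay_for_budget()` inverts the expenditure: given a budget cap below
the undiscounted NWBI it finds the unique $k$ whose analytic total meets the
cap, by bracketed root search (`stats::uniroot`) on $[0, \ln(f\mathrm{PRICE}/0.01)]$ —
the upper bracket is the rate that discounts the price to one cent within a
single patient, so the root is always interior. The bracketed solver was
chosen over derivative methods for unconditional convergence on this
monotone objective; the solution satisfies
$|\text{total} - \text{cap}|/\text{cap} < 10^{-10}$.

## The nomogram

Each reference agreement contributes a point $(\mathrm{NWBI},\;
100\cdot\mathrm{PHP}/\mathrm{totPT})$: heavier budget impacts have been
answered with proportionally faster decays. Two design choices were
genuinely open:

- **Interpolation axis.** NWBI spans orders of magnitude (181 million to
  2.25 billion EUR across the two shipped references), so raw-linear
  interpolation would be dominated by the largest reference. The nomogram
  interpolates `php_pct` linearly in $\log_{10}(\mathrm{NWBI})$; the mode is
  recorded in the object and its file sidecar so it can be revisited.
- **Extrapolation.** Outside the reference range the nearest endpoint's
  value is returned with an explicit `extrapolated` flag and a warning.
  With few references the relationship is only suggestive, and silent
  extrapolation would overstate it.

The shipped two-reference nomogram is a *reconstruction* from the public
price pairs and the populations at which the discounted prices were
reported; it is labelled as such and not presented as an official chart.

## Synthetic data

`simulate_observations()` draws volumes evenly (or uniformly at random) on
$[0, n_{\max}]$ and perturbs the curve with multiplicative log-normal noise,
$\varepsilon_i \sim N(0, \sigma^2)$ on the log scale. Log-normal noise is
the default because the model is linear in log-price, keeping the noise
conjugate to the OLS fit and prices positive by construction; additive EUR
noise is available as an option. Volumes are noise-free — the payer counts
patients exactly. The generator is deterministic given its seed and restores
the global RNG state.

What the recovery experiments emulate — and what they do not: the tests
show that with 50 observations at $\sigma = 0.05$ the decay rate is
recovered with median relative error under 5% and negligible bias over 200
replicate seeds (problem sizes chosen to keep the full suite under a minute
on one CPU). Real agreement data are far sparser (often exactly two public
points), stepped rather than continuous, and their "noise" is negotiation
rather than measurement error, so passing recovery tests demonstrates the
estimator's correctness, not that real schedules follow the model.

## Numerical choices and degenerate inputs

- Equal prices at two volumes give $k = 0$ and PHP $=\infty$ — a flat price
  is a valid no-discount agreement, not an error.
- Duplicate volumes, non-positive prices, rising two-point prices,
  non-positive populations and caps are rejected with specific errors.
- A budget cap at or above the undiscounted NWBI returns the flat model with
  a `no_discount_needed` flag instead of a spurious root.
- Queries at a nomogram endpoint never flag as extrapolation (a $10^{-9}$
  relative slack absorbs log/antilog round-off).
- JSON serialization keeps 15 significant digits; CSV fixtures and reports
  round only at the presentation layer.

## Limitations

The model commits to a single decay shape; no alternative (linear,
logistic, piecewise) is offered. Two-point fits have no meaningful
uncertainty, and OLS fits report only a residual standard error. The
nomogram rests on two reference points and one predictor; it suggests a
starting value for negotiation, nothing more.
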