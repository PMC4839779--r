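# pricevolume

Modelling price-volume agreements for drug pricing.

Price-volume agreements are managed-entry contracts in which the per-patient
price of a drug falls as the cumulative number of treated patients rises.
They are the standard payer response when a drug is individually
cost-effective but its nationwide budget impact (NWBI) — full price per
patient times the candidate population — is unsustainable, as with the
direct-acting antivirals for hepatitis C. In practice the decay schedules
have been negotiated empirically; this package implements a simple
quantitative framework for designing and analysing them, aimed at HTA
analysts and pharmacoeconomists.

## The model

The per-patient price is assumed to undergo first-order exponential decay in
the cumulative number of treated patients `Npt`:

```
PRICE(Npt) = fPRICE · exp(−k · Npt)
```

where `fPRICE` is the full (launch) price and `k` is the decay constant in
patients⁻¹. By direct analogy with pharmacokinetic half-life, the model's
characteristic scale is the **price-halving population**

```
PHP = 0.693 / k
```

the number of patients over which the price halves (the conventional
constant 0.693 is the default; `log(2)` is available for exact halving).
A logarithmic transformation of the price axis makes the model linear, so it
is fitted either exactly through two published price points or by ordinary
least squares on many observations.

Derived quantities:

- **Total expenditure** over `n` patients is the area under the price-volume
  curve, `fPRICE · (1 − exp(−k·n)) / k`, also available via the composite
  trapezoidal rule as a numerical cross-check.
- **Average cost per patient** is total expenditure divided by `n`,
  equivalently `(fPRICE − PRICE(n)) / (k·n)`.
- **NWBI** is `fPRICE · totPT`, the undiscounted worst case.
- A **nomogram** maps NWBI to PHP expressed as a percentage of the candidate
  population, so the decay rates implied by known national agreements can
  suggest a rate for a new drug.
- An **inverse solver** finds the decay constant whose total expenditure
  meets a prescribed budget cap, and a **tier schedule** converts the
  continuous curve into stepped per-band prices that conserve expenditure.

## Worked example

Two national agreements ship as fixtures: ranibizumab for macular
degeneration (9,050 EUR per patient at launch, 6,500 EUR after 20,000
patients) and sofosbuvir for hepatitis C (37,500 EUR per 12-week course at
launch, 4,000 EUR after 60,000 patients).

```r
library(pricevolume)

m <- fit_two_points(pv_point(0, 9050), pv_point(20000, 6500))
m
#> Price-volume decay model
#>   full price (f_price): 9,050 EUR per patient
#>   decay constant (k):   1.65481e-05 patients^-1
#>   PHP (0.693 / k):       41,878 patients

round(average_cost(m, 20000))
#> [1] 7705

s <- pv_example_agreement("sofosbuvir")
round(php_of(s$model))
#> [1] 18579
round(average_cost(s$model, 60000))
#> [1] 14968
```

The ranibizumab price halves every 41,878 patients and the average cost over
the first 20,000 patients is 7,705 EUR, about 15% below the launch price.
Sofosbuvir, with a budget impact an order of magnitude larger
(2.25 billion vs 181 million EUR), was given a much faster decay: its price
halves every 18,579 patients.

A nomogram built from the two agreements suggests decay parameters for a new
drug from its budget impact alone:

```r
nom <- build_nomogram(list(pv_example_agreement("ranibizumab"), s))
predict_php(nom, f_price = 20000, tot_pt = 50000)
#> $nwbi_eur      1e+09
#> $php_pct       88.4    (per cent of totPT)
#> $php           44,188  patients
#> $decay_k       1.57e-05
#> $extrapolated  FALSE
```

A command-line front end (`inst/cli/pv.R`) exposes `fit`, `predict`,
`expenditure`, `nomogram` and `simulate` subcommands over the same
functions; JSON goes to stdout, diagnostics to stderr.

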