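Package: pricevolume
Title: Modelling Price-Volume Agreements for Drug Pricing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the exponential price-decay model behind pharmaceutical
    price-volume agreements, in which the per-patient treatment price falls
    as the cumulative number of treated patients grows. The model is
    parameterized by the price-halving population (PHP), the patient count
    over which the price halves. Provides two-point and log-linear
    least-squares fitting, total-expenditure computation (analytic closed
    form and trapezoidal area under the price-volume curve), average cost
    per patient, nationwide budget impact (NWBI), an inverse solver that
    finds the decay rate meeting a budget cap, tiered (stepped) price
    schedules, a NWBI-to-PHP nomogram for suggesting decay rates for new
    drugs, and a synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
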