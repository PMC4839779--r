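#' Nationwide budget impact
#'
#' The undiscounted worst case: full price per patient times the total
#' candidate population. This is deliberately not the decay-adjusted
#' expenditure — it is the number that motivates a price-volume agreement
#' in the first place.
#'
#' @param f_price Full price per patient in EUR; positive.
#' @param tot_pt Total candidate population; positive.
#' @return NWBI in EUR.
#' @examples
#' nwbi(35000, 1e6)   # 35 billion EUR
#' @export
nwbi <- function(f_price, tot_pt) {
  stopifnot(is.numeric(f_price), is.numeric(tot_pt))
  if (any(f_price <= 0) || any(tot_pt <= 0))
    stop("'f_price' and 'tot_pt' must be strictly positive", call. = FALSE)
  f_price * tot_pt
}

#' Total expenditure over a treated population
#'
#' The total expenditure for treating the first `n` patients is the area
#' under the price-volume curve from 0 to `n`. Two routes are provided:
#' the exact integral of the exponential model,
#' `f_price * (1 - exp(-k n)) / k` (or `f_price * n` for a flat model), and
#' the composite trapezoidal rule on a uniform grid of `step` patients (the
#' final partial panel is handled exactly). The trapezoid total always lies
#' at or above the analytic total, since the integrand is convex, and
#' converges at O(step^2).
#'
#' @param model A [pv_model()].
#' @param n Number of treated patients; positive.
#' @param method `"analytic"` (default) or `"trapezoid"`.
#' @param step Grid spacing in patients for the trapezoid method; defaults
#'   to `max(1, n / 1e5)`. Recorded in the result, never silent.
#' @return An object of class `pv_expenditure`: list with `total`,
#'   `average_per_patient`, `n_patients`, `method`, and `step` (trapezoid
#'   only, else `NA`).
#' @examples
#' m <- fit_two_points(pv_point(0, 9050), pv_point(20000, 6500))
#' total_expenditure(m, 20000)
#' @export
total_expenditure <- function(model, n, method = c("analytic", "trapezoid"),
                              step = NULL) {
  stopifnot(inherits(model, "pv_model"), is.numeric(n), length(n) == 1L)
  method <- match.arg(method)
  if (!is.finite(n) || n <= 0)
    stop("'n' must be a finite positive patient count", call. = FALSE)
  if (model$decay_k < 0)
    stop("expenditure is undefined for a rising-price model", call. = FALSE)
  if (method == "analytic") {
    total <- if (model$decay_k == 0) model$f_price * n
             else model$f_price * (1 - exp(-model$decay_k * n)) / model$decay_k
    step <- NA_real_
  } else {
    if (is.null(step)) step <- max(1, n / 1e5)
    if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
        step <= 0 || step > n)
      stop("'step' must satisfy 0 < step <= n", call. = FALSE)
    grid <- seq(0, n, by = step)
    if (grid[length(grid)] < n) grid <- c(grid, n)
    total <- pracma::trapz(grid, price_at(model, grid))
  }
  structure(list(total = total,
                 average_per_patient = total / n,
                 n_patients = n,
                 method = method,
                 step = step),
            class = "pv_expenditure")
}

#' @export
print.pv_expenditure <- function(x, ...) {
  cat(sprintf("Expenditure over %s patients (%s%s)\n",
              format(x$n_patients, big.mark = ","), x$method,
              if (x$method == "trapezoid") sprintf(", step = %g", x$step) else ""))
  cat(sprintf("  total:               %s EUR\n", format(round(x$total), big.mark = ",")))
  cat(sprintf("  average per patient: %s EUR\n",
              format(round(x$average_per_patient), big.mark = ",")))
  invisible(x)
}

#' Average cost per patient, closed form
#'
#' `(f_price - price_at(tot_pt)) / (decay_k * tot_pt)` — algebraically
#' identical to the analytic total expenditure divided by `tot_pt`, with
#' `price_at(tot_pt)` being the price reached at the last treated patient.
#' Equals `f_price` for a flat model.
#'
#' @param model A [pv_model()].
#' @param tot_pt Number of treated patients; positive.
#' @return Average cost per patient in EUR.
#' @examples
#' m <- fit_two_points(pv_point(0, 37500), pv_point(60000, 4000))
#' round(average_cost(m, 60000))
#' @export
average_cost <- function(model, tot_pt) {
  stopifnot(inherits(model, "pv_model"), is.numeric(tot_pt), length(tot_pt) == 1L)
  if (!is.finite(tot_pt) || tot_pt <= 0)
    stop("'tot_pt' must be a finite positive patient count", call. = FALSE)
  if (model$decay_k == 0) return(model$f_price)
  (model$f_price - price_at(model, tot_pt)) / (model$decay_k * tot_pt)
}

#' Solve for the decay rate that meets a budget cap
#'
#' Inverse budget problem: given the full price, the candidate population,
#' and a national budget cap, find the decay constant whose analytic total
#' expenditure over `tot_pt` patients equals the cap. The total is strictly
#' decreasing in `decay_k`, so the root is unique; it is located by a
#' bracketed root search on `[0, log(f_price / 0.01)]` (the upper bracket is
#' the rate that discounts the price to one cent within a single patient)
#' and refined to relative accuracy 1e-10 on the total.
#'
#' @param f_price Full price per patient in EUR.
#' @param tot_pt Candidate population; positive.
#' @param budget_cap Target total expenditure in EUR; must be positive.
#'   A cap at or above `f_price * tot_pt` needs no discount: a flat model is
#'   returned with `attr(model, "no_discount_needed") = TRUE`.
#' @param half_life_const Passed to the model constructor.
#' @return A [pv_model()].
#' @examples
#' m <- solve_decay_for_budget(37500, 60000, 9e8)
#' total_expenditure(m, 60000)$total
#' @export
solve_decay_for_budget <- function(f_price, tot_pt, budget_cap,
                                   half_life_const = 0.693) {
  stopifnot(is.numeric(f_price), is.numeric(tot_pt), is.numeric(budget_cap))
  if (f_price <= 0 || tot_pt <= 0)
    stop("'f_price' and 'tot_pt' must be strictly positive", call. = FALSE)
  if (budget_cap <= 0)
    stop("'budget_cap' must be strictly positive", call. = FALSE)
  if (budget_cap >= f_price * tot_pt) {
    m <- pv_model(f_price, 0, half_life_const)
    attr(m, "no_discount_needed") <- TRUE
    return(m)
  }
  total_at <- function(k) {
    if (k == 0) f_price * tot_pt else f_price * (1 - exp(-k * tot_pt)) / k
  }
  k_hi <- log(f_price / 0.01)
  if (total_at(k_hi) > budget_cap)
    stop("budget cap below the attainable minimum expenditure", call. = FALSE)
  root <- stats::uniroot(function(k) total_at(k) - budget_cap,
                         lower = 0, upper = k_hi,
                         tol = .Machine$double.eps * k_hi)
  pv_model(f_price, root$root, half_life_const)
}

#' Tiered (stepped) price schedule matching the continuous model
#'
#' Real agreements publish stepped prices per volume band rather than a
#' continuous curve. Each band `[lo, hi)` receives the volume-averaged model
#' price over the band (analytic area over the band divided by band width),
#' so the schedule's total expenditure over any whole band equals the
#' continuous model's exactly.
#'
#' @param model A [pv_model()].
#' @param band_edges Strictly ascending upper band edges in patients, all
#'   positive; bands are `[0, e1), [e1, e2), ...`.
#' @return A data frame with columns `lower`, `upper`, `price_eur`.
#' @examples
#' m <- fit_two_points(pv_point(0, 37500), pv_point(60000, 4000))
#' tier_schedule(m, c(20000, 40000, 60000))
#' @export
tier_schedule <- function(model, band_edges) {
  stopifnot(inherits(model, "pv_model"), is.numeric(band_edges))
  if (length(band_edges) < 1L || any(!is.finite(band_edges)) ||
      band_edges[1L] <= 0 || any(diff(band_edges) <= 0))
    stop("'band_edges' must be strictly ascending and start above 0", call. = FALSE)
  lower <- c(0, band_edges[-length(band_edges)])
  upper <- band_edges
  auc_to <- function(n) {
    if (model$decay_k == 0) model$f_price * n
    else model$f_price * (1 - exp(-model$decay_k * n)) / model$decay_k
  }
  band_auc <- vapply(upper, auc_to, numeric(1L)) - vapply(lower, auc_to, numeric(1L))
  data.frame(lower = lower, upper = upper,
             price_eur = band_auc / (upper - lower))
}

#' Construct a named drug agreement
#'
#' Bundles a fitted decay model with the drug's total candidate population.
#' The nationwide budget impact (`f_price * tot_pt`) is derived on
#' construction; these are the objects a nomogram is built from.
#'
#' @param drug Drug name (label only).
#' @param model A [pv_model()].
#' @param tot_pt Total candidate population; positive.
#' @return An object of class `pv_agreement`: list with `drug`, `model`,
#'   `tot_pt`, `nwbi`.
#' @examples
#' m <- fit_two_points(pv_point(0, 9050), pv_point(20000, 6500))
#' pv_agreement("ranibizumab", m, tot_pt = 20000)
#' @export
pv_agreement <- function(drug, model, tot_pt) {
  stopifnot(is.character(drug), length(drug) == 1L,
            inherits(model, "pv_model"),
            is.numeric(tot_pt), length(tot_pt) == 1L)
  if (!is.finite(tot_pt) || tot_pt <= 0)
    stop("'tot_pt' must be a finite positive patient count", call. = FALSE)
  structure(list(drug = drug, model = model, tot_pt = as.numeric(tot_pt),
                 nwbi = nwbi(model$f_price, tot_pt)),
            class = "pv_agreement")
}

#' @export
print.pv_agreement <- function(x, ...) {
  cat(sprintf("Price-volume agreement: %s\n", x$drug))
  cat(sprintf("  candidate population (totPT): %s patients\n",
              format(x$tot_pt, big.mark = ",")))
  cat(sprintf("  nationwide budget impact:     %s EUR\n",
              format(x$nwbi, big.mark = ",", scientific = FALSE)))
  print(x$model)
  invisible(x)
}
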