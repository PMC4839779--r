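#' Construct a price-volume observation
#'
#' One observation of a price-volume agreement: the cumulative number of
#' patients treated so far and the per-patient treatment price charged at
#' that volume. Volumes may be fractional (e.g. vials prorated to patient
#' equivalents); prices must be strictly positive.
#'
#' @param n_treated Cumulative number of treated patients (non-negative).
#' @param price Price per patient in EUR (strictly positive).
#' @return An object of class `pv_point`: a list with elements `n_treated`
#'   and `price`.
#' @examples
#' pv_point(0, 9050)
#' pv_point(20000, 6500)
#' @export
pv_point <- function(n_treated, price) {
  stopifnot(is.numeric(n_treated), length(n_treated) == 1L,
            is.numeric(price), length(price) == 1L)
  if (!is.finite(n_treated) || n_treated < 0)
    stop("'n_treated' must be a finite non-negative number", call. = FALSE)
  if (!is.finite(price) || price <= 0)
    stop("'price' must be a finite, strictly positive number", call. = FALSE)
  structure(list(n_treated = as.numeric(n_treated), price = as.numeric(price)),
            class = "pv_point")
}

#' Construct an exponential price-decay model
#'
#' The model assumes the per-patient price undergoes first-order exponential
#' decay in the cumulative number of treated patients `n`:
#' `price(n) = f_price * exp(-decay_k * n)`. Its "half-life" expressed in
#' patients is the price-halving population (PHP), `half_life_const / decay_k`.
#'
#' @param f_price Full (undiscounted) price per patient in EUR at `n = 0`;
#'   strictly positive.
#' @param decay_k First-order decay constant, units patients^-1; non-negative.
#'   `decay_k = 0` is a legitimate flat-price (no-discount) agreement whose
#'   PHP is infinite.
#' @param half_life_const Dimensionless constant converting `decay_k` to PHP.
#'   Defaults to `0.693`; `log(2)` gives an exact halving at `n = php`.
#' @return An object of class `pv_model`.
#' @seealso [price_at()], [php_of()], [fit_two_points()], [fit_log_linear()]
#' @examples
#' m <- pv_model(f_price = 9050, decay_k = 1.655e-5)
#' price_at(m, 20000)
#' @export
pv_model <- function(f_price, decay_k, half_life_const = 0.693) {
  m <- new_pv_model(f_price, decay_k, half_life_const)
  if (m$decay_k < 0)
    stop("'decay_k' must be non-negative (a rising price is not a price-volume agreement)",
         call. = FALSE)
  m
}

# internal constructor: permits decay_k < 0 so that fit_log_linear can return
# a flagged rising-price fit instead of silently clamping it
new_pv_model <- function(f_price, decay_k, half_life_const = 0.693) {
  stopifnot(is.numeric(f_price), length(f_price) == 1L,
            is.numeric(decay_k), length(decay_k) == 1L,
            is.numeric(half_life_const), length(half_life_const) == 1L)
  if (!is.finite(f_price) || f_price <= 0)
    stop("'f_price' must be a finite, strictly positive number", call. = FALSE)
  if (!is.finite(decay_k))
    stop("'decay_k' must be finite", call. = FALSE)
  if (!is.finite(half_life_const) || half_life_const <= 0)
    stop("'half_life_const' must be positive", call. = FALSE)
  structure(list(f_price = as.numeric(f_price),
                 decay_k = as.numeric(decay_k),
                 half_life_const = as.numeric(half_life_const)),
            class = "pv_model")
}

#' @export
print.pv_model <- function(x, ...) {
  cat("Price-volume decay model\n")
  cat(sprintf("  full price (f_price): %s EUR per patient\n",
              format(x$f_price, big.mark = ",")))
  cat(sprintf("  decay constant (k):   %.6g patients^-1\n", x$decay_k))
  php <- php_of(x)
  cat(sprintf("  PHP (%s / k):       %s patients\n", format(x$half_life_const),
              if (is.finite(php)) format(round(php), big.mark = ",") else "infinite (flat price)"))
  if (isTRUE(attr(x, "rising_price")))
    cat("  WARNING: fitted slope implies a rising price (decay_k < 0)\n")
  invisible(x)
}

#' Price at a given cumulative patient volume
#'
#' Evaluates `f_price * exp(-decay_k * n)`. Strictly decreasing in `n` when
#' `decay_k > 0`; constant at `f_price` for a flat model.
#'
#' @param model A [pv_model()].
#' @param n Cumulative treated patients; non-negative, may be a vector.
#' @return Price(s) per patient in EUR.
#' @examples
#' m <- fit_two_points(pv_point(0, 9050), pv_point(20000, 6500))
#' price_at(m, c(0, 20000))
#' @export
price_at <- function(model, n) {
  stopifnot(inherits(model, "pv_model"), is.numeric(n))
  if (any(!is.finite(n)) || any(n < 0))
    stop("'n' must be finite and non-negative", call. = FALSE)
  model$f_price * exp(-model$decay_k * n)
}

#' Fit the decay model through two price-volume observations
#'
#' Exact two-point fit: `decay_k = (log(p1) - log(p2)) / (n2 - n1)`. When the
#' first observation sits at `n = 0` (the usual anchoring, since the launch
#' price is public), `f_price` is taken directly from it; otherwise `f_price`
#' is back-extrapolated to `n = 0`. The fitted model reproduces both inputs
#' to floating precision.
#'
#' @param p1,p2 [pv_point()] observations with `p1$n_treated < p2$n_treated`.
#' @param half_life_const Passed to [pv_model()].
#' @return A [pv_model()].
#' @examples
#' fit_two_points(pv_point(0, 37500), pv_point(60000, 4000))
#' @export
fit_two_points <- function(p1, p2, half_life_const = 0.693) {
  stopifnot(inherits(p1, "pv_point"), inherits(p2, "pv_point"))
  if (p1$n_treated == p2$n_treated)
    stop("degenerate input: the two observations have equal 'n_treated'", call. = FALSE)
  if (p1$n_treated > p2$n_treated)
    stop("'p1' must precede 'p2': p1$n_treated < p2$n_treated", call. = FALSE)
  if (p2$price > p1$price)
    stop("price rises between the two observations; a price-volume agreement requires a non-increasing price",
         call. = FALSE)
  k <- (log(p1$price) - log(p2$price)) / (p2$n_treated - p1$n_treated)
  f <- if (p1$n_treated == 0) p1$price else p1$price * exp(k * p1$n_treated)
  pv_model(f_price = f, decay_k = k, half_life_const = half_life_const)
}

#' Fit the decay model to many observations by log-linear least squares
#'
#' A logarithmic transformation of the price axis turns the exponential decay
#' into a straight line, so the model is fitted by ordinary least squares of
#' `log(price)` on `n_treated`: the slope estimates `-decay_k` and the
#' intercept `log(f_price)`. With `anchor_f_price` supplied, the intercept is
#' fixed at `log(anchor_f_price)` and only `decay_k` is estimated
#' (one-parameter constrained least squares). With exactly two points the
#' result equals [fit_two_points()] bit-for-bit (two-point OLS is exact
#' interpolation).
#'
#' A fitted positive slope (rising price, `decay_k < 0`) — possible under
#' noise — is not clamped: the model is returned with a warning and with
#' `attr(model, "rising_price") = TRUE`, and the caller decides.
#'
#' @param points A list of [pv_point()]s, or a data frame with columns
#'   `n_treated` and `price_eur` (the observation CSV dialect).
#' @param anchor_f_price Optional known full price fixing the intercept.
#' @param half_life_const Passed to the model constructor.
#' @return A [pv_model()] with attribute `sigma` (residual standard error on
#'   the log scale; `NA` for a saturated two-point fit).
#' @examples
#' obs <- simulate_observations(f_price = 9050, decay_k = 1.655e-5,
#'                              n_points = 20, n_max = 40000,
#'                              noise_sigma = 0.05, seed = 1)
#' fit_log_linear(obs)
#' @export
fit_log_linear <- function(points, anchor_f_price = NULL, half_life_const = 0.693) {
  df <- as_pv_frame(points)
  if (length(unique(df$n_treated)) < 2L)
    stop("degenerate input: need at least 2 observations with distinct 'n_treated'",
         call. = FALSE)
  if (!is.null(anchor_f_price)) {
    if (!is.numeric(anchor_f_price) || anchor_f_price <= 0)
      stop("'anchor_f_price' must be strictly positive", call. = FALSE)
    # intercept fixed at log(anchor): minimize sum((y - b0 + k*n)^2) over k
    y <- log(df$price_eur) - log(anchor_f_price)
    k <- -sum(df$n_treated * y) / sum(df$n_treated^2)
    f <- anchor_f_price
    res <- y + k * df$n_treated
    sigma <- if (nrow(df) > 1L) sqrt(sum(res^2) / (nrow(df) - 1L)) else NA_real_
  } else if (nrow(df) == 2L) {
    # closed two-point form, identical to fit_two_points
    o <- df[order(df$n_treated), ]
    k <- (log(o$price_eur[1L]) - log(o$price_eur[2L])) / (o$n_treated[2L] - o$n_treated[1L])
    f <- if (o$n_treated[1L] == 0) o$price_eur[1L] else o$price_eur[1L] * exp(k * o$n_treated[1L])
    sigma <- NA_real_
  } else {
    fit <- stats::lm(log(price_eur) ~ n_treated, data = df)
    k <- -unname(stats::coef(fit)[["n_treated"]])
    f <- exp(unname(stats::coef(fit)[["(Intercept)"]]))
    # computed directly so a perfect (noise-free) fit stays silent
    sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  }
  m <- new_pv_model(f_price = f, decay_k = k, half_life_const = half_life_const)
  attr(m, "sigma") <- sigma
  if (k < 0) {
    attr(m, "rising_price") <- TRUE
    warning("fitted slope implies a rising price (decay_k < 0); model returned flagged, not clamped",
            call. = FALSE)
  }
  m
}

# accept list-of-pv_point, data.frame, or 2-column matrix
as_pv_frame <- function(points) {
  if (is.data.frame(points)) {
    nm <- names(points)
    ncol_ok <- all(c("n_treated", "price_eur") %in% nm)
    if (!ncol_ok && all(c("n_treated", "price") %in% nm)) {
      points$price_eur <- points$price
      ncol_ok <- TRUE
    }
    if (!ncol_ok)
      stop("data frame must have columns 'n_treated' and 'price_eur'", call. = FALSE)
    df <- points[, c("n_treated", "price_eur")]
  } else if (is.list(points) && length(points) > 0L &&
             all(vapply(points, inherits, logical(1L), "pv_point"))) {
    df <- data.frame(n_treated = vapply(points, `[[`, numeric(1L), "n_treated"),
                     price_eur = vapply(points, `[[`, numeric(1L), "price"))
  } else {
    stop("'points' must be a data frame or a list of pv_point objects", call. = FALSE)
  }
  if (nrow(df) < 2L)
    stop("degenerate input: need at least 2 observations", call. = FALSE)
  if (any(!is.finite(df$n_treated)) || any(df$n_treated < 0))
    stop("'n_treated' values must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(df$price_eur)) || any(df$price_eur <= 0))
    stop("prices must be finite and strictly positive", call. = FALSE)
  df
}

#' Price-halving population of a fitted model
#'
#' The number of patients over which the price halves:
#' `half_life_const / decay_k`, computed on the unrounded decay constant.
#' Rounding to whole patients is presentation only. A flat model
#' (`decay_k = 0`) has an infinite PHP.
#'
#' @param model A [pv_model()].
#' @return PHP in patients; `Inf` for a flat model.
#' @examples
#' m <- fit_two_points(pv_point(0, 9050), pv_point(20000, 6500))
#' round(php_of(m))   # 41878
#' @export
php_of <- function(model) {
  stopifnot(inherits(model, "pv_model"))
  if (model$decay_k == 0) return(Inf)
  if (model$decay_k < 0) {
    warning("model has a rising price (decay_k < 0); PHP is undefined", call. = FALSE)
    return(NA_real_)
  }
  model$half_life_const / model$decay_k
}

#' Decay constant implied by a price-halving population
#'
#' Inverse of [php_of()]: `half_life_const / php`. Round-trips with
#' [php_of()] to machine precision; an infinite PHP maps to `decay_k = 0`.
#'
#' @param php Price-halving population in patients; positive (may be `Inf`).
#' @param half_life_const Dimensionless halving constant (default 0.693).
#' @return Decay constant in patients^-1.
#' @examples
#' k_from_php(41878)
#' @export
k_from_php <- function(php, half_life_const = 0.693) {
  stopifnot(is.numeric(php), length(php) == 1L)
  if (is.na(php) || php <= 0)
    stop("'php' must be strictly positive", call. = FALSE)
  if (is.infinite(php)) return(0)
  half_life_const / php
}
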