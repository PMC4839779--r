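#' Simulate noisy price-volume observations from a known decay model
#'
#' Generates `n_points` observations whose volumes span `[0, n_max]` —
#' evenly spaced by default, or drawn uniformly — and whose prices are the
#' model curve perturbed by noise. The default noise is multiplicative
#' log-normal, `price_i = f_price * exp(-decay_k * n_i) * exp(eps_i)` with
#' `eps_i ~ N(0, noise_sigma^2)`: the model is linear in log-price, so this
#' keeps the noise conjugate to the log-linear least-squares fit and prices
#' strictly positive by construction. Additive EUR noise is available as an
#' option (negative draws are rejected and resampled). Volumes are
#' noise-free: the payer counts patients exactly.
#'
#' The same spec and seed always reproduce the identical dataset; the
#' global RNG state is left untouched.
#'
#' @param f_price Full price per patient in EUR; positive.
#' @param decay_k Decay constant in patients^-1; non-negative.
#' @param n_points Number of observations; at least 2.
#' @param n_max Largest volume; positive.
#' @param noise_sigma Noise scale: log-scale SD for `"lognormal"`, EUR SD
#'   for `"additive"`. Non-negative; 0 gives points exactly on the curve.
#' @param seed RNG seed (integer).
#' @param spacing `"even"` (default) or `"uniform"` random volumes.
#' @param noise `"lognormal"` (default) or `"additive"`.
#' @return A data frame with columns `n_treated`, `price_eur` — the same
#'   dialect the fitting functions and the observation CSV use.
#' @examples
#' obs <- simulate_observations(9050, 1.655e-5, n_points = 50,
#'                              n_max = 40000, noise_sigma = 0.05, seed = 42)
#' fit_log_linear(obs)
#' @export
simulate_observations <- function(f_price, decay_k, n_points, n_max,
                                  noise_sigma = 0, seed = 1L,
                                  spacing = c("even", "uniform"),
                                  noise = c("lognormal", "additive")) {
  spacing <- match.arg(spacing)
  noise <- match.arg(noise)
  stopifnot(is.numeric(f_price), is.numeric(decay_k), is.numeric(n_points),
            is.numeric(n_max), is.numeric(noise_sigma))
  if (f_price <= 0) stop("'f_price' must be strictly positive", call. = FALSE)
  if (decay_k < 0) stop("'decay_k' must be non-negative", call. = FALSE)
  if (n_points < 2) stop("'n_points' must be at least 2", call. = FALSE)
  if (n_max <= 0) stop("'n_max' must be strictly positive", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n <- if (spacing == "even") seq(0, n_max, length.out = n_points)
       else sort(stats::runif(n_points, 0, n_max))
  curve <- f_price * exp(-decay_k * n)
  price <- if (noise == "lognormal") {
    curve * exp(stats::rnorm(n_points, 0, noise_sigma))
  } else {
    p <- curve + stats::rnorm(n_points, 0, noise_sigma)
    while (any(p <= 0))
      p[p <= 0] <- curve[p <= 0] + stats::rnorm(sum(p <= 0), 0, noise_sigma)
    p
  }
  data.frame(n_treated = n, price_eur = price)
}
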