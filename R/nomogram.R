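#' Build a NWBI-to-PHP nomogram from reference agreements
#'
#' Each reference agreement contributes one point: its nationwide budget
#' impact on the x-axis and its price-halving population expressed as a
#' percentage of the candidate population (`100 * php / tot_pt`) on the
#' y-axis. Drugs with a heavier budget impact need a faster price decay,
#' i.e. a smaller PHP relative to their population; the nomogram turns that
#' observed relationship into a lookup rule for new drugs.
#'
#' Flat-price agreements (infinite PHP) carry no decay information and are
#' excluded with a warning. Points are sorted by ascending NWBI; duplicate
#' NWBI values are rejected.
#'
#' @param agreements A list of [pv_agreement()] objects, at least 2 with a
#'   finite PHP.
#' @return An object of class `pv_nomogram`: list with `points` (data frame
#'   `nwbi_eur`, `php_pct`, `drug`) and `interpolation` (`"log_linear"`).
#' @examples
#' nom <- build_nomogram(list(pv_example_agreement("ranibizumab"),
#'                            pv_example_agreement("sofosbuvir")))
#' nom
#' @export
build_nomogram <- function(agreements) {
  if (inherits(agreements, "pv_agreement")) agreements <- list(agreements)
  stopifnot(is.list(agreements),
            all(vapply(agreements, inherits, logical(1L), "pv_agreement")))
  php <- vapply(agreements, function(a) php_of(a$model), numeric(1L))
  flat <- !is.finite(php)
  if (any(flat)) {
    warning(sprintf("excluding %d flat-price agreement(s) with infinite PHP", sum(flat)),
            call. = FALSE)
    agreements <- agreements[!flat]
    php <- php[!flat]
  }
  if (length(agreements) < 2L)
    stop("need at least 2 reference agreements with a finite PHP", call. = FALSE)
  pts <- data.frame(
    nwbi_eur = vapply(agreements, `[[`, numeric(1L), "nwbi"),
    php_pct  = 100 * php / vapply(agreements, `[[`, numeric(1L), "tot_pt"),
    drug     = vapply(agreements, `[[`, character(1L), "drug"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(pts$nwbi_eur))
    stop("degenerate input: duplicate NWBI values among the references", call. = FALSE)
  pts <- pts[order(pts$nwbi_eur), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, interpolation = "log_linear"),
            class = "pv_nomogram")
}

#' @export
print.pv_nomogram <- function(x, ...) {
  cat(sprintf("NWBI-to-PHP nomogram (%d reference points, %s interpolation)\n",
              nrow(x$points), x$interpolation))
  print(transform(x$points, php_pct = round(php_pct, 2)), row.names = FALSE)
  invisible(x)
}

#' Read PHP percentage off the nomogram for a given budget impact
#'
#' Linear interpolation of `php_pct` against `log10(nwbi)` between the
#' bracketing reference points: the billions-scale x-axis makes raw-linear
#' interpolation pathological, and log spacing matches how budget impacts
#' are compared in practice. Queries at a reference NWBI return that
#' reference's value exactly. Outside the reference range, the nearest
#' endpoint's value is returned and the result carries
#' `attr(., "extrapolated") = TRUE` — never a silent extrapolation, since
#' with few references the relationship is only suggestive.
#'
#' @param nomogram A [build_nomogram()] result.
#' @param nwbi_eur Query budget impact in EUR; positive, may be a vector.
#' @return PHP as a percentage of totPT, with attribute `extrapolated`
#'   (logical, same length).
#' @export
predict_php_pct <- function(nomogram, nwbi_eur) {
  stopifnot(inherits(nomogram, "pv_nomogram"), is.numeric(nwbi_eur))
  if (any(!is.finite(nwbi_eur)) || any(nwbi_eur <= 0))
    stop("'nwbi_eur' must be finite and strictly positive", call. = FALSE)
  pts <- nomogram$points
  out <- stats::approx(x = log10(pts$nwbi_eur), y = pts$php_pct,
                       xout = log10(nwbi_eur), method = "linear",
                       rule = 2, ties = "ordered")$y
  # relative slack so queries at the endpoints themselves never flag
  extrap <- nwbi_eur < min(pts$nwbi_eur) * (1 - 1e-9) |
            nwbi_eur > max(pts$nwbi_eur) * (1 + 1e-9)
  if (any(extrap))
    warning("query outside the nomogram's reference range; clamped to the nearest endpoint",
            call. = FALSE)
  attr(out, "extrapolated") <- extrap
  out
}

#' Suggest a PHP (and decay rate) for a new drug
#'
#' Computes the drug's NWBI from its full price and candidate population,
#' reads the PHP percentage off the nomogram, and converts it back to a
#' patient count (`php_pct / 100 * tot_pt`) and to the implied decay
#' constant.
#'
#' @param nomogram A [build_nomogram()] result.
#' @param f_price Full price per patient in EUR.
#' @param tot_pt Candidate population in patients.
#' @param half_life_const Halving constant for the implied decay rate.
#' @return A list with `nwbi_eur`, `php_pct`, `php`, `decay_k`, and
#'   `extrapolated`.
#' @examples
#' nom <- build_nomogram(list(pv_example_agreement("ranibizumab"),
#'                            pv_example_agreement("sofosbuvir")))
#' predict_php(nom, f_price = 9050, tot_pt = 20000)
#' @export
predict_php <- function(nomogram, f_price, tot_pt, half_life_const = 0.693) {
  stopifnot(is.numeric(f_price), length(f_price) == 1L,
            is.numeric(tot_pt), length(tot_pt) == 1L)
  if (f_price <= 0 || tot_pt <= 0)
    stop("'f_price' and 'tot_pt' must be strictly positive", call. = FALSE)
  x <- nwbi(f_price, tot_pt)
  pct <- predict_php_pct(nomogram, x)
  php <- as.numeric(pct) / 100 * tot_pt
  list(nwbi_eur = x,
       php_pct = as.numeric(pct),
       php = php,
       decay_k = k_from_php(php, half_life_const),
       extrapolated = as.logical(attr(pct, "extrapolated")))
}
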