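#' Read price-volume observations from CSV
#'
#' The observation dialect is a UTF-8 CSV with header `n_treated,price_eur`
#' and dot decimal separator.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `n_treated`, `price_eur`.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("n_treated", "price_eur") %in% names(df)))
    stop("expected CSV header 'n_treated,price_eur' in ", path, call. = FALSE)
  bad <- which(!is.finite(df$n_treated) | !is.finite(df$price_eur) |
                 df$n_treated < 0 | df$price_eur <= 0)
  if (length(bad))
    stop(sprintf("invalid observation on data line %d of %s", bad[1L], path),
         call. = FALSE)
  if (nrow(df) < 2L)
    stop("need at least 2 points in ", path, call. = FALSE)
  df[, c("n_treated", "price_eur")]
}

#' Write price-volume observations to CSV
#'
#' @param obs Data frame with columns `n_treated`, `price_eur`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(is.data.frame(obs), all(c("n_treated", "price_eur") %in% names(obs)))
  utils::write.csv(obs[, c("n_treated", "price_eur")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize / deserialize a fitted model as flat JSON
#'
#' The on-disk form is a flat JSON object
#' `{drug, f_price, decay_k, half_life_const}` with that field order; the
#' round trip preserves 15 significant digits.
#'
#' @param model A [pv_model()].
#' @param path Output path.
#' @param drug Optional drug label stored alongside the parameters.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a [pv_model()] with attribute `drug`.
#' @export
write_model_json <- function(model, path, drug = NA_character_) {
  stopifnot(inherits(model, "pv_model"))
  obj <- list(drug = drug, f_price = model$f_price,
              decay_k = model$decay_k, half_life_const = model$half_life_const)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("f_price", "decay_k", "half_life_const"))
    if (is.null(obj[[f]]))
      stop("model JSON is missing required field '", f, "'", call. = FALSE)
  m <- pv_model(obj$f_price, obj$decay_k, obj$half_life_const)
  attr(m, "drug") <- if (is.null(obj$drug)) NA_character_ else obj$drug
  m
}

#' Read an agreement descriptor JSON
#'
#' The descriptor is `{drug, f_price_eur, tot_pt, data_pairs: [[n, price],
#' ...]}`. The model is fitted from `data_pairs` (two-point fit for exactly
#' two pairs, log-linear otherwise); `f_price_eur`, when present, anchors
#' the fit's intercept and is cross-checked against the pairs.
#'
#' @param path Path to the descriptor JSON.
#' @param half_life_const Halving constant for the fit.
#' @return A [pv_agreement()].
#' @export
read_agreement <- function(path, half_life_const = 0.693) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("drug", "tot_pt", "data_pairs"))
    if (is.null(obj[[f]]))
      stop("agreement JSON is missing required field '", f, "'", call. = FALSE)
  pairs <- obj$data_pairs
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.numeric(pairs), ncol = 2)
  df <- data.frame(n_treated = pairs[, 1L], price_eur = pairs[, 2L])
  model <- if (nrow(df) == 2L) {
    o <- df[order(df$n_treated), ]
    fit_two_points(pv_point(o$n_treated[1L], o$price_eur[1L]),
                   pv_point(o$n_treated[2L], o$price_eur[2L]),
                   half_life_const = half_life_const)
  } else {
    fit_log_linear(df, half_life_const = half_life_const)
  }
  if (!is.null(obj$f_price_eur) &&
      abs(model$f_price - obj$f_price_eur) > 1e-6 * obj$f_price_eur)
    warning("declared 'f_price_eur' disagrees with the fitted full price",
            call. = FALSE)
  pv_agreement(obj$drug, model, obj$tot_pt)
}

#' Write a nomogram to CSV with a JSON sidecar
#'
#' The CSV carries the reference points (`nwbi_eur,php_pct`); the sidecar
#' (`<path>.json`) records the interpolation mode and the drug labels, so
#' the provenance of each reference survives the round trip.
#'
#' @param nomogram A [build_nomogram()] result.
#' @param path Output CSV path.
#' @return `write_nomogram()` returns `path` invisibly; `read_nomogram()`
#'   returns a `pv_nomogram`.
#' @export
write_nomogram <- function(nomogram, path) {
  stopifnot(inherits(nomogram, "pv_nomogram"))
  utils::write.csv(nomogram$points[, c("nwbi_eur", "php_pct")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(interpolation = nomogram$interpolation,
                            drugs = nomogram$points$drug),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nomogram
#' @export
read_nomogram <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("nwbi_eur", "php_pct") %in% names(df)))
    stop("expected CSV header 'nwbi_eur,php_pct' in ", path, call. = FALSE)
  side <- paste0(path, ".json")
  interp <- "log_linear"
  drugs <- rep(NA_character_, nrow(df))
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$interpolation)) interp <- meta$interpolation
    if (!is.null(meta$drugs) && length(meta$drugs) == nrow(df)) drugs <- meta$drugs
  }
  df <- df[order(df$nwbi_eur), , drop = FALSE]
  pts <- data.frame(nwbi_eur = df$nwbi_eur, php_pct = df$php_pct,
                    drug = drugs, stringsAsFactors = FALSE)
  rownames(pts) <- NULL
  if (nrow(pts) < 2L || anyDuplicated(pts$nwbi_eur))
    stop("nomogram needs >= 2 reference points with distinct NWBI", call. = FALSE)
  structure(list(points = pts, interpolation = interp), class = "pv_nomogram")
}

#' Packaged reference data: the two worked national agreements
#'
#' Two national price-volume agreements ship with the package as fixtures:
#' ranibizumab for macular degeneration (launch price 9,050 EUR per
#' patient, discounted to 6,500 EUR after 20,000 treated patients) and
#' sofosbuvir for hepatitis C (37,500 EUR per 12-week treatment,
#' discounted to 4,000 EUR after 60,000 patients). The candidate-population
#' values attached to the agreements (20,000 and 60,000) are the volumes at
#' which the discounted prices were reported; the resulting nomogram is a
#' reconstruction, not an official chart.
#'
#' `pv_example_path()` returns the path to a fixture file;
#' `pv_example_agreement()` returns the fitted [pv_agreement()].
#'
#' @param drug `"ranibizumab"` or `"sofosbuvir"`.
#' @param type For `pv_example_path()`: `"csv"` (observations) or `"json"`
#'   (agreement descriptor).
#' @return A file path, or a [pv_agreement()].
#' @examples
#' read_observations(pv_example_path("ranibizumab"))
#' pv_example_agreement("sofosbuvir")
#' @export
pv_example_path <- function(drug = c("ranibizumab", "sofosbuvir"),
                            type = c("csv", "json")) {
  drug <- match.arg(drug)
  type <- match.arg(type)
  system.file("extdata", paste0(drug, ".", type), package = "pricevolume",
              mustWork = TRUE)
}

#' @rdname pv_example_path
#' @export
pv_example_agreement <- function(drug = c("ranibizumab", "sofosbuvir")) {
  drug <- match.arg(drug)
  read_agreement(pv_example_path(drug, "json"))
}
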