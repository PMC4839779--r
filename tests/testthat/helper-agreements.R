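# The two worked national agreements, rebuilt from their public price pairs.
ranibizumab_model <- function(half_life_const = 0.693) {
  fit_two_points(pv_point(0, 9050), pv_point(20000, 6500),
                 half_life_const = half_life_const)
}

sofosbuvir_model <- function(half_life_const = 0.693) {
  fit_two_points(pv_point(0, 37500), pv_point(60000, 4000),
                 half_life_const = half_life_const)
}

reference_agreements <- function() {
  list(pv_agreement("ranibizumab", ranibizumab_model(), tot_pt = 20000),
       pv_agreement("sofosbuvir", sofosbuvir_model(), tot_pt = 60000))
}

# Run the packaged CLI in a child Rscript; returns stdout lines with the
# exit status in attr(., "status") (NULL means 0).
run_pv_cli <- function(args) {
  script <- system.file("cli", "pv.R", package = "pricevolume")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  suppressWarnings(system2(rscript, c(shQuote(script), args),
                           stdout = TRUE, stderr = FALSE,
                           env = paste0("R_LIBS=", shQuote(libs))))
}
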