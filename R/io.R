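# Small plain-text exporters for the package's result objects.

#' Write a path ledger to CSV (small runs only)
#'
#' One row per detected photon with its per-layer path lengths; intended
#' for small diagnostic runs, not 1e7-photon campaigns.
#'
#' @param ledger A [run_white_mc()] ledger.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  ledger_check(ledger)
  utils::write.csv(as.data.frame(tidy(ledger)), path, row.names = FALSE)
  invisible(path)
}

#' Write a reflectance table to CSV
#'
#' Amplitude/phase representation with component standard errors and the
#' modulation frequency, one row per source-detector pair.
#'
#' @param reflectance A `ds_reflectance` from [assemble_reflectance()].
#' @param path Output CSV path.
#' @param wavelength_nm Optional wavelength annotation column.
#' @return `path`, invisibly.
#' @export
write_reflectance_csv <- function(reflectance, path, wavelength_nm = NA) {
  r <- tibble::as_tibble(reflectance)
  out <- data.frame(
    source = r$source, detector = r$detector, rho_mm = r$rho,
    amplitude = Mod(r$value), phase_rad = Arg(r$value),
    se_amp = se_log_amp(r$value, r$se_re, r$se_im) * Mod(r$value),
    se_phase = se_phase(r$value, r$se_re, r$se_im),
    omega_rad_s = attr(reflectance, "omega"),
    wavelength_nm = wavelength_nm
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a layer-sensitivity matrix to JSON with provenance
#'
#' @param sensitivity A [build_sensitivity_matrix()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_json <- function(sensitivity, path) {
  stopifnot(inherits(sensitivity, "layer_sensitivity"))
  jsonlite::write_json(list(
    S = as.data.frame(sensitivity$S),
    fractions = as.data.frame(sensitivity$fractions),
    J_sum = as.list(sensitivity$J_sum),
    rank = sensitivity$rank, condition = sensitivity$condition,
    baseline_mua = sensitivity$mua, omega = sensitivity$omega
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
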