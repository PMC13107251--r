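# Dual-slope engine: the six DS FD-NIRS data types, the self-calibrated fit
# of effective homogeneous optical properties from dual-slope baseline data,
# retrieval of effective absorption changes, and Beer's-law conversion to
# hemoglobin concentration changes.

se_log_amp <- function(value, se_re, se_im) {
  a <- Mod(value)
  sqrt((Re(value) * se_re)^2 + (Im(value) * se_im)^2) / a^2
}

se_phase <- function(value, se_re, se_im) {
  a2 <- Mod(value)^2
  sqrt((Im(value) * se_re)^2 + (Re(value) * se_im)^2) / a2
}

#' Compute the six DS FD-NIRS data types from one dual-slope set
#'
#' From the four source-detector reflectances of a dual-slope set
#' (two sources, each with one short and one long distance), computes:
#' `sdi25`/`sdi37` (ln(rho^2 I) at the short/long distance, mirror pairs
#' averaged), `sdphi25`/`sdphi37` (phase, unwrapped within each source's
#' pair), and the dual slopes `dsi`/`dsphi` (mean of the two per-source
#' two-point slopes versus rho). The dual slopes are self-calibrating:
#' multiplying any single source's or detector's reflectances by an
#' arbitrary complex coupling factor leaves them unchanged.
#'
#' Column names keep the conventional 25/37 mm labels; the actual distances
#' are taken from the data and stored as attributes.
#'
#' @param reflectance A `ds_reflectance` tibble with the four pairs of one
#'   DS set (columns `source, detector, rho, value`, optionally
#'   `se_re, se_im`).
#' @return One-row tibble (class `ds_datatypes`) with the six data types
#'   and, when input uncertainties are present, their standard errors.
#' @export
compute_datatypes <- function(reflectance) {
  r <- tibble::as_tibble(reflectance)
  need <- c("source", "detector", "rho", "value")
  if (!all(need %in% names(r)))
    stop("reflectance must have columns source, detector, rho, value",
         call. = FALSE)
  if (nrow(r) != 4 || length(unique(r$source)) != 2)
    stop("a dual-slope set needs exactly four source-detector pairs ",
         "(two sources x two distances)", call. = FALSE)
  if (any(Mod(r$value) <= 0))
    stop("non-positive reflectance amplitude", call. = FALSE)
  rho_s <- min(r$rho); rho_l <- max(r$rho)
  if (rho_l - rho_s < 1e-9)
    stop("degenerate distance set: the two distances must differ",
         call. = FALSE)
  drho <- rho_l - rho_s
  has_se <- all(c("se_re", "se_im") %in% names(r))

  r$lnr2i <- log(r$rho^2 * Mod(r$value))
  if (has_se) {
    r$se_ln <- se_log_amp(r$value, r$se_re, r$se_im)
    r$se_ph <- se_phase(r$value, r$se_re, r$se_im)
  }

  per_src <- lapply(split(r, r$source), function(d) {
    d <- d[order(d$rho), ]
    if (nrow(d) != 2)
      stop("each source needs one short- and one long-distance pair",
           call. = FALSE)
    ph_s <- Arg(d$value[1])
    dph <- Arg(d$value[2] / d$value[1])   # nearest-branch unwrapping
    stopifnot(abs(dph) < pi)
    tibble::tibble(
      ln_s = d$lnr2i[1], ln_l = d$lnr2i[2],
      ph_s = ph_s, ph_l = ph_s + dph,
      slope_i = (d$lnr2i[2] - d$lnr2i[1]) / drho,
      slope_phi = dph / drho,
      se_ln_s = if (has_se) d$se_ln[1] else NA_real_,
      se_ln_l = if (has_se) d$se_ln[2] else NA_real_,
      se_ph_s = if (has_se) d$se_ph[1] else NA_real_,
      se_ph_l = if (has_se) d$se_ph[2] else NA_real_
    )
  })
  ps <- dplyr::bind_rows(per_src)

  out <- tibble::tibble(
    sdi25 = mean(ps$ln_s), sdi37 = mean(ps$ln_l),
    sdphi25 = mean(ps$ph_s), sdphi37 = mean(ps$ph_l),
    dsi = mean(ps$slope_i), dsphi = mean(ps$slope_phi)
  )
  if (has_se) {
    half <- function(a, b) sqrt(a^2 + b^2) / 2
    out$se_sdi25 <- half(ps$se_ln_s[1], ps$se_ln_s[2])
    out$se_sdi37 <- half(ps$se_ln_l[1], ps$se_ln_l[2])
    out$se_sdphi25 <- half(ps$se_ph_s[1], ps$se_ph_s[2])
    out$se_sdphi37 <- half(ps$se_ph_l[1], ps$se_ph_l[2])
    se_slope <- sqrt(ps$se_ln_s^2 + ps$se_ln_l^2) / drho
    out$se_dsi <- sqrt(sum(se_slope^2)) / 2
    se_slope_ph <- sqrt(ps$se_ph_s^2 + ps$se_ph_l^2) / drho
    out$se_dsphi <- sqrt(sum(se_slope_ph^2)) / 2
  }
  attr(out, "rho_short") <- rho_s
  attr(out, "rho_long") <- rho_l
  attr(out, "omega") <- attr(reflectance, "omega")
  class(out) <- c("ds_datatypes", class(out))
  out
}

#' Names of the six DS FD-NIRS data types
#' @export
DATA_TYPES <- c("sdi25", "sdi37", "sdphi25", "sdphi37", "dsi", "dsphi")

#' Fit effective homogeneous optical properties from dual-slope baselines
#'
#' Self-calibrated retrieval of (mua, musp) from the measured dual slopes
#' of ln(rho^2 I) and phase. An initial guess comes from the
#' infinite-medium closed forms on the slopes
#' (`kr^2 - ki^2 = 3 mua musp`, `2 kr ki = 3 musp omega n / c` with
#' `kr = -dsi`, `ki = dsphi`), then a damped Newton iteration matches the
#' analytic semi-infinite extrapolated-boundary model's dual slopes to the
#' measured ones.
#'
#' @param datatypes A `ds_datatypes` row (only `dsi` and `dsphi` are used),
#'   or any list with `dsi` and `dsphi` elements.
#' @param omega Angular modulation frequency (rad/s).
#' @param n_in Internal refractive index.
#' @param rho_short,rho_long Distances of the DS set (mm); defaults come
#'   from the `ds_datatypes` attributes when present.
#' @param tol Convergence tolerance on both slope residuals (mm^-1).
#' @param max_iter Iteration cap; non-convergence is flagged, not silent.
#' @return An object of class `ds_fit`: `mua`, `musp` (mm^-1), `converged`,
#'   `n_iterations`, `residual`.
#' @export
fit_absolute_properties <- function(datatypes, omega = OMEGA_DEFAULT,
                                    n_in = 1.4,
                                    rho_short = NULL, rho_long = NULL,
                                    tol = 1e-9, max_iter = 100) {
  dsi <- datatypes$dsi
  dsphi <- datatypes$dsphi
  if (is.null(rho_short))
    rho_short <- attr(datatypes, "rho_short") %||% 25
  if (is.null(rho_long))
    rho_long <- attr(datatypes, "rho_long") %||% 37
  if (!is.finite(dsi) || !is.finite(dsphi) || dsi >= 0 || dsphi <= 0)
    stop("expected dsi < 0 (decaying intensity) and dsphi > 0 (phase lag)",
         call. = FALSE)

  # infinite-medium initial guess from the slope pair
  kr <- -dsi; ki <- dsphi
  wn_c <- omega * n_in / C_MM_S
  mua0 <- (wn_c / 2) * (kr / ki - ki / kr)
  musp0 <- 2 * kr * ki / (3 * wn_c)
  if (!is.finite(mua0) || mua0 <= 0) mua0 <- 0.001
  if (!is.finite(musp0) || musp0 <= 0) musp0 <- 0.5

  meas <- c(dsi, dsphi)
  slopes <- function(p) {
    m <- model_datatypes(p[1], p[2], omega, rho_short, rho_long, n_in)
    c(m[["dsi"]], m[["dsphi"]])
  }
  p <- c(mua0, musp0)
  res <- slopes(p) - meas
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    if (max(abs(res)) < tol) { converged <- TRUE; break }
    # numeric Jacobian of the slope map
    h <- pmax(abs(p) * 1e-6, 1e-9)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      pp <- p; pp[j] <- pp[j] + h[j]
      J[, j] <- (slopes(pp) - meas - res) / h[j]
    }
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      pn <- p + lam * step
      if (all(pn > 0)) {
        rn <- slopes(pn)
        if (all(is.finite(rn))) {
          rn <- rn - meas
          if (sum(rn^2) < sum(res^2) || lam < 1e-6) break
        }
      }
      lam <- lam / 2
      if (lam < 1e-8) { pn <- p; rn <- res; break }
    }
    if (identical(pn, p)) break
    p <- pn; res <- rn
  }
  if (max(abs(res)) < tol) converged <- TRUE

  structure(list(mua = p[1], musp = p[2], converged = converged,
                 n_iterations = it, residual = max(abs(res)),
                 omega = omega, n_in = n_in,
                 rho_short = rho_short, rho_long = rho_long,
                 dsi = dsi, dsphi = dsphi),
            class = "ds_fit")
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf(
    "<ds_fit> mua = %.5f mm^-1, musp = %.4f mm^-1 (%s, %d iterations)\n",
    x$mua, x$musp, if (x$converged) "converged" else "NOT converged",
    x$n_iterations))
  invisible(x)
}

#' @export
tidy.ds_fit <- function(x, ...) {
  tibble::tibble(term = c("mua", "musp"), estimate = c(x$mua, x$musp),
                 unit = "mm^-1")
}

#' @export
glance.ds_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, n_iterations = x$n_iterations,
                 residual = x$residual)
}

#' Retrieve effective absorption changes from data-type changes
#'
#' First-order conversion `dmua_M = dM / J_M` for each data type, with
#' standard errors scaled by `1 / |J_M|`.
#'
#' @param delta_M Named numeric vector (or one-row data frame) of data-type
#'   changes; names from [DATA_TYPES]. Optional `se_*` columns/entries give
#'   uncertainties.
#' @param jacobians Named numeric vector of Jacobians, as from
#'   [homogeneous_jacobian()] or the summed-layer column of
#'   [build_sensitivity_matrix()].
#' @return A tibble: `data_type, delta_M, jacobian, dmua` and `se` when
#'   available.
#' @export
retrieve_dmua <- function(delta_M, jacobians) {
  if (is.data.frame(delta_M)) {
    row <- delta_M[1, , drop = FALSE]
    dm <- vapply(DATA_TYPES, function(m) row[[m]], 0)
    se <- vapply(DATA_TYPES, function(m) {
      s <- row[[paste0("se_", m)]]
      if (is.null(s)) NA_real_ else s
    }, 0)
  } else {
    dm <- delta_M[DATA_TYPES]
    se <- rep(NA_real_, length(DATA_TYPES))
  }
  j <- jacobians[DATA_TYPES]
  if (any(!is.finite(j)) || any(j == 0))
    stop("zero or non-finite Jacobian: degenerate configuration",
         call. = FALSE)
  tibble::tibble(
    data_type = DATA_TYPES,
    delta_M = unname(dm), jacobian = unname(j),
    dmua = unname(dm / j),
    se = unname(abs(se / j))
  )
}

#' Default hemoglobin extinction coefficients at 690 and 830 nm
#'
#' Molar (decadic) extinction coefficients in cm^-1 / (mol/L) from the
#' widely used Prahl compilation of the Gratzer/Kollias tabulations;
#' override by passing your own table to [beer_lambert()].
#'
#' @return Tibble with `wavelength_nm, eps_hbo2, eps_hb`.
#' @export
extinction_defaults <- function() {
  tibble::tibble(
    wavelength_nm = c(690, 830),
    eps_hbo2 = c(276.0, 974.0),
    eps_hb = c(2051.96, 693.04)
  )
}

#' Convert absorption changes at two wavelengths to hemoglobin changes
#'
#' Solves Beer's law
#' `dmua(lambda) = ln(10) * (eps_HbO2 dHbO2 + eps_Hb dHb)` at the two
#' wavelengths for the oxy- and deoxy-hemoglobin concentration changes.
#'
#' @param dmua_690,dmua_830 Absorption changes (mm^-1) at 690 and 830 nm.
#' @param extinction Extinction table as in [extinction_defaults()]
#'   (cm^-1 per mol/L).
#' @return Tibble with `dHbO2, dHb` in micromolar.
#' @export
beer_lambert <- function(dmua_690, dmua_830,
                         extinction = extinction_defaults()) {
  ext <- extinction[match(c(690, 830), extinction$wavelength_nm), ]
  if (anyNA(ext$eps_hbo2))
    stop("extinction table must provide 690 and 830 nm rows", call. = FALSE)
  # mm^-1 per uM: ln(10) * eps[cm^-1/M] * 1e-6 M * 0.1 cm/mm
  E <- log(10) * cbind(ext$eps_hbo2, ext$eps_hb) * 1e-7
  if (abs(det(E)) < 1e-12)
    stop("singular extinction matrix", call. = FALSE)
  sol <- solve(E, c(dmua_690, dmua_830))
  tibble::tibble(dHbO2 = sol[1], dHb = sol[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
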