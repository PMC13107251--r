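# Frequency-domain forward models: reflectance assembly from a white-MC path
# ledger (exact absorption re-weighting) and the analytic homogeneous
# semi-infinite diffusion model with extrapolated boundary conditions.

#' Speed of light in vacuum, mm/s
#' @export
C_MM_S <- 2.99792458e11

#' Default angular modulation frequency (140.625 MHz), rad/s
#' @export
OMEGA_DEFAULT <- 2 * pi * 140.625e6

the_cache <- new.env(parent = emptyenv())

#' Effective reflection coefficient of a refractive-index-mismatched boundary
#'
#' Angular integrals of the unpolarized Fresnel reflectance (fluence- and
#' flux-weighted) combined into the effective coefficient used for the
#' extrapolated-boundary distance. For n_in/n_out = 1.4 this is about 0.493.
#'
#' @param n_in,n_out Refractive indices inside and outside the medium.
#' @return Effective reflection coefficient in \[0, 1).
#' @export
effective_reflection <- function(n_in = 1.4, n_out = 1.0) {
  key <- sprintf("reff_%.6f", n_in / n_out)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  rf <- function(th) vapply(cos(th), fresnel_R_cpp, 0, n_in = n_in, n_out = n_out)
  r_phi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                            0, pi / 2, rel.tol = 1e-10)$value
  r_j <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th),
                          0, pi / 2, rel.tol = 1e-10)$value
  reff <- (r_phi + r_j) / (2 - r_phi + r_j)
  the_cache[[key]] <- reff
  reff
}

photon_weights <- function(ledger, mua_per_layer, omega) {
  L <- ledger$paths
  if (length(mua_per_layer) != ledger$n_layers)
    stop("mua_per_layer must have one value per layer", call. = FALSE)
  if (any(mua_per_layer < 0)) stop("mua must be >= 0", call. = FALSE)
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  att <- drop(L %*% mua_per_layer)
  ph <- drop(L %*% (omega * ledger$n_refr / C_MM_S))
  exp(-att) * exp(1i * ph)
}

# Sum complex per-photon weights by (source, detector) and normalize by
# launched photons and collection area; standard errors from the sample
# variance of the summands (zeros included for undetected photons).
sum_by_pair <- function(ledger, w, extra = NULL) {
  key <- paste(ledger$source, ledger$detector)
  ord <- sort(unique(key))
  n <- ledger$n_launched_per_source
  out <- lapply(ord, function(kk) {
    idx <- which(key == kk)
    src <- ledger$source[idx[1]]; det <- ledger$detector[idx[1]]
    area <- ledger$area_of(src, det)[1]
    wi <- w[idx]
    s1 <- sum(wi)
    se_re <- sqrt(pmax(sum(Re(wi)^2) / n - (Re(s1) / n)^2, 0) / n) / area
    se_im <- sqrt(pmax(sum(Im(wi)^2) / n - (Im(s1) / n)^2, 0) / n) / area
    row <- tibble::tibble(
      source = src, detector = det, rho = ledger$rho[idx[1]],
      value = s1 / (n * area), se_re = se_re, se_im = se_im,
      n_detected = length(idx)
    )
    if (!is.null(extra)) row <- dplyr::bind_cols(row, extra(idx, n, area))
    row
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$source, .data$rho)
}

#' Assemble complex reflectance from a path ledger
#'
#' Applies an absorption set and a modulation frequency to the recorded
#' per-layer path lengths: each detected photon contributes
#' `exp(-sum_j mua_j l_jk) * exp(i omega sum_j l_jk n_j / c)`, and the sum is
#' normalized by launched photons and collection area. This re-weighting is
#' exact, so one white simulation serves any absorption values.
#'
#' @param ledger A [run_white_mc()] path ledger.
#' @param mua_per_layer Absorption coefficients, one per layer (mm^-1).
#' @param omega Angular modulation frequency (rad/s).
#' @return A tibble (class `ds_reflectance`), one row per source-detector
#'   pair: `source, detector, rho, value` (complex, mm^-2), component
#'   standard errors, and detected counts.
#' @export
assemble_reflectance <- function(ledger, mua_per_layer, omega = OMEGA_DEFAULT) {
  ledger_check(ledger)
  w <- photon_weights(ledger, mua_per_layer, omega)
  out <- sum_by_pair(ledger, w)
  attr(out, "omega") <- omega
  attr(out, "mua") <- mua_per_layer
  class(out) <- c("ds_reflectance", class(out))
  out
}

#' Baseline and perturbed reflectance from one shared ledger
#'
#' Computes the reflectance at `mua_per_layer` and at
#' `mua_per_layer + delta_mua_per_layer` from the same photons, so the
#' difference is exactly correlated (far lower variance than two
#' independent simulations).
#'
#' @inheritParams assemble_reflectance
#' @param delta_mua_per_layer Absorption perturbation per layer (mm^-1).
#' @return A list with elements `base`, `perturbed` (both `ds_reflectance`)
#'   and `delta` (tibble of complex differences).
#' @export
perturbed_reflectance <- function(ledger, mua_per_layer, delta_mua_per_layer,
                                  omega = OMEGA_DEFAULT) {
  base <- assemble_reflectance(ledger, mua_per_layer, omega)
  pert <- assemble_reflectance(ledger, mua_per_layer + delta_mua_per_layer,
                               omega)
  delta <- dplyr::mutate(
    dplyr::select(base, "source", "detector", "rho"),
    delta = pert$value - base$value)
  list(base = base, perturbed = pert, delta = delta)
}

#' Per-layer absorption derivatives of the complex reflectance
#'
#' Exact analytic differentiation of the re-weighted sum:
#' `dR/dmua_j = -(1/norm) sum_k l_jk exp(-sum mua l) exp(i omega sum l n / c)`.
#'
#' @inheritParams assemble_reflectance
#' @return A tibble (class `layer_derivatives`), one row per
#'   (source, detector, layer): complex `dR_dmua` plus the baseline `value`.
#' @export
layer_derivatives <- function(ledger, mua_per_layer, omega = OMEGA_DEFAULT) {
  ledger_check(ledger)
  w <- photon_weights(ledger, mua_per_layer, omega)
  base <- sum_by_pair(ledger, w)
  nl <- ledger$n_layers
  rows <- lapply(seq_len(nl), function(j) {
    dj <- sum_by_pair(ledger, -ledger$paths[, j] * w)
    tibble::tibble(source = dj$source, detector = dj$detector, rho = dj$rho,
                   layer = j, dR_dmua = dj$value)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out,
    dplyr::select(base, "source", "detector", value = "value"),
    by = c("source", "detector"))
  attr(out, "omega") <- omega
  attr(out, "mua") <- mua_per_layer
  class(out) <- c("layer_derivatives", class(out))
  out
}

#' Analytic semi-infinite diffusion reflectance (extrapolated boundary)
#'
#' Complex photon-density-wave fluence at the surface of a homogeneous
#' semi-infinite medium, from the image-source construction: real isotropic
#' source at depth `z0 = 1/musp`, image source at `-(z0 + 2 zb)` with
#' `zb = 2 D (1 + Reff) / (1 - Reff)`, `D = 1/(3 musp)` by default, and
#' complex attenuation `k = sqrt((mua - i omega n_in / c) / D)` (principal
#' root), so the phase grows with distance (a lag).
#'
#' @param rho Source-detector distance(s) in mm.
#' @param mua,musp Absorption and reduced scattering coefficients (mm^-1).
#' @param omega Angular modulation frequency (rad/s).
#' @param n_in,n_out Refractive indices inside / outside.
#' @param D_mode `"musp"` (default, `D = 1/(3 musp)`) or `"mua_musp"`
#'   (`D = 1/(3 (mua + musp))`).
#' @return Complex reflectance value(s).
#' @export
diffusion_reflectance <- function(rho, mua, musp, omega = OMEGA_DEFAULT,
                                  n_in = 1.4, n_out = 1.0,
                                  D_mode = c("musp", "mua_musp")) {
  D_mode <- match.arg(D_mode)
  stopifnot(all(rho > 0), mua >= 0, musp > 0)
  D <- if (D_mode == "musp") 1 / (3 * musp) else 1 / (3 * (mua + musp))
  z0 <- 1 / musp
  reff <- effective_reflection(n_in, n_out)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  k <- sqrt(as.complex(mua / D) - 1i * omega * n_in / (C_MM_S * D))
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * D)
}

# The six DS FD-NIRS data types evaluated on the analytic homogeneous model.
model_datatypes <- function(mua, musp, omega = OMEGA_DEFAULT,
                            rho_short = 25, rho_long = 37, n_in = 1.4) {
  rs <- diffusion_reflectance(rho_short, mua, musp, omega, n_in)
  rl <- diffusion_reflectance(rho_long, mua, musp, omega, n_in)
  drho <- rho_long - rho_short
  sdi25 <- log(rho_short^2 * Mod(rs))
  sdi37 <- log(rho_long^2 * Mod(rl))
  sdphi25 <- Arg(rs)
  sdphi37 <- sdphi25 + Arg(rl / rs)   # nearest-branch continuation
  c(sdi25 = sdi25, sdi37 = sdi37, sdphi25 = sdphi25, sdphi37 = sdphi37,
    dsi = (sdi37 - sdi25) / drho, dsphi = (sdphi37 - sdphi25) / drho)
}

#' Homogeneous-model Jacobians of the six data types with respect to mua
#'
#' Central finite difference (default step 1e-5 mm^-1) of each data type
#' evaluated on the analytic semi-infinite diffusion model at the given
#' absolute optical properties. These Jacobians convert a measured change
#' dM into an effective homogeneous absorption change dM / J.
#'
#' @param mua,musp Baseline absolute optical properties (mm^-1).
#' @param omega Angular modulation frequency (rad/s).
#' @param rho_short,rho_long The two source-detector distances (mm).
#' @param n_in Internal refractive index.
#' @param step Finite-difference step on mua (mm^-1).
#' @param data_type Optional subset of
#'   `c("sdi25","sdi37","sdphi25","sdphi37","dsi","dsphi")`.
#' @return Named numeric vector of Jacobians (per data type).
#' @export
homogeneous_jacobian <- function(mua, musp, omega = OMEGA_DEFAULT,
                                 rho_short = 25, rho_long = 37, n_in = 1.4,
                                 step = 1e-5, data_type = NULL) {
  if (abs(rho_long - rho_short) < 1e-9)
    stop("degenerate distance set: slope Jacobians undefined", call. = FALSE)
  up <- model_datatypes(mua + step, musp, omega, rho_short, rho_long, n_in)
  dn <- model_datatypes(max(mua - step, 0), musp, omega, rho_short, rho_long,
                        n_in)
  h <- (mua + step) - max(mua - step, 0)
  j <- (up - dn) / h
  if (!is.null(data_type)) j <- j[data_type]
  j
}
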