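# Synthetic functional DS FD-NIRS time series with the statistical structure
# of a block-design visual-stimulation experiment, driven through the layered
# forward model, so the functional pipeline is testable end to end with a
# known planted truth.

#' Block-protocol definition
#'
#' The default mirrors a standard visual-stimulation block design: 60 s
#' baseline, seven cycles of 15 s stimulus + 30 s rest, 60 s final
#' baseline.
#'
#' @param baseline_pre,baseline_post Baseline durations (s).
#' @param n_cycles Number of stimulus-rest cycles.
#' @param stim_s,rest_s Stimulus and rest durations (s).
#' @param sample_rate Sampling rate (Hz).
#' @return Object of class `ds_protocol`.
#' @export
ds_protocol <- function(baseline_pre = 60, n_cycles = 7, stim_s = 15,
                        rest_s = 30, baseline_post = 60, sample_rate = 10) {
  stopifnot(baseline_pre >= 0, n_cycles >= 1, stim_s > 0, rest_s >= 0,
            baseline_post >= 0, sample_rate > 0)
  cycle_s <- stim_s + rest_s
  structure(list(baseline_pre = baseline_pre, n_cycles = n_cycles,
                 stim_s = stim_s, rest_s = rest_s,
                 baseline_post = baseline_post, sample_rate = sample_rate,
                 cycle_s = cycle_s,
                 duration = baseline_pre + n_cycles * cycle_s + baseline_post),
            class = "ds_protocol")
}

protocol_time <- function(protocol) {
  seq(0, protocol$duration - 1 / protocol$sample_rate,
      by = 1 / protocol$sample_rate)
}

protocol_block <- function(protocol, t) {
  p <- protocol
  inside <- t >= p$baseline_pre & t < p$baseline_pre + p$n_cycles * p$cycle_s
  tc <- (t - p$baseline_pre) %% p$cycle_s
  dplyr::case_when(
    t < p$baseline_pre ~ "baseline_pre",
    inside & tc < p$stim_s ~ "stim",
    inside ~ "rest",
    TRUE ~ "baseline_post"
  )
}

kernel_shape <- function(t, onset_delay, rise_tau, fall_tau) {
  tt <- pmax(t - onset_delay, 0)
  g1 <- stats::dgamma(tt, shape = 3, scale = rise_tau)
  g2 <- stats::dgamma(tt, shape = 3, scale = fall_tau * 2)
  g1 / max(stats::dgamma((3 - 1) * rise_tau, shape = 3, scale = rise_tau), 1e-300) -
    0.1 * g2 / max(stats::dgamma((3 - 1) * fall_tau * 2, shape = 3,
                                 scale = fall_tau * 2), 1e-300)
}

#' Hemodynamic response kernel over one stimulus-rest cycle
#'
#' A smooth difference-of-gammas shape: zero at cycle start, peaking during
#' or shortly after the stimulus, relaxing toward zero (with a small
#' undershoot) during rest, normalized so its maximum equals `peak_dmua`.
#' The shape is explicitly synthetic: the pipeline needs a known planted
#' truth, not physiological fidelity.
#'
#' @param peak_dmua Peak absorption change (mm^-1).
#' @param onset_delay Response onset after stimulus onset (s).
#' @param rise_tau,fall_tau Rise and fall time constants (s).
#' @param cycle_s Cycle duration (s).
#' @param sample_rate Sampling rate (Hz).
#' @return Tibble `t_cycle, dmua` over one cycle.
#' @export
hemodynamic_kernel <- function(peak_dmua, onset_delay = 2, rise_tau = 4,
                               fall_tau = 6, cycle_s = 45, sample_rate = 10) {
  stopifnot(is.finite(peak_dmua), rise_tau > 0, fall_tau > 0)
  t <- seq(0, cycle_s - 1 / sample_rate, by = 1 / sample_rate)
  if (peak_dmua == 0)
    return(tibble::tibble(t_cycle = t, dmua = rep(0, length(t))))
  h <- kernel_shape(t, onset_delay, rise_tau, fall_tau)
  tibble::tibble(t_cycle = t, dmua = peak_dmua * h / max(h))
}

#' Forward model linking per-layer absorption changes to data-type changes
#'
#' Builds the linear map `dM = sum_j (dM/dmua_j) dmua_j` either from a
#' Monte Carlo path ledger of a layered medium (per-layer derivatives by
#' exact differentiation of the re-weighted sum, baseline properties from
#' the self-calibrated dual-slope fit) or analytically for a homogeneous
#' medium. The homogeneous-model Jacobians at the fitted baseline are also
#' stored so data-type changes can be turned back into effective
#' absorption changes.
#'
#' @param ledger Optional [run_white_mc()] ledger (layered MC route).
#' @param mua,musp Homogeneous properties (analytic route, used when no
#'   ledger is given).
#' @param omega Angular modulation frequency (rad/s).
#' @param n_in Internal refractive index.
#' @return Object of class `ds_forward`: `dM_dmua` (6 x n_layers),
#'   `J_hom` (6), the baseline `fit`, and bookkeeping.
#' @export
forward_model <- function(ledger = NULL, mua = NULL, musp = NULL,
                          omega = OMEGA_DEFAULT, n_in = 1.4) {
  if (!is.null(ledger)) {
    ledger_check(ledger)
    mua_layers <- ledger$medium$layers$mua
    base <- assemble_reflectance(ledger, mua_layers, omega)
    dts <- compute_datatypes(base)
    fit <- fit_absolute_properties(dts, omega = omega, n_in = n_in)
    ld <- layer_derivatives(ledger, mua_layers, omega)
    dM <- datatype_derivs_from_layers(ld)
    n_layers <- ncol(dM)
  } else {
    stopifnot(!is.null(mua), !is.null(musp))
    fit <- list(mua = mua, musp = musp, converged = TRUE)
    dM <- matrix(homogeneous_jacobian(mua, musp, omega, n_in = n_in),
                 ncol = 1, dimnames = list(DATA_TYPES, "layer1"))
    n_layers <- 1L
  }
  J_hom <- homogeneous_jacobian(fit$mua, fit$musp, omega, n_in = n_in)
  structure(list(dM_dmua = dM, J_hom = J_hom, fit = fit,
                 n_layers = n_layers, omega = omega, n_in = n_in,
                 ledger = ledger),
            class = "ds_forward")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic functional dual-slope run
#'
#' Plants a hemodynamic-kernel absorption response in the deepest layer
#' (and optionally the top layer) of the forward model's medium, tiled over
#' the block protocol, maps it to changes of the six data types, adds
#' per-data-type white noise and optional sinusoidal physiological
#' components (as global absorption oscillations), and converts back to
#' effective absorption changes with the homogeneous Jacobians.
#'
#' @param forward A [forward_model()].
#' @param protocol A [ds_protocol()].
#' @param deep_peak_dmua Planted peak absorption change in the deepest
#'   layer (mm^-1).
#' @param superficial_peak_dmua Planted peak change in the top layer.
#' @param noise_sd Per-data-type white-noise standard deviation in the
#'   units of each data type; a single number is recycled, or a named
#'   vector over [DATA_TYPES].
#' @param physio Optional list of components, each
#'   `list(freq_hz =, amp_dmua =)`, added as homogeneous absorption
#'   oscillations (e.g. ~1 Hz cardiac, ~0.1 Hz vasomotion).
#' @param seed Integer seed (bit-reproducible traces).
#' @param path `"linear"` (first-order layered derivatives, default) or
#'   `"exact"` (re-exponentiates the path ledger per time sample; requires
#'   an MC forward model).
#' @param kernel_args List of overrides for [hemodynamic_kernel()] shape
#'   parameters.
#' @return A long tibble (class `ds_timeseries`): `time_s, block, cycle,
#'   data_type, delta_M, dmua`, with the protocol and planted truth as
#'   attributes.
#' @export
generate_functional_run <- function(forward, protocol = ds_protocol(),
                                    deep_peak_dmua,
                                    superficial_peak_dmua = 0,
                                    noise_sd = 0, physio = NULL, seed = 1,
                                    path = c("linear", "exact"),
                                    kernel_args = list()) {
  path <- match.arg(path)
  stopifnot(inherits(forward, "ds_forward"), inherits(protocol, "ds_protocol"))
  if (any(noise_sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  nz <- if (length(noise_sd) == 1) stats::setNames(rep(noise_sd, 6), DATA_TYPES)
        else noise_sd[DATA_TYPES]

  t <- protocol_time(protocol)
  block <- protocol_block(protocol, t)
  tc <- (t - protocol$baseline_pre) %% protocol$cycle_s
  in_cycles <- block %in% c("stim", "rest")
  cycle <- ifelse(in_cycles,
                  floor((t - protocol$baseline_pre) / protocol$cycle_s) + 1, NA)

  ka <- utils::modifyList(list(onset_delay = 2, rise_tau = 4, fall_tau = 6), kernel_args)
  shape <- kernel_shape(tc, ka$onset_delay, ka$rise_tau, ka$fall_tau)
  shape <- shape / max(shape)
  shape[!in_cycles] <- 0
  deep_t <- deep_peak_dmua * shape
  sup_t <- superficial_peak_dmua * shape

  nl <- forward$n_layers
  if (path == "exact") {
    if (is.null(forward$ledger))
      stop("exact path requires an MC forward model", call. = FALSE)
    mua0 <- forward$ledger$medium$layers$mua
    base_dt <- compute_datatypes(
      assemble_reflectance(forward$ledger, mua0, forward$omega))
    dM_t <- vapply(seq_along(t), function(i) {
      d <- rep(0, nl); d[nl] <- deep_t[i]; d[1] <- d[1] + sup_t[i]
      dt_i <- compute_datatypes(
        assemble_reflectance(forward$ledger, mua0 + d, forward$omega))
      unlist(dt_i[1, DATA_TYPES]) - unlist(base_dt[1, DATA_TYPES])
    }, numeric(6))
  } else {
    dmua_layers <- matrix(0, nl, length(t))
    dmua_layers[nl, ] <- deep_t
    dmua_layers[1, ] <- dmua_layers[1, ] + sup_t
    dM_t <- forward$dM_dmua %*% dmua_layers
  }

  if (!is.null(physio)) {
    osc <- rep(0, length(t))
    for (cmp in physio)
      osc <- osc + cmp$amp_dmua * sin(2 * pi * cmp$freq_hz * t)
    dM_t <- dM_t + outer(forward$J_hom, osc)
  }

  if (any(nz > 0)) {
    dM_t <- with_seed(as.integer(seed), {
      dM_t + matrix(stats::rnorm(length(dM_t), sd = rep(nz, ncol(dM_t))),
                    nrow = 6)
    })
  }

  dmua_t <- dM_t / forward$J_hom

  out <- tibble::tibble(
    time_s = rep(t, each = 6),
    block = rep(block, each = 6),
    cycle = rep(cycle, each = 6),
    data_type = rep(DATA_TYPES, length(t)),
    delta_M = as.vector(dM_t),
    dmua = as.vector(dmua_t)
  )
  attr(out, "protocol") <- protocol
  attr(out, "truth") <- list(deep_peak_dmua = deep_peak_dmua,
                             superficial_peak_dmua = superficial_peak_dmua,
                             noise_sd = nz, seed = seed, kernel = ka)
  class(out) <- c("ds_timeseries", class(out))
  out
}

#' Write a functional time series (plus ground truth) to CSV + JSON sidecar
#'
#' @param ts A `ds_timeseries`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  truth <- attr(ts, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
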