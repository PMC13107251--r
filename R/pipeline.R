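# Functional analysis chain: folding average over stimulus-rest cycles,
# moving-average smoothing, noise estimation on a short segment, 3-sigma
# peak detection with a +/-1 s reporting window, and module-level summary.

#' Folding average over stimulus-rest cycles
#'
#' Averages the per-data-type traces sample-wise across the complete
#' stimulus-rest cycles, aligned to stimulus onset; the pre/post baselines
#' are excluded (they serve baseline property fitting, not folding).
#'
#' @param series A `ds_timeseries` from [generate_functional_run()] (or any
#'   tibble with `time_s, block, cycle, data_type` and a value column plus
#'   a `ds_protocol` attribute).
#' @param value Name of the value column to fold (default `"dmua"`).
#' @return Tibble (class `ds_folded`): `t_cycle, data_type, mean, sd,
#'   n_cycles`.
#' @export
folding_average <- function(series, value = "dmua") {
  protocol <- attr(series, "protocol")
  if (is.null(protocol)) stop("series lacks a protocol attribute", call. = FALSE)
  d <- dplyr::filter(tibble::as_tibble(series), !is.na(.data$cycle))
  if (nrow(d) == 0) stop("no complete stimulus-rest cycles to fold", call. = FALSE)
  sr <- protocol$sample_rate
  d$t_cycle <- round(((d$time_s - protocol$baseline_pre) %% protocol$cycle_s) * sr) / sr
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$data_type, .data$t_cycle),
    mean = mean(.data[[value]]), sd = stats::sd(.data[[value]]),
    n_cycles = dplyr::n(), .groups = "drop")
  out <- dplyr::arrange(out, .data$data_type, .data$t_cycle)
  attr(out, "sample_rate") <- sr
  attr(out, "cycle_s") <- protocol$cycle_s
  class(out) <- c("ds_folded", class(out))
  out
}

#' Centered moving average with shrunken edge windows
#'
#' @param x Numeric vector, or a `ds_folded` trace (smoothed per data
#'   type).
#' @param window_s Window length in seconds (default 3).
#' @param sample_rate Samples per second; taken from the folded trace's
#'   attribute when smoothing a `ds_folded`.
#' @return Same type as the input.
#' @export
moving_average <- function(x, window_s = 3, sample_rate = NULL) {
  UseMethod("moving_average")
}

#' @export
moving_average.numeric <- function(x, window_s = 3, sample_rate = NULL) {
  if (is.null(sample_rate)) stop("sample_rate required for numeric input",
                                 call. = FALSE)
  n <- length(x)
  h <- floor(window_s * sample_rate / 2)
  if (2 * h + 1 > n) stop("window longer than the trace", call. = FALSE)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1); hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
moving_average.ds_folded <- function(x, window_s = 3, sample_rate = NULL) {
  sr <- sample_rate %||% attr(x, "sample_rate")
  out <- dplyr::mutate(
    dplyr::group_by(x, .data$data_type),
    mean = moving_average(.data$mean, window_s, sr))
  out <- dplyr::ungroup(out)
  attr(out, "sample_rate") <- attr(x, "sample_rate")
  attr(out, "cycle_s") <- attr(x, "cycle_s")
  attr(out, "smoothed_s") <- window_s
  class(out) <- class(x)
  out
}

#' Detect the response peak on a folded trace at a 3-sigma threshold
#'
#' Per data type: estimates the noise level as the standard deviation of
#' the unsmoothed folded trace over a short designated segment, smooths the
#' trace with a centered moving average, finds the maximum over the full
#' cycle (earliest sample on ties), declares a detection when the maximum
#' exceeds `threshold * sigma`, and reports the mean over a +/-1 s window
#' centered on the peak time (truncated and flagged at the cycle edges).
#' Estimating sigma before smoothing matters: the smoothed trace is so
#' strongly autocorrelated over a 2 s segment that its sample SD would
#' grossly underestimate the noise and the threshold would fire on noise
#' alone.
#'
#' @param folded An unsmoothed `ds_folded` from [folding_average()].
#' @param noise_segment Two times (s) in the cycle delimiting the noise
#'   segment; default 20-22 s, i.e. early rest after the response peak.
#' @param threshold Detection threshold in sigmas (default 3).
#' @param window_s Half-width of the reporting window (s, default 1).
#' @param smooth_window_s Moving-average window applied before peak search
#'   (s, default 3); set to 0 to skip smoothing.
#' @return Tibble (`peak_result`): `data_type, peak_value, peak_time,
#'   sigma_est, detected, edge_truncated`.
#' @export
detect_peak <- function(folded, noise_segment = c(20, 22), threshold = 3,
                        window_s = 1, smooth_window_s = 3) {
  stopifnot(inherits(folded, "ds_folded"), length(noise_segment) == 2)
  sr <- attr(folded, "sample_rate")
  out <- lapply(split(folded, folded$data_type), function(d) {
    d <- d[order(d$t_cycle), ]
    seg <- d$mean[d$t_cycle >= noise_segment[1] & d$t_cycle < noise_segment[2]]
    if (length(seg) < 2)
      stop("noise segment too short at this sampling rate", call. = FALSE)
    sigma <- stats::sd(seg)
    sm <- if (smooth_window_s > 0)
      moving_average(d$mean, smooth_window_s, sr) else d$mean
    imax <- which.max(sm)   # earliest index on exact ties
    tmax <- d$t_cycle[imax]
    win <- abs(d$t_cycle - tmax) <= window_s + 1e-9
    edge <- (tmax - window_s < min(d$t_cycle) - 1e-9) ||
            (tmax + window_s > max(d$t_cycle) + 1e-9)
    tibble::tibble(
      data_type = d$data_type[1],
      peak_value = mean(sm[win]),
      peak_time = tmax,
      sigma_est = sigma,
      detected = sm[imax] > threshold * sigma,
      edge_truncated = edge
    )
  })
  out <- dplyr::bind_rows(out)
  out <- out[match(intersect(DATA_TYPES, out$data_type), out$data_type), ]
  class(out) <- c("peak_result", class(out))
  out
}

#' Summarize peak values across the dual-slope sets of a module
#'
#' Mean and standard error of the mean per data type (and wavelength, when
#' present) over the module's DS sets; single-set groups get a flagged
#' undefined SEM.
#'
#' @param peaks Tibble of peak results across sets, with at least
#'   `data_type` and `peak_value` columns (plus optional `ds_set`,
#'   `wavelength_nm`).
#' @return Tibble: grouping columns, `mean, sem, n_sets, sem_defined`.
#' @export
summarize_module <- function(peaks) {
  stopifnot(all(c("data_type", "peak_value") %in% names(peaks)))
  grp <- intersect(c("data_type", "wavelength_nm"), names(peaks))
  out <- dplyr::summarise(
    dplyr::group_by(peaks, dplyr::across(dplyr::all_of(grp))),
    mean = mean(.data$peak_value),
    sem = stats::sd(.data$peak_value) / sqrt(dplyr::n()),
    n_sets = dplyr::n(), .groups = "drop")
  out$sem_defined <- out$n_sets >= 2
  out$sem[!out$sem_defined] <- NA_real_
  out
}

#' Run the full functional pipeline on a time series
#'
#' Convenience chain in the fixed order fold -> smooth -> noise estimate ->
#' threshold -> window-average.
#'
#' @inheritParams folding_average
#' @inheritParams detect_peak
#' @param smooth_window_s Moving-average window (s).
#' @return A `peak_result` tibble.
#' @export
functional_pipeline <- function(series, value = "dmua", smooth_window_s = 3,
                                noise_segment = c(20, 22), threshold = 3) {
  folded <- folding_average(series, value = value)
  detect_peak(folded, noise_segment = noise_segment, threshold = threshold,
              smooth_window_s = smooth_window_s)
}
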