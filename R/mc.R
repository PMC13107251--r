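#' Unpolarized Fresnel reflectance at a planar index step
#'
#' Probability that a photon hitting a flat interface from the `n_in` side
#' is specularly reflected; beyond the critical angle this is 1 (total
#' internal reflection).
#'
#' @param cos_theta Cosine of the angle of incidence (0..1).
#' @param n_in,n_out Refractive indices on the incident and far side.
#' @return Reflectance in \[0, 1\].
#' @export
fresnel_reflectance <- function(cos_theta, n_in, n_out) {
  stopifnot(cos_theta >= 0, cos_theta <= 1, n_in >= 1, n_out >= 1)
  fresnel_R_cpp(cos_theta, n_in, n_out)
}

#' Run the white Monte Carlo and record a per-layer path ledger
#'
#' Simulates photon random walks at zero absorption in a layered slab and
#' records, for every detected photon, the path length traveled in each
#' layer (the "path ledger"). Any absorption set can then be applied
#' afterwards by exact exponential re-weighting, and the modulation phase
#' by the same per-layer path lengths, so a single simulation serves an
#' entire absorption sweep.
#'
#' Two tally modes are available. The default `"annular"` mode exploits the
#' lateral homogeneity of the medium: photons exiting the top surface are
#' collected on annular rings centered on their source, 2 mm wide around
#' each nominal source-detector distance, reaching usable statistics with
#' about 1e7 photons. The `"disc"` mode uses the physical 1 mm radius disc
#' detectors of the optode array and requires far larger photon budgets.
#'
#' @param medium A [layered_medium()].
#' @param optodes An [make_ds_array()] optode array.
#' @param n_photons Total photons to launch (split evenly across the two
#'   sources).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param tally `"annular"` (default) or `"disc"`.
#' @param ring_width Annular ring width in mm (annular mode).
#' @param max_path Total-path cutoff in mm beyond which a photon is
#'   terminated; at mua >= 0.002 mm^-1 the discarded weight is < e^-4.
#' @return A `path_ledger` object: per detected photon the source, the
#'   detector, and the path length in each layer, plus launch counts,
#'   collection areas, and photon-fate tallies.
#' @export
run_white_mc <- function(medium, optodes, n_photons, seed,
                         tally = c("annular", "disc"),
                         ring_width = 2, max_path = 2000) {
  tally <- match.arg(tally)
  stopifnot(inherits(medium, "layered_medium"), inherits(optodes, "optode_array"))
  if (!is.finite(n_photons) || n_photons < 1)
    stop("n_photons must be >= 1", call. = FALSE)

  lay <- medium$layers
  # center the box laterally on the optode span
  ctr <- mean(range(c(optodes$sources$x, optodes$detectors$x)))
  xlim <- c(ctr - medium$box[1] / 2, ctr + medium$box[1] / 2)
  ylim <- c(-medium$box[2] / 2, medium$box[2] / 2)

  rho <- c(optodes$rho_short, optodes$rho_long)
  rings <- cbind(rho - ring_width / 2, rho + ring_width / 2)
  det_xy <- cbind(optodes$detectors$x, optodes$detectors$y)

  npp <- floor(n_photons / nrow(optodes$sources))
  res <- mc_kernel(
    boundaries = medium$boundaries,
    mus = lay$musp / (1 - lay$g), g = lay$g, n_layer = lay$n, n_out = 1.0,
    xlim = xlim, ylim = ylim,
    src_x = optodes$sources$x, src_y = optodes$sources$y,
    det_xy = det_xy, det_radius = optodes$detector_radius,
    rings = rings, annular = (tally == "annular"),
    n_photons_per_source = npp, seed = as.integer(seed), max_path = max_path
  )

  if (tally == "annular") {
    # kernel detector index is the ring (1 = short, 2 = long); map to the
    # physical detector of this source's DS pair
    ring <- res$detector
    detector <- ifelse(res$source == 1L, ring, 3L - ring)
    rho_k <- rho[ring]
    areas <- pi * (rings[, 2]^2 - rings[, 1]^2)   # per ring
    area_of <- function(src, det) {
      ring_id <- ifelse(src == 1L, det, 3L - det)
      areas[ring_id]
    }
  } else {
    detector <- res$detector
    pr <- optodes$pairs
    rho_k <- pr$rho[match(paste(res$source, detector),
                          paste(pr$source, pr$detector))]
    area_of <- function(src, det) rep(pi * optodes$detector_radius^2,
                                      length(src))
  }

  if (res$n_detected == 0)
    warning("no photons detected; downstream operations will reject this ledger")

  structure(list(
    paths = res$paths, source = res$source, detector = as.integer(detector),
    rho = rho_k,
    n_layers = nrow(lay), n_launched_per_source = npp,
    n_sources = nrow(optodes$sources),
    area_of = area_of,
    n_refr = lay$n,
    counts = c(detected = res$n_detected, top_other = res$n_top_other,
               side = res$n_side, bottom = res$n_bottom,
               cutoff = res$n_cutoff),
    tally = tally, seed = as.integer(seed), max_path = max_path,
    medium = medium, optodes = optodes
  ), class = "path_ledger")
}

#' @export
print.path_ledger <- function(x, ...) {
  cat("<path_ledger> ", format(x$counts[["detected"]], big.mark = ","),
      " detected / ", format(x$n_launched_per_source * x$n_sources,
                             big.mark = ","),
      " launched (", x$tally, " tally, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Tidy a path ledger into a tibble
#'
#' @param x A `path_ledger`.
#' @param ... Unused.
#' @return One row per detected photon: source, detector, rho, and one
#'   `l_<j>` column per layer (mm).
#' @export
tidy.path_ledger <- function(x, ...) {
  pl <- tibble::as_tibble(x$paths, .name_repair = ~ paste0("l_", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(source = x$source, detector = x$detector, rho = x$rho), pl)
}

#' @export
glance.path_ledger <- function(x, ...) {
  tibble::tibble(
    n_launched = x$n_launched_per_source * x$n_sources,
    n_detected = unname(x$counts[["detected"]]),
    n_layers = x$n_layers, tally = x$tally, seed = x$seed
  )
}

ledger_check <- function(ledger) {
  if (!inherits(ledger, "path_ledger"))
    stop("expected a path_ledger", call. = FALSE)
  if (ledger$counts[["detected"]] == 0)
    stop("empty path ledger: no detected photons", call. = FALSE)
  invisible(ledger)
}
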