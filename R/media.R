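#' Construct a single optical layer
#'
#' A layer is described by its thickness and the optical properties that
#' govern near-infrared light propagation: the absorption coefficient
#' `mua` (mm^-1), the reduced scattering coefficient `musp` (mm^-1), the
#' refractive index `n`, and the scattering anisotropy `g`. The default
#' `n = 1.4` represents an effective index for heterogeneous head tissue,
#' and `g = 0` keeps the random walk isotropic (only `musp = mus * (1 - g)`
#' matters in the diffusive regime).
#'
#' @param thickness Layer thickness in mm (> 0).
#' @param mua Absorption coefficient in mm^-1 (>= 0).
#' @param musp Reduced scattering coefficient in mm^-1 (> 0; a CSF-like
#'   layer may go as low as 0.001).
#' @param n Refractive index (>= 1).
#' @param g Scattering anisotropy, -1 < g < 1.
#' @return A one-row tibble with class `optical_layer` columns.
#' @export
optical_layer <- function(thickness, mua, musp, n = 1.4, g = 0) {
  if (!is.finite(thickness) || thickness <= 0)
    stop("layer thickness must be positive", call. = FALSE)
  if (!is.finite(mua) || mua < 0)
    stop("mua must be >= 0", call. = FALSE)
  if (!is.finite(musp) || musp < 0.001)
    stop("musp must be >= 0.001 mm^-1", call. = FALSE)
  if (n < 1) stop("refractive index must be >= 1", call. = FALSE)
  if (g <= -1 || g >= 1) stop("anisotropy g must be in (-1, 1)", call. = FALSE)
  tibble::tibble(thickness = thickness, mua = mua, musp = musp, n = n, g = g)
}

#' Construct a layered medium
#'
#' Stacks layers top-first inside a rectangular simulation box. The last
#' layer is extended to fill the box depth, so it is effectively
#' semi-infinite within the box.
#'
#' @param layers A tibble of layers (rows ordered top first), as returned by
#'   [optical_layer()] and `dplyr::bind_rows()`.
#' @param box Numeric length-3 vector `c(x, y, z)` of box extents in mm.
#' @return An object of class `layered_medium`.
#' @export
layered_medium <- function(layers, box = c(200, 100, 100)) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1, length(box) == 3)
  layers <- tibble::as_tibble(layers)
  depth <- box[3]
  above <- if (nrow(layers) > 1) sum(layers$thickness[-nrow(layers)]) else 0
  if (above >= depth)
    stop("layer thicknesses above the last layer exceed the box depth",
         call. = FALSE)
  layers$thickness[nrow(layers)] <- depth - above
  bnd <- cumsum(layers$thickness)
  if (any(diff(c(0, bnd)) <= 0) || max(bnd) > depth + 1e-9)
    stop("layer boundaries must be strictly increasing within the box",
         call. = FALSE)
  structure(list(layers = layers, box = as.numeric(box), boundaries = bnd),
            class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  cat("<layered_medium> ", nrow(x$layers), " layer(s), box ",
      paste(x$box, collapse = " x "), " mm\n", sep = "")
  print(x$layers)
  invisible(x)
}

#' Two-layer head-mimicking medium
#'
#' Layer 1 models the combined scalp + skull, layer 2 the cerebral tissue;
#' layer 2 fills the box to its full depth.
#'
#' @param L1 Top layer thickness in mm.
#' @param mua1,mua2 Absorption coefficients (mm^-1) of layers 1 and 2.
#' @param musp1,musp2 Reduced scattering coefficients (mm^-1).
#' @param n,g Refractive index and anisotropy shared by both layers.
#' @param box Simulation box extents in mm.
#' @return A `layered_medium`.
#' @examples
#' make_two_layer(L1 = 10, mua1 = 0.017, mua2 = 0.021,
#'                musp1 = 1.45, musp2 = 1.1)
#' @export
make_two_layer <- function(L1, mua1, mua2, musp1, musp2, n = 1.4, g = 0,
                           box = c(200, 100, 100)) {
  if (!is.finite(L1) || L1 <= 0) stop("L1 must be positive", call. = FALSE)
  L1 <- min(L1, box[3])
  if (L1 >= box[3]) {
    # degenerate: top layer fills the box
    return(layered_medium(optical_layer(box[3], mua1, musp1, n, g), box))
  }
  layered_medium(dplyr::bind_rows(
    optical_layer(L1, mua1, musp1, n, g),
    optical_layer(box[3] - L1, mua2, musp2, n, g)
  ), box)
}

#' Three-layer head-mimicking medium with a CSF-like middle layer
#'
#' Layer 1 is scalp + skull, layer 2 the CSF-filled subarachnoid space
#' (thin, weakly absorbing and weakly scattering), layer 3 the cerebral
#' tissue filling the rest of the box.
#'
#' @param L1 Scalp + skull thickness in mm.
#' @param L2 CSF layer thickness in mm (default 2).
#' @param mua1,mua2,mua3 Absorption coefficients (mm^-1); `mua2` defaults to
#'   0.0027 (CSF at 830 nm).
#' @param musp1,musp2,musp3 Reduced scattering coefficients (mm^-1); `musp2`
#'   defaults to 0.01.
#' @inheritParams make_two_layer
#' @return A `layered_medium`.
#' @examples
#' make_three_layer(L1 = 10, mua1 = 0.017, mua3 = 0.021,
#'                  musp1 = 0.75, musp3 = 1.1)
#' @export
make_three_layer <- function(L1, L2 = 2, mua1, mua2 = 0.0027, mua3,
                             musp1, musp2 = 0.01, musp3, n = 1.4, g = 0,
                             box = c(200, 100, 100)) {
  if (!is.finite(L1) || L1 <= 0) stop("L1 must be positive", call. = FALSE)
  if (!is.finite(L2) || L2 <= 0) stop("L2 must be positive", call. = FALSE)
  if (L1 + L2 >= box[3])
    stop("L1 + L2 must be smaller than the box depth", call. = FALSE)
  layered_medium(dplyr::bind_rows(
    optical_layer(L1, mua1, musp1, n, g),
    optical_layer(L2, mua2, musp2, n, g),
    optical_layer(box[3] - L1 - L2, mua3, musp3, n, g)
  ), box)
}

#' Default collinear dual-slope optode array
#'
#' One dual-slope (DS) set: source A at x = 0, detector 1 at x = 25,
#' detector 2 at x = 37, source B at x = 62, all on the top surface along
#' the +x axis. Each source sees one short (25 mm) and one long (37 mm)
#' source-detector distance, mirrored between the two sources, which is
#' what makes the averaged slope self-calibrating.
#'
#' @param rho_short,rho_long The two source-detector distances in mm.
#' @param detector_radius Disc detector radius in mm (disc tally mode).
#' @return An object of class `optode_array` with sources, detectors, and
#'   the DS-set distance table.
#' @export
make_ds_array <- function(rho_short = 25, rho_long = 37, detector_radius = 1) {
  if (!is.finite(rho_short) || !is.finite(rho_long) ||
      rho_short <= 0 || rho_long <= 0)
    stop("source-detector distances must be positive", call. = FALSE)
  if (abs(rho_long - rho_short) < 1e-9)
    stop("rho_short and rho_long must differ (slope undefined otherwise)",
         call. = FALSE)
  span <- rho_short + rho_long
  sources <- tibble::tibble(source = c(1L, 2L), label = c("A", "B"),
                            x = c(0, span), y = 0)
  detectors <- tibble::tibble(detector = c(1L, 2L),
                              x = c(rho_short, rho_long), y = 0)
  pairs <- tidyr::crossing(source = sources$source, detector = detectors$detector)
  pairs$rho <- abs(sources$x[pairs$source] - detectors$x[pairs$detector])
  structure(list(sources = sources, detectors = detectors,
                 detector_radius = detector_radius,
                 pairs = pairs, rho_short = rho_short, rho_long = rho_long),
            class = "optode_array")
}

#' @export
print.optode_array <- function(x, ...) {
  cat("<optode_array> dual-slope set, rho =", x$rho_short, "/", x$rho_long,
      "mm, detector radius", x$detector_radius, "mm\n")
  print(x$pairs)
  invisible(x)
}

#' Serialize a medium and optode array to a YAML config
#'
#' @param medium A `layered_medium`.
#' @param optodes An `optode_array` (optional).
#' @param path File to write; if `NULL`, the YAML text is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
media_to_yaml <- function(medium, optodes = NULL, path = NULL) {
  cfg <- list(
    box = as.numeric(medium$box),
    layers = purrr::pmap(medium$layers, function(thickness, mua, musp, n, g) {
      list(thickness = thickness, mua = mua, musp = musp, n = n, g = g)
    })
  )
  if (!is.null(optodes)) {
    cfg$optodes <- list(rho_short = optodes$rho_short,
                        rho_long = optodes$rho_long,
                        detector_radius = optodes$detector_radius)
  }
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a medium (and optode array) back from a YAML config
#'
#' @param path YAML file written by [media_to_yaml()].
#' @return A list with elements `medium` and (if present) `optodes`.
#' @export
media_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- dplyr::bind_rows(lapply(cfg$layers, function(l) {
    optical_layer(l$thickness, l$mua, l$musp, l$n, l$g)
  }))
  out <- list(medium = layered_medium(layers, box = as.numeric(cfg$box)))
  if (!is.null(cfg$optodes)) {
    out$optodes <- make_ds_array(cfg$optodes$rho_short, cfg$optodes$rho_long,
                                 cfg$optodes$detector_radius)
  }
  out
}
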