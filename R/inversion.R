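# Layer-sensitivity matrix and two-unknown least-squares separation of
# superficial and cerebral absorption changes.

# chain rule from complex reflectance derivatives to the six data types:
# intensity types go through ln|.| (Re(R'/R)), phase types through arg(.)
# (Im(R'/R)), slope types through the two-point difference over rho.
datatype_derivs_from_layers <- function(layer_derivs) {
  ld <- tibble::as_tibble(layer_derivs)
  ld$ratio <- ld$dR_dmua / ld$value
  rho_s <- min(ld$rho); rho_l <- max(ld$rho)
  drho <- rho_l - rho_s
  nl <- max(ld$layer)
  out <- matrix(0, 6, nl, dimnames = list(DATA_TYPES, paste0("layer", 1:nl)))
  for (j in seq_len(nl)) {
    dj <- ld[ld$layer == j, ]
    short <- dj$rho == rho_s
    dln_s <- mean(Re(dj$ratio[short]))
    dln_l <- mean(Re(dj$ratio[!short]))
    dph_s <- mean(Im(dj$ratio[short]))
    dph_l <- mean(Im(dj$ratio[!short]))
    # per-source slopes then average = difference of mirror-averaged values
    out[, j] <- c(dln_s, dln_l, dph_s, dph_l,
                  (dln_l - dln_s) / drho, (dph_l - dph_s) / drho)
  }
  out
}

#' Build the normalized layer-sensitivity matrix
#'
#' From the per-layer complex reflectance derivatives of a layered medium,
#' forms the derivative of each of the six data types with respect to each
#' layer's absorption, normalizes every row by the sum over ALL layers
#' (including the CSF layer), and keeps the columns for the first and the
#' deepest layer only: the CSF layer is excluded from the unknowns because
#' its absorption changes are expected to be negligible, but it still
#' contributes to the normalization.
#'
#' @param layer_derivs A [layer_derivatives()] tibble for the dual-slope
#'   set (three-layer media give the canonical 6 x 2 matrix; two-layer
#'   media give first/last = the two layers).
#' @return An object of class `layer_sensitivity`: `S` (6 x 2, rows =
#'   data types, columns = superficial / deep layer), `fractions` (all
#'   layers, rows summing to 1), `J_sum` (the summed-layer Jacobian per
#'   data type, i.e. the normalization denominator), and diagnostics.
#' @export
build_sensitivity_matrix <- function(layer_derivs) {
  dM <- datatype_derivs_from_layers(layer_derivs)
  nl <- ncol(dM)
  J_sum <- rowSums(dM)
  if (any(abs(J_sum) < 1e-300))
    stop("zero summed-layer Jacobian: pathological configuration",
         call. = FALSE)
  fractions <- sweep(dM, 1, J_sum, "/")
  keep <- c(1L, nl)
  S <- fractions[, keep, drop = FALSE]
  colnames(S) <- c("superficial", "deep")
  sv <- svd(S)$d
  structure(list(
    S = S, fractions = fractions, J_sum = J_sum, derivs = dM,
    layers_kept = keep, n_layers = nl,
    rank = sum(sv > max(sv) * 1e-10),
    condition = sv[1] / sv[length(sv)],
    mua = attr(layer_derivs, "mua"), omega = attr(layer_derivs, "omega")
  ), class = "layer_sensitivity")
}

#' @export
print.layer_sensitivity <- function(x, ...) {
  cat("<layer_sensitivity> 6 x", ncol(x$S), "(rank", x$rank,
      ", condition", format(x$condition, digits = 4), ")\n")
  print(round(x$S, 4))
  invisible(x)
}

#' @export
tidy.layer_sensitivity <- function(x, ...) {
  tibble::tibble(
    data_type = rep(rownames(x$S), ncol(x$S)),
    layer = rep(colnames(x$S), each = nrow(x$S)),
    sensitivity = as.vector(x$S)
  )
}

pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > max(s$d) * tol
  if (!any(keep)) stop("matrix is numerically zero", call. = FALSE)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Solve for superficial and deep absorption changes
#'
#' Moore-Penrose least-squares solution of the 6-equation, 2-unknown
#' system `dmua_M = S dmua_L`, where the measurement vector holds the six
#' effective absorption changes (obtained with the summed-layer Jacobian)
#' and S is the normalized layer-sensitivity matrix.
#'
#' @param dmua_M Numeric vector of the six effective absorption changes in
#'   [DATA_TYPES] order, or a [retrieve_dmua()] tibble.
#' @param sensitivity A [build_sensitivity_matrix()] result.
#' @param sem Optional vector of standard errors of `dmua_M` to propagate.
#' @return Object of class `layer_solution`: `dmua_superficial`,
#'   `dmua_deep` (mm^-1), their SEMs (if `sem` given), and the residual
#'   norm.
#' @export
solve_layers <- function(dmua_M, sensitivity, sem = NULL) {
  stopifnot(inherits(sensitivity, "layer_sensitivity"))
  if (is.data.frame(dmua_M)) {
    if (is.null(sem) && "se" %in% names(dmua_M) && all(is.finite(dmua_M$se)))
      sem <- dmua_M$se[match(DATA_TYPES, dmua_M$data_type)]
    dmua_M <- dmua_M$dmua[match(DATA_TYPES, dmua_M$data_type)]
  }
  stopifnot(length(dmua_M) == 6, all(is.finite(dmua_M)))
  S <- sensitivity$S
  if (sensitivity$rank < ncol(S))
    stop(sprintf("rank-deficient sensitivity matrix (rank %d, condition %g)",
                 sensitivity$rank, sensitivity$condition), call. = FALSE)
  Sp <- pinv(S)
  sol <- drop(Sp %*% dmua_M)
  resid <- sqrt(sum((dmua_M - drop(S %*% sol))^2))
  sems <- if (!is.null(sem)) propagate_sem(sensitivity, sem) else
    c(superficial = NA_real_, deep = NA_real_)
  structure(list(dmua_superficial = sol[1], dmua_deep = sol[2],
                 sem_superficial = unname(sems[1]), sem_deep = unname(sems[2]),
                 residual_norm = resid, pinv = Sp),
            class = "layer_solution")
}

#' @export
print.layer_solution <- function(x, ...) {
  cat(sprintf(
    "<layer_solution> superficial %.2e +/- %.1e, deep %.2e +/- %.1e mm^-1\n",
    x$dmua_superficial, x$sem_superficial, x$dmua_deep, x$sem_deep))
  invisible(x)
}

#' @export
tidy.layer_solution <- function(x, ...) {
  tibble::tibble(
    layer = c("superficial", "deep"),
    dmua = c(x$dmua_superficial, x$dmua_deep),
    sem = c(x$sem_superficial, x$sem_deep)
  )
}

#' @export
glance.layer_solution <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm)
}

#' Propagate measurement SEMs through the pseudoinverse
#'
#' Element-wise variance propagation assuming uncorrelated noise across the
#' six data types: `var(dmua_L_i) = sum_M (S+\[i,M\])^2 sem_M^2`.
#'
#' @param sensitivity A `layer_sensitivity`.
#' @param sem_vector Nonnegative SEMs of the six measurement-vector entries.
#' @return Named vector `c(superficial, deep)` of SEMs.
#' @export
propagate_sem <- function(sensitivity, sem_vector) {
  stopifnot(length(sem_vector) == 6, all(sem_vector >= 0))
  Sp <- pinv(sensitivity$S)
  out <- sqrt(drop(Sp^2 %*% sem_vector^2))
  stats::setNames(out, c("superficial", "deep"))
}
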