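# Campaign runner: sweeps of layered-medium configurations through the
# MC -> baseline-fit -> perturbation -> retrieval chain, with ledger reuse
# across absorption grids (white MC permits exact absorption re-weighting,
# so one ledger per geometry/scattering set serves all mua values).

#' Define a sweep over layered-medium configurations
#'
#' @param model `"two_layer"` or `"three_layer"`.
#' @param L1 Grid of top-layer thicknesses (mm); default 8-16 mm step 2.
#' @param vary Optional list `list(param =, values =)` naming one constant
#'   to sweep (`"mua1"`, `"musp1"`, or `"delta_mua1"`).
#' @param constants Named list of medium parameters passed to
#'   [make_two_layer()] / [make_three_layer()].
#' @param delta_mua_deep Absorption perturbation planted in the deepest
#'   layer (mm^-1, default 0.001).
#' @param photons Photons per MC run (default 1e7).
#' @param seed Base seed; each geometry gets `seed + index`.
#' @param omega Angular modulation frequency (rad/s).
#' @param tally MC tally mode.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(model = c("two_layer", "three_layer"),
                       L1 = seq(8, 16, by = 2), vary = NULL,
                       constants = list(), delta_mua_deep = 0.001,
                       photons = 1e7, seed = 1, omega = OMEGA_DEFAULT,
                       tally = "annular") {
  model <- match.arg(model)
  if (length(L1) < 1) stop("empty L1 grid", call. = FALSE)
  if (!is.null(vary)) {
    stopifnot(is.list(vary), !is.null(vary$param), length(vary$values) >= 1)
    if (!vary$param %in% c("mua1", "musp1", "delta_mua1"))
      stop("vary$param must be one of mua1, musp1, delta_mua1", call. = FALSE)
  }
  need <- if (model == "two_layer") c("mua1", "mua2", "musp1", "musp2")
          else c("mua1", "mua3", "musp1", "musp3")
  have <- union(names(constants), if (is.null(vary)) character() else vary$param)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing held constants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(model = model, L1 = L1, vary = vary, constants = constants,
                 delta_mua_deep = delta_mua_deep, photons = photons,
                 seed = seed, omega = omega, tally = tally),
            class = "sweep_spec")
}

build_medium <- function(spec, L1, pars) {
  if (spec$model == "two_layer") {
    make_two_layer(L1 = L1, mua1 = pars$mua1, mua2 = pars$mua2,
                   musp1 = pars$musp1, musp2 = pars$musp2)
  } else {
    make_three_layer(L1 = L1, L2 = pars$L2 %||% 2,
                     mua1 = pars$mua1, mua2 = pars$mua2 %||% 0.0027,
                     mua3 = pars$mua3,
                     musp1 = pars$musp1, musp2 = pars$musp2 %||% 0.01,
                     musp3 = pars$musp3)
  }
}

#' Run a configuration sweep
#'
#' For each grid point: run (or reuse) the white MC, fit the effective
#' homogeneous baseline properties from the dual slopes, perturb the
#' deepest layer's absorption (plus any top-layer perturbation from a
#' `delta_mua1` sweep), and retrieve the six effective absorption changes.
#' Absorption sweeps reuse one ledger per geometry because the white
#' ledger re-weights exactly; scattering or thickness changes trigger a
#' fresh simulation. An MC failure at a grid point flags the rows and the
#' campaign continues.
#'
#' @param spec A [sweep_spec()].
#' @param optodes Optode array (default [make_ds_array()]).
#' @param ledger_cache Optional environment reusing ledgers across calls.
#' @return Tibble (class `campaign_result`), one row per
#'   (grid point, data type), with full provenance columns.
#' @export
run_campaign <- function(spec, optodes = make_ds_array(),
                         ledger_cache = new.env(parent = emptyenv())) {
  stopifnot(inherits(spec, "sweep_spec"))
  values <- if (is.null(spec$vary)) NA_real_ else spec$vary$values
  grid <- tidyr::crossing(L1 = spec$L1, value = values)
  rows <- vector("list", nrow(grid))
  geom_id <- 0

  for (i in seq_len(nrow(grid))) {
    L1 <- grid$L1[i]; val <- grid$value[i]
    pars <- spec$constants
    delta_top <- 0
    if (!is.null(spec$vary)) {
      if (spec$vary$param == "delta_mua1") delta_top <- val
      else pars[[spec$vary$param]] <- val
    }
    key <- paste0("L1=", L1, ";musp1=", pars$musp1,
                  ";musp2=", pars$musp2 %||% NA, ";musp3=", pars$musp3 %||% NA)
    rows[[i]] <- tryCatch({
      medium <- build_medium(spec, L1, pars)
      if (is.null(ledger_cache[[key]])) {
        geom_id <- geom_id + 1
        ledger_cache[[key]] <- run_white_mc(
          medium, optodes, n_photons = spec$photons,
          seed = spec$seed + geom_id, tally = spec$tally)
      }
      ledger <- ledger_cache[[key]]
      mua_layers <- medium$layers$mua
      nl <- length(mua_layers)
      delta <- rep(0, nl); delta[nl] <- spec$delta_mua_deep
      delta[1] <- delta[1] + delta_top

      base <- assemble_reflectance(ledger, mua_layers, spec$omega)
      pert <- assemble_reflectance(ledger, mua_layers + delta, spec$omega)
      dt_base <- compute_datatypes(base)
      dt_pert <- compute_datatypes(pert)
      fit <- fit_absolute_properties(dt_base, omega = spec$omega)
      jac <- homogeneous_jacobian(fit$mua, fit$musp, spec$omega,
                                  rho_short = optodes$rho_short,
                                  rho_long = optodes$rho_long)
      dM <- unlist(dt_pert[1, DATA_TYPES]) - unlist(dt_base[1, DATA_TYPES])
      ret <- retrieve_dmua(dM, jac)
      tibble::tibble(
        model = spec$model, L1 = L1,
        varied = if (is.null(spec$vary)) NA_character_ else spec$vary$param,
        value = val,
        data_type = ret$data_type, dmua = ret$dmua, delta_M = ret$delta_M,
        jacobian = ret$jacobian,
        fit_mua = fit$mua, fit_musp = fit$musp, converged = fit$converged,
        delta_mua_deep = spec$delta_mua_deep, delta_mua_top = delta_top,
        photons = spec$photons, seed = ledger$seed, tally = spec$tally,
        ok = TRUE, note = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(
        model = spec$model, L1 = L1,
        varied = if (is.null(spec$vary)) NA_character_ else spec$vary$param,
        value = val, data_type = DATA_TYPES,
        dmua = NA_real_, delta_M = NA_real_, jacobian = NA_real_,
        fit_mua = NA_real_, fit_musp = NA_real_, converged = FALSE,
        delta_mua_deep = spec$delta_mua_deep, delta_mua_top = delta_top,
        photons = spec$photons, seed = NA_integer_, tally = spec$tally,
        ok = FALSE, note = conditionMessage(e)
      )
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  class(out) <- c("campaign_result", class(out))
  out
}

#' Export campaign results to CSV and JSON with provenance
#'
#' @param table A `campaign_result` (or any nonempty data frame).
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.csv` and `<prefix>.json`.
#' @return Named character vector of the written files, invisibly.
#' @export
export_results <- function(table, path_prefix) {
  if (nrow(table) == 0) stop("refusing to export an empty table", call. = FALSE)
  df <- as.data.frame(tibble::as_tibble(table))
  csv <- paste0(path_prefix, ".csv")
  jsn <- paste0(path_prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)

  spec <- attr(table, "spec")
  cfg_json <- jsonlite::toJSON(unclass(spec) %||% list(), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)

  jsonlite::write_json(
    list(schema_version = "1.0", config_hash = hash,
         spec = if (is.null(spec)) NULL else unclass(spec), results = df),
    jsn, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv, json = jsn))
}

#' Read campaign results back from CSV
#'
#' @param path CSV written by [export_results()].
#' @return Tibble of results.
#' @export
read_results_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
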