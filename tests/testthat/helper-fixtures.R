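# Shared fixtures: media with the published caption constants, and a
# session-level ledger cache so heavy Monte Carlo runs are computed once and
# reused across test files.

two_layer_default <- function(L1 = 10, mua1 = 0.017) {
  make_two_layer(L1 = L1, mua1 = mua1, mua2 = 0.021,
                 musp1 = 1.45, musp2 = 1.1)
}

three_layer_highscatter <- function(L1 = 10, mua1 = 0.017, musp1 = 1.45) {
  make_three_layer(L1 = L1, L2 = 2, mua1 = mua1, mua2 = 0.0027, mua3 = 0.021,
                   musp1 = musp1, musp2 = 0.01, musp3 = 1.1)
}

three_layer_reference <- function(L1 = 10) {
  make_three_layer(L1 = L1, L2 = 2, mua1 = 0.017, mua2 = 0.0027, mua3 = 0.021,
                   musp1 = 0.75, musp2 = 0.01, musp3 = 1.1)
}

two_layer_scatter_variant <- function(musp1) {
  make_two_layer(L1 = 10, mua1 = 0.017, mua2 = 0.021,
                 musp1 = musp1, musp2 = 1.1)
}

.ledger_cache <- new.env(parent = emptyenv())

cached_ledger <- function(key, medium, n_photons, seed) {
  if (is.null(.ledger_cache[[key]])) {
    .ledger_cache[[key]] <- run_white_mc(medium, make_ds_array(),
                                         n_photons = n_photons, seed = seed)
  }
  .ledger_cache[[key]]
}

# MC -> baseline datatypes -> self-calibrated fit, the chain used throughout
mc_fit <- function(ledger) {
  dt <- compute_datatypes(assemble_reflectance(ledger,
                                               ledger$medium$layers$mua))
  fit_absolute_properties(dt)
}

# retrieve the six effective absorption changes for a deep perturbation;
# mua overrides the medium's baseline absorption (exact ledger re-weighting)
mc_retrieve <- function(ledger, delta, jac = NULL, mua = NULL) {
  if (is.null(mua)) mua <- ledger$medium$layers$mua
  pr <- perturbed_reflectance(ledger, mua, delta)
  dtb <- compute_datatypes(pr$base)
  dtp <- compute_datatypes(pr$perturbed)
  if (is.null(jac)) {
    fit <- fit_absolute_properties(dtb)
    jac <- homogeneous_jacobian(fit$mua, fit$musp)
  }
  dM <- unlist(dtp[1, DATA_TYPES]) - unlist(dtb[1, DATA_TYPES])
  retrieve_dmua(dM, jac)
}

expect_ordering <- function(ret) {
  d <- stats::setNames(ret$dmua, ret$data_type)
  expect_lt(d[["sdi25"]], d[["sdi37"]])
  expect_lt(d[["sdi37"]], d[["dsi"]])
  expect_lt(d[["sdphi25"]], d[["sdphi37"]])
  expect_lt(d[["sdphi37"]], d[["dsphi"]])
}
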