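analytic_ds_set <- function(mua, musp, omega = OMEGA_DEFAULT) {
  arr <- make_ds_array()
  p <- arr$pairs
  v <- diffusion_reflectance(p$rho, mua, musp, omega)
  out <- tibble::tibble(source = p$source, detector = p$detector,
                        rho = p$rho, value = v)
  attr(out, "omega") <- omega
  out
}

test_that("dual slopes are invariant to arbitrary optode coupling factors", {
  r <- analytic_ds_set(0.01, 1.0)
  dt0 <- compute_datatypes(r)
  # couple detector 1 and source 2 with arbitrary complex factors
  r2 <- r
  r2$value[r2$detector == 1] <- r2$value[r2$detector == 1] * (3 * exp(0.2i))
  r2$value[r2$source == 2] <- r2$value[r2$source == 2] * (0.4 * exp(-1.1i))
  dt2 <- compute_datatypes(r2)
  expect_equal(dt2$dsi, dt0$dsi, tolerance = 1e-12)
  expect_equal(dt2$dsphi, dt0$dsphi, tolerance = 1e-12)
  # but the SD values do move
  expect_false(isTRUE(all.equal(dt2$sdi25, dt0$sdi25)))
})

test_that("mirror-symmetric inputs give equal single slopes", {
  r <- analytic_ds_set(0.01, 1.0)
  dt <- compute_datatypes(r)
  # analytic inputs are perfectly mirror-symmetric: DS slope equals the
  # slope computed from either source alone
  m <- layerlight:::model_datatypes(0.01, 1.0)
  expect_equal(dt$dsi, m[["dsi"]], tolerance = 1e-12)
  expect_equal(dt$dsphi, m[["dsphi"]], tolerance = 1e-12)
  expect_lt(dt$dsi, 0)
  expect_gt(dt$dsphi, 0)
})

test_that("malformed DS sets are rejected", {
  r <- analytic_ds_set(0.01, 1.0)
  expect_error(compute_datatypes(r[1:3, ]), "four")
  bad <- r; bad$value[1] <- 0 + 0i
  expect_error(compute_datatypes(bad), "amplitude")
})

test_that("fit recovers planted properties to 0.1% across the grid", {
  for (mua in c(0.005, 0.01, 0.018, 0.025)) {
    for (musp in c(0.4, 0.8, 1.2, 1.8)) {
      dt <- compute_datatypes(analytic_ds_set(mua, musp))
      fit <- fit_absolute_properties(dt)
      expect_true(fit$converged)
      expect_lt(abs(fit$mua - mua) / mua, 1e-3)
      expect_lt(abs(fit$musp - musp) / musp, 1e-3)
    }
  }
})

test_that("fit rejects slopes with unphysical signs", {
  dt <- list(dsi = 0.1, dsphi = 0.03)
  expect_error(fit_absolute_properties(dt), "dsi")
})

test_that("retrieval divides changes by the Jacobians with SE scaling", {
  j <- homogeneous_jacobian(0.01, 1.0)
  # zero change -> zero retrieval
  z <- retrieve_dmua(stats::setNames(rep(0, 6), DATA_TYPES), j)
  expect_true(all(z$dmua == 0))
  # degenerate Jacobian rejected
  jbad <- j; jbad[["dsi"]] <- 0
  expect_error(retrieve_dmua(stats::setNames(rep(1, 6), DATA_TYPES), jbad),
               "Jacobian")
  # SEs scale by 1/|J|
  row <- tibble::as_tibble(as.list(stats::setNames(j * 2e-4, DATA_TYPES)))
  for (m in DATA_TYPES) row[[paste0("se_", m)]] <- abs(j[[m]]) * 1e-5
  ret <- retrieve_dmua(row, j)
  expect_equal(ret$dmua, rep(2e-4, 6), tolerance = 1e-12)
  expect_equal(ret$se, rep(1e-5, 6), tolerance = 1e-12)
})

test_that("retrieval is linear in the true absorption change", {
  j <- homogeneous_jacobian(0.015, 1.1)
  m0 <- layerlight:::model_datatypes(0.015, 1.1)
  for (d in c(1e-5, 1e-4, 1e-3)) {
    rec <- (layerlight:::model_datatypes(0.015 + d, 1.1) - m0) / j
    # slope 1 within 2% at and below 1e-3 for intensity; phase grows to
    # ~4% at 1e-3 from curvature, so assert the 2% bound at <= 1e-4 only
    if (d <= 1e-4) expect_true(all(abs(rec / d - 1) < 0.02))
    else expect_true(all(abs(rec / d - 1) < 0.05))
  }
})

test_that("Beer's law conversion round-trips and has the right signs", {
  # zero in, zero out
  z <- beer_lambert(0, 0)
  expect_equal(unlist(z), c(dHbO2 = 0, dHb = 0))
  # round trip through the forward extinction matrix
  ext <- extinction_defaults()
  E <- log(10) * cbind(ext$eps_hbo2, ext$eps_hb) * 1e-7
  dmua <- drop(E %*% c(1.0, -0.3))
  back <- beer_lambert(dmua[1], dmua[2])
  expect_equal(back$dHbO2, 1.0, tolerance = 1e-12)
  expect_equal(back$dHb, -0.3, tolerance = 1e-12)
  # absorption increase at 830 nm with flat 690 nm: HbO2 up, Hb down
  act <- beer_lambert(0, 1e-4)
  expect_gt(act$dHbO2, 0)
  expect_lt(act$dHb, 0)
})
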