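test_that("reflectance assembly reduces to counts/(N area) at mua=0, omega=0", {
  led <- cached_ledger("unit_small", two_layer_default(), 2e5, 31)
  r <- assemble_reflectance(led, c(0, 0), omega = 0)
  expect_true(all(Im(r$value) == 0))
  n <- led$n_launched_per_source
  for (i in seq_len(nrow(r))) {
    area <- led$area_of(r$source[i], r$detector[i])[1]
    expect_equal(Re(r$value[i]), r$n_detected[i] / (n * area),
                 tolerance = 1e-12)
  }
})

test_that("single-photon ledger gives the closed-form summand", {
  led <- cached_ledger("unit_small", two_layer_default(), 2e5, 31)
  one <- led
  keep <- 1L
  one$paths <- matrix(c(10, 0), 1, 2)   # 10 mm in layer 1 only
  one$source <- one$source[keep]; one$detector <- one$detector[keep]
  one$rho <- one$rho[keep]
  one$counts[["detected"]] <- 1
  r <- assemble_reflectance(one, c(0.1, 0), omega = 0)
  n <- one$n_launched_per_source
  area <- one$area_of(r$source[1], r$detector[1])[1]
  expect_equal(Re(r$value[1]), exp(-1) / (n * area), tolerance = 1e-12)
  # with modulation the phase is omega * l * n / c
  r2 <- assemble_reflectance(one, c(0, 0), omega = OMEGA_DEFAULT)
  expect_equal(Arg(r2$value[1]), OMEGA_DEFAULT * 10 * 1.4 / C_MM_S,
               tolerance = 1e-12)
})

test_that("correlated perturbation is exact and monotone", {
  led <- cached_ledger("unit_small", two_layer_default(), 2e5, 31)
  mua <- led$medium$layers$mua
  # zero perturbation: exactly zero change
  pr0 <- perturbed_reflectance(led, mua, c(0, 0))
  expect_true(all(pr0$delta$delta == 0))
  # deep absorption increase damps the amplitude
  pr <- perturbed_reflectance(led, mua, c(0, 0.001))
  expect_true(all(Mod(pr$perturbed$value) < Mod(pr$base$value)))
  # perturbing an unvisited layer changes nothing: kill the deep paths
  led0 <- led
  led0$paths[, 2] <- 0
  pr2 <- perturbed_reflectance(led0, mua, c(0, 0.5))
  expect_true(all(pr2$delta$delta == 0))
})

test_that("analytic layer derivatives match central finite differences", {
  led <- cached_ledger("unit_small", two_layer_default(), 2e5, 31)
  mua <- led$medium$layers$mua
  ld <- layer_derivatives(led, mua)
  h <- 1e-6
  for (j in 1:2) {
    dh <- rep(0, 2); dh[j] <- h
    up <- assemble_reflectance(led, mua + dh)
    dn <- assemble_reflectance(led, mua - dh)
    fd <- (up$value - dn$value) / (2 * h)
    an <- ld$dR_dmua[ld$layer == j]
    expect_lt(max(Mod(fd - an) / Mod(an)), 1e-6)
  }
  # homogeneous-equivalent additivity: sum over layers = total-path derivative
  w <- layerlight:::photon_weights(led, mua, OMEGA_DEFAULT)
  tot <- layerlight:::sum_by_pair(led, -rowSums(led$paths) * w)
  by_layer <- tapply(ld$dR_dmua, paste(ld$source, ld$detector), sum)
  expect_equal(as.vector(by_layer[paste(tot$source, tot$detector)]),
               tot$value, tolerance = 1e-12)
})

test_that("diffusion model has the correct DC and distance behavior", {
  # DC limit: real, monotone decreasing in rho and mua
  r_dc <- diffusion_reflectance(c(10, 20, 30, 40), 0.01, 1.0, omega = 0)
  expect_true(all(Im(r_dc) == 0))
  expect_true(all(diff(Re(r_dc)) < 0))
  r_mua <- vapply(c(0.005, 0.01, 0.02, 0.04),
                  function(m) Mod(diffusion_reflectance(25, m, 1.0, omega = 0)),
                  0)
  expect_true(all(diff(r_mua) < 0))
  # phase grows with rho across a physiological grid at 140.625 MHz
  for (mua in c(0.005, 0.01, 0.02)) {
    for (musp in c(0.5, 1.0, 1.8)) {
      ph <- Arg(diffusion_reflectance(c(25, 37), mua, musp))
      expect_gt(ph[2], ph[1])
    }
  }
})

test_that("homogeneous Jacobians obey slope linearity and step stability", {
  j <- homogeneous_jacobian(0.01, 1.0)
  # slope Jacobian is the difference of the SD Jacobians over delta rho
  expect_equal(j[["dsi"]], (j[["sdi37"]] - j[["sdi25"]]) / 12,
               tolerance = 1e-10)
  expect_equal(j[["dsphi"]], (j[["sdphi37"]] - j[["sdphi25"]]) / 12,
               tolerance = 1e-10)
  # signs: intensity Jacobians negative; phase Jacobians negative here
  expect_true(all(j[c("sdi25", "sdi37", "dsi")] < 0))
  # Richardson step-halving stability
  j2 <- homogeneous_jacobian(0.01, 1.0, step = 5e-6)
  expect_lt(max(abs(j2 - j) / abs(j)), 1e-4)
  expect_error(homogeneous_jacobian(0.01, 1.0, rho_short = 25, rho_long = 25),
               "degenerate")
})

test_that("analytic retrieval identity recovers a small planted change", {
  m0 <- layerlight:::model_datatypes(0.012, 0.9)
  m1 <- layerlight:::model_datatypes(0.012 + 1e-4, 0.9)
  j <- homogeneous_jacobian(0.012, 0.9)
  rec <- (m1 - m0) / j
  expect_true(all(abs(rec / 1e-4 - 1) < 0.01))
})

test_that("shared-ledger perturbation beats independent ledgers on variance", {
  med <- two_layer_default()
  opt <- make_ds_array()
  mua <- med$layers$mua
  deltas_shared <- c(); deltas_indep <- c()
  for (s in 1:4) {
    la <- run_white_mc(med, opt, 5e4, seed = 200 + s)
    lb <- run_white_mc(med, opt, 5e4, seed = 300 + s)
    pr <- perturbed_reflectance(la, mua, c(0, 0.001))
    i25 <- which(pr$base$rho == 25)[1]
    deltas_shared <- c(deltas_shared, Mod(pr$delta$delta[i25]))
    ra <- assemble_reflectance(la, mua)
    rb <- assemble_reflectance(lb, mua + c(0, 0.001))
    deltas_indep <- c(deltas_indep, Mod(rb$value[i25] - ra$value[i25]))
  }
  expect_lt(stats::var(deltas_shared), stats::var(deltas_indep))
})
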