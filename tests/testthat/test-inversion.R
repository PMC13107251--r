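toy_sensitivity <- function() {
  led <- cached_ledger("unit_3l", three_layer_reference(), 5e5, 41)
  build_sensitivity_matrix(layer_derivatives(led, led$medium$layers$mua))
}

test_that("sensitivity rows are normalized over all layers and rank 2", {
  S <- toy_sensitivity()
  expect_equal(unname(rowSums(S$fractions)), rep(1, 6), tolerance = 1e-12)
  expect_equal(S$rank, 2)
  expect_equal(dim(S$S), c(6, 2))
  # the CSF column is excluded from the unknowns but kept in the denominator
  expect_equal(S$layers_kept, c(1L, 3L))
  # pseudoinverse is a left inverse: S+ S = I
  expect_equal(layerlight:::pinv(S$S) %*% S$S, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("homogeneous-equivalent layer derivatives sum to the homogeneous Jacobian", {
  med <- make_three_layer(L1 = 30, L2 = 30, mua1 = 0.01, mua2 = 0.01,
                          mua3 = 0.01, musp1 = 1.0, musp2 = 1.0, musp3 = 1.0)
  led <- cached_ledger("unit_3l_homog", med, 2e6, 42)
  S <- build_sensitivity_matrix(layer_derivatives(led, med$layers$mua))
  j <- homogeneous_jacobian(0.01, 1.0)
  # MC summed-layer Jacobian vs analytic homogeneous Jacobian: a few percent
  # (MC noise + diffusion-vs-transport)
  expect_equal(unname(S$J_sum[c("dsi", "dsphi")]),
               unname(j[c("dsi", "dsphi")]), tolerance = 0.1)
})

test_that("consistent synthetic systems are recovered exactly", {
  S <- toy_sensitivity()
  planted <- c(2e-4, 1.5e-3)
  sol <- solve_layers(drop(S$S %*% planted), S)
  expect_equal(sol$dmua_superficial, planted[1], tolerance = 1e-12)
  expect_equal(sol$dmua_deep, planted[2], tolerance = 1e-12)
  expect_lt(sol$residual_norm, 1e-15)
})

test_that("noisy recovery is unbiased over replicates", {
  S <- toy_sensitivity()
  planted <- c(0, 1e-3)
  truth <- drop(S$S %*% planted)
  sup <- dp <- numeric(200)
  set.seed(4242)
  for (i in 1:200) {
    sol <- solve_layers(truth + stats::rnorm(6, sd = 1e-5), S)
    sup[i] <- sol$dmua_superficial; dp[i] <- sol$dmua_deep
  }
  # mean recovered superficial change consistent with 0 within 3 SE
  expect_lt(abs(mean(sup)), 3 * stats::sd(sup) / sqrt(200))
  expect_lt(abs(mean(dp) - 1e-3), 3 * stats::sd(dp) / sqrt(200))
})

test_that("SEM propagation matches its closed forms", {
  S <- toy_sensitivity()
  Sp <- layerlight:::pinv(S$S)
  # zero in, zero out
  expect_equal(unname(propagate_sem(S, rep(0, 6))), c(0, 0))
  # single nonzero entry: |pseudoinverse column| times the entry
  sem <- rep(0, 6); sem[3] <- 2e-5
  expect_equal(unname(propagate_sem(S, sem)), abs(Sp[, 3]) * 2e-5,
               tolerance = 1e-12)
  # equal entries: s * row norms
  expect_equal(unname(propagate_sem(S, rep(1e-5, 6))),
               1e-5 * sqrt(rowSums(Sp^2)), tolerance = 1e-12)
})

test_that("own pseudoinverse agrees with an independent implementation", {
  S <- toy_sensitivity()
  expect_equal(layerlight:::pinv(S$S), MASS::ginv(S$S), tolerance = 1e-10)
})

test_that("rank-deficient sensitivity matrices are rejected", {
  S <- toy_sensitivity()
  S$S[, 2] <- S$S[, 1]
  sv <- svd(S$S)$d
  S$rank <- sum(sv > max(sv) * 1e-10)
  expect_error(solve_layers(rep(1e-4, 6), S), "rank")
})
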