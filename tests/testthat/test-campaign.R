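small_spec <- function(...) {
  sweep_spec(model = "two_layer", L1 = 10,
             constants = list(mua1 = 0.017, mua2 = 0.021,
                              musp1 = 1.45, musp2 = 1.1),
             photons = 2e5, seed = 61, ...)
}

test_that("sweep specs validate their grids and constants", {
  expect_error(sweep_spec("two_layer", L1 = numeric(0),
                          constants = list(mua1 = 1, mua2 = 1, musp1 = 1,
                                           musp2 = 1)), "L1")
  expect_error(sweep_spec("two_layer", constants = list(mua1 = 0.01)),
               "missing held constants")
  # a varied parameter counts as provided
  s <- sweep_spec("two_layer", vary = list(param = "mua1", values = c(0.01)),
                  constants = list(mua2 = 0.02, musp1 = 1, musp2 = 1))
  expect_s3_class(s, "sweep_spec")
})

test_that("a homogeneous single-point campaign recovers the perturbation", {
  # L1 at box depth: one layer, so the "deepest layer" is the whole medium
  spec <- sweep_spec(model = "two_layer", L1 = 100,
                     constants = list(mua1 = 0.017, mua2 = 0.017,
                                      musp1 = 1.1, musp2 = 1.1),
                     photons = 2e6, seed = 62)
  res <- run_campaign(spec)
  expect_equal(nrow(res), 6)
  expect_true(all(res$ok))
  # intensity types: linearization (~1%) + MC/fit error
  ii <- res$data_type %in% c("sdi25", "sdi37", "dsi")
  expect_true(all(abs(res$dmua[ii] - 0.001) / 0.001 < 0.10))
  # phase types carry the diffusion-approximation bias of the phase
  # Jacobian (~10%) on top of curvature (~4%); see the methods vignette
  expect_true(all(abs(res$dmua[!ii] - 0.001) / 0.001 < 0.25))
})

test_that("absorption sweeps reuse one ledger per geometry", {
  cache <- new.env(parent = emptyenv())
  spec <- small_spec(vary = list(param = "mua1", values = c(0.012, 0.017)))
  res <- run_campaign(spec, ledger_cache = cache)
  expect_equal(length(ls(cache)), 1)   # one geometry, two mua values
  expect_equal(nrow(res), 12)
  expect_true(all(res$ok))
  # provenance columns are populated
  expect_true(all(c("photons", "seed", "fit_mua", "converged") %in%
                  names(res)))
})

test_that("campaigns are deterministic given spec and seed", {
  spec <- small_spec()
  r1 <- run_campaign(spec)
  r2 <- run_campaign(spec)
  expect_identical(r1$dmua, r2$dmua)
})

test_that("results round-trip through CSV and JSON export", {
  res <- run_campaign(small_spec())
  pref <- file.path(withr::local_tempdir(), "sweep")
  files <- export_results(res, pref)
  back <- read_results_csv(files[["csv"]])
  expect_equal(back$dmua, res$dmua, tolerance = 1e-12)
  expect_equal(names(back), names(res))
  js <- jsonlite::read_json(files[["json"]])
  expect_true(nzchar(js$config_hash))
  expect_equal(js$schema_version, "1.0")
  expect_error(export_results(res[0, ], pref), "empty")
})

test_that("top-layer perturbation sweeps carry both planted changes", {
  spec <- small_spec(vary = list(param = "delta_mua1",
                                 values = c(0, 5e-4)))
  res <- run_campaign(spec)
  expect_equal(sort(unique(res$delta_mua_top)), c(0, 5e-4))
  expect_true(all(res$delta_mua_deep == 0.001))
  # intensity types are contaminated more by the superficial change than
  # the deep-weighted DS phase
  base <- res[res$delta_mua_top == 0, ]
  cont <- res[res$delta_mua_top == 5e-4, ]
  lift <- (cont$dmua - base$dmua)[match(c("sdi25", "dsphi"), base$data_type)]
  expect_gt(lift[1], lift[2])
})

test_that("ledgers, reflectance tables and sensitivities serialize to text", {
  led <- cached_ledger("unit_small", two_layer_default(), 2e5, 31)
  dir <- withr::local_tempdir()
  lc <- file.path(dir, "ledger.csv")
  write_ledger_csv(led, lc)
  back <- utils::read.csv(lc)
  expect_equal(nrow(back), unname(led$counts[["detected"]]))
  expect_true(all(c("source", "detector", "l_1", "l_2") %in% names(back)))

  r <- assemble_reflectance(led, led$medium$layers$mua)
  rc <- file.path(dir, "refl.csv")
  write_reflectance_csv(r, rc, wavelength_nm = 830)
  rb <- utils::read.csv(rc)
  expect_equal(rb$amplitude, Mod(r$value), tolerance = 1e-12)
  expect_equal(rb$omega_rad_s, rep(OMEGA_DEFAULT, 4))

  led3 <- cached_ledger("unit_3l", three_layer_reference(), 5e5, 41)
  S <- build_sensitivity_matrix(layer_derivatives(led3,
                                                  led3$medium$layers$mua))
  sj <- file.path(dir, "S.json")
  write_sensitivity_json(S, sj)
  js <- jsonlite::read_json(sj)
  expect_equal(js$rank, 2)
  expect_equal(length(js$S), 6)   # one record per data type
  expect_true(all(c("superficial", "deep") %in% names(js$S[[1]])))
})

test_that("re-weighting one white ledger matches an independent simulation", {
  # transport is absorption-free, so two ledgers differ only by seed; the
  # absorption set enters purely through re-weighting
  med <- two_layer_default()
  opt <- make_ds_array()
  la <- run_white_mc(med, opt, 4e5, seed = 71)
  lb <- run_white_mc(med, opt, 4e5, seed = 72)
  target <- c(0.012, 0.021)
  ra <- assemble_reflectance(la, target)   # "re-weighted" ledger
  rb <- assemble_reflectance(lb, target)   # "independent" simulation
  for (i in seq_len(nrow(ra))) {
    for (part in list(Re, Im)) {
      d <- abs(part(ra$value[i]) - part(rb$value[i]))
      se <- sqrt((if (identical(part, Re)) ra$se_re[i]^2 + rb$se_re[i]^2
                  else ra$se_im[i]^2 + rb$se_im[i]^2))
      expect_lt(d, 3.5 * se)
    }
  }
})
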