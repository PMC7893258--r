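test_that("tissue density is recovered from noisy synthetic glides", {
  p <- truth_params()
  gl <- simulateGlides(p, n_glides = 200, noise_sd = 0.01, seed = 501)
  fit <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                       mcmc = fast_mcmc(502, iterations = 6000))
  rho <- param_row(fit, "^rho0")
  expect_lt(abs(rho$mean - 1036), 1.0)
  expect_true(rho$ci_lo <= 1036 && 1036 <= rho$ci_hi)
  expect_true(fit$converged)
  # error scale recovered too
  expect_equal(param_row(fit, "^sigma")$mean, 0.01, tolerance = 0.25)
})

test_that("the posterior collapses on noiseless data", {
  gl <- simulateGlides(truth_params(), n_glides = 100, noise_sd = 0, seed = 503)
  fit <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                       mcmc = fast_mcmc(504))
  rho <- param_row(fit, "^rho0")
  expect_lt(rho$ci_hi - rho$ci_lo, 0.2)
  expect_lt(abs(rho$mean - 1036), 0.1)
})

test_that("individual-scope densities keep the planted ordering", {
  ps <- list(lean = hydroParams(1044, 12e-6, 3.73e-5),
             mid = hydroParams(1037, 12e-6, 3.73e-5),
             fat = hydroParams(1030, 12e-6, 3.73e-5))
  gl <- simulateGlides(ps, n_glides = 80, noise_sd = 0.01, seed = 505)
  fit <- fitHydroModel(gl, modelStructure("individual", "global", "global"),
                       mcmc = fast_mcmc(506))
  est <- fit$whales$rho_tissue_mean[match(c("fat", "mid", "lean"),
                                          fit$whales$whale_id)]
  expect_true(all(diff(est) > 0))
  expect_equal(est, c(1030, 1037, 1044), tolerance = 2 / 1030)
})

test_that("grid oracle recovers an on-grid truth exactly from noiseless data", {
  gl <- simulateGlides(truth_params(), n_glides = 60, noise_sd = 0, seed = 507)
  go <- gridOracle(gl, seq(1030, 1042, by = 0.5), seq(8e-6, 16e-6, by = 5e-7),
                   air_per_mass = 3.73e-5)
  expect_equal(go$rho_tissue, 1036)
  expect_equal(go$drag_term, 12e-6)
  expect_lt(go$ssr, 1e-18)
  expect_error(gridOracle(gl[0, ], 1030, 1e-5, 0))
})

test_that("MCMC and the grid oracle agree within one grid cell on noisy data", {
  gl <- simulateGlides(truth_params(), n_glides = 200, noise_sd = 0.01,
                       seed = 508)
  fit <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                       mcmc = fast_mcmc(509, iterations = 6000))
  rho_step <- 0.25; drag_step <- 2.5e-7
  go <- gridOracle(gl, seq(1030, 1042, by = rho_step),
                   seq(8e-6, 16e-6, by = drag_step), air_per_mass = 3.73e-5)
  expect_lte(abs(param_row(fit, "^rho0")$mean - go$rho_tissue), rho_step)
  expect_lte(abs(param_row(fit, "^drag")$mean * 1e-6 - go$drag_term), drag_step)
})

test_that("identical seed and settings give identical draws", {
  gl <- simulateGlides(truth_params(), n_glides = 60, noise_sd = 0.01, seed = 510)
  f1 <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                      mcmc = fast_mcmc(511, iterations = 2000))
  f2 <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                      mcmc = fast_mcmc(511, iterations = 2000))
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
})

test_that("posterior means are invariant to glide order within MC error", {
  gl <- simulateGlides(truth_params(), n_glides = 150, noise_sd = 0.01, seed = 512)
  f1 <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                      mcmc = fast_mcmc(513))
  set.seed(514)
  f2 <- fitHydroModel(gl[sample(nrow(gl)), ],
                      modelStructure("global", "global", "global"),
                      mcmc = fast_mcmc(513))
  r1 <- param_row(f1, "^rho0"); r2 <- param_row(f2, "^rho0")
  expect_lt(abs(r1$mean - r2$mean), 4 * sqrt(r1$sd^2 / r1$ess + r2$sd^2 / r2$ess))
})

test_that("DIC selects heterogeneity when planted and parsimony when not", {
  cands <- list(modelStructure("individual", "global", "global"),
                modelStructure("global", "global", "global"))
  het <- simulateGlides(list(a = hydroParams(1030, 12e-6, 3.73e-5),
                             b = hydroParams(1037, 12e-6, 3.73e-5),
                             c = hydroParams(1044, 12e-6, 3.73e-5)),
                        n_glides = 60, noise_sd = 0.01, seed = 515)
  sel <- selectStructure(het, cands, mcmc = fast_mcmc(516, iterations = 3000))
  expect_equal(sel$structure$tissue_density_scope, "individual")
  hom <- simulateGlides(list(a = hydroParams(1037, 12e-6, 3.73e-5),
                             b = hydroParams(1037, 12e-6, 3.73e-5),
                             c = hydroParams(1037, 12e-6, 3.73e-5)),
                        n_glides = 60, noise_sd = 0.01, seed = 517)
  sel2 <- selectStructure(hom, cands, mcmc = fast_mcmc(518, iterations = 3000))
  tab <- attr(sel2, "dic_table")
  # global wins outright or ties within 2 DIC units (parsimony tie-break)
  expect_equal(sel2$structure$tissue_density_scope, "global")
  expect_lt(tab$dic[2] - min(tab$dic), 2 + 1e-9)
  # single candidate passes through
  one <- selectStructure(hom[hom$whale_id == "a", ], cands[2],
                         mcmc = fast_mcmc(519, iterations = 2000))
  expect_equal(one$structure$tissue_density_scope, "global")
})

test_that("inflating the per-glide errors widens the density CI", {
  gl <- simulateGlides(truth_params(), n_glides = 120, noise_sd = 0.02, seed = 520)
  st <- modelStructure("global", "global", "global", "per_glide_se")
  f1 <- fitHydroModel(gl, st, mcmc = fast_mcmc(521))
  gl10 <- gl; gl10$accel_se <- gl10$accel_se * 10
  f2 <- fitHydroModel(gl10, st, mcmc = fast_mcmc(521))
  w1 <- param_row(f1, "^rho0")$ci_hi - param_row(f1, "^rho0")$ci_lo
  w2 <- param_row(f2, "^rho0")$ci_hi - param_row(f2, "^rho0")$ci_lo
  expect_gt(w2, w1)
})

test_that("near-horizontal glides trigger an identifiability warning", {
  gl <- simulateGlides(truth_params(), n_glides = 40, noise_sd = 0.01,
                       pitch_mean_deg = 3, pitch_sd_deg = 1, seed = 522)
  expect_warning(
    fitHydroModel(gl, modelStructure("global", "global", "global"),
                  mcmc = fast_mcmc(523, iterations = 1000)),
    "identifiable")
})
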