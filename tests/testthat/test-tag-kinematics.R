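test_that("depth-rate speed follows |dz/dt| / sin(pitch) with a pitch floor", {
  expect_equal(speedFromDepthRate(1.2, -pi / 2), 1.2)
  expect_equal(speedFromDepthRate(0.6, pi / 6), 1.2)
  expect_error(speedFromDepthRate(0.5, 0.05, pitch_floor = 0.52), "pitch floor")
  # scale equivariance
  dr <- c(0.4, 0.9, 1.3)
  expect_equal(speedFromDepthRate(2 * dr, rep(0.8, 3)),
               2 * speedFromDepthRate(dr, rep(0.8, 3)))
})

test_that("a record stroking everywhere contains no glide", {
  sim <- simulateTimeseries(n_dives = 1, glide_s = 0, surface_s = 0, seed = 101)
  expect_equal(nrow(detectGlides(sim$series)), 0)
})

test_that("planted stroke-free windows are recovered within one sample", {
  sim <- simulateTimeseries(n_dives = 2, glide_s = c(12, 7, 0, 0),
                            surface_s = 40, seed = 102)
  win <- detectGlides(sim$series)
  expect_equal(nrow(win), nrow(sim$windows))
  tol <- 1  # samples
  expect_true(all(abs(win$start - sim$windows$start) <= tol))
  expect_true(all(abs(win$end - sim$windows$end) <= tol))
  # every window is at least the minimum duration and non-overlapping
  expect_true(all(win$duration >= 5 - 1 / sim$series$fs))
  expect_true(all(diff(win$start) > 0) && all(win$end[-nrow(win)] < win$start[-1]))
})

test_that("surface resting windows survive detection but die at the pitch filter", {
  sim <- simulateTimeseries(n_dives = 1, glide_s = 0, surface_s = 60, seed = 103)
  win <- detectGlides(sim$series)
  expect_gt(nrow(win), 0)  # the surface rest is stroke-free
  ctd <- simulateCtd(1025, 0.01, 200)
  expect_message(segs <- segmentGlides(win, sim$series, ctd), "pitch floor")
  # near-zero-pitch surface segments are all dropped
  expect_true(all(abs(segs$pitch) >= glideConfig()$pitch_floor))
})

test_that("windows are tiled into floor(duration/5) segments", {
  fs <- 5
  n <- 12 * fs
  t <- seq(0, by = 1 / fs, length.out = n)
  s <- tagSeries(t, depth = 20 + t, accel_dv = rnorm(n, 0, 0.01),
                 pitch = rep(-0.6, n), speed = rep(1.5, n))
  win <- tibble::tibble(start = 1L, end = n, start_time = t[1], end_time = t[n],
                        duration = t[n] - t[1])
  segs <- segmentGlides(win, s, simulateCtd(1024, 0, 100))
  expect_equal(nrow(segs), 2)  # floor(12/5)
})

test_that("segment acceleration is the OLS slope of speed on time", {
  fs <- 5
  n <- 5 * fs
  t <- seq(0, by = 1 / fs, length.out = n)
  # speed exactly linear 1.0 -> 1.5 over 5 s: slope 0.1, zero residual
  v <- 1.0 + 0.1 * t
  s <- tagSeries(t, depth = rep(30, n), accel_dv = rep(0, n),
                 pitch = rep(-0.7, n), speed = v)
  win <- tibble::tibble(start = 1L, end = as.integer(n))
  segs <- segmentGlides(win, s, simulateCtd(1025, 0, 100))
  expect_equal(segs$accel, 0.1, tolerance = 1e-10)
  expect_equal(segs$accel_se, 0, tolerance = 1e-8)
  expect_equal(segs$speed, mean(v))
  expect_equal(segs$depth, 30)
})

test_that("OLS slope and SE agree with the normal-equations oracle", {
  set.seed(104)
  fs <- 5
  n <- 5 * fs
  t <- seq(0, by = 1 / fs, length.out = n)
  for (rep in 1:5) {
    v <- 1.5 + 0.05 * t + rnorm(n, 0, 0.03)
    s <- tagSeries(t, depth = rep(40, n), accel_dv = rep(0, n),
                   pitch = rep(0.8, n), speed = v)
    segs <- segmentGlides(tibble::tibble(start = 1L, end = as.integer(n)),
                          s, simulateCtd(1025, 0, 100))
    orc <- ols_oracle(t, v)
    expect_equal(segs$accel, orc$slope, tolerance = 1e-10)
    expect_equal(segs$accel_se, orc$se, tolerance = 1e-10)
  }
})

test_that("a noiseless synthetic glide reproduces the forward model", {
  # plant a 5 s glide whose speed follows the eq-of-motion slope at the
  # segment conditions, then check extraction returns that acceleration
  p <- truth_params()
  fs <- 5
  n <- 5 * fs
  t <- seq(0, by = 1 / fs, length.out = n)
  d <- 60; pit <- -0.8; vbar <- 1.5
  ctd <- simulateCtd(1025, 0, 200)
  a_true <- glideAcceleration(p, d, pit, vbar, ctdDensityAt(ctd, d))
  v <- vbar + a_true * (t - mean(t))
  s <- tagSeries(t, depth = rep(d, n), accel_dv = rep(0, n),
                 pitch = rep(pit, n), speed = v)
  segs <- segmentGlides(tibble::tibble(start = 1L, end = as.integer(n)), s, ctd)
  a_model <- glideAcceleration(p, segs$depth, segs$pitch, segs$speed, segs$rho_sw)
  expect_equal(segs$accel, a_model, tolerance = 1e-6)
})

test_that("glide-poor whales are excluded at the stated threshold", {
  mk <- function(id, k) tibble::tibble(whale_id = rep(id, k))
  g <- rbind(mk("nine", 9), mk("ten", 10), mk("many", 25))
  expect_message(out <- filterWhales(g, 10), "excluded 1")
  expect_setequal(unique(out$whale_id), c("ten", "many"))
  expect_equal(attr(out, "excluded")$whale_id, "nine")
})

test_that("a 70-whale population with 11 glide-poor whales keeps 59", {
  set.seed(105)
  n_gl <- c(sample(10:40, 59, replace = TRUE), sample(1:9, 11, replace = TRUE))
  g <- tibble::tibble(whale_id = rep(sprintf("w%02d", 1:70), n_gl))
  out <- suppressMessages(filterWhales(g, 10))
  expect_equal(length(unique(out$whale_id)), 59)
})

test_that("pitch is recovered from the surge axis when absent", {
  fs <- 8
  t <- seq(0, 120, by = 1 / fs)
  p0 <- 0.6
  f_stroke <- 0.5
  surge <- 9.8 * sin(p0) + 0.5 * sin(2 * pi * f_stroke * t) + rnorm(length(t), 0, 0.02)
  pit <- pitchFromAcceleration(surge, fs, f_stroke)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_equal(mean(pit[mid]), p0, tolerance = 0.02)
})

test_that("CTD lookup interpolates linearly and clamps at the ends", {
  ctd <- ctdProfile(c(0, 100), c(1023, 1027))
  expect_equal(ctdDensityAt(ctd, 50), 1025)
  expect_equal(ctdDensityAt(ctd, 250), 1027)  # constant extrapolation
  expect_equal(ctdDensityAt(ctd, -5), 1023)
  expect_error(ctdProfile(c(0, 100), c(990, 1027)))
})

test_that("tag series validation rejects malformed records", {
  t <- c(0, 0.2, 0.4, 0.7)  # non-uniform
  expect_error(tagSeries(t, rep(1, 4), rep(0, 4), pitch = rep(0, 4)),
               "uniform")
  t2 <- seq(0, 3, by = 0.2)
  expect_error(tagSeries(t2, rep(1, length(t2)), rep(0, length(t2))),
               "pitch or surge")
})

test_that("end-to-end round trip recovers planted glide kinematics", {
  sim <- simulateTimeseries(n_dives = 3, glide_s = 10, dive_depth = 90,
                            pitch_deg = 55, speed = 1.8, seed = 106)
  win <- detectGlides(sim$series)
  segs <- suppressMessages(
    segmentGlides(win, sim$series, simulateCtd(1024, 0.01, 200)))
  dive_segs <- segs[abs(segs$pitch) > 0.5, ]
  expect_gte(nrow(dive_segs), 4)
  expect_equal(unname(abs(dive_segs$pitch)), rep(55 * pi / 180, nrow(dive_segs)),
               tolerance = 1e-6)
  expect_equal(dive_segs$speed, rep(1.8, nrow(dive_segs)), tolerance = 0.02)
  expect_true(all(dive_segs$depth > 0 & dive_segs$depth < 90))
})
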