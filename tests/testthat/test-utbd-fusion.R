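test_that("whale records are validated", {
  ok <- tibble::tibble(whale_id = "a", location = "Canada", season_day = 160,
                       sex = "female", pregnant = 0, lactating = 0,
                       immature = 0, tbd_mean = 1036, tbd_sd = 2, lssai = 0.08)
  expect_silent(whaleRecords(ok))
  bad <- ok; bad$tbd_mean <- NA; bad$lssai <- NA
  expect_error(whaleRecords(bad), "no observation channel")
  bad2 <- ok; bad2$sex <- "male"; bad2$pregnant <- 1
  expect_error(whaleRecords(bad2), "female")
  bad3 <- ok; bad3$tbd_sd <- NA
  expect_error(whaleRecords(bad3), "sd")
})

test_that("season day continues the Norwegian winter past the new year", {
  expect_equal(seasonDay(as.Date("2017-01-22"), "Norway"),
               22 + 365)
  expect_equal(seasonDay(as.Date("2016-06-23"), "Canada"), 175)
  expect_equal(seasonDay(as.Date("2017-11-20"), "Norway"), 324)
  # the late-season classification (day > 190) is preserved
  expect_gt(seasonDay(as.Date("2018-01-13"), "Norway"), 190)
})

test_that("the two channels correlate as published in the 21-whale table", {
  ct <- correlateChannels(crossvalRecords())
  expect_equal(ct$n, 21)
  expect_equal(round(ct$r, 2), -0.48)
  expect_equal(ct$p, 0.0265, tolerance = 0.02)
  # degenerate checks
  x <- c(1, 2, 3, 5, 8)
  d <- tibble::tibble(tbd_mean = x, lssai = x)
  expect_equal(correlateChannels(d)$r, 1)
  d2 <- tibble::tibble(tbd_mean = x, lssai = 10 - x)
  expect_equal(correlateChannels(d2)$r, -1)
  expect_error(correlateChannels(d[1:2, ]), "at least 3")
})

test_that("a null link slope is recovered as null", {
  tr <- populationTruthDefault(link_gamma = 0)
  pop <- simulatePopulation(n = 60, n_tbd = 45, n_lssai = 40, n_both = 25,
                            truth = tr, seed = 601)
  fit <- fitUtbd(pop, mcmc = fast_mcmc(602, iterations = 6000))
  g <- fit$link[fit$link$parameter == "gamma", ]
  expect_true(g$ci_lo <= 0 && 0 <= g$ci_hi)
})

test_that("latent densities stay positive and single-channel whales are vaguer", {
  pop <- simulatePopulation(n = 60, n_tbd = 40, n_lssai = 40, n_both = 20,
                            seed = 603)
  fit <- suppressWarnings(fitUtbd(pop, mcmc = fast_mcmc(604, iterations = 6000)))
  expect_true(all(fit$u_draws > 0))
  w <- fit$whales
  expect_gt(mean(w$utbd_sd[!w$has_tbd]),           # LSSAI-only
            mean(w$utbd_sd[w$has_tbd & w$has_lssai]))
})

test_that("effects are exact response-scale contrasts of the draws", {
  pop <- simulatePopulation(n = 50, n_tbd = 35, n_lssai = 30, n_both = 15,
                            seed = 605)
  fit <- fitUtbd(pop, mcmc = fast_mcmc(606, iterations = 4000))
  b0 <- fit$beta_draws[, "(Intercept)"]
  for (nm in c("pregnant", "lactating")) {
    contr <- exp(b0 + fit$beta_draws[, nm]) - exp(b0)
    row <- fit$effects[fit$effects$effect == nm, ]
    expect_equal(row$mean, mean(contr))
    expect_equal(row$sd, sd(contr))
    # small-coefficient linearization agrees to ~3 significant figures
    approx_eff <- mean(exp(b0)) * mean(fit$beta_draws[, nm])
    expect_equal(row$mean, approx_eff, tolerance = 5e-3 * max(1, abs(row$mean)))
  }
})

test_that("shifting the season axis moves only the intercept", {
  pop <- simulatePopulation(n = 50, n_tbd = 50, n_lssai = 0, n_both = 0,
                            p_norway = 0, seed = 607)
  pop <- suppressWarnings(whaleRecords(pop))
  f1 <- suppressWarnings(fitUtbd(pop, mcmc = fast_mcmc(608, iterations = 4000),
                                 interaction = FALSE))
  pop2 <- pop; pop2$season_day <- pop2$season_day + 50
  f2 <- suppressWarnings(fitUtbd(pop2, mcmc = fast_mcmc(608, iterations = 4000),
                                 interaction = FALSE))
  d1 <- f1$effects[f1$effects$effect == "day100", ]
  d2 <- f2$effects[f2$effects$effect == "day100", ]
  # day-axis shift is absorbed by the (re-centred) intercept: slope unchanged
  expect_lt(abs(d1$mean - d2$mean), 3 * sqrt(d1$sd^2 + d2$sd^2) / sqrt(50))
})

test_that("dropping the LSSAI channel reduces to a TBD-only Gamma regression", {
  pop <- simulatePopulation(n = 40, n_tbd = 40, n_lssai = 10, n_both = 10,
                            seed = 609)
  pop_t <- pop; pop_t$lssai <- NA_real_
  w <- capture_warnings(f_t <- fitUtbd(pop_t, mcmc = fast_mcmc(610, iterations = 4000)))
  expect_true(any(grepl("no LSSAI", w)))
  expect_null(f_t$link)
  f_full <- suppressWarnings(fitUtbd(pop, mcmc = fast_mcmc(610, iterations = 4000)))
  # with only 10 weak LSSAI rows the coefficient posteriors must agree
  for (nm in c("pregnant", "day100")) {
    a <- f_t$effects[f_t$effects$effect == nm, ]
    b <- f_full$effects[f_full$effects$effect == nm, ]
    expect_lt(abs(a$mean - b$mean), 1.5 * sqrt(a$sd^2 + b$sd^2))
  }
})

test_that("sparse factor levels are fixed at zero with a warning", {
  pop <- simulatePopulation(n = 30, n_tbd = 30, n_lssai = 0, n_both = 0,
                            seed = 611)
  pop$pregnant <- 0; pop$pregnant[which(pop$sex == "female")[1]] <- 1
  w <- capture_warnings(f <- fitUtbd(pop, mcmc = fast_mcmc(612, iterations = 2000)))
  expect_true(any(grepl("fewer than 2", w)))
  expect_false("pregnant" %in% f$effects$effect)
})

test_that("missing channels are predicted from the posterior", {
  tr <- populationTruthDefault()
  pop <- simulatePopulation(n = 60, n_tbd = 40, n_lssai = 40, n_both = 20,
                            truth = tr, seed = 613)
  fit <- suppressWarnings(fitUtbd(pop, mcmc = fast_mcmc(614, iterations = 6000)))
  lonly <- fit$whales$whale_id[!fit$whales$has_tbd][1]
  pt <- predictMissing(fit, lonly, "tbd")
  expect_true(pt$mean > 1000 && pt$mean < 1070)
  expect_true(pt$ci[1] < pt$mean && pt$mean < pt$ci[2])
  tonly <- fit$whales$whale_id[!fit$whales$has_lssai][1]
  pl <- predictMissing(fit, tonly, "lssai")
  expect_true(pl$mean > 0.04 && pl$mean < 0.12)
  expect_error(predictMissing(fit, "nope", "tbd"), "not in the fitted")
})

test_that("a noise-free link gives needle-sharp LSSAI predictions", {
  tr <- populationTruthDefault(link_sigma = 1e-6)
  pop <- simulatePopulation(n = 40, n_tbd = 40, n_lssai = 40, n_both = 40,
                            truth = tr, seed = 615)
  fit <- suppressWarnings(fitUtbd(pop, mcmc = fast_mcmc(616, iterations = 6000),
                                  sigL_scale = 0.02))
  pl <- predictMissing(fit, fit$whales$whale_id[1], "lssai")
  # predictive width collapses toward the (tiny) generator noise
  expect_lt(pl$ci[2] - pl$ci[1], 0.01)
})

test_that("held-out channels are covered by the posterior predictive", {
  hits_t <- 0; hits_l <- 0; reps <- 10
  for (i in seq_len(reps)) {
    pop <- simulatePopulation(n = 40, n_tbd = 40, n_lssai = 40, n_both = 40,
                              seed = 700 + i)
    # hold out one whale's channels by masking
    hold <- pop[1, ]
    pop$lssai[1] <- NA
    # short chains: convergence flags are tolerated, coverage is the check
    fit <- suppressWarnings(
      fitUtbd(pop, mcmc = fast_mcmc(720 + i, iterations = 3000)))
    pl <- predictMissing(fit, pop$whale_id[1], "lssai")
    hits_l <- hits_l + (pl$ci[1] <= hold$lssai && hold$lssai <= pl$ci[2])
    pt <- predictMissing(fit, pop$whale_id[1], "tbd")
    ok_t <- (pt$ci[1] - 2 * hold$tbd_sd <= hold$tbd_mean) &&
      (hold$tbd_mean <= pt$ci[2] + 2 * hold$tbd_sd)
    hits_t <- hits_t + ok_t
  }
  expect_gte(hits_l / reps, 0.9)
  expect_gte(hits_t / reps, 0.9)
})
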