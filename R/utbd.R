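#' Feeding-season day axis
#'
#' Converts calendar dates to a monotone feeding-season day axis: the
#' Julian day of year, with Norwegian winter deployments (January--March,
#' the late-season Tromso fieldwork that crosses the new year) shifted by
#' +365 so that "late season" days follow "early season" days
#' numerically. The published late-season threshold (Julian day > 190) is
#' preserved by this axis.
#'
#' @param date `Date` vector (or ISO-8601 strings).
#' @param location character vector, "Canada" or "Norway".
#' @return numeric season day.
#' @export
seasonDay <- function(date, location) {
  date <- as.Date(date)
  jday <- as.numeric(format(date, "%j"))
  jday + ifelse(location == "Norway" & jday < 100, 365, 0)
}

#' Validate whale records for the fusion model
#'
#' Checks the unit-of-analysis table for the latent-density model: every
#' whale must carry at least one observation channel (TBD and/or LSSAI),
#' a TBD observation must come with its sd, and reproductive flags must
#' be compatible with sex (pregnant/lactating implies female).
#'
#' @param records tibble with columns `whale_id, location, season_day,
#'   sex, pregnant, lactating, immature, tbd_mean, tbd_sd, lssai`
#'   (`NA` = missing channel).
#' @return the validated tibble, invisibly classed `whale_records`.
#' @export
whaleRecords <- function(records) {
  need <- c("whale_id", "location", "season_day", "sex", "pregnant",
            "lactating", "immature", "tbd_mean", "tbd_sd", "lssai")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(records$location %in% c("Canada", "Norway")),
            all(records$sex %in% c("female", "male", "unknown")))
  no_channel <- is.na(records$tbd_mean) & is.na(records$lssai)
  if (any(no_channel)) {
    stop("whale(s) with no observation channel: ",
         paste(records$whale_id[no_channel], collapse = ", "))
  }
  if (any(!is.na(records$tbd_mean) & is.na(records$tbd_sd))) {
    stop("TBD observations require a per-observation sd")
  }
  bad_flag <- (records$pregnant == 1 | records$lactating == 1) &
    records$sex != "female"
  if (any(bad_flag)) {
    stop("pregnant/lactating flags require sex == female: ",
         paste(records$whale_id[bad_flag], collapse = ", "))
  }
  class(records) <- unique(c("whale_records", class(records)))
  invisible(records)
}

.utbdModelString <- function(has_lssai, has_tbd = TRUE) {
  paste0(
    "model {\n",
    "  for (j in 1:n) {\n",
    "    log(mu[j]) <- inprod(X[j, ], beta)\n",
    "    u[j] ~ dgamma(kshape, kshape / mu[j])\n",
    "  }\n",
    if (has_tbd) paste0(
      "  for (i in 1:nt) {\n",
      "    tbd[i] ~ dnorm(u[wt[i]], 1 / (tsd[i] * tsd[i]))\n",
      "  }\n") else "",
    if (has_lssai) paste0(
      "  for (i in 1:nl) {\n",
      "    lss[i] ~ dnorm(alpha_c + gam * (u[wl[i]] - ucenter),\n",
      "                   1 / (sigL * sigL))\n",
      "  }\n",
      "  alpha_c ~ dnorm(0, 1e-4)\n",
      "  gam ~ dnorm(0, 1)\n",
      "  sigL ~ dnorm(0, sigL_prior_tau) T(1e-6,)\n") else "",
    "  beta[1] ~ dnorm(b0_mu, b0_tau)\n",
    "  for (q in 2:P) { beta[q] ~ dnorm(0, 1) }\n",
    "  kshape ~ dnorm(0, k_prior_tau) T(1,)\n",
    "}\n")
}

#' Fit the hierarchical latent tissue-density model
#'
#' Fuses the two body-condition observation channels in a single
#' hierarchical model of the latent ("underlying") tissue body density
#' uTBD of each whale:
#' \deqn{\log \mu_j = X_j \beta, \quad
#'       uTBD_j \sim \mathrm{Gamma}(\text{mean } \mu_j, \text{shape } k)}
#' \deqn{TBD_j \sim N(uTBD_j, sd_j) \quad (sd_j \text{ supplied}),\qquad
#'       LSSAI_j \sim N(\alpha + \gamma\, uTBD_j, \sigma_L).}
#' The default linear predictor is intercept + location + day/100 +
#' location:(day/100) + sex + pregnant + lactating + immature, with the
#' season-day axis centred at its sample minimum. Factor levels observed
#' on fewer than two whales are dropped (coefficient fixed at 0, with a
#' warning); if no whale carries an LSSAI observation the link parameters
#' are dropped entirely. The LSSAI link is sampled in a centred
#' parameterization, \eqn{\alpha_c + \gamma (uTBD - 1037)}, for sampler
#' conditioning; the reported intercept is \eqn{\alpha = \alpha_c - 1037\gamma}.
#'
#' Covariate effects are reported on the response scale, as the contrast
#' in predicted uTBD (kg m^-3) at the reference covariates (Canada,
#' season-day start, adult resting female) when the covariate is
#' switched on; the day effect is per +100 days at the reference.
#'
#' @param records a [whaleRecords()]-valid tibble.
#' @param mcmc an [mcmcConfig()].
#' @param interaction include the location-by-day interaction (default
#'   TRUE; the early-season location contrast is expected to shrink over
#'   the season).
#' @param b0_prior mean/sd of the normal prior on the log-scale intercept.
#' @param k_scale half-normal prior scale of the Gamma shape.
#' @param sigL_scale half-normal prior scale of the LSSAI error sd.
#' @param quiet suppress JAGS output.
#' @return object of class `utbd_fit` with `effects` (response-scale
#'   tibble), `summaries` (raw-parameter tibble), `whales` (per-whale
#'   uTBD posterior mean/sd/CI and channel availability), `link`
#'   (alpha/gamma/sigma_L summaries or NULL), `converged`, the design
#'   matrix info, and the coda draws.
#' @export
fitUtbd <- function(records, mcmc = mcmcConfig(iterations = 12000),
                    interaction = TRUE,
                    b0_prior = c(log(1037), 0.05),
                    k_scale = 1e4, sigL_scale = 0.02, quiet = TRUE) {
  records <- whaleRecords(tibble::as_tibble(records))
  n <- nrow(records)
  day0 <- min(records$season_day)
  dd <- (records$season_day - day0) / 100
  loc <- as.numeric(records$location == "Norway")
  cols <- list(
    `(Intercept)` = rep(1, n),
    locationNorway = loc,
    day100 = dd,
    `locationNorway:day100` = if (interaction) loc * dd else NULL,
    sexmale = as.numeric(records$sex == "male"),
    sexunknown = as.numeric(records$sex == "unknown"),
    pregnant = as.numeric(records$pregnant),
    lactating = as.numeric(records$lactating),
    immature = as.numeric(records$immature)
  )
  cols <- Filter(Negate(is.null), cols)
  # drop non-intercept terms supported by < 2 whales
  keep <- vapply(names(cols), function(nm) {
    nm == "(Intercept)" || nm == "day100" || sum(cols[[nm]] != 0) >= 2
  }, logical(1))
  if (any(!keep)) {
    warning("covariate(s) fixed at 0 (fewer than 2 whales): ",
            paste(names(cols)[!keep], collapse = ", "))
  }
  X <- do.call(cbind, cols[keep])
  has_t <- !is.na(records$tbd_mean)
  has_l <- !is.na(records$lssai)
  has_lssai <- any(has_l)
  if (!has_lssai) {
    warning("no LSSAI observations: link parameters (alpha, gamma, sigma_L) dropped")
  }
  has_tbd <- any(has_t)
  if (!has_tbd) {
    warning("no TBD observations: uTBD is informed by the LSSAI channel only")
  }
  ucenter <- 1037
  dat <- list(n = n, P = ncol(X), X = X,
              b0_mu = b0_prior[1], b0_tau = 1 / b0_prior[2]^2,
              k_prior_tau = 1 / k_scale^2)
  if (has_tbd) {
    dat <- c(dat, list(nt = sum(has_t), wt = which(has_t),
                       tbd = records$tbd_mean[has_t],
                       tsd = records$tbd_sd[has_t]))
  }
  if (has_lssai) {
    dat <- c(dat, list(nl = sum(has_l), wl = which(has_l),
                       lss = records$lssai[has_l], ucenter = ucenter,
                       sigL_prior_tau = 1 / sigL_scale^2))
  }
  inits_extra <- list(u = rep(1037, n), kshape = min(1e4, k_scale))
  jm <- rjags::jags.model(textConnection(.utbdModelString(has_lssai, has_tbd)),
                          data = dat, inits = .jagsInits(mcmc, inits_extra),
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = quiet)
  burn <- round(mcmc$iterations * mcmc$burnin_frac)
  stats::update(jm, burn, progress.bar = "none")
  monitors <- c("beta", "kshape", "u",
                if (has_lssai) c("alpha_c", "gam", "sigL"))
  draws <- rjags::coda.samples(jm, monitors, n.iter = mcmc$iterations - burn,
                               thin = mcmc$thin, progress.bar = "none")
  m <- as.matrix(draws)
  vn <- colnames(m)
  beta_idx <- .orderedCols(vn, "beta")
  beta_m <- m[, beta_idx, drop = FALSE]
  colnames(beta_m) <- colnames(X)
  u_idx <- .orderedCols(vn, "u")
  u_m <- m[, u_idx, drop = FALSE]
  # convergence on the structural parameters only (latent u are many)
  core <- setdiff(vn, vn[u_idx])
  rhat <- .rhat(draws[, core, drop = FALSE])
  ess <- coda::effectiveSize(draws[, core, drop = FALSE])
  summaries <- tibble::tibble(
    parameter = c(colnames(X), setdiff(core, vn[beta_idx])),
    mean = unname(c(colMeans(beta_m),
                    colMeans(m[, setdiff(core, vn[beta_idx]), drop = FALSE]))),
    sd = unname(c(apply(beta_m, 2, stats::sd),
                  apply(m[, setdiff(core, vn[beta_idx]), drop = FALSE], 2,
                        stats::sd))),
    rhat = as.numeric(rhat[c(vn[beta_idx], setdiff(core, vn[beta_idx]))]),
    ess = as.numeric(ess[c(vn[beta_idx], setdiff(core, vn[beta_idx]))])
  )
  converged <- all(is.na(summaries$rhat) | summaries$rhat < mcmc$rhat_threshold)
  if (!converged) {
    warning("fit flagged non-converged: max R-hat = ",
            round(max(summaries$rhat, na.rm = TRUE), 3))
  }
  # response-scale effects at the reference whale
  b0 <- beta_m[, "(Intercept)"]
  mu_ref <- exp(b0)
  eff_terms <- setdiff(colnames(X), "(Intercept)")
  effects <- do.call(rbind, lapply(eff_terms, function(nm) {
    contr <- exp(b0 + beta_m[, nm]) - mu_ref
    tibble::tibble(effect = nm, mean = mean(contr), sd = stats::sd(contr),
                   ci_lo = unname(stats::quantile(contr, 0.025)),
                   ci_hi = unname(stats::quantile(contr, 0.975)))
  }))
  link <- NULL
  if (has_lssai) {
    alpha <- m[, "alpha_c"] - ucenter * m[, "gam"]
    link <- tibble::tibble(
      parameter = c("alpha", "gamma", "sigma_L"),
      mean = c(mean(alpha), mean(m[, "gam"]), mean(m[, "sigL"])),
      sd = c(stats::sd(alpha), stats::sd(m[, "gam"]), stats::sd(m[, "sigL"])),
      ci_lo = unname(c(stats::quantile(alpha, 0.025),
                       stats::quantile(m[, "gam"], 0.025),
                       stats::quantile(m[, "sigL"], 0.025))),
      ci_hi = unname(c(stats::quantile(alpha, 0.975),
                       stats::quantile(m[, "gam"], 0.975),
                       stats::quantile(m[, "sigL"], 0.975))))
  }
  per_whale <- tibble::tibble(
    whale_id = records$whale_id,
    utbd_mean = unname(colMeans(u_m)),
    utbd_sd = unname(apply(u_m, 2, stats::sd)),
    ci_lo = unname(apply(u_m, 2, stats::quantile, 0.025)),
    ci_hi = unname(apply(u_m, 2, stats::quantile, 0.975)),
    has_tbd = has_t, has_lssai = has_l
  )
  structure(list(effects = effects, summaries = summaries, link = link,
                 whales = per_whale, converged = converged,
                 records = records, day0 = day0, ucenter = ucenter,
                 design = colnames(X), draws = draws,
                 u_draws = u_m, beta_draws = beta_m,
                 link_draws = if (has_lssai)
                   m[, c("alpha_c", "gam", "sigL"), drop = FALSE] else NULL),
            class = "utbd_fit")
}

#' @export
print.utbd_fit <- function(x, ...) {
  cat("<utbd_fit>", nrow(x$whales), "whales (",
      sum(x$whales$has_tbd), "TBD,", sum(x$whales$has_lssai), "LSSAI );",
      if (!x$converged) "[NOT CONVERGED]" else "converged", "\n")
  cat("Response-scale effects (kg m^-3) at reference covariates:\n")
  print(x$effects)
  invisible(x)
}

#' Posterior prediction of a missing channel
#'
#' For a whale in the fitted model, returns the posterior predictive of
#' the requested channel: TBD prediction is the posterior of that
#' whale's latent uTBD; LSSAI prediction propagates uTBD through the
#' estimated link plus observation noise.
#'
#' @param fit a [fitUtbd()] result.
#' @param whale_id whale identifier present in the fit.
#' @param channel "tbd" or "lssai".
#' @return list: `mean`, `ci` (2.5/97.5 predictive interval), `draws`.
#' @export
predictMissing <- function(fit, whale_id, channel = c("tbd", "lssai")) {
  stopifnot(inherits(fit, "utbd_fit"))
  channel <- match.arg(channel)
  j <- match(whale_id, fit$whales$whale_id)
  if (is.na(j)) stop("whale '", whale_id, "' not in the fitted records")
  u <- fit$u_draws[, j]
  if (channel == "tbd") {
    draws <- u
  } else {
    if (is.null(fit$link_draws)) {
      stop("LSSAI link was not estimated (no LSSAI observations in the fit)")
    }
    mu <- fit$link_draws[, "alpha_c"] +
      fit$link_draws[, "gam"] * (u - fit$ucenter)
    draws <- stats::rnorm(length(mu), mu, fit$link_draws[, "sigL"])
  }
  list(mean = mean(draws),
       ci = unname(stats::quantile(draws, c(0.025, 0.975))),
       draws = draws)
}

#' Pearson correlation between the two body-condition channels
#'
#' Product-moment correlation between per-whale tag-derived tissue
#' density and LSSAI over whales carrying both observations, with the
#' two-sided test p-value.
#'
#' @param records tibble with `tbd_mean` and `lssai` columns.
#' @return list: `r`, `p`, `n` (complete pairs), and the `cor.test`
#'   object as `test`.
#' @export
correlateChannels <- function(records) {
  ok <- !is.na(records$tbd_mean) & !is.na(records$lssai)
  if (sum(ok) < 3) stop("need at least 3 complete (TBD, LSSAI) pairs")
  ct <- stats::cor.test(records$tbd_mean[ok], records$lssai[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), test = ct)
}
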