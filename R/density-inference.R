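#' Parameter-sharing structure for the glide-model fit
#'
#' The unknowns of the glide model can be individual-specific or shared
#' ('global') across whales; the diving air volume can additionally vary
#' between dives (with a common hierarchical mean). The acceleration
#' error is either a single estimated sd or built from each glide's
#' regression standard error (plus an estimated excess sd, which guards
#' the noiseless limit).
#'
#' @param tissue_density_scope "individual" or "global".
#' @param drag_scope "individual" or "global".
#' @param air_scope "per-dive" or "global".
#' @param error_model "global_sigma" or "per_glide_se".
#' @return list of class `model_structure`.
#' @export
modelStructure <- function(tissue_density_scope = c("individual", "global"),
                           drag_scope = c("global", "individual"),
                           air_scope = c("global", "per-dive"),
                           error_model = c("global_sigma", "per_glide_se")) {
  structure(list(tissue_density_scope = match.arg(tissue_density_scope),
                 drag_scope = match.arg(drag_scope),
                 air_scope = match.arg(air_scope),
                 error_model = match.arg(error_model)),
            class = "model_structure")
}

#' Priors for the glide-model fit
#'
#' Weakly informative defaults: tissue density uniform on 800--1200
#' kg m^-3 (brackets all reported whale tissue densities), drag from
#' [dragPriorDefault()], air volume uniform on 0--200 ml kg^-1, and a
#' half-normal error scale.
#'
#' @param rho_range uniform prior range for tissue density, kg m^-3.
#' @param drag prior list from [dragPriorDefault()].
#' @param vair_max upper bound of the uniform air-volume prior, m^3 kg^-1.
#' @param sigma_scale half-normal scale of the acceleration error sd,
#'   m s^-2.
#' @return list of class `hydro_priors`.
#' @export
hydroPriors <- function(rho_range = c(800, 1200), drag = dragPriorDefault(),
                        vair_max = 2e-4, sigma_scale = 0.1) {
  stopifnot(rho_range[1] < rho_range[2], vair_max > 0, sigma_scale > 0)
  structure(list(rho_range = rho_range, drag = drag, vair_max = vair_max,
                 sigma_scale = sigma_scale), class = "hydro_priors")
}

#' MCMC settings
#'
#' @param chains number of chains.
#' @param iterations total iterations per chain (burn-in included).
#' @param burnin_frac fraction discarded as burn-in.
#' @param thin thinning interval.
#' @param adapt adaptation steps.
#' @param seed integer seed; chain RNGs are seeded deterministically from
#'   it, so identical settings give identical draws.
#' @param rhat_threshold convergence threshold on the potential scale
#'   reduction factor.
#' @return list of class `mcmc_config`.
#' @export
mcmcConfig <- function(chains = 3, iterations = 20000, burnin_frac = 0.5,
                       thin = 5, adapt = 500, seed = 1,
                       rhat_threshold = 1.05) {
  stopifnot(chains >= 1, iterations >= 100, burnin_frac > 0, burnin_frac < 1)
  structure(list(chains = chains, iterations = iterations,
                 burnin_frac = burnin_frac, thin = thin, adapt = adapt,
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

.jagsInits <- function(mcmc, extra = NULL) {
  lapply(seq_len(mcmc$chains), function(ch) {
    c(list(.RNG.name = "base::Wichmann-Hill",
           .RNG.seed = mcmc$seed * 1000L + ch), extra)
  })
}

# Build the JAGS model string for a given structure.
# Scaled parameterization: drag in 1e-6 m^2 kg^-1, vair in 1e-6 m^3 kg^-1
# (= ml kg^-1) for sampler conditioning.
.hydroModelString <- function(structure, priors) {
  rho_decl <- if (structure$tissue_density_scope == "individual") {
    "for (w in 1:W) { rho0[w] ~ dunif(rho_lo, rho_hi) }"
  } else {
    "rho0g ~ dunif(rho_lo, rho_hi)\n  for (w in 1:W) { rho0[w] <- rho0g }"
  }
  drag_decl <- if (structure$drag_scope == "individual") {
    "for (w in 1:W) { drag_u[w] ~ dnorm(drag_mu, drag_tau) T(0,) }"
  } else {
    paste0("drag_ug ~ dnorm(drag_mu, drag_tau) T(0,)\n",
           "  for (w in 1:W) { drag_u[w] <- drag_ug }")
  }
  air_decl <- if (structure$air_scope == "per-dive") {
    paste0("vair_mu ~ dunif(0, vair_hi)\n",
           "  vair_sd ~ dnorm(0, 0.01) T(0,)\n",
           "  vair_tau <- 1/(vair_sd*vair_sd)\n",
           "  for (k in 1:K) { vair_u[k] ~ dnorm(vair_mu, vair_tau) T(0,) }")
  } else {
    paste0("vair_mu ~ dunif(0, vair_hi)\n",
           "  for (k in 1:K) { vair_u[k] <- vair_mu }")
  }
  tau_expr <- if (structure$error_model == "per_glide_se") {
    "tau[i] <- 1/(se[i]*se[i] + sigma*sigma)"
  } else {
    "tau[i] <- 1/(sigma*sigma)"
  }
  paste0("model {\n",
         "  for (i in 1:N) {\n",
         "    pr[i] <- 1 + 0.1*d[i]\n",
         "    rhod[i] <- rho0[w[i]] / (1 - r*pr[i]*patm)\n",
         "    mu[i] <- -0.5*drag_u[w[i]]*1e-6*rsw[i]*v[i]*v[i] +\n",
         "             (rsw[i]/rhod[i] - 1)*g*sin(p[i]) +\n",
         "             vair_u[k[i]]*1e-6*g*sin(p[i])*(rsw[i] - rair*pr[i])/pr[i]\n",
         "    ", tau_expr, "\n",
         "    a[i] ~ dnorm(mu[i], tau[i])\n",
         "  }\n",
         "  ", rho_decl, "\n",
         "  ", drag_decl, "\n",
         "  ", air_decl, "\n",
         "  sigma ~ dnorm(0, sigma_prior_tau) T(0,)\n",
         "}\n")
}

# deviance of the glide likelihood at one parameter setting (R-side, used
# for the classic Spiegelhalter DIC)
.hydroDeviance <- function(theta, dat, structure, constants) {
  rho0 <- theta$rho0[dat$w]
  drag <- theta$drag_u[dat$w] * 1e-6
  vair <- theta$vair_u[dat$k] * 1e-6
  pr <- 1 + 0.1 * dat$d
  rhod <- rho0 / (1 - dat$r * pr * dat$patm)
  mu <- -0.5 * drag * dat$rsw * dat$v^2 + (dat$rsw / rhod - 1) * dat$g * sin(dat$p) +
    vair * dat$g * sin(dat$p) * (dat$rsw - dat$rair * pr) / pr
  sd_i <- if (structure$error_model == "per_glide_se") {
    sqrt(dat$se^2 + theta$sigma^2)
  } else rep(theta$sigma, dat$N)
  -2 * sum(stats::dnorm(dat$a, mu, sd_i, log = TRUE))
}

#' Fit the hydrodynamic glide model by MCMC
#'
#' Estimates tissue body density, the combined drag term and the diving
#' air volume per unit mass from glide observations, by Gibbs sampling of
#' the glide-acceleration likelihood (observed along-path acceleration
#' normal about the forward-model prediction). Parameter sharing across
#' whales/dives follows `structure`. Reported per parameter: posterior
#' mean, sd, 95% credible interval (2.5/97.5 percentiles), effective
#' sample size and the potential scale reduction factor (R-hat); the fit
#' is flagged non-converged if any R-hat exceeds the threshold. The
#' deviance information criterion uses the classic effective-parameter
#' count, mean deviance minus deviance at the posterior means.
#'
#' @param glides tibble of glide observations ([segmentGlides()] schema).
#' @param structure a [modelStructure()].
#' @param priors a [hydroPriors()].
#' @param mcmc an [mcmcConfig()].
#' @param constants a [physicalConstants()].
#' @param compressibility fixed tissue compressibility, Pa^-1.
#' @param quiet suppress JAGS progress output.
#' @return object of class `hydro_fit`: `summaries` (per-parameter
#'   tibble), `whales` (per-whale tissue density mean/sd/CI), `dic`,
#'   `converged`, `structure`, and the posterior draws (coda
#'   `mcmc.list`).
#' @export
fitHydroModel <- function(glides, structure = modelStructure("individual"),
                          priors = hydroPriors(), mcmc = mcmcConfig(),
                          constants = physicalConstants(),
                          compressibility = 0.38e-9, quiet = TRUE) {
  stopifnot(nrow(glides) > 0, inherits(structure, "model_structure"))
  whales <- sort(unique(glides$whale_id))
  wi <- match(glides$whale_id, whales)
  dive_key <- if (structure$air_scope == "per-dive") {
    paste(glides$whale_id, glides$dive_id, sep = "//")
  } else rep("all", nrow(glides))
  dives <- unique(dive_key)
  ki <- match(dive_key, dives)
  if (all(abs(glides$pitch) < 10 * pi / 180)) {
    warning("all glides near-horizontal pitch: tissue density is weakly ",
            "identifiable (buoyancy terms vanish as sin(pitch) -> 0)")
  }
  dat <- list(N = nrow(glides), W = length(whales), K = length(dives),
              a = glides$accel, d = glides$depth, p = glides$pitch,
              v = glides$speed, rsw = glides$rho_sw,
              w = wi, k = ki,
              g = constants$g, rair = constants$rho_air,
              patm = constants$atmosphere_pa, r = compressibility,
              rho_lo = priors$rho_range[1], rho_hi = priors$rho_range[2],
              drag_mu = priors$drag$mean * 1e6,
              drag_tau = 1 / (priors$drag$sd * 1e6)^2,
              vair_hi = priors$vair_max * 1e6,
              sigma_prior_tau = 1 / priors$sigma_scale^2)
  if (structure$error_model == "per_glide_se") dat$se <- glides$accel_se
  mstr <- .hydroModelString(structure, priors)
  jm <- rjags::jags.model(textConnection(mstr), data = dat,
                          inits = .jagsInits(mcmc),
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = quiet)
  burn <- round(mcmc$iterations * mcmc$burnin_frac)
  stats::update(jm, burn, progress.bar = "none")
  monitors <- c("rho0", "drag_u", "vair_u", "sigma")
  draws <- rjags::coda.samples(jm, monitors, n.iter = mcmc$iterations - burn,
                               thin = mcmc$thin, progress.bar = "none")
  .summarizeHydro(draws, dat, structure, mcmc, whales, dives, glides)
}

.rhat <- function(draws) {
  if (coda::nchain(draws) < 2) return(rep(NA_real_, coda::nvar(draws)))
  gd <- try(coda::gelman.diag(draws, multivariate = FALSE, autoburnin = FALSE),
            silent = TRUE)
  if (inherits(gd, "try-error")) return(rep(NA_real_, coda::nvar(draws)))
  psrf <- gd$psrf[, 1]
  # a degenerate (point-mass) posterior has no mixing to diagnose
  sds <- apply(as.matrix(draws), 2, stats::sd)
  mns <- abs(colMeans(as.matrix(draws)))
  psrf[sds < 1e-9 * pmax(mns, 1)] <- NA_real_
  names(psrf) <- coda::varnames(draws)
  psrf
}

# columns of `base` or `base[i]` in natural index order
.orderedCols <- function(vn, base) {
  hit <- grep(paste0("^", base, "(\\[|$)"), vn)
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\]$", "\\1", vn[hit])))
  idx[is.na(idx)] <- 1L
  hit[order(idx)]
}

.summarizeHydro <- function(draws, dat, structure, mcmc, whales, dives, glides) {
  m <- as.matrix(draws)
  vn <- colnames(m)
  rhat <- .rhat(draws)
  ess <- coda::effectiveSize(draws)
  summaries <- tibble::tibble(
    parameter = vn,
    mean = unname(colMeans(m)),
    sd = unname(apply(m, 2, stats::sd)),
    ci_lo = unname(apply(m, 2, stats::quantile, 0.025)),
    ci_hi = unname(apply(m, 2, stats::quantile, 0.975)),
    ess = as.numeric(ess[vn]),
    rhat = as.numeric(rhat[vn])
  )
  converged <- all(is.na(summaries$rhat) |
                     summaries$rhat < mcmc$rhat_threshold)
  if (!converged) {
    warning("fit flagged non-converged: max R-hat = ",
            round(max(summaries$rhat, na.rm = TRUE), 3))
  }
  rho_cols <- .orderedCols(vn, "rho0")
  rho_m <- m[, rho_cols, drop = FALSE]
  n_gl <- as.integer(table(factor(glides$whale_id, levels = whales)))
  per_whale <- tibble::tibble(
    whale_id = whales,
    rho_tissue_mean = unname(colMeans(rho_m))[seq_along(whales)],
    rho_tissue_sd = unname(apply(rho_m, 2, stats::sd))[seq_along(whales)],
    ci_lo = unname(apply(rho_m, 2, stats::quantile, 0.025))[seq_along(whales)],
    ci_hi = unname(apply(rho_m, 2, stats::quantile, 0.975))[seq_along(whales)],
    n_glides = n_gl
  )
  # classic DIC from a subsample of the kept draws
  take <- seq(1, nrow(m), length.out = min(1000, nrow(m)))
  rho_idx <- .orderedCols(vn, "rho0")
  drag_idx <- .orderedCols(vn, "drag_u")
  vair_idx <- .orderedCols(vn, "vair_u")
  thetaOf <- function(row) {
    list(rho0 = rep_len(unname(row[rho_idx]), length(whales)),
         drag_u = rep_len(unname(row[drag_idx]), length(whales)),
         vair_u = rep_len(unname(row[vair_idx]), length(dives)),
         sigma = unname(row["sigma"]))
  }
  devs <- vapply(take, function(i) {
    .hydroDeviance(thetaOf(m[i, ]), dat, structure,
                   constants = NULL)
  }, numeric(1))
  dev_at_mean <- .hydroDeviance(thetaOf(colMeans(m)), dat, structure, NULL)
  p_d <- mean(devs) - dev_at_mean
  dic <- mean(devs) + p_d
  structure(list(summaries = summaries, whales = per_whale, dic = dic,
                 p_d = p_d, converged = converged, structure = structure,
                 draws = draws, whale_ids = whales, dive_ids = dives),
            class = "hydro_fit")
}

#' @export
print.hydro_fit <- function(x, ...) {
  cat("<hydro_fit>", x$structure$tissue_density_scope, "tissue density,",
      x$structure$drag_scope, "drag,", x$structure$air_scope, "air;",
      nrow(x$whales), "whale(s); DIC =", round(x$dic, 1),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(x$whales)
  invisible(x)
}

#' Select the parameter structure by DIC
#'
#' Fits every candidate structure and returns the one with the lowest
#' deviance information criterion; non-converged candidates are excluded
#' (with a warning), and DIC ties within `tie_tol` are broken toward the
#' structure with fewer distinct parameters.
#'
#' @param glides glide observations.
#' @param candidates list of [modelStructure()] objects (>= 1; a single
#'   candidate is returned unchanged after fitting).
#' @param priors,mcmc,constants,compressibility passed to [fitHydroModel()].
#' @param tie_tol DIC difference regarded as a tie.
#' @return the winning `hydro_fit`, with a `dic_table` attribute
#'   (tibble: structure label, DIC, effective parameters, converged).
#' @export
selectStructure <- function(glides, candidates, priors = hydroPriors(),
                            mcmc = mcmcConfig(),
                            constants = physicalConstants(),
                            compressibility = 0.38e-9, tie_tol = 2) {
  stopifnot(length(candidates) >= 1)
  fits <- lapply(candidates, function(st) {
    fitHydroModel(glides, st, priors, mcmc, constants, compressibility)
  })
  n_w <- length(unique(glides$whale_id))
  n_par <- vapply(fits, function(f) {
    (if (f$structure$tissue_density_scope == "individual") n_w else 1) +
      (if (f$structure$drag_scope == "individual") n_w else 1) +
      (if (f$structure$air_scope == "per-dive") length(f$dive_ids) + 2 else 1) + 1
  }, numeric(1))
  lab <- vapply(fits, function(f) {
    paste(f$structure$tissue_density_scope, f$structure$drag_scope,
          f$structure$air_scope, sep = "/")
  }, character(1))
  tab <- tibble::tibble(structure = lab,
                        dic = vapply(fits, `[[`, numeric(1), "dic"),
                        p_d = vapply(fits, `[[`, numeric(1), "p_d"),
                        n_parameters = n_par,
                        converged = vapply(fits, `[[`, logical(1), "converged"))
  ok <- which(tab$converged)
  if (!length(ok)) {
    warning("no candidate converged; returning the minimum-DIC fit anyway")
    ok <- seq_along(fits)
  } else if (length(ok) < length(fits)) {
    warning(sum(!tab$converged), " non-converged candidate(s) excluded ",
            "from selection")
  }
  best_dic <- min(tab$dic[ok])
  tied <- ok[tab$dic[ok] <= best_dic + tie_tol]
  win <- tied[which.min(tab$n_parameters[tied])]
  out <- fits[[win]]
  attr(out, "dic_table") <- tab
  out
}

#' Brute-force least-squares oracle on a parameter grid
#'
#' Independent verification of the MCMC fit: evaluates the sum of squared
#' residuals of the glide-acceleration forward model over a grid of
#' (tissue density, drag term) with the air volume held fixed, and
#' returns the minimizing grid point. With noiseless data whose truth
#' lies on the grid this recovers the truth exactly (zero residual).
#'
#' @param glides glide observations (single parameter set assumed, i.e.
#'   pooled; typically one whale).
#' @param rho_grid tissue-density grid, kg m^-3.
#' @param drag_grid drag-term grid, m^2 kg^-1.
#' @param air_per_mass fixed air volume per mass, m^3 kg^-1.
#' @param constants a [physicalConstants()].
#' @param compressibility Pa^-1.
#' @return list: `rho_tissue`, `drag_term`, `ssr` at the optimum, and the
#'   full `ssr` matrix (rho x drag).
#' @export
gridOracle <- function(glides, rho_grid, drag_grid, air_per_mass,
                       constants = physicalConstants(),
                       compressibility = 0.38e-9) {
  stopifnot(nrow(glides) > 0, length(rho_grid) > 0, length(drag_grid) > 0)
  pr <- 1 + 0.1 * glides$depth
  sinp <- sin(glides$pitch)
  air <- air_per_mass * constants$g * sinp *
    (glides$rho_sw - constants$rho_air * pr) / pr
  rhod <- vapply(seq_along(rho_grid), function(i) {
    tissueDensityAtDepth(rho_grid[i], compressibility, glides$depth,
                         constants$atmosphere_pa)
  }, numeric(nrow(glides)))
  rhod <- matrix(rhod, nrow = nrow(glides))
  tissue <- t((glides$rho_sw / rhod - 1) * constants$g * sinp)    # rho x N
  drag_unit <- -0.5 * glides$rho_sw * glides$speed^2              # N
  ssr <- matrix(NA_real_, length(rho_grid), length(drag_grid))
  for (j in seq_along(drag_grid)) {
    mu <- tissue + rep(1, length(rho_grid)) %o% (drag_grid[j] * drag_unit + air)
    res <- sweep(mu, 2, glides$accel)
    ssr[, j] <- rowSums(res^2)
  }
  ij <- arrayInd(which.min(ssr), dim(ssr))
  list(rho_tissue = rho_grid[ij[1]], drag_term = drag_grid[ij[2]],
       ssr = min(ssr), ssr_matrix = ssr)
}
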