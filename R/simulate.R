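#' Simulate glide observations from the forward model
#'
#' Draws glide conditions (depth, pitch, speed) for one or more whales and
#' computes the along-path acceleration from the hydrodynamic forward
#' model plus Gaussian noise. Pitch magnitudes are centred on 49.1 degrees
#' with a 13.7-degree spread (the distribution observed in humpback glide
#' data), with random sign (descent/ascent); depths are uniform on
#' 10--120 m (shallow feeding dives) and speeds lognormal around
#' 1.5 m s^-1.
#'
#' @param params a [hydroParams()] or a named list of one per whale.
#' @param n_glides glides per whale, >= 1.
#' @param noise_sd acceleration noise sd, m s^-2, >= 0.
#' @param ctd optional [ctdProfile()]; default a Canada-like profile from
#'   [simulateCtd()].
#' @param depth_range uniform depth sampling range, metres.
#' @param pitch_mean_deg,pitch_sd_deg pitch-magnitude distribution, degrees.
#' @param speed_meanlog,speed_sdlog lognormal speed parameters.
#' @param dives_per_whale glides are assigned round-robin to this many
#'   dives (air volume can vary by dive in the fitted model).
#' @param seed RNG seed (integer) for reproducibility.
#' @param constants a [physicalConstants()].
#' @return tibble of glide observations (schema of [segmentGlides()]);
#'   attribute `truth` stores the generating parameters and noise sd.
#' @export
simulateGlides <- function(params, n_glides = 200, noise_sd = 0.01,
                           ctd = NULL, depth_range = c(10, 120),
                           pitch_mean_deg = 49.1, pitch_sd_deg = 13.7,
                           speed_meanlog = log(1.5), speed_sdlog = 0.2,
                           dives_per_whale = 4, seed = NULL,
                           constants = physicalConstants()) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "hydro_params")) params <- list(whale1 = params)
  stopifnot(n_glides >= 1, noise_sd >= 0)
  if (is.null(ctd)) ctd <- simulateCtd(1023.3, 0.02, 300)
  out <- lapply(names(params), function(id) {
    pp <- params[[id]]
    d <- stats::runif(n_glides, depth_range[1], depth_range[2])
    p_mag <- abs(stats::rnorm(n_glides, pitch_mean_deg, pitch_sd_deg))
    p <- sample(c(-1, 1), n_glides, replace = TRUE) *
      pmin(p_mag, 89) * pi / 180
    v <- stats::rlnorm(n_glides, speed_meanlog, speed_sdlog)
    rsw <- ctdDensityAt(ctd, d)
    a_true <- glideAcceleration(pp, d, p, v, rsw, constants)
    tibble::tibble(
      whale_id = id,
      dive_id = rep_len(seq_len(dives_per_whale), n_glides),
      start_time = seq(0, by = 60, length.out = n_glides),
      duration = 5,
      depth = d, pitch = p, speed = v, rho_sw = rsw,
      accel = a_true + stats::rnorm(n_glides, 0, noise_sd),
      accel_se = noise_sd
    )
  })
  res <- do.call(rbind, out)
  attr(res, "truth") <- list(params = params, noise_sd = noise_sd)
  res
}

#' Simulate a tag time series with planted glide windows
#'
#' Builds a kinematically consistent record of V-shaped dives: pitch and
#' speed profiles are specified, depth is the integral of
#' \eqn{-v \sin p} (positive down), and the dorsoventral channel carries a
#' stroke oscillation at `stroke_freq` plus sensor noise, silenced inside
#' the planted glide windows. Each dive can plant one glide on the descent
#' and one on the ascent.
#'
#' @param n_dives number of V-shaped dives.
#' @param fs sampling rate, Hz (>= 5).
#' @param dive_depth target dive depth, metres.
#' @param pitch_deg dive pitch magnitude, degrees.
#' @param speed swim speed during dive phases, m s^-1.
#' @param surface_s surface interval between dives, seconds.
#' @param stroke_freq fluke-stroke frequency, Hz.
#' @param stroke_amp stroke amplitude on the dorsoventral channel, m s^-2.
#' @param noise_sd sensor noise sd, m s^-2.
#' @param glide_s planted glide duration, seconds; scalar or vector
#'   recycled over descents/ascents. Use 0 to plant none.
#' @param whale_id identifier.
#' @param seed RNG seed.
#' @return list with `series` (a [tagSeries()]), `windows` (tibble of
#'   planted stroke-free windows: sample indices and times),
#'   `speed_true` (the planted per-sample swim speed, m s^-1; the series
#'   itself carries no propeller channel) and the generating parameters.
#' @export
simulateTimeseries <- function(n_dives = 3, fs = 5, dive_depth = 80,
                               pitch_deg = 50, speed = 1.6, surface_s = 40,
                               stroke_freq = 0.5, stroke_amp = 1.0,
                               noise_sd = 0.02, glide_s = 12,
                               whale_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(fs >= 5, n_dives >= 1)
  p0 <- pitch_deg * pi / 180
  phase_s <- dive_depth / (speed * sin(p0))   # descent (= ascent) duration
  pitch <- c(); spd <- c(); dive_id <- c()
  glide <- c()                                 # logical: stroke-free sample
  n_ph <- round(phase_s * fs)
  n_su <- round(surface_s * fs)
  glide_s <- rep_len(glide_s, 2 * n_dives)
  gi <- 1
  for (k in seq_len(n_dives)) {
    for (phase in c(-1, 1)) {                  # descent then ascent
      g_n <- round(glide_s[gi] * fs); gi <- gi + 1
      ph_glide <- rep(FALSE, n_ph)
      if (g_n > 0 && g_n < n_ph - 2) {
        g0 <- floor((n_ph - g_n) / 2)          # centre the glide in the phase
        ph_glide[(g0 + 1):(g0 + g_n)] <- TRUE
      }
      pitch <- c(pitch, rep(phase * p0, n_ph))   # -p0 descending, +p0 ascending
      spd <- c(spd, rep(speed, n_ph))
      glide <- c(glide, ph_glide)
      dive_id <- c(dive_id, rep(k, n_ph))
    }
    pitch <- c(pitch, rep(0, n_su))
    spd <- c(spd, rep(0, n_su))
    glide <- c(glide, rep(TRUE, n_su))         # no stroking at the surface
    dive_id <- c(dive_id, rep(k, n_su))
  }
  n <- length(pitch)
  time <- seq(0, by = 1 / fs, length.out = n)
  depth_rate <- -spd * sin(pitch)              # depth positive down
  depth <- pmax(cumsum(depth_rate) / fs, 0)
  stroke <- stroke_amp * sin(2 * pi * stroke_freq * time)
  stroke[glide] <- 0
  accel_dv <- stroke + stats::rnorm(n, 0, noise_sd)
  series <- tagSeries(time, depth, accel_dv, pitch = pitch,
                      whale_id = whale_id, dive_id = dive_id)
  # planted windows: maximal stroke-free runs (excluding the surface rest,
  # which is stroke-free too and reported as part of the truth)
  runs <- .runs(glide)
  windows <- tibble::tibble(start = as.integer(runs[, 1]),
                            end = as.integer(runs[, 2]),
                            start_time = time[runs[, 1]],
                            end_time = time[runs[, 2]])
  windows$duration <- windows$end_time - windows$start_time
  list(series = series, windows = windows,
       speed_true = spd,
       params = list(fs = fs, stroke_freq = stroke_freq,
                     stroke_amp = stroke_amp, noise_sd = noise_sd,
                     pitch = p0, speed = speed))
}

# humpback-like half-width template at the 21 section boundaries
# (fraction of total length; broad mid-body, tapering to rostrum and flukes)
.outlineTemplate <- c(0.020, 0.070, 0.105, 0.135, 0.155, 0.170, 0.180,
                      0.187, 0.190, 0.189, 0.184, 0.176, 0.165, 0.150,
                      0.133, 0.114, 0.094, 0.073, 0.052, 0.032, 0.012)

#' Simulate a whale outline with a target LSSAI
#'
#' Starts from a humpback-like width template, jitters the mid-body
#' boundary widths (the sections that vary most across whales), rescales
#' so the trapezoid-sum LSSAI equals the target exactly, then applies a
#' single multiplicative measurement error so the realized LSSAI is
#' `target` up to sd `noise`.
#'
#' @param target target LSSAI, in [0.05, 0.12].
#' @param total_length rendered body length, pixels.
#' @param noise sd of the realized LSSAI about the target (0 = exact).
#' @param shape_jitter relative sd of per-boundary width jitter
#'   (concentrated mid-body).
#' @param score optional [frameScore()] to attach.
#' @param whale_id,frame_id identifiers.
#' @param seed RNG seed.
#' @return a [whaleOutline()]; attribute `truth` stores the target.
#' @export
simulateOutline <- function(target, total_length = 2000, noise = 0,
                            shape_jitter = 0.03, score = NULL,
                            whale_id = NA_character_,
                            frame_id = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(target >= 0.05, target <= 0.12, noise >= 0)
  # jitter weights: peak over boundaries 7..17, zero at the extremities
  wgt <- exp(-((0:20 - 10) / 6)^2)
  w <- .outlineTemplate * (1 + stats::rnorm(21, 0, shape_jitter) * wgt)
  w <- pmax(w, 1e-4)
  base <- whaleOutline(total_length, w * total_length)
  scale <- target / lssai(base)
  if (noise > 0) scale <- scale * (1 + stats::rnorm(1, 0, noise / target))
  out <- whaleOutline(total_length, pmax(w * scale, 0) * total_length,
                      score = score, whale_id = whale_id, frame_id = frame_id)
  attr(out, "truth") <- list(target = target, noise = noise)
  out
}

#' Default truth coefficients for the population generator
#'
#' Log-scale regression coefficients calibrated so that the
#' response-scale contrasts at the reference whale (Canada, season start,
#' adult resting female) equal the stated effects in kg m^-3: pregnant
#' -3.5, lactating +6.0, Norway (early season) +5.3, season slope -2.7
#' per 100 days, with the Norway effect vanishing by Julian day 190
#' through the location-by-day interaction.
#'
#' @param mu_ref reference-whale uTBD at season start, kg m^-3.
#' @param day0 season-start Julian day (reference for the day axis).
#' @param effect_pregnant,effect_lactating,effect_norway_early,effect_day
#'   response-scale effects, kg m^-3 (day effect per 100 days).
#' @param effect_male response-scale male-vs-female contrast, kg m^-3.
#' @param norway_equal_day season day at which the location contrast
#'   crosses 0. The default (350) centres the crossing in the observed
#'   Norwegian late-season window (days 305--395), so the late-season
#'   location contrast is ~0 across that window while the early-season
#'   contrast at `day0` equals `effect_norway_early` — the published
#'   pattern (locations differ early, converge late).
#' @param shape Gamma shape of the latent uTBD (between-whale residual
#'   CV = 1/sqrt(shape)).
#' @param link_alpha_c,link_gamma,link_sigma LSSAI channel: centred
#'   intercept (LSSAI at uTBD = 1037), slope per kg m^-3, and error sd.
#' @return named list of truth parameters.
#' @export
populationTruthDefault <- function(mu_ref = 1038.7, day0 = 130,
                                   effect_pregnant = -3.5,
                                   effect_lactating = 6.0,
                                   effect_norway_early = 5.3,
                                   effect_day = -2.7,
                                   effect_male = -0.2,
                                   norway_equal_day = 350,
                                   shape = 6e4,
                                   link_alpha_c = 0.077,
                                   link_gamma = -8.8e-4,
                                   link_sigma = 0.004) {
  b <- function(delta) log(1 + delta / mu_ref)
  b_loc <- b(effect_norway_early)
  list(
    b0 = log(mu_ref), day0 = day0,
    b_loc = b_loc,
    b_day = b(effect_day),
    b_locday = -b_loc / ((norway_equal_day - day0) / 100),
    b_male = b(effect_male), b_sexunk = 0,
    b_pregnant = b(effect_pregnant),
    b_lactating = b(effect_lactating),
    b_immature = 0,
    shape = shape,
    link_alpha_c = link_alpha_c, link_gamma = link_gamma,
    link_sigma = link_sigma, link_center = 1037
  )
}

#' Simulate a whale population for the latent-density fusion model
#'
#' Generates covariates (location, feeding-season day, sex, reproductive
#' status), draws latent uTBD from the log-linear Gamma regression, and
#' produces the two observation channels: a tag-derived TBD observation
#' with its own known sd, and an LSSAI observation through the linear
#' link. Channels are then masked to the study-like pattern (default:
#' 59 of 93 whales with TBD, 55 with LSSAI, 21 with both).
#'
#' @param n number of whales.
#' @param truth coefficient list from [populationTruthDefault()].
#' @param p_norway proportion of whales in Norway.
#' @param n_tbd,n_lssai,n_both channel availability counts (must satisfy
#'   `n_tbd + n_lssai - n_both = n`).
#' @param tbd_sd_range per-whale TBD observation sd drawn uniformly from
#'   this range, kg m^-3.
#' @param seed RNG seed.
#' @return tibble of whale records:
#'   `whale_id, location, season_day, sex, pregnant, lactating, immature,
#'   tbd_mean, tbd_sd, lssai` (NA where a channel is masked); attribute
#'   `truth` stores the generating coefficients and per-whale latent uTBD.
#' @export
simulatePopulation <- function(n = 93, truth = populationTruthDefault(),
                               p_norway = 40 / 93,
                               n_tbd = 59, n_lssai = 55, n_both = 21,
                               tbd_sd_range = c(1, 5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, n_tbd + n_lssai - n_both == n,
            n_both <= min(n_tbd, n_lssai))
  loc <- stats::rbinom(n, 1, p_norway)                       # 1 = Norway
  # Canada: Jun-Sep; Norway: Svalbard May-Jun (early) or Tromso Nov-Jan
  # (late; Julian day continued past 365 across the new year)
  day <- ifelse(loc == 0, stats::runif(n, 150, 260),
                ifelse(stats::runif(n) < 0.4, stats::runif(n, 130, 180),
                       stats::runif(n, 305, 395)))
  sex <- sample(c("female", "male", "unknown"), n, TRUE, c(0.55, 0.3, 0.15))
  pregnant <- as.integer(sex == "female" & stats::runif(n) < 0.3)
  lactating <- as.integer(sex == "female" & pregnant == 0 & stats::runif(n) < 0.15)
  immature <- as.integer(stats::runif(n) < 0.1)
  dd <- (day - truth$day0) / 100
  lp <- truth$b0 + truth$b_loc * loc + truth$b_day * dd +
    truth$b_locday * loc * dd +
    truth$b_male * (sex == "male") + truth$b_sexunk * (sex == "unknown") +
    truth$b_pregnant * pregnant + truth$b_lactating * lactating +
    truth$b_immature * immature
  mu <- exp(lp)
  utbd <- stats::rgamma(n, shape = truth$shape, rate = truth$shape / mu)
  tbd_sd <- stats::runif(n, tbd_sd_range[1], tbd_sd_range[2])
  tbd <- stats::rnorm(n, utbd, tbd_sd)
  lss <- stats::rnorm(n, truth$link_alpha_c +
                        truth$link_gamma * (utbd - truth$link_center),
                      truth$link_sigma)
  idx <- sample(n)
  has_t <- rep(FALSE, n); has_l <- rep(FALSE, n)
  has_t[idx[seq_len(n_tbd)]] <- TRUE
  has_l[idx[seq(n_tbd - n_both + 1, n_tbd - n_both + n_lssai)]] <- TRUE
  rec <- tibble::tibble(
    whale_id = sprintf("W%03d", seq_len(n)),
    location = ifelse(loc == 1, "Norway", "Canada"),
    season_day = day,
    sex = sex, pregnant = pregnant, lactating = lactating,
    immature = immature,
    tbd_mean = ifelse(has_t, tbd, NA_real_),
    tbd_sd = ifelse(has_t, tbd_sd, NA_real_),
    lssai = ifelse(has_l, lss, NA_real_)
  )
  attr(rec, "truth") <- c(truth, list(utbd = utbd))
  rec
}

#' Simulate a CTD seawater-density profile
#'
#' Linear density increase with depth from a surface value, clamped to
#' the physically admissible range. Canada-like (1023.3 kg m^-3) and
#' Norway-like (1027.3 kg m^-3) surface densities are both representable.
#'
#' @param surface_density surface seawater density, kg m^-3.
#' @param gradient density increase per metre, kg m^-4.
#' @param max_depth profile extent, metres.
#' @param step depth-grid spacing, metres.
#' @return a [ctdProfile()].
#' @export
simulateCtd <- function(surface_density = 1025, gradient = 0.01,
                        max_depth = 200, step = 5) {
  stopifnot(gradient >= 0)
  d <- seq(0, max_depth, by = step)
  rho <- pmin(pmax(surface_density + gradient * d, 1000), 1035)
  ctdProfile(d, rho)
}
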