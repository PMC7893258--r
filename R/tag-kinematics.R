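#' Tag time series
#'
#' Container for a processed suction-cup tag record sampled at a uniform
#' rate of at least 1 Hz: depth from pressure, pitch from low-frequency
#' acceleration (or supplied directly), the high-frequency dorsoventral
#' acceleration channel used for fluke-stroke detection, and optionally a
#' propeller-derived swim speed.
#'
#' @param time sample times, seconds, strictly increasing and uniformly
#'   spaced (within 1e-6 of the median step).
#' @param depth depth, metres, positive down, >= 0.
#' @param accel_dv dorsoventral acceleration, m s^-2 (stroke channel).
#' @param pitch pitch, radians, positive = ascending, |pitch| <= pi/2.
#'   May be `NULL` if `surge_accel` is given (see
#'   [pitchFromAcceleration()]).
#' @param surge_accel longitudinal (surge-axis) acceleration, m s^-2,
#'   used to recover pitch when `pitch` is absent.
#' @param speed optional propeller swim speed, m s^-1.
#' @param whale_id identifier.
#' @param dive_id optional per-sample dive identifier.
#' @return list of class `tag_series`; element `fs` is the sampling rate (Hz).
#' @export
tagSeries <- function(time, depth, accel_dv, pitch = NULL, surge_accel = NULL,
                      speed = NULL, whale_id = "whale", dive_id = NULL) {
  n <- length(time)
  stopifnot(n > 1, length(depth) == n, length(accel_dv) == n)
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - stats::median(dt))) > 1e-6) {
    stop("time must be strictly increasing and uniformly sampled")
  }
  fs <- 1 / stats::median(dt)
  if (fs < 1) stop("sampling rate must be >= 1 Hz")
  stopifnot(all(depth >= -1e-9))
  if (!is.null(pitch)) {
    stopifnot(length(pitch) == n, all(abs(pitch) <= pi / 2 + 1e-9))
  }
  if (is.null(pitch) && is.null(surge_accel)) {
    stop("either pitch or surge_accel must be supplied")
  }
  if (!is.null(speed)) stopifnot(length(speed) == n)
  structure(list(time = time, depth = pmax(depth, 0), pitch = pitch,
                 surge_accel = surge_accel, accel_dv = accel_dv,
                 speed = speed, whale_id = whale_id,
                 dive_id = if (is.null(dive_id)) rep(1L, n) else dive_id,
                 fs = fs, n = n),
            class = "tag_series")
}

#' @export
print.tag_series <- function(x, ...) {
  cat("<tag_series>", x$whale_id, ":", x$n, "samples @", round(x$fs, 3), "Hz,",
      round(x$n / x$fs / 60, 1), "min; depth", round(min(x$depth), 1), "-",
      round(max(x$depth), 1), "m;",
      if (is.null(x$speed)) "no propeller speed" else "propeller speed", "\n")
  invisible(x)
}

#' CTD seawater-density profile
#'
#' @param depth depth grid, metres, strictly increasing.
#' @param density seawater density, kg m^-3, within [1000, 1035].
#' @return list of class `ctd_profile`.
#' @export
ctdProfile <- function(depth, density) {
  stopifnot(length(depth) == length(density), length(depth) >= 1,
            all(diff(depth) > 0) || length(depth) == 1,
            all(density >= 1000), all(density <= 1035))
  structure(list(depth = depth, density = density), class = "ctd_profile")
}

#' Seawater density at depth
#'
#' Linear interpolation in the CTD profile, constant extrapolation beyond
#' the profile ends.
#'
#' @param ctd a [ctdProfile()].
#' @param d depth(s), metres.
#' @return seawater density, kg m^-3.
#' @export
ctdDensityAt <- function(ctd, d) {
  stopifnot(inherits(ctd, "ctd_profile"))
  if (length(ctd$depth) == 1) return(rep(ctd$density, length(d)))
  stats::approx(ctd$depth, ctd$density, xout = d, rule = 2)$y
}

#' Dominant fluke-stroke frequency
#'
#' Spectral peak of the dorsoventral acceleration channel (smoothed
#' periodogram), restricted to frequencies above `min_freq` to avoid
#' locking onto postural drift.
#'
#' @param accel_dv dorsoventral acceleration, m s^-2.
#' @param fs sampling rate, Hz.
#' @param min_freq lower bound on the admissible stroke frequency, Hz.
#' @return frequency, Hz.
#' @export
dominantStrokeFrequency <- function(accel_dv, fs, min_freq = 0.1) {
  sp <- stats::spec.pgram(stats::ts(accel_dv, frequency = fs),
                          spans = c(7, 7), detrend = TRUE, plot = FALSE)
  keep <- sp$freq >= min_freq
  sp$freq[keep][which.max(sp$spec[keep])]
}

#' Pitch from the surge acceleration channel
#'
#' Low-pass filters the surge (longitudinal) accelerometer axis at a
#' fraction of the stroke frequency to isolate the static (gravitational)
#' component, then recovers pitch as arcsin(static surge / g).
#'
#' @param surge_accel surge-axis acceleration, m s^-2.
#' @param fs sampling rate, Hz.
#' @param stroke_freq dominant stroke frequency, Hz.
#' @param lowpass_factor cutoff as a fraction of `stroke_freq`; default 0.2.
#' @param g gravitational acceleration.
#' @return pitch, radians.
#' @export
pitchFromAcceleration <- function(surge_accel, fs, stroke_freq,
                                  lowpass_factor = 0.2, g = 9.8) {
  wc <- lowpass_factor * stroke_freq / (fs / 2)
  stopifnot(wc > 0, wc < 1)
  bf <- signal::butter(2, wc, type = "low")
  static <- signal::filtfilt(bf, surge_accel)
  asin(pmin(1, pmax(-1, static / g)))
}

#' Glide-detection configuration
#'
#' @param k_mad multiplier on the robust scale (MAD) of the high-passed
#'   stroke channel; samples exceeding the threshold are strokes.
#' @param abs_ceiling absolute ceiling on the stroke threshold, m s^-2.
#'   The working threshold is `min(k_mad * MAD, abs_ceiling)`: the MAD term
#'   adapts to instrument noise, the ceiling guarantees that records
#'   dominated by stroking (where the MAD itself scales with stroke
#'   amplitude) are still recognized as stroking.
#' @param highpass_factor high-pass cutoff as a fraction of the dominant
#'   stroke frequency.
#' @param merge_factor stroke marks closer than `merge_factor / f_stroke`
#'   seconds are merged into one stroke bout (bridges the zero crossings
#'   of the stroke oscillation).
#' @param min_duration minimum glide duration, seconds.
#' @param refine_edges refine stroke-bout edges on the detrended raw
#'   channel, which is free of filter ring-down, recovering glide
#'   boundaries to about one sample.
#' @param pitch_floor minimum |pitch| (radians) for a depth-rate speed
#'   estimate; segments below it are dropped when no propeller speed is
#'   available. Default 30 degrees.
#' @param segment_duration glide segment length, seconds.
#' @return list of class `glide_config`.
#' @export
glideConfig <- function(k_mad = 5, abs_ceiling = 0.1, highpass_factor = 0.4,
                        merge_factor = 1.25, min_duration = 5,
                        refine_edges = TRUE, pitch_floor = 30 * pi / 180,
                        segment_duration = 5) {
  stopifnot(k_mad > 0, abs_ceiling > 0, highpass_factor > 0,
            highpass_factor < 1, min_duration > 0, pitch_floor >= 0)
  structure(list(k_mad = k_mad, abs_ceiling = abs_ceiling,
                 highpass_factor = highpass_factor,
                 merge_factor = merge_factor, min_duration = min_duration,
                 refine_edges = refine_edges, pitch_floor = pitch_floor,
                 segment_duration = segment_duration),
            class = "glide_config")
}

# maximal runs of TRUE in a logical vector -> matrix [start, end] (indices)
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect stroke-free glide windows
#'
#' Two-pass detector. Pass 1: high-pass the dorsoventral acceleration at
#' `highpass_factor` times the dominant stroke frequency (zero-phase
#' Butterworth), flag samples whose magnitude exceeds
#' `min(k_mad * MAD, abs_ceiling)`, and merge flags closer than about one
#' stroke period into stroke bouts. Pass 2 (edge refinement): the IIR
#' filter rings past the true end of a stroke bout, so each bout edge is
#' pulled in to the outermost sample at which the raw channel, detrended
#' by a running median, itself exceeds the threshold. Glide windows are
#' the maximal stroke-free intervals of at least `min_duration` seconds.
#'
#' @param series a [tagSeries()].
#' @param config a [glideConfig()].
#' @return tibble with columns `start`, `end` (sample indices),
#'   `start_time`, `end_time` (seconds) and `duration`; zero rows if no
#'   glide exists. Attribute `stroke_freq` carries the estimated stroke
#'   frequency.
#' @export
detectGlides <- function(series, config = glideConfig()) {
  stopifnot(inherits(series, "tag_series"), inherits(config, "glide_config"))
  if (is.null(series$accel_dv)) stop("dorsoventral acceleration channel required")
  fs <- series$fs
  f_d <- dominantStrokeFrequency(series$accel_dv, fs)
  wc <- min(config$highpass_factor * f_d / (fs / 2), 0.95)
  bf <- signal::butter(2, wc, type = "high")
  hp <- signal::filtfilt(bf, series$accel_dv)
  tau <- min(config$k_mad * stats::mad(hp), config$abs_ceiling)
  stroke <- abs(hp) > tau
  # bridge zero crossings of the stroke oscillation
  gap <- max(1L, ceiling(config$merge_factor / f_d * fs))
  stroke <- .dilateGaps(stroke, gap)
  if (config$refine_edges && any(stroke)) {
    med_k <- ceiling(3 / f_d * fs)
    med_k <- med_k + (1 - med_k %% 2)          # odd
    det <- series$accel_dv -
      stats::runmed(series$accel_dv, min(med_k, series$n - (1 - series$n %% 2)))
    hot <- abs(det) > tau
    bouts <- .runs(stroke)
    refined <- rep(FALSE, series$n)
    if (nrow(bouts)) {
      for (i in seq_len(nrow(bouts))) {
        idx <- bouts[i, 1]:bouts[i, 2]
        hi <- idx[hot[idx]]
        if (length(hi)) refined[min(hi):max(hi)] <- TRUE
      }
    }
    stroke <- .dilateGaps(refined, gap)
  }
  win <- .runs(!stroke)
  if (nrow(win)) {
    dur <- (win[, 2] - win[, 1]) / fs
    win <- win[dur >= config$min_duration, , drop = FALSE]
  }
  out <- tibble::tibble(
    start = as.integer(win[, 1]), end = as.integer(win[, 2]),
    start_time = series$time[win[, 1]], end_time = series$time[win[, 2]]
  )
  out$duration <- out$end_time - out$start_time
  attr(out, "stroke_freq") <- f_d
  out
}

# mark as TRUE any FALSE-run shorter than `gap` samples between TRUE runs
.dilateGaps <- function(mask, gap) {
  if (!any(mask)) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inner <- which(!r$values & r$lengths < gap &
                   seq_along(r$values) > 1 & seq_along(r$values) < length(r$values))
  for (i in inner) mask[starts[i]:ends[i]] <- TRUE
  mask
}

#' Swim speed from depth rate and pitch
#'
#' When no propeller speed is recorded, swim speed is the rate of change
#' of depth divided by the sine of pitch (in magnitude). The estimate
#' degrades as 1/sin(pitch) near horizontal swimming, so pitches below
#' `pitch_floor` in magnitude are rejected.
#'
#' @param depth_rate rate of change of depth, m s^-1.
#' @param pitch pitch, radians.
#' @param pitch_floor minimum |pitch|, radians; default 30 degrees.
#' @return speed, m s^-1 (non-negative). Vectorized; errors if any pitch
#'   is below the floor.
#' @export
#' @examples
#' speedFromDepthRate(0.6, pi / 6) # 1.2
speedFromDepthRate <- function(depth_rate, pitch, pitch_floor = 30 * pi / 180) {
  if (any(abs(pitch) < pitch_floor)) {
    stop("speed undefined: |pitch| below the pitch floor (",
         signif(pitch_floor, 3), " rad)")
  }
  abs(depth_rate / sin(pitch))
}

# central-difference depth rate, one-sided at the ends
.depthRate <- function(depth, time) {
  n <- length(depth)
  dr <- numeric(n)
  dr[2:(n - 1)] <- (depth[3:n] - depth[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
  dr[1] <- (depth[2] - depth[1]) / (time[2] - time[1])
  dr[n] <- (depth[n] - depth[n - 1]) / (time[n] - time[n - 1])
  dr
}

#' Cut glide windows into 5 s observation segments
#'
#' Tiles each glide window into non-overlapping segments of
#' `segment_duration` seconds starting at the window start (a remainder
#' shorter than one segment is discarded). For each segment the along-path
#' acceleration is the OLS slope of speed on time, with its standard
#' error; depth, pitch and speed are segment means; and seawater density
#' is interpolated from the CTD profile at the mean depth. When the tag
#' has no propeller channel, speed comes from [speedFromDepthRate()], and
#' segments whose mean |pitch| is below the pitch floor are dropped (with
#' a message).
#'
#' @param windows glide windows from [detectGlides()].
#' @param series the [tagSeries()].
#' @param ctd a [ctdProfile()].
#' @param config a [glideConfig()].
#' @return tibble of glide observations, one row per 5 s segment:
#'   `whale_id, dive_id, start_time, duration, depth, pitch, speed,
#'   rho_sw, accel, accel_se`.
#' @export
segmentGlides <- function(windows, series, ctd, config = glideConfig()) {
  stopifnot(inherits(series, "tag_series"), inherits(ctd, "ctd_profile"))
  fs <- series$fs
  seg_n <- round(config$segment_duration * fs)
  pitch <- series$pitch
  if (is.null(pitch)) {
    f_d <- attr(windows, "stroke_freq")
    if (is.null(f_d)) f_d <- dominantStrokeFrequency(series$accel_dv, fs)
    pitch <- pitchFromAcceleration(series$surge_accel, fs, f_d)
  }
  have_prop <- !is.null(series$speed)
  dr <- .depthRate(series$depth, series$time)
  rows <- list()
  dropped <- 0L
  for (w in seq_len(nrow(windows))) {
    i0 <- windows$start[w]
    len <- windows$end[w] - i0 + 1L
    n_seg <- floor(len / seg_n)
    for (s in seq_len(n_seg)) {
      idx <- (i0 + (s - 1L) * seg_n):(i0 + s * seg_n - 1L)
      p_bar <- mean(pitch[idx])
      if (have_prop) {
        v <- series$speed[idx]
      } else {
        if (abs(p_bar) < config$pitch_floor) { dropped <- dropped + 1L; next }
        v <- abs(dr[idx] / sin(pitch[idx]))
      }
      tt <- series$time[idx]
      fit <- stats::lm.fit(cbind(1, tt - tt[1]), v)
      slope <- fit$coefficients[2]
      rss <- sum(fit$residuals^2)
      sxx <- sum((tt - mean(tt))^2)
      se <- if (length(idx) > 2) sqrt(rss / (length(idx) - 2) / sxx) else 0
      d_bar <- mean(series$depth[idx])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        whale_id = series$whale_id,
        dive_id = series$dive_id[idx[1]],
        start_time = tt[1],
        duration = config$segment_duration,
        depth = d_bar,
        pitch = p_bar,
        speed = mean(v),
        rho_sw = ctdDensityAt(ctd, d_bar),
        accel = unname(slope),
        accel_se = unname(se)
      )
    }
  }
  if (dropped > 0) {
    message(dropped, " segment(s) dropped: |mean pitch| below the pitch floor ",
            "with no propeller speed")
  }
  if (!length(rows)) {
    return(tibble::tibble(whale_id = character(), dive_id = integer(),
                          start_time = numeric(), duration = numeric(),
                          depth = numeric(), pitch = numeric(),
                          speed = numeric(), rho_sw = numeric(),
                          accel = numeric(), accel_se = numeric()))
  }
  do.call(rbind, rows)
}

#' Drop whales with too few glide segments
#'
#' Individual-level density estimation needs enough glides per whale;
#' whales below `min_glides` segments are removed (default 10).
#'
#' @param glides tibble of glide observations with a `whale_id` column.
#' @param min_glides minimum number of 5 s glide segments, >= 1.
#' @return the retained rows; attribute `excluded` lists the removed
#'   whales and their counts.
#' @export
filterWhales <- function(glides, min_glides = 10) {
  stopifnot(min_glides >= 1, "whale_id" %in% names(glides))
  counts <- table(glides$whale_id)
  bad <- names(counts)[counts < min_glides]
  if (length(bad)) {
    message("excluded ", length(bad), " whale(s) with < ", min_glides,
            " glides: ", paste(bad, collapse = ", "))
  }
  out <- glides[!glides$whale_id %in% bad, , drop = FALSE]
  attr(out, "excluded") <- data.frame(whale_id = bad,
                                      n_glides = as.integer(counts[bad]))
  out
}
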