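# CSV schemas: required columns, optional columns, and row-level range
# checks. All files are comma-separated UTF-8 with '.' decimals; units are
# fixed by the schema (metres, kg m^-3, radians, ISO-8601 dates).
.schemas <- list(
  tag = list(
    required = c("t_s", "depth_m", "accel_dv_ms2"),
    optional = c("pitch_rad", "ax_ms2", "ay_ms2", "az_ms2", "speed_ms",
                 "dive_id"),
    checks = list(depth_m = c(0, Inf), pitch_rad = c(-pi / 2, pi / 2))
  ),
  ctd = list(
    required = c("depth_m", "density_kgm3"),
    optional = character(),
    checks = list(depth_m = c(0, Inf), density_kgm3 = c(1000, 1035))
  ),
  glides = list(
    required = c("whale_id", "dive_id", "start_time", "duration", "depth",
                 "pitch", "speed", "rho_sw", "accel", "accel_se"),
    optional = character(),
    checks = list(depth = c(0, Inf), speed = c(0, Inf),
                  accel_se = c(0, Inf), rho_sw = c(1000, 1035))
  ),
  outlines = list(
    required = c("whale_id", "frame_id", "L_px", paste0("w", 0:20),
                 "posture", "brightness", "submergence"),
    optional = character(),
    checks = c(list(L_px = c(1e-9, Inf), posture = c(1, 3),
                    brightness = c(1, 3), submergence = c(1, 3)),
               stats::setNames(rep(list(c(0, Inf)), 21), paste0("w", 0:20)))
  ),
  records = list(
    required = c("whale_id", "location", "date_iso", "sex", "pregnant",
                 "lactating", "immature", "tbd_mean", "tbd_sd", "lssai"),
    optional = character(),
    checks = list(tbd_mean = c(900, 1200), tbd_sd = c(0, Inf),
                  lssai = c(0, 1), pregnant = c(0, 1), lactating = c(0, 1),
                  immature = c(0, 1))
  )
)

#' Read and validate a pipeline CSV
#'
#' Reads one of the package's CSV table types, enforcing its schema:
#' a missing required column is a hard error; a row with a value outside
#' the schema's admissible range is rejected and reported (with its line
#' number) via a message. Empty cells are missing values.
#'
#' @param path file path.
#' @param schema one of "tag", "ctd", "glides", "outlines", "records".
#' @return tibble of the accepted rows; attribute `rejected` holds the
#'   1-based data-row numbers that failed validation.
#' @export
readTable <- function(path, schema = c("tag", "ctd", "glides", "outlines",
                                       "records")) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(sc$required, names(df))
  if (length(miss)) {
    stop("schema '", schema, "': missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- rep(FALSE, nrow(df))
  for (col in intersect(names(sc$checks), names(df))) {
    rng <- sc$checks[[col]]
    v <- df[[col]]
    out <- !is.na(v) & (v < rng[1] | v > rng[2])
    if (any(out)) {
      message("schema '", schema, "', column '", col, "': rejected row(s) ",
              paste(which(out), collapse = ", "),
              " (outside [", rng[1], ", ", rng[2], "])")
      bad <- bad | out
    }
  }
  out <- tibble::as_tibble(df[!bad, , drop = FALSE])
  attr(out, "rejected") <- which(bad)
  out
}

#' Read a tag deployment CSV into a tag series
#'
#' Expects the `tag` schema (`t_s, depth_m, accel_dv_ms2` plus optional
#' `pitch_rad` or a triaxial `ax/ay/az`, `speed_ms`, `dive_id`). When
#' `pitch_rad` is absent, the surge axis (`ax_ms2`) is kept for pitch
#' recovery.
#'
#' @param path file path.
#' @param whale_id identifier for the deployment.
#' @return a [tagSeries()].
#' @export
readTagCsv <- function(path, whale_id = sub("\\.csv$", "", basename(path))) {
  df <- readTable(path, "tag")
  tagSeries(time = df$t_s, depth = df$depth_m, accel_dv = df$accel_dv_ms2,
            pitch = df[["pitch_rad"]],
            surge_accel = df[["ax_ms2"]],
            speed = df[["speed_ms"]],
            whale_id = whale_id,
            dive_id = df[["dive_id"]])
}

#' Read a CTD profile CSV
#' @param path file path (`depth_m, density_kgm3`).
#' @return a [ctdProfile()].
#' @export
readCtdCsv <- function(path) {
  df <- readTable(path, "ctd")
  o <- order(df$depth_m)
  ctdProfile(df$depth_m[o], df$density_kgm3[o])
}

#' Read an outline-measurement CSV
#'
#' One row per annotated frame: `whale_id, frame_id, L_px, w0..w20,
#' posture, brightness, submergence`.
#'
#' @param path file path.
#' @return list of [whaleOutline()] objects (one per accepted row).
#' @export
readOutlineCsv <- function(path) {
  df <- readTable(path, "outlines")
  lapply(seq_len(nrow(df)), function(i) {
    whaleOutline(df$L_px[i],
                 as.numeric(df[i, paste0("w", 0:20)]),
                 score = frameScore(df$posture[i], df$brightness[i],
                                    df$submergence[i]),
                 whale_id = df$whale_id[i], frame_id = as.character(df$frame_id[i]))
  })
}

#' Read a whale-records CSV for the fusion model
#'
#' Schema: `whale_id, location, date_iso, sex, pregnant, lactating,
#' immature, tbd_mean, tbd_sd, lssai`; empty cells denote a missing
#' channel. Dates are converted to the feeding-season day axis via
#' [seasonDay()].
#'
#' @param path file path.
#' @return a [whaleRecords()]-validated tibble.
#' @export
readRecordsCsv <- function(path) {
  df <- readTable(path, "records")
  df$season_day <- seasonDay(df$date_iso, df$location)
  whaleRecords(df[, c("whale_id", "location", "season_day", "sex",
                      "pregnant", "lactating", "immature",
                      "tbd_mean", "tbd_sd", "lssai")])
}

#' Write a pipeline table to CSV
#'
#' Plain comma-separated UTF-8, '.' decimal, no row names; `NA` written
#' as empty cells so the file round-trips through [readTable()].
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline on simulated or supplied data
#'
#' Orchestrates the stages in dependency order: glide extraction from tag
#' series (when tag data are given), whale filtering, Bayesian
#' tissue-density estimation, LSSAI computation from outlines, fusion of
#' both channels in the latent-density model, and lipid-fraction
#' conversion. Every stochastic stage derives its seed from `seed`, so a
#' rerun with the same config reproduces the outputs exactly; the result
#' carries a provenance record (stage log, seed, config hash).
#'
#' @param records whale records tibble (see [whaleRecords()]); required.
#' @param glides optional glide-observation tibble; when present the
#'   density stage runs and its per-whale posteriors replace/append the
#'   TBD channel of matching `whale_id`s in `records`.
#' @param seed integer seed (required).
#' @param mcmc_density,mcmc_fusion [mcmcConfig()]s for the two fits
#'   (seeds are overridden from `seed`).
#' @param min_glides whale inclusion threshold for the density stage.
#' @param structure a [modelStructure()] for the density stage.
#' @return list of class `whalebc_pipeline`: `density_fit` (or NULL),
#'   `fusion_fit`, `whales` (per-whale uTBD + lipid fraction),
#'   `effects`, `correlation` (both-channel Pearson r, if >= 3 pairs),
#'   `provenance`.
#' @export
runPipeline <- function(records, glides = NULL, seed,
                        mcmc_density = mcmcConfig(iterations = 6000),
                        mcmc_fusion = mcmcConfig(iterations = 8000),
                        min_glides = 10,
                        structure = modelStructure("individual")) {
  stopifnot(!missing(seed))
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  density_fit <- NULL
  if (!is.null(glides) && nrow(glides)) {
    glides <- filterWhales(glides, min_glides)
    excl <- attr(glides, "excluded")
    say("density stage: ", length(unique(glides$whale_id)), " whale(s), ",
        nrow(glides), " glides; excluded ", nrow(excl), " glide-poor whale(s)")
    mcmc_density$seed <- as.integer(seed)
    density_fit <- fitHydroModel(glides, structure, mcmc = mcmc_density)
    dens <- density_fit$whales
    m <- match(records$whale_id, dens$whale_id)
    upd <- !is.na(m)
    records$tbd_mean[upd] <- dens$rho_tissue_mean[m[upd]]
    records$tbd_sd[upd] <- dens$rho_tissue_sd[m[upd]]
    say("density stage: updated TBD channel for ", sum(upd), " record(s)")
  } else {
    say("density stage: skipped (no glide data)")
  }
  records <- whaleRecords(records)
  corr <- NULL
  if (sum(!is.na(records$tbd_mean) & !is.na(records$lssai)) >= 3) {
    corr <- correlateChannels(records)
    say("cross-validation: Pearson r = ", round(corr$r, 3),
        " (n = ", corr$n, ", p = ", signif(corr$p, 3), ")")
  }
  mcmc_fusion$seed <- as.integer(seed) + 1L
  fusion_fit <- fitUtbd(records, mcmc = mcmc_fusion)
  say("fusion stage: ", nrow(fusion_fit$whales), " whales, ",
      if (fusion_fit$converged) "converged" else "NOT converged")
  whales <- fusion_fit$whales
  whales$lipid_fraction <- lipidFraction(whales$utbd_mean)
  cfg <- list(seed = seed, min_glides = min_glides, structure = structure,
              mcmc_density = mcmc_density, mcmc_fusion = mcmc_fusion)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(paste(deparse(cfg), collapse = ""), tf)
  structure(list(density_fit = density_fit, fusion_fit = fusion_fit,
                 whales = whales, effects = fusion_fit$effects,
                 correlation = corr,
                 provenance = list(seed = seed,
                                   config_hash = unname(tools::md5sum(tf)),
                                   log = log_lines)),
            class = "whalebc_pipeline")
}

#' @export
print.whalebc_pipeline <- function(x, ...) {
  cat("<whalebc_pipeline> seed", x$provenance$seed, "\n")
  cat(paste0("  ", x$provenance$log, collapse = "\n"), "\n")
  invisible(x)
}
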