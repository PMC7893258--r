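#' Tissue-density-to-lipid calibration
#'
#' An approximate, species-extrapolated affine map from tissue body density
#' to the proportion of body lipid, anchored on two published
#' density/lipid-fraction pairs for a repeatedly sampled adult male
#' humpback: (1037.0 kg m^-3, 36.3%) and (1031.2 kg m^-3, 39.0%). Lipid is
#' less dense than lean tissue, so the slope is negative: denser whales are
#' leaner. The calibration derives from work on northern elephant seals and
#' is an extrapolation; converting a humpback TBD to an exact lipid content
#' would require species-specific lipid and lean-tissue densities.
#'
#' @param anchor1,anchor2 numeric length-2 vectors `c(density, fraction)`
#'   with density in kg m^-3 and lipid as a fraction in 0..1.
#' @return list of class `lipid_calibration` with `slope` and `intercept`
#'   of P_lipid(rho).
#' @export
lipidCalibration <- function(anchor1 = c(1037.0, 0.363),
                             anchor2 = c(1031.2, 0.390)) {
  stopifnot(length(anchor1) == 2, length(anchor2) == 2,
            anchor1[1] != anchor2[1])
  slope <- (anchor2[2] - anchor1[2]) / (anchor2[1] - anchor1[1])
  if (slope >= 0) stop("calibration slope must be negative (denser => leaner)")
  structure(list(slope = slope,
                 intercept = anchor1[2] - slope * anchor1[1],
                 anchors = rbind(anchor1, anchor2)),
            class = "lipid_calibration")
}

#' Approximate lipid-store fraction from tissue body density
#'
#' Applies the affine [lipidCalibration()]. Densities outside the plausible
#' whale-tissue range 1000--1070 kg m^-3 trigger an extrapolation warning
#' but are still computed.
#'
#' @param rho tissue body density, kg m^-3. Vectorized.
#' @param calib a [lipidCalibration()].
#' @return lipid proportion of body tissue (fraction, not percent).
#' @export
#' @examples
#' lipidFraction(1037.0) # 0.363
#' lipidFraction(1043.2) # 0.334
lipidFraction <- function(rho, calib = lipidCalibration()) {
  stopifnot(inherits(calib, "lipid_calibration"), is.numeric(rho))
  if (any(rho < 1000 | rho > 1070)) {
    warning("tissue density outside the plausible range [1000, 1070] kg m^-3; ",
            "lipid fraction is an extrapolation")
  }
  calib$intercept + calib$slope * rho
}
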