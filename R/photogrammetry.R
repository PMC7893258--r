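#' Frame quality score
#'
#' Overhead video frames are scored 1 (poor) to 3 (good) on three criteria:
#' animal posture, image brightness, and the animal's depth relative to the
#' water surface. The frame used for measurement is the one with the highest
#' arithmetic mean score.
#'
#' @param posture,brightness,submergence integer scores in 1..3.
#' @return list of class `frame_score` with the three scores and their mean.
#' @export
frameScore <- function(posture, brightness, submergence) {
  sc <- c(posture = posture, brightness = brightness, submergence = submergence)
  stopifnot(all(sc %in% 1:3))
  structure(list(posture = posture, brightness = brightness,
                 submergence = submergence, mean = mean(sc)),
            class = "frame_score")
}

#' Whale body outline from an overhead image
#'
#' A whale outline is summarized by its total length (rostrum tip to fluke
#' notch, pixels) and 21 boundary widths w0..w20 (pixels) measured at the
#' boundaries of 20 equal-length body sections (w0 at the rostrum, w20 at
#' the fluke notch). All downstream quantities are standardized by length,
#' so pixel units cancel.
#'
#' @param total_length total body length, pixels (> 0).
#' @param boundary_widths numeric vector of exactly 21 non-negative widths,
#'   pixels; `NA` allowed outside the mid-body sections used by [lssai()].
#' @param score optional [frameScore()].
#' @param whale_id,frame_id optional identifiers.
#' @return list of class `whale_outline`.
#' @export
whaleOutline <- function(total_length, boundary_widths, score = NULL,
                         whale_id = NA_character_, frame_id = NA_character_) {
  stopifnot(is.numeric(total_length), total_length > 0,
            length(boundary_widths) == 21,
            all(boundary_widths >= 0, na.rm = TRUE))
  structure(list(total_length = total_length,
                 boundary_widths = as.numeric(boundary_widths),
                 section_height = total_length / 20,
                 score = score, whale_id = whale_id, frame_id = frame_id),
            class = "whale_outline")
}

#' @export
print.whale_outline <- function(x, ...) {
  cat("<whale_outline>", if (!is.na(x$whale_id)) x$whale_id else "",
      "L =", x$total_length, "px;",
      sum(!is.na(x$boundary_widths)), "of 21 boundary widths\n")
  invisible(x)
}

#' Select the best-scored frame
#'
#' Returns the outline whose frame score has the highest mean; ties are
#' broken toward the earliest frame in the list.
#'
#' @param frames list of [whaleOutline()] objects, each carrying a
#'   [frameScore()].
#' @return the selected `whale_outline`.
#' @export
selectBestFrame <- function(frames) {
  stopifnot(length(frames) >= 1)
  means <- vapply(frames, function(f) {
    stopifnot(inherits(f, "whale_outline"), inherits(f$score, "frame_score"))
    f$score$mean
  }, numeric(1))
  frames[[which.max(means)]]   # which.max returns the first maximum
}

#' Length-standardized projected area of one body section
#'
#' The projected area of a body section is the area of the trapezoid with
#' parallel sides `B` (top width) and `b` (bottom width) and height `h`,
#' with every dimension standardized by total length `L`:
#' \deqn{PA = (B/L + b/L) \cdot (h/L) / 2.}
#' The result is dimensionless and invariant to uniform rescaling of all
#' pixel measurements.
#'
#' @param B,b widths of the two section boundaries, pixels.
#' @param h section height, pixels.
#' @param L total body length, pixels (> 0).
#' @return dimensionless projected area. Vectorized.
#' @export
#' @examples
#' projectedArea(140, 130, 50, 1000) # 0.00675
projectedArea <- function(B, b, h, L) {
  stopifnot(all(L > 0), all(B >= 0), all(b >= 0), all(h >= 0))
  (B / L + b / L) * (h / L) / 2
}

#' Length-standardized surface area index (LSSAI)
#'
#' Sums the length-standardized projected areas of body sections 7--17
#' (inclusive, 11 sections spanning 30--85% of body length from the
#' rostrum), the mid-body region that carries most of the between-whale
#' shape variation. Section `i` uses boundary widths `w[i-1]` and `w[i]`
#' and height `L/20`.
#'
#' @param outline a [whaleOutline()].
#' @param sections integer section indices to sum; default `7:17`.
#' @return dimensionless LSSAI.
#' @export
lssai <- function(outline, sections = 7:17) {
  stopifnot(inherits(outline, "whale_outline"),
            all(sections >= 1), all(sections <= 20))
  w <- outline$boundary_widths
  need <- sort(unique(c(sections - 1L, sections))) + 1L  # 1-based indices into w0..w20
  if (anyNA(w[need])) {
    stop("missing boundary width inside sections ", min(sections), "..",
         max(sections), "; no imputation is performed")
  }
  L <- outline$total_length
  pa <- projectedArea(B = w[sections], b = w[sections + 1L],
                      h = outline$section_height, L = L)
  sum(pa)
}

#' Rasterized-mask area oracle for LSSAI
#'
#' Independent check of [lssai()]: renders the outline as a filled polygon
#' (widths interpolated linearly between section boundaries, symmetric
#' about the body axis) on a pixel grid and counts pixels whose centre
#' falls inside the body between 30% and 85% of body length, divided by
#' the squared rendered length. Converges to the trapezoid-sum LSSAI as
#' resolution increases because the outline is piecewise linear.
#'
#' @param outline a [whaleOutline()].
#' @param resolution rendered body length in pixels (>= 2000).
#' @param from,to body-axis range as fractions of length; default 0.30--0.85
#'   (sections 7--17).
#' @return dimensionless area ratio approximating LSSAI.
#' @export
pixelMaskOracle <- function(outline, resolution = 4000, from = 0.30, to = 0.85) {
  stopifnot(inherits(outline, "whale_outline"), resolution >= 2000)
  w <- outline$boundary_widths
  stopifnot(!anyNA(w))
  L <- outline$total_length
  # rescale so rendered length = resolution px
  scale <- resolution / L
  wr <- w * scale
  xb <- seq(0, resolution, length.out = 21)       # boundary positions
  x <- seq(0.5, resolution - 0.5, by = 1)         # pixel-column centres
  half_w <- stats::approx(xb, wr / 2, xout = x)$y
  keep <- x > from * resolution & x <= to * resolution
  # pixel rows inside the body in column x: centres at ±0.5, ±1.5, ... about axis
  n_rows <- 2 * floor(half_w[keep] + 0.5)         # rows with |centre| <= half width
  sum(n_rows) / resolution^2
}
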