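#' Polarized image pair
#'
#' Container for a registered pair of co- and cross-polarized 8-bit
#' fluorescence images acquired simultaneously by the two detection channels
#' behind a polarizing beam splitter.
#'
#' @param co,cross Numeric matrices of identical dimensions with values in
#'   `[0, 255]` (8-bit grayscale). `co` is the channel co-polarized with the
#'   excitation, `cross` the perpendicular one.
#' @param pixel_size_um Optional pixel size in micrometres (metadata only).
#' @return An object of class `polarized_pair`.
#' @export
polarized_pair <- function(co, cross, pixel_size_um = NULL) {
  co <- as.matrix(co)
  cross <- as.matrix(cross)
  if (!identical(dim(co), dim(cross))) {
    stop("co and cross images must have identical dimensions")
  }
  if (anyNA(co) || anyNA(cross)) stop("polarized images must not contain NA")
  rng <- range(co, cross)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("polarized image intensities must lie in [0, 255]")
  }
  structure(
    list(co = co, cross = cross, pixel_size_um = pixel_size_um),
    class = "polarized_pair"
  )
}

#' @export
print.polarized_pair <- function(x, ...) {
  cat(sprintf(
    "<polarized_pair> %d x %d px, co range [%g, %g], cross range [%g, %g]\n",
    nrow(x$co), ncol(x$co), min(x$co), max(x$co), min(x$cross), max(x$cross)
  ))
  invisible(x)
}

#' G-factor of the detection system
#'
#' The G-factor corrects for the unequal sensitivity of the co- and
#' cross-polarized detection channels. It multiplies the cross-polarized
#' intensity everywhere fluorescence polarization is computed.
#'
#' @param value Positive finite scalar.
#' @param source Either `"configured"` (user-supplied) or `"calibrated"`
#'   (estimated from a zero-polarization reference by [calibrate_g()]).
#' @return An object of class `g_factor`.
#' @export
g_factor <- function(value, source = c("configured", "calibrated")) {
  source <- match.arg(source)
  value <- as.numeric(value)
  if (length(value) != 1L || !is.finite(value) || value <= 0) {
    stop("G-factor must be a single finite value > 0")
  }
  structure(list(value = value, source = source), class = "g_factor")
}

as_g <- function(g) {
  if (inherits(g, "g_factor")) g$value else g_factor(g)$value
}

#' @export
print.g_factor <- function(x, ...) {
  cat(sprintf("<g_factor> %g (%s)\n", x$value, x$source))
  invisible(x)
}

#' Intensity threshold rule
#'
#' Pixels are kept only when their intensity lies within `[low, high]`
#' (inclusive) in *both* channels; this removes dark background and saturated
#' pixels before any polarization arithmetic. The defaults exclude values
#' 0--1 (background) and 255 (saturation).
#'
#' @param low,high Integer bounds in `[0, 255]`, `low <= high`.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(low = 2, high = 254) {
  if (low < 0 || high > 255 || low > high) {
    stop("threshold rule requires 0 <= low <= high <= 255")
  }
  structure(list(low = low, high = high), class = "threshold_rule")
}

#' Fluorescence polarization of a pair of intensities
#'
#' Computes `(i_co - g * i_cross) / (i_co + g * i_cross)`, the G-factor
#' corrected degree of fluorescence polarization. Vectorized over intensities.
#'
#' @param i_co,i_cross Non-negative intensities (scalars or arrays of equal
#'   shape).
#' @param g G-factor: a [g_factor()] object or a positive number.
#' @return Fpol values in `[-1, 1]`.
#' @export
#' @examples
#' compute_fpol(100, 100 / 0.75, 0.75) # zero polarization
#' compute_fpol(100, 100, 0.75)        # 25/175
compute_fpol <- function(i_co, i_cross, g) {
  gv <- as_g(g)
  if (any(i_co < 0) || any(i_cross < 0)) {
    stop("intensities must be non-negative")
  }
  denom <- i_co + gv * i_cross
  if (any(denom == 0)) {
    stop("Fpol undefined where i_co + G * i_cross = 0")
  }
  (i_co - gv * i_cross) / denom
}

#' Valid-pixel mask from a threshold rule
#'
#' A pixel is valid iff its intensity lies within the rule's inclusive bounds
#' in both the co- and the cross-polarized channel: a pixel saturated or
#' empty in either channel corrupts the polarization ratio.
#'
#' @param pair A [polarized_pair()].
#' @param rule A [threshold_rule()].
#' @return Logical matrix of the pair's dimensions.
#' @export
apply_threshold <- function(pair, rule = threshold_rule()) {
  stopifnot(inherits(pair, "polarized_pair"), inherits(rule, "threshold_rule"))
  ok <- pair$co >= rule$low & pair$co <= rule$high &
    pair$cross >= rule$low & pair$cross <= rule$high
  if (!any(ok)) {
    warning("threshold rule leaves no valid pixels")
  }
  ok
}

#' Pixel-wise fluorescence polarization map
#'
#' Applies the Fpol ratio pixel by pixel on thresholded channels, in floating
#' point (no intermediate 8-bit rounding). The emission image
#' `i_co + G * i_cross` and difference image `i_co - G * i_cross` used by the
#' ratio are exposed as intermediate products.
#'
#' @inheritParams apply_threshold
#' @param g G-factor ([g_factor()] or number).
#' @return An object of class `fpol_map` with elements `fpol` (matrix, `NA`
#'   outside the valid mask), `valid_mask`, `emission`, `difference`, and the
#'   `g` and `rule` used.
#' @export
fpol_map <- function(pair, g, rule = threshold_rule()) {
  stopifnot(inherits(pair, "polarized_pair"))
  gv <- as_g(g)
  valid <- suppressWarnings(apply_threshold(pair, rule))
  emission <- pair$co + gv * pair$cross
  difference <- pair$co - gv * pair$cross
  fp <- matrix(NA_real_, nrow(pair$co), ncol(pair$co))
  fp[valid] <- difference[valid] / emission[valid]
  structure(
    list(
      fpol = fp, valid_mask = valid,
      emission = emission, difference = difference,
      g = gv, rule = rule
    ),
    class = "fpol_map"
  )
}

#' @export
print.fpol_map <- function(x, ...) {
  v <- x$fpol[x$valid_mask]
  cat(sprintf(
    "<fpol_map> %d x %d px, %d valid (%.1f%%), Fpol median %.4f\n",
    nrow(x$fpol), ncol(x$fpol), sum(x$valid_mask),
    100 * mean(x$valid_mask), stats::median(v)
  ))
  invisible(x)
}

#' Pseudo-colour lookup table for quantitative maps
#'
#' A 256-entry monotone colour map running black -> blue -> green -> yellow ->
#' red, so that the low end of the display range is black and the high end
#' red.
#'
#' @param n Number of entries.
#' @return Character vector of hex colours.
#' @export
fpol_lut <- function(n = 256L) {
  grDevices::colorRampPalette(
    c("black", "#2020B0", "#00A0A0", "#00C000", "#E0E000", "#E06000", "#E00000")
  )(n)
}

#' Render an Fpol map as a pseudo-colour RGB image
#'
#' Values are clamped to `[range_lo, range_hi]` and mapped through a monotone
#' 256-entry LUT with black at the low end and red at the high end; invalid
#' pixels are rendered black. The default display range 0--0.34 is the
#' conventional one for methylene-blue Fpol images of cells.
#'
#' @param map An [fpol_map()].
#' @param range_lo,range_hi Display range, `range_lo < range_hi`.
#' @param lut Character vector of colours (any monotone map; default
#'   [fpol_lut()]).
#' @return An `height x width x 3` array of RGB values in `[0, 1]`.
#' @export
render_fpol <- function(map, range_lo = 0, range_hi = 0.34, lut = fpol_lut()) {
  stopifnot(inherits(map, "fpol_map"), range_lo < range_hi)
  render_scalar_map(map$fpol, map$valid_mask, range_lo, range_hi, lut)
}

# Shared renderer: clamp values to [lo, hi], map through lut, invalid -> black.
render_scalar_map <- function(values, valid, lo, hi, lut) {
  n <- length(lut)
  idx <- matrix(1L, nrow(values), ncol(values))
  v <- values[valid]
  i <- 1L + as.integer(floor((n - 1) * pmin(pmax((v - lo) / (hi - lo), 0), 1) + 0.5))
  idx[valid] <- i
  rgb <- grDevices::col2rgb(lut[idx]) / 255
  out <- array(0, c(nrow(values), ncol(values), 3L))
  out[, , 1] <- matrix(rgb[1, ], nrow(values))
  out[, , 2] <- matrix(rgb[2, ], nrow(values))
  out[, , 3] <- matrix(rgb[3, ], nrow(values))
  # invalid pixels forced to black regardless of LUT low end
  for (k in 1:3) {
    ch <- out[, , k]
    ch[!valid] <- 0
    out[, , k] <- ch
  }
  out
}

#' Calibrate the G-factor from a zero-polarization reference
#'
#' A homogeneous solution of freely rotating dye in a non-viscous solvent has
#' zero fluorescence polarization; for such a reference the G-factor is the
#' ratio of mean co- to mean cross-polarized intensity over valid pixels,
#' because `G` must satisfy `mean(I_co) = G * mean(I_cross)` when Fpol = 0.
#'
#' @param reference_pair A [polarized_pair()] of the reference solution.
#' @param rule Threshold rule applied before averaging.
#' @param min_valid Minimum number of valid pixels for a stable estimate.
#' @return A [g_factor()] with `source = "calibrated"`.
#' @export
calibrate_g <- function(reference_pair, rule = threshold_rule(),
                        min_valid = 100L) {
  valid <- suppressWarnings(apply_threshold(reference_pair, rule))
  n <- sum(valid)
  if (n < min_valid) {
    stop(sprintf(
      "G-factor calibration needs >= %d valid pixels, got %d", min_valid, n
    ))
  }
  m_cross <- mean(reference_pair$cross[valid])
  if (m_cross == 0) stop("mean cross-polarized intensity is zero")
  g_factor(mean(reference_pair$co[valid]) / m_cross, source = "calibrated")
}
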