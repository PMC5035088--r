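#' Frame registration by 1D profile cross-correlation
#'
#' Stage and chip drift is corrected per frame against the first frame of
#' the series. Instead of correlating full 2D images, the horizontal and
#' vertical mean-intensity profiles are cross-correlated independently,
#' which is fast and robust for the strongly structured device layout.
#' Registration is integer-pixel: the downstream 1D analysis tolerates
#' +/- 1 px.
#'
#' @param reference reference frame (matrix), normally frame 1.
#' @param frame frame to register (matrix, same dimensions).
#' @return named integer vector `c(dx, dy)`: the displacement of `frame`
#'   relative to `reference` (positive = moved towards +x / +y). Attribute
#'   `degenerate` is `TRUE` when either axis had no structure to register
#'   (the shift is then reported as 0 on that axis).
#' @export
estimate_shift <- function(reference, frame) {
  if (!identical(dim(reference), dim(frame)))
    stop("reference and frame dimensions differ")
  dx <- xcorr_argmax(mean_profile(reference, "horizontal"),
                     mean_profile(frame, "horizontal"))
  dy <- xcorr_argmax(mean_profile(reference, "vertical"),
                     mean_profile(frame, "vertical"))
  structure(c(dx = as.integer(dx), dy = as.integer(dy)),
            degenerate = isTRUE(attr(dx, "degenerate")) ||
                         isTRUE(attr(dy, "degenerate")))
}

#' Translate an image by an integer pixel shift
#'
#' Content moves by `+dx` columns and `+dy` rows; vacated pixels are filled
#' with the image median, which approximates the background level. Output
#' dimensions equal input dimensions. To undo an estimated displacement,
#' apply the negated shift.
#'
#' @param image numeric matrix.
#' @param shift numeric/integer `c(dx, dy)`.
#' @param fill fill value for vacated pixels (default: median intensity).
#' @return shifted matrix.
#' @export
apply_shift <- function(image, shift, fill = stats::median(image)) {
  dx <- as.integer(round(shift[[1]])); dy <- as.integer(round(shift[[2]]))
  h <- nrow(image); w <- ncol(image)
  if (abs(dx) >= w || abs(dy) >= h)
    stop("shift exceeds image dimensions")
  if (dx == 0L && dy == 0L) return(image)
  out <- matrix(fill, h, w)
  src_r <- max(1L, 1L - dy):min(h, h - dy)
  src_c <- max(1L, 1L - dx):min(w, w - dx)
  out[src_r + dy, src_c + dx] <- image[src_r, src_c]
  out
}

#' Estimate the global rotation angle of the device structure
#'
#' The image is sliced into `n_strips` vertical strips of width
#' `d = W / n_strips`. Each strip's smoothed vertical mean-intensity profile
#' is differenced; cross-correlating the difference profiles of adjacent
#' strips yields per-strip shifts `s_n`. Shifts deviating by two or more
#' standard deviations from their median are discarded as outliers
#' (artifacts, local aberrations), and the angle is
#' `theta = atan(mean(kept) / d)`.
#'
#' Positive `theta` means structure features move towards larger y as x
#' increases (image tilted "downhill to the right"); rotating by `-theta`
#' with [rotate_image()] levels the structure.
#'
#' @param image numeric matrix; `ncol(image) >= 8 * n_strips`.
#' @param n_strips number of strips `N >= 3` (default 16: enough samples
#'   for the outlier rule while keeping strips wide enough for stable
#'   profiles).
#' @param smooth_window Hamming window length for profile smoothing.
#' @return list of class `mm_rotation`: `theta` (radians), `strip_shifts`,
#'   `kept_mask`, `strip_width`.
#' @export
estimate_rotation <- function(image, n_strips = 16L, smooth_window = 15L) {
  n_strips <- as.integer(n_strips)
  w <- ncol(image); h <- nrow(image)
  if (n_strips < 3L) stop("need at least 3 strips")
  if (w < 8L * n_strips) stop("strips too narrow: reduce `n_strips`")
  d <- w / n_strips
  bounds <- round(seq(0, w, length.out = n_strips + 1L))
  sw <- min(smooth_window, h)
  fns <- lapply(seq_len(n_strips), function(n) {
    v <- rowMeans(image[, (bounds[n] + 1L):bounds[n + 1L], drop = FALSE])
    diff(smooth_profile(v, sw))
  })
  # the inter-strip shift of a physically mounted chip is bounded by the
  # plausibility limit on the rotation angle (15 deg); restricting the
  # lag search keeps structurally dissimilar strip pairs (e.g. a strip
  # full of cells next to a channel-free margin) from returning
  # arbitrarily wild shifts
  max_lag <- ceiling(tan(15 * pi / 180) * d)
  s <- vapply(seq_len(n_strips - 1L), function(n) {
    as.numeric(xcorr_lag_refined(fns[[n]], fns[[n + 1L]], max_lag = max_lag))
  }, numeric(1))
  # robust spread estimate: strips over channel-free margins can produce
  # arbitrarily wild shifts, which would inflate a plain standard
  # deviation until the 2-sigma rule keeps the very outliers it should
  # reject
  sig <- stats::mad(s)
  if (is.na(sig) || sig == 0) sig <- stats::sd(s)
  kept <- if (is.na(sig) || sig == 0) rep(TRUE, length(s))
          else abs(s - stats::median(s)) < 2 * sig
  if (sum(kept) < 2L)
    stop("rotation estimation failed: fewer than 2 consistent strip shifts")
  structure(list(theta = atan(mean(s[kept]) / d),
                 strip_shifts = s, kept_mask = kept, strip_width = d),
            class = "mm_rotation")
}

#' @export
print.mm_rotation <- function(x, ...) {
  cat(sprintf("<mm_rotation> theta = %.3f deg (%d/%d strips kept)\n",
              x$theta * 180 / pi, sum(x$kept_mask), length(x$kept_mask)))
  invisible(x)
}

# Precompute the bilinear inverse-mapping for a rotation about the image
# centre. Rotating every frame of a stack reuses one map, so the per-frame
# cost is four gathers plus arithmetic.
rotation_map <- function(dim_hw, theta) {
  h <- dim_hw[1]; w <- dim_hw[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ct <- cos(theta); st <- sin(theta)
  X <- matrix(rep(seq_len(w), each = h), h, w) - cx
  Y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  # source position: inverse rotation of the output grid
  sx <- ct * X + st * Y + cx
  sy <- -st * X + ct * Y + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  i00 <- (x0 - 1) * h + y0 # [y0, x0] linear index
  list(h = h, w = w, inside = inside,
       i00 = i00[inside], i10 = (i00 + h)[inside],
       i01 = (i00 + 1)[inside], i11 = (i00 + h + 1)[inside],
       w00 = ((1 - fx) * (1 - fy))[inside], w10 = (fx * (1 - fy))[inside],
       w01 = ((1 - fx) * fy)[inside], w11 = (fx * fy)[inside])
}

apply_rotation_map <- function(image, map, fill = stats::median(image)) {
  out <- matrix(fill, map$h, map$w)
  v <- image
  out[map$inside] <- map$w00 * v[map$i00] + map$w10 * v[map$i10] +
    map$w01 * v[map$i01] + map$w11 * v[map$i11]
  out
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation; output dimensions equal input dimensions;
#' out-of-frame pixels are filled with the median intensity. Angles beyond
#' 15 degrees are physically implausible for a mounted chip and trigger a
#' warning (the rotation is still applied). `theta = 0` returns the input
#' unchanged.
#'
#' @param image numeric matrix.
#' @param theta angle in radians; positive `theta` tilts structure features
#'   towards larger y for larger x (the inverse of what
#'   [estimate_rotation()] reports for a level scene rotated by `theta`).
#' @param fill fill intensity for pixels rotated in from outside the frame.
#' @return rotated matrix.
#' @export
rotate_image <- function(image, theta, fill = stats::median(image)) {
  if (abs(theta) > 15 * pi / 180)
    warning("implausibly large rotation angle: ",
            format(theta * 180 / pi, digits = 3), " deg")
  if (theta == 0) return(image)
  apply_rotation_map(image, rotation_map(dim(image), theta), fill)
}
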