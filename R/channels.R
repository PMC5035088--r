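#' Growth-channel detection
#'
#' The mother machine's channel array is strictly periodic, so it is
#' located in the frequency domain: the dominant period of the horizontal
#' mean-intensity profile gives the channel interval `i_C`, and the array's
#' vertical extent is the largest run of horizontal strips whose own
#' dominant period matches the whole image's. Individual channels are then
#' localised from the derivative of the horizontal profile: channels are
#' brighter than the device material, so each channel contributes a rising
#' edge on its left and a falling edge on its right flank. A binary
#' reference comb at interval `i_C` and width `w_C`, phase-matched to the
#' observed edge signal, weights the edges into a robustified channel
#' signal whose thresholding rejects channel-free border regions.
#'
#' @name channel-detection
NULL

structure_error <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("mm_structure_error", "error", "condition")))
}

#' Vertical extent of the channel array
#'
#' Splits the image into horizontal strips of `strip_height` rows and
#' keeps the largest run of consecutive strips whose horizontal-profile
#' dominant period matches the whole image's dominant channel period
#' within a relative tolerance. A strip packed with cells may lock onto
#' a harmonic of the channel comb (e.g. the two wall halos per period);
#' harmonic matches (k = 1..3) are accepted as the same structure, and
#' gaps of up to two strips flanked by solid matching runs are closed
#' (the aggregate cell layout can dominate an individual strip's
#' spectrum). Boundaries are snapped to strip edges. A profile whose spectrum
#' carries no significant peak near the channel frequency raises a
#' structure error.
#'
#' @param image numeric matrix.
#' @param strip_height strip height in pixels.
#' @param tol relative period tolerance (default 0.2).
#' @param period optional known channel interval (px); estimated from the
#'   full image when omitted.
#' @return integer vector `c(top, bottom)`, 0-based half-open row interval.
#' @export
find_vertical_extent <- function(image, strip_height = 16L, tol = 0.2,
                                 period = NULL) {
  h <- nrow(image); w <- ncol(image)
  hp <- mean_profile(image, "horizontal")
  if (is.null(period)) period <- dominant_frequency(hp)$period_px
  kg <- as.integer(round(w / period))
  half <- w %/% 2L
  if (kg < 2L || kg > half)
    structure_error("channel period out of range for this image")
  pw <- Mod(stats::fft(hp - mean(hp)))^2
  near <- pmin(pmax(kg + (-1:1), 2L), half)
  if (max(pw[near + 1L]) < 10 * stats::median(pw[2L:(half + 1L)]))
    structure_error("no significant channel frequency in the image")
  starts <- seq(1L, h, by = strip_height)
  ok <- vapply(starts, function(s) {
    rows <- s:min(h, s + strip_height - 1L)
    p <- tryCatch(
      dominant_frequency(colMeans(image[rows, , drop = FALSE]))$period_px,
      error = function(e) NA_real_)
    if (is.na(p)) return(FALSE)
    k <- round(period / p)
    k >= 1 && k <= 3 && abs(p * k - period) / period <= tol
  }, logical(1))
  if (!any(ok)) structure_error("no strip matches the global channel period")
  # a strip inside the array can fail the match when the aggregate cell
  # layout dominates its spectrum; close gaps of up to two strips that
  # are flanked by solid matching runs on both sides
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$values)) {
    if (!r$values[i] && r$lengths[i] <= 2L &&
        i > 1L && i < length(r$values) &&
        r$lengths[i - 1L] >= 2L && r$lengths[i + 1L] >= 2L)
      ok[(ends[i] - r$lengths[i] + 1L):ends[i]] <- TRUE
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  first <- ends[best] - r$lengths[best] + 1L
  top <- starts[first] - 1L
  bottom <- min(h, starts[ends[best]] + strip_height - 1L)
  c(top = top, bottom = bottom)
}

# Split the finite-difference derivative of a horizontal profile into the
# rising ("left" channel flank) and falling ("right" flank) edge signals.
edge_signals <- function(h) {
  hp <- c(diff(h), 0) # forward differences, zero-padded to full length
  list(c_l = (abs(hp) + hp) / 2, c_r = (abs(hp) - hp) / 2)
}

#' Channel width from edge-signal cross-correlation
#'
#' Left flanks lead right flanks by exactly the channel width, so the lag
#' maximising the cross-correlation of the rising-edge signal against the
#' falling-edge signal, restricted to `(0, i_C)`, is `w_C`.
#'
#' @param h horizontal mean-intensity profile of the cropped array
#'   (smoothed), or a list as returned by `edge_signals`.
#' @param interval_px channel interval `i_C` bounding the search.
#' @return integer width in pixels.
#' @export
channel_width <- function(h, interval_px) {
  es <- if (is.list(h)) h else edge_signals(h)
  hi <- ceiling(interval_px) - 1L
  if (hi < 1L) structure_error("channel interval too small")
  w <- tryCatch(xcorr_argmax(es$c_l, es$c_r, lag_range = c(1L, hi)),
                error = function(e) structure_error(conditionMessage(e)))
  if (isTRUE(attr(w, "degenerate")))
    structure_error("flat profile: no channel edges")
  as.integer(w)
}

#' Binary reference channel comb
#'
#' `a(x) = 1` iff `x mod i_C == 0` or `(x - w_C) mod i_C == 0` (x 0-based):
#' a tooth at the expected left and right flank of every channel.
#'
#' @param interval_px integer channel interval `i_C`.
#' @param width_px integer channel width `w_C`, `0 < w_C < i_C`.
#' @param length signal length (image width).
#' @return binary numeric vector.
#' @export
build_reference_signal <- function(interval_px, width_px, length) {
  interval_px <- as.integer(round(interval_px))
  width_px <- as.integer(round(width_px))
  if (width_px <= 0L || width_px >= interval_px || interval_px > length)
    stop("need 0 < width_px < interval_px <= length")
  x <- 0:(length - 1L)
  as.numeric(x %% interval_px == 0L | (x - width_px) %% interval_px == 0L)
}

#' Phase of the channel array relative to the reference comb
#'
#' The lag at which the summed edge signal best aligns with the reference
#' comb, reduced modulo `i_C` into `[0, i_C)`.
#'
#' @param a reference comb from [build_reference_signal()].
#' @param edges summed edge signal `c_l + c_r`.
#' @param interval_px integer channel interval.
#' @return integer phase in `[0, interval_px)`.
#' @export
estimate_phase <- function(a, edges, interval_px) {
  if (all(edges == 0)) structure_error("degenerate edge signal")
  s <- xcorr_argmax(a, edges)
  as.integer(((as.integer(s) %% interval_px) + interval_px) %% interval_px)
}

#' Robustified channel signal
#'
#' Element-wise product of the phase-shifted comb with the summed edge
#' signal: `h_tau(x) = a(x - phi) * (c_l(x) + c_r(x))`. Nonzero only where
#' the comb expects a channel flank, which amplifies channels and
#' suppresses spurious edges elsewhere.
#'
#' @param a reference comb.
#' @param phi integer phase (px, >= 0).
#' @param c_l,c_r edge signals.
#' @return numeric vector of the same length.
#' @export
robust_channel_signal <- function(a, phi, c_l, c_r) {
  n <- length(a)
  stopifnot(length(c_l) == n, length(c_r) == n)
  phi <- as.integer(phi)
  a_shift <- if (phi > 0L) c(numeric(phi), a[1:(n - phi)]) else a
  a_shift * (c_l + c_r)
}

#' Channel geometry of one frame
#'
#' Runs the full channel-detection chain on a registered, orientation-
#' corrected frame and returns the detected geometry: array extent, channel
#' interval, width, phase and per-channel column boxes.
#'
#' @param image numeric matrix (one corrected frame).
#' @param strip_height strip height for the vertical-extent search.
#' @param tol relative dominant-period match tolerance.
#' @param threshold_fraction comb positions whose edge support falls below
#'   this fraction of the mean per-tooth support are rejected as border
#'   (channel-free) regions.
#' @param smooth_window Hamming window for the horizontal profile.
#' @param interval_px optional fixed channel interval (px), e.g. the modal
#'   interval across frames; estimated from the image when `NULL`.
#' @param width_px optional fixed channel width (px). Interval and width
#'   are properties of the device, not of a frame; estimating them on a
#'   sparsely populated frame (e.g. the seeding frame) and passing them as
#'   priors keeps the per-frame relocalisation unambiguous even when
#'   channels are packed with cells, whose body edges otherwise compete
#'   with the wall edges.
#' @return object of class `mm_channel_geometry` with fields `array_top`,
#'   `array_bottom`, `interval_px`, `width_px`, `phase_px` and
#'   `channel_boxes` (matrix of 0-based half-open `[x_left, x_right)`).
#' @export
detect_channel_geometry <- function(image, strip_height = 16L, tol = 0.2,
                                    threshold_fraction = 0.5,
                                    smooth_window = 3L, interval_px = NULL,
                                    width_px = NULL) {
  w_img <- ncol(image)
  est_interval <- is.null(interval_px)
  if (est_interval) {
    hp <- mean_profile(image, "horizontal")
    df <- dominant_frequency(hp)
    # a real channel array towers over the rest of the spectrum; on a
    # structure-free image the "dominant" peak is just the largest noise
    # ripple and sits near the median spectral power
    p <- Mod(stats::fft(hp - mean(hp)))^2
    p <- p[3:(length(hp) %/% 2 + 1L)]
    if (df$power < 20 * stats::median(p))
      structure_error("no periodic channel structure in the image")
    interval_px <- df$period_px
  }
  ext <- find_vertical_extent(image, strip_height, tol, period = interval_px)
  crop <- image[(ext[1] + 1L):ext[2], , drop = FALSE]
  if (est_interval)
    interval_px <- dominant_frequency(mean_profile(crop, "horizontal"))$period_px
  h <- smooth_profile(colMeans(crop), min(smooth_window, w_img))
  es <- edge_signals(h)
  edges <- es$c_l + es$c_r
  # the spectral period has bin-limited resolution (worse the fewer
  # channels are in view); the integer comb spacing is pinned by the
  # edge-signal autocorrelation peak nearest the spectral estimate
  lo <- max(2L, floor(0.8 * interval_px))
  hi <- min(w_img - 1L, ceiling(1.2 * interval_px))
  ic <- tryCatch({
    r <- xcorr_argmax(edges, edges, lag_range = c(lo, hi))
    if (isTRUE(attr(r, "degenerate"))) round(interval_px) else as.integer(r)
  }, error = function(e) as.integer(round(interval_px)))
  # on crowded frames the spectral estimate can land on a harmonic of
  # the comb (half or a third of the true interval). If the candidate
  # interval were true, the per-overlap autocorrelation at its multiples
  # would be no better than at the candidate itself; a decisively
  # stronger multiple therefore reveals a harmonic lock
  e0 <- edges - mean(edges)
  acorr_norm <- function(lag) {
    n <- length(e0)
    if (lag < 1L || lag >= n) return(-Inf)
    sum(e0[1:(n - lag)] * e0[(lag + 1):n]) / (n - lag)
  }
  base <- acorr_norm(ic)
  for (m in 3:2) if (m * ic < w_img %/% 2L &&
                     acorr_norm(m * ic) > 1.3 * max(base, 0)) {
    ic <- m * ic
    break
  }
  wc <- if (is.null(width_px)) channel_width(es, ic)
        else as.integer(width_px)
  if (wc <= 0L || wc >= ic) structure_error("implausible channel width")
  a <- build_reference_signal(ic, wc, w_img)
  phi <- estimate_phase(a, edges, ic)
  htau <- robust_channel_signal(a, phi, es$c_l, es$c_r)
  boxes <- extract_channel_boxes(htau, phi, ic, wc, w_img, threshold_fraction,
                                 es$c_l, es$c_r)
  if (!nrow(boxes)) structure_error("zero channels detected")
  structure(list(array_top = unname(ext[1]), array_bottom = unname(ext[2]),
                 interval_px = interval_px, width_px = wc, phase_px = phi,
                 channel_boxes = boxes, W = w_img, H = nrow(image)),
            class = "mm_channel_geometry")
}

# Comb positions with enough h_tau support become channel boxes. The
# comb phase locates each channel to a few pixels; each flank is then
# snapped to the local peak of its edge signal (the forward difference
# peaks half a pixel before the first/last lumen column, so the box edge
# is the peak position + 1), which removes the bias the halo's secondary
# edges induce in the global width/phase correlation.
extract_channel_boxes <- function(htau, phi, interval_px, width_px, w_img,
                                  threshold_fraction = 0.5,
                                  c_l = NULL, c_r = NULL) {
  tooth_mass <- function(x0) { # 0-based tooth position, +/- 2 px
    idx <- (x0 - 2L):(x0 + 2L) + 1L
    sum(htau[idx[idx >= 1L & idx <= w_img]])
  }
  lefts <- seq(phi, w_img - width_px - 1L, by = interval_px)
  if (!length(lefts)) return(matrix(numeric(0), 0, 2))
  support <- vapply(lefts, function(x0) tooth_mass(x0) + tooth_mass(x0 + width_px),
                    numeric(1))
  keep <- support > threshold_fraction * mean(support)
  lefts <- lefts[keep]
  rights <- lefts + width_px
  if (!is.null(c_l) && !is.null(c_r)) {
    snap <- function(sig, x0) { # local 0-based argmax within +/- 2 px
      idx <- (x0 - 2L):(x0 + 2L)
      idx <- idx[idx >= 0L & idx < w_img]
      idx[which.max(sig[idx + 1L])]
    }
    for (i in seq_along(lefts)) {
      xl <- snap(c_l, lefts[i]) + 1L
      xr <- snap(c_r, rights[i] - 1L) + 1L
      if (abs((xr - xl) - width_px) <= 1L && xl < xr) {
        lefts[i] <- xl; rights[i] <- xr
      } else {
        lefts[i] <- lefts[i] + 1L; rights[i] <- rights[i] + 1L
      }
    }
  }
  cbind(x_left = lefts, x_right = rights)
}

#' Crop the detected channels out of a frame
#'
#' The crop is extended by `margin_px` rows above the detected array
#' extent (clamped to the frame): the closed channel end then contributes
#' a device-to-cell intensity transition above the mother cell, so the
#' mother's top boundary is a real profile maximum rather than the crop
#' border. The margin is kept below the minimum cell length so a
#' margin-only candidate can never pass the length filter.
#'
#' @param image corrected frame.
#' @param geometry an `mm_channel_geometry` for that frame.
#' @param margin_px extra rows above the closed end.
#' @return list of channel crops, each carrying attribute `row_offset`
#'   (0-based frame row of the crop's first row).
#' @export
extract_channels <- function(image, geometry, margin_px = 12L) {
  top <- max(0L, geometry$array_top - margin_px)
  bottom <- min(nrow(image), geometry$array_bottom)
  rows <- (top + 1L):bottom
  lapply(seq_len(nrow(geometry$channel_boxes)), function(i) {
    b <- geometry$channel_boxes[i, ]
    structure(image[rows, (b[1] + 1L):b[2], drop = FALSE], row_offset = top)
  })
}

#' @export
print.mm_channel_geometry <- function(x, ...) {
  cat(sprintf(paste0("<mm_channel_geometry> %d channels, interval %.2f px, ",
                     "width %d px, phase %d px, rows [%d, %d)\n"),
              nrow(x$channel_boxes), x$interval_px, x$width_px, x$phase_px,
              x$array_top, x$array_bottom))
  invisible(x)
}

# Match per-frame channel boxes to reference channel x-positions so each
# physical channel keeps a stable identity across frames. Boxes farther
# than interval/2 from every reference position start new identities
# when `allow_new`, otherwise they get id 0 (the device is static, so a
# pipeline run fixes its identities from the reference frame and treats
# unmatched boxes - e.g. bright non-channel device structure that
# occasionally passes the support threshold - as spurious).
match_channel_ids <- function(lefts, ref_lefts, interval_px,
                              allow_new = TRUE) {
  ids <- integer(length(lefts))
  taken <- logical(length(ref_lefts))
  for (i in seq_along(lefts)) {
    d <- abs(ref_lefts - lefts[i])
    d[taken] <- Inf
    j <- if (length(d)) which.min(d) else integer(0)
    if (length(j) && d[j] < interval_px / 2) {
      ids[i] <- j; taken[j] <- TRUE
    } else if (allow_new) {
      ref_lefts <- c(ref_lefts, lefts[i])
      taken <- c(taken, TRUE)
      ids[i] <- length(ref_lefts)
    } # else ids[i] stays 0: spurious box
  }
  list(ids = ids, ref_lefts = ref_lefts)
}
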