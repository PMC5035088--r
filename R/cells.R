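#' 1D cell detection inside a growth channel crop
#'
#' Cells fill the channel width and stack along its axis without overlap,
#' so a cell is fully described by a 1D coordinate pair `[top, bottom)` on
#' the channel axis. Detection works on the cleaned vertical intensity
#' profile of the channel crop: cells are dark, inter-cell constrictions
#' and cell-free regions bright, so cells are the intervals between
#' adjacent profile maxima. Candidates are then filtered by three
#' independent criteria - physical length, blackness (Otsu dark-class
#' fraction) and prominence (envelope depth of the intensity dip) - since
#' no single criterion separates cells from debris, bright gaps and noise
#' dips reliably on low-SNR phase-contrast data.
#'
#' @name cell-detection
NULL

#' Cell detection parameters
#'
#' @param min_length_um minimum physical cell length (default 1 um;
#'   anything shorter is debris or a split artifact).
#' @param blackness_min minimum dark-class fraction over the candidate's
#'   extent (default 0.5). Cells are dark objects, so a true cell sits well
#'   above 50% while bright inter-cell gaps fall far below; set
#'   `cells_are_dark = FALSE` for contrast-inverted data, which flips the
#'   criterion to `1 - blackness >= blackness_min`.
#' @param cells_are_dark polarity flag, see above.
#' @param prominence_min minimum envelope prominence; `NULL` (default)
#'   means 2% of the crop's intensity range, much lower than the blackness
#'   threshold - it only rejects numerically flat jitter dips.
#' @param extrema_window_px sliding window for extrema detection (odd,
#'   >= 3). `NULL` (default) derives it from the physical minimum cell
#'   length at detection time (`min_length_um` in pixels, rounded to odd):
#'   profile wiggles below the minimal cell scale are never real cell
#'   boundaries, so the window should span that scale.
#' @param smooth_window_px Hamming window for the final profile smoothing.
#' @param boundary_contrast minimum height of a boundary maximum above its
#'   adjacent minima, as an absolute intensity; `NULL` (default) means 5%
#'   of the crop's intensity range. Prunes noise-scale wiggles inside flat
#'   cell interiors that would otherwise split a long cell in two; real
#'   inter-cell constrictions are several times brighter.
#' @return list of class `mm_detection_params`.
#' @export
detection_params <- function(min_length_um = 1.0, blackness_min = 0.5,
                             cells_are_dark = TRUE, prominence_min = NULL,
                             extrema_window_px = NULL, smooth_window_px = 5L,
                             boundary_contrast = NULL) {
  stopifnot(min_length_um > 0, blackness_min > 0, blackness_min < 1,
            is.null(extrema_window_px) ||
              (extrema_window_px >= 3L && extrema_window_px %% 2L == 1L))
  structure(as.list(environment()), class = "mm_detection_params")
}

# odd sliding-window size spanning the minimal physical cell length
derive_extrema_window <- function(params, pixel_size_um) {
  w <- params$extrema_window_px
  if (is.null(w)) {
    w <- as.integer(round(params$min_length_um / pixel_size_um))
    if (w %% 2L == 0L) w <- w + 1L
  }
  max(3L, w)
}

#' Cleaned vertical intensity profile of a channel crop
#'
#' The raw vertical mean profile is baseline-corrected by subtracting a
#' maximally smoothed version of itself (Hamming window spanning the whole
#' profile), which removes illumination ramps and the channel's intensity
#' pedestal, and then smoothed again with a short window. The result
#' oscillates around zero: minima at cells, maxima at constrictions and
#' cell-free regions.
#'
#' @param crop channel crop matrix (rows = channel axis), height >= 8 px.
#' @param smooth_window_px short smoothing window.
#' @return numeric vector (length = crop height); empty for degenerate
#'   crops.
#' @export
cleaned_profile <- function(crop, smooth_window_px = 5L) {
  if (is.null(dim(crop)) || nrow(crop) < 8L) return(numeric(0))
  prof <- rowMeans(crop)
  baseline <- smooth_profile(prof, length(prof))
  smooth_profile(prof - baseline, min(smooth_window_px, length(prof)))
}

#' Local extrema by a sliding window
#'
#' Position `p` is a maximum iff it attains the maximum of its centred
#' window (truncated at the profile ends) and the window is not flat;
#' dually for minima. Plateaus of equal values yield their centre as the
#' single representative extremum, and maxima/minima are forced to
#' alternate by keeping only the most extreme point of any same-type run.
#'
#' Weak maxima can optionally be pruned: a maximum whose height exceeds
#' its adjacent minima by less than `min_contrast` is a noise wiggle on a
#' flat (typically intra-cell) stretch, not a cell boundary; pruning it
#' merges the neighbouring minima (keeping the lower) so alternation is
#' preserved.
#'
#' @param x numeric profile.
#' @param window odd window length >= 3.
#' @param min_contrast minimum height of a maximum above its adjacent
#'   minima (same units as `x`); 0 disables pruning.
#' @return list with integer vectors `maxima` and `minima` (1-based
#'   positions, alternating).
#' @export
find_extrema <- function(x, window = 5L, min_contrast = 0) {
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L)
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  h <- (window - 1L) %/% 2L
  shift_pad <- function(v, k, pad) { # v displaced by k, pad at the ends
    if (k > 0) c(v[-seq_len(k)], rep(pad, k))
    else if (k < 0) c(rep(pad, -k), v[seq_len(n + k)])
    else v
  }
  rmax <- x; rmin <- x
  for (k in seq_len(h)) {
    rmax <- pmax(rmax, shift_pad(x, k, -Inf), shift_pad(x, -k, -Inf))
    rmin <- pmin(rmin, shift_pad(x, k, Inf), shift_pad(x, -k, Inf))
  }
  # collapse equal-valued candidate runs to their centre; a run counts
  # only if it strictly dominates both neighbours (where they exist)
  run_centres <- function(cand, sgn) {
    pos <- which(cand)
    if (!length(pos)) return(integer(0))
    grp <- cumsum(c(1L, diff(pos) != 1L | diff(x[pos]) != 0))
    out <- vapply(split(pos, grp), function(p) {
      v <- x[p[1L]]
      lo <- p[1L] - 1L; hi <- p[length(p)] + 1L
      ok <- (lo < 1L || sgn * (v - x[lo]) > 0) &&
            (hi > n || sgn * (v - x[hi]) > 0)
      if (ok) p[ceiling(length(p) / 2)] else NA_integer_
    }, integer(1))
    unname(out[!is.na(out)])
  }
  maxima <- run_centres(x == rmax, +1)
  minima <- run_centres(x == rmin, -1)
  if (!length(maxima) || !length(minima))
    return(list(maxima = maxima, minima = minima))
  # enforce alternation: of any same-type run keep the most extreme point
  ev <- rbind(data.frame(pos = maxima, type = 1L),
              data.frame(pos = minima, type = -1L))
  ev <- ev[order(ev$pos), ]
  keep <- rep(TRUE, nrow(ev))
  i <- 1L
  while (i < nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1L] == ev$type[i]) j <- j + 1L
    if (j > i) {
      run <- i:j
      best <- run[which.max(ev$type[i] * x[ev$pos[run]])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j + 1L
  }
  ev <- ev[keep, ]
  if (min_contrast > 0) ev <- prune_weak_maxima(ev, x, min_contrast)
  list(maxima = ev$pos[ev$type == 1L], minima = ev$pos[ev$type == -1L])
}

# Iteratively remove the weakest under-contrast maximum and merge its
# flanking minima until every maximum clears `min_contrast`.
prune_weak_maxima <- function(ev, x, min_contrast) {
  repeat {
    imax <- which(ev$type == 1L)
    if (!length(imax)) return(ev)
    contrast <- vapply(imax, function(i) {
      adj <- c(if (i > 1L) x[ev$pos[i - 1L]],
               if (i < nrow(ev)) x[ev$pos[i + 1L]])
      if (!length(adj)) return(Inf)
      x[ev$pos[i]] - max(adj)
    }, numeric(1))
    weak <- imax[contrast < min_contrast]
    if (!length(weak)) return(ev)
    i <- weak[which.min(contrast[match(weak, imax)])]
    drop <- i
    if (i > 1L && i < nrow(ev)) { # merge flanking minima, keep the lower
      drop <- c(drop, if (x[ev$pos[i - 1L]] >= x[ev$pos[i + 1L]]) i - 1L
                      else i + 1L)
    }
    ev <- ev[-drop, , drop = FALSE]
  }
}

#' Cell candidates from adjacent profile maxima
#'
#' Each pair of adjacent maxima brackets one candidate: the bright points
#' on both sides of a dark dip. Candidates share boundary maxima and are
#' therefore non-overlapping half-open intervals.
#'
#' @param maxima sorted 1-based maxima positions.
#' @return data frame with 0-based `top_px`, `bottom_px` (half-open).
#' @export
candidates_from_extrema <- function(maxima) {
  if (length(maxima) < 2L)
    return(data.frame(top_px = integer(0), bottom_px = integer(0)))
  data.frame(top_px = maxima[-length(maxima)] - 1L,
             bottom_px = maxima[-1L] - 1L)
}

#' Refine candidate boundaries to half-height crossings
#'
#' A candidate's bracketing maxima can sit far from the actual cell edge
#' when the cell borders a wide bright region (the empty stretch before
#' the open channel end, the dead-end pocket): the extent then contains
#' many bright rows that dilute the blackness score and bias the length.
#' Each boundary is therefore moved inward to where the cleaned profile
#' crosses halfway between the boundary maximum and the dip minimum - the
#' 1D analogue of a full-width-at-half-maximum extent, which tracks the
#' physical cell edge to within the blur scale.
#'
#' @param cand data frame from [candidates_from_extrema()].
#' @param cleaned the cleaned profile the maxima were found on.
#' @return the data frame with `top_px` / `bottom_px` tightened.
#' @export
refine_boundaries <- function(cand, cleaned) {
  for (i in seq_len(nrow(cand))) {
    m1 <- cand$top_px[i] + 1L; m2 <- cand$bottom_px[i] + 1L # 1-based maxima
    seg <- cleaned[m1:m2]
    p <- m1 + which.min(seg) - 1L
    vmin <- cleaned[p]
    half_l <- (cleaned[m1] + vmin) / 2
    half_r <- (cleaned[m2] + vmin) / 2
    xl <- m1:p; xl <- xl[cleaned[xl] >= half_l]
    xr <- p:m2; xr <- xr[cleaned[xr] >= half_r]
    cand$top_px[i] <- (if (length(xl)) max(xl) else m1) - 1L
    cand$bottom_px[i] <- (if (length(xr)) min(xr) else m2) - 1L
  }
  cand[cand$bottom_px > cand$top_px, , drop = FALSE]
}

#' Blackness of a candidate
#'
#' The channel crop is Otsu-binarised (dark class = 1); the candidate's
#' blackness is the mean of the binary image's vertical mean profile over
#' the candidate's extent, i.e. the dark-area fraction of its bounding
#' box. For a degenerate (constant) crop the blackness is 0.
#'
#' @param top_px,bottom_px 0-based half-open candidate extent.
#' @param crop channel crop matrix.
#' @param threshold optional precomputed Otsu threshold.
#' @return fraction in `[0, 1]`.
#' @export
score_blackness <- function(top_px, bottom_px, crop, threshold = NULL) {
  if (is.null(threshold))
    threshold <- tryCatch(otsu_threshold(crop), error = function(e) NA_real_)
  if (is.na(threshold)) return(0)
  bprof <- rowMeans(crop < threshold)
  mean(bprof[(top_px + 1L):bottom_px])
}

# Interpolating envelope through (pos, value) support points: natural
# cubic spline for >= 4 points, linear for 2-3, constant for 1.
envelope_fun <- function(pos, val) {
  n <- length(pos)
  if (n == 0L) return(function(x) rep(0, length(x)))
  if (n == 1L) return(function(x) rep(val, length(x)))
  if (n >= 4L) return(stats::splinefun(pos, val, method = "natural"))
  stats::approxfun(pos, val, rule = 2)
}

#' Prominence of a candidate
#'
#' Depth of the candidate's intensity dip, measured as the gap between an
#' upper envelope interpolating the cleaned profile's maxima and a lower
#' envelope interpolating its minima, evaluated at the candidate centre.
#' Real cells produce deep dips between bright constrictions; noise
#' wiggles on a flat profile have near-zero envelope separation.
#'
#' @param top_px,bottom_px 0-based half-open candidate extent.
#' @param cleaned cleaned profile from [cleaned_profile()].
#' @param maxima,minima extrema positions from [find_extrema()].
#' @return non-negative prominence (intensity units).
#' @export
score_prominence <- function(top_px, bottom_px, cleaned, maxima, minima) {
  centre <- (top_px + bottom_px) / 2 + 1 # back to 1-based axis
  upper <- envelope_fun(maxima, cleaned[maxima])
  lower <- envelope_fun(minima, cleaned[minima])
  max(0, upper(centre) - lower(centre))
}

#' Detect cells in one channel crop
#'
#' Runs the full chain - cleaned profile, extrema, candidate pairing,
#' three-criterion filter - and returns the accepted cells top-to-bottom.
#' The full candidate list with scores and per-criterion verdicts is
#' attached as attribute `candidates` for preview and debugging.
#'
#' @param crop channel crop matrix (rows = channel axis).
#' @param params a [detection_params()].
#' @param pixel_size_um calibration (um/px).
#' @param valid_px optional 0-based half-open row interval within the crop
#'   (the growth channel proper); candidates whose centroid falls outside
#'   it - crop margin or strip-rounding rows - are rejected.
#' @return data frame of accepted cells: `top_px`, `bottom_px` (0-based
#'   half-open), `centroid_px`, `length_um`, `blackness`, `prominence`.
#' @export
detect_cells <- function(crop, params = detection_params(), pixel_size_um,
                         valid_px = NULL) {
  empty <- data.frame(top_px = integer(0), bottom_px = integer(0),
                      centroid_px = numeric(0), length_um = numeric(0),
                      blackness = numeric(0), prominence = numeric(0))
  cleaned <- cleaned_profile(crop, params$smooth_window_px)
  if (!length(cleaned)) return(empty)
  prom_min <- params$prominence_min
  if (is.null(prom_min)) prom_min <- 0.02 * diff(range(crop))
  bc <- params$boundary_contrast
  if (is.null(bc)) bc <- 0.05 * diff(range(crop))
  ex <- find_extrema(cleaned, derive_extrema_window(params, pixel_size_um),
                     min_contrast = bc)
  cand <- candidates_from_extrema(ex$maxima)
  if (!nrow(cand)) return(structure(empty, candidates = empty))
  cand <- refine_boundaries(cand, cleaned)
  thr <- tryCatch(otsu_threshold(crop), error = function(e) NA_real_)
  cand$centroid_px <- (cand$top_px + cand$bottom_px) / 2
  cand$length_um <- (cand$bottom_px - cand$top_px) * pixel_size_um
  cand$blackness <- vapply(seq_len(nrow(cand)), function(i)
    score_blackness(cand$top_px[i], cand$bottom_px[i], crop, thr), numeric(1))
  if (!params$cells_are_dark) cand$blackness <- 1 - cand$blackness
  cand$prominence <- vapply(seq_len(nrow(cand)), function(i)
    score_prominence(cand$top_px[i], cand$bottom_px[i], cleaned,
                     ex$maxima, ex$minima), numeric(1))
  cand$pass_valid <- if (is.null(valid_px)) TRUE
    else cand$centroid_px >= valid_px[1] & cand$centroid_px < valid_px[2]
  cand$pass_length <- cand$length_um >= params$min_length_um
  cand$pass_blackness <- cand$blackness >= params$blackness_min
  cand$pass_prominence <- cand$prominence >= prom_min
  acc <- cand[cand$pass_valid & cand$pass_length & cand$pass_blackness &
                cand$pass_prominence,
              c("top_px", "bottom_px", "centroid_px", "length_um",
                "blackness", "prominence")]
  rownames(acc) <- NULL
  structure(acc, candidates = cand)
}
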