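#' End-to-end analysis of a mother machine frame series
#'
#' Runs the full pipeline in the canonical order: (1) registration of
#' every frame against frame 1 by profile cross-correlation; (2)
#' orientation correction with the rotation angle estimated once on the
#' registered first frame (chip rotation is physically constant; per-frame
#' re-estimation is available but adds jitter); (3) channel detection per
#' frame, with the channel interval and width fixed from the first
#' analysable frame and channels matched across frames by x-position to
#' stable identities; (4) 1D cell detection in every channel crop; (5)
#' greedy constrained-assignment tracking per channel, followed by
#' fluorescence quantification where fluorescence frames exist.
#'
#' Frames whose structure detection fails are skipped with a warning and
#' bridged by the tracker. Per-frame stages (2-4) are independent and can
#' run on several workers; results are identical to serial execution.
#'
#' @param series an [frame_series()] (from [load_stack()] or
#'   [generate_stack()]).
#' @param detection a [detection_params()].
#' @param tracking a [tracking_params()].
#' @param stride temporal subsampling stride (see [subsample()]).
#' @param n_strips strips for rotation estimation.
#' @param strip_height strip height (px) for the vertical-extent search.
#' @param threshold_fraction channel-support threshold, see
#'   [detect_channel_geometry()].
#' @param mu_bounds physiological growth-rate bounds (per hour) applied
#'   when deriving division-time statistics.
#' @param register,rotate logical switches for the correction stages.
#' @param rotate_per_frame re-estimate the rotation on every frame
#'   instead of once.
#' @param crop_margin_px crop margin above the closed channel end.
#' @param workers number of parallel workers for per-frame stages.
#' @return object of class `mm_analysis`: the lineage, division events
#'   and statistics, per-frame geometry and shifts, stage counters and
#'   warnings, and everything needed to reproduce crops for kymographs.
#' @export
mm_analyze <- function(series, detection = detection_params(),
                       tracking = tracking_params(), stride = 1L,
                       n_strips = 16L, strip_height = 16L,
                       threshold_fraction = 0.5, mu_bounds = c(0.01, 1.0),
                       register = TRUE, rotate = TRUE,
                       rotate_per_frame = FALSE, crop_margin_px = 12L,
                       workers = 1L) {
  stopifnot(inherits(series, "mm_frame_series"))
  if (stride > 1L) series <- subsample(series, stride)
  T_ <- length(series$frames)
  ps <- series$calibration$pixel_size_um
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  ## 1. registration --------------------------------------------------
  ## the frame-1 reference estimate is exact while the scene still
  ## resembles frame 1, but a drifting field whose content changes
  ## wholesale (channels filling with cells) can mislock the periodic
  ## profile; chaining adjacent-frame estimates is immune to content
  ## change but accumulates error. Use the direct estimate whenever it
  ## agrees with the chain (which also resets the chain), and fall back
  ## to the chain when it does not.
  ref <- series$frames[[1L]]
  shifts <- matrix(0L, T_, 2L, dimnames = list(NULL, c("dx", "dy")))
  if (register && T_ > 1L) {
    acc <- c(0L, 0L)
    for (t in 2:T_) {
      step <- estimate_shift(series$frames[[t - 1L]], series$frames[[t]])
      acc <- acc + as.integer(step)
      direct <- estimate_shift(ref, series$frames[[t]])
      if (isTRUE(attr(direct, "degenerate")))
        note(sprintf("frame %d: degenerate registration signal", t))
      if (max(abs(as.integer(direct) - acc)) <= 2L) {
        shifts[t, ] <- as.integer(direct)
        acc <- as.integer(direct)
      } else shifts[t, ] <- acc
    }
  }
  correct1 <- function(t) {
    f <- series$frames[[t]]
    if (any(shifts[t, ] != 0L)) f <- apply_shift(f, -shifts[t, ]) else f
  }

  ## 2. orientation ----------------------------------------------------
  theta <- 0
  rot_map <- NULL
  # strips must stay wide enough for stable vertical profiles: clamp the
  # strip count so each strip spans at least ~40 px
  ns <- max(4L, min(n_strips, ncol(ref) %/% 40L))
  if (rotate) {
    r1 <- tryCatch(estimate_rotation(correct1(1L), n_strips = ns),
                   error = function(e) NULL)
    if (is.null(r1)) {
      note("rotation estimation failed; assuming 0")
    } else theta <- r1$theta
    if (abs(theta) > 1e-5)
      rot_map <- rotation_map(dim(ref), -theta)
  }
  correct <- function(t) {
    f <- correct1(t)
    if (rotate_per_frame) {
      rt <- tryCatch(estimate_rotation(f, n_strips = ns),
                     error = function(e) NULL)
      if (!is.null(rt) && abs(rt$theta) > 1e-5)
        return(rotate_image(f, -rt$theta))
      return(f)
    }
    if (!is.null(rot_map)) apply_rotation_map(f, rot_map) else f
  }

  ## 3+4. per-frame geometry and cells ---------------------------------
  ## the device interval/width are stack constants: fix them from the
  ## first analysable frame, then relocalise phase/extent per frame
  g0 <- NULL
  for (t in seq_len(T_)) {
    g0 <- tryCatch(detect_channel_geometry(
      correct(t), strip_height = strip_height,
      threshold_fraction = threshold_fraction), error = function(e) NULL)
    if (!is.null(g0)) break
  }
  if (is.null(g0)) stop("channel structure not found on any frame")

  per_frame <- function(t) {
    f <- correct(t)
    g <- tryCatch(detect_channel_geometry(
      f, strip_height = strip_height,
      threshold_fraction = threshold_fraction,
      interval_px = g0$interval_px, width_px = g0$width_px),
      error = function(e) NULL)
    if (is.null(g)) return(NULL)
    crops <- extract_channels(f, g, margin_px = crop_margin_px)
    off <- attr(crops[[1L]], "row_offset")
    vp <- c(g$array_top - off, g$array_bottom - off)
    cells <- lapply(crops, function(cr)
      detect_cells(cr, detection, ps, valid_px = vp))
    list(geometry = g, cells = cells, row_offset = off)
  }
  frame_results <-
    if (workers > 1L)
      parallel::mclapply(seq_len(T_), per_frame, mc.cores = workers)
    else lapply(seq_len(T_), per_frame)

  skipped <- which(vapply(frame_results, is.null, logical(1)))
  for (t in skipped) note(sprintf("frame %d skipped: structure not found", t))

  ## stable channel identities across frames ---------------------------
  ## the device is static: identities are the reference frame's boxes;
  ## per-frame boxes that match none of them (bright non-channel device
  ## structure occasionally passing the support threshold) are spurious
  ref_lefts <- g0$channel_boxes[, 1]
  detections <- vector("list", T_)
  for (t in seq_len(T_)) {
    fr <- frame_results[[t]]
    if (is.null(fr)) next
    lefts <- fr$geometry$channel_boxes[, 1]
    m <- match_channel_ids(lefts, ref_lefts, g0$interval_px,
                           allow_new = FALSE)
    det <- list()
    for (i in seq_along(m$ids)) {
      if (m$ids[i] == 0L) next
      cells <- fr$cells[[i]]
      # report frame-absolute pixel rows
      if (nrow(cells)) {
        cells$top_px <- cells$top_px + fr$row_offset
        cells$bottom_px <- cells$bottom_px + fr$row_offset
        cells$centroid_px <- cells$centroid_px + fr$row_offset
      }
      attr(cells, "candidates") <- NULL
      det[[as.character(m$ids[i])]] <- cells
    }
    detections[[t]] <- det
  }

  ## 5. tracking -------------------------------------------------------
  lineage <- track_series(detections, series$calibration$timestamps_h,
                          tracking)

  ## fluorescence ------------------------------------------------------
  for (chn in names(series$fluor)) {
    col <- paste0("fluor_", chn)
    lineage$sightings[[col]] <- NA_real_
    for (t in seq_len(T_)) {
      ff <- series$fluor[[chn]][[t]]
      fr <- frame_results[[t]]
      if (is.null(ff) || is.null(fr)) next
      ffc <- ff
      if (any(shifts[t, ] != 0L))
        ffc <- apply_shift(ffc, -shifts[t, ])
      if (!rotate_per_frame && !is.null(rot_map))
        ffc <- apply_rotation_map(ffc, rot_map)
      rows <- which(lineage$sightings$frame == t)
      for (r in rows) {
        ch_id <- as.integer(lineage$sightings$channel[r])
        box_i <- which(match_channel_ids(
          fr$geometry$channel_boxes[, 1], ref_lefts,
          g0$interval_px)$ids == ch_id)
        if (!length(box_i)) next
        lineage$sightings[[col]][r] <- cell_fluorescence(
          lineage$sightings$top_px[r], lineage$sightings$bottom_px[r],
          box_i, ffc, fr$geometry)
      }
    }
  }

  events <- division_times(
    lineage, mu_bounds = mu_bounds,
    frame_interval_h = series$calibration$frame_interval_min / 60)

  structure(list(
    lineage = lineage, events = events, stats = division_stats(events),
    theta = theta, shifts = shifts, geometry = g0,
    frame_geometry = lapply(frame_results, function(fr)
      if (is.null(fr)) NULL else fr$geometry),
    ref_lefts = ref_lefts, skipped_frames = skipped,
    counters = c(frames = T_, frames_analyzed = T_ - length(skipped),
                 channels = length(ref_lefts),
                 sightings = nrow(lineage$sightings),
                 tracks = nrow(lineage$tracks),
                 divisions = nrow(lineage$divisions)),
    mu_bounds = mu_bounds, detection = detection, tracking = tracking,
    calibration = series$calibration, position = series$position,
    crop_margin_px = crop_margin_px, warnings = warnings),
    class = "mm_analysis")
}

#' @export
print.mm_analysis <- function(x, ...) {
  cat("<mm_analysis> position", x$position, "\n")
  cat(sprintf("  frames: %d analyzed / %d total; rotation %.2f deg\n",
              x$counters[["frames_analyzed"]], x$counters[["frames"]],
              x$theta * 180 / pi))
  cat(sprintf("  channels: %d | sightings: %d | tracks: %d | divisions: %d\n",
              x$counters[["channels"]], x$counters[["sightings"]],
              x$counters[["tracks"]], x$counters[["divisions"]]))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
summary.mm_analysis <- function(object, ...) {
  print(object)
  st <- object$stats
  if (st$n_events) {
    cat(sprintf(paste0("  division time: %.2f +/- %.2f h (n = %d, mu in ",
                       "[%.2f, %.2f] 1/h)\n  growth rate: %.2f 1/h\n"),
                st$mean_td_h, st$sd_td_h, st$n_events,
                object$mu_bounds[1], object$mu_bounds[2], st$mu_per_h))
  } else cat("  no division events within the growth-rate bounds\n")
  invisible(st)
}

#' Recompute the corrected crops of one channel
#'
#' Re-applies the stored registration and rotation to the original series
#' and crops the given channel on every analysable frame; used by the
#' kymograph plot so that the analysis object does not need to retain
#' full corrected frames.
#'
#' @param x an `mm_analysis`.
#' @param series the frame series that was analyzed (after any stride).
#' @param channel stable channel id.
#' @return list with `crops` and the corresponding `frames` indices.
#' @export
channel_crops <- function(x, series, channel) {
  T_ <- length(series$frames)
  rot_map <- if (abs(x$theta) > 1e-5)
    rotation_map(dim(series$frames[[1]]), -x$theta) else NULL
  crops <- list(); frames <- integer(0)
  # fixed-size crops aligned to the reference geometry for tidy tiling
  xl <- round(x$ref_lefts[channel])
  xr <- xl + x$geometry$width_px
  top <- max(0L, x$geometry$array_top - x$crop_margin_px)
  bottom <- x$geometry$array_bottom
  for (t in seq_len(T_)) {
    g <- x$frame_geometry[[t]]
    if (is.null(g)) next
    ids <- match_channel_ids(g$channel_boxes[, 1], x$ref_lefts,
                             x$geometry$interval_px)$ids
    if (!any(ids == channel)) next
    f <- series$frames[[t]]
    if (any(x$shifts[t, ] != 0L)) f <- apply_shift(f, -x$shifts[t, ])
    if (!is.null(rot_map)) f <- apply_rotation_map(f, rot_map)
    crops[[length(crops) + 1L]] <-
      f[(top + 1L):bottom, (xl + 1L):xr, drop = FALSE]
    frames <- c(frames, t)
  }
  list(crops = crops, frames = frames, row_offset = top)
}

#' Kymograph plot of an analysed channel
#'
#' @param x an `mm_analysis`.
#' @param series the analysed frame series.
#' @param channel stable channel id to draw.
#' @param path optional PNG path.
#' @param ... ignored.
#' @export
plot.mm_analysis <- function(x, series, channel = 1L, path = NULL, ...) {
  cc <- channel_crops(x, series, channel)
  lin <- x$lineage
  # kymograph works in crop coordinates
  lin$sightings$centroid_px <- lin$sightings$centroid_px - cc$row_offset
  render_kymograph(cc$crops, lin, as.character(channel),
                   frames = cc$frames, path = path)
}
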