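#' Single-cell read-outs from a tracked lineage
#'
#' Division times, growth rates, precision/recall against reference
#' division annotations, background-corrected fluorescence, tabular
#' export and kymograph rendering.
#'
#' @name quantify
NULL

#' Growth rate from doubling time
#'
#' `mu = ln(2) / t_d`, the exponential growth rate corresponding to a
#' doubling time, in reciprocal hours when `t_d` is in hours.
#'
#' @param mean_td_h doubling time(s) in hours, > 0.
#' @return growth rate(s) per hour.
#' @export
growth_rate <- function(mean_td_h) {
  if (any(!is.finite(mean_td_h)) || any(mean_td_h <= 0))
    stop("doubling time must be positive and finite")
  log(2) / mean_td_h
}

#' Division events with division times
#'
#' One event per division whose parent was itself born in an observed
#' division: the division time is the time between the two divisions on
#' that lineage path (equivalently, parent birth to parent division).
#' Tracks that appear de novo - at the start of the series or mid-series -
#' have an unobserved birth, so their (first) division carries no division
#' time and contributes no event; this avoids biasing the statistics with
#' censored intervals.
#'
#' Events are filtered to physiological growth-rate bounds: an event with
#' implied `mu = ln(2) / t_d` outside `mu_bounds` is an artifact (e.g. a
#' spurious split or a track mix-up) and is excluded.
#'
#' @param lineage an `mm_lineage` from [track_series()].
#' @param mu_bounds lower/upper growth-rate bounds per hour
#'   (default `c(0.01, 1.0)`).
#' @param frame_interval_h frame interval in hours; when supplied, the
#'   event's division age is also reported in frames.
#' @return data frame of class `mm_division_events`: channel, frame,
#'   time_h, parent_track, birth_frame, division_time_h, mu_per_h,
#'   age_frames (when the interval is known), daughter lengths.
#' @export
division_times <- function(lineage, mu_bounds = c(0.01, 1.0),
                           frame_interval_h = NULL) {
  dv <- lineage$divisions
  tk <- lineage$tracks
  out <- data.frame(channel = character(0), frame = integer(0),
                    time_h = numeric(0), parent_track = integer(0),
                    birth_frame = integer(0), division_time_h = numeric(0),
                    mu_per_h = numeric(0), age_frames = numeric(0),
                    d1_length_um = numeric(0), d2_length_um = numeric(0))
  if (!nrow(dv)) return(structure(out, class = c("mm_division_events",
                                                 class(out))))
  pt <- match(dv$parent_track, tk$track_id)
  born_by_division <- !is.na(tk$parent_id[pt])
  birth_frame <- tk$start_frame[pt]
  birth_time <- lineage$timestamps_h[birth_frame]
  dt_h <- lineage$timestamps_h[dv$frame] - birth_time
  keep <- born_by_division & dt_h > 0
  mu <- ifelse(dt_h > 0, log(2) / dt_h, NA_real_)
  keep <- keep & mu >= mu_bounds[1] & mu <= mu_bounds[2]
  out <- data.frame(channel = dv$channel, frame = dv$frame,
                    time_h = lineage$timestamps_h[dv$frame],
                    parent_track = dv$parent_track,
                    birth_frame = birth_frame,
                    division_time_h = dt_h, mu_per_h = mu,
                    age_frames = if (is.null(frame_interval_h)) NA_real_
                                 else dt_h / frame_interval_h,
                    d1_length_um = dv$d1_length_um,
                    d2_length_um = dv$d2_length_um)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mm_division_events", class(out)))
}

#' Summary statistics of division times
#'
#' @param events an `mm_division_events` data frame.
#' @return list with `mean_td_h`, `sd_td_h`, `n_events` and
#'   `mu_per_h = ln(2) / mean_td_h`.
#' @export
division_stats <- function(events) {
  n <- nrow(events)
  m <- if (n) mean(events$division_time_h) else NA_real_
  list(mean_td_h = m,
       sd_td_h = if (n > 1) stats::sd(events$division_time_h) else NA_real_,
       n_events = n,
       mu_per_h = if (n) growth_rate(m) else NA_real_)
}

#' Pair automated against reference division events
#'
#' Greedy one-to-one matching by ascending Manhattan distance in the
#' (occurrence frame, division age in frames) plane; pairs differing by
#' more than `max_offset_frames` in either coordinate are not allowed.
#' Precision is the matched fraction of automated events, recall the
#' matched fraction of reference events.
#'
#' @param auto,reference data frames with columns `frame` and
#'   `age_frames` (events from [division_times()] work directly).
#' @param max_offset_frames maximum per-coordinate offset.
#' @return list with `precision`, `recall` (NA when `reference` is
#'   empty), `n_matched`, and the matched index pairs.
#' @export
pair_events <- function(auto, reference, max_offset_frames = 2) {
  na <- nrow(auto); nr <- nrow(reference)
  if (!na || !nr)
    return(list(precision = if (na) 0 else NA_real_,
                recall = if (nr) 0 else NA_real_,
                n_matched = 0L, pairs = cbind(auto = integer(0),
                                              reference = integer(0))))
  df <- abs(outer(auto$frame, reference$frame, "-"))
  da <- abs(outer(auto$age_frames, reference$age_frames, "-"))
  ok <- df <= max_offset_frames & da <= max_offset_frames
  dist <- df + da
  cand <- which(ok, arr.ind = TRUE)
  cand <- cand[order(dist[cand], cand[, 1], cand[, 2]), , drop = FALSE]
  used_a <- logical(na); used_r <- logical(nr)
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; r <- cand[i, 2]
    if (used_a[a] || used_r[r]) next
    used_a[a] <- TRUE; used_r[r] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(a, r)
  }
  m <- length(pairs)
  list(precision = m / na, recall = m / nr, n_matched = m,
       pairs = if (m) do.call(rbind, pairs) else
         cbind(auto = integer(0), reference = integer(0)))
}

#' Moving-average growth-rate curve over division events
#'
#' Per-event growth rates `ln(2) / t_d` are averaged with a centred moving
#' window over the time-ordered events. The curve is undefined (NA)
#' wherever a time bin produced fewer than `min_events` division events:
#' sparse stretches would otherwise show spurious rates driven by single
#' artifacts.
#'
#' @param events an `mm_division_events` data frame.
#' @param window moving-average window in events (default 25).
#' @param min_events minimum events per time bin for the curve to be
#'   defined there (default 5).
#' @param bin_h time bin width in hours.
#' @return data frame with `time_h`, `mu_per_h` (per event) and `mu_ma`
#'   (moving average, NA where undefined).
#' @export
growth_rate_curve <- function(events, window = 25L, min_events = 5L,
                              bin_h = 1) {
  ev <- events[order(events$time_h), ]
  n <- nrow(ev)
  ma <- rep(NA_real_, n)
  if (n >= window) {
    ma <- stats::filter(ev$mu_per_h, rep(1 / window, window), sides = 2)
    ma <- as.numeric(ma)
  }
  bins <- floor(ev$time_h / bin_h)
  counts <- table(bins)
  ma[counts[as.character(bins)] < min_events] <- NA_real_
  data.frame(time_h = ev$time_h, mu_per_h = ev$mu_per_h, mu_ma = ma)
}

#' Background-corrected cell fluorescence
#'
#' Mean fluorescence over the cell's rectangular bounding box (channel
#' box columns by the cell's row extent) minus the background, measured
#' as the mean over stripes between the growth channels - the central
#' half of each inter-channel gap, restricted to the same rows - so that
#' device autofluorescence is removed without touching channel interiors.
#'
#' @param top_px,bottom_px cell extent, 0-based half-open frame rows.
#' @param channel index of the cell's channel box in `geometry`.
#' @param fluor_frame fluorescence image (matrix, same geometry as the
#'   corrected frame).
#' @param geometry an `mm_channel_geometry`.
#' @return background-corrected mean intensity (scalar).
#' @export
cell_fluorescence <- function(top_px, bottom_px, channel, fluor_frame,
                              geometry) {
  rows <- (top_px + 1L):bottom_px
  rows <- rows[rows >= 1L & rows <= nrow(fluor_frame)]
  b <- geometry$channel_boxes[channel, ]
  cell <- mean(fluor_frame[rows, (b[1] + 1L):b[2]])
  boxes <- geometry$channel_boxes
  bg <- c()
  for (i in seq_len(nrow(boxes) - 1L)) {
    gl <- boxes[i, 2]; gr <- boxes[i + 1L, 1]
    gw <- gr - gl
    if (gw < 4L) next
    x0 <- gl + floor(gw / 4); x1 <- gr - floor(gw / 4)
    bg <- c(bg, fluor_frame[rows, (x0 + 1L):x1])
  }
  cell - if (length(bg)) mean(bg) else 0
}

#' Export per-sighting results as a TSV table
#'
#' One row per cell sighting: position, channel, 1-based frame, time,
#' track and parent identifiers, pixel extent, physical length, the
#' detection scores, fluorescence values where present, and the track's
#' final fate. Columns are stable; an empty lineage yields a header-only
#' file.
#'
#' @param lineage an `mm_lineage`.
#' @param path output file path.
#' @param position position label recorded in every row.
#' @return `path`, invisibly.
#' @export
export_table <- function(lineage, path, position = "pos1") {
  s <- lineage$sightings
  fate <- lineage$tracks$fate[match(s$track_id, lineage$tracks$track_id)]
  cols <- c("frame", "time_h", "channel", "track_id", "parent_id",
            "top_px", "bottom_px", "length_um", "blackness", "prominence")
  extra <- setdiff(names(s), c(cols, "centroid_px"))
  out <- cbind(data.frame(position = rep(position, nrow(s))),
               s[, intersect(cols, names(s)), drop = FALSE],
               s[, extra, drop = FALSE],
               data.frame(fate = if (nrow(s)) fate else character(0)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Render a kymograph of one channel
#'
#' Concatenates the channel's crops over time side by side and overlays
#' each track as a polyline through its sighting centroids, one colour
#' per track; division events are marked at the parent's last centroid.
#'
#' @param crops list of channel crop matrices, one per frame (equal
#'   dimensions).
#' @param lineage an `mm_lineage` (only the sightings/divisions of
#'   `channel` are drawn).
#' @param channel channel id to draw.
#' @param frames frame indices corresponding to `crops` (defaults to
#'   `seq_along(crops)`).
#' @param path optional PNG output path; when `NULL`, draws on the
#'   current graphics device.
#' @param scale display magnification.
#' @return the montage matrix, invisibly.
#' @export
render_kymograph <- function(crops, lineage, channel,
                             frames = seq_along(crops), path = NULL,
                             scale = 2) {
  stopifnot(length(crops) >= 1L)
  h <- nrow(crops[[1]]); w <- ncol(crops[[1]])
  montage <- do.call(cbind, crops)
  montage <- pmin(pmax(montage, 0), 1)
  if (!is.null(path))
    grDevices::png(path, width = ncol(montage) * scale,
                   height = h * scale)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); if (!is.null(path)) grDevices::dev.off() })
  graphics::plot(NA, xlim = c(0, ncol(montage)), ylim = c(h, 0),
                 xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(montage), 0, h,
                        ncol(montage), 0, interpolate = FALSE)
  s <- lineage$sightings
  s <- s[s$channel == channel & s$frame %in% frames, , drop = FALSE]
  if (nrow(s)) {
    tile <- match(s$frame, frames) - 1L
    xs <- tile * w + w / 2
    ids <- unique(s$track_id)
    cols <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")
    for (i in seq_along(ids)) {
      si <- s[s$track_id == ids[i], ]
      o <- order(si$frame)
      graphics::lines(xs[s$track_id == ids[i]][o],
                      si$centroid_px[o], col = cols[i], lwd = 2)
    }
    dv <- lineage$divisions
    dv <- dv[dv$channel == channel & dv$frame %in% frames, , drop = FALSE]
    if (nrow(dv)) {
      last <- s[match(dv$parent_track, s$track_id), ] # any sighting row
      for (r in seq_len(nrow(dv))) {
        sp <- s[s$track_id == dv$parent_track[r], ]
        if (!nrow(sp)) next
        sp <- sp[which.max(sp$frame), ]
        graphics::points((match(sp$frame, frames) - 1L) * w + w / 2,
                         sp$centroid_px, pch = 8, col = "white", cex = 1.2)
      }
    }
  }
  invisible(montage)
}
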