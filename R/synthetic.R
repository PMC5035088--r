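#' Synthetic mother machine scenes with full ground truth
#'
#' Renders time-lapse stacks that emulate the phase-contrast appearance of
#' a mother machine array: bright, evenly spaced vertical growth channels
#' on a darker device background, dark rod-shaped cells stacked without
#' overlap inside the channels, exponential single-cell elongation with
#' threshold-triggered division, push-out at the open channel end, global
#' frame drift, a small global rotation, smooth uneven illumination and
#' additive Gaussian noise. Every stochastic choice derives from the scene
#' seed, and the generator records complete ground truth (geometry,
#' per-frame cell extents, lineage, drift, rotation), so each pipeline
#' stage can be validated without external data.
#'
#' The optics are deliberately simple - a three-level intensity model plus
#' a 1 px Gaussian blur; phase-contrast halos are not modelled - because
#' the profile-based algorithms only rely on channels being brighter than
#' the device and cells darker than the channel.
#'
#' @name synthetic-scenes
NULL

#' Scene configuration
#'
#' Defaults describe a 20-channel array imaged every 5 minutes for 240
#' frames at 0.065 um/px, with mild drift, a 0.5 degree chip rotation, 4%
#' additive noise and a 10% illumination gradient.
#'
#' @param W,H image size in pixels.
#' @param n_channels number of growth channels.
#' @param interval_px channel interval `i_C` (px).
#' @param width_px channel width `w_C` (px).
#' @param phase_px x-position of the first channel's left flank (px).
#' @param array_top,array_bottom 0-based half-open row extent of the array.
#' @param closed_end `"top"`: the mother cell sits at the top dead end.
#' @param end_gap_um bright medium pocket between the dead-end wall and
#'   the mother cell (um); real mothers do not touch the wall, and the
#'   pocket gives the mother's top boundary its profile maximum.
#' @param rotation_deg global scene rotation (degrees).
#' @param drift `NULL` for a seeded bounded random walk, otherwise a `T x 2`
#'   matrix of integer per-frame (dx, dy) displacements.
#' @param drift_step_px,drift_max_px random-walk step s.d. and bound (px).
#' @param noise_sigma additive Gaussian noise s.d. as a fraction of the
#'   dynamic range.
#' @param illumination_amplitude relative amplitude of the smooth
#'   illumination plane.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_min minutes between frames.
#' @param T_frames number of frames.
#' @param seed integer seed fixing all randomness of the scene.
#' @return list of class `mm_scene_config`.
#' @export
scene_config <- function(W = 660L, H = 360L, n_channels = 20L,
                         interval_px = 30L, width_px = 10L, phase_px = 17L,
                         array_top = 80L, array_bottom = 280L,
                         closed_end = "top", end_gap_um = 0.35,
                         rotation_deg = 0.5,
                         drift = NULL, drift_step_px = 0.3, drift_max_px = 8L,
                         noise_sigma = 0.04, illumination_amplitude = 0.1,
                         pixel_size_um = 0.065, frame_interval_min = 5,
                         T_frames = 240L, seed = 1L) {
  stopifnot(width_px < interval_px,
            phase_px + n_channels * interval_px <= W + interval_px - width_px,
            array_top < array_bottom, array_bottom <= H)
  structure(as.list(environment()), class = "mm_scene_config")
}

# Truncated normal around 0.5: division asymmetry of binary fission.
rasym <- function(n, sd = 0.05, lo = 0.35, hi = 0.65) {
  pmin(hi, pmax(lo, stats::rnorm(n, 0.5, sd)))
}

#' Simulate a mother machine lineage
#'
#' Per channel, the mother cell elongates exponentially at rate
#' `ln(2) / doubling_time_h` (with per-cell rate jitter) and divides once
#' it reaches its division length threshold (drawn per cell around
#' `division_length_um`); daughters split the length at a ratio sampled
#' around 0.5 and stack towards the open end, separated by a small visible
#' constriction gap. Cells whose extent passes the open end are removed
#' and recorded as flushed. All randomness derives from `config$seed`
#' (already applied by [generate_stack()]; call `set.seed` yourself when
#' using this function directly).
#'
#' @param config a [scene_config()].
#' @param doubling_time_h scripted doubling time (hours).
#' @param division_length_um mean division length threshold (um).
#' @param length_sd_um s.d. of the per-cell division threshold (um).
#' @param gap_um inter-cell constriction gap (um).
#' @param asym_sd s.d. of the division asymmetry ratio.
#' @param rate_cv coefficient of variation of per-cell elongation rates.
#' @return list with `states` (per-frame data frames: channel, cell_id,
#'   parent_id, top_um, length_um), `divisions`, `flushed` and the scripted
#'   parameters.
#' @export
simulate_lineage <- function(config, doubling_time_h = 1.3,
                             division_length_um = 3.0, length_sd_um = 0.2,
                             gap_um = 0.25, asym_sd = 0.05, rate_cv = 0.05) {
  stopifnot(doubling_time_h >= 0)
  ps <- config$pixel_size_um
  chan_len_um <- (config$array_bottom - config$array_top) * ps -
    config$end_gap_um
  dt_h <- config$frame_interval_min / 60
  mu0 <- if (doubling_time_h > 0) log(2) / doubling_time_h else 0
  next_id <- 0L
  new_cell <- function(channel, length, parent = NA_integer_) {
    next_id <<- next_id + 1L
    list(id = next_id, channel = channel, length = length, parent = parent,
         rate = mu0 * max(0, 1 + stats::rnorm(1, 0, rate_cv)),
         thresh = max(division_length_um / 2,
                      division_length_um + stats::rnorm(1, 0, length_sd_um)))
  }
  cells <- lapply(seq_len(config$n_channels), function(ch)
    list(new_cell(ch, stats::runif(1, 0.55, 0.95) * division_length_um)))
  divisions <- list(); flushed <- list(); states <- vector("list", config$T_frames)

  snapshot <- function(frame) {
    do.call(rbind, lapply(cells, function(chn) {
      if (!length(chn)) return(NULL)
      tops <- cumsum(c(0, vapply(chn, `[[`, 0, "length")[-length(chn)] + gap_um))
      data.frame(frame = frame,
                 channel = vapply(chn, `[[`, 0L, "channel"),
                 cell_id = vapply(chn, `[[`, 0L, "id"),
                 parent_id = vapply(chn, `[[`, NA_integer_, "parent"),
                 top_um = tops,
                 length_um = vapply(chn, `[[`, 0, "length"))
    }))
  }

  states[[1L]] <- snapshot(1L)
  for (t in seq_len(config$T_frames)[-1L]) {
    for (ch in seq_along(cells)) {
      chn <- cells[[ch]]
      if (!length(chn)) next
      out <- list()
      for (cell in chn) {
        cell$length <- cell$length * exp(cell$rate * dt_h)
        if (doubling_time_h > 0 && cell$length >= cell$thresh) {
          r <- rasym(1, asym_sd)
          d1 <- new_cell(ch, r * cell$length, cell$id)
          d2 <- new_cell(ch, (1 - r) * cell$length, cell$id)
          divisions[[length(divisions) + 1L]] <-
            data.frame(frame = t, channel = ch, parent_id = cell$id,
                       d1 = d1$id, d2 = d2$id,
                       parent_length_um = cell$length,
                       d1_length_um = d1$length, d2_length_um = d2$length,
                       observable = TRUE)
          out <- c(out, list(d1), list(d2))
        } else out <- c(out, list(cell))
      }
      # restack from the dead end; flush cells protruding past the open end
      tops <- cumsum(c(0, vapply(out, `[[`, 0, "length")[-length(out)] + gap_um))
      keep <- tops + vapply(out, `[[`, 0, "length") <= chan_len_um
      if (any(!keep))
        flushed[[length(flushed) + 1L]] <-
          data.frame(frame = t, channel = ch,
                     cell_id = vapply(out[!keep], `[[`, 0L, "id"))
      cells[[ch]] <- out[keep]
      # a division whose daughter is flushed in the same step is never
      # rendered as a two-cell configuration: mark it unobservable
      if (length(divisions)) {
        lastd <- divisions[[length(divisions)]]
        if (all(lastd$frame == t)) {
          ids <- vapply(cells[[ch]], `[[`, 0L, "id")
          for (li in seq_along(divisions)) {
            dd <- divisions[[li]]
            if (dd$frame == t && dd$channel == ch)
              divisions[[li]]$observable <-
                dd$d1 %in% ids && dd$d2 %in% ids
          }
        }
      }
    }
    states[[t]] <- snapshot(t)
  }
  list(states = states,
       divisions = if (length(divisions)) do.call(rbind, divisions)
                   else data.frame(frame = integer(0), channel = integer(0),
                                   parent_id = integer(0), d1 = integer(0),
                                   d2 = integer(0), parent_length_um = numeric(0),
                                   d1_length_um = numeric(0), d2_length_um = numeric(0),
                                   observable = logical(0)),
       flushed = if (length(flushed)) do.call(rbind, flushed)
                 else data.frame(frame = integer(0), channel = integer(0),
                                 cell_id = integer(0)),
       doubling_time_h = doubling_time_h,
       division_length_um = division_length_um, gap_um = gap_um)
}

#' Ground-truth channel boxes of a synthetic scene
#'
#' @param config a [scene_config()].
#' @return matrix of 0-based half-open `[x_left, x_right)` column
#'   intervals, one row per channel.
#' @export
scene_boxes <- function(config) {
  lefts <- config$phase_px + (seq_len(config$n_channels) - 1L) * config$interval_px
  cbind(x_left = lefts, x_right = lefts + config$width_px)
}

#' Render one frame of a synthetic scene
#'
#' Paints the three-level scene (device background, bright channel
#' stripes, dark cells), blurs it with a 1 px Gaussian so profiles have
#' realistic extrema, then applies rotation, drift, the illumination
#' gradient and additive noise, in that order, and quantises to the 16-bit
#' grid. Noise is drawn from the current RNG stream.
#'
#' Besides the channels themselves, two static device features of
#' phase-contrast MM images are reproduced because the profile
#' algorithms rely on them: the bright halo lines at the channel walls
#' (PDMS-medium interface) and the bright nutrient feed trench running
#' across the open channel ends. Cells are drawn narrower than the
#' channel lumen with bright medium showing alongside, as in real
#' phase-contrast data, so the wall halos are never occluded.
#'
#' @param state data frame of cells for this frame (as in
#'   `simulate_lineage()$states`), or `NULL` for an empty device.
#' @param config a [scene_config()].
#' @param drift_xy integer `c(dx, dy)` displacement for this frame.
#' @param levels intensity levels
#'   `c(device, channel, cell, halo, trench)`.
#' @return numeric matrix in `[0, 1]`.
#' @export
render_frame <- function(state, config, drift_xy = c(0L, 0L),
                         levels = c(device = 0.35, channel = 0.62,
                                    cell = 0.22, halo = 0.75, trench = 0.7)) {
  ps <- config$pixel_size_um
  img <- matrix(levels[["device"]], config$H, config$W)
  rows <- (config$array_top + 1L):config$array_bottom
  boxes <- scene_boxes(config)
  tr_top <- config$array_bottom + 12L
  if (tr_top + 30L <= config$H)
    img[(tr_top + 1L):(tr_top + 30L), ] <- levels[["trench"]]
  for (i in seq_len(nrow(boxes))) {
    img[rows, (boxes[i, 1] + 1L):boxes[i, 2]] <- levels[["channel"]]
    # wall halos on the innermost lumen columns; never occluded by cells
    img[rows, boxes[i, 1] + 1L] <- levels[["halo"]]
    img[rows, boxes[i, 2]] <- levels[["halo"]]
  }
  if (!is.null(state) && nrow(state)) {
    gap0 <- round(config$end_gap_um / ps)
    for (i in seq_len(nrow(state))) {
      top <- config$array_top + gap0 + round(state$top_um[i] / ps)
      bot <- config$array_top + gap0 +
        round((state$top_um[i] + state$length_um[i]) / ps)
      top <- max(top, config$array_top); bot <- min(bot, config$array_bottom)
      if (bot <= top) next
      b <- boxes[state$channel[i], ]
      img[(top + 1L):bot, (b[1] + 2L):(b[2] - 1L)] <- levels[["cell"]]
    }
  }
  img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = 1)), nrow(img))
  if (config$rotation_deg != 0)
    img <- rotate_image(img, config$rotation_deg * pi / 180,
                        fill = levels[["device"]])
  if (any(drift_xy != 0L))
    img <- apply_shift(img, drift_xy, fill = levels[["device"]])
  if (config$illumination_amplitude != 0) {
    gx <- (seq_len(config$W) / config$W - 0.5)
    gy <- (seq_len(config$H) / config$H - 0.5)
    plane <- 1 + config$illumination_amplitude *
      (outer(gy, gx, function(y, x) 1.6 * x + 0.4 * y))
    img <- img * plane
  }
  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sigma),
                        nrow(img))
  round(pmin(pmax(img, 0), 1) * 65535) / 65535
}

#' Generate a complete synthetic stack with ground truth
#'
#' Seeds the RNG from `config$seed`, simulates the lineage, draws the drift
#' trajectory (bounded random walk unless supplied), renders every frame
#' and optionally a sparser fluorescence channel, and wraps the result as a
#' [frame_series()] plus a ground-truth record.
#'
#' The optional fluorescence channel emulates a biosensor read-out: frames
#' are acquired every `period_frames` frames only, each cell's bounding box
#' is painted at an intensity drawn around `level_growth` before
#' `switch_frame` and around `level_production` after it, on top of a
#' uniform device autofluorescence `background` (arbitrary units).
#'
#' @param config a [scene_config()].
#' @param doubling_time_h scripted doubling time (hours); see
#'   [simulate_lineage()] for the remaining kinetic parameters.
#' @param division_length_um,length_sd_um,gap_um,asym_sd,rate_cv passed to
#'   [simulate_lineage()].
#' @param fluor `NULL`, or a list with elements `period_frames`,
#'   `switch_frame`, `level_growth`, `sd_growth`, `level_production`,
#'   `sd_production`, `background`, `noise_sd`.
#' @return list with `series` (an `mm_frame_series`) and `truth` (states,
#'   divisions, flushed, drift, geometry, scripted parameters, and - when a
#'   fluorescence channel was rendered - the per-sighting scripted values).
#' @export
generate_stack <- function(config, doubling_time_h = 1.3,
                           division_length_um = 3.0, length_sd_um = 0.2,
                           gap_um = 0.25, asym_sd = 0.05, rate_cv = 0.05,
                           fluor = NULL) {
  set.seed(config$seed)
  sim <- simulate_lineage(config, doubling_time_h, division_length_um,
                          length_sd_um, gap_um, asym_sd, rate_cv)
  T_ <- config$T_frames
  drift <- config$drift
  if (is.null(drift)) {
    step <- function() pmin(config$drift_max_px,
                            pmax(-config$drift_max_px,
                                 round(cumsum(stats::rnorm(T_, 0, config$drift_step_px)))))
    drift <- cbind(dx = step(), dy = step())
    drift[1L, ] <- 0L
  }
  frames <- lapply(seq_len(T_), function(t)
    render_frame(sim$states[[t]], config, drift[t, ]))

  fluor_frames <- list(); fluor_truth <- NULL
  if (!is.null(fluor)) {
    sched <- seq(1L, T_, by = fluor$period_frames)
    slots <- vector("list", T_)
    boxes <- scene_boxes(config)
    ps <- config$pixel_size_um
    vals <- list()
    for (t in sched) {
      img <- matrix(fluor$background, config$H, config$W)
      st <- sim$states[[t]]
      if (!is.null(st) && nrow(st)) {
        lv <- if (t >= fluor$switch_frame)
          c(fluor$level_production, fluor$sd_production)
        else c(fluor$level_growth, fluor$sd_growth)
        v <- pmax(0, stats::rnorm(nrow(st), lv[1], lv[2]))
        vals[[length(vals) + 1L]] <-
          data.frame(frame = t, channel = st$channel, cell_id = st$cell_id,
                     value = v)
        gap0 <- round(config$end_gap_um / ps)
        for (i in seq_len(nrow(st))) {
          top <- config$array_top + gap0 + round(st$top_um[i] / ps)
          bot <- config$array_top + gap0 +
            round((st$top_um[i] + st$length_um[i]) / ps)
          top <- max(top, config$array_top); bot <- min(bot, config$array_bottom)
          if (bot <= top) next
          b <- boxes[st$channel[i], ]
          img[(top + 1L):bot, (b[1] + 1L):b[2]] <-
            img[(top + 1L):bot, (b[1] + 1L):b[2]] + v[i]
        }
      }
      img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = 1)), nrow(img))
      if (config$rotation_deg != 0)
        img <- rotate_image(img, config$rotation_deg * pi / 180,
                            fill = fluor$background)
      if (any(drift[t, ] != 0L))
        img <- apply_shift(img, drift[t, ], fill = fluor$background)
      if (fluor$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, fluor$noise_sd),
                            nrow(img))
      slots[[t]] <- img
    }
    fluor_frames <- list(fl = slots)
    fluor_truth <- list(schedule = sched, values = do.call(rbind, vals),
                        params = fluor)
  }

  series <- frame_series(frames, config$pixel_size_um,
                         frame_interval_min = config$frame_interval_min,
                         fluor = fluor_frames, position = "synthetic")
  truth <- list(states = sim$states, divisions = sim$divisions,
                flushed = sim$flushed, drift = drift,
                rotation_deg = config$rotation_deg,
                geometry = list(boxes = scene_boxes(config),
                                array_top = config$array_top,
                                array_bottom = config$array_bottom,
                                interval_px = config$interval_px,
                                width_px = config$width_px,
                                phase_px = config$phase_px),
                doubling_time_h = doubling_time_h,
                division_length_um = division_length_um,
                config = config, fluor = fluor_truth)
  list(series = series, truth = truth)
}
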