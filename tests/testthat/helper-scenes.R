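# Small scene factories shared by the tests. Unit tests use compact
# arrays so each test stays fast; the acceptance suite uses the full-size
# defaults.

small_config <- function(..., seed = 1L) {
  defaults <- list(W = 280L, H = 220L, n_channels = 8L, interval_px = 30L,
                   width_px = 10L, phase_px = 17L, array_top = 50L,
                   array_bottom = 180L, T_frames = 1L, rotation_deg = 0,
                   drift = matrix(0L, 1, 2), noise_sigma = 0.02,
                   illumination_amplitude = 0.05, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  if (!("drift" %in% names(list(...))))
    args$drift <- matrix(0L, args$T_frames, 2L)
  do.call(scene_config, args)
}

# a single rendered, drift/rotation-free frame plus its config
static_frame <- function(with_cells = FALSE, seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  keep <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  state <- NULL
  if (with_cells) {
    set.seed(seed)
    state <- simulate_lineage(cfg, doubling_time_h = 1.3)$states[[1L]]
  }
  set.seed(seed + 1000L)
  img <- render_frame(state, cfg)
  if (!is.null(keep)) assign(".Random.seed", keep, globalenv())
  list(img = img, cfg = cfg, state = state)
}

# ground-truth 0-based pixel extents of the cells of one channel
truth_extents <- function(cfg, state, channel) {
  ps <- cfg$pixel_size_um
  gap0 <- round(cfg$end_gap_um / ps)
  tr <- state[state$channel == channel, , drop = FALSE]
  cbind(top = cfg$array_top + gap0 + round(tr$top_um / ps),
        bottom = cfg$array_top + gap0 +
          round((tr$top_um + tr$length_um) / ps))
}

# Channel crop rendered inside a normal multi-channel array (frequency-
# domain structure detection needs several comb teeth): the given cells
# (um extents from the channel top) are painted into channel 1; truth is
# returned in crop pixel coordinates.
render_channel_crop <- function(cells_um, noise_sigma = 0.02, seed = 1L) {
  sc <- render_channel_scene(list(cells_um), noise_sigma = noise_sigma,
                             seed = seed)
  list(crop = sc$crops[[1]], truth = sc$truth[[1]], cfg = sc$cfg,
       valid_px = sc$valid_px)
}

# Multi-channel variant: cells_list gives the cell extents per channel;
# channels beyond the list stay empty (synchronised identical content in
# every channel would be unphysical and degenerate).
render_channel_scene <- function(cells_list, noise_sigma = 0.02,
                                 seed = 1L) {
  cfg <- small_config(seed = seed, noise_sigma = noise_sigma,
                      H = 260L, array_bottom = 220L)
  rows <- list()
  for (ch in seq_len(cfg$n_channels)) {
    if (ch > length(cells_list)) next
    cu <- cells_list[[ch]]
    if (is.null(cu) || !nrow(cu)) next
    rows[[length(rows) + 1L]] <-
      data.frame(frame = 1L, channel = ch,
                 cell_id = seq_len(nrow(cu)), parent_id = NA_integer_,
                 top_um = cu[, 1], length_um = cu[, 2] - cu[, 1])
  }
  state <- if (length(rows)) do.call(rbind, rows) else NULL
  keep <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  img <- render_frame(state, cfg)
  if (!is.null(keep)) assign(".Random.seed", keep, globalenv()) # do not leak the reset
  # crops from the scripted geometry: these scenes isolate the cell
  # detection stage; geometry recovery is validated on its own scenes
  g <- structure(list(array_top = cfg$array_top,
                      array_bottom = cfg$array_bottom,
                      interval_px = cfg$interval_px,
                      width_px = cfg$width_px, phase_px = cfg$phase_px,
                      channel_boxes = scene_boxes(cfg),
                      W = cfg$W, H = cfg$H),
                 class = "mm_channel_geometry")
  crops <- extract_channels(img, g)
  off <- attr(crops[[1]], "row_offset")
  ps <- cfg$pixel_size_um
  gap0 <- round(cfg$end_gap_um / ps)
  truth <- lapply(seq_len(cfg$n_channels), function(ch) {
    cu <- if (ch > length(cells_list)) NULL else cells_list[[ch]]
    if (is.null(cu) || !nrow(cu))
      return(cbind(top = integer(0), bottom = integer(0)))
    cbind(top = cfg$array_top + gap0 + round(cu[, 1] / ps) - off,
          bottom = cfg$array_top + gap0 + round(cu[, 2] / ps) - off)
  })
  list(crops = crops, truth = truth, cfg = cfg, geometry = g,
       valid_px = c(g$array_top - off, g$array_bottom - off))
}
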