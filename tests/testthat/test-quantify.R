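# hand-built lineage: track 1 (de novo, frame 1) divides at frame 5 into
# tracks 2+3; track 2 divides again at frame 9; timestamps in hours
toy_lineage <- function(interval_h = 0.25) {
  ts <- (0:11) * interval_h
  tracks <- data.frame(
    track_id = 1:5,
    channel = "1",
    parent_id = c(NA, 1L, 1L, 2L, 2L),
    start_frame = c(1L, 5L, 5L, 9L, 9L),
    end_frame = c(5L, 9L, 12L, 12L, 12L),
    fate = c("division", "division", "end", "end", "end"))
  divisions <- data.frame(
    channel = "1", frame = c(5L, 9L), time_h = ts[c(5, 9)],
    parent_track = c(1L, 2L), daughter1 = c(2L, 4L), daughter2 = c(3L, 5L),
    d1_length_um = c(1.6, 1.5), d2_length_um = c(1.5, 1.4))
  structure(list(sightings = data.frame(), tracks = tracks,
                 divisions = divisions, timestamps_h = ts),
            class = "mm_lineage")
}

test_that("growth rate follows mu = ln(2) / t_d", {
  expect_equal(round(growth_rate(1.27), 2), 0.55)
  expect_equal(round(growth_rate(1.33), 2), 0.52)
  expect_equal(round(growth_rate(1.72), 2), 0.40)
  expect_equal(round(growth_rate(1.73), 2), 0.40)
  expect_equal(growth_rate(log(2)), 1.0)
  expect_error(growth_rate(0), "positive")
  expect_error(growth_rate(-1), "positive")
})

test_that("division times span consecutive divisions on a lineage path", {
  lin <- toy_lineage(0.25)
  ev <- division_times(lin, mu_bounds = c(0.01, 1.0),
                       frame_interval_h = 0.25)
  # only track 2's division has an observed birth (frame 5 -> frame 9)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$division_time_h, 1.0)
  expect_equal(ev$age_frames, 4)
  expect_equal(ev$mu_per_h, log(2))
  # explicit subtraction: birth 8.7 h, division 10 h -> 1.3 h
  lin2 <- toy_lineage()
  lin2$timestamps_h <- c(rep(0, 4), 8.7, 0, 0, 0, 10, 0, 0, 0)
  ev2 <- division_times(lin2)
  expect_equal(ev2$division_time_h, 1.3)
})

test_that("physiological growth-rate bounds exclude artifact events", {
  lin <- toy_lineage(0.125) # division interval 0.5 h -> mu = 1.39
  ev <- division_times(lin, mu_bounds = c(0.01, 1.0))
  expect_identical(nrow(ev), 0L)
  ev2 <- division_times(lin, mu_bounds = c(0.01, 2.0))
  expect_identical(nrow(ev2), 1L)
})

test_that("a constant scripted division interval is recovered exactly", {
  cfg <- small_config(T_frames = 60L, n_channels = 3L)
  set.seed(13)
  # zero threshold noise and zero rate jitter: division intervals are
  # quantised multiples of the frame interval
  sim <- simulate_lineage(cfg, doubling_time_h = 1.0, length_sd_um = 0,
                          rate_cv = 0, asym_sd = 0)
  ps <- cfg$pixel_size_um
  det <- lapply(sim$states, function(st) {
    out <- list()
    for (ch in unique(st$channel)) {
      tr <- st[st$channel == ch, ]
      out[[as.character(ch)]] <-
        data.frame(top_px = round(tr$top_um / ps),
                   bottom_px = round((tr$top_um + tr$length_um) / ps),
                   centroid_px = round(tr$top_um / ps) + tr$length_um / ps / 2,
                   length_um = tr$length_um)
    }
    out
  })
  lin <- track_series(det, (seq_len(60L) - 1) * cfg$frame_interval_min / 60)
  ev <- division_times(lin)
  expect_gt(nrow(ev), 5)
  steps_h <- ev$division_time_h / (cfg$frame_interval_min / 60)
  expect_true(all(abs(steps_h - round(steps_h)) < 1e-9))
  expect_lt(abs(mean(ev$division_time_h) - 1.0),
            cfg$frame_interval_min / 60)
})

test_that("event pairing gives the stated precision/recall", {
  ev <- data.frame(frame = c(10, 20, 30), age_frames = c(12, 14, 16))
  same <- pair_events(ev, ev, max_offset_frames = 0)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  shifted <- transform(ev, frame = frame + 1)
  off0 <- pair_events(shifted, ev, max_offset_frames = 0)
  expect_equal(off0$precision, 0)
  off1 <- pair_events(shifted, ev, max_offset_frames = 1)
  expect_equal(off1$precision, 1)
  # 10 vs 10 with exactly 7 pairable at offset <= 2
  set.seed(3)
  ref <- data.frame(frame = seq(10, 100, by = 10),
                    age_frames = rep(12, 10))
  auto <- ref
  auto$frame[1:7] <- auto$frame[1:7] + c(0, 1, -1, 2, -2, 1, 0)
  auto$frame[8:10] <- auto$frame[8:10] + 5
  pr <- pair_events(auto, ref, max_offset_frames = 2)
  expect_equal(pr$precision, 0.7)
  expect_equal(pr$recall, 0.7)
  # empty reference: recall undefined
  none <- pair_events(ev, ev[0, ], max_offset_frames = 2)
  expect_true(is.na(none$recall))
})

test_that("fluorescence is bounding-box mean minus inter-channel background", {
  geometry <- structure(list(
    array_top = 0L, array_bottom = 60L, interval_px = 30, width_px = 10L,
    phase_px = 5L,
    channel_boxes = cbind(x_left = c(5L, 35L), x_right = c(15L, 45L)),
    W = 60L, H = 60L), class = "mm_channel_geometry")
  uniform <- matrix(7, 60, 60)
  expect_equal(cell_fluorescence(10, 30, 1, uniform, geometry), 0)
  painted <- matrix(7, 60, 60)
  painted[11:30, 6:15] <- 7 + 42
  v <- cell_fluorescence(10, 30, 1, painted, geometry)
  expect_equal(v, 42, tolerance = 1e-9)
  # background stripes exclude channel interiors: painting a channel
  # interior must not change the background estimate
  painted2 <- painted
  painted2[, 36:45] <- 1000
  expect_equal(cell_fluorescence(10, 30, 1, painted2, geometry), v)
})

test_that("fluorescence recovery straddles a scripted biosensor step", {
  cfg <- small_config(T_frames = 24L, frame_interval_min = 15,
                      n_channels = 6L)
  fl <- list(period_frames = 4L, switch_frame = 12L, level_growth = 16.07,
             sd_growth = 10.98, level_production = 330.67,
             sd_production = 197.96, background = 20, noise_sd = 2)
  gs <- generate_stack(cfg, doubling_time_h = 1.3, fluor = fl)
  an <- mm_analyze(gs$series)
  s <- an$lineage$sightings
  pre <- s$fluor_fl[s$frame < 12 & !is.na(s$fluor_fl)]
  post <- s$fluor_fl[s$frame >= 12 & !is.na(s$fluor_fl)]
  expect_gt(length(pre), 5); expect_gt(length(post), 5)
  expect_lt(mean(pre), 60)
  expect_gt(mean(post), 150)
  expect_lt(abs(mean(post) - 330.67) / 330.67, 0.35)
})

test_that("the results table has one row per sighting, stable columns", {
  cfg <- small_config(T_frames = 10L, n_channels = 4L)
  gs <- generate_stack(cfg, doubling_time_h = 1.3)
  an <- mm_analyze(gs$series)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_table(an$lineage, path, position = "p0")
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), nrow(an$lineage$sightings))
  expect_true(all(c("position", "frame", "time_h", "channel", "track_id",
                    "parent_id", "top_px", "bottom_px", "length_um",
                    "blackness", "prominence", "fate") %in% names(tab)))
  # binary fission: every division parent appears as parent of exactly 2
  # track starts
  par_counts <- table(an$lineage$tracks$parent_id)
  expect_true(all(par_counts == 2))
  # empty lineage -> header-only file
  lin0 <- track_series(list(), numeric(0))
  p0 <- withr::local_tempfile(fileext = ".tsv")
  export_table(lin0, p0)
  expect_identical(nrow(utils::read.delim(p0)), 0L)
})

test_that("moving-average growth curve is undefined in sparse bins", {
  set.seed(4)
  dense <- data.frame(time_h = sort(runif(80, 0, 4)),
                      division_time_h = rnorm(80, 1.3, 0.1))
  sparse <- data.frame(time_h = sort(runif(3, 6, 7)),
                       division_time_h = rnorm(3, 1.3, 0.1))
  ev <- rbind(dense, sparse)
  ev$mu_per_h <- log(2) / ev$division_time_h
  curve <- growth_rate_curve(ev, window = 25, min_events = 5, bin_h = 1)
  expect_true(all(is.na(curve$mu_ma[curve$time_h >= 6])))
  mid <- curve$mu_ma[curve$time_h > 1 & curve$time_h < 3]
  expect_true(any(!is.na(mid)))
  expect_lt(abs(mean(mid, na.rm = TRUE) - log(2) / 1.3), 0.05)
})

test_that("kymographs render montages with lineage overlays", {
  cfg <- small_config(T_frames = 12L, n_channels = 4L)
  gs <- generate_stack(cfg, doubling_time_h = 1.3)
  an <- mm_analyze(gs$series)
  path <- withr::local_tempfile(fileext = ".png")
  m <- plot(an, gs$series, channel = 1L, path = path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
  cc <- channel_crops(an, gs$series, 1L)
  expect_identical(ncol(m), ncol(cc$crops[[1]]) * length(cc$crops))
  # single frame: montage is a single crop
  gs1 <- generate_stack(small_config(T_frames = 1L), doubling_time_h = 0)
  an1 <- mm_analyze(gs1$series)
  p1 <- withr::local_tempfile(fileext = ".png")
  m1 <- plot(an1, gs1$series, channel = 1L, path = p1)
  cc1 <- channel_crops(an1, gs1$series, 1L)
  expect_identical(dim(m1), dim(cc1$crops[[1]]))
})
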