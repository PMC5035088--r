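test_that("reference comb follows its closed-form definition", {
  a <- build_reference_signal(30, 10, 90)
  expect_identical(which(a == 1) - 1L, c(0L, 10L, 30L, 40L, 60L, 70L))
  # half-interval width gives evenly spaced teeth
  a2 <- build_reference_signal(30, 15, 120)
  expect_equal(diff(which(a2 == 1)), rep(15, 7))
  # tooth count: two per full interval up to boundary terms
  expect_lte(abs(sum(a) - 2 * ceiling(90 / 30)), 2)
  expect_error(build_reference_signal(30, 30, 90), "width_px")
  expect_error(build_reference_signal(30, 0, 90), "width_px")
})

test_that("channel width is recovered from edge-signal correlation", {
  sc <- static_frame()
  g <- detect_channel_geometry(sc$img)
  expect_lte(abs(g$width_px - (sc$cfg$width_px + 1)), 1)
  # brute-force check of the constrained correlation argmax
  crop <- sc$img[(g$array_top + 1):g$array_bottom, ]
  h <- smooth_profile(colMeans(crop), 3)
  hp <- c(diff(h), 0)
  c_l <- (abs(hp) + hp) / 2; c_r <- (abs(hp) - hp) / 2
  w <- channel_width(list(c_l = c_l, c_r = c_r), g$interval_px)
  expect_identical(as.integer(w),
                   as.integer(brute_xcorr_argmax(c_l, c_r,
                     c(1, ceiling(g$interval_px) - 1))))
  expect_error(channel_width(list(c_l = rep(0, 50), c_r = rep(0, 50)), 30),
               class = "mm_structure_error")
})

test_that("phase estimation locates a shifted comb modulo the interval", {
  n <- 300L
  edges <- rep(0, n)
  teeth <- c(outer(c(0, 10), seq(13, n - 20, by = 30), "+"))
  edges[teeth + 1] <- 1
  a <- build_reference_signal(30, 10, n)
  phi <- estimate_phase(a, edges, 30L)
  expect_identical(as.integer(phi), 13L)
  expect_identical(
    as.integer(((brute_xcorr_argmax(a, edges) %% 30) + 30) %% 30), 13L)
  expect_error(estimate_phase(a, rep(0, n), 30L),
               class = "mm_structure_error")
})

test_that("robustified channel signal has the stated algebraic limits", {
  n <- 120L
  c_l <- runif(n); c_r <- runif(n)
  ones <- rep(1, n); zeros <- rep(0, n)
  expect_equal(robust_channel_signal(ones, 0L, c_l, c_r), c_l + c_r)
  expect_equal(robust_channel_signal(zeros, 0L, c_l, c_r), zeros)
  # phase-shifting the comb by a full interval leaves the support pattern
  a <- build_reference_signal(30, 10, n)
  h1 <- robust_channel_signal(a, 3L, c_l, c_r)
  h2 <- robust_channel_signal(a, 33L, c_l, c_r)
  expect_equal(which(h1[40:n] > 0), which(h2[40:n] > 0))
})

test_that("vertical extent snaps to the array within one strip height", {
  sc <- static_frame()
  ext <- find_vertical_extent(sc$img, strip_height = 16L)
  expect_lte(abs(ext[1] - sc$cfg$array_top), 16)
  expect_lte(abs(ext[2] - sc$cfg$array_bottom), 16)
  # an all-structure image returns the full height
  strip <- sc$img[(sc$cfg$array_top + 1):sc$cfg$array_bottom, ]
  ext2 <- find_vertical_extent(strip, strip_height = 16L)
  expect_identical(unname(ext2), c(0L, nrow(strip)))
  set.seed(5)
  expect_error(find_vertical_extent(matrix(rnorm(200 * 280), 200), 16L,
                                    period = 30),
               class = "mm_structure_error")
})

test_that("all channels are found with boxes near truth, cells or not", {
  for (with_cells in c(FALSE, TRUE)) {
    sc <- static_frame(with_cells = with_cells)
    g <- detect_channel_geometry(sc$img)
    expect_identical(nrow(g$channel_boxes), sc$cfg$n_channels)
    truth_lefts <- scene_boxes(sc$cfg)[, 1]
    expect_lte(max(abs(g$channel_boxes[, 1] - truth_lefts)), 2)
    # boxes are sorted, non-overlapping, constant width
    expect_true(all(diff(g$channel_boxes[, 1]) > 0))
    expect_true(all(g$channel_boxes[-nrow(g$channel_boxes), 2] <=
                      g$channel_boxes[-1, 1]))
    expect_true(all(abs((g$channel_boxes[, 2] - g$channel_boxes[, 1]) -
                          g$width_px) <= 1))
  }
})

test_that("channel-free borders are rejected by the support threshold", {
  # wide margins: comb positions beyond the real channels get no support
  sc <- static_frame(W = 400L, phase_px = 77L)
  g <- detect_channel_geometry(sc$img)
  expect_identical(nrow(g$channel_boxes), sc$cfg$n_channels)
  expect_gte(min(g$channel_boxes[, 1]), 70)
  expect_lte(max(g$channel_boxes[, 2]), 330)
})

test_that("geometry recovery holds across random configurations", {
  set.seed(99)
  for (i in 1:25) {
    ic <- sample(20:60, 1)
    wc <- sample(6:14, 1)
    n <- sample(4:8, 1)
    cfg <- scene_config(W = n * ic + 2L * ic, H = 200L, n_channels = n,
                        interval_px = ic, width_px = wc,
                        phase_px = ic, array_top = 40L, array_bottom = 160L,
                        T_frames = 1L, rotation_deg = 0,
                        drift = matrix(0L, 1, 2),
                        noise_sigma = runif(1, 0, 0.1),
                        illumination_amplitude = runif(1, 0, 0.15),
                        seed = i)
    set.seed(i)
    img <- render_frame(NULL, cfg)
    g <- detect_channel_geometry(img)
    expect_identical(nrow(g$channel_boxes), n)
    expect_lte(max(abs(g$channel_boxes[, 1] - scene_boxes(cfg)[, 1])), 2)
    expect_lte(abs(g$interval_px - ic) / ic, 0.05)
  }
})

test_that("interval estimate is invariant to intensity scaling/gradients", {
  sc <- static_frame(illumination_amplitude = 0)
  g0 <- detect_channel_geometry(sc$img)
  g1 <- detect_channel_geometry(0.5 + 0.4 * sc$img)
  grad <- sc$img * matrix(rep(seq(0.8, 1.2, length.out = ncol(sc$img)),
                              each = nrow(sc$img)), nrow(sc$img))
  g2 <- detect_channel_geometry(grad)
  expect_lte(abs(g1$interval_px - g0$interval_px), 1)
  expect_lte(abs(g2$interval_px - g0$interval_px), 1)
})

test_that("channel identities are matched stably across frames", {
  m <- match_channel_ids <- mmpipe:::match_channel_ids
  r <- m(c(17, 47, 77), numeric(0), 30)
  expect_identical(r$ids, 1:3)
  # small jitter keeps identities; a far box opens a new identity
  r2 <- m(c(18, 46, 78, 140), r$ref_lefts, 30)
  expect_identical(r2$ids, c(1:3, 4L))
})
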