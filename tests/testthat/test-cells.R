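test_that("cleaned profile removes baseline and ramps", {
  expect_equal(cleaned_profile(matrix(0.5, 60, 8)), rep(0, 60),
               tolerance = 1e-9)
  expect_length(cleaned_profile(matrix(0.5, 4, 8)), 0L)
  # linear illumination ramp with two dark cells: ramp removed, two
  # clear minima remain
  prof_rows <- 120L
  crop <- matrix(rep(seq(0.4, 0.8, length.out = prof_rows), 8), prof_rows)
  crop[20:45, ] <- crop[20:45, ] - 0.3
  crop[70:100, ] <- crop[70:100, ] - 0.3
  cl <- cleaned_profile(crop)
  expect_lt(abs(mean(cl)), 0.01 * diff(range(cl)))
  ex <- find_extrema(cl, 11)
  deep <- ex$minima[cl[ex$minima] < -0.05]
  expect_length(deep, 2L)
  expect_true(deep[1] >= 18 && deep[1] <= 47)
  expect_true(deep[2] >= 68 && deep[2] <= 102)
})

test_that("sliding-window extrema find peaks, plateaus and nothing else", {
  x <- sin(2 * pi * (0:199) / 40)
  ex <- find_extrema(x, 11)
  interior <- setdiff(ex$maxima, c(1L, 200L)) # profile ends may qualify
  expect_length(interior, 5L)
  expect_true(all(abs((interior - 1) %% 40 - 10) <= 1))
  mono <- find_extrema(as.numeric(1:50), 5)
  expect_true(all(mono$maxima %in% c(1L, 50L))) # boundary only
  plateau <- c(0, 1, 2, 3, 3, 3, 3, 3, 2, 1, 0)
  exp_ <- find_extrema(plateau, 3)
  expect_identical(exp_$maxima, 6L) # plateau centre
})

test_that("weak maxima are pruned while real boundaries survive", {
  x <- rep(0, 100)
  x[30] <- 0.5 # real boundary between deep dips
  x[c(20, 40)] <- -0.5
  x[60] <- 0.02 # noise wiggle on a flat stretch
  x[c(58, 62)] <- -0.01
  ex0 <- find_extrema(x, 5, min_contrast = 0)
  ex1 <- find_extrema(x, 5, min_contrast = 0.1)
  expect_true(30 %in% ex0$maxima && 60 %in% ex0$maxima)
  expect_true(30 %in% ex1$maxima)
  expect_false(60 %in% ex1$maxima)
})

test_that("candidates pair adjacent maxima", {
  cand <- candidates_from_extrema(c(10L, 40L, 80L))
  expect_equal(cand$top_px, c(9L, 39L))
  expect_equal(cand$bottom_px, c(39L, 79L))
  expect_identical(nrow(candidates_from_extrema(c(25L))), 0L)
  expect_identical(nrow(candidates_from_extrema(integer(0))), 0L)
})

test_that("blackness scores dark, bright and partial extents correctly", {
  crop <- matrix(0.8, 100, 10)
  crop[21:60, ] <- 0.1
  expect_gt(score_blackness(20, 60, crop), 0.95)
  expect_lt(score_blackness(0, 20, crop), 0.05)
  # a cell filling 80% of its candidate box
  crop2 <- matrix(0.8, 100, 10)
  crop2[21:52, ] <- 0.1
  expect_lt(abs(score_blackness(20, 60, crop2) - 0.8), 0.05)
  # degenerate crop
  expect_identical(score_blackness(0, 10, matrix(1, 20, 5)), 0)
})

test_that("prominence measures the envelope gap", {
  x <- sin(2 * pi * (0:199) / 40)
  ex <- find_extrema(x, 11)
  cand <- candidates_from_extrema(ex$maxima)
  # strictly interior candidates see the full envelope gap 2A = 2;
  # candidates near the profile ends feel the envelope end conditions
  interior <- which(cand$top_px > 20 & cand$bottom_px < 160)
  expect_gte(length(interior), 2L)
  for (i in interior) {
    p <- score_prominence(cand$top_px[i], cand$bottom_px[i], x,
                          ex$maxima, ex$minima)
    expect_lt(abs(p - 2), 0.1)
  }
  # deep cell dip vs shallow noise dip
  y <- rep(0, 200)
  y[c(40, 100, 160)] <- 0.4
  y[70] <- -0.5 # deep dip between maxima 40 and 100
  y[130] <- -0.02 # shallow jitter between 100 and 160
  y <- smooth_profile(y, 9)
  ey <- find_extrema(y, 9)
  cd <- candidates_from_extrema(ey$maxima)
  proms <- vapply(seq_len(nrow(cd)), function(i)
    score_prominence(cd$top_px[i], cd$bottom_px[i], y, ey$maxima,
                     ey$minima), numeric(1))
  expect_gt(max(proms), 5 * min(proms))
})

test_that("each filter rejects its constructed violator", {
  # 0.5 um debris between two real cells -> length filter
  sc <- render_channel_crop(cbind(c(0.5, 3.3, 6.8), c(2.9, 3.8, 9.6)))
  cells <- detect_cells(sc$crop, detection_params(), 0.065,
                        valid_px = sc$valid_px)
  cand <- attr(cells, "candidates")
  expect_identical(nrow(cells), 2L)
  debris <- cand[cand$length_um < 1 & cand$blackness > 0.3, ]
  expect_true(nrow(debris) >= 1 && all(!debris$pass_length))

  # bright inter-cell gap candidate -> blackness filter at 50%
  sc2 <- render_channel_crop(cbind(c(0.5, 7.0), c(3.5, 10.0)))
  cells2 <- detect_cells(sc2$crop, detection_params(), 0.065,
                         valid_px = sc2$valid_px)
  cand2 <- attr(cells2, "candidates")
  gap_cand <- cand2[cand2$blackness < 0.5, ]
  expect_identical(nrow(cells2), 2L)
  expect_true(all(!gap_cand$pass_blackness))

  # jitter dip on an empty channel -> prominence (and blackness) filters
  sc3 <- render_channel_crop(matrix(numeric(0), 0, 2), noise_sigma = 0.03)
  cells3 <- detect_cells(sc3$crop, detection_params(), 0.065,
                         valid_px = sc3$valid_px)
  expect_identical(nrow(cells3), 0L)
})

test_that("accepted cells never overlap and sit near truth", {
  set.seed(21)
  ok <- 0; total <- 0; maes <- c()
  for (i in 1:40) {
    k <- sample(1:4, 1)
    lens <- runif(k, 1.4, 2.8)
    gaps <- runif(k, 0.25, 0.6)
    tops <- cumsum(c(0.3, head(lens + gaps, -1)))
    while (tops[k] + lens[k] > 10.5 && k > 1) { # fit the channel
      k <- k - 1L
      lens <- lens[1:k]; tops <- tops[1:k]
    }
    sc <- render_channel_crop(cbind(tops, tops + lens), seed = i,
                              noise_sigma = 0.03)
    cells <- detect_cells(sc$crop, detection_params(), 0.065,
                          valid_px = sc$valid_px)
    total <- total + 1
    if (nrow(cells) > 1)
      expect_true(all(cells$bottom_px[-nrow(cells)] <= cells$top_px[-1]))
    if (nrow(cells) == k) {
      ok <- ok + 1
      maes <- c(maes, abs(cells$top_px - sc$truth[, 1]),
                abs(cells$bottom_px - sc$truth[, 2]))
    }
  }
  expect_gte(ok / total, 0.9)
  expect_lte(mean(maes), 2)
})

test_that("detection is invariant under affine intensity rescaling", {
  sc <- render_channel_crop(cbind(c(0.5, 3.4), c(3.0, 6.2)))
  a <- detect_cells(sc$crop, detection_params(), 0.065,
                    valid_px = sc$valid_px)
  b <- detect_cells(0.25 + 0.5 * sc$crop, detection_params(), 0.065,
                    valid_px = sc$valid_px)
  expect_equal(a$top_px, b$top_px)
  expect_equal(a$bottom_px, b$bottom_px)
  expect_equal(a$blackness, b$blackness, tolerance = 0.02)
})
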