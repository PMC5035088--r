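cells_df <- function(tops_px, lens_um, px = 0.065) {
  data.frame(top_px = tops_px, bottom_px = tops_px + lens_um / px,
             centroid_px = tops_px + lens_um / px / 2, length_um = lens_um)
}

test_that("identical cell lists make the diagonal the cheapest same-link", {
  cells <- cells_df(c(10, 60, 110), c(2.2, 2.5, 1.8))
  costs <- build_costs(cells, cells)
  for (j in 1:3)
    expect_identical(which.min(costs$C_S[j, ]), j)
  expect_true(all(diag(costs$C_S) < 1e-9))
})

test_that("a halving pair is cheaper as division than as same-link", {
  parent <- cells_df(50, 4.0)
  pair <- cells_df(c(50, 84), c(2.1, 1.9))
  costs <- build_costs(parent, pair)
  expect_lt(costs$C_D[1, 1], min(costs$C_S[1, ]))
})

test_that("empty frames produce all-new or all-lost fates", {
  none <- cells_df(numeric(0), numeric(0))
  some <- cells_df(c(10, 60), c(2, 2))
  a1 <- solve_assignment(build_costs(none, some), 0L, 2L)
  expect_true(all(a1$N))
  a2 <- solve_assignment(build_costs(some, none), 2L, 0L)
  expect_true(all(a2$L))
})

test_that("trivial and division assignments resolve as expected", {
  one <- cells_df(40, 2.0)
  a <- solve_assignment(build_costs(one, one), 1L, 1L)
  expect_true(a$S[1, 1])
  expect_false(any(a$D) || any(a$N) || any(a$L))
  pair <- cells_df(c(40, 74), c(1.05, 1.0))
  parent <- cells_df(40, 2.0)
  ad <- solve_assignment(build_costs(parent, pair), 1L, 2L)
  expect_true(ad$D[1, 1])
  expect_false(any(ad$S) || any(ad$N) || any(ad$L))
})

test_that("greedy matches the exhaustive optimum on plausible instances", {
  set.seed(31)
  agree <- 0; n_inst <- 100
  for (i in seq_len(n_inst)) {
    inst <- random_tracking_instance()
    J <- nrow(inst$t); K <- nrow(inst$t1)
    costs <- build_costs(inst$t, inst$t1)
    g <- solve_assignment(costs, J, K)
    CD <- costs$C_D
    b <- brute_assignment(costs$C_S, CD, costs$c_N, costs$c_L, J, K)
    expect_lte(g$total_cost, 1.1 * b$cost + 1e-9)
    bm <- brute_fate_matrices(b, J, K)
    agree <- agree + (identical(g$S, bm$S) && identical(g$D, bm$D))
  }
  expect_gte(agree / n_inst, 0.9)
})

test_that("fates partition both frames and links never cross", {
  set.seed(32)
  for (i in 1:60) {
    inst <- random_tracking_instance()
    J <- nrow(inst$t); K <- nrow(inst$t1)
    a <- solve_assignment(build_costs(inst$t, inst$t1), J, K)
    # each frame-t cell has exactly one fate
    row_fates <- rowSums(a$S) + rowSums(a$D) + a$L
    expect_true(all(row_fates == 1))
    # each frame-t+1 cell has exactly one origin
    origin <- colSums(a$S) + a$N
    for (j in seq_len(J)) for (k in which(a$D[j, ]))
      origin[c(k, k + 1L)] <- origin[c(k, k + 1L)] + 1L
    expect_true(all(origin == 1))
    # non-crossing: link intervals ordered like their j
    links <- list()
    for (j in seq_len(J)) {
      k <- which(a$S[j, ]); if (length(k)) links[[length(links) + 1]] <- c(j, k, k)
      k <- which(a$D[j, ]); if (length(k)) links[[length(links) + 1]] <- c(j, k, k + 1)
    }
    if (length(links) > 1) {
      L <- do.call(rbind, links)
      L <- L[order(L[, 1]), , drop = FALSE]
      expect_true(all(diff(L[, 2]) > 0))
      expect_true(all(L[-nrow(L), 3] < L[-1, 2]))
    }
  }
})

test_that("a single non-dividing cell yields one track, no divisions", {
  det <- lapply(1:10, function(f)
    list(`1` = cells_df(40 + f, 2 + 0.01 * f)))
  lin <- track_series(det, timestamps_h = (0:9) / 12)
  expect_identical(nrow(lin$tracks), 1L)
  expect_identical(lin$tracks$fate, "end")
  expect_identical(nrow(lin$divisions), 0L)
  expect_identical(nrow(lin$sightings), 10L)
})

test_that("a flushed cell ends its track as lost at the right frame", {
  det <- lapply(1:8, function(f) {
    if (f <= 5) list(`1` = cells_df(c(10, 60), c(2, 2)))
    else list(`1` = cells_df(10, 2))
  })
  lin <- track_series(det, timestamps_h = (0:7) / 12)
  lost <- lin$tracks[lin$tracks$fate == "lost", ]
  expect_identical(nrow(lost), 1L)
  expect_identical(lost$end_frame, 5L)
})

test_that("scripted divisions are recovered from simulated detections", {
  # noiseless detections straight from the simulator: tracking alone
  # must recover every observable division
  cfg <- small_config(T_frames = 40L, n_channels = 4L)
  set.seed(8)
  sim <- simulate_lineage(cfg, doubling_time_h = 1.0)
  ps <- cfg$pixel_size_um
  det <- lapply(sim$states, function(st) {
    out <- list()
    for (ch in unique(st$channel)) {
      tr <- st[st$channel == ch, ]
      out[[as.character(ch)]] <-
        cells_df(round(tr$top_um / ps), tr$length_um)
    }
    out
  })
  lin <- track_series(det, timestamps_h = (seq_len(40L) - 1) *
                        cfg$frame_interval_min / 60)
  expect_equal(nrow(lin$divisions),
               sum(sim$divisions$observable), tolerance = 0.05)
  # every sighting belongs to exactly one track
  expect_false(any(duplicated(
    lin$sightings[, c("frame", "channel", "top_px")])))
})

test_that("exponential history weighting predicts movement", {
  ew <- mmpipe:::ew_mean
  expect_identical(ew(numeric(0), 3, 0), 0)
  expect_identical(ew(c(1, 2, 4), 3, 0), (4 + 2 / 2 + 1 / 4) / (1.75))
  expect_identical(ew(c(9, 9, 1, 2, 4), 3, 0), ew(c(1, 2, 4), 3, 0))
})
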