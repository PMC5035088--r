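#' Lineage tracking as a constrained assignment problem
#'
#' Between consecutive frames, each cell of frame t has exactly one fate:
#' it is the *same* cell as one cell of frame t+1 (S), it *divides* into
#' two adjacent cells of frame t+1 (D), or it is *lost* (L, flushed out or
#' lysed); cells of frame t+1 not accounted for appear *de novo* (N).
#' Every possible fate is priced by a cost reflecting its biological
#' plausibility given the cell's recent movement and elongation, and the
#' cheapest feasible combination is selected greedily under two
#' constraints: one fate per cell, and no crossing of links - cells cannot
#' swap order inside a one-dimensional channel, so the selected link set
#' must be monotone in both frame indices.
#'
#' The cost terms are quadratic deviations: predicted vs observed position
#' (normalised by a position scale) and predicted vs observed length
#' (relative, normalised by a length scale), with constant penalties for
#' appearance and loss chosen to exceed typical movement costs, and a
#' small constant division penalty so that a division is only preferred
#' when the length evidence supports it.
#'
#' @name tracking
NULL

#' Tracking cost parameters
#'
#' @param pos_scale_px position deviation scale (px): one unit of cost per
#'   `pos_scale_px` of unexplained movement, squared.
#' @param len_scale relative length deviation scale: one unit of cost per
#'   `len_scale` fractional deviation from the predicted length, squared.
#' @param div_penalty constant added to division costs; breaks the tie
#'   against two same-links when lengths alone are ambiguous.
#' @param new_cost,lost_cost constant costs of de-novo appearance and of
#'   loss; higher than typical movement/division costs so they only fire
#'   when no plausible link exists.
#' @param history_span number of most recent sightings used for the
#'   exponentially weighted movement/elongation history.
#' @return list of class `mm_tracking_params`.
#' @export
tracking_params <- function(pos_scale_px = 8, len_scale = 0.15,
                            div_penalty = 1, new_cost = 20, lost_cost = 20,
                            history_span = 3L) {
  stopifnot(pos_scale_px > 0, len_scale > 0, div_penalty >= 0,
            new_cost > 0, lost_cost > 0, history_span >= 1L)
  structure(as.list(environment()), class = "mm_tracking_params")
}

#' Fate cost matrices for one frame pair
#'
#' @param cells_t,cells_t1 data frames of detected cells (sorted
#'   top-to-bottom) with columns `centroid_px` and `length_um`.
#' @param history optional list with numeric vectors `velocity_px` (px per
#'   frame step) and `growth` (length factor per frame step), one entry
#'   per cell of `cells_t`; zeros / ones when absent (cold start).
#' @param params a [tracking_params()].
#' @param gap number of skipped frames bridged by this step (>= 1);
#'   predictions and the position tolerance scale with it.
#' @return list with `C_S` (J x K), `C_D` (J x (K-1), daughter pair
#'   (k, k+1) indexed by its upper daughter), `c_N`, `c_L`.
#' @export
build_costs <- function(cells_t, cells_t1, history = NULL,
                        params = tracking_params(), gap = 1L) {
  J <- nrow(cells_t); K <- nrow(cells_t1)
  vel <- if (!is.null(history)) history$velocity_px else rep(0, J)
  gro <- if (!is.null(history)) history$growth else rep(1, J)
  pos_scale <- params$pos_scale_px * gap
  pred_pos <- cells_t$centroid_px + vel * gap
  pred_len <- cells_t$length_um * gro^gap
  C_S <- matrix(Inf, max(J, 0L), max(K, 0L))
  C_D <- matrix(Inf, max(J, 0L), max(K - 1L, 0L))
  if (J && K) {
    for (j in seq_len(J)) {
      C_S[j, ] <- ((cells_t1$centroid_px - pred_pos[j]) / pos_scale)^2 +
        ((cells_t1$length_um - pred_len[j]) /
           (pred_len[j] * params$len_scale))^2
      if (K >= 2L) {
        pair_len <- cells_t1$length_um[-K] + cells_t1$length_um[-1L]
        pair_mid <- (cells_t1$top_px[-K] + cells_t1$bottom_px[-1L]) / 2
        C_D[j, ] <- ((pair_mid - pred_pos[j]) / pos_scale)^2 +
          ((pair_len - pred_len[j]) / (pred_len[j] * params$len_scale))^2 +
          params$div_penalty
      }
    }
  }
  list(C_S = C_S, C_D = C_D, c_N = params$new_cost, c_L = params$lost_cost)
}

#' Solve one frame-pair assignment greedily
#'
#' Enumerates every possible fate (each S link, each D triple with
#' adjacent daughters, one N per frame-t+1 cell, one L per frame-t cell),
#' then repeatedly picks the globally cheapest fate compatible with the
#' fates already picked - the one-fate constraints plus the non-crossing
#' (order-preserving) constraint - until every cell of both frames is
#' covered. N and L guarantee feasibility. Ties are broken towards smaller
#' j, then smaller k, making the solution deterministic.
#'
#' @param costs list from [build_costs()].
#' @param J,K cell counts in frames t and t+1.
#' @return list of class `mm_assignment`: logical matrices `S` (J x K) and
#'   `D` (J x K, `TRUE` at the upper daughter k of the pair (k, k+1)),
#'   logical vectors `N` (K) and `L` (J), and `total_cost`.
#' @export
solve_assignment <- function(costs, J, K) {
  ty <- character(0); jj <- integer(0); kk <- integer(0); cc <- numeric(0)
  if (J && K) {
    ty <- rep("S", J * K); jj <- rep(seq_len(J), K)
    kk <- rep(seq_len(K), each = J); cc <- as.vector(costs$C_S)
    if (K >= 2L) {
      ty <- c(ty, rep("D", J * (K - 1L)))
      jj <- c(jj, rep(seq_len(J), K - 1L))
      kk <- c(kk, rep(seq_len(K - 1L), each = J))
      cc <- c(cc, as.vector(costs$C_D))
    }
  }
  if (K) {
    ty <- c(ty, rep("N", K)); jj <- c(jj, rep(NA_integer_, K))
    kk <- c(kk, seq_len(K)); cc <- c(cc, rep(costs$c_N, K))
  }
  if (J) {
    ty <- c(ty, rep("L", J)); jj <- c(jj, seq_len(J))
    kk <- c(kk, rep(NA_integer_, J)); cc <- c(cc, rep(costs$c_L, J))
  }
  fin <- is.finite(cc)
  o <- order(cc[fin], jj[fin], kk[fin])
  cand <- list(type = ty[fin][o], j = jj[fin][o], k = kk[fin][o],
               cost = cc[fin][o])

  S <- matrix(FALSE, J, K); D <- matrix(FALSE, J, K)
  Nv <- logical(K); Lv <- logical(J)
  j_used <- logical(J); k_used <- logical(K)
  links <- matrix(numeric(0), 0, 3) # j, k_lo, k_hi of placed S/D links
  total <- 0
  crosses <- function(j, klo, khi) {
    if (!nrow(links)) return(FALSE)
    any((j < links[, 1] & khi >= links[, 2]) |
        (j > links[, 1] & klo <= links[, 3]))
  }
  for (i in seq_along(cand$type)) {
    if (all(j_used) && all(k_used)) break
    ty <- cand$type[i]; j <- cand$j[i]; k <- cand$k[i]
    if (ty == "S") {
      if (j_used[j] || k_used[k] || crosses(j, k, k)) next
      S[j, k] <- TRUE; j_used[j] <- TRUE; k_used[k] <- TRUE
      links <- rbind(links, c(j, k, k))
    } else if (ty == "D") {
      if (j_used[j] || k_used[k] || k_used[k + 1L] ||
          crosses(j, k, k + 1L)) next
      D[j, k] <- TRUE; j_used[j] <- TRUE
      k_used[k] <- TRUE; k_used[k + 1L] <- TRUE
      links <- rbind(links, c(j, k, k + 1L))
    } else if (ty == "N") {
      if (k_used[k]) next
      Nv[k] <- TRUE; k_used[k] <- TRUE
    } else {
      if (j_used[j]) next
      Lv[j] <- TRUE; j_used[j] <- TRUE
    }
    total <- total + cand$cost[i]
  }
  structure(list(S = S, D = D, N = Nv, L = Lv, total_cost = total),
            class = "mm_assignment")
}

# Exponentially weighted mean of the most recent values (last first).
ew_mean <- function(values, span, default) {
  v <- utils::tail(values, span)
  if (!length(v)) return(default)
  w <- 0.5^(rev(seq_along(v)) - 1L) # most recent value gets weight 1
  sum(v * w) / sum(w)
}

#' Track a series of per-frame detections into a lineage
#'
#' Chains frame-pair assignments per channel into cell tracks. A division
#' ends the parent track and starts two daughter tracks; N starts a track
#' without a parent; L (or the end of the series) ends a track. Skipped
#' frames (e.g. frames whose structure detection failed) are bridged as a
#' single step with the position tolerance inflated by the gap length.
#'
#' @param detections list over frames; each element a named list (by
#'   channel id) of detection data frames from [detect_cells()].
#' @param timestamps_h per-frame acquisition times (hours).
#' @param params a [tracking_params()].
#' @return object of class `mm_lineage` with data frames `sightings`
#'   (one row per detected cell per frame), `tracks` (one row per track)
#'   and `divisions` (one row per division event).
#' @export
track_series <- function(detections, timestamps_h,
                         params = tracking_params()) {
  channels <- unique(unlist(lapply(detections, names)))
  next_track <- 0L
  sightings <- list(); tracks <- list(); divisions <- list()

  new_track <- function(channel, parent, frame) {
    next_track <<- next_track + 1L
    list(id = next_track, channel = channel, parent = parent,
         start_frame = frame, end_frame = frame, fate = "open",
         vel = numeric(0), gro = numeric(0))
  }
  close_track <- function(tr, fate) {
    tracks[[length(tracks) + 1L]] <<-
      data.frame(track_id = tr$id, channel = tr$channel,
                 parent_id = if (is.null(tr$parent)) NA_integer_ else tr$parent,
                 start_frame = tr$start_frame, end_frame = tr$end_frame,
                 fate = fate)
  }
  record_frame <- function(frame, channel, cells, track_list) {
    ids <- vapply(track_list, function(tr)
      if (is.null(tr)) NA_integer_ else tr$id, integer(1))
    pars <- vapply(track_list, function(tr)
      if (is.null(tr) || is.null(tr$parent)) NA_integer_ else tr$parent,
      integer(1))
    sightings[[length(sightings) + 1L]] <<-
      cbind(data.frame(frame = frame, time_h = timestamps_h[frame],
                       channel = channel, track_id = ids, parent_id = pars),
            cells)
  }

  for (ch in channels) {
    seen <- which(vapply(detections, function(d) !is.null(d[[ch]]), logical(1)))
    if (!length(seen)) next
    active <- list() # track states, ordered as the cells of the last frame
    cells_prev <- NULL; frame_prev <- NA_integer_
    for (f in seen) {
      cells <- detections[[f]][[ch]]
      J <- if (is.null(cells_prev)) 0L else nrow(cells_prev)
      K <- nrow(cells)
      if (J == 0L) {
        active <- lapply(seq_len(K), function(k) new_track(ch, NULL, f))
        if (K) record_frame(f, ch, cells, active)
      } else {
        gap <- f - frame_prev
        hist <- list(
          velocity_px = vapply(active, function(tr)
            ew_mean(tr$vel, params$history_span, 0), numeric(1)),
          growth = vapply(active, function(tr)
            ew_mean(tr$gro, params$history_span, 1), numeric(1)))
        asg <- solve_assignment(
          build_costs(cells_prev, cells, hist, params, gap), J, K)
        nxt <- vector("list", K)
        for (j in seq_len(J)) {
          tr <- active[[j]]
          k <- which(asg$S[j, ])
          if (length(k)) {
            tr$vel <- c(tr$vel, (cells$centroid_px[k] -
                                   cells_prev$centroid_px[j]) / gap)
            tr$gro <- c(tr$gro, (cells$length_um[k] /
                                   cells_prev$length_um[j])^(1 / gap))
            tr$end_frame <- f
            nxt[[k]] <- tr
            next
          }
          k <- which(asg$D[j, ])
          if (length(k)) {
            tr$end_frame <- f
            close_track(tr, "division")
            d1 <- new_track(ch, tr$id, f)
            d2 <- new_track(ch, tr$id, f)
            nxt[[k]] <- d1; nxt[[k + 1L]] <- d2
            divisions[[length(divisions) + 1L]] <-
              data.frame(channel = ch, frame = f, time_h = timestamps_h[f],
                         parent_track = tr$id, daughter1 = d1$id,
                         daughter2 = d2$id,
                         d1_length_um = cells$length_um[k],
                         d2_length_um = cells$length_um[k + 1L])
            next
          }
          close_track(tr, "lost")
        }
        for (k in which(asg$N)) nxt[[k]] <- new_track(ch, NULL, f)
        if (K) record_frame(f, ch, cells, nxt)
        active <- nxt
      }
      cells_prev <- cells; frame_prev <- f
    }
    for (tr in active) close_track(tr, "end")
  }

  empty_s <- data.frame(frame = integer(0), time_h = numeric(0),
                        channel = character(0), track_id = integer(0),
                        parent_id = integer(0))
  structure(list(
    sightings = if (length(sightings)) do.call(rbind, sightings) else empty_s,
    tracks = if (length(tracks)) do.call(rbind, tracks)
             else data.frame(track_id = integer(0), channel = character(0),
                             parent_id = integer(0), start_frame = integer(0),
                             end_frame = integer(0), fate = character(0)),
    divisions = if (length(divisions)) do.call(rbind, divisions)
                else data.frame(channel = character(0), frame = integer(0),
                                time_h = numeric(0), parent_track = integer(0),
                                daughter1 = integer(0), daughter2 = integer(0),
                                d1_length_um = numeric(0),
                                d2_length_um = numeric(0)),
    timestamps_h = timestamps_h),
    class = "mm_lineage")
}

#' @export
print.mm_lineage <- function(x, ...) {
  cat(sprintf("<mm_lineage> %d sightings, %d tracks, %d divisions\n",
              nrow(x$sightings), nrow(x$tracks) , nrow(x$divisions)))
  invisible(x)
}
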