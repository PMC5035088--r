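# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (direct O(n^2) scans, exhaustive enumeration) so they
# share no code path with the implementations they check.

# Direct-sum linear cross-correlation argmax; same sign and tie rules as
# the contract: positive lag means b displaced +x relative to a.
brute_xcorr_argmax <- function(a, b, lag_range = NULL) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  lags <- -(n - 1):(n - 1)
  if (!is.null(lag_range))
    lags <- lags[lags >= lag_range[1] & lags <= lag_range[2]]
  vals <- vapply(lags, function(k) {
    i <- seq_len(n); j <- i + k
    ok <- j >= 1 & j <= n
    sum(a[i[ok]] * b[j[ok]])
  }, numeric(1))
  o <- order(abs(lags), -sign(lags))
  lags <- lags[o]; vals <- vals[o]
  lags[which.max(vals)]
}

# Exhaustive inter-class variance scan over the same 256-bin histogram.
brute_otsu <- function(v) {
  r <- range(v)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - r[1]) / (r[2] - r[1]) * nb)),
                nbins = nb)
  mids <- r[1] + (seq_len(nb) - 0.5) / nb * (r[2] - r[1])
  v2 <- rep(-Inf, nb - 1L)
  for (t in 1:(nb - 1L)) {
    w0 <- sum(h[1:t]); w1 <- sum(h[(t + 1L):nb])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1L):nb] * mids[(t + 1L):nb]) / w1
    v2[t] <- w0 * w1 * (m0 - m1)^2
  }
  ties <- which(v2 >= max(v2) - 1e-10 * abs(max(v2)))
  r[1] + ties[ceiling(length(ties) / 2)] / nb * (r[2] - r[1])
}

# Exhaustive enumeration of all feasible fate combinations (one fate per
# cell, non-crossing links); returns the minimal total cost and its fates.
brute_assignment <- function(CS, CD, cN, cL, J, K) {
  best <- list(cost = Inf, fates = list())
  rec <- function(j, kmin, cost, fates) {
    if (cost >= best$cost) return(invisible())
    if (j > J) {
      used <- sum(vapply(fates, function(f)
        if (f$type == "S") 1L else if (f$type == "D") 2L else 0L, 0L))
      tot <- cost + cN * (K - used)
      if (tot < best$cost) best <<- list(cost = tot, fates = fates)
      return(invisible())
    }
    rec(j + 1L, kmin, cost + cL, c(fates, list(list(type = "L", j = j))))
    if (kmin <= K) for (k in kmin:K) {
      rec(j + 1L, k + 1L, cost + CS[j, k],
          c(fates, list(list(type = "S", j = j, k = k))))
      if (k < K)
        rec(j + 1L, k + 2L, cost + CD[j, k],
            c(fates, list(list(type = "D", j = j, k = k))))
    }
    invisible()
  }
  rec(1L, 1L, 0, list())
  best
}

brute_fate_matrices <- function(best, J, K) {
  S <- matrix(FALSE, J, K); D <- matrix(FALSE, J, K)
  for (f in best$fates) {
    if (f$type == "S") S[f$j, f$k] <- TRUE
    if (f$type == "D") D[f$j, f$k] <- TRUE
  }
  list(S = S, D = D)
}

# Random plausible frame-pair tracking instance: stacked cells that grow a
# few percent, sometimes divide near division length, are lost at the open
# end or appear de novo; the population the tracker actually faces.
random_tracking_instance <- function() {
  J <- sample(1:4, 1)
  len <- runif(J, 1.4, 3.0)
  gap <- 4
  px <- 0.065
  top <- cumsum(c(10, utils::head(len, -1) / px + gap))
  cells_t <- data.frame(top_px = top, bottom_px = top + len / px,
                        centroid_px = top + len / px / 2, length_um = len)
  nl <- c()
  for (j in seq_len(J)) {
    L <- len[j] * 1.03
    if (runif(1) < 0.2 && L > 2.2) {
      r <- runif(1, 0.45, 0.55)
      nl <- c(nl, L * r, L * (1 - r))
    } else if (j == J && runif(1) < 0.15) next
    else nl <- c(nl, L)
  }
  if (runif(1) < 0.1 || !length(nl)) nl <- c(nl, runif(1, 1.5, 2.5))
  top2 <- cumsum(c(10 + rnorm(1, 0, 1.5), utils::head(nl, -1) / px + gap))
  cells_t1 <- data.frame(top_px = top2, bottom_px = top2 + nl / px,
                         centroid_px = top2 + nl / px / 2, length_um = nl)
  list(t = cells_t, t1 = cells_t1)
}
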