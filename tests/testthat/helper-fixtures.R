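# shared fixtures built in code

# a small constant-background movie
const_movie <- function(value = 100, H = 16, W = 16, T = 10,
                        px = 0.1, dt = 1) {
  movie(array(value, dim = c(H, W, T)), px, dt)
}

# single rendered Gaussian spot
spot_image <- function(y, x, amp = 52, sigma = 1, H = 64, W = 64, bg = 0) {
  wormwound:::add_gaussian_spot(matrix(bg, H, W), y, x, amp, sigma)
}

# ideal annulus image: Gaussian radial cross-section at radius r
ring_image <- function(r_px, centre = c(64.5, 64.5), H = 128, W = 128,
                       amp = 52, sigma = 3, bg = 0) {
  D <- sqrt(outer((seq_len(H) - centre[1])^2,
                  (seq_len(W) - centre[2])^2, `+`))
  bg + amp * exp(-(D - r_px)^2 / (2 * sigma^2))
}

# sort-based temporal median oracle: symmetric shrinking centred window
median_subtract_oracle <- function(arr, k) {
  d <- dim(arr)
  out <- arr
  h <- (k - 1) / 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- arr[i, j, ]
    for (t in seq_len(d[3])) {
      hh <- min(h, t - 1, d[3] - t)
      out[i, j, t] <- v[t] - median(sort(v[(t - hh):(t + hh)]))
    }
  }
  out
}

# brute-force minimal-cost frame-pair matching oracle (cost: distances of
# links + max_dist per unmatched point); returns the optimal total cost
brute_force_match_cost <- function(ay, ax, by, bx, max_dist) {
  n <- length(ay); m <- length(by)
  if (n == 0 && m == 0) return(0)
  D <- sqrt(outer(ay, by, `-`)^2 + outer(ax, bx, `-`)^2)
  D[D > max_dist] <- Inf
  best <- Inf
  rec <- function(i, used, cost, k) {
    if (i > n) {
      best <<- min(best, cost + max_dist * ((n - k) + (m - k)))
      return(invisible())
    }
    rec(i + 1, used, cost, k)
    for (j in seq_len(m)) {
      if (m > 0 && !used[j] && is.finite(D[i, j])) {
        u <- used; u[j] <- TRUE
        rec(i + 1, u, cost + D[i, j], k + 1)
      }
    }
  }
  rec(1, rep(FALSE, m), 0, 0)
  best
}

# cost of a match_points() solution under the same objective
match_cost <- function(links, ay, ax, by, bx, max_dist) {
  d <- if (nrow(links)) sum(sqrt((ay[links[, 1]] - by[links[, 2]])^2 +
                                 (ax[links[, 1]] - bx[links[, 2]])^2)) else 0
  d + max_dist * ((length(ay) - nrow(links)) + (length(by) - nrow(links)))
}

# independent naive Huang threshold oracle: direct per-candidate evaluation
huang_oracle <- function(v) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  g <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  h <- tabulate(g + 1L, 256L)
  n <- length(v)
  best_T <- NA; best_E <- Inf
  for (T in 0:254) {
    in0 <- 0:255 <= T
    w0 <- sum(h[in0]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[in0] * (0:255)[in0]) / w0
    mu1 <- sum(h[!in0] * (0:255)[!in0]) / w1
    E <- 0
    for (gl in 0:255) {
      if (h[gl + 1] == 0) next
      mu <- if (gl <= T) mu0 else mu1
      u <- 1 / (1 + abs(gl - mu) / 255)
      s <- if (u >= 1 - 1e-12) 0 else -u * log(u) - (1 - u) * log(1 - u)
      E <- E + h[gl + 1] * s
    }
    E <- E / n
    if (E < best_E - 1e-12) { best_E <- E; best_T <- T }
  }
  lo + (best_T + 0.5) / 256 * (hi - lo)
}
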