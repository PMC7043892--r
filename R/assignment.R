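# Minimum-cost square assignment (Jonker-Volgenant style shortest augmenting
# path with potentials). `cost` may contain Inf for forbidden pairs but every
# row must have at least one finite completion. Returns, for each row, the
# assigned column.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  VC <- n + 1L                       # virtual start column
  u <- numeric(n); v <- numeric(VC)
  p <- integer(VC)                   # p[j]: row currently assigned to col j
  way <- integer(n)
  for (i in seq_len(n)) {
    p[VC] <- i
    j0 <- VC
    minv <- rep(Inf, n)
    used <- rep(FALSE, VC)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      if (length(free) == 0L) stop("assignment infeasible")
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      jrel <- which.min(minv[free])
      delta <- minv[free][jrel]
      if (!is.finite(delta)) stop("assignment infeasible")
      j1 <- free[jrel]
      uj <- which(used)
      u[p[uj]] <- u[p[uj]] + delta
      v[uj] <- v[uj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == VC) break
    }
  }
  rowsol <- integer(n)
  rowsol[p[seq_len(n)]] <- seq_len(n)
  rowsol
}

# Optimal frame-pair (or end-start) matching a la the linear assignment
# particle-linking framework: candidate pairs cost their distance, declining
# a link costs `alt_cost` per unmatched point. Since every admissible
# distance is <= alt_cost, the optimum maximizes the number of links and
# then minimizes total distance. Returns a two-column matrix (index in A,
# index in B) of links.
match_points <- function(ay, ax, by, bx, max_dist, alt_cost = max_dist) {
  n <- length(ay); m <- length(by)
  if (n == 0L || m == 0L) return(matrix(integer(0), 0, 2))
  D <- sqrt(outer(ay, by, `-`)^2 + outer(ax, bx, `-`)^2)
  D[D > max_dist] <- Inf
  if (all(!is.finite(D))) return(matrix(integer(0), 0, 2))
  N <- n + m
  C <- matrix(Inf, N, N)
  C[seq_len(n), seq_len(m)] <- D
  C[seq_len(n), m + seq_len(n)] <- ifelse(diag(n) == 1, alt_cost, Inf)
  C[n + seq_len(m), seq_len(m)] <- ifelse(diag(m) == 1, alt_cost, Inf)
  C[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- lap_solve(C)
  links <- cbind(seq_len(n), sol[seq_len(n)])
  links <- links[links[, 2] <= m, , drop = FALSE]
  links
}
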