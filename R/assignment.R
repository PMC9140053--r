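# Globally optimal one-to-one assignment (rectangular, with forbidden
# pairs), used to match predicted tracks to localizations within the gate.
# Shortest-augmenting-path Hungarian method with potentials on the square
# padded cost matrix; forbidden pairs carry a large finite cost and are
# dropped from the returned assignment, which therefore is the
# minimum-total-cost assignment of maximum cardinality over allowed pairs.

.ASSIGN_BIG <- 1e8

#' Solve a minimum-cost one-to-one assignment
#'
#' @param cost numeric matrix (rows = tracks, cols = localizations);
#'   `Inf` marks a forbidden pair (for example, outside the gate).
#' @return integer vector of length `nrow(cost)`: for each row the assigned
#'   column, or `NA` if unassigned.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  stop_if_not(all(cost >= 0 | is.infinite(cost), na.rm = TRUE),
              "costs must be non-negative")
  N <- max(n, m)
  C <- matrix(.ASSIGN_BIG, N, N)
  C[seq_len(n), seq_len(m)] <- pmin(cost, .ASSIGN_BIG)

  u <- numeric(N)          # row potentials
  v <- numeric(N + 1)      # col potentials, v[1] is the virtual column 0
  p <- integer(N + 1)      # p[j+1] = row assigned to column j (0 = none)
  way <- integer(N + 1)
  for (i in seq_len(N)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, N)
    used <- rep(FALSE, N + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- C[i0, free] - u[i0] - v[free + 1]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedc <- which(used)
      u[p[usedc]] <- u[p[usedc]] + delta
      v[usedc] <- v[usedc] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- rep(NA_integer_, n)
  for (j in seq_len(N)) {
    i <- p[j + 1]
    if (i >= 1 && i <= n && j <= m && is.finite(cost[i, j]) &&
        cost[i, j] < .ASSIGN_BIG) out[i] <- j
  }
  out
}
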