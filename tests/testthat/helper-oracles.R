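# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Exhaustive transitive-closure clustering of entry times at a gap
# threshold: entries i, j are linked when |t_i - t_j| <= gap; clusters are
# the connected components. O(n^2) per day.
oracle_gap_clusters <- function(times, gap = 30) {
  n <- length(times)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(times[i] - times[j]) <= gap && comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(times)]))
}

# Fine-grid numeric integration of the incremental area: each inter-sample
# segment subdivided, linear interpolation, trapezoid of the (clipped)
# increment, minutes -> seconds.
oracle_iauc <- function(time_min, conc, horizon, policy = "clip", subdiv = 20000) {
  grid <- unique(sort(c(unlist(lapply(seq_len(length(time_min) - 1), function(i) {
    seq(time_min[i], time_min[i + 1], length.out = subdiv + 1)
  })), horizon)))
  grid <- grid[grid <= horizon]
  y <- approx(time_min, conc, xout = grid)$y - conc[1]
  if (policy == "clip") y <- pmax(y, 0)
  sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2) * 60
}

# Brute-force Benjamini-Hochberg step-up: adj(i) = min over j with
# p(j) >= p(i) of m * p(j) / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Random piecewise-linear postprandial curve on a fixed sampling grid.
random_curve <- function(tpts = c(0, 15, 30, 60, 120, 180, 240, 270, 300, 360)) {
  base <- runif(1, 3, 7)
  list(t = tpts, y = pmax(0, base + c(0, rnorm(length(tpts) - 1, 0, 1.5))))
}
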