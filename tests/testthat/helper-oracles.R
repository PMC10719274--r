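# Independent brute-force oracles used to check the graph metrics, plus
# small fixture generators. These deliberately share no code with the
# package implementation (Floyd-Warshall and exhaustive grid scans vs
# Dijkstra/Brandes/L-BFGS-B).

# all-pairs shortest paths by Floyd-Warshall on edge lengths d = 1/W
fw_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      alt <- D[i, k] + D[k, ]
      upd <- alt < D[i, ]
      D[i, upd] <- alt[upd]
    }
  }
  D
}

fw_lp <- function(W) {
  D <- fw_distances(W)
  v <- D[upper.tri(D)]
  mean(v[is.finite(v)])
}

fw_eglob <- function(W) {
  n <- nrow(W)
  D <- fw_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# betweenness by Floyd-Warshall with shortest-path counting: a path is
# counted when its highest-indexed intermediate vertex is processed, then
# nodal dependencies are accumulated by the pair-splitting identity.
fw_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  N <- (W > 0) * 1
  diag(N) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k) next
      for (j in seq_len(n)) {
        if (j == i || j == k) next
        alt <- D[i, k] + D[k, j]
        if (!is.finite(alt)) next
        if (alt < D[i, j] - tol) {
          D[i, j] <- alt
          N[i, j] <- N[i, k] * N[k, j]
        } else if (abs(alt - D[i, j]) <= tol) {
          N[i, j] <- N[i, j] + N[i, k] * N[k, j]
        }
      }
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(D[s, t]) || N[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            abs(D[s, v] + D[v, t] - D[s, t]) <= tol) {
          btw[v] <- btw[v] + N[s, v] * N[v, t] / N[s, t]
        }
      }
    }
  }
  btw
}

# random symmetric weighted graph with at least `min_edges` edges
rand_wgraph <- function(n, p = 0.6, unit = FALSE, min_edges = 2) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    sel <- up[stats::runif(length(up)) < p]
    if (length(sel) < min_edges) next
    A[sel] <- if (unit) 1 else stats::runif(length(sel), 0.5, 1.5)
    return(A + t(A))
  }
}

# exhaustive grid scan of the discounting likelihood (oracle for the
# optimizer): returns the minimum negative log-likelihood over the grid
dd_grid_scan <- function(trials, k_grid = 10^seq(-4, 0, length.out = 200),
                         beta_grid = 10^seq(-4, 0, length.out = 200)) {
  best <- Inf
  ch1 <- trials$choice == 1
  for (k in k_grid) {
    dsv <- trials$delayed_amount / (1 + k * trials$delay_days) -
      trials$immediate_amount
    for (b in beta_grid) {
      x <- b * dsv
      nll <- -sum(ifelse(ch1, stats::plogis(x, log.p = TRUE),
                         stats::plogis(-x, log.p = TRUE)))
      if (nll < best) best <- nll
    }
  }
  best
}

# textbook Spearman: average ranks computed by hand, Pearson via moment sums
spearman_textbook <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (u in unique(v)) {
      r[v == u] <- mean(which(sort(v) == u))
    }
    r
  }
  a <- avg_rank(x)
  b <- avg_rank(y)
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# small unit-weight standards
unit_complete <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  W
}

unit_path3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  W
}

empty_edges <- function() {
  data.frame(node_i = integer(0), node_j = integer(0),
             fiber_count = numeric(0), mean_fa = numeric(0))
}
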