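# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: path enumeration instead of dynamic programming,
# boot::simplex instead of the package simplex, and a hand-rolled growth
# loop instead of grow_network().

# All feasible paths of a tiered system, as a matrix with one node index
# per tier per row, in lexicographic order (tier 1 varies slowest).
enumerate_paths <- function(ts) {
  K <- length(ts$tiers)
  sizes <- vapply(ts$tiers, length, 1L)
  grid <- do.call(expand.grid, c(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE))
  grid <- as.matrix(grid[, K:1, drop = FALSE])
  if (!is.null(ts$adjacency)) {
    ok <- rep(TRUE, nrow(grid))
    for (k in seq_len(K - 1L)) {
      Ak <- ts$adjacency[[k]]
      if (is.null(Ak)) next
      ok <- ok & Ak[cbind(grid[, k], grid[, k + 1L])] != 0
    }
    grid <- grid[ok, , drop = FALSE]
  }
  grid
}

# Brute-force least-unfit path: minimum of sum_k q[j_k] * U[j_k] over all
# feasible paths; returns list(cost, path) with the lexicographically first
# minimiser.
brute_force_path <- function(ts, q) {
  paths <- enumerate_paths(ts)
  stopifnot(nrow(paths) > 0)
  w <- lapply(seq_along(ts$tiers), function(k) q[[k]] * ts$tiers[[k]]$unfitness)
  cost <- rowSums(vapply(seq_along(w), function(k) w[[k]][paths[, k]],
                         numeric(nrow(paths))))
  best <- which.min(cost)
  list(cost = cost[best], path = paths[best, ])
}

# LP oracle via boot::simplex (an implementation entirely separate from the
# package's): min V s.t. p_j U_j - V <= 0, sum p = 1, p >= 0.
boot_simplex_p0 <- function(fv) {
  n <- length(fv)
  U <- fv$unfitness
  # variables (p_1..p_n, V); maximise -V
  a <- c(rep(0, n), -1)
  A1 <- cbind(diag(U, n), -1)     # exposure rows, <= 0
  b1 <- rep(0, n)
  A3 <- matrix(c(rep(1, n), 0), 1)
  b3 <- 1
  res <- boot::simplex(a = a, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = TRUE)
  stopifnot(res$solved == 1)
  list(p = unname(res$soln[seq_len(n)]), value = unname(res$soln[n + 1]))
}

# Reference growth loop with a fixed uniform kernel, mirroring
# grow_network()'s RNG schedule for an explicit (pre-supplied) fitness
# vector: the only RNG draws are the sample() calls.
grow_uniform_reference <- function(n_final, m_edges, m0, seed) {
  set.seed(seed)
  n_edges <- (m0 * (m0 - 1)) %/% 2 + (n_final - m0) * m_edges
  edges <- matrix(0L, n_edges, 2)
  k <- 0L
  if (m0 > 1L) {
    sp <- utils::combn(m0, 2)
    k <- ncol(sp)
    edges[seq_len(k), ] <- t(sp)
  }
  for (v in (m0 + 1L):n_final) {
    existing <- seq_len(v - 1L)
    prob <- rep(1 / (v - 1L), v - 1L)
    targets <- sample(existing, size = m_edges, replace = FALSE, prob = prob)
    edges[k + seq_len(m_edges), 1] <- targets
    edges[k + seq_len(m_edges), 2] <- v
    k <- k + m_edges
  }
  edges
}

# Random sparse-but-feasible adjacency between consecutive tiers.
random_adjacency <- function(sizes, p_keep = 0.5) {
  K <- length(sizes)
  lapply(seq_len(K - 1L), function(k) {
    repeat {
      M <- matrix(as.integer(runif(sizes[k] * sizes[k + 1]) < p_keep),
                  sizes[k], sizes[k + 1])
      if (all(rowSums(M) > 0) && all(colSums(M) > 0)) return(M)
    }
  })
}

sample_moments <- function(x) {
  m <- mean(x); s <- sd(x)
  z <- (x - m) / s
  c(skew = mean(z^3), exkurt = mean(z^4) - 3)
}
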