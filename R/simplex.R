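# Dense two-phase primal simplex with Bland's rule, for the small minmax
# exposure programs (tens of variables).  Written here because the runtime
# environment ships no dedicated LP package; kept deliberately textbook so
# it can serve as an oracle route independent of both the closed form and
# the iterative game algorithms.  Duals are recovered from the optimal
# basis (y' = c_B' B^{-1}) via a clean linear solve against the original
# constraint matrix, which also polishes the primal solution to near
# machine precision.

# min c'x  s.t.  A x = b, x >= 0.  Returns x, objective, duals y, basis.
simplex_lp <- function(cvec, A, b, tol = 1e-11, max_pivots = 10000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # tableau over [A | I_artificial | b]; artificial columns double as B^{-1}
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  art <- n + seq_len(m)

  pivot <- function(Tab, r, s) {
    Tab[r, ] <- Tab[r, ] / Tab[r, s]
    for (i in seq_len(nrow(Tab))) {
      if (i != r && Tab[i, s] != 0) Tab[i, ] <- Tab[i, ] - Tab[i, s] * Tab[r, ]
    }
    Tab
  }

  run_phase <- function(Tab, basis, cost, allowed) {
    for (it in seq_len(max_pivots)) {
      cb <- cost[basis]
      red <- cost[allowed] - as.vector(crossprod(cb, Tab[, allowed, drop = FALSE]))
      ent <- allowed[which(red < -tol)]
      if (length(ent) == 0L) return(list(Tab = Tab, basis = basis, status = "optimal"))
      s <- min(ent)                               # Bland: lowest index enters
      col <- Tab[, s]
      rows <- which(col > tol)
      if (length(rows) == 0L) return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[rows, ncol(Tab)] / col[rows]
      cand <- rows[ratio <= min(ratio) + tol]
      r <- cand[which.min(basis[cand])]           # Bland: lowest basic index leaves
      Tab <- pivot(Tab, r, s)
      basis[r] <- s
    }
    list(Tab = Tab, basis = basis, status = "pivot_limit")
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(1, m), 0)
  ph1 <- run_phase(Tab, basis, cost1, seq_len(n + m))
  if (ph1$status != "optimal")
    return(list(status = paste0("phase1_", ph1$status)))
  Tab <- ph1$Tab; basis <- ph1$basis
  if (sum(cost1[basis] * Tab[, ncol(Tab)]) > 1e-7)
    return(list(status = "infeasible"))
  # force lingering (degenerate) artificials out of the basis
  for (r in which(basis %in% art)) {
    s <- which(abs(Tab[r, seq_len(n)]) > tol)
    if (length(s) > 0L) { Tab <- pivot(Tab, r, min(s)); basis[r] <- min(s) }
  }
  keep <- !(basis %in% art)
  if (!all(keep)) {  # redundant rows: drop them and the matching artificials
    Tab <- Tab[keep, , drop = FALSE]
    basis <- basis[keep]
    A <- A[keep, , drop = FALSE]; b <- b[keep]
  }

  # phase 2: true objective, artificial columns barred
  cost2 <- c(cvec, rep(0, length(art)), 0)
  ph2 <- run_phase(Tab, basis, cost2, seq_len(n))
  if (ph2$status != "optimal") return(list(status = ph2$status))
  basis <- ph2$basis

  # polish primal and dual from the optimal basis against the original data
  B <- A[, basis, drop = FALSE]
  xb <- solve(B, b)
  x <- numeric(n); x[basis] <- xb
  y <- solve(t(B), cvec[basis])
  list(status = "optimal", x = x, obj = sum(cvec * x), y = as.numeric(y),
       basis = basis)
}
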