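#' Closed-form minmax attachment probabilities
#'
#' Choosing attachment probabilities to minimise the maximum expected
#' exposure to node unfitness \eqn{U_j = 1/\phi_j} has the closed-form
#' solution \eqn{p_j^* = \phi_j / \sum_i \phi_i}: attachment proportional to
#' fitness.  At this solution every exposure product \eqn{p_j U_j} equals
#' the minmax value \eqn{V^* = 1 / \sum_i \phi_i}.
#'
#' @param fv a [fitness_vector()].
#' @return Numeric probability vector over nodes (sums to 1).
#' @examples
#' closed_form_attachment(fitness_vector(c(1, 2, 3, 4)))  # 0.1 0.2 0.3 0.4
#' @export
closed_form_attachment <- function(fv) {
  assert_fitness_vector(fv)
  fv$phi / sum(fv$phi)
}

#' Minmax expected network unfitness
#'
#' @param fv a [fitness_vector()].
#' @return The scalar \eqn{V^* = 1 / \sum_j \phi_j}.
#' @examples
#' minmax_value(fitness_vector(c(1, 2, 3, 4)))  # 0.1
#' @export
minmax_value <- function(fv) {
  assert_fitness_vector(fv)
  1 / sum(fv$phi)
}

new_minmax_solution <- function(p, q, value, lambda_dual, method, node_id,
                                converged = TRUE, iterations = NA_real_,
                                gap = NA_real_, error_bound = NA_real_) {
  structure(list(node_id = node_id, p = p, q = q, value = value,
                 lambda_dual = lambda_dual, method = method,
                 converged = converged, iterations = iterations,
                 gap = gap, error_bound = error_bound),
            class = "minmax_solution")
}

#' @export
print.minmax_solution <- function(x, ...) {
  cat(sprintf("<minmax_solution> method=%s, %d nodes, V=%.6g, lambda=%.6g%s\n",
              x$method, length(x$p), x$value, x$lambda_dual,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Solve the homogeneous minmax-exposure problem in closed form
#'
#' @param fv a [fitness_vector()].
#' @return A `minmax_solution` with `p = q = phi/sum(phi)` and
#'   `value = lambda_dual = 1/sum(phi)`.
#' @export
solve_closed_form <- function(fv) {
  p <- closed_form_attachment(fv)
  v <- minmax_value(fv)
  new_minmax_solution(p = p, q = p, value = v, lambda_dual = v,
                      method = "closed", node_id = fv$node_id)
}

#' Solve the homogeneous minmax-exposure problem as a linear program
#'
#' Solves `min V` subject to `p_j U_j <= V` for every node, `sum(p) = 1`,
#' `p >= 0`, by a two-phase simplex, and extracts the dual weights `q` on
#' the exposure constraints together with the multiplier `lambda` on the
#' simplex constraint.  At the optimum `q` equals `p` and `lambda` equals
#' `V` whenever all fitness values are positive.  This route never uses the
#' closed form; it exists as an independent check of it.
#'
#' @param fv a [fitness_vector()].
#' @return A `minmax_solution` with fields `p`, `q` (duals, normalised to
#'   sum to 1), `value` (V), and `lambda_dual`.
#' @examples
#' sol <- solve_lp_p0(fitness_vector(c(1, 3)))
#' sol$p       # 0.25 0.75
#' sol$value   # 0.25
#' @export
solve_lp_p0 <- function(fv) {
  assert_fitness_vector(fv)
  n <- length(fv)
  U <- fv$unfitness
  # variables: p (n), V (1), slacks (n); rows: U_j p_j - V + s_j = 0; sum p = 1
  A <- cbind(rbind(diag(U, n), 1),
             c(rep(-1, n), 0),
             rbind(diag(n), 0))
  b <- c(rep(0, n), 1)
  cvec <- c(rep(0, n), 1, rep(0, n))
  res <- simplex_lp(cvec, A, b)
  if (res$status != "optimal")
    stop("LP solver failed with status: ", res$status, call. = FALSE)
  p <- res$x[seq_len(n)]
  V <- res$x[n + 1]
  q_raw <- -res$y[seq_len(n)]       # exposure-row duals; <= 0 by LP duality
  lambda <- res$y[n + 1]
  new_minmax_solution(p = p, q = q_raw / sum(q_raw), value = V,
                      lambda_dual = lambda, method = "lp",
                      node_id = fv$node_id)
}

#' Initialise the state of the iterative game algorithm
#'
#' Both players start from the uniform distribution; the iteration counter
#' starts at `m = 1` so the first averaging step uses
#' \eqn{\alpha_1 = 1/2}.
#'
#' @param fv a [fitness_vector()].
#' @return An object of class `game_state` with fields `m`, `p`, `q`,
#'   `upper_bound` (`max_j p_j U_j`), `lower_bound` (`min_j q_j U_j`).
#' @export
game_state_init <- function(fv) {
  assert_fitness_vector(fv)
  n <- length(fv)
  p <- rep(1 / n, n)
  new_game_state(m = 1L, p = p, q = p, fv = fv)
}

new_game_state <- function(m, p, q, fv) {
  structure(list(m = m, p = p, q = q,
                 upper_bound = max(p * fv$unfitness),
                 lower_bound = min(q * fv$unfitness)),
            class = "game_state")
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("<game_state> m=%d, gap=%.4g (upper %.6g, lower %.6g)\n",
              x$m, x$upper_bound - x$lower_bound, x$upper_bound, x$lower_bound))
  invisible(x)
}

#' One iteration of the homogeneous scheduler-vs-demon game
#'
#' With step size \eqn{\alpha_m = 1/(m+1)}: the scheduler finds the node
#' with the lowest weighted unfitness \eqn{q_j U_j} and moves `p` toward
#' that vertex; the demon then finds the node with the highest expected
#' unfitness \eqn{p_i U_i} (using the updated `p`) and moves `q` toward
#' that vertex; `m` is incremented.  Ties break at the lowest node index.
#'
#' @param state a `game_state`.
#' @param fv the [fitness_vector()] the game is played on.
#' @return The updated `game_state`.
#' @export
a0_step <- function(state, fv) {
  assert_fitness_vector(fv)
  stopifnot(inherits(state, "game_state"))
  U <- fv$unfitness
  a <- 1 / (state$m + 1)
  jstar <- which.min(state$q * U)          # lowest weighted unfitness
  p <- (1 - a) * state$p
  p[jstar] <- p[jstar] + a
  istar <- which.max(p * U)                # highest expected unfitness
  q <- (1 - a) * state$q
  q[istar] <- q[istar] + a
  new_game_state(m = state$m + 1L, p = p, q = q, fv = fv)
}

#' Solve the homogeneous problem by the method of successive averages
#'
#' Runs the two-player zero-sum game until convergence.  Two stopping rules
#' are available: `"gap"` stops when the duality gap
#' \eqn{\max_j p_j U_j - \min_j q_j U_j \le} `tol` (the default; the gap
#' brackets the game value \eqn{V^*} from both sides), and
#' `"error_bound"` stops when a certified a-posteriori bound on both
#' players' errors, \eqn{\max_j \max(|p_j - p_j^*|, |q_j - q_j^*|)}, is at
#' most `tol` (derived from
#' \eqn{|x_j - \phi_j V^*| = \phi_j |x_j U_j - V^*|} with \eqn{V^*}
#' bracketed by the running bounds; strictly stronger than the gap, and the
#' right choice when the fitness spread is large).  The closed form is never consulted.
#'
#' @param fv a [fitness_vector()].
#' @param tol convergence tolerance (default `1e-4`).
#' @param max_iter iteration cap (default `1e6`); reaching it flags
#'   non-convergence in the result rather than raising an error.
#' @param criterion `"gap"`, `"error_bound"`, or `"both"` (gap at most
#'   `tol` and certified error at most `error_tol` simultaneously).
#' @param error_tol error-bound tolerance used by `criterion = "both"`
#'   (defaults to `tol`).
#' @param check_every check the stopping rule every this many iterations.
#' @param trace_every record `(m, upper, lower)` every this many iterations;
#'   `NULL` thins automatically to about 1000 rows; `0` disables the trace.
#' @return A list with elements `solution` (a `minmax_solution` whose
#'   `value` is the final upper bound and `lambda_dual` the final lower
#'   bound) and `state` (final `game_state` plus `converged`, `iterations`,
#'   and a `trace` data frame).
#' @examples
#' fit <- fitness_vector(c(1, 3))
#' run_a0(fit, tol = 1e-3)$solution$p   # ~ 0.25 0.75
#' @export
run_a0 <- function(fv, tol = 1e-4, max_iter = 1e6,
                   criterion = c("gap", "error_bound", "both"),
                   error_tol = tol, check_every = 16L, trace_every = NULL) {
  assert_fitness_vector(fv)
  criterion <- match.arg(criterion)
  if (!is.numeric(tol) || tol <= 0) stop_validation("tol must be > 0")
  if (max_iter < 1) stop_validation("max_iter must be >= 1")
  if (is.null(trace_every)) trace_every <- max(1, floor(max_iter / 1000))
  st <- game_state_init(fv)
  res <- .msa_a0_cpp(fv$phi, st$p, st$q, st$m, tol, error_tol, max_iter,
                     match(criterion, c("gap", "error_bound", "both")) - 1L,
                     as.integer(check_every), trace_every)
  state <- new_game_state(m = as.integer(res$m), p = res$p, q = res$q, fv = fv)
  state$converged <- res$converged
  state$iterations <- res$steps
  state$trace <- data.frame(iteration = res$trace_m,
                            upper_bound = res$trace_upper,
                            lower_bound = res$trace_lower)
  sol <- new_minmax_solution(p = res$p, q = res$q, value = res$upper,
                             lambda_dual = res$lower, method = "a0",
                             node_id = fv$node_id, converged = res$converged,
                             iterations = res$steps, gap = res$gap,
                             error_bound = res$error_bound)
  list(solution = sol, state = state)
}
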