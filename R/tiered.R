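#' Construct a tiered system
#'
#' A tiered system is an ordered sequence of node sets (tiers) — e.g.
#' suppliers, manufacturers, distributors, retailers in a supply chain —
#' where links are only feasible between consecutive tiers and a feasible
#' selection is a path taking exactly one node per tier.  Tier 1 is the most
#' upstream.
#'
#' @param tiers a list of [fitness_vector()]s (or bare numeric fitness
#'   vectors, which are coerced), one per tier, at least two.
#' @param adjacency `NULL` for complete bipartite adjacency between every
#'   consecutive pair (the default), or a list of `length(tiers) - 1`
#'   elements, each either `NULL` (complete) or a logical/0-1 matrix with
#'   rows indexing the upstream tier and columns the downstream tier.
#' @param tier_names optional character names for the tiers.
#' @return An object of class `tiered_system`.
#' @examples
#' ts <- tiered_system(list(c(1, 1), c(1, 3)))
#' per_tier_closed_form(ts)   # list(c(0.5, 0.5), c(0.25, 0.75))
#' @export
tiered_system <- function(tiers, adjacency = NULL, tier_names = NULL) {
  if (!is.list(tiers) || length(tiers) < 2L)
    stop_validation("a tiered system needs at least two tiers")
  tiers <- lapply(seq_along(tiers), function(k) {
    tk <- tiers[[k]]
    if (inherits(tk, "fitness_vector")) tk
    else fitness_vector(tk, node_ids = paste0("t", k, "_n", seq_along(tk)))
  })
  K <- length(tiers)
  if (is.null(tier_names)) tier_names <- paste0("tier", seq_len(K))
  if (length(tier_names) != K) stop_validation("tier_names length mismatch")
  if (!is.null(adjacency)) {
    if (!is.list(adjacency) || length(adjacency) != K - 1L)
      stop_validation("adjacency must be a list of length(tiers) - 1")
    for (k in seq_len(K - 1L)) {
      Ak <- adjacency[[k]]
      if (is.null(Ak)) next
      Ak <- (as.matrix(Ak) != 0) * 1L
      if (!all(dim(Ak) == c(length(tiers[[k]]), length(tiers[[k + 1]]))))
        stop_validation("adjacency[[", k, "]] has wrong dimensions")
      adjacency[[k]] <- Ak
    }
  }
  ts <- structure(list(tiers = tiers, adjacency = adjacency,
                       tier_names = tier_names),
                  class = "tiered_system")
  if (!any(is.finite(path_reachability(ts))))
    stop_validation("no feasible path traverses all tiers")
  ts
}

# cost-0 reachability: finite entries mark last-tier nodes reachable from tier 1
path_reachability <- function(ts) {
  K <- length(ts$tiers)
  reach <- rep(0, length(ts$tiers[[1]]))
  for (k in seq_len(K - 1L)) {
    Ak <- if (is.null(ts$adjacency)) NULL else ts$adjacency[[k]]
    nxt <- rep(Inf, length(ts$tiers[[k + 1]]))
    if (is.null(Ak)) {
      if (any(is.finite(reach))) nxt[] <- 0
    } else {
      for (j in seq_along(nxt))
        if (any(is.finite(reach[Ak[, j] != 0]))) nxt[j] <- 0
    }
    reach <- nxt
  }
  reach
}

#' @export
print.tiered_system <- function(x, ...) {
  cat(sprintf("<tiered_system> %d tiers (%s); adjacency: %s\n",
              length(x$tiers),
              paste(vapply(x$tiers, length, 1L), collapse = ", "),
              if (is.null(x$adjacency)) "complete" else "restricted"))
  invisible(x)
}

#' Per-tier closed-form attachment probabilities
#'
#' Because every feasible path passes through each tier exactly once, the
#' tiered minmax-exposure problem decouples into one homogeneous problem
#' per tier, each with the fitness-proportional solution.
#'
#' @param ts a [tiered_system()].
#' @return A list with one probability vector per tier,
#'   `p_jk = phi_jk / sum_tier(phi)`.
#' @export
per_tier_closed_form <- function(ts) {
  assert_tiered(ts)
  lapply(ts$tiers, closed_form_attachment)
}

#' Minmax expected unfitness of each tier
#'
#' @param ts a [tiered_system()].
#' @return Numeric vector, `V_k = 1 / sum_{j in tier k} phi_jk`.
#' @export
tier_minmax_values <- function(ts) {
  assert_tiered(ts)
  vapply(ts$tiers, minmax_value, numeric(1))
}

#' Solve the tiered minmax-exposure problem tier by tier with an LP
#'
#' Each tier's program is solved independently by [solve_lp_p0()]; the
#' total reported value is the sum of tier values.
#'
#' @param ts a [tiered_system()].
#' @return A list with `solutions` (one `minmax_solution` per tier) and
#'   `total_value` (`sum_k V_k`).
#' @export
solve_lp_p2 <- function(ts) {
  assert_tiered(ts)
  sols <- lapply(ts$tiers, solve_lp_p0)
  list(solutions = sols,
       total_value = sum(vapply(sols, function(s) s$value, numeric(1))))
}

#' Least-unfit path through a tiered system
#'
#' Finds the path (one node per tier, consecutive nodes adjacent) minimising
#' the sum of avoidance-weighted unfitness \eqn{q_{jk} U_{jk}} by dynamic
#' programming over the layered DAG — no path enumeration.  Ties break
#' toward the lowest node index at every choice; under complete adjacency
#' the result is simply the per-tier argmin.
#'
#' @param ts a [tiered_system()].
#' @param q a list with one probability vector per tier (avoidance
#'   weights); defaults to uniform in every tier.
#' @return An object of class `path_selection`: list with `indices` (one
#'   node index per tier), `node_ids`, and `cost`.
#' @export
shortest_unfit_path <- function(ts, q = NULL) {
  assert_tiered(ts)
  K <- length(ts$tiers)
  if (is.null(q)) q <- lapply(ts$tiers, function(tk) rep(1 / length(tk), length(tk)))
  stopifnot(length(q) == K)
  w <- lapply(seq_len(K), function(k) q[[k]] * ts$tiers[[k]]$unfitness)

  best <- vector("list", K); pred <- vector("list", K)
  best[[1]] <- w[[1]]; pred[[1]] <- rep(NA_integer_, length(w[[1]]))
  for (k in 2:K) {
    Ak <- if (is.null(ts$adjacency)) NULL else ts$adjacency[[k - 1]]
    nk <- length(w[[k]])
    best[[k]] <- rep(Inf, nk); pred[[k]] <- rep(NA_integer_, nk)
    if (is.null(Ak)) {
      imin <- which.min(best[[k - 1]])
      best[[k]] <- best[[k - 1]][imin] + w[[k]]
      pred[[k]][] <- imin
    } else {
      for (j in seq_len(nk)) {
        up <- which(Ak[, j] != 0)
        up <- up[is.finite(best[[k - 1]][up])]
        if (length(up) > 0L) {
          i <- up[which.min(best[[k - 1]][up])]
          best[[k]][j] <- best[[k - 1]][i] + w[[k]][j]
          pred[[k]][j] <- i
        }
      }
    }
  }
  last <- which.min(best[[K]])
  if (!is.finite(best[[K]][last]))
    stop("no feasible path through the tiers", call. = FALSE)
  idx <- integer(K); idx[K] <- last
  for (k in K:2) idx[k - 1] <- pred[[k]][idx[k]]
  structure(list(indices = idx,
                 node_ids = vapply(seq_len(K),
                                   function(k) ts$tiers[[k]]$node_id[idx[k]], ""),
                 cost = best[[K]][last]),
            class = "path_selection")
}

#' @export
print.path_selection <- function(x, ...) {
  cat(sprintf("<path_selection> %s (cost %.6g)\n",
              paste(x$node_ids, collapse = " -> "), x$cost))
  invisible(x)
}

#' Initialise the tiered game state
#'
#' @param ts a [tiered_system()].
#' @return A `tiered_game_state` with uniform `p` and `q` in every tier and
#'   `m = 1`.
#' @export
tiered_game_state_init <- function(ts) {
  assert_tiered(ts)
  p <- lapply(ts$tiers, function(tk) rep(1 / length(tk), length(tk)))
  new_tiered_game_state(m = 1L, p = p, q = p, ts = ts)
}

new_tiered_game_state <- function(m, p, q, ts) {
  ub <- mapply(function(pk, tk) max(pk * tk$unfitness), p, ts$tiers)
  lb <- mapply(function(qk, tk) min(qk * tk$unfitness), q, ts$tiers)
  structure(list(m = m, p = p, q = q, upper_bound = ub, lower_bound = lb),
            class = "tiered_game_state")
}

#' @export
print.tiered_game_state <- function(x, ...) {
  cat(sprintf("<tiered_game_state> m=%d, max tier gap=%.4g\n",
              x$m, max(x$upper_bound - x$lower_bound)))
  invisible(x)
}

#' One iteration of the tiered scheduler-vs-demon game
#'
#' The scheduler picks the least-unfit feasible path under the demon's
#' weights and moves every tier's `p` toward that path's node; the demon
#' then picks, per tier, the node most exposed to unfitness under the
#' updated `p` and moves `q` toward it.  Step size \eqn{\alpha_m = 1/(m+1)},
#' lowest-index tie-breaks, as in [a0_step()].
#'
#' @param state a `tiered_game_state`.
#' @param ts the [tiered_system()].
#' @return The updated `tiered_game_state`.
#' @export
a1_step <- function(state, ts) {
  assert_tiered(ts)
  stopifnot(inherits(state, "tiered_game_state"))
  a <- 1 / (state$m + 1)
  path <- shortest_unfit_path(ts, state$q)
  K <- length(ts$tiers)
  p <- state$p; q <- state$q
  for (k in seq_len(K)) {
    p[[k]] <- (1 - a) * p[[k]]
    p[[k]][path$indices[k]] <- p[[k]][path$indices[k]] + a
    istar <- which.max(p[[k]] * ts$tiers[[k]]$unfitness)
    q[[k]] <- (1 - a) * q[[k]]
    q[[k]][istar] <- q[[k]][istar] + a
  }
  new_tiered_game_state(m = state$m + 1L, p = p, q = q, ts = ts)
}

#' Solve the tiered problem by the method of successive averages
#'
#' Iterates [a1_step()] (in compiled code) until every tier meets the
#' stopping rule, or `max_iter` is reached (flagged, not an error).
#' Stopping rules as in [run_a0()], applied per tier.
#'
#' @param ts a [tiered_system()].
#' @inheritParams run_a0
#' @return A list with `solutions` (one `minmax_solution` per tier, whose
#'   `value`/`lambda_dual` are the tier's final upper/lower bounds),
#'   `state` (final `tiered_game_state` with `converged`, `iterations`, and
#'   a per-tier bounds `trace`), and `total_value`.
#' @examples
#' ts <- tiered_system(list(c(1, 1), c(1, 3)))
#' run_a1(ts, tol = 1e-3)$solutions[[2]]$p   # ~ 0.25 0.75
#' @export
run_a1 <- function(ts, tol = 1e-4, max_iter = 1e6,
                   criterion = c("gap", "error_bound", "both"),
                   error_tol = tol, check_every = 64L, trace_every = NULL) {
  assert_tiered(ts)
  criterion <- match.arg(criterion)
  if (!is.numeric(tol) || tol <= 0) stop_validation("tol must be > 0")
  if (max_iter < 1) stop_validation("max_iter must be >= 1")
  if (is.null(trace_every)) trace_every <- max(1, floor(max_iter / 1000))
  st <- tiered_game_state_init(ts)
  phi <- lapply(ts$tiers, `[[`, "phi")
  adj <- if (is.null(ts$adjacency)) vector("list", length(phi) - 1L) else ts$adjacency
  adj <- lapply(adj, function(a) if (is.null(a)) NULL else matrix(as.integer(a), nrow(a)))
  res <- .msa_a1_cpp(phi, st$p, st$q, adj, st$m, tol, error_tol, max_iter,
                     match(criterion, c("gap", "error_bound", "both")) - 1L,
                     as.integer(check_every), trace_every)
  state <- new_tiered_game_state(m = as.integer(res$m), p = res$p, q = res$q, ts = ts)
  state$converged <- res$converged
  state$iterations <- res$steps
  state$trace <- lapply(seq_along(phi), function(k)
    data.frame(iteration = res$trace_m,
               upper_bound = res$trace_upper[[k]],
               lower_bound = res$trace_lower[[k]]))
  sols <- lapply(seq_along(phi), function(k)
    new_minmax_solution(p = res$p[[k]], q = res$q[[k]], value = res$upper[k],
                        lambda_dual = res$lower[k], method = "a1",
                        node_id = ts$tiers[[k]]$node_id,
                        converged = res$converged, iterations = res$steps,
                        gap = res$gap[k], error_bound = res$error_bound[k]))
  list(solutions = sols, state = state,
       total_value = sum(res$upper))
}

assert_tiered <- function(ts) {
  if (!inherits(ts, "tiered_system")) stop_validation("expected a tiered_system")
  invisible(ts)
}
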