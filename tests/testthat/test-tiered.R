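test_that("tiered_system validates structure and feasibility", {
  ts <- tiered_system(list(c(1, 1), c(1, 3)))
  expect_s3_class(ts, "tiered_system")
  expect_error(tiered_system(list(c(1, 2))), "at least two tiers")
  expect_error(tiered_system(list(c(1, 2), numeric(0))), "non-empty")
  # adjacency with no path from tier 1 to tier 3
  bad <- list(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(0, 1, 0, 1), 2, 2))
  expect_error(tiered_system(list(c(1, 1), c(1, 1), c(1, 1)), adjacency = bad),
               "no feasible path")
  expect_error(tiered_system(list(c(1, 1), c(1, 1)),
                             adjacency = list(matrix(1, 3, 2))),
               "wrong dimensions")
})

test_that("per-tier closed form and tier values decompose the problem", {
  ts <- tiered_system(list(c(1, 1), c(1, 3)))
  expect_equal(per_tier_closed_form(ts), list(c(0.5, 0.5), c(0.25, 0.75)))
  expect_equal(tier_minmax_values(ts), c(0.5, 0.25))

  single <- tiered_system(list(5, 2, 9))
  expect_equal(per_tier_closed_form(single), list(1, 1, 1))

  same <- tiered_system(list(c(1, 3), c(1, 3), c(1, 3)))
  expect_equal(tier_minmax_values(same), rep(0.25, 3))
  # equalization holds tier-wise
  for (k in 1:2) {
    p <- per_tier_closed_form(ts)[[k]]
    expect_equal(max(p * ts$tiers[[k]]$unfitness), tier_minmax_values(ts)[k])
  }
})

test_that("per-tier LP matches the closed form, duals and all", {
  ts <- fixture_tiered(seed = 21, nodes_per_tier = 3L)
  res <- solve_lp_p2(ts)
  pc <- per_tier_closed_form(ts)
  vk <- tier_minmax_values(ts)
  for (k in seq_along(pc)) {
    expect_lt(max(abs(res$solutions[[k]]$p - pc[[k]])), 1e-8)
    expect_lt(abs(res$solutions[[k]]$value - vk[k]), 1e-10)
    expect_lt(max(abs(res$solutions[[k]]$q - res$solutions[[k]]$p)), 1e-6)
  }
  expect_equal(res$total_value, sum(vk), tolerance = 1e-9)

  uniform_tier <- tiered_system(list(rep(2, 4), c(1, 3)))
  expect_equal(solve_lp_p2(uniform_tier)$solutions[[1]]$p, rep(0.25, 4),
               tolerance = 1e-10)
})

test_that("shortest path separates per tier under complete adjacency", {
  ts <- fixture_tiered(seed = 5, nodes_per_tier = 4L)
  q <- lapply(ts$tiers, function(tk) { w <- runif(length(tk)); w / sum(w) })
  ps <- shortest_unfit_path(ts, q)
  manual <- vapply(seq_along(q),
                   function(k) which.min(q[[k]] * ts$tiers[[k]]$unfitness), 1L)
  expect_equal(ps$indices, manual)
})

test_that("dynamic programming equals brute-force path enumeration", {
  for (s in 1:10) {
    set.seed(900 + s)
    sizes <- sample(2:4, 4, replace = TRUE)
    adj <- random_adjacency(sizes)
    tiers <- lapply(sizes, function(n) runif(n, 0.2, 5))
    ts <- tiered_system(tiers, adjacency = adj)
    q <- lapply(sizes, function(n) { w <- runif(n); w / sum(w) })
    dp <- shortest_unfit_path(ts, q)
    bf <- brute_force_path(ts, q)
    expect_equal(dp$cost, bf$cost, tolerance = 1e-12)
  }
})

test_that("ties break toward the lowest-index path", {
  ts <- tiered_system(list(c(1, 1, 1), c(1, 1), c(1, 1)))
  ps <- shortest_unfit_path(ts)        # uniform q, equal fitness
  expect_equal(ps$indices, c(1L, 1L, 1L))
})

test_that("a1_step follows the update rule by hand", {
  ts <- tiered_system(list(c(1, 1), c(1, 1)))
  st <- tiered_game_state_init(ts)
  expect_equal(st$m, 1L)
  st1 <- a1_step(st, ts)
  expect_equal(st1$p, list(c(0.75, 0.25), c(0.75, 0.25)))
  expect_equal(st1$q, list(c(0.75, 0.25), c(0.75, 0.25)))
  expect_equal(st1$m, 2L)
})

test_that("a1_step preserves per-tier simplexes and the fixed point", {
  ts <- tiered_system(list(c(1, 3), c(2, 2)))
  pc <- per_tier_closed_form(ts)
  st <- minmaxfit:::new_tiered_game_state(m = 9L, p = pc, q = pc, ts = ts)
  expect_equal(st$upper_bound, tier_minmax_values(ts))
  expect_equal(st$lower_bound, tier_minmax_values(ts))

  for (s in 1:10) {
    set.seed(1000 + s)
    sizes <- sample(2:5, 3, replace = TRUE)
    ts <- tiered_system(lapply(sizes, function(n) runif(n, 0.1, 4)))
    rand_simplex <- function(n) { w <- runif(n); w / sum(w) }
    st <- minmaxfit:::new_tiered_game_state(
      m = sample(1:40, 1),
      p = lapply(sizes, rand_simplex), q = lapply(sizes, rand_simplex), ts = ts)
    st1 <- a1_step(st, ts)
    for (k in seq_along(sizes)) {
      expect_equal(sum(st1$p[[k]]), 1)
      expect_equal(sum(st1$q[[k]]), 1)
      expect_true(all(st1$p[[k]] >= 0) && all(st1$q[[k]] >= 0))
    }
  }
})

test_that("the compiled tiered loop reproduces the R steps exactly", {
  set.seed(31)
  sizes <- c(3, 2, 4)
  adj <- random_adjacency(sizes)
  ts <- tiered_system(lapply(sizes, function(n) runif(n, 0.2, 4)),
                      adjacency = adj)
  st <- tiered_game_state_init(ts)
  for (i in 1:20) st <- a1_step(st, ts)
  res <- run_a1(ts, tol = 1e-30, max_iter = 20, check_every = 1e9,
                trace_every = 0)
  expect_identical(res$state$p, st$p)
  expect_identical(res$state$q, st$q)
  expect_equal(res$state$m, st$m)
})

test_that("run_a1 converges to the per-tier closed form", {
  ts <- tiered_system(list(c(1, 1), c(1, 3)))
  res <- run_a1(ts, tol = 1e-3)
  expect_true(res$state$converged)
  expect_lt(max(abs(res$solutions[[1]]$p - c(0.5, 0.5))), 1e-3)
  expect_lt(max(abs(res$solutions[[2]]$p - c(0.25, 0.75))), 1e-3)
})

test_that("with complete adjacency A1 follows A0 applied tier-wise", {
  ts <- fixture_tiered(seed = 14, nodes_per_tier = 3L,
                       shape_sigma = c(1, 0.5))
  resA1 <- run_a1(ts, tol = 1e-30, max_iter = 500, check_every = 1e9,
                  trace_every = 0)
  for (k in 1:2) {
    resA0 <- run_a0(ts$tiers[[k]], tol = 1e-30, max_iter = 500,
                    check_every = 1e9, trace_every = 0)
    expect_identical(resA1$state$p[[k]], resA0$state$p)
    expect_identical(resA1$state$q[[k]], resA0$state$q)
  }
})

test_that("tiered decomposition invariant: A1 limit equals per-tier A0 limit", {
  for (s in 1:50) {
    set.seed(1100 + s)
    sizes <- rep(sample(2:4, 1), 3)
    ts <- tiered_system(lapply(sizes, function(n) runif(n, 0.3, 3)))
    tol <- 1e-3
    resA1 <- run_a1(ts, tol = tol, max_iter = 1e7, criterion = "error_bound")
    for (k in seq_along(sizes)) {
      hom <- run_a0(ts$tiers[[k]], tol = tol, max_iter = 1e7,
                    criterion = "error_bound")
      expect_lt(max(abs(resA1$solutions[[k]]$p - hom$solution$p)), 2 * tol)
    }
  }
})
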