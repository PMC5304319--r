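test_that("fitness TSV round trips at full precision", {
  fv <- fixture_homogeneous(seed = 33)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_tsv(fv, path)
  back <- read_fitness_tsv(path)
  expect_identical(back$phi, fv$phi)
  expect_identical(back$node_id, fv$node_id)

  ts <- fixture_tiered(seed = 33, nodes_per_tier = 3L)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_tsv(ts, path2)
  back2 <- read_fitness_tsv(path2)
  expect_identical(lapply(back2$tiers, `[[`, "phi"),
                   lapply(ts$tiers, `[[`, "phi"))
  expect_identical(back2$tier_names, ts$tier_names)
})

test_that("malformed fitness TSVs are rejected with line numbers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\tfitness", "a\t1.5", "b\t0"), p)
  expect_error(read_fitness_tsv(p), "line 3.*> 0")

  writeLines(c("node_id\tfitness", "a\t1.5", "b\tx"), p)
  expect_error(read_fitness_tsv(p), "line 3.*not a number")

  writeLines(c("node_id\tfitness", "a\t1.5", "a\t2"), p)
  expect_error(read_fitness_tsv(p), "line 3.*duplicate")

  # mixed tiered/untiered rows
  writeLines(c("node_id\tfitness", "a\t1.5", "b\tt1\t2"), p)
  expect_error(read_fitness_tsv(p), "line 3.*expected 2")

  writeLines(c("id\tfit", "a\t1"), p)
  expect_error(read_fitness_tsv(p), "line 1.*header")
})

test_that("adjacency TSV restricts the allowed links", {
  fit <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_id\ttier\tfitness",
               "s1\tup\t1", "s2\tup\t1", "r1\tdown\t1", "r2\tdown\t1"), fit)
  adj <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tier_index\tupstream_node\tdownstream_node",
               "1\ts1\tr2", "1\ts2\tr1"), adj)
  ts <- read_fitness_tsv(fit, adjacency = adj)
  expect_identical(ts$adjacency[[1]], matrix(c(0L, 1L, 1L, 0L), 2, 2))
  path <- shortest_unfit_path(ts, list(c(0.9, 0.1), c(0.5, 0.5)))
  expect_equal(path$node_ids, c("s2", "r1"))
})

test_that("result and trace TSVs are written with closed-form reference", {
  fv <- fitness_vector(c(1, 3), node_ids = c("a", "b"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_result_tsv(solve_lp_p0(fv), fv, out)
  df <- read.delim(out)
  expect_identical(names(df), c("node_id", "p", "q", "p_closed_form"))
  expect_equal(df$p, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(df$p_closed_form, c(0.25, 0.75))

  res <- run_a0(fv, tol = 1e-3, trace_every = 10)
  trp <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(res$state, trp)
  tr <- read.delim(trp)
  expect_identical(names(tr), c("iteration", "upper_bound", "lower_bound"))
  expect_true(all(tr$upper_bound >= tr$lower_bound))
})

test_that("fixtures are reproducible and match their stated world", {
  f1 <- fixture_homogeneous(seed = 2)
  expect_length(f1, 12)
  expect_true(all(f1$phi > 0))
  expect_identical(fixture_homogeneous(seed = 2)$phi, f1$phi)
  expect_equal(sum(closed_form_attachment(f1)), 1)

  ts <- fixture_tiered(seed = 2)
  expect_length(ts$tiers, 4L)
  expect_identical(vapply(ts$tiers, length, 1L), rep(25L, 4))
  expect_identical(ts$tier_names,
                   c("supplier", "manufacturer", "distributor", "retailer"))
  expect_true(all(unlist(lapply(ts$tiers, `[[`, "phi")) > 0))
  expect_identical(fixture_tiered(seed = 2)$tiers[[1]]$phi, ts$tiers[[1]]$phi)

  # wider shape upstream: supplier fitness spread beats retail spread
  # in expectation (Monte Carlo over 100 seeds)
  ratios <- vapply(1:100, function(s) {
    tt <- fixture_tiered(seed = 3000 + s, nodes_per_tier = 10L)
    r <- vapply(tt$tiers, function(tk) max(tk$phi) / min(tk$phi), 1)
    r[1] > r[4]
  }, logical(1))
  expect_gt(mean(ratios), 0.95)
})

test_that("the CLI runs every subcommand with reproducible output", {
  dir <- withr::local_tempdir()
  fit <- file.path(dir, "fit.tsv")

  expect_identical(suppressMessages(
    mmf_main(c("sample-fitness", "--n", "8", "--sigma", "1", "--seed", "5",
               "--out", fit))), 0L)
  fit2 <- file.path(dir, "fit2.tsv")
  suppressMessages(mmf_main(c("sample-fitness", "--n", "8", "--sigma", "1",
                              "--seed", "5", "--out", fit2)))
  expect_identical(readLines(fit), readLines(fit2))

  out <- file.path(dir, "sol.tsv")
  expect_identical(suppressMessages(
    mmf_main(c("solve-homogeneous", "--fitness", fit, "--method", "a0",
               "--tol", "1e-3", "--out", out))), 0L)
  df <- read.delim(out)
  expect_lt(max(abs(df$p - df$p_closed_form)), 1e-2)

  # strict mode surfaces non-convergence as exit code 4
  expect_identical(suppressMessages(
    mmf_main(c("solve-homogeneous", "--fitness", fit, "--method", "a0",
               "--max-iter", "3", "--strict", "--out", out))), 4L)

  fx <- file.path(dir, "fx")
  expect_identical(suppressMessages(mmf_main(c("fixtures", "--seed", "1",
                                               "--out-prefix", fx))), 0L)
  tfile <- paste0(fx, "_tiered12.tsv")
  sol <- file.path(dir, "tier_sol.tsv")
  expect_identical(suppressMessages(
    mmf_main(c("solve-tiered", "--fitness", tfile, "--method", "lp",
               "--out", sol))), 0L)
  tdf <- read.delim(sol)
  expect_identical(names(tdf), c("tier", "node_id", "p", "q", "p_closed_form"))
  expect_lt(max(abs(tdf$p - tdf$p_closed_form)), 1e-8)

  gp <- file.path(dir, "net")
  expect_identical(suppressMessages(
    mmf_main(c("grow", "--kernel", "fitness", "--n", "50", "--m", "2",
               "--m0", "3", "--seed", "2", "--out-prefix", gp))), 0L)
  edges <- read.delim(paste0(gp, "_edges.tsv"))
  expect_identical(nrow(edges), 3L + 47L * 2L)

  # config file supplies defaults, flags win
  conf <- file.path(dir, "conf.json")
  jsonlite::write_json(list(n = 8, sigma = 1, seed = 5), conf,
                       auto_unbox = TRUE)
  fit3 <- file.path(dir, "fit3.tsv")
  expect_identical(suppressMessages(
    mmf_main(c("sample-fitness", "--config", conf, "--out", fit3))), 0L)
  expect_identical(readLines(fit3), readLines(fit))

  # validation failures exit 2
  expect_identical(suppressMessages(mmf_main(c("nope"))), 2L)
  expect_identical(suppressMessages(
    mmf_main(c("solve-homogeneous", "--fitness", tfile, "--out", out))), 2L)
  expect_identical(suppressMessages(
    mmf_main(c("sample-fitness", "--n", "0", "--seed", "1", "--out", fit))), 2L)
})
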