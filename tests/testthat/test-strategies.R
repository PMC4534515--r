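test_that("fixed heuristics reproduce the library default formulas", {
  p <- libsvm_heuristic(1024)
  expect_equal(hp_C(p), 1)
  expect_equal(hp_gamma(p), 1 / 1024)
  expect_equal(hp_gamma(libsvm_heuristic(1)), 1)
  expect_equal(hp_gamma(libsvm_heuristic(79)), 1 / 79, tolerance = 1e-12)
  expect_error(libsvm_heuristic(0), "positive")

  # all rows with exactly 4 set bits -> C = 1/4
  X <- matrix(0L, 6, 166); X[, 1:4] <- 1L
  d4 <- structure(list(features = X, labels = rep(c(1L, -1L), 3), d = 166L),
                  class = "fp_dataset")
  q <- svmlight_heuristic(d4)
  expect_equal(hp_C(q), 0.25)
  expect_equal(hp_gamma(q), 1 / 166)
  # rows with squared norms 2 and 6 -> mean 4 -> C = 1/4
  X2 <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L, 1L))
  d26 <- structure(list(features = X2, labels = c(1L, -1L), d = 6L),
                   class = "fp_dataset")
  expect_equal(hp_C(svmlight_heuristic(d26)), 0.25)
  # all-zero features are a division-by-zero error
  dz <- structure(list(features = matrix(0L, 3, 4),
                       labels = c(1L, -1L, 1L), d = 4L),
                  class = "fp_dataset")
  expect_error(svmlight_heuristic(dz), "all-zero")
})

test_that("random sampling is log-uniform, independent, and in the box", {
  space <- default_search_space()
  pts <- withr::with_seed(123, sample_random(space, 10000))
  lc <- vapply(pts, function(p) p$log10_C, numeric(1))
  lg <- vapply(pts, function(p) p$log10_gamma, numeric(1))
  expect_true(all(lc >= -2 & lc <= 5))
  expect_true(all(lg >= -10 & lg <= 3))
  expect_gt(stats::ks.test(lc, "punif", -2, 5)$p.value, 0.01)
  expect_gt(stats::ks.test(lg, "punif", -10, 3)$p.value, 0.01)
  expect_lt(abs(stats::cor(lc, lg)), 0.03)
})

test_that("grid points are log-regular with column raveling", {
  space <- default_search_space()
  pts <- grid_points(space, grid_spec(8, 2))
  expect_equal(vapply(pts[1:8], hp_C, numeric(1)), 10^seq(-2, 5))
  # first half shares gamma_min, second half gamma_max
  expect_true(all(vapply(pts[1:8], function(p) p$log10_gamma, numeric(1)) == -10))
  expect_true(all(vapply(pts[9:16], function(p) p$log10_gamma, numeric(1)) == 3))

  p22 <- grid_points(space, grid_spec(2, 2))
  coords <- t(vapply(p22, function(p) c(p$log10_C, p$log10_gamma), numeric(2)))
  expect_equal(unname(coords),
               rbind(c(-2, -10), c(5, -10), c(-2, 3), c(5, 3)))

  p14 <- grid_points(space, grid_spec(14, 14))
  expect_length(p14, 196L)
  expect_true(all(vapply(p14[1:14], function(p) p$log10_gamma, numeric(1)) == -10))
  expect_error(grid_points(space, grid_spec(1, 5)), ">= 2")
})

test_that("small grid fills the budget with range-proportional axes", {
  space <- default_search_space()
  sg <- small_grid_points(space, 20)
  expect_length(sg, 18L)   # 3 x 6: gamma range is ~13/7 of the C range
  lc <- unique(vapply(sg, function(p) p$log10_C, numeric(1)))
  lg <- unique(vapply(sg, function(p) p$log10_gamma, numeric(1)))
  expect_length(lc, 3L)
  expect_length(lg, 6L)
  expect_length(small_grid_points(space, 4), 4L)  # minimum 2 x 2
  for (p in sg) expect_true(in_space(space, p))
  expect_error(small_grid_points(space, 3), ">= 4")
})

test_that("fixed-sequence runs record points in order with incumbent max", {
  obj <- analytic_objective(analytic_benchmark("two_bump"))
  pts <- grid_points(default_search_space(), grid_spec(4, 4))
  tr <- run_fixed_sequence(obj, pts, budget = 10, name = "grid")
  expect_s3_class(tr, "opt_trace")
  expect_identical(nrow(tr$entries), 10L)
  expect_equal(incumbent(tr)$value, max(tr$entries$value))
  # earliest index wins ties
  tie <- trace_from_values(c(0.4, 0.9, 0.9, 0.1))
  expect_identical(incumbent(tie)$index, 2L)
  # heuristic = 1-point sequence
  tr1 <- run_fixed_sequence(obj, list(hyperparam_point(0, -2)), name = "h")
  expect_identical(nrow(tr1$entries), 1L)
  expect_error(run_fixed_sequence(obj, pts, budget = 0), ">= 1")
  expect_error(run_fixed_sequence(obj, list()), "non-empty")
})

test_that("random search is seeded, budget-respecting, and monotone in prefix", {
  bm <- analytic_benchmark("two_bump")
  tr1 <- run_random_search(analytic_objective(bm), default_search_space(),
                           budget = 150, seed = 31)
  tr2 <- run_random_search(analytic_objective(bm), default_search_space(),
                           budget = 150, seed = 31)
  expect_identical(nrow(tr1$entries), 150L)
  expect_identical(tr1$entries, tr2$entries)
  # incumbent along a growing prefix of one stream is non-decreasing
  inc <- cummax(tr1$entries$value)
  expect_true(all(diff(inc) >= 0))
  # prefix of the same stream equals a shorter run
  tr3 <- run_random_search(analytic_objective(bm), default_search_space(),
                           budget = 40, seed = 31)
  expect_equal(tr3$entries, tr1$entries[1:40, ])
})

test_that("random search converges to the known optimum at large budgets", {
  bm <- analytic_benchmark("two_bump")
  hits <- vapply(1:25, function(s) {
    tr <- run_random_search(analytic_objective(bm), default_search_space(),
                            budget = 3000, seed = s)
    bm$f_opt - incumbent(tr)$value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("nested grids have non-decreasing incumbents on a fixed surface", {
  bm <- analytic_benchmark("plateau_cliff")
  space <- default_search_space()
  finals <- vapply(c(3, 5, 9), function(m) {
    obj <- analytic_objective(bm)
    incumbent(run_fixed_sequence(obj, grid_points(space, grid_spec(m, m)),
                                 name = "grid"))$value
  }, numeric(1))
  # 3, 5, 9 levels nest (endpoints shared, midpoints refined)
  expect_true(all(diff(finals) >= 0))
})

test_that("traces serialize to JSONL and back byte-stably", {
  dir <- withr::local_tempdir()
  bm <- analytic_benchmark("two_bump")
  tr <- run_random_search(analytic_objective(bm), default_search_space(),
                          budget = 7, seed = 3)
  p1 <- file.path(dir, "t1.jsonl")
  p2 <- file.path(dir, "t2.jsonl")
  write_trace(tr, p1)
  back <- read_trace(p1)
  expect_equal(back$entries, tr$entries)
  expect_identical(back$strategy_name, tr$strategy_name)
  expect_identical(back$budget, tr$budget)
  write_trace(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
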