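test_that("GP posterior interpolates noise-free observations", {
  k <- kernel_config()
  pts <- list(hyperparam_point(0, -5), hyperparam_point(2, -2),
              hyperparam_point(-1, 1))
  vals <- c(0.7, 0.9, 0.6)
  m <- gp_fit(pts, vals, k)
  for (i in seq_along(pts)) {
    pr <- gp_predict(m, pts[[i]])
    expect_lt(abs(pr$mean - vals[i]), 1e-6)
    expect_lte(pr$sd, 1e-4)
  }
  # single point
  m1 <- gp_fit(pts[1], vals[1], k)
  expect_lt(abs(gp_predict(m1, pts[[1]])$mean - vals[1]), 1e-6)
  expect_error(gp_fit(list(pts[[1]], pts[[1]]), c(0.5, 0.6), k), "duplicate")
})

test_that("GP reverts to the prior far from all data", {
  k <- kernel_config(signal_variance = 0.5, length_scales = c(0.05, 0.05))
  pts <- list(hyperparam_point(-2, -10), hyperparam_point(-1.8, -9.8))
  vals <- c(0.6, 0.8)
  m <- gp_fit(pts, vals, k)
  far <- gp_predict(m, hyperparam_point(5, 3))  # >> 10 length scales away
  expect_lt(abs(far$mean - mean(vals)), 0.01 * abs(mean(vals)))
  expect_lt(abs(far$sd - sqrt(0.5)), 0.01 * sqrt(0.5))
})

test_that("posterior std never exceeds the prior std", {
  k <- kernel_config(signal_variance = 2, length_scales = c(0.3, 0.2),
                     noise_variance = 1e-4)
  pts <- withr::with_seed(5, sample_random(default_search_space(), 12))
  vals <- withr::with_seed(6, runif(12, 0.5, 0.9))
  m <- gp_fit(pts, vals, k)
  grid <- grid_points(default_search_space(), grid_spec(15, 15))
  sds <- vapply(grid, function(p) gp_predict(m, p)$sd, numeric(1))
  expect_true(all(sds <= sqrt(2) + 1e-8))
  expect_true(all(sds >= 0))
})

test_that("GP posterior matches a brute-force dense-solve oracle", {
  space <- default_search_space()
  for (i in 1:10) {
    n <- withr::with_seed(1000 + i, sample(3:20, 1))
    pts <- withr::with_seed(2000 + i, sample_random(space, n))
    if (n == 1) pts <- list(pts)
    vals <- withr::with_seed(3000 + i, runif(n, 0.4, 1))
    k <- kernel_config(signal_variance = 1,
                       length_scales = c(0.25, 0.35),
                       noise_variance = 1e-5, jitter = 1e-10)
    m <- gp_fit(pts, vals, k, space)
    qs <- withr::with_seed(4000 + i, sample_random(space, 5))
    for (q in qs) {
      got <- gp_predict(m, q)
      want <- gp_oracle_predict(pts, vals, k, space, q)
      expect_lt(abs(got$mean - want$mean), 1e-6)
      expect_lt(abs(got$sd - want$sd), 1e-6)
    }
  }
})

test_that("predictions respect axis symmetry of symmetric designs", {
  # design symmetric about the C midpoint (log10 C = 1.5)
  k <- kernel_config(length_scales = c(0.2, 0.3))
  pts <- list(hyperparam_point(0, -4), hyperparam_point(3, -4))
  m <- gp_fit(pts, c(0.8, 0.8), k)
  a <- gp_predict(m, hyperparam_point(1.0, -4))
  b <- gp_predict(m, hyperparam_point(2.0, -4))
  expect_lt(abs(a$mean - b$mean), 1e-8)
  expect_lt(abs(a$sd - b$sd), 1e-8)
  expect_error(gp_predict(m, hyperparam_point(6, 0)), "outside")
})

test_that("expected improvement matches its closed form and limits", {
  expect_equal(expected_improvement(0.5, 0, 0.7), 0)      # sigma = 0, below
  expect_equal(expected_improvement(0.9, 0, 0.7), 0.2)    # sigma = 0, above
  expect_equal(expected_improvement(0.5, 1, 0.5), dnorm(0), tolerance = 1e-12)
  pr <- structure(list(mean = 0.5, sd = 1), class = "gp_prediction")
  expect_equal(expected_improvement(pr, f_best = 0.5), dnorm(0),
               tolerance = 1e-12)
})

test_that("EI agrees with a Monte-Carlo oracle and is monotone", {
  set.seed(77)
  mc <- function(mean, sd, f_best, n = 2e5) {
    x <- rnorm(n, mean, sd)
    imp <- pmax(x - f_best, 0)
    c(est = mean(imp), se = sd(imp) / sqrt(n))
  }
  for (i in 1:5) {
    mu <- runif(1, 0, 1); s <- runif(1, 0.05, 0.5); fb <- runif(1, 0, 1)
    o <- mc(mu, s, fb)
    # floor at the MC resolution: with ~0 positive draws the SE collapses
    expect_lt(abs(expected_improvement(mu, s, fb) - o["est"]),
              max(3 * o["se"], 1e-7))
  }
  # monotone in sd at fixed mean, and in mean at fixed sd
  sds <- seq(0, 2, by = 0.1)
  expect_true(all(diff(expected_improvement(rep(0.5, 21), sds, 0.7)) >= 0))
  mus <- seq(0, 1, by = 0.05)
  expect_true(all(diff(expected_improvement(mus, rep(0.2, 21), 0.7)) >= 0))
  expect_true(all(expected_improvement(mus, rep(0.2, 21), 0.7) >= 0))
})

test_that("EI at a noise-free incumbent training point is negligible", {
  k <- kernel_config()  # noise 0, tiny jitter
  pts <- list(hyperparam_point(0, -5), hyperparam_point(2, -2))
  vals <- c(0.7, 0.9)
  m <- gp_fit(pts, vals, k)
  pr <- gp_predict(m, pts[[2]])           # the incumbent
  expect_lte(expected_improvement(pr, f_best = 0.9), 1e-6)
})

test_that("proposals stay in the box and explore away from clustered data", {
  space <- default_search_space()
  # all data clustered in one corner with equal values
  pts <- lapply(seq(0, 0.3, length.out = 5),
                function(o) hyperparam_point(-2 + o, -10 + o))
  m <- gp_fit(pts, rep(0.8, 5), kernel_config(length_scales = c(0.15, 0.15)),
              space)
  prop <- withr::with_seed(9, propose_next(m, space, f_best = 0.8))
  expect_true(in_space(space, prop))
  # farther than one length scale (normalized) from the cluster
  un <- svmtune:::normalize_coords(
    rbind(c(prop$log10_C, prop$log10_gamma)), space)
  U <- svmtune:::normalize_coords(
    svmtune:::log_matrix_from_points(pts), space)
  dmin <- min(sqrt(rowSums(sweep(U, 2, as.numeric(un))^2)))
  expect_gt(dmin, 0.15)
  # n_candidates = 1 still returns a valid in-box point
  p1 <- withr::with_seed(10, propose_next(m, space, 0.8, n_candidates = 1))
  expect_true(in_space(space, p1))
})

test_that("bayesopt traces are seeded, share their init with random search,
           and have non-decreasing incumbents", {
  bm <- analytic_benchmark("two_bump")
  sp <- default_search_space()
  tr <- run_bayesopt(analytic_objective(bm), sp, budget = 20, init_count = 5,
                     seed = 41)
  expect_identical(nrow(tr$entries), 20L)
  tr2 <- run_bayesopt(analytic_objective(bm), sp, budget = 20, init_count = 5,
                      seed = 41)
  expect_identical(tr$entries, tr2$entries)
  rs <- run_random_search(analytic_objective(bm), sp, budget = 20, seed = 41)
  expect_equal(tr$entries[1:5, ], rs$entries[1:5, ])
  expect_true(all(diff(cummax(tr$entries$value)) >= 0))
  for (i in seq_len(nrow(tr$entries)))
    expect_true(in_space(sp, hyperparam_point(tr$entries$log10_C[i],
                                              tr$entries$log10_gamma[i])))
  expect_error(run_bayesopt(analytic_objective(bm), sp, budget = 5,
                            init_count = 5, seed = 1), "init_count")
})

test_that("marginal-likelihood refit recovers a plausible surrogate", {
  bm <- analytic_benchmark("plateau_cliff")
  sp <- default_search_space()
  pts <- withr::with_seed(8, sample_random(sp, 25))
  vals <- vapply(pts, function(p) bm$fn(p$log10_C, p$log10_gamma), numeric(1))
  m <- withr::with_seed(9, gp_fit_ml(pts, vals, sp))
  expect_s3_class(m, "gp_model")
  # fitted surrogate predicts held-out surface values reasonably well
  qs <- withr::with_seed(10, sample_random(sp, 30))
  pred <- vapply(qs, function(q) gp_predict(m, q)$mean, numeric(1))
  truth <- vapply(qs, function(q) bm$fn(q$log10_C, q$log10_gamma), numeric(1))
  expect_lt(sqrt(mean((pred - truth)^2)), 0.1)
})
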