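#' Gaussian-process kernel configuration
#'
#' Anisotropic squared-exponential covariance on min-max-normalized log10
#' coordinates:
#' `k(u, v) = signal_variance * exp(-sum_a (u_a - v_a)^2 / (2 length_scales_a^2))`
#' plus `(noise_variance + jitter)` on the diagonal.  Length scales are in
#' normalized box units (1 = the full extent of an axis).  `jitter` is a pure
#' numerical floor; it is escalated automatically (up to `1e-4`) if the
#' covariance Cholesky fails.
#'
#' @param signal_variance Positive prior variance of the surrogate.
#' @param length_scales Length-2 positive vector, one scale per axis
#'   (`log10 C`, `log10 gamma`).
#' @param noise_variance Non-negative observation noise variance.
#' @param jitter Positive numerical floor added to the diagonal (<= 1e-4).
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(signal_variance = 1,
                          length_scales = c(0.2, 0.2),
                          noise_variance = 0,
                          jitter = 1e-12) {
  if (!is.numeric(signal_variance) || signal_variance <= 0)
    stop("`signal_variance` must be positive", call. = FALSE)
  if (length(length_scales) != 2L || any(length_scales <= 0))
    stop("`length_scales` must be two positive numbers", call. = FALSE)
  if (!is.numeric(noise_variance) || noise_variance < 0)
    stop("`noise_variance` must be non-negative", call. = FALSE)
  if (!is.numeric(jitter) || jitter <= 0 || jitter > 1e-4)
    stop("`jitter` must be in (0, 1e-4]", call. = FALSE)
  if (!all(is.finite(c(signal_variance, length_scales, noise_variance))))
    stop("kernel parameters must be finite", call. = FALSE)
  structure(list(signal_variance = signal_variance,
                 length_scales = as.numeric(length_scales),
                 noise_variance = noise_variance, jitter = jitter),
            class = "kernel_config")
}

# Internal: normalize an n x 2 log10-coordinate matrix to the unit square.
normalize_coords <- function(m, space) {
  cbind((m[, 1L] - space$log10_C_min) /
          (space$log10_C_max - space$log10_C_min),
        (m[, 2L] - space$log10_gamma_min) /
          (space$log10_gamma_max - space$log10_gamma_min))
}

# Internal: squared-exponential cross-covariance of two coordinate matrices.
se_cov <- function(U, V, kernel) {
  d1 <- outer(U[, 1L], V[, 1L], "-") / kernel$length_scales[1L]
  d2 <- outer(U[, 2L], V[, 2L], "-") / kernel$length_scales[2L]
  kernel$signal_variance * exp(-0.5 * (d1^2 + d2^2))
}

#' Fit a Gaussian-process surrogate to observed objective values
#'
#' Builds the GP posterior over the search box from observed
#' `(lambda, value)` pairs, using the squared-exponential kernel of
#' [kernel_config()] on min-max-normalized log10 coordinates and a constant
#' prior mean equal to the mean of the training values.  The Cholesky factor
#' of the training covariance is stored so posterior queries are direct
#' triangular solves.
#'
#' @param points List of [hyperparam_point()]s (>= 1, no duplicates when
#'   `noise_variance = 0`).
#' @param values Numeric vector of observed objective values, same length.
#' @param kernel A [kernel_config()].
#' @param space The [search_space()] used for coordinate normalization.
#' @return An object of class `gp_model`.
#' @export
gp_fit <- function(points, values, kernel, space = default_search_space()) {
  stopifnot(inherits(kernel, "kernel_config"), inherits(space, "search_space"))
  if (length(points) < 1L || length(points) != length(values))
    stop("need >= 1 point and equally many values", call. = FALSE)
  U <- normalize_coords(log_matrix_from_points(points), space)
  if (kernel$noise_variance == 0 && nrow(U) > 1L) {
    dmin <- min(stats::dist(U))
    if (dmin < 1e-12)
      stop("duplicate training points with zero noise variance",
           call. = FALSE)
  }
  prior_mean <- mean(values)
  K <- se_cov(U, U, kernel)
  n <- nrow(U)
  jit <- kernel$jitter
  L <- NULL
  repeat {
    Kj <- K + diag(kernel$noise_variance + jit, n)
    L <- tryCatch(chol(Kj), error = function(e) NULL)
    if (!is.null(L)) break
    jit <- jit * 100
    if (jit > 1e-4)
      stop("covariance matrix not positive definite after jitter escalation",
           call. = FALSE)
  }
  alpha <- backsolve(L, forwardsolve(t(L), values - prior_mean))
  structure(list(U = U, values = values, kernel = kernel, space = space,
                 prior_mean = prior_mean, L = L, alpha = alpha,
                 jitter_used = jit),
            class = "gp_model")
}

# Internal: posterior mean/sd at normalized query coordinates (matrix in,
# list of vectors out).  Predictive variance is for the latent function
# (no observation noise added back).
gp_predict_matrix <- function(model, Uq) {
  Ks <- se_cov(Uq, model$U, model$kernel)
  mean <- model$prior_mean + as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$L), t(Ks))
  var <- pmax(model$kernel$signal_variance - colSums(V^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' Gaussian-process posterior prediction at one point
#'
#' @param model A `gp_model` from [gp_fit()].
#' @param point A [hyperparam_point()] inside the model's search box.
#' @return An object of class `gp_prediction`: list with `mean` and `sd`
#'   (posterior standard deviation, >= 0).
#' @export
gp_predict <- function(model, point) {
  stopifnot(inherits(model, "gp_model"), inherits(point, "hyperparam_point"))
  if (!in_space(model$space, point))
    stop("query point outside the search box", call. = FALSE)
  Uq <- normalize_coords(matrix(c(point$log10_C, point$log10_gamma), 1L), model$space)
  pr <- gp_predict_matrix(model, Uq)
  structure(list(mean = pr$mean, sd = pr$sd), class = "gp_prediction")
}

#' Expected improvement acquisition in closed form
#'
#' For a Gaussian posterior with mean `mu` and standard deviation `sigma` at
#' a candidate point, and incumbent value `f_best`, the expected improvement
#' is `sigma * (z * Phi(z) + phi(z))` with `z = (mu - f_best) / sigma`,
#' where `Phi`/`phi` are the standard normal CDF/density.  In the `sigma = 0`
#' limit it degenerates to `max(0, mu - f_best)`.  Vectorized over
#' `mean`/`sd`.
#'
#' @param mean Posterior mean(s), or a `gp_prediction`.
#' @param sd Posterior standard deviation(s) (>= 0); ignored when `mean` is
#'   a `gp_prediction`.
#' @param f_best Incumbent objective value.
#' @return Non-negative expected improvement value(s).
#' @examples
#' expected_improvement(0.5, 1, 0.5)  # dnorm(0) = 0.3989
#' @export
expected_improvement <- function(mean, sd = NULL, f_best) {
  if (inherits(mean, "gp_prediction")) {
    sd <- mean$sd
    mean <- mean$mean
  }
  stopifnot(length(mean) == length(sd), all(sd >= 0))
  ei <- pmax(mean - f_best, 0)      # sigma == 0 branch
  pos <- sd > 0
  if (any(pos)) {
    z <- (mean[pos] - f_best) / sd[pos]
    ei[pos] <- sd[pos] * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  pmax(ei, 0)
}

# Internal: corners and center of the box in log10 coordinates.
space_anchor_points <- function(space) {
  rbind(c(space$log10_C_min, space$log10_gamma_min),
        c(space$log10_C_max, space$log10_gamma_min),
        c(space$log10_C_min, space$log10_gamma_max),
        c(space$log10_C_max, space$log10_gamma_max),
        c((space$log10_C_min + space$log10_C_max) / 2,
          (space$log10_gamma_min + space$log10_gamma_max) / 2))
}

#' Propose the next evaluation point by maximizing expected improvement
#'
#' Evaluates EI on `n_candidates` log-uniform random candidates plus the four
#' corners and the center of the box, and returns the maximizer (earliest
#' candidate on exact ties).  A proposal within `1e-9` (normalized
#' coordinates) of an already-observed point is replaced by the next-best
#' candidate, which keeps the training covariance non-singular.  Uses the
#' current RNG stream for the candidates.
#'
#' @param model A `gp_model`.
#' @param space A [search_space()].
#' @param f_best Incumbent objective value.
#' @param n_candidates Number of random candidates (>= 1; default 2048).
#' @return A [hyperparam_point()] inside the box.
#' @export
propose_next <- function(model, space, f_best, n_candidates = 2048L) {
  stopifnot(inherits(model, "gp_model"), n_candidates >= 1)
  m <- rbind(sample_random_matrix(space, n_candidates),
             space_anchor_points(space))
  Uq <- normalize_coords(m, space)
  pr <- gp_predict_matrix(model, Uq)
  ei <- expected_improvement(pr$mean, pr$sd, f_best)
  # EI values within 1e-12 are treated as tied so the lowest-index candidate
  # wins; otherwise microscopic posterior-variance differences make flat
  # acquisition surfaces degenerate to perpetual corner proposals
  ord <- order(-round(ei, 12), seq_along(ei))
  for (i in ord) {
    dmin <- min(sqrt(rowSums((sweep(model$U, 2L, Uq[i, ]))^2)))
    if (dmin > 1e-9)
      return(hyperparam_point(m[i, 1L], m[i, 2L]))
  }
  # every candidate coincides with an observation; fall back to the EI argmax
  i <- ord[1L]
  hyperparam_point(m[i, 1L], m[i, 2L])
}

# Internal: negative log marginal likelihood of the GP for optimizing kernel
# hyperparameters; theta = log(signal_var, ls1, ls2, noise_var).
gp_neg_log_marginal <- function(theta, U, values, jitter) {
  kernel <- list(signal_variance = exp(theta[1L]),
                 length_scales = exp(theta[2:3]))
  noise <- exp(theta[4L])
  K <- se_cov(U, U, kernel) + diag(noise + jitter, nrow(U))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  y <- values - mean(values)
  a <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

#' Fit a GP with kernel hyperparameters chosen by marginal likelihood
#'
#' Maximizes the log marginal likelihood over signal variance, per-axis
#' length scales (bounded to `[0.01, 10]` in normalized units), and noise
#' variance (floored at `1e-6`) with L-BFGS-B from `n_starts` starting
#' points: one conventional default plus `n_starts - 1` random draws from
#' the current RNG stream.
#'
#' @inheritParams gp_fit
#' @param n_starts Number of optimizer starts (default 3).
#' @param noise_floor Lower bound on the fitted noise variance.
#' @param init_theta Optional warm-start parameter vector
#'   `log(c(signal_variance, length_scale_C, length_scale_gamma,
#'   noise_variance))` used as the first start (replacing the conventional
#'   default); the Bayesian-optimization loop passes the previous iteration's
#'   fit here.
#' @param maxit Iteration cap per L-BFGS-B start.  The marginal-likelihood
#'   surface is low-dimensional and smooth; a moderate cap costs a negligible
#'   amount of likelihood while keeping per-iteration refits cheap.
#' @return A `gp_model` whose kernel maximizes the marginal likelihood among
#'   the starts tried; the winning parameters are stored as `theta` for
#'   warm-starting.
#' @export
gp_fit_ml <- function(points, values, space = default_search_space(),
                      n_starts = 3L, noise_floor = 1e-6, init_theta = NULL,
                      maxit = 30L) {
  U <- normalize_coords(log_matrix_from_points(points), space)
  jitter <- 1e-12
  sv0 <- max(stats::var(values), 1e-6)
  lower <- c(log(1e-4), log(0.01), log(0.01), log(noise_floor))
  upper <- c(log(10), log(10), log(10), log(1))
  clamp <- function(th) pmin(pmax(th, lower), upper)
  starts <- list(
    if (is.null(init_theta)) c(log(sv0), log(0.2), log(0.2), log(1e-4))
    else clamp(init_theta))
  if (n_starts > 1L) {
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- lower + stats::runif(4L) * (upper - lower)
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_neg_log_marginal, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit),
                   U = U, values = values, jitter = jitter),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("marginal-likelihood optimization failed for all starts",
         call. = FALSE)
  kernel <- kernel_config(signal_variance = exp(best$par[1L]),
                          length_scales = exp(best$par[2:3]),
                          noise_variance = max(exp(best$par[4L]), noise_floor),
                          jitter = jitter)
  model <- gp_fit(points, values, kernel, space)
  model$theta <- best$par
  model
}

#' Gaussian-process Bayesian optimization with expected improvement
#'
#' Evaluates `init_count` seeded log-uniform points, then iterates: fit the
#' GP surrogate to all observations (refitting kernel hyperparameters by
#' marginal likelihood unless a fixed `kernel` is supplied), propose the EI
#' maximizer, evaluate it, until `budget` evaluations in total.  The calculated
#' posterior of each iteration serves as the prior for the next; kernel
#' refits warm-start from the previous iteration's parameters, with a
#' 3-start multi-start search at the first fit and every
#' `multistart_every` iterations thereafter to escape stale local optima.  Identical
#' seeds give identical traces, and the first `init_count` points coincide
#' with [run_random_search()]'s first points under the same seed.  If a GP
#' fit fails numerically at some iteration, that iteration falls back to a
#' random point and the trace records the event in its `fallbacks` field.
#'
#' @param obj An objective supporting [evaluate_point()].
#' @param space A [search_space()].
#' @param budget Total number of objective evaluations.
#' @param init_count Number of initial random evaluations
#'   (`1 <= init_count < budget`).
#' @param kernel `NULL` (default) to refit kernel hyperparameters each
#'   iteration via [gp_fit_ml()], or a fixed [kernel_config()].
#' @param seed Integer seed for the whole run.
#' @param n_candidates Random candidates per EI maximization.
#' @param multistart_every Period (in iterations) of full multi-start kernel
#'   refits between cheap warm-started ones; ignored with a fixed `kernel`.
#' @return An `opt_trace` of length `budget`.
#' @export
run_bayesopt <- function(obj, space, budget, init_count = 5L, kernel = NULL,
                         seed = 1L, n_candidates = 2048L,
                         multistart_every = 10L) {
  stopifnot(inherits(space, "search_space"))
  if (!is.numeric(budget) || !is.numeric(init_count) ||
      init_count < 1 || init_count >= budget)
    stop("need 1 <= init_count < budget", call. = FALSE)
  budget <- as.integer(budget)
  init_count <- as.integer(init_count)
  fallbacks <- integer(0)
  pts <- vector("list", budget)
  values <- numeric(budget)
  withr::with_seed(as.integer(seed), {
    init <- sample_random(space, init_count)
    if (init_count == 1L) init <- list(init)
    for (i in seq_len(init_count)) {
      pts[[i]] <- init[[i]]
      values[i] <- evaluate_point(obj, init[[i]])
    }
    theta <- NULL
    for (i in seq.int(init_count + 1L, budget)) {
      seen <- pts[seq_len(i - 1L)]
      if (max(values[seq_len(i - 1L)]) - min(values[seq_len(i - 1L)]) < 1e-12) {
        # constant history: the surrogate is uninformative (a flat response
        # plateau), so explore with a log-uniform draw instead
        nxt <- sample_random(space, 1L)
        pts[[i]] <- nxt
        values[i] <- evaluate_point(obj, nxt)
        next
      }
      multi <- is.null(theta) ||
        (i - init_count - 1L) %% as.integer(multistart_every) == 0L
      model <- tryCatch({
        if (is.null(kernel))
          gp_fit_ml(seen, values[seq_len(i - 1L)], space,
                    n_starts = if (multi) 3L else 1L, init_theta = theta)
        else gp_fit(seen, values[seq_len(i - 1L)], kernel, space)
      }, error = function(e) NULL)
      if (!is.null(model) && !is.null(model$theta)) theta <- model$theta
      nxt <- if (is.null(model)) {
        fallbacks <- c(fallbacks, i)
        sample_random(space, 1L)
      } else {
        propose_next(model, space, f_best = max(values[seq_len(i - 1L)]),
                     n_candidates = n_candidates)
      }
      pts[[i]] <- nxt
      values[i] <- evaluate_point(obj, nxt)
    }
  })
  tr <- new_trace(log_matrix_from_points(pts), values, "bayes", seed, budget)
  tr$fallbacks <- fallbacks
  tr
}
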