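#' Hyperparameter search space
#'
#' The rectangular search box `L = [C_min, C_max] x [gamma_min, gamma_max]`
#' in log10 coordinates.  The defaults, `log10(C) in [-2, 5]` and
#' `log10(gamma) in [-10, 3]`, are the standard ranges for RBF-SVM tuning on
#' fingerprint data.
#'
#' @param log10_C_min,log10_C_max Bounds for `log10(C)`.
#' @param log10_gamma_min,log10_gamma_max Bounds for `log10(gamma)`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(log10_C_min = -2, log10_C_max = 5,
                         log10_gamma_min = -10, log10_gamma_max = 3) {
  if (!(log10_C_min < log10_C_max) || !(log10_gamma_min < log10_gamma_max))
    stop("search-space bounds must satisfy min < max on both axes",
         call. = FALSE)
  structure(list(log10_C_min = log10_C_min, log10_C_max = log10_C_max,
                 log10_gamma_min = log10_gamma_min,
                 log10_gamma_max = log10_gamma_max),
            class = "search_space")
}

#' @rdname search_space
#' @export
default_search_space <- function() search_space()

#' @rdname search_space
#' @param space A `search_space`.
#' @param point A [hyperparam_point()].
#' @export
in_space <- function(space, point) {
  point$log10_C >= space$log10_C_min && point$log10_C <= space$log10_C_max &&
    point$log10_gamma >= space$log10_gamma_min &&
    point$log10_gamma <= space$log10_gamma_max
}

#' Grid dimensions for grid search
#'
#' @param M_C,M_gamma Number of grid levels per axis (each >= 2).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(M_C, M_gamma) {
  if (!is.numeric(M_C) || M_C < 2 || M_C != round(M_C) ||
      !is.numeric(M_gamma) || M_gamma < 2 || M_gamma != round(M_gamma))
    stop("grid dimensions must be integers >= 2", call. = FALSE)
  structure(list(M_C = as.integer(M_C), M_gamma = as.integer(M_gamma)),
            class = "grid_spec")
}

#' Fixed-heuristic hyperparameter choices
#'
#' `libsvm_heuristic()` returns the WEKA/libSVM default `C = 1`,
#' `gamma = 1/d` for feature dimension `d`.  `svmlight_heuristic()` returns
#' the SVMlight default `C = 1 / mean_i ||x_i||^2`, `gamma = 1/d`, computed
#' from the dataset's rows (for binary fingerprints `||x||^2` is the number
#' of set bits).
#'
#' @param d Feature dimension (positive integer).
#' @return A [hyperparam_point()].
#' @examples
#' libsvm_heuristic(1024)  # C = 1, gamma = 1/1024
#' @export
libsvm_heuristic <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d))
    stop("`d` must be a positive integer", call. = FALSE)
  hp_from_linear(1, 1 / d)
}

#' @rdname libsvm_heuristic
#' @param dataset An `fp_dataset` with at least one set bit.
#' @export
svmlight_heuristic <- function(dataset) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (nrow(dataset$features) == 0L) stop("dataset is empty", call. = FALSE)
  mean_sq_norm <- mean(rowSums(dataset$features^2))
  if (mean_sq_norm == 0)
    stop("all-zero feature matrix: SVMlight heuristic C is undefined",
         call. = FALSE)
  hp_from_linear(1 / mean_sq_norm, 1 / dataset$d)
}

#' Log-uniform random sampling of hyperparameter points
#'
#' Draws `n` points with `log10(C) ~ Uniform(C bounds)` and `log10(gamma) ~
#' Uniform(gamma bounds)`, independently.  Uses (and advances) the current
#' global RNG stream; callers that need reproducibility seed it themselves.
#' Coordinates of one point are drawn consecutively, so the first `k` points
#' of any sized draw coincide with a draw of `k` points from the same stream.
#'
#' @param space A [search_space()].
#' @param n Number of points.
#' @return For `n = 1` a [hyperparam_point()]; otherwise a list of them.
#' @export
sample_random <- function(space, n = 1L) {
  pts <- points_from_log_matrix(sample_random_matrix(space, n))
  if (n == 1L) pts[[1L]] else pts
}

# Internal: matrix-level log-uniform sampler sharing the RNG consumption
# pattern of sample_random() (coordinates of one point drawn consecutively).
sample_random_matrix <- function(space, n) {
  stopifnot(inherits(space, "search_space"), n >= 1)
  u <- matrix(stats::runif(2L * n), ncol = 2L, byrow = TRUE)
  cbind(space$log10_C_min + u[, 1L] * (space$log10_C_max - space$log10_C_min),
        space$log10_gamma_min +
          u[, 2L] * (space$log10_gamma_max - space$log10_gamma_min))
}

#' Grid-search point enumeration with column raveling
#'
#' Places `M_C` levels of `C` and `M_gamma` levels of `gamma` uniformly in
#' log10 scale (endpoints included):
#' `C_i = 10^(log10 C_min + (i-1) * (log10 C_max - log10 C_min) / (M_C - 1))`
#' and analogously for `gamma_j`.  The `(i, j)` matrix of pairs is raveled by
#' column: for each `gamma_j` in turn, all `C_i` are emitted, so `C` sweeps
#' fastest at fixed `gamma`.
#'
#' @param space A [search_space()].
#' @param grid A [grid_spec()].
#' @return An ordered list of [hyperparam_point()]s of length
#'   `M_C * M_gamma`.
#' @examples
#' pts <- grid_points(search_space(), grid_spec(8, 2))
#' sapply(pts[1:8], hp_C)  # 1e-2, 1e-1, ..., 1e5
#' @export
grid_points <- function(space, grid) {
  stopifnot(inherits(space, "search_space"), inherits(grid, "grid_spec"))
  cs <- seq(space$log10_C_min, space$log10_C_max, length.out = grid$M_C)
  gs <- seq(space$log10_gamma_min, space$log10_gamma_max,
            length.out = grid$M_gamma)
  m <- cbind(rep(cs, times = grid$M_gamma), rep(gs, each = grid$M_C))
  points_from_log_matrix(m)
}

#' Budget-constrained "small grid"
#'
#' A truncated grid-search variant for small evaluation budgets: among all
#' grids with `M_C, M_gamma >= 2` and `M_C * M_gamma <= budget`, the axis
#' counts are chosen so that `M_gamma / M_C` is closest (in log ratio) to the
#' ratio of the gamma and C log-ranges of the box; ties are broken toward
#' more total points, then toward larger `M_gamma`.  Points are enumerated
#' exactly as in [grid_points()] (column raveling).  The construction keeps
#' the method a strict grid search whose resolution per axis is proportional
#' to the axis extent.
#'
#' @param space A [search_space()].
#' @param budget Maximum number of points (>= 4).
#' @return An ordered list of [hyperparam_point()]s.
#' @examples
#' length(small_grid_points(search_space(), 20))  # 18 (3 x 6 grid)
#' @export
small_grid_points <- function(space, budget) {
  stopifnot(inherits(space, "search_space"))
  if (!is.numeric(budget) || budget < 4)
    stop("`budget` must be >= 4", call. = FALSE)
  budget <- as.integer(budget)
  range_C <- space$log10_C_max - space$log10_C_min
  range_g <- space$log10_gamma_max - space$log10_gamma_min
  target <- log(range_g / range_C)
  best <- NULL
  for (mc in 2:max(2L, budget %/% 2L)) {
    for (mg in 2:max(2L, budget %/% mc)) {
      if (mc * mg > budget) next
      cand <- list(M_C = mc, M_gamma = mg,
                   dev = abs(log(mg / mc) - target), total = mc * mg)
      if (is.null(best) ||
          cand$dev < best$dev - 1e-12 ||
          (abs(cand$dev - best$dev) <= 1e-12 &&
             (cand$total > best$total ||
                (cand$total == best$total && cand$M_gamma > best$M_gamma)))) {
        best <- cand
      }
    }
  }
  grid_points(space, grid_spec(best$M_C, best$M_gamma))
}

# ---------------------------------------------------------------------------
# Trace: the ordered record of one strategy run.

new_trace <- function(log_matrix, values, strategy_name, seed, budget) {
  entries <- data.frame(iteration = seq_along(values),
                        log10_C = log_matrix[, 1L],
                        log10_gamma = log_matrix[, 2L],
                        value = values)
  structure(list(entries = entries, strategy_name = strategy_name,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 budget = as.integer(budget)),
            class = "opt_trace")
}

#' Incumbent of an optimization trace
#'
#' Returns the best hyperparameter point observed so far in a trace: the
#' entry with maximal objective value, at the earliest index on ties.
#'
#' @param trace An `opt_trace` produced by a strategy run.
#' @return A list with `index`, `point` (a [hyperparam_point()]), and
#'   `value`.
#' @export
incumbent <- function(trace) {
  stopifnot(inherits(trace, "opt_trace"))
  if (nrow(trace$entries) == 0L) stop("empty trace", call. = FALSE)
  i <- which.max(trace$entries$value)
  list(index = i,
       point = hyperparam_point(trace$entries$log10_C[i],
                                trace$entries$log10_gamma[i]),
       value = trace$entries$value[i])
}

#' @export
print.opt_trace <- function(x, ...) {
  inc <- incumbent(x)
  cat(sprintf(
    "opt_trace [%s]: %d/%d evaluations, incumbent %.4f at iteration %d\n",
    x$strategy_name, nrow(x$entries), x$budget, inc$value, inc$index))
  invisible(x)
}

#' Serialize optimization traces as JSON lines
#'
#' One metadata line (strategy name, seed, budget) followed by one JSON
#' object per iteration (`iteration`, `log10_C`, `log10_gamma`, `value`).
#' Output is byte-stable for identical traces.
#'
#' @param trace An `opt_trace`.
#' @param path Output file path.
#' @return `write_trace()` invisibly returns `path`; `read_trace()` returns
#'   the `opt_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "opt_trace"))
  meta <- jsonlite::toJSON(
    list(strategy = trace$strategy_name, seed = trace$seed,
         budget = trace$budget),
    auto_unbox = TRUE, digits = NA, na = "null")
  rows <- vapply(seq_len(nrow(trace$entries)), function(i) {
    as.character(jsonlite::toJSON(as.list(trace$entries[i, ]),
                                  auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(meta), rows), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1L])
  if (length(lines) > 1L) {
    rows <- lapply(lines[-1L], jsonlite::fromJSON)
    m <- cbind(vapply(rows, `[[`, 0, "log10_C"),
               vapply(rows, `[[`, 0, "log10_gamma"))
    vals <- vapply(rows, `[[`, 0, "value")
  } else {
    m <- matrix(numeric(0), ncol = 2L)
    vals <- numeric(0)
  }
  new_trace(m, vals, meta$strategy,
            if (is.null(meta$seed)) NA_integer_ else meta$seed, meta$budget)
}

#' Run a strategy defined by a fixed point sequence
#'
#' Evaluates the first `min(budget, length(points))` points in order through
#' the objective and records each `(lambda, value)` pair.  Grid search,
#' "small grid", and the one-point heuristics are all fixed sequences.
#'
#' @param obj An objective supporting [evaluate_point()].
#' @param points Non-empty ordered list of [hyperparam_point()]s.
#' @param budget Evaluation budget (>= 1); defaults to `length(points)`.
#' @param name Strategy name stored in the trace.
#' @return An `opt_trace`.
#' @export
run_fixed_sequence <- function(obj, points, budget = length(points),
                               name = "fixed") {
  if (length(points) == 0L) stop("`points` must be non-empty", call. = FALSE)
  if (!is.numeric(budget) || budget < 1)
    stop("`budget` must be >= 1", call. = FALSE)
  n <- min(as.integer(budget), length(points))
  pts <- points[seq_len(n)]
  values <- vapply(pts, function(p) evaluate_point(obj, p), numeric(1))
  new_trace(log_matrix_from_points(pts), values, name, NULL, budget)
}

#' Log-uniform random search
#'
#' In each iteration a point is drawn from the independent log-uniform
#' distribution over the box, ignoring all previous samples and their
#' results; the incumbent is the maximum of the values obtained.  Identical
#' seeds give bit-identical traces.
#'
#' @param obj An objective supporting [evaluate_point()].
#' @param space A [search_space()].
#' @param budget Number of evaluations (>= 1).
#' @param seed Integer seed for the sampling stream.
#' @return An `opt_trace`.
#' @export
run_random_search <- function(obj, space, budget, seed) {
  stopifnot(inherits(space, "search_space"))
  if (!is.numeric(budget) || budget < 1)
    stop("`budget` must be >= 1", call. = FALSE)
  budget <- as.integer(budget)
  pts <- withr::with_seed(as.integer(seed), sample_random(space, budget))
  if (budget == 1L) pts <- list(pts)
  values <- vapply(pts, function(p) evaluate_point(obj, p), numeric(1))
  tr <- new_trace(log_matrix_from_points(pts), values, "random", seed, budget)
  tr
}
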