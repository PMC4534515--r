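#' Best-so-far curve of an optimization trace
#'
#' The anytime-performance view of a strategy run: `curve[k]` is the maximum
#' objective value among the first `k` evaluations.  Single-point traces
#' (the fixed heuristics) yield a length-1 curve.
#'
#' @param trace An `opt_trace`.
#' @return An object of class `curve_summary`: list with `curve`
#'   (non-decreasing), `final_value`, `iterations_to_optimum` (1-based index
#'   of the first element equal to `final_value`), and `auc`/`regret` fields
#'   filled by [curve_auc()] / [simple_regret()].
#' @export
best_so_far <- function(trace) {
  stopifnot(inherits(trace, "opt_trace"))
  v <- trace$entries$value
  if (length(v) == 0L) stop("empty trace", call. = FALSE)
  curve <- cummax(v)
  final <- curve[length(curve)]
  structure(list(curve = curve, final_value = final,
                 iterations_to_optimum = which(curve >= final)[1L],
                 auc = NA_real_, regret = NA_real_,
                 strategy_name = trace$strategy_name, seed = trace$seed),
            class = "curve_summary")
}

#' Normalized area under a best-so-far curve
#'
#' Trapezoidal area of the best-so-far curve over an iteration axis
#' normalized to `[0, 1]` with `axis_length` positions.  Curves shorter than
#' `axis_length` — including the length-1 curves of the fixed heuristics —
#' are extended at their final value to the full axis, so a constant
#' strategy's AUC equals its accuracy, and for every non-decreasing curve
#' `min(curve) <= AUC <= final value`.  The AUC measures how quickly a
#' strategy converges to a strong model.
#'
#' @param summary A `curve_summary` from [best_so_far()].
#' @param axis_length Number of iteration positions of the common axis
#'   (>= curve length); typically the largest budget in a comparison.
#' @return The AUC, a number in `[0, 1]` for accuracy curves.
#' @export
curve_auc <- function(summary, axis_length) {
  stopifnot(inherits(summary, "curve_summary"))
  k <- length(summary$curve)
  if (axis_length < k)
    stop("`axis_length` must be >= the curve length", call. = FALSE)
  y <- c(summary$curve, rep(summary$final_value, axis_length - k))
  if (axis_length == 1L) return(y)
  sum((y[-1L] + y[-axis_length]) / 2) / (axis_length - 1L)
}

#' Simple regret against a known optimum
#'
#' `regret = f_opt - final_value`, clipped at zero: the gap between the known
#' optimal objective value and the incumbent's value at the end of the run.
#' Only meaningful on benchmarks with a known optimum (see
#' [analytic_benchmark()]).
#'
#' @param summary A `curve_summary`.
#' @param f_opt Known optimal objective value (must not be below the final
#'   value by more than `1e-9`).
#' @return Non-negative regret.
#' @export
simple_regret <- function(summary, f_opt) {
  stopifnot(inherits(summary, "curve_summary"))
  if (f_opt < summary$final_value - 1e-9)
    stop("`f_opt` is below the achieved final value: inconsistent optimum",
         call. = FALSE)
  max(f_opt - summary$final_value, 0)
}

#' Count per-strategy wins across a suite of experiments
#'
#' For each experiment cell (dataset, replicate seed), every strategy whose
#' final value equals the maximum over strategies — values compared after
#' rounding to `digits` decimals — is credited one win, so draws are counted
#' for all tied strategies and win totals can exceed the number of cells.
#' Aggregates are returned overall and grouped by fingerprint and by target.
#'
#' @param results A suite results data frame from [run_suite()] (columns
#'   `dataset`, `target`, `fingerprint`, `strategy`, `seed`, `final_value`).
#' @param digits Rounding used for tie comparison (default 4).
#' @return A list with data frames `overall`, `by_fingerprint`, `by_target`,
#'   each mapping strategy to win counts.
#' @export
count_wins <- function(results, digits = 4L) {
  stopifnot(is.data.frame(results))
  need <- c("dataset", "strategy", "seed", "final_value")
  if (!all(need %in% names(results)))
    stop("`results` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  strategies <- sort(unique(results$strategy))
  cells <- split(results, list(results$dataset, results$seed), drop = TRUE)
  if (any(vapply(cells, function(df) length(unique(df$strategy)), 0L) < 2L))
    stop("every cell needs results from >= 2 strategies", call. = FALSE)
  win_rows <- do.call(rbind, lapply(cells, function(df) {
    v <- round(df$final_value, digits)
    df$win <- as.integer(v == max(v))
    df
  }))
  tab <- function(rows, group = NULL) {
    if (is.null(group)) {
      agg <- stats::aggregate(win ~ strategy, rows, sum)
    } else {
      agg <- stats::aggregate(stats::as.formula(paste("win ~ strategy +", group)),
                              rows, sum)
    }
    agg
  }
  list(overall = tab(win_rows),
       by_fingerprint = if ("fingerprint" %in% names(win_rows))
         tab(win_rows, "fingerprint") else NULL,
       by_target = if ("target" %in% names(win_rows))
         tab(win_rows, "target") else NULL)
}

#' Analytic benchmark surfaces with known optima
#'
#' Deterministic closed-form objectives over the default search box, scaled
#' to `[0, 1]`, used to measure simple regret where the true optimum is
#' known.
#'
#' * `"two_bump"` — a weighted sum of two anisotropic Gaussian bumps in
#'   `(log10 C, log10 gamma)`: a dominant bump of height 1.0 centered at
#'   `(1.8, -4)` with scales `(1.5, 2.5)` and a secondary bump of height 0.7
#'   at `(-1.5, 1.5)` with scales `(0.8, 1.2)`, clipped to `[0, 1]`.  The
#'   bumps are far enough apart (in scale units) that their overlap is below
#'   double-precision resolution of the maximum.  Global maximum: value 1.0
#'   at `(1.8, -4)`.
#' * `"plateau_cliff"` — a smooth accuracy plateau: a logistic ramp in
#'   `log10 C` times a Gaussian band in `log10 gamma`, on a 0.5 floor,
#'   mimicking the wide high-accuracy plateaus of real SVM response
#'   surfaces.  Global maximum: value 1.0 at `(5, -4)` (the ramp saturates
#'   at the C upper bound).
#'
#' @param name One of `"two_bump"`, `"plateau_cliff"`.
#' @return A list of class `analytic_benchmark` with `name`, `fn` (vectorized
#'   function of `log10_C`, `log10_gamma`), `optimum` (a
#'   [hyperparam_point()]), `f_opt`, and `space`.
#' @seealso [analytic_objective()] to wrap a benchmark in the strategy
#'   evaluation contract.
#' @export
analytic_benchmark <- function(name = c("two_bump", "plateau_cliff")) {
  name <- match.arg(name)
  space <- default_search_space()
  if (name == "two_bump") {
    fn <- function(log10_C, log10_gamma) {
      b1 <- exp(-((log10_C - 1.8)^2 / (2 * 1.5^2) +
                    (log10_gamma + 4)^2 / (2 * 2.5^2)))
      b2 <- 0.7 * exp(-((log10_C + 1.5)^2 / (2 * 0.8^2) +
                          (log10_gamma - 1.5)^2 / (2 * 1.2^2)))
      pmin(pmax(b1 + b2, 0), 1)
    }
    optimum <- hyperparam_point(1.8, -4)
  } else {
    fn <- function(log10_C, log10_gamma) {
      ramp <- stats::plogis(5 * (log10_C + 1))
      band <- exp(-(log10_gamma + 4)^2 / (2 * 3^2))
      pmin(pmax(0.5 + 0.5 * ramp * band, 0), 1)
    }
    optimum <- hyperparam_point(5, -4)
  }
  structure(list(name = name, fn = fn, optimum = optimum,
                 f_opt = fn(optimum$log10_C, optimum$log10_gamma),
                 space = space),
            class = "analytic_benchmark")
}

#' Wrap an analytic benchmark in the objective evaluation contract
#'
#' Lets every strategy run unchanged on a deterministic closed-form surface.
#' Evaluations are cached and counted exactly as for the CV objective.
#'
#' @param benchmark An [analytic_benchmark()].
#' @return An object of class `analytic_objective` supporting
#'   [evaluate_point()] and [eval_count()].
#' @export
analytic_objective <- function(benchmark) {
  stopifnot(inherits(benchmark, "analytic_benchmark"))
  state <- new.env(parent = emptyenv())
  state$cache <- new.env(parent = emptyenv(), hash = TRUE)
  state$eval_count <- 0L
  structure(list(benchmark = benchmark, state = state),
            class = "analytic_objective")
}

#' @export
evaluate_point.analytic_objective <- function(obj, point, ...) {
  key <- point_cache_key(point)
  st <- obj$state
  hit <- get0(key, envir = st$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  val <- obj$benchmark$fn(point$log10_C, point$log10_gamma)
  assign(key, val, envir = st$cache)
  st$eval_count <- st$eval_count + 1L
  val
}

# ---------------------------------------------------------------------------
# Suite runner

# Internal: run one strategy on one objective, returning an opt_trace.
run_strategy <- function(strategy, obj, space, budget, seed, settings, d,
                         dataset) {
  switch(strategy,
    random = run_random_search(obj, space, budget, seed),
    bayes = run_bayesopt(obj, space, budget,
                         init_count = settings$init_count %||% 5L,
                         kernel = settings$kernel,
                         seed = seed,
                         n_candidates = settings$n_candidates %||% 2048L),
    grid = run_fixed_sequence(
      obj,
      grid_points(space, grid_spec(settings$M_C %||% 14L,
                                   settings$M_gamma %||% 14L)),
      budget = budget, name = "grid"),
    small_grid = run_fixed_sequence(
      obj, small_grid_points(space, budget), budget = budget,
      name = "small_grid"),
    libsvm = run_fixed_sequence(obj, list(libsvm_heuristic(d)),
                                budget = budget, name = "libsvm"),
    svmlight = run_fixed_sequence(obj, list(svmlight_heuristic(dataset)),
                                  budget = budget, name = "svmlight"),
    stop("unknown strategy `", strategy, "`; valid strategies: ",
         "bayes, random, grid, small_grid, libsvm, svmlight", call. = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run a strategy-comparison suite
#'
#' Runs every configured strategy on every dataset at every replicate seed,
#' and summarizes each run at every requested budget.  Each stochastic
#' strategy is executed once at the largest budget per seed; summaries at
#' smaller budgets are prefix truncations of that trace, which is exact
#' because all implemented strategies are anytime algorithms (their first
#' `b` evaluations do not depend on the total budget).  Deterministic
#' strategies (grid, small grid, heuristics) are replicated across seeds via
#' the objective cache at no extra solver cost, so win counting compares all
#' strategies within every (dataset, seed) cell.
#'
#' When `out_dir` is given, each trace is written to
#' `<dataset>_<strategy>_s<seed>.jsonl` and existing trace files are loaded
#' instead of re-running the objective, making long suites resumable.
#' Failures in one cell are recorded (value columns `NA`) without aborting
#' the suite.
#'
#' @param suite An `fp_suite`, or a named list of elements with fields
#'   `name`, `target`, `fingerprint`, `dataset`.
#' @param strategies Named list: names are strategy identifiers (`"bayes"`,
#'   `"random"`, `"grid"`, `"small_grid"`, `"libsvm"`, `"svmlight"`), values
#'   are per-strategy settings lists (possibly empty).
#' @param budgets Integer vector of evaluation budgets; summaries are
#'   produced at each, with curve AUC normalized to the largest
#'   (default `c(20, 30, 50, 75, 100, 150)`).
#' @param seeds Integer vector of replicate seeds for stochastic strategies.
#' @param n_folds,fold_seed Passed to [svm_objective()]; one objective (and
#'   hence one fold assignment and one evaluation cache) is shared by all
#'   strategies on a dataset.
#' @param out_dir Optional directory for resumable trace files.
#' @param verbose Print one line per completed cell.
#' @return A data frame of class `suite_result` with one row per
#'   (dataset, strategy, seed, budget): columns `dataset`, `target`,
#'   `fingerprint`, `strategy`, `seed`, `budget`, `final_value`, `auc`,
#'   `iterations_to_optimum`.
#' @export
run_suite <- function(suite, strategies, budgets = c(20L, 30L, 50L, 75L, 100L, 150L),
                      seeds = 1L, n_folds = 5L, fold_seed = 1L,
                      out_dir = NULL, verbose = FALSE) {
  stopifnot(length(suite) >= 1L, length(strategies) >= 1L,
            length(budgets) >= 1L, length(seeds) >= 1L)
  budgets <- sort(as.integer(budgets))
  max_budget <- max(budgets)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (el in suite) {
    obj <- svm_objective(el$dataset, n_folds = n_folds, fold_seed = fold_seed)
    space <- default_search_space()
    for (strat in names(strategies)) {
      for (seed in seeds) {
        tr <- NULL
        tfile <- if (!is.null(out_dir))
          file.path(out_dir, sprintf("%s_%s_s%d.jsonl", el$name, strat, seed))
        if (!is.null(tfile) && file.exists(tfile)) {
          tr <- read_trace(tfile)
        } else {
          tr <- tryCatch(
            run_strategy(strat, obj, space, max_budget, seed,
                         strategies[[strat]], el$dataset$d, el$dataset),
            error = function(e) {
              warning(sprintf("cell %s/%s/seed %d failed: %s", el$name, strat,
                              seed, conditionMessage(e)), call. = FALSE)
              NULL
            })
          if (!is.null(tr) && !is.null(tfile)) write_trace(tr, tfile)
        }
        for (b in budgets) {
          if (is.null(tr)) {
            rows[[length(rows) + 1L]] <- data.frame(
              dataset = el$name, target = el$target %||% NA_character_,
              fingerprint = el$fingerprint %||% NA_character_,
              strategy = strat, seed = seed, budget = b,
              final_value = NA_real_, auc = NA_real_,
              iterations_to_optimum = NA_integer_)
            next
          }
          k <- min(b, nrow(tr$entries))
          sub <- tr
          sub$entries <- tr$entries[seq_len(k), , drop = FALSE]
          cs <- best_so_far(sub)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = el$name, target = el$target %||% NA_character_,
            fingerprint = el$fingerprint %||% NA_character_,
            strategy = strat, seed = seed, budget = b,
            final_value = cs$final_value,
            auc = curve_auc(cs, axis_length = b),
            iterations_to_optimum = cs$iterations_to_optimum)
        }
        if (verbose && !is.null(tr)) {
          cat(sprintf("[run_suite] %s %-10s seed %d incumbent %.4f\n",
                      el$name, strat, seed, incumbent(tr)$value))
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("suite_result", class(res))
  res
}

#' Iterations until a regret threshold is reached
#'
#' 1-based index of the first iteration at which the best-so-far value is
#' within `threshold` of `f_opt`; `Inf` if the trace never reaches it.
#'
#' @param trace An `opt_trace`.
#' @param f_opt Known optimum value.
#' @param threshold Regret threshold.
#' @return A positive integer or `Inf`.
#' @export
iterations_to_regret <- function(trace, f_opt, threshold) {
  curve <- cummax(trace$entries$value)
  hit <- which(f_opt - curve < threshold)
  if (length(hit) == 0L) Inf else hit[1L]
}
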