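#' Hyperparameter point in log10 coordinates
#'
#' A candidate pair of SVM hyperparameters lambda = (C, gamma), stored on the
#' log10 scale on which all search strategies operate.  `C` is the soft-margin
#' regularization strength and `gamma` the width of the RBF kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)`.
#'
#' @param log10_C Base-10 logarithm of the regularization strength `C`.
#' @param log10_gamma Base-10 logarithm of the kernel width `gamma`.
#' @return An object of class `hyperparam_point`.
#' @seealso [hp_C()], [hp_gamma()], [hp_from_linear()]
#' @examples
#' p <- hyperparam_point(0, -3)
#' hp_C(p)      # 1
#' hp_gamma(p)  # 0.001
#' @export
hyperparam_point <- function(log10_C, log10_gamma) {
  if (!is.numeric(log10_C) || length(log10_C) != 1L || !is.finite(log10_C))
    stop("`log10_C` must be a single finite number", call. = FALSE)
  if (!is.numeric(log10_gamma) || length(log10_gamma) != 1L ||
      !is.finite(log10_gamma))
    stop("`log10_gamma` must be a single finite number", call. = FALSE)
  structure(
    list(log10_C = as.numeric(log10_C), log10_gamma = as.numeric(log10_gamma)),
    class = "hyperparam_point"
  )
}

#' @rdname hyperparam_point
#' @param C,gamma Hyperparameters on the linear scale; both must be positive.
#' @export
hp_from_linear <- function(C, gamma) {
  if (!is.numeric(C) || C <= 0 || !is.numeric(gamma) || gamma <= 0)
    stop("`C` and `gamma` must be positive", call. = FALSE)
  hyperparam_point(log10(C), log10(gamma))
}

#' @rdname hyperparam_point
#' @param p A `hyperparam_point`.
#' @export
hp_C <- function(p) 10^p$log10_C

#' @rdname hyperparam_point
#' @export
hp_gamma <- function(p) 10^p$log10_gamma

#' @export
print.hyperparam_point <- function(x, ...) {
  cat(sprintf("hyperparam_point: C = %.6g (log10 %.4f), gamma = %.6g (log10 %.4f)\n",
              hp_C(x), x$log10_C, hp_gamma(x), x$log10_gamma))
  invisible(x)
}

# Internal: coerce an n x 2 matrix of log10 coordinates to a list of points.
points_from_log_matrix <- function(m) {
  lapply(seq_len(nrow(m)), function(i) hyperparam_point(m[i, 1L], m[i, 2L]))
}

# Internal: stack a list of points into an n x 2 log10-coordinate matrix.
log_matrix_from_points <- function(points) {
  m <- matrix(0, nrow = length(points), ncol = 2L,
              dimnames = list(NULL, c("log10_C", "log10_gamma")))
  for (i in seq_along(points)) {
    m[i, 1L] <- points[[i]]$log10_C
    m[i, 2L] <- points[[i]]$log10_gamma
  }
  m
}
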