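# broom-style summaries of fitted objects.

#' Tidy a fitted shape GMM
#'
#' One row per mixture component: weight, log-determinant of the particle
#' covariance factor and the radius of gyration of the mean structure.
#'
#' @param x a `shape_gmm`.
#' @param ... unused.
#' @method tidy shape_gmm
#' @export
tidy.shape_gmm <- function(x, ...) {
  data.frame(
    component = seq_len(x$K),
    weight = as.numeric(x$phi),
    logdet_cov = vapply(x$logdets, identity, numeric(1)),
    mean_rgyr = vapply(x$means, function(m) sqrt(mean(rowSums(m^2))),
                       numeric(1)))
}

#' @rdname tidy.shape_gmm
#' @method glance shape_gmm
#' @export
glance.shape_gmm <- function(x, ...) {
  data.frame(K = x$K, train_log_likelihood = x$train_log_likelihood,
             iterations = x$iterations %||% NA_integer_,
             converged = isTRUE(x$converged),
             seed = x$seed %||% NA_integer_)
}

#' Tidy a state-matching result
#'
#' The Bhattacharyya distance table in long format, with a logical column
#' marking the selected component for each reference.
#'
#' @param x a `match_result`.
#' @param ... unused.
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) {
  K <- nrow(x$distance_table)
  data.frame(
    component = rep(seq_len(K), 2),
    reference = rep(c("A", "B"), each = K),
    distance = c(x$distance_table[, 1], x$distance_table[, 2]),
    selected = c(seq_len(K) == x$index_A, seq_len(K) == x$index_B))
}

#' Summaries of a refinement run history
#'
#' One row per iteration: transit counts and FES mean absolute error against
#' the previous iteration.
#'
#' @param x a list returned by [iterate_cv()].
#' @param ... unused.
#' @export
tidy_history <- function(x, ...) {
  recs <- x$history
  data.frame(
    iteration = vapply(recs, function(r) r$index, integer(1)),
    transit_count = vapply(recs, function(r)
      as.integer(r$transit_count %||% NA_integer_), integer(1)),
    mae_vs_previous = vapply(recs, function(r) r$mae_vs_previous, numeric(1)))
}
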