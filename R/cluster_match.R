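# Bhattacharyya-distance matching of refitted mixture components to the two
# reference states.  Distances use the Gaussian closed form evaluated on the
# N x N Kronecker covariance factors (log-determinant exponents x3), after
# rotating one state's mean onto the other's under the pooled covariance so
# that both live in a shared aligned frame.

#' Gaussian state summary
#'
#' @param mean `N x 3` mean structure (centered internally).
#' @param covariance_N symmetric `N x N` particle covariance factor.
#' @param label optional text label.
#' @export
gaussian_state <- function(mean, covariance_N, label = "") {
  mean <- center_frame(as.matrix(mean))
  covariance_N <- as.matrix(covariance_N)
  if (max(abs(covariance_N - t(covariance_N))) > 1e-8)
    stop_shapecv("covariance_N must be symmetric", "shapecv_invalid_input")
  structure(list(mean = mean, covariance_N = covariance_N, label = label),
            class = "gaussian_state")
}

#' Bhattacharyya distance between two Gaussians (scalar case)
#'
#' Closed form `(m1-m2)^2/(8 vbar) + 0.5 log(vbar / sqrt(v1 v2))` with
#' `vbar = (v1+v2)/2`; equals `-log` of the Bhattacharyya coefficient
#' `integral sqrt(p q)`.
#'
#' @param m1,m2 means; `v1,v2` variances.
#' @export
bhattacharyya_gaussian_1d <- function(m1, v1, m2, v2) {
  vbar <- (v1 + v2) / 2
  (m1 - m2)^2 / (8 * vbar) + 0.5 * log(vbar / sqrt(v1 * v2))
}

#' Bhattacharyya distance between two Gaussian shape states
#'
#' Evaluates the multivariate Gaussian closed form
#' `D_B = 1/8 dmu' Sbar^-1 dmu + 1/2 log(det Sbar / sqrt(det Sa det Sb))`
#' in the Kronecker structure: the quadratic form runs through the pooled
#' `N x N` precision and all log-determinants carry the factor 3 from the
#' three Cartesian axes.  Unless `align = FALSE`, state `b`'s mean is first
#' rotated onto `a`'s by the Mahalanobis-optimal rotation under the pooled
#' covariance, so the distance is evaluated in a shared aligned frame and is
#' invariant to rigid transforms of either state.
#'
#' @param a,b `gaussian_state` objects on the same particle set.
#' @param align rotate `b` onto `a` before evaluating.
#' @param delta covariance ridge applied to each factor before use.
#' @return nonnegative scalar distance.
#' @export
bhattacharyya_distance <- function(a, b, align = TRUE, delta = 1e-6) {
  stopifnot(inherits(a, "gaussian_state"), inherits(b, "gaussian_state"))
  if (!all(dim(a$mean) == dim(b$mean)))
    stop_shapecv("states must live on the same particle set",
                 "shapecv_invalid_input")
  Sa <- regularize_covariance(a$covariance_N, delta)
  Sb <- regularize_covariance(b$covariance_N, delta)
  Sbar <- (Sa + Sb) / 2
  Pbar <- solve(Sbar)
  mb <- b$mean
  if (align) {
    R <- optimal_rotation_cpp(mb, a$mean, Pbar)
    mb <- mb %*% R
  }
  dmu <- mb - a$mean
  ld <- function(S) 2 * sum(log(diag(chol(S))))
  quad <- sum(dmu * (Pbar %*% dmu)) / 8
  logterm <- 0.5 * (3 * ld(Sbar) - 1.5 * (ld(Sa) + ld(Sb)))
  db <- quad + logterm
  if (db < 0 && db > -1e-10) db <- 0
  db
}

#' Match mixture components to two reference states
#'
#' Computes the `K x 2` table of Bhattacharyya distances from every component
#' of a fitted shape GMM to the two reference states, then selects the
#' component closest to `ref_A` and, among the remaining ones, the component
#' closest to `ref_B`.  If a single component is closest to both references,
#' it is assigned to the reference with the smaller distance and the
#' runner-up is taken for the other, with a warning.
#'
#' @param model a `shape_gmm` with `K >= 2`.
#' @param ref_A,ref_B `gaussian_state` reference states.
#' @param delta covariance ridge.
#' @return list of class `match_result` with `index_A`, `index_B` and the
#'   `distance_table` (rows = components, columns = references).
#' @export
match_states <- function(model, ref_A, ref_B, delta = 1e-6) {
  stopifnot(inherits(model, "shape_gmm"))
  if (model$K < 2)
    stop_shapecv("need at least two components to match two states",
                 "shapecv_invalid_input")
  tab <- matrix(NA_real_, model$K, 2,
                dimnames = list(NULL, c("ref_A", "ref_B")))
  for (j in seq_len(model$K)) {
    st <- gaussian_state(model$means[[j]], model$covariances_N[[j]])
    tab[j, 1] <- bhattacharyya_distance(ref_A, st, delta = delta)
    tab[j, 2] <- bhattacharyya_distance(ref_B, st, delta = delta)
  }
  iA <- which.min(tab[, 1])
  iB <- which.min(tab[, 2])
  if (iA == iB) {
    warning("one component is closest to both references; ",
            "resolving by smaller distance")
    if (tab[iA, 1] <= tab[iB, 2]) {
      iB <- setdiff(order(tab[, 2]), iA)[1]
    } else {
      iA <- setdiff(order(tab[, 1]), iB)[1]
    }
  }
  structure(list(index_A = iA, index_B = iB, distance_table = tab),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: A -> component %d (D_B = %.4g), B -> component %d (D_B = %.4g)>\n",
              x$index_A, x$distance_table[x$index_A, 1],
              x$index_B, x$distance_table[x$index_B, 2]))
  invisible(x)
}

#' Write a cluster-to-reference distance table as delimited text
#' @param match a `match_result`.
#' @param path output file.
#' @export
write_distance_table <- function(match, path) {
  df <- data.frame(cluster = seq_len(nrow(match$distance_table)),
                   match$distance_table)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
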