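# Frame-weighted linear discriminant analysis on aligned particle positions.
#
# Frames are flattened to 3N vectors (column-major: all x, then y, then z).
# The weighted within-class scatter S_W = sum_j sum_{i in j} w_i d_i d_i'
# (d_i the deviation from the weighted class mean) and the between-class
# scatter S_B = sum_j W_j (mu_j - mu)(mu_j - mu)' are built directly; the
# discriminant directions maximize tr((G'S_W G)^-1 G'S_B G).  Positional
# scatter matrices are always rank-deficient (centering and alignment remove
# rigid-body modes), so the solver whitens on the retained within-class
# spectrum only.

flatten_frames <- function(coords) {
  M <- dim(coords)[1]
  matrix(coords, nrow = M)  # M x 3N, column-major (x.., y.., z..)
}

vec_to_frame <- function(v) matrix(v, ncol = 3)

#' Weighted within- and between-class scatter matrices
#'
#' @param aligned_frames a `frame_ensemble`, jointly aligned (see
#'   [align_ensemble()] with `covariance_N = "kronecker"`).
#' @param labels integer class labels in `1..K`, one per frame.
#' @param weights frame weights (normalized internally).
#' @return list of class `scatter_pair` with `S_W`, `S_B` (`3N x 3N`),
#'   per-class totals `class_weights`, the weighted `class_means` (3N
#'   vectors), and the weighted `global_mean`.
#' @export
weighted_scatter_matrices <- function(aligned_frames, labels, weights = NULL) {
  stopifnot(inherits(aligned_frames, "frame_ensemble"))
  M <- n_frames(aligned_frames)
  w <- resolve_weights(weights, M)
  labels <- as.integer(labels)
  if (length(labels) != M)
    stop_shapecv("need one label per frame", "shapecv_invalid_input")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop_shapecv("need at least two classes", "shapecv_invalid_input")
  X <- flatten_frames(aligned_frames$coords)
  p <- ncol(X)
  gm <- drop(crossprod(X, w))  # weighted global mean
  S_W <- matrix(0, p, p)
  S_B <- matrix(0, p, p)
  class_weights <- numeric(length(classes))
  class_means <- matrix(0, length(classes), p)
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    if (length(idx) == 0)
      stop_shapecv(sprintf("class %d is empty", classes[k]),
                   "shapecv_invalid_input")
    wk <- w[idx]
    Wk <- sum(wk)
    mk <- drop(crossprod(X[idx, , drop = FALSE], wk)) / Wk
    D <- sweep(X[idx, , drop = FALSE], 2, mk)
    S_W <- S_W + crossprod(D * wk, D)
    dB <- mk - gm
    S_B <- S_B + Wk * tcrossprod(dB)
    class_weights[k] <- Wk
    class_means[k, ] <- mk
  }
  structure(list(S_W = (S_W + t(S_W)) / 2, S_B = (S_B + t(S_B)) / 2,
                 class_weights = class_weights, class_means = class_means,
                 global_mean = gm, classes = classes),
            class = "scatter_pair")
}

#' Solve the weighted LDA eigenproblem
#'
#' Maximizes the Fisher ratio `tr((G'S_W G)^-1 G'S_B G)` by whitening on the
#' within-class spectrum and diagonalizing the whitened between-class
#' scatter.  Within-class eigendirections whose eigenvalue falls below
#' `floor_ratio` times the largest are discarded (they are rigid-body null
#' modes of positional data), which keeps the solver valid for singular
#' `S_W`.  For two classes a single unit vector is returned, with the
#' deterministic sign convention that the largest-magnitude coefficient is
#' positive.
#'
#' @param scatter a `scatter_pair`.
#' @param n_components number of discriminants (at most `K - 1`).
#' @param floor_ratio relative spectral floor on the within-class spectrum.
#' @return a `3N x n_components` matrix of unit-norm directions (drops to a
#'   vector for one component).
#' @export
wlda_solve <- function(scatter, n_components = 1, floor_ratio = 1e-10) {
  K <- length(scatter$classes)
  if (n_components > K - 1)
    stop_shapecv("n_components must be at most K - 1", "shapecv_invalid_input")
  if (max(abs(scatter$S_B)) < 1e-14)
    stop_shapecv("between-class scatter is zero: classes are not separated",
                 "shapecv_no_discriminant")
  ew <- eigen(scatter$S_W, symmetric = TRUE)
  lmax <- max(ew$values)
  keep <- ew$values > floor_ratio * lmax
  if (!any(keep))
    stop_shapecv("within-class scatter has no usable spectrum",
                 "shapecv_numerical_error")
  U <- ew$vectors[, keep, drop = FALSE]
  Wh <- U %*% (t(U) / sqrt(ew$values[keep]))  # truncated S_W^{-1/2}
  Tm <- Wh %*% scatter$S_B %*% Wh
  eb <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
  V <- Wh %*% eb$vectors[, seq_len(n_components), drop = FALSE]
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  if (n_components == 1) drop(V) else V
}

#' Construct a linear-discriminant coordinate
#'
#' Packages a discriminant direction with its alignment reference so that the
#' coordinate can be evaluated on the fly on arbitrary frames:
#' `l(x) = v . (R (x - xi) - mu)` where `xi` translates the frame's geometric
#' mean onto the reference's and `R` is the Mahalanobis-optimal rotation
#' against `ref_mean` under `ref_covariance_N`.
#'
#' @param v discriminant direction (`N x 3` matrix or `3N` vector); normalized
#'   to unit Euclidean norm.
#' @param ref_mean centered `N x 3` reference structure.
#' @param ref_covariance_N `N x N` covariance factor defining the alignment
#'   metric (typically the pooled weighted within-class covariance of the two
#'   training states).
#' @param align if `FALSE` the rotation is skipped and the coordinate is a
#'   plain linear projection of the centered frame (useful for fixed
#'   reference axes of synthetic systems).
#' @param value_range optional observed `(min, max)` of the coordinate on
#'   training data.
#' @param delta covariance ridge.
#' @export
lda_coordinate <- function(v, ref_mean, ref_covariance_N = NULL,
                           align = TRUE, value_range = NULL, delta = 1e-6) {
  if (!is.matrix(v)) v <- vec_to_frame(v)
  nv <- sqrt(sum(v^2))
  if (abs(nv - 1) > 1e-12) v <- v / nv  # keep already-unit vectors bit-exact
  ref_mean <- as.matrix(ref_mean)
  check_centered(ref_mean, "ref_mean")
  N <- nrow(ref_mean)
  if (is.null(ref_covariance_N)) ref_covariance_N <- diag(N)
  precision <- solve(regularize_covariance(ref_covariance_N, delta))
  structure(list(v = v, ref_mean = ref_mean,
                 ref_covariance_N = ref_covariance_N,
                 precision_N = precision, align = align,
                 value_range = value_range, delta = delta),
            class = "lda_coordinate")
}

#' @export
print.lda_coordinate <- function(x, ...) {
  cat(sprintf("<lda_coordinate: %d particles, %s%s>\n", nrow(x$v),
              if (x$align) "Mahalanobis-aligned" else "linear (no alignment)",
              if (is.null(x$value_range)) ""
              else sprintf(", trained range [%.3g, %.3g]",
                           x$value_range[1], x$value_range[2])))
  invisible(x)
}

#' Evaluate a linear-discriminant coordinate on a frame
#'
#' Translates the frame by the geometric-mean difference to the reference,
#' rotates it by the Mahalanobis-minimizing rotation (unless
#' `coordinate$align` is `FALSE`), and returns the dot product with the
#' coefficient vector.  With `gradient = TRUE` the analytic derivative with
#' respect to every coordinate is returned as well (the rotation's dependence
#' on the frame is differentiated through the quaternion eigenproblem), as
#' needed for biased sampling.
#'
#' @param frame `N x 3` matrix of coordinates.
#' @param coordinate an `lda_coordinate`.
#' @param gradient also return `d l / d x` (`N x 3`).
#' @return the scalar value, or a list `(value, grad, rotation)` when
#'   `gradient = TRUE`.
#' @export
evaluate_ld <- function(frame, coordinate, gradient = FALSE) {
  stopifnot(inherits(coordinate, "lda_coordinate"))
  if (!all(is.finite(frame)))
    stop_shapecv("non-finite frame", "shapecv_invalid_input")
  res <- ld_eval_cpp(as.matrix(frame), coordinate$v, coordinate$ref_mean,
                     coordinate$precision_N, coordinate$align, gradient)
  if (gradient) res else res$value
}

#' Evaluate a coordinate on every frame of an ensemble
#'
#' @param frames a `frame_ensemble`.
#' @param coordinate an `lda_coordinate`.
#' @return numeric vector of length M.
#' @export
evaluate_ld_ensemble <- function(frames, coordinate) {
  stopifnot(inherits(frames, "frame_ensemble"))
  vapply(seq_len(n_frames(frames)),
         function(i) evaluate_ld(get_frame(frames, i), coordinate),
         numeric(1))
}
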