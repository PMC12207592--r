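# Rigid-body geometry: translation removal and optimal (Mahalanobis) rotations.
#
# A configuration is an N x 3 matrix of particle coordinates in Angstrom; an
# ensemble stacks M of them into an M x N x 3 array.  Alignment works in the
# equivalence class of configurations under rigid-body transforms: frames are
# translated so their geometric mean sits at the origin, then rotated to
# minimize the (covariance-weighted) squared distance to a reference.

#' Construct a frame ensemble
#'
#' Bundles an `M x N x 3` coordinate array (or a single `N x 3` matrix) into a
#' validated ensemble object.  Coordinates are Cartesian, in Angstrom.
#'
#' @param coords `M x N x 3` array or `N x 3` matrix of finite coordinates.
#' @param elements optional character vector of length `N` with element
#'   symbols, preserved verbatim on XYZ round trips.
#' @return An object of class `frame_ensemble`.
#' @export
frame_ensemble <- function(coords, elements = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_shapecv("coords must be an M x N x 3 array", "shapecv_invalid_input")
  if (!all(is.finite(coords)))
    stop_shapecv("non-finite coordinates in ensemble", "shapecv_invalid_input")
  if (dim(coords)[2] < 3L)
    stop_shapecv("need at least 3 particles for rotations to be well-posed",
                 "shapecv_invalid_input")
  if (!is.null(elements) && length(elements) != dim(coords)[2])
    stop_shapecv("elements must have one entry per particle",
                 "shapecv_invalid_input")
  structure(list(coords = coords, elements = elements),
            class = "frame_ensemble")
}

#' @export
print.frame_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<frame_ensemble: %d frames x %d particles x 3 (Angstrom)>\n",
              d[1], d[2]))
  invisible(x)
}

#' Number of frames / particles in an ensemble
#' @param x a `frame_ensemble`
#' @return integer count.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(x) dim(x$coords)[2]

#' Extract one frame as an N x 3 matrix
#' @param x a `frame_ensemble`
#' @param i frame index
#' @export
get_frame <- function(x, i) {
  matrix(x$coords[i, , ], ncol = 3L)
}

#' Subset frames of an ensemble
#' @param x a `frame_ensemble`
#' @param idx integer or logical frame index
#' @export
subset_frames <- function(x, idx) {
  frame_ensemble(x$coords[idx, , , drop = FALSE], elements = x$elements)
}

#' Rigid transform (rotation + translation)
#'
#' Represents `x -> x R + 1 t'` applied to row-vector coordinates.  The
#' rotation must be special orthogonal.
#'
#' @param rotation 3 x 3 special orthogonal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop_shapecv("rotation must be special orthogonal (R'R = I, det = +1)",
                 "shapecv_invalid_input")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a frame
#' @param frame N x 3 matrix.
#' @param transform a `rigid_transform`.
#' @export
apply_rigid_transform <- function(frame, transform) {
  frame %*% transform$rotation +
    matrix(transform$translation, nrow(frame), 3, byrow = TRUE)
}

#' Draw random rotations uniformly from SO(3)
#' @param n number of rotations
#' @return a list of 3 x 3 rotation matrices.
#' @export
random_rotation <- function(n = 1) {
  out <- lapply(seq_len(n), function(i) {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_rotation(q)
  })
  if (n == 1) out[[1]] else out
}

quat_rotation <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2
  ), 3, 3, byrow = TRUE)
}

#' Remove translation from every frame
#'
#' Translates each frame so that the unweighted geometric mean of its
#' particles is exactly at the origin.
#'
#' @param frames a `frame_ensemble`.
#' @return list with the centered `frames` and an `M x 3` matrix of the
#'   removed `translations`.
#' @export
remove_translation <- function(frames) {
  stopifnot(inherits(frames, "frame_ensemble"))
  M <- n_frames(frames)
  out <- frames$coords
  translations <- matrix(0, M, 3)
  for (i in seq_len(M)) {
    f <- matrix(out[i, , ], ncol = 3)
    mu <- colMeans(f)
    translations[i, ] <- mu
    out[i, , ] <- sweep(f, 2, mu)
  }
  list(frames = frame_ensemble(out, elements = frames$elements),
       translations = translations)
}

center_frame <- function(frame) sweep(frame, 2, colMeans(frame))

check_centered <- function(frame, what, tol = 1e-6) {
  if (max(abs(colMeans(frame))) > tol)
    stop_shapecv(paste0(what, " must be centered at the origin"),
                 "shapecv_invalid_input")
}

#' Optimal rotation onto a reference (uniform covariance)
#'
#' Kabsch-type rotation minimizing the summed squared deviation between a
#' centered frame and a centered reference; reflections are excluded so the
#' result is always a proper rotation.
#'
#' @param frame,reference centered `N x 3` matrices.
#' @return a `rigid_transform` with zero translation; applying it to `frame`
#'   gives the aligned coordinates.
#' @export
kabsch_rotation <- function(frame, reference) {
  check_centered(frame, "frame"); check_centered(reference, "reference")
  M <- crossprod(frame, reference)
  sv <- svd(M)
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300))
    warning("near-degenerate (collinear) configuration; rotation is best-effort")
  R <- optimal_rotation_cpp(frame, reference, diag(nrow(frame)))
  rigid_transform(rotation = R)
}

#' Optimal rotation under a Kronecker-structured Mahalanobis metric
#'
#' Returns the proper rotation minimizing
#' `tr((frame R - mean)' precision_N (frame R - mean))`, the squared
#' Mahalanobis distance under the covariance `Sigma_N (x) I_3`.  Reduces to
#' [kabsch_rotation()] when `precision_N` is the identity.
#'
#' @param frame,mean centered `N x 3` matrices.
#' @param precision_N symmetric positive semidefinite `N x N` matrix
#'   (inverse of the particle covariance factor).
#' @return a `rigid_transform` with zero translation.
#' @export
kronecker_rotation <- function(frame, mean, precision_N) {
  check_centered(frame, "frame"); check_centered(mean, "mean")
  if (max(abs(precision_N - t(precision_N))) > 1e-8)
    stop_shapecv("precision_N must be symmetric", "shapecv_invalid_input")
  R <- optimal_rotation_cpp(frame, mean, precision_N)
  rigid_transform(rotation = R)
}

#' Regularize a particle covariance factor
#'
#' Adds `delta * I` before inversion; the centered particle covariance is
#' always rank-deficient, so a small ridge keeps it positive definite.
#'
#' @param covariance_N symmetric `N x N` matrix.
#' @param delta ridge magnitude in Angstrom^2.
#' @export
regularize_covariance <- function(covariance_N, delta = 1e-6) {
  covariance_N + delta * diag(nrow(covariance_N))
}

mahalanobis_sq <- function(dev, precision_N) {
  sum(dev * (precision_N %*% dev))
}

# weighted Kronecker covariance factor of aligned deviations about mu,
# normalized by the total weight: (1/3) sum_i w_i D_i D_i' / sum_i w_i
weighted_cov_N <- function(coords, mu, w) {
  weighted_cov_cpp(coords, mu, w)
}

weighted_mean_frame <- function(coords, w) {
  apply(coords * w, c(2, 3), sum) / sum(w)
}

#' Align an ensemble to a reference or to self-consistency
#'
#' With `mean` given, every frame is centered and rotated onto the fixed
#' reference under the requested metric.  With `mean = NULL` the reference is
#' found self-consistently: frames are aligned to the current (frame-weighted)
#' mean, the mean is recomputed from the aligned frames, and the loop repeats
#' until the mean drifts less than `tol` between passes.  With
#' `covariance_N = "kronecker"` the particle covariance factor is re-estimated
#' from the weighted aligned frames on each pass, giving the frame-weighted
#' Kronecker-covariance alignment used throughout model fitting.
#'
#' @param frames a `frame_ensemble`.
#' @param mean optional centered `N x 3` reference structure.
#' @param covariance_N `"uniform"` for the unweighted metric, a fixed `N x N`
#'   covariance factor, or `"kronecker"` (self-consistent mode only).
#' @param weights optional frame weights (normalized internally).
#' @param max_passes,tol self-consistency controls; `tol` is the maximum mean
#'   drift in Angstrom between passes.
#' @param delta covariance ridge, Angstrom^2.
#' @param mean_init,cov_init optional warm starts for the self-consistent
#'   reference (used heavily inside EM, where the previous component
#'   parameters are excellent starting points).
#' @return list of class `alignment_result` with elements `aligned`
#'   (ensemble), `transforms` (list of `rigid_transform`), `mahalanobis`
#'   (per-frame squared distance), `mean`, `covariance_N`, `passes`.
#' @export
align_ensemble <- function(frames, mean = NULL, covariance_N = "uniform",
                           weights = NULL, max_passes = 500, tol = 1e-6,
                           delta = 1e-6, mean_init = NULL, cov_init = NULL) {
  stopifnot(inherits(frames, "frame_ensemble"))
  M <- n_frames(frames); N <- n_particles(frames)
  w <- if (is.null(weights)) rep(1 / M, M) else weights / sum(weights)

  precision_of <- function(cov) {
    if (is.character(cov) && cov == "uniform") return(diag(N))
    solve(regularize_covariance(cov, delta))
  }

  align_pass <- function(mu, P) {
    res <- align_frames_cpp(frames$coords, mu, P)
    list(coords = res$aligned, rotations = res$rotations,
         translations = res$translations,
         mahalanobis = as.numeric(res$mahalanobis))
  }
  build_transforms <- function(pass) {
    lapply(seq_len(M), function(i) {
      structure(list(rotation = pass$rotations[, , i],
                     translation = pass$translations[i, ]),
                class = "rigid_transform")
    })
  }

  if (!is.null(mean)) {
    check_centered(mean, "mean")
    if (is.character(covariance_N) && covariance_N == "kronecker")
      stop_shapecv("covariance_N = \"kronecker\" requires self-consistent mode",
                   "shapecv_invalid_input")
    P <- precision_of(covariance_N)
    pass <- align_pass(mean, P)
    covN <- if (is.character(covariance_N)) diag(N) else covariance_N
    return(structure(list(
      aligned = frame_ensemble(pass$coords, elements = frames$elements),
      transforms = build_transforms(pass), mahalanobis = pass$mahalanobis,
      mean = mean, covariance_N = covN, passes = 1L),
      class = "alignment_result"))
  }

  kron <- is.character(covariance_N) && covariance_N == "kronecker"
  covN <- if (!is.null(cov_init)) cov_init
  else if (is.matrix(covariance_N)) covariance_N else diag(N)
  mu <- if (!is.null(mean_init)) center_frame(mean_init)
  else center_frame(weighted_mean_frame(frames$coords, w))

  # one inner sweep: converge the mean at a fixed metric (fast; the
  # reference is gauge-fixed by rotating each update back onto the previous
  # mean so drift measures genuine shape change), then refresh the
  # covariance from the aligned frames
  pass <- NULL
  sweep_once <- function(mu, covN) {
    P <- precision_of(if (kron || is.matrix(covariance_N)) covN else "uniform")
    for (q in seq_len(max_passes)) {
      pass <<- align_pass(mu, P)
      mu_new <- center_frame(weighted_mean_frame(pass$coords, w))
      mu_new <- mu_new %*% optimal_rotation_cpp(mu_new, mu, diag(N))
      dq <- max(abs(mu_new - mu))
      mu <- mu_new
      if (dq < 0.01 * tol) break
    }
    if (kron) covN <- weighted_cov_N(pass$coords, mu, w)
    list(mu = mu, covN = covN)
  }

  finish <- function(mu, covN, p) {
    structure(list(
      aligned = frame_ensemble(pass$coords, elements = frames$elements),
      transforms = build_transforms(pass), mahalanobis = pass$mahalanobis,
      mean = mu, covariance_N = covN, passes = p),
      class = "alignment_result")
  }

  # outer loop over metric refreshes; the joint (mean, covariance) fixed
  # point is approached geometrically and can contract very slowly on
  # strongly multimodal data, so a guarded Aitken extrapolation jumps along
  # the dominant slow mode when its decay ratio is stable
  z_prev <- NULL
  dz_prev <- NULL
  for (p in seq_len(max_passes)) {
    up <- sweep_once(mu, covN)
    mu_new <- up$mu; cov_new <- up$covN
    drift <- max(abs(mu_new - mu))
    mu <- mu_new; covN <- cov_new
    # with a fixed metric the inner sweep already converged the mean
    if (!kron || drift < tol) return(finish(mu, covN, p))
    z <- c(as.numeric(mu), as.numeric(covN))
    jumped <- FALSE
    if (!is.null(z_prev)) {
      dz <- z - z_prev
      if (!is.null(dz_prev)) {
        r <- sqrt(sum(dz^2) / sum(dz_prev^2))
        ca <- sum(dz * dz_prev) / sqrt(sum(dz^2) * sum(dz_prev^2))
        if (is.finite(r) && r > 0.3 && r < 0.9999 && ca > 0.99) {
          zx <- z + dz * r / (1 - r)
          mu_x <- center_frame(matrix(zx[seq_len(N * 3)], N, 3))
          cov_x <- matrix(zx[-seq_len(N * 3)], N, N)
          cov_x <- (cov_x + t(cov_x)) / 2
          # the centered covariance is legitimately singular; only reject
          # genuinely indefinite extrapolations (the ridge handles the rest)
          if (min(eigen(cov_x, symmetric = TRUE,
                        only.values = TRUE)$values) > -delta / 2) {
            mu <- mu_x
            covN <- cov_x
            jumped <- TRUE
          }
        }
      }
      dz_prev <- if (jumped) NULL else dz
    }
    z_prev <- if (jumped) NULL else z
  }
  stop_shapecv(
    sprintf("alignment failed to reach self-consistency in %d passes",
            max_passes),
    "shapecv_convergence_error", last_mean = mu, last_covariance = covN)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: %d frames, %d pass(es), mean Mahalanobis %.4g>\n",
              n_frames(x$aligned), x$passes, mean(x$mahalanobis)))
  invisible(x)
}
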