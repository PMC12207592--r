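# Frame-weighted Gaussian mixture model on aligned Cartesian coordinates
# ("shape" GMM): each component is a multivariate Gaussian over the 3N
# coordinates with mean structure mu_j and Kronecker covariance
# Sigma_Nj (x) I_3, evaluated on the rigid-body-aligned representative of
# each frame.  Frame weights w_i (summing to one) enter the E step as
# gamma_ij = w_i * posterior_ij, so weighted averages estimate unbiased
# expectations from biased trajectories.

#' Validate and normalize frame weights
#'
#' @param w nonnegative numeric vector.
#' @param normalize divide by the sum so weights total one (the convention
#'   assumed everywhere else).
#' @return numeric vector of class `frame_weights` summing to one.
#' @export
frame_weights <- function(w, normalize = TRUE) {
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0))
    stop_shapecv("frame weights must be finite and nonnegative",
                 "shapecv_invalid_input")
  if (sum(w) <= 0)
    stop_shapecv("frame weights must not all be zero", "shapecv_invalid_input")
  if (normalize) w <- w / sum(w)
  else if (abs(sum(w) - 1) > 1e-12)
    stop_shapecv("frame weights must sum to one", "shapecv_invalid_input")
  structure(w, class = "frame_weights")
}

resolve_weights <- function(weights, M) {
  if (is.null(weights)) return(rep(1 / M, M))
  w <- unclass(frame_weights(weights))
  if (length(w) != M)
    stop_shapecv("length(weights) must equal the number of frames",
                 "shapecv_invalid_input")
  w
}

# log N(x | mu, Sigma_N (x) I3) for a single aligned deviation, using the
# Kronecker structure: quadratic form through the N x N precision and
# log-determinant 3 * logdet(Sigma_N).
log_density_aligned <- function(dev, precision_N, logdet_N) {
  N <- nrow(dev)
  -0.5 * mahalanobis_sq(dev, precision_N) - 1.5 * logdet_N -
    1.5 * N * log(2 * pi)
}

# per-component alignment + log density for all frames; returns M x K matrix.
# the batched aligner returns the squared Mahalanobis distance, which is the
# quadratic form of the Gaussian exponent.
component_log_densities <- function(model, frames) {
  M <- n_frames(frames)
  N <- n_particles(frames)
  K <- model$K
  logd <- matrix(0, M, K)
  for (j in seq_len(K)) {
    res <- align_frames_cpp(frames$coords, model$means[[j]],
                            model$precisions[[j]])
    logd[, j] <- -0.5 * as.numeric(res$mahalanobis) -
      1.5 * model$logdets[[j]] - 1.5 * N * log(2 * pi)
  }
  logd
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

new_shape_gmm <- function(K, phi, means, covariances_N, delta,
                          train_log_likelihood = NA_real_, ...) {
  precisions <- lapply(covariances_N,
                       function(S) solve(regularize_covariance(S, delta)))
  logdets <- lapply(covariances_N, function(S) {
    2 * sum(log(diag(chol(regularize_covariance(S, delta)))))
  })
  structure(list(K = K, phi = phi, means = means,
                 covariances_N = covariances_N, precisions = precisions,
                 logdets = logdets, delta = delta,
                 train_log_likelihood = train_log_likelihood, ...),
            class = "shape_gmm")
}

#' Weighted E step
#'
#' Computes the frame-weighted responsibilities
#' `gamma[i, j] = w_i * phi_j N_j(x_i) / sum_k phi_k N_k(x_i)`, with each
#' density evaluated on the frame aligned to that component's mean under its
#' Kronecker covariance.  Row `i` sums to `w_i`.
#'
#' @param model a `shape_gmm`.
#' @param frames a `frame_ensemble`.
#' @param weights frame weights (default uniform).
#' @return `M x K` responsibility matrix.
#' @export
weighted_e_step <- function(model, frames, weights = NULL) {
  M <- n_frames(frames)
  w <- resolve_weights(weights, M)
  logd <- component_log_densities(model, frames)
  gamma <- matrix(0, M, model$K)
  lphi <- log(model$phi)
  for (i in seq_len(M)) {
    lp <- lphi + logd[i, ]
    if (all(!is.finite(lp)))
      stop_shapecv(sprintf("all component densities degenerate for frame %d", i),
                   "shapecv_numerical_error")
    gamma[i, ] <- w[i] * exp(lp - logsumexp(lp))
  }
  gamma
}

#' Weighted M step
#'
#' Re-estimates mixture weights, mean structures and Kronecker covariance
#' factors from responsibilities: `phi_j = sum_i gamma_ij`, `mu_j` the
#' responsibility-weighted mean of frames aligned to component `j`, and
#' `Sigma_Nj` the responsibility-weighted particle covariance of the aligned
#' deviations (averaged over the three Cartesian axes).  Alignment to each
#' component is iterated to self-consistency.
#'
#' @param responsibilities `M x K` matrix from [weighted_e_step()].
#' @param frames a `frame_ensemble`.
#' @param delta covariance ridge.
#' @param warm_start optional `shape_gmm` whose parameters seed the
#'   per-component self-consistent alignment.
#' @return a `shape_gmm`.
#' @export
weighted_m_step <- function(responsibilities, frames, delta = 1e-6,
                            warm_start = NULL) {
  gamma <- as.matrix(responsibilities)
  K <- ncol(gamma)
  totals <- colSums(gamma)
  if (any(totals < 1e-12))
    stop_shapecv(
      paste0("component ", which.min(totals), " has vanishing total ",
             "responsibility; try smaller K or a different seed"),
      "shapecv_empty_component")
  phi <- totals / sum(totals)
  means <- vector("list", K)
  covs <- vector("list", K)
  for (j in seq_len(K)) {
    al <- align_ensemble(frames, covariance_N = "kronecker",
                         weights = gamma[, j], delta = delta,
                         mean_init = warm_start$means[[j]],
                         cov_init = warm_start$covariances_N[[j]])
    means[[j]] <- al$mean
    covs[[j]] <- al$covariance_N
  }
  new_shape_gmm(K, phi, means, covs, delta)
}

#' Weighted log-likelihood of an ensemble under a shape GMM
#'
#' Returns `sum_i w_i log sum_j phi_j N_j(x_i)` with per-component optimal
#' alignment, i.e. the per-frame weighted average log-likelihood.
#'
#' @inheritParams weighted_e_step
#' @export
weighted_log_likelihood <- function(model, frames, weights = NULL) {
  M <- n_frames(frames)
  w <- resolve_weights(weights, M)
  logd <- component_log_densities(model, frames)
  lphi <- log(model$phi)
  ll <- 0
  for (i in seq_len(M)) {
    if (w[i] == 0) next
    ll <- ll + w[i] * logsumexp(lphi + logd[i, ])
  }
  ll
}

# k-means++-style seeding on flattened uniformly aligned frames, with frame
# weights entering the seeding probabilities and the assignment step.
init_responsibilities <- function(frames, w, K, delta) {
  al <- align_ensemble(frames, covariance_N = "uniform", delta = delta)
  M <- n_frames(frames)
  X <- t(apply(al$aligned$coords, 1, as.numeric))  # M x 3N
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(M, 1, prob = w)
  centers[1, ] <- X[first, ]
  if (K > 1) {
    for (k in 2:K) {
      d2 <- apply(centers[seq_len(k - 1), , drop = FALSE], 1,
                  function(cc) rowSums(sweep(X, 2, cc)^2))
      dmin <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      p <- w * dmin
      if (sum(p) <= 0) p <- w
      centers[k, ] <- X[sample.int(M, 1, prob = p), ]
    }
  }
  d2 <- sapply(seq_len(K), function(k) rowSums(sweep(X, 2, centers[k, ])^2))
  lab <- max.col(-d2, ties.method = "first")
  gamma <- matrix(0, M, K)
  gamma[cbind(seq_len(M), lab)] <- w
  # guard: every component needs some weight
  for (k in seq_len(K)) {
    if (sum(gamma[, k]) < 1e-12) {
      i <- which.max(w)
      gamma[i, ] <- 0
      gamma[i, k] <- w[i]
    }
  }
  gamma
}

#' Fit a frame-weighted shape GMM by expectation maximization
#'
#' Alternates [weighted_e_step()] and [weighted_m_step()] (with per-component
#' realignment) until the weighted log-likelihood changes by less than `tol`,
#' starting from a weighted k-means++-style hard assignment on uniformly
#' aligned frames.  Several seeds are tried and the fit with the best final
#' log-likelihood is returned.
#'
#' @param frames a `frame_ensemble` with `M > K` frames.
#' @param weights frame weights (default uniform).
#' @param K number of mixture components.
#' @param seeds integer vector of RNG seeds for initialization.
#' @param max_iter,tol EM stopping controls (`tol` on the per-frame weighted
#'   log-likelihood).
#' @param delta covariance ridge, Angstrom^2.
#' @return a `shape_gmm` with elements `phi`, `means`, `covariances_N`,
#'   `train_log_likelihood`, `ll_history`, `responsibilities`, `seed`,
#'   `iterations`, `converged`.
#' @export
weighted_em_fit <- function(frames, weights = NULL, K, seeds = 1:3,
                            max_iter = 200, tol = 1e-6, delta = 1e-6) {
  M <- n_frames(frames)
  if (M <= K)
    stop_shapecv("need more frames than components", "shapecv_invalid_input")
  w <- resolve_weights(weights, M)

  best <- NULL
  diagnostics <- list()
  for (seed in seeds) {
    fit <- tryCatch(
      em_single_seed(frames, w, K, seed, max_iter, tol, delta),
      shapecv_error = function(e) e)
    if (inherits(fit, "condition")) {
      diagnostics[[as.character(seed)]] <- conditionMessage(fit)
      next
    }
    if (is.null(best) || fit$train_log_likelihood > best$train_log_likelihood)
      best <- fit
  }
  if (is.null(best))
    stop_shapecv(
      paste0("no seed converged; per-seed diagnostics: ",
             paste(sprintf("[%s] %s", names(diagnostics),
                           unlist(diagnostics)), collapse = "; ")),
      "shapecv_convergence_error")
  best
}

em_single_seed <- function(frames, w, K, seed, max_iter, tol, delta) {
  set.seed(seed)
  gamma <- init_responsibilities(frames, w, K, delta)
  model <- weighted_m_step(gamma, frames, delta = delta)
  ll_old <- -Inf
  ll_history <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    gamma <- weighted_e_step(model, frames, w)
    model <- weighted_m_step(gamma, frames, delta = delta, warm_start = model)
    ll <- weighted_log_likelihood(model, frames, w)
    ll_history <- c(ll_history, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  model$train_log_likelihood <- ll_old
  model$ll_history <- ll_history
  model$responsibilities <- gamma
  model$weights <- w
  model$seed <- seed
  model$iterations <- it
  model$converged <- converged
  model
}

#' @export
print.shape_gmm <- function(x, ...) {
  cat(sprintf("<shape_gmm: K = %d, N = %d particles, logL = %.4f%s>\n",
              x$K, nrow(x$means[[1]]), x$train_log_likelihood,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  cat("  phi:", paste(sprintf("%.3f", x$phi), collapse = " "), "\n")
  invisible(x)
}

#' Assign frames to mixture components
#'
#' Labels each frame with the component of maximal unweighted posterior
#' probability; exact ties break deterministically to the lowest index.
#'
#' @param model a `shape_gmm`.
#' @param frames a `frame_ensemble`.
#' @return list with integer `labels` and the `M x K` posterior matrix
#'   `responsibilities` (rows sum to one).
#' @export
predict_assignments <- function(model, frames) {
  M <- n_frames(frames)
  logd <- component_log_densities(model, frames)
  lphi <- log(model$phi)
  post <- matrix(0, M, model$K)
  for (i in seq_len(M)) {
    lp <- lphi + logd[i, ]
    post[i, ] <- exp(lp - logsumexp(lp))
  }
  labels <- apply(post, 1, function(p) which(p >= max(p) - 1e-12)[1])
  list(labels = labels, responsibilities = post)
}

#' @export
predict.shape_gmm <- function(object, newdata, ...) {
  predict_assignments(object, newdata)$labels
}

#' Scan the number of mixture components with held-out validation
#'
#' For every `(K, seed)` pair, splits the frames into a training and a
#' held-out set (weights renormalized on each split), fits a weighted shape
#' GMM on the training split, and reports the weighted log-likelihood on both
#' splits.  Errors for individual rows (e.g. `K` exceeding the training size)
#' are recorded and the scan continues.
#'
#' @param frames a `frame_ensemble`.
#' @param weights frame weights.
#' @param K_range integer vector of component counts to try.
#' @param train_frac fraction of frames in the training split.
#' @param seeds seeds controlling both the split and the EM initialization.
#' @param ... passed to [weighted_em_fit()].
#' @return a data frame of class `cluster_scan` with columns `K`, `seed`,
#'   `train_ll`, `cv_ll`, `error`.
#' @export
scan_num_clusters <- function(frames, weights = NULL, K_range = 1:4,
                              train_frac = 0.9, seeds = 1:3, ...) {
  M <- n_frames(frames)
  w <- resolve_weights(weights, M)
  n_train <- floor(train_frac * M)
  if (n_train < 2 || n_train >= M)
    stop_shapecv("train_frac leaves too few frames for the requested split",
                 "shapecv_invalid_input")
  rows <- list()
  for (seed in seeds) {
    set.seed(seed)
    idx <- sample.int(M, n_train)
    tr <- subset_frames(frames, idx)
    cv <- subset_frames(frames, -idx)
    w_tr <- w[idx] / sum(w[idx])
    w_cv <- w[-idx] / sum(w[-idx])
    for (K in K_range) {
      row <- data.frame(K = K, seed = seed, train_ll = NA_real_,
                        cv_ll = NA_real_, error = NA_character_)
      res <- tryCatch({
        if (K >= n_frames(tr))
          stop_shapecv("K exceeds training frames", "shapecv_invalid_input")
        fit <- weighted_em_fit(tr, w_tr, K = K, seeds = seed, ...)
        list(train = fit$train_log_likelihood,
             cv = weighted_log_likelihood(fit, cv, w_cv))
      }, shapecv_error = function(e) e)
      if (inherits(res, "condition")) {
        row$error <- conditionMessage(res)
      } else {
        row$train_ll <- res$train
        row$cv_ll <- res$cv
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_scan", "data.frame")
  out
}
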