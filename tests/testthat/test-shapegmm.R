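make_model_from_system <- function(sys) {
  shapecv:::new_shape_gmm(
    K = 2, phi = sys$mixture_weights,
    means = lapply(sys$means, function(m) sweep(m, 2, colMeans(m))),
    covariances_N = sys$covariances_N, delta = 1e-6)
}

test_that("weighted E step reproduces the direct posterior formula", {
  sys <- toy_fixture(seed = 2)
  model <- make_model_from_system(sys)
  tr <- sample_iid(sys, 40, seed = 3)
  set.seed(4)
  w <- frame_weights(runif(40))

  gamma <- weighted_e_step(model, tr$frames, w)
  expect_equal(rowSums(gamma), as.numeric(w), tolerance = 1e-10)

  # direct evaluation: align each frame per component, then explicit
  # quadratic form and log-determinant on the full 3N covariance
  for (i in c(1, 7, 23)) {
    f <- get_frame(tr$frames, i)
    logd <- vapply(1:2, function(j) {
      y <- sweep(f, 2, colMeans(f))
      R <- kronecker_rotation(y, model$means[[j]],
                              model$precisions[[j]])$rotation
      direct_log_density(y %*% R - model$means[[j]],
                         model$covariances_N[[j]])
    }, numeric(1))
    lp <- log(model$phi) + logd
    expect_equal(gamma[i, ], w[i] * exp(lp - max(lp)) / sum(exp(lp - max(lp))),
                 tolerance = 1e-10)
  }

  # K = 1: responsibilities are exactly the frame weights
  m1 <- shapecv:::new_shape_gmm(1, 1, model$means[1],
                                model$covariances_N[1], 1e-6)
  g1 <- weighted_e_step(m1, tr$frames, w)
  expect_identical(dim(g1), c(40L, 1L))
  expect_equal(g1[, 1], as.numeric(w), tolerance = 0)

  # a frame at a component mean of a well-separated model is fully assigned
  msep <- make_model_from_system(separated_fixture(seed = 2))
  fe <- frame_ensemble(msep$means[[1]])
  g <- weighted_e_step(msep, fe, frame_weights(1, normalize = FALSE))
  expect_gt(g[1, 1], 0.999)
})

test_that("weighted M step matches per-cluster weighted statistics", {
  sys <- toy_fixture(seed = 5)
  tr <- sample_iid(sys, 40, seed = 6)
  set.seed(7)
  w <- frame_weights(runif(40))
  gamma <- matrix(0, 40, 2)
  gamma[cbind(1:40, tr$labels)] <- w

  model <- weighted_m_step(gamma, tr$frames)
  expect_equal(model$phi, vapply(1:2, function(k) sum(w[tr$labels == k]),
                                 numeric(1)), tolerance = 1e-12)
  for (k in 1:2) {
    idx <- tr$labels == k
    al <- align_ensemble(subset_frames(tr$frames, idx),
                         covariance_N = "kronecker", weights = w[idx])
    expect_frames_equal(model$means[[k]], al$mean, 1e-8)
    expect_frames_equal(model$covariances_N[[k]], al$covariance_N, 1e-8)
  }

  # splitting one frame's weight across duplicates changes nothing: apply
  # the M-step map from the same converged start to both data sets
  co <- tr$frames$coords[c(1:40, 1), , ]
  gamma2 <- rbind(gamma, gamma[1, ] / 2)
  gamma2[1, ] <- gamma2[1, ] / 2
  m1 <- weighted_m_step(gamma, tr$frames, warm_start = model)
  m2 <- weighted_m_step(gamma2, frame_ensemble(co), warm_start = model)
  expect_frames_equal(m2$means[[1]], m1$means[[1]], 1e-12)
  expect_frames_equal(m2$covariances_N[[1]], m1$covariances_N[[1]], 1e-12)
  expect_equal(m2$phi, m1$phi, tolerance = 1e-12)

  gamma[, 2] <- 0
  expect_error(weighted_m_step(gamma, tr$frames),
               class = "shapecv_empty_component")
})

test_that("weighted log-likelihood matches a direct evaluator", {
  sys <- toy_fixture(seed = 8)
  model <- make_model_from_system(sys)
  tr <- sample_iid(sys, 25, seed = 9)
  set.seed(10)
  w <- frame_weights(runif(25))

  ll <- weighted_log_likelihood(model, tr$frames, w)
  direct <- 0
  for (i in 1:25) {
    f <- get_frame(tr$frames, i)
    y <- sweep(f, 2, colMeans(f))
    dens <- vapply(1:2, function(j) {
      R <- kronecker_rotation(y, model$means[[j]],
                              model$precisions[[j]])$rotation
      model$phi[j] * exp(direct_log_density(y %*% R - model$means[[j]],
                                            model$covariances_N[[j]]))
    }, numeric(1))
    direct <- direct + w[i] * log(sum(dens))
  }
  expect_equal(ll, direct, tolerance = 1e-10)

  # zero-weight frames are excluded exactly
  two <- subset_frames(tr$frames, 1:2)
  ll10 <- weighted_log_likelihood(model, two, c(1, 0))
  ll1 <- weighted_log_likelihood(model, subset_frames(tr$frames, 1), 1)
  expect_equal(ll10, ll1, tolerance = 1e-12)

  # frame exactly at the mean of a K = 1 model: only the normalization term
  m1 <- shapecv:::new_shape_gmm(1, 1, model$means[1],
                                model$covariances_N[1], 1e-6)
  llmean <- weighted_log_likelihood(m1, frame_ensemble(model$means[[1]]), 1)
  expect_equal(llmean, -1.5 * m1$logdets[[1]] - 1.5 * sys$N * log(2 * pi),
               tolerance = 1e-10)
})

test_that("EM recovers generator parameters and is monotone", {
  sys <- separated_fixture(seed = 12)
  tr <- sample_iid(sys, 600, seed = 13)
  fit <- weighted_em_fit(tr$frames, K = 2, seeds = 1:2)
  expect_true(all(diff(fit$ll_history) > -1e-8))
  expect_true(fit$converged)
  # best-match pairing of components to generator states
  d11 <- aligned_rmsd(fit$means[[1]], sys$means[[1]])
  d12 <- aligned_rmsd(fit$means[[1]], sys$means[[2]])
  perm <- if (d11 < d12) c(1, 2) else c(2, 1)
  for (k in 1:2)
    expect_lt(aligned_rmsd(fit$means[[perm[k]]], sys$means[[k]]), 0.05)
  expect_equal(sort(fit$phi), sort(sys$mixture_weights), tolerance = 0.06)

  # single-component recovery within 3 standard errors
  sys1 <- make_two_state_system(separation = 0.0001, N = 5, seed = 14)
  tr1 <- sample_iid(sys1, 400, seed = 15)
  fit1 <- weighted_em_fit(tr1$frames, K = 1, seeds = 1)
  se <- sys1$spread / sqrt(400)
  expect_lt(aligned_rmsd(fit1$means[[1]], sweep(sys1$means[[1]], 2,
                                                colMeans(sys1$means[[1]]))),
            3 * se * sqrt(3))
})

test_that("uniform weights reproduce the unweighted fit and frame order is irrelevant", {
  sys <- toy_fixture(seed = 16)
  tr <- sample_iid(sys, 150, seed = 17)
  f1 <- weighted_em_fit(tr$frames, weights = NULL, K = 2, seeds = 3)
  f2 <- weighted_em_fit(tr$frames, weights = rep(1 / 150, 150), K = 2,
                        seeds = 3)
  expect_equal(f1$train_log_likelihood, f2$train_log_likelihood,
               tolerance = 1e-8)
  expect_frames_equal(f1$means[[1]], f2$means[[1]], 1e-8)

  # rigid-transform invariance of the fitted model
  set.seed(18)
  co <- tr$frames$coords
  for (i in seq_len(dim(co)[1])) {
    R <- random_rotation()
    co[i, , ] <- matrix(co[i, , ], ncol = 3) %*% R +
      matrix(rnorm(3, sd = 3), sys$N, 3, byrow = TRUE)
  }
  f3 <- weighted_em_fit(frame_ensemble(co), K = 2, seeds = 3)
  expect_equal(sort(f3$phi), sort(f1$phi), tolerance = 1e-6)
  ll_cross <- abs(f3$train_log_likelihood - f1$train_log_likelihood)
  expect_lt(ll_cross, 1e-5)
  perm <- if (aligned_rmsd(f3$means[[1]], f1$means[[1]]) <
              aligned_rmsd(f3$means[[1]], f1$means[[2]])) c(1, 2) else c(2, 1)
  for (k in 1:2)
    expect_lt(aligned_rmsd(f3$means[[perm[k]]], f1$means[[k]]), 1e-5)
})

test_that("predicted assignments match generator labels with deterministic ties", {
  sys <- separated_fixture(seed = 19)
  model <- make_model_from_system(sys)
  tr <- sample_iid(sys, 300, seed = 20)
  pred <- predict_assignments(model, tr$frames)
  expect_gte(mean(pred$labels == tr$labels), 0.99)
  expect_equal(rowSums(pred$responsibilities), rep(1, 300), tolerance = 1e-10)

  # exactly symmetric frame between two identical components: lowest index
  msym <- shapecv:::new_shape_gmm(
    2, c(0.5, 0.5), list(model$means[[1]], model$means[[1]]),
    list(sys$covariances_N[[1]], sys$covariances_N[[1]]), 1e-6)
  p <- predict_assignments(msym, frame_ensemble(model$means[[1]]))
  expect_identical(p$labels, 1L)
})

test_that("cluster-number scan prefers the generating K on held-out data", {
  sys <- toy_fixture(seed = 22)
  tr <- sample_iid(sys, 240, seed = 23)
  scan <- scan_num_clusters(tr$frames, K_range = 1:2, train_frac = 0.75,
                            seeds = 1:3)
  expect_s3_class(scan, "cluster_scan")
  expect_identical(nrow(scan), 6L)
  cv1 <- mean(scan$cv_ll[scan$K == 1])
  cv2 <- mean(scan$cv_ll[scan$K == 2])
  expect_gt(cv2, cv1)
  # no overfitting possible at K = 1 on i.i.d. data: train and held-out
  # log-likelihoods agree to sampling accuracy
  expect_lt(max(abs(scan$train_ll[scan$K == 1] - scan$cv_ll[scan$K == 1])),
            1.5)
  # oversized K produces an error row, and the scan continues
  tiny <- subset_frames(tr$frames, 1:8)
  scan2 <- scan_num_clusters(tiny, K_range = c(1, 7), train_frac = 0.75,
                             seeds = 1)
  expect_true(any(!is.na(scan2$error)))
  expect_true(any(is.finite(scan2$cv_ll)))
})
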