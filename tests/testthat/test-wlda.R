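make_labeled_frames <- function(M, N, sep_axis, seed = 1, spread = 0.2) {
  set.seed(seed)
  labels <- rep(1:2, each = M / 2)
  coords <- array(rnorm(M * N * 3, sd = spread), dim = c(M, N, 3))
  base <- random_centered_frame(N)
  for (i in seq_len(M)) {
    coords[i, , ] <- coords[i, , ] + base +
      (if (labels[i] == 1) -0.5 else 0.5) * sep_axis
  }
  list(frames = frame_ensemble(coords), labels = labels)
}

test_that("weighted scatter matrices match a direct double-loop evaluation", {
  set.seed(101)
  M <- 12; N <- 3
  coords <- array(rnorm(M * N * 3), dim = c(M, N, 3))
  fe <- frame_ensemble(coords)
  labels <- rep(1:2, each = 6)
  w <- frame_weights(runif(M))

  sc <- weighted_scatter_matrices(fe, labels, w)
  X <- matrix(coords, nrow = M)
  mu_g <- colSums(X * as.numeric(w))
  S_W <- matrix(0, 3 * N, 3 * N); S_B <- matrix(0, 3 * N, 3 * N)
  for (k in 1:2) {
    idx <- which(labels == k)
    Wk <- sum(w[idx])
    mk <- colSums(X[idx, ] * w[idx]) / Wk
    for (i in idx)
      S_W <- S_W + w[i] * tcrossprod(X[i, ] - mk)
    S_B <- S_B + Wk * tcrossprod(mk - mu_g)
  }
  expect_equal(sc$S_W, S_W, tolerance = 1e-10)
  expect_equal(sc$S_B, S_B, tolerance = 1e-10)
  expect_equal(sc$class_weights,
               c(sum(w[labels == 1]), sum(w[labels == 2])),
               tolerance = 1e-12)

  # uniform weights reduce to classical scatter matrices scaled by 1/M
  scu <- weighted_scatter_matrices(fe, labels, NULL)
  S_W_c <- matrix(0, 3 * N, 3 * N)
  for (k in 1:2) {
    idx <- which(labels == k)
    mk <- colMeans(X[idx, ])
    for (i in idx) S_W_c <- S_W_c + tcrossprod(X[i, ] - mk)
  }
  expect_equal(scu$S_W, S_W_c / M, tolerance = 1e-10)

  # identical class means kill the between-class scatter
  sym <- rbind(X[1:6, ], X[1:6, ])
  fe_sym <- frame_ensemble(array(sym, dim = c(M, N, 3)))
  sc_sym <- weighted_scatter_matrices(fe_sym, labels, NULL)
  expect_lt(max(abs(sc_sym$S_B)), 1e-12)
  expect_error(weighted_scatter_matrices(fe, rep(1L, M), NULL),
               class = "shapecv_invalid_input")
})

test_that("wlda_solve finds the separating axis and maximizes the Fisher ratio", {
  set.seed(102)
  N <- 4
  # exactly isotropic within-class spread, separation purely along one axis:
  # the discriminant must be that axis
  d_axis <- numeric(3 * N); d_axis[2] <- 1
  sc_exact <- structure(list(
    S_W = 0.01 * diag(3 * N),
    S_B = 0.25 * tcrossprod(d_axis),
    class_weights = c(0.5, 0.5),
    class_means = rbind(-0.5 * d_axis, 0.5 * d_axis),
    global_mean = numeric(3 * N), classes = 1:2), class = "scatter_pair")
  v_exact <- wlda_solve(sc_exact)
  expect_equal(abs(sum(v_exact * d_axis)), 1, tolerance = 1e-6)

  M <- 200
  axis <- matrix(0, N, 3); axis[2, 1] <- 1  # pure x-displacement, particle 2
  coords <- array(rnorm(M * N * 3, sd = 0.1), dim = c(M, N, 3))
  labels <- rep(1:2, each = M / 2)
  for (i in seq_len(M))
    coords[i, , ] <- coords[i, , ] + (if (labels[i] == 1) -1 else 1) * axis
  sc <- weighted_scatter_matrices(frame_ensemble(coords), labels, NULL)
  v <- wlda_solve(sc)

  # Fisher ratio at the solution dominates random directions
  fisher <- function(u) drop(t(u) %*% sc$S_B %*% u / (t(u) %*% sc$S_W %*% u))
  fr <- fisher(v)
  for (r in 1:2000) {
    u <- rnorm(3 * N); u <- u / sqrt(sum(u^2))
    expect_gte(fr, fisher(u) - 1e-8)
  }

  # relabeling flips nothing observable (sign convention is deterministic)
  sc2 <- weighted_scatter_matrices(frame_ensemble(coords),
                                   3L - labels, NULL)
  v2 <- wlda_solve(sc2)
  expect_equal(abs(sum(v * v2)), 1, tolerance = 1e-8)

  sc$S_B <- sc$S_B * 0
  expect_error(wlda_solve(sc), class = "shapecv_no_discriminant")
})

test_that("uniform-weight wLDA equals classical LDA on the same data", {
  set.seed(103)
  N <- 4
  lab <- make_labeled_frames(120, N, sep_axis = {
    a <- matrix(0, N, 3); a[1, 2] <- 1.5; a
  }, seed = 104)
  sc <- weighted_scatter_matrices(lab$frames, lab$labels, NULL)
  v <- wlda_solve(sc)
  # classical two-class LDA direction via the pseudo-inverse of S_W
  X <- matrix(lab$frames$coords, nrow = 120)
  m1 <- colMeans(X[lab$labels == 1, ]); m2 <- colMeans(X[lab$labels == 2, ])
  Sw <- matrix(0, 3 * N, 3 * N)
  for (i in 1:120) {
    mk <- if (lab$labels[i] == 1) m1 else m2
    Sw <- Sw + tcrossprod(X[i, ] - mk)
  }
  u <- drop(MASS::ginv(Sw) %*% (m2 - m1))
  u <- u / sqrt(sum(u^2))
  angle <- acos(min(1, abs(sum(u * v))))
  expect_lt(angle, 1e-6)
})

test_that("the LD coordinate is rigid-invariant with an exact gradient", {
  set.seed(105)
  N <- 5
  ref <- random_centered_frame(N)
  covN <- random_spd(N, base = 0.5)
  coord <- lda_coordinate(matrix(rnorm(N * 3), N, 3), ref_mean = ref,
                          ref_covariance_N = covN)
  expect_equal(sqrt(sum(coord$v^2)), 1, tolerance = 1e-10)

  # zero displacement at the reference itself
  expect_equal(evaluate_ld(ref, coord), 0, tolerance = 1e-10)

  for (rep in 1:5) {
    x <- ref + 0.4 * matrix(rnorm(N * 3), N, 3)
    # invariance under rigid transforms
    g <- random_rotation()
    xg <- x %*% g + matrix(rnorm(3, sd = 4), N, 3, byrow = TRUE)
    expect_equal(evaluate_ld(x, coord), evaluate_ld(xg, coord),
                 tolerance = 1e-6)
    # analytic gradient against central finite differences
    res <- evaluate_ld(x, coord, gradient = TRUE)
    h <- 1e-6
    fd <- matrix(0, N, 3)
    for (i in seq_len(N)) for (c in 1:3) {
      xp <- x; xm <- x
      xp[i, c] <- xp[i, c] + h; xm[i, c] <- xm[i, c] - h
      fd[i, c] <- (evaluate_ld(xp, coord) - evaluate_ld(xm, coord)) / (2 * h)
    }
    expect_lt(max(abs(res$grad - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("the coordinate is linear in small displacements along v", {
  set.seed(106)
  N <- 5
  ref <- random_centered_frame(N)
  covN <- random_spd(N, base = 0.5)
  coord <- lda_coordinate(matrix(rnorm(N * 3), N, 3), ref_mean = ref,
                          ref_covariance_N = covN)
  # l(ref + c v) ~ c <grad l(ref), v> for small c, with the quadratic
  # remainder vanishing as c^2
  g0 <- evaluate_ld(ref, coord, gradient = TRUE)$grad
  slope <- sum(g0 * coord$v)
  err <- vapply(c(1e-3, 1e-4), function(c_small) {
    abs(evaluate_ld(ref + c_small * coord$v, coord) - c_small * slope) /
      c_small
  }, numeric(1))
  expect_lt(err[2], 1e-3)
  expect_lt(err[2], err[1] / 5 + 1e-12)  # second-order decay
})

test_that("equal-state weighting only rescales class totals", {
  set.seed(107)
  N <- 4
  axisA <- matrix(0, N, 3); axisA[3, 1] <- 1
  lab <- make_labeled_frames(80, N, axisA, seed = 108)
  w <- runif(80); w[lab$labels == 1] <- w[lab$labels == 1] * 3
  w <- w / sum(w)
  # direct recomputation: renormalize each class to one half, rebuild scatter
  w_eq <- w
  for (k in 1:2) {
    idx <- lab$labels == k
    w_eq[idx] <- 0.5 * w[idx] / sum(w[idx])
  }
  sc_eq <- weighted_scatter_matrices(lab$frames, lab$labels, w_eq)
  expect_equal(sc_eq$class_weights, c(0.5, 0.5), tolerance = 1e-12)
  # within-class scatter of class k scales by the class renormalization
  sc_raw <- weighted_scatter_matrices(lab$frames, lab$labels, w)
  for (k in 1:2) {
    idx <- which(lab$labels == k)
    Xk <- matrix(lab$frames$coords, nrow = 80)[idx, ]
    mk <- colSums(Xk * w[idx]) / sum(w[idx])
    mk_eq <- colSums(Xk * w_eq[idx]) / sum(w_eq[idx])
    expect_equal(mk, mk_eq, tolerance = 1e-12)  # class means unchanged
  }
})
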