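test_that("the mirror system is exactly symmetric with the stated barrier", {
  sys <- toy_fixture(seed = 3)
  mirror <- function(x) x %*% diag(c(1, 1, -1))
  set.seed(401)
  for (r in 1:5) {
    x <- sys$means[[1]] + 0.5 * matrix(rnorm(sys$N * 3), sys$N, 3)
    expect_equal(toy_potential(sys, x), toy_potential(sys, mirror(x)),
                 tolerance = 1e-10)
  }
  # barrier equals the direct line evaluation of -kT log(mixture)
  tgrid <- seq(0, 1, length.out = 201)
  u <- vapply(tgrid, function(t) {
    toy_potential(sys, (1 - t) * sys$means[[1]] + t * sys$means[[2]])
  }, numeric(1))
  expect_equal(barrier_height(sys), max(u) - min(u[c(1, 201)]),
               tolerance = 1e-12)
  expect_equal(barrier_height(sys) / sys$kT, 6, tolerance = 0.1)
})

test_that("the i.i.d. sampler reproduces the generator statistics", {
  sys <- toy_fixture(seed = 4)
  tr <- sample_iid(sys, 10000, seed = 5)
  # binomial component frequencies
  p1 <- mean(tr$labels == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 10000))
  # per-component Kronecker covariance factor within 5 percent (raw
  # deviations from the known mean; alignment would deliberately project
  # out rigid-body modes and shrink the estimate by O(1/N))
  for (k in 1:2) {
    idx <- which(tr$labels == k)
    devsum <- matrix(0, sys$N, sys$N)
    for (i in idx) {
      D <- matrix(tr$frames$coords[i, , ], ncol = 3) - sys$means[[k]]
      devsum <- devsum + tcrossprod(D)
    }
    covN <- devsum / (3 * length(idx))
    expect_lt(max(abs(covN - sys$covariances_N[[k]])) /
                max(abs(sys$covariances_N[[k]])), 0.05)
  }
})

test_that("rigid jitter scrambles poses but not shape statistics", {
  sys <- toy_fixture(seed = 6)
  t_plain <- sample_iid(sys, 800, seed = 7)
  t_jit <- sample_iid(sys, 800, seed = 7, rigid_jitter = TRUE)
  mu_ref <- sweep(sys$means[[1]], 2, colMeans(sys$means[[1]]))
  aligned_cov <- function(tr) {
    sub <- subset_frames(tr$frames, tr$labels == 1)
    al <- align_ensemble(sub, mean = mu_ref,
                         covariance_N = sys$covariances_N[[1]])
    shapecv:::weighted_cov_N(al$aligned$coords, mu_ref,
                             rep(1 / n_frames(sub), n_frames(sub)))
  }
  # identical draws, so the aligned shape statistics agree to rounding
  expect_lt(max(abs(aligned_cov(t_jit) - aligned_cov(t_plain))), 1e-10)
})

test_that("analytic linear marginals are exact", {
  sys <- toy_fixture(seed = 8)
  grid <- seq(-2, 2, length.out = 61)

  # single-component limit: quadratic with curvature kT / variance
  sys1 <- make_two_state_system(separation = 1e-6, N = 5, seed = 9)
  d <- matrix(0, 5, 3); d[1, 1] <- 1 / sqrt(2); d[2, 1] <- -1 / sqrt(2)
  f1 <- analytic_fes_linear(sys1, d, grid)
  vd <- sum(diag(t(d) %*% sys1$covariances_N[[1]] %*% d))
  expect_equal(f1$free_energy, sys1$kT * grid^2 / (2 * vd) -
                 min(sys1$kT * grid^2 / (2 * vd)), tolerance = 1e-6)

  # mirror symmetry along the inter-state axis
  f <- analytic_fes_linear(sys, sys$axis, grid)
  expect_equal(f$free_energy, rev(f$free_energy), tolerance = 1e-10)

  # Monte-Carlo histogram agrees with the closed form
  tr <- sample_iid(sys, 2e5, seed = 10)
  ctr <- (sys$means[[1]] + sys$means[[2]]) / 2
  s <- vapply(seq_len(2e5), function(i)
    sum(sys$axis * (matrix(tr$frames$coords[i, , ], ncol = 3) - ctr)),
    numeric(1))
  grid2 <- seq(-1.4, 1.4, length.out = 29)
  fh <- reweighted_fes(s, rep(1 / 2e5, 2e5), grid2, sys$kT)
  fa <- analytic_fes_linear(sys, sys$axis, grid2, center = ctr)
  mask <- fa$free_energy < 4 & !is.na(fh$free_energy)
  expect_lt(max(abs(fh$free_energy - fa$free_energy)[mask]), 0.15)
})

test_that("unbiased Langevin sampling obeys the stationary law", {
  # equilibrium variance along random directions in a single well
  sys1 <- make_two_state_system(separation = 1e-6, N = 5, seed = 11,
                                spread = 0.25)
  run <- run_biased_langevin(sys1, steps = 2e5, seed = 12, save_every = 5)
  set.seed(13)
  X <- matrix(run$trajectory$frames$coords, nrow = 4e4)
  keep <- 2001:40000  # drop equilibration
  for (r in 1:3) {
    d <- random_centered_frame(5); d <- d / sqrt(sum(d^2))
    proj <- X[keep, ] %*% as.numeric(d)
    v_true <- sum(diag(t(d) %*% sys1$covariances_N[[1]] %*% d))
    expect_lt(abs(var(proj) - v_true) / v_true, 0.05)
  }

  # detailed-balance check on a low-barrier system: histogram matches the
  # analytic marginal where F < 4 kcal/mol
  sysl <- make_two_state_system(separation = 1.2, N = 5, seed = 14)
  runl <- run_biased_langevin(sysl, steps = 4e5, seed = 15, save_every = 5)
  rc <- reference_coordinate(sysl)
  s <- evaluate_ld_ensemble(runl$trajectory$frames, rc)
  grid <- seq(-0.9, 0.9, length.out = 31)
  fh <- reweighted_fes(s[8001:length(s)], NULL, grid, sysl$kT)
  fa <- analytic_fes_linear(sysl, rc$v, grid,
                            center = (sysl$means[[1]] + sysl$means[[2]]) / 2)
  mask <- fa$free_energy < 4 & !is.na(fh$free_energy)
  expect_lt(max(abs(fh$free_energy - fa$free_energy)[mask]), 0.3)
})

test_that("trajectories are bit-reproducible and quenches descend", {
  sys <- toy_fixture(seed = 16)
  r1 <- run_biased_langevin(sys, steps = 2000, seed = 17, save_every = 10)
  r2 <- run_biased_langevin(sys, steps = 2000, seed = 17, save_every = 10)
  expect_identical(r1$trajectory$frames$coords, r2$trajectory$frames$coords)

  # zero-temperature quench from a perturbed start descends monotonically
  set.seed(18)
  x0 <- sys$means[[1]] + 0.6 * matrix(rnorm(sys$N * 3), sys$N, 3)
  rq <- run_biased_langevin(sys, steps = 300, seed = 19, save_every = 10,
                            x0 = x0, kT_noise = 0)
  u <- vapply(seq_len(30), function(i)
    toy_potential(sys, get_frame(rq$trajectory$frames, i)), numeric(1))
  expect_true(all(diff(u) < 1e-10))
})

test_that("biasing multiplies the transition rate", {
  sys <- toy_fixture(seed = 20)  # ~6 kT barrier
  rc <- reference_coordinate(sys)
  thr <- sys$separation / 4
  count_transits <- function(cv) {
    state <- 0L; n <- 0L
    for (s in cv) {
      if (s < -thr) { if (state == 2L) n <- n + 1L; state <- 1L }
      else if (s > thr) { if (state == 1L) n <- n + 1L; state <- 2L }
    }
    n
  }
  r_un <- run_biased_langevin(sys, steps = 1e5, seed = 21, save_every = 10)
  s_un <- evaluate_ld_ensemble(r_un$trajectory$frames, rc)
  r_b <- run_biased_langevin(sys, coordinate = rc, scheme = "wtmetad",
                             steps = 1e5, seed = 21, save_every = 10,
                             h0 = 0.7, gamma = 8, pace = 500)
  n_un <- count_transits(s_un)
  n_b <- count_transits(r_b$trajectory$cv_values)
  expect_gte(n_b, 10 * max(n_un, 1))
})

test_that("trajectories round-trip through multi-frame XYZ", {
  sys <- toy_fixture(seed = 22)
  tr <- sample_iid(sys, 5, seed = 23)
  tr$frames$elements <- c("C", "N", "O", "Ca", "Zn", "H")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr$frames, path)
  back <- read_xyz(path)
  expect_identical(back$elements, tr$frames$elements)
  expect_equal(back$coords, tr$frames$coords, tolerance = 1e-9)
})
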