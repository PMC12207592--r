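# shared fixtures and small independent oracles for the test suite

random_centered_frame <- function(N, scale = 1) {
  f <- matrix(rnorm(N * 3), N, 3) * scale
  sweep(f, 2, colMeans(f))
}

random_spd <- function(N, base = 1) {
  S <- crossprod(matrix(rnorm(N * N), N, N)) / N + base * diag(N)
  (S + t(S)) / 2
}

# direct multivariate Gaussian log-density on the flattened 3N coordinates,
# building the full Kronecker covariance explicitly (independent of the
# package's structured evaluation)
direct_log_density <- function(dev, covariance_N, delta = 1e-6) {
  Sfull <- kronecker(diag(3), regularize_covariance(covariance_N, delta))
  x <- as.numeric(dev)  # column-major: x.., y.., z..
  p <- length(x)
  -0.5 * drop(t(x) %*% solve(Sfull, x)) -
    0.5 * determinant(Sfull, logarithm = TRUE)$modulus -
    0.5 * p * log(2 * pi)
}

# numerical-quadrature Bhattacharyya distance for scalar Gaussians
quadrature_db_1d <- function(m1, v1, m2, v2) {
  f <- function(x) sqrt(dnorm(x, m1, sqrt(v1)) * dnorm(x, m2, sqrt(v2)))
  lo <- min(m1 - 12 * sqrt(v1), m2 - 12 * sqrt(v2))
  hi <- max(m1 + 12 * sqrt(v1), m2 + 12 * sqrt(v2))
  -log(integrate(f, lo, hi, rel.tol = 1e-12)$value)
}

# standard two-state fixture used across module tests
toy_fixture <- function(seed = 1, ...) {
  make_two_state_system(N = 6, seed = seed, ...)
}

# strongly separated variant: the rotation-aligned distance between the two
# mean shapes is large compared to the spread, so clusters are unambiguous
separated_fixture <- function(seed = 1) {
  make_two_state_system(separation = 4, spread = 0.15, N = 6, seed = seed)
}

# align one mean structure onto another (uniform metric) and report RMSD
aligned_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  R <- kabsch_rotation(a, b)$rotation
  sqrt(mean((a %*% R - b)^2) * 3)
}

expect_frames_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
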