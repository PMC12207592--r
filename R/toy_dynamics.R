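# Synthetic two-state particle systems and an overdamped Langevin engine.
#
# The toy potential is a Gaussian-mixture free energy,
#   U(x) = -kT log sum_j pi_j N(x | mu_j, Sigma_Nj (x) I3),
# evaluated with plain (unaligned) Gaussian densities, so the Boltzmann
# distribution at temperature kT is exactly the mixture: the i.i.d. sampler
# is exact and every linear marginal has a closed form.  The mirror-symmetric
# variant reflects the first state's mean through the z = 0 plane; for a
# generic (chiral) structure the two states are not superposable by proper
# rotations, like left- and right-handed helices, and have equal statistical
# weight by construction.

#' Build a synthetic two-state Gaussian-mixture system
#'
#' The first state's mean is a random centered structure whose extent along
#' z is scaled so that the two means are exactly `separation` apart (in
#' Frobenius norm); the second state is its mirror image through z = 0
#' (`mirror_symmetric = TRUE`) or a displaced copy.  Both states share the
#' particle covariance `spread^2 * Q D Q'` where `D` spans
#' `[1/anisotropy, anisotropy]` with geometric mean one.
#'
#' @param separation distance between the two state means, Angstrom.
#' @param spread typical per-particle fluctuation, Angstrom.
#' @param anisotropy ratio of largest to typical covariance eigenvalue
#'   (1 = isotropic).
#' @param N number of particles (>= 3).
#' @param kT thermal energy, kcal/mol.
#' @param mixture_weights length-2 probabilities (sum to one).
#' @param mirror_symmetric make state B the reflection of state A (equal
#'   covariances), guaranteeing an exactly symmetric free energy surface.
#' @param friction,dt Langevin friction coefficient and time step.
#' @param seed RNG seed fixing the structure draw.
#' @return object of class `toy_two_state`.
#' @export
make_two_state_system <- function(separation = 2.2, spread = 0.3,
                                  anisotropy = 1, N = 6, kT = 0.593,
                                  mixture_weights = c(0.5, 0.5),
                                  mirror_symmetric = TRUE,
                                  friction = 1, dt = 0.02, seed = 1) {
  if (N < 3) stop_shapecv("N must be at least 3", "shapecv_invalid_input")
  if (separation < 0 || spread <= 0)
    stop_shapecv("separation must be >= 0 and spread > 0",
                 "shapecv_invalid_input")
  if (abs(sum(mixture_weights) - 1) > 1e-12 || any(mixture_weights < 0))
    stop_shapecv("mixture_weights must be nonnegative and sum to one",
                 "shapecv_invalid_input")
  set.seed(seed)
  mu1 <- matrix(rnorm(N * 3), N, 3)
  mu1 <- center_frame(mu1)
  # scale so the structure has a healthy 3d extent relative to the spread
  mu1 <- mu1 * (2 / sqrt(mean(rowSums(mu1^2))))
  if (mirror_symmetric) {
    # mirror distance is twice the z-extent: rescale z to hit `separation`
    zn <- sqrt(sum(mu1[, 3]^2))
    mu1[, 3] <- mu1[, 3] * (separation / 2) / zn
    mu2 <- mu1 %*% diag(c(1, 1, -1))
  } else {
    dir <- matrix(rnorm(N * 3), N, 3)
    dir <- center_frame(dir)
    dir <- dir / sqrt(sum(dir^2))
    mu2 <- mu1 + separation * dir
  }
  if (anisotropy < 1)
    stop_shapecv("anisotropy must be >= 1", "shapecv_invalid_input")
  if (anisotropy == 1) {
    S <- spread^2 * diag(N)
  } else {
    Q <- qr.Q(qr(matrix(rnorm(N * N), N, N)))
    d <- exp(seq(-log(anisotropy), log(anisotropy), length.out = N) / 2)
    S <- spread^2 * Q %*% diag(d) %*% t(Q)
    S <- (S + t(S)) / 2
  }
  axis <- (mu2 - mu1)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(
    mixture_weights = mixture_weights, means = list(mu1, mu2),
    covariances_N = list(S, S), precisions = list(solve(S), solve(S)),
    logdets = rep(2 * sum(log(diag(chol(S)))), 2),
    kT = kT, friction = friction, dt = dt, N = N,
    separation = separation, spread = spread,
    mirror_symmetric = mirror_symmetric, axis = axis, seed = seed),
    class = "toy_two_state")
}

#' @export
print.toy_two_state <- function(x, ...) {
  cat(sprintf(
    "<toy_two_state: %d particles, separation %.3g A, spread %.3g A, barrier %.3g kT%s>\n",
    x$N, x$separation, x$spread, barrier_height(x) / x$kT,
    if (x$mirror_symmetric) ", mirror-symmetric" else ""))
  invisible(x)
}

#' Potential energy of the toy mixture
#'
#' Direct evaluation of `U(x) = -kT log sum_j pi_j N(x|mu_j, Sigma_j (x) I3)`.
#'
#' @param system a `toy_two_state`.
#' @param frame `N x 3` coordinates.
#' @export
toy_potential <- function(system, frame) {
  lp <- vapply(seq_along(system$means), function(j) {
    dev <- frame - system$means[[j]]
    log(system$mixture_weights[j]) -
      0.5 * mahalanobis_sq(dev, system$precisions[[j]]) -
      1.5 * system$logdets[j] - 1.5 * system$N * log(2 * pi)
  }, numeric(1))
  -system$kT * logsumexp(lp)
}

#' Barrier height along the inter-state line
#'
#' Maximum of `U` on the straight segment between the two means, relative to
#' the deeper end, in kcal/mol.
#'
#' @param system a `toy_two_state`.
#' @param n number of points along the segment.
#' @export
barrier_height <- function(system, n = 201) {
  tgrid <- seq(0, 1, length.out = n)
  u <- vapply(tgrid, function(t) {
    toy_potential(system, (1 - t) * system$means[[1]] + t * system$means[[2]])
  }, numeric(1))
  max(u) - min(u[c(1, n)])
}

#' Draw exact i.i.d. samples from the toy Boltzmann distribution
#'
#' Chooses a component for each frame, then draws each Cartesian column from
#' `N(mu_col, Sigma_N)`.  With `rigid_jitter = TRUE`, a random rotation and a
#' random translation are applied to every frame afterwards, scrambling the
#' rigid-body pose without changing the shape statistics.
#'
#' @param system a `toy_two_state`.
#' @param M number of frames.
#' @param seed RNG seed.
#' @param rigid_jitter apply random rigid transforms per frame.
#' @return a `trajectory` (frames, generator `labels`, no CV values).
#' @export
sample_iid <- function(system, M, seed = 1, rigid_jitter = FALSE) {
  set.seed(seed)
  N <- system$N
  Ls <- lapply(system$covariances_N, function(S) t(chol(S)))
  labels <- sample.int(2, M, replace = TRUE, prob = system$mixture_weights)
  coords <- array(0, dim = c(M, N, 3))
  for (i in seq_len(M)) {
    coords[i, , ] <- system$means[[labels[i]]] +
      Ls[[labels[i]]] %*% matrix(rnorm(N * 3), N, 3)
  }
  # jitter is applied after all shape draws, so the same seed yields the
  # same underlying configurations with and without pose scrambling
  if (rigid_jitter) {
    for (i in seq_len(M)) {
      R <- random_rotation()
      coords[i, , ] <- matrix(coords[i, , ], ncol = 3) %*% R +
        matrix(rnorm(3, sd = 2), N, 3, byrow = TRUE)
    }
  }
  trajectory(frame_ensemble(coords), labels = labels)
}

#' Trajectory container
#'
#' @param frames a `frame_ensemble`.
#' @param cv_values per-frame biased-CV value (or `NULL`).
#' @param bias per-frame bias energy, kcal/mol (or `NULL`).
#' @param labels optional generator-state labels.
#' @export
trajectory <- function(frames, cv_values = NULL, bias = NULL, labels = NULL) {
  M <- n_frames(frames)
  for (v in list(cv_values, bias, labels))
    if (!is.null(v) && length(v) != M)
      stop_shapecv("trajectory fields must have one entry per frame",
                   "shapecv_invalid_input")
  structure(list(frames = frames, cv_values = cv_values, bias = bias,
                 labels = labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames%s%s>\n", n_frames(x$frames),
              if (is.null(x$cv_values)) "" else ", with CV values",
              if (is.null(x$labels)) "" else ", with labels"))
  invisible(x)
}

#' Exact free energy along a linear coordinate
#'
#' For a linear CV `s = <D, x - center>` the marginal of the mixture is again
#' a Gaussian mixture, so
#' `F(s) = -kT log sum_j pi_j N(s | <D, mu_j - center>, tr(D' Sigma_j D))`
#' is exact.  Min-shifted on the grid.
#'
#' @param system a `toy_two_state`.
#' @param direction unit-norm `N x 3` matrix (or 3N vector).
#' @param grid bin centers.
#' @param center reference structure subtracted before projecting (defaults
#'   to the mixture mean).
#' @return a `fes_profile`.
#' @export
analytic_fes_linear <- function(system, direction, grid, center = NULL) {
  D <- if (is.matrix(direction)) direction else vec_to_frame(direction)
  if (abs(sqrt(sum(D^2)) - 1) > 1e-8)
    stop_shapecv("direction must have unit norm", "shapecv_invalid_input")
  if (is.null(center))
    center <- Reduce(`+`, Map(`*`, system$means, system$mixture_weights))
  dens <- rowSums(vapply(seq_along(system$means), function(j) {
    m <- sum(D * (system$means[[j]] - center))
    v <- sum(diag(crossprod(D, system$covariances_N[[j]] %*% D)))
    system$mixture_weights[j] * dnorm(grid, m, sqrt(v))
  }, numeric(length(grid))))
  f <- -system$kT * log(dens)
  fes_profile(grid, f - min(f), system$kT)
}

#' The system's fixed inter-state reference coordinate
#'
#' A linear (alignment-free) coordinate along the normalized difference of
#' the two state means, centered midway: the analog of a physically defined
#' helicity coordinate used to compare free energy surfaces across
#' iterations of the refinement loop.  The two states sit near
#' `-separation/2` and `+separation/2`.
#'
#' @param system a `toy_two_state`.
#' @return an `lda_coordinate` with `align = FALSE`.
#' @export
reference_coordinate <- function(system) {
  ctr <- center_frame((system$means[[1]] + system$means[[2]]) / 2)
  lda_coordinate(system$axis, ref_mean = ctr,
                 ref_covariance_N = system$covariances_N[[1]],
                 align = FALSE,
                 value_range = c(-1, 1) * system$separation / 2)
}

#' Run (biased) overdamped Langevin dynamics on the toy potential
#'
#' First-order update
#' `x <- x - (dt/friction) grad(U + V o l) + sqrt(2 kT dt / friction) eta`
#' with standard-normal `eta`, optional bias deposits every `pace` steps
#' along a linear-discriminant coordinate, and quadratic walls.  Bias forces
#' include the full analytic derivative of the coordinate (through the
#' optimal rotation when the coordinate is alignment-based).
#'
#' @param system a `toy_two_state`.
#' @param coordinate an `lda_coordinate` to bias along, or `NULL`.
#' @param scheme `"none"`, `"wtmetad"` or `"opes"`.
#' @param steps number of integration steps.
#' @param seed RNG seed (trajectories are bit-reproducible per seed).
#' @param x0 starting configuration (defaults to the first state mean).
#' @param save_every store every `save_every`-th frame.
#' @param h0 initial hill height (WT-MetaD), kcal/mol.
#' @param sigma hill / kernel width in CV units; defaults to 1/20 of the
#'   coordinate's trained range.
#' @param gamma bias factor.
#' @param pace steps between deposits.
#' @param deltaE OPES bias cap, kcal/mol.
#' @param walls optional `wall_spec`; by default quadratic walls with
#'   `kappa = 125` are placed `wall_offset` beyond the coordinate's trained
#'   range.
#' @param wall_offset distance beyond the trained range for default walls.
#' @param bound sanity bound on `|x|`, Angstrom.
#' @param kT_noise thermostat temperature for the noise term, kcal/mol
#'   (defaults to the system's `kT`; set to 0 for a gradient quench).
#' @param bias_init optional `wtmetad_state` / `opes_state` whose deposit
#'   history seeds the run, so sampling can be extended in chunks.
#' @return list with `trajectory` (frames, CV values, instantaneous bias),
#'   `bias_state` (an R-side `wtmetad_state` / `opes_state` rebuilt from the
#'   deposit log, or `NULL`), `walls`, and the deposit log `deposits`.
#' @export
run_biased_langevin <- function(system, coordinate = NULL,
                                scheme = c("none", "wtmetad", "opes"),
                                steps = 50000, seed = 1, x0 = NULL,
                                save_every = 10, h0 = 0.7, sigma = NULL,
                                gamma = 8, pace = 500, deltaE = 10,
                                walls = NULL, wall_offset = 10,
                                bound = 1e5, kT_noise = NULL,
                                bias_init = NULL) {
  scheme <- match.arg(scheme)
  use_cv <- !is.null(coordinate)
  if (scheme != "none" && !use_cv)
    stop_shapecv("biasing requires a coordinate", "shapecv_invalid_input")
  # stability: dt * max curvature / friction must stay well below 1
  max_curv <- system$kT * max(vapply(system$precisions,
                                     function(P) max(eigen(P, symmetric = TRUE,
                                                           only.values = TRUE)$values),
                                     numeric(1)))
  if (system$dt * max_curv / system$friction >= 0.5)
    stop_shapecv(sprintf(
      "dt too large for stability (dt * curvature / friction = %.3g >= 0.5)",
      system$dt * max_curv / system$friction), "shapecv_invalid_input")
  if (is.null(x0)) x0 <- system$means[[1]]
  cvv <- matrix(0, system$N, 3); cvmu <- cvv; cvP <- diag(system$N)
  cv_align <- FALSE
  if (use_cv) {
    cvv <- coordinate$v; cvmu <- coordinate$ref_mean
    cvP <- coordinate$precision_N; cv_align <- coordinate$align
    if (is.null(sigma)) {
      rng <- coordinate$value_range
      sigma <- if (is.null(rng)) 0.1 else diff(rng) / 20
    }
    if (is.null(walls) && scheme != "none") {
      rng <- coordinate$value_range %||%
        c(-system$separation / 2, system$separation / 2)
      walls <- wall_spec(rng[1] - wall_offset, rng[2] + wall_offset,
                         kappa = 125)
    }
  }
  if (is.null(sigma)) sigma <- 0.1
  scheme_code <- match(scheme, c("none", "wtmetad", "opes")) - 1L
  wl <- walls %||% list(lower = -Inf, upper = Inf, kappa = 0)

  init_centers <- numeric(0); init_heights <- numeric(0)
  if (!is.null(bias_init)) {
    init_centers <- bias_init$centers
    init_heights <- if (scheme == "wtmetad") bias_init$heights
    else bias_init$kweights
  }
  set.seed(seed)
  res <- run_langevin_cpp(
    x0, system$means, system$precisions, system$logdets,
    system$mixture_weights, system$kT, system$friction, system$dt,
    as.integer(steps), as.integer(save_every),
    use_cv, cvv, cvmu, cvP, cv_align, scheme_code,
    h0, sigma, gamma, as.integer(pace), deltaE,
    if (is.finite(wl$lower)) wl$lower else -1e30,
    if (is.finite(wl$upper)) wl$upper else 1e30,
    wl$kappa, bound, kT_noise %||% system$kT, init_centers, init_heights)

  nsave <- dim(res$frames)[3]
  coords <- aperm(res$frames, c(3, 1, 2))
  traj <- trajectory(frame_ensemble(coords),
                     cv_values = if (use_cv) as.numeric(res$cv) else NULL,
                     bias = if (use_cv) as.numeric(res$bias) else NULL)
  bias_state <- NULL
  if (scheme == "wtmetad") {
    bias_state <- wtmetad_state(h0 = h0, sigma = sigma, gamma = gamma,
                                kT = system$kT, pace = pace)
    bias_state$centers <- c(init_centers, res$deposits[, 2])
    bias_state$heights <- c(init_heights, res$deposits[, 3])
  } else if (scheme == "opes") {
    bias_state <- opes_state(sigma = sigma, gamma = gamma, deltaE = deltaE,
                             kT = system$kT, pace = pace)
    bias_state$centers <- c(init_centers, res$deposits[, 2])
    bias_state$kweights <- c(init_heights, res$deposits[, 3])
    bias_state$Z <- res$opes_Z
  }
  deposits <- as.data.frame(res$deposits)
  names(deposits) <- c("step", "center", "height", "width")
  list(trajectory = traj, bias_state = bias_state, walls = walls,
       deposits = deposits, final = res$final)
}

#' Count state round trips along a CV trace
#'
#' A transit is an excursion from below `lower` to above `upper` or back; a
#' round trip is two consecutive transits (A to B and back to A).
#'
#' @param cv numeric CV trace.
#' @param lower,upper thresholds bracketing the barrier region.
#' @return integer number of completed round trips.
#' @export
count_round_trips <- function(cv, lower, upper) {
  state <- 0L  # 0 unset, 1 below, 2 above
  transits <- 0L
  for (s in cv) {
    if (s < lower) {
      if (state == 2L) transits <- transits + 1L
      state <- 1L
    } else if (s > upper) {
      if (state == 1L) transits <- transits + 1L
      state <- 2L
    }
  }
  transits %/% 2L
}
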