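# Bias bookkeeping along a scalar CV: well-tempered metadynamics (WT-MetaD)
# hill lists, OPES kernel lists with a hard bias cap, quadratic walls,
# free-energy-surface (FES) estimation from the bias or by reweighting, and
# the mean-absolute-error convergence metric.
#
# Energies are in kcal/mol throughout; the CV is dimensionless (a linear
# projection of coordinates in Angstrom by a unit vector in 1/Angstrom).

#' Well-tempered metadynamics bias state
#'
#' A history-dependent sum of progressively shrinking Gaussian hills: each
#' deposit at CV value `s` adds a hill of height `h0 * exp(-V(s)/((gamma-1) kT))`
#' where `V` is the bias already present.  The bias factor
#' `gamma = (T + DeltaT)/T` controls how quickly hills shrink and how flat
#' the sampled distribution becomes.
#'
#' @param h0 initial hill height, kcal/mol.
#' @param sigma hill width in CV units.
#' @param gamma bias factor (> 1).
#' @param kT thermal energy, kcal/mol.
#' @param pace steps between deposits (bookkeeping only).
#' @export
wtmetad_state <- function(h0, sigma, gamma = 8, kT = 0.593, pace = 500) {
  if (gamma <= 1) stop_shapecv("gamma must exceed 1", "shapecv_invalid_input")
  if (h0 <= 0 || sigma <= 0)
    stop_shapecv("h0 and sigma must be positive", "shapecv_invalid_input")
  structure(list(centers = numeric(0), heights = numeric(0),
                 h0 = h0, sigma = sigma, gamma = gamma, kT = kT,
                 deltaT_energy = (gamma - 1) * kT, pace = pace),
            class = c("wtmetad_state", "bias_state"))
}

#' Deposit a WT-MetaD hill
#'
#' @param state a `wtmetad_state`.
#' @param s current CV value.
#' @return the updated state.
#' @export
wtmetad_update <- function(state, s) {
  stopifnot(inherits(state, "wtmetad_state"))
  if (!is.finite(s)) stop_shapecv("non-finite CV value", "shapecv_invalid_input")
  V <- hill_sum(state, s)$V
  h <- state$h0 * exp(-V / state$deltaT_energy)
  state$centers <- c(state$centers, s)
  state$heights <- c(state$heights, h)
  state
}

hill_sum <- function(state, s) {
  if (length(state$centers) == 0)
    return(list(V = numeric(length(s)), dV = numeric(length(s))))
  s2 <- state$sigma^2
  V <- numeric(length(s)); dV <- numeric(length(s))
  for (k in seq_along(state$centers)) {
    d <- s - state$centers[k]
    e <- state$heights[k] * exp(-0.5 * d^2 / s2)
    V <- V + e
    dV <- dV - e * d / s2
  }
  list(V = V, dV = dV)
}

#' OPES-MetaD bias state
#'
#' On-the-fly probability enhanced sampling: the bias is
#' `V(s) = kT (gamma-1)/gamma * log(P(s)/Z + eps)` where `P` is a kernel
#' density estimate of the unbiased CV distribution (kernels reweighted by
#' `exp(V/kT)` at deposit time), `Z` the mean of `P` over kernel centers, and
#' `eps = exp(-DeltaE / (kT (gamma-1)/gamma))` a regularizer guaranteeing the
#' bias never exceeds `DeltaE` in magnitude anywhere.
#'
#' @param sigma kernel bandwidth in CV units (fixed).
#' @param gamma bias factor.
#' @param deltaE bias cap, kcal/mol.
#' @param kT thermal energy, kcal/mol.
#' @param pace steps between deposits (bookkeeping only).
#' @export
opes_state <- function(sigma, gamma = 8, deltaE = 10, kT = 0.593, pace = 500) {
  if (gamma <= 1) stop_shapecv("gamma must exceed 1", "shapecv_invalid_input")
  a <- kT * (gamma - 1) / gamma
  structure(list(centers = numeric(0), kweights = numeric(0),
                 sigma = sigma, gamma = gamma, deltaE = deltaE, kT = kT,
                 prefactor = a, epsilon = exp(-deltaE / a), Z = 1,
                 pace = pace),
            class = c("opes_state", "bias_state"))
}

opes_prob <- function(state, s) {
  n <- length(state$centers)
  if (n == 0) return(list(P = numeric(length(s)), dP = numeric(length(s))))
  s2 <- state$sigma^2
  nrm <- 1 / (state$sigma * sqrt(2 * pi))
  P <- numeric(length(s)); dP <- numeric(length(s))
  for (k in seq_len(n)) {
    d <- s - state$centers[k]
    g <- state$kweights[k] * nrm * exp(-0.5 * d^2 / s2)
    P <- P + g
    dP <- dP - g * d / s2
  }
  sw <- sum(state$kweights)
  list(P = P / sw, dP = dP / sw)
}

opes_bias <- function(state, s) {
  if (length(state$centers) == 0)
    return(list(V = numeric(length(s)), dV = numeric(length(s))))
  pr <- opes_prob(state, s)
  arg <- pr$P / state$Z + state$epsilon
  list(V = state$prefactor * log(arg),
       dV = state$prefactor * (pr$dP / state$Z) / arg)
}

#' Deposit an OPES kernel
#'
#' Adds a kernel at the current CV value with weight `exp(V(s)/kT)` (undoing
#' the bias present at deposit time) and refreshes the normalization `Z` as
#' the mean of the probability estimate over all kernel centers.
#'
#' @param state an `opes_state`.
#' @param s current CV value.
#' @return the updated state.
#' @export
opes_update <- function(state, s) {
  stopifnot(inherits(state, "opes_state"))
  if (!is.finite(s)) stop_shapecv("non-finite CV value", "shapecv_invalid_input")
  w <- exp(opes_bias(state, s)$V / state$kT)
  state$centers <- c(state$centers, s)
  state$kweights <- c(state$kweights, w)
  state$Z <- mean(opes_prob(state, state$centers)$P)
  if (state$Z <= 0) state$Z <- 1
  state
}

#' Quadratic wall specification
#'
#' Harmonic restraints `kappa (s - bound)^2` applied beyond the lower and
#' upper CV bounds.
#'
#' @param lower,upper CV bounds (`lower < upper`).
#' @param kappa bias coefficient, kcal/mol per CV-unit squared.
#' @export
wall_spec <- function(lower, upper, kappa = 125) {
  if (lower >= upper) stop_shapecv("lower must be below upper",
                                   "shapecv_invalid_input")
  if (kappa < 0) stop_shapecv("kappa must be nonnegative",
                              "shapecv_invalid_input")
  structure(list(lower = lower, upper = upper, kappa = kappa),
            class = "wall_spec")
}

wall_sum <- function(walls, s) {
  V <- numeric(length(s)); dV <- numeric(length(s))
  if (is.null(walls) || walls$kappa == 0) return(list(V = V, dV = dV))
  hi <- s > walls$upper
  lo <- s < walls$lower
  V[hi] <- walls$kappa * (s[hi] - walls$upper)^2
  dV[hi] <- 2 * walls$kappa * (s[hi] - walls$upper)
  V[lo] <- walls$kappa * (s[lo] - walls$lower)^2
  dV[lo] <- 2 * walls$kappa * (s[lo] - walls$lower)
  list(V = V, dV = dV)
}

#' Total bias potential and derivative
#'
#' Sums the hill or kernel bias of a WT-MetaD / OPES state and any quadratic
#' wall penalties, returning both the energy and its analytic derivative with
#' respect to the CV.  Vectorized over `s`.
#'
#' @param state a `wtmetad_state` or `opes_state` (or `NULL` for walls only).
#' @param s CV values.
#' @param walls optional `wall_spec`.
#' @return list with numeric vectors `V` and `dV`.
#' @export
bias_potential <- function(state, s, walls = NULL) {
  core <- if (is.null(state)) list(V = numeric(length(s)),
                                   dV = numeric(length(s)))
  else if (inherits(state, "wtmetad_state")) hill_sum(state, s)
  else if (inherits(state, "opes_state")) opes_bias(state, s)
  else stop_shapecv("unknown bias state", "shapecv_invalid_input")
  wl <- wall_sum(walls, s)
  list(V = core$V + wl$V, dV = core$dV + wl$dV)
}

#' Free energy profile container
#'
#' A gridded one-dimensional free energy in kcal/mol with its minimum
#' shifted to zero; unvisited bins are `NA`.
#'
#' @param grid strictly increasing bin centers, CV units.
#' @param free_energy free energies, kcal/mol (may contain `NA`).
#' @param kT thermal energy used to build the profile.
#' @export
fes_profile <- function(grid, free_energy, kT) {
  if (any(diff(grid) <= 0))
    stop_shapecv("grid must be strictly increasing", "shapecv_invalid_input")
  if (length(grid) != length(free_energy))
    stop_shapecv("grid and free_energy lengths differ", "shapecv_invalid_input")
  fmin <- suppressWarnings(min(free_energy, na.rm = TRUE))
  if (!is.finite(fmin))
    stop_shapecv("free energy profile is empty", "shapecv_invalid_input")
  structure(list(grid = grid, free_energy = free_energy - fmin, kT = kT),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf("<fes_profile: %d bins on [%.3g, %.3g], max F = %.3g kcal/mol>\n",
              length(x$grid), min(x$grid), max(x$grid),
              suppressWarnings(max(x$free_energy, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.fes_profile <- function(x, ...) {
  data.frame(grid = x$grid, free_energy = x$free_energy)
}

#' Estimate the FES directly from the deposited bias
#'
#' Uses the asymptotic relation `F(s) = -gamma/(gamma-1) V(s)` of
#' well-tempered biasing (walls excluded), shifted so the minimum is zero.
#'
#' @param state a `wtmetad_state` or `opes_state`.
#' @param grid bin centers covering the sampled range.
#' @return a `fes_profile`.
#' @export
fes_from_bias <- function(state, grid) {
  V <- bias_potential(state, grid)$V
  f <- -state$gamma / (state$gamma - 1) * V
  fes_profile(grid, f - min(f), state$kT)
}

#' Frame weights that undo an applied bias
#'
#' `w_i` proportional to `exp(+V(s_i)/kT)` under the final bias, normalized
#' to sum one; the maximum is subtracted before exponentiation to avoid
#' overflow.
#'
#' @param state a bias state (or `NULL` for zero bias).
#' @param s_values CV values of the frames.
#' @param kT thermal energy, kcal/mol.
#' @param walls optional `wall_spec` included in the bias.
#' @return a `frame_weights` vector.
#' @export
weights_from_bias <- function(state, s_values, kT, walls = NULL) {
  if (any(!is.finite(s_values)))
    stop_shapecv("non-finite CV values", "shapecv_invalid_input")
  V <- bias_potential(state, s_values, walls)$V
  u <- V / kT
  w <- exp(u - max(u))
  frame_weights(w)
}

#' Reweighted free energy profile from samples
#'
#' Weighted histogram of a scalar observable turned into a free energy,
#' `F = -kT log(hist)`; empty bins are `NA` and the minimum is shifted to
#' zero.
#'
#' @param values scalar observable per frame (the biased CV or any reference
#'   coordinate).
#' @param weights normalized frame weights.
#' @param grid strictly increasing bin centers; bin edges are midpoints.
#' @param kT thermal energy, kcal/mol.
#' @return a `fes_profile`.
#' @export
reweighted_fes <- function(values, weights, grid, kT) {
  w <- resolve_weights(weights, length(values))
  edges <- c(grid[1] - diff(grid[1:2]) / 2,
             grid[-length(grid)] + diff(grid) / 2,
             grid[length(grid)] + diff(grid)[length(grid) - 1] / 2)
  h <- numeric(length(grid))
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= length(grid)
  for (i in which(ok)) h[bin[i]] <- h[bin[i]] + w[i]
  if (all(h == 0))
    stop_shapecv("no samples fall inside the grid", "shapecv_invalid_input")
  f <- ifelse(h > 0, -kT * log(h), NA_real_)
  fes_profile(grid, f, kT)
}

#' Mean absolute error between two free energy profiles
#'
#' Averages `|F_a - F_b|` over bins where the reference profile `b` lies
#' below `cutoff` and both profiles are defined.  Both profiles must share
#' the same grid and are min-shifted by construction.
#'
#' @param a,b `fes_profile` objects on the same grid; `b` is the reference.
#' @param cutoff reference free-energy cutoff, kcal/mol (bins with
#'   `F_b >= cutoff` are excluded).
#' @return scalar MAE in kcal/mol.
#' @export
fes_mae <- function(a, b, cutoff = 7.5) {
  stopifnot(inherits(a, "fes_profile"), inherits(b, "fes_profile"))
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-9)
    stop_shapecv("profiles must share the same grid", "shapecv_invalid_input")
  mask <- !is.na(a$free_energy) & !is.na(b$free_energy) &
    b$free_energy < cutoff
  if (!any(mask))
    stop_shapecv("no qualifying bins below the cutoff", "shapecv_invalid_input")
  mean(abs(a$free_energy[mask] - b$free_energy[mask]))
}
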