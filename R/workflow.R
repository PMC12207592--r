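# Orchestration of the iterative CV-refinement loop:
#  1. short unbiased runs in each state  2. initial LDA coordinate
#  3. biased sampling along the coordinate  4. FES convergence check
#  5. frame-weighted re-clustering of the biased data + state matching
#  6. frame-weighted LDA between the matched clusters -> new coordinate
# repeated until the FES along a fixed reference coordinate converges.

#' Protocol configuration for the refinement loop
#'
#' @param K number of mixture components refit at each iteration.
#' @param seeds EM initialization seeds per fit.
#' @param scheme `"wtmetad"` or `"opes"`.
#' @param gamma bias factor.
#' @param h0 initial hill height (WT-MetaD), kcal/mol.
#' @param sigma hill/kernel width in CV units (`NULL`: 1/20 of the
#'   coordinate's trained range).
#' @param pace steps between bias deposits.
#' @param deltaE OPES bias cap, kcal/mol.
#' @param wall_offset distance beyond the coordinate's trained range at which
#'   quadratic walls are placed.
#' @param wall_kappa wall bias coefficient, kcal/mol per CV-unit squared.
#' @param steps Langevin steps per iteration.
#' @param init_steps unbiased steps per state for the initial data.
#' @param save_every frame-saving stride.
#' @param grid_n number of FES bins along the reference coordinate.
#' @param tol_mae convergence tolerance on the FES mean absolute error,
#'   kcal/mol.
#' @param max_iterations cap on refinement iterations.
#' @param equal_state_weights renormalize each matched state's weights to a
#'   combined total of one half before the weighted LDA.
#' @param subsample_cap maximum number of biased frames fed to re-clustering
#'   (evenly strided, weights renormalized).
#' @param discard_frac fraction of each biased trajectory discarded as
#'   bias-fill equilibration before reweighting, clustering and FES
#'   estimation.
#' @param max_chunks maximum number of `steps`-long sampling chunks per
#'   iteration; sampling is extended chunk by chunk until at least two
#'   round trips between the states are observed.
#' @export
protocol_config <- function(K = 2, seeds = 1:3, scheme = c("wtmetad", "opes"),
                            gamma = 8, h0 = 0.7, sigma = NULL, pace = 500,
                            deltaE = 10, wall_offset = 10, wall_kappa = 125,
                            steps = 60000, init_steps = 4000, save_every = 10,
                            grid_n = 61, tol_mae = 0.5, max_iterations = 5,
                            equal_state_weights = FALSE,
                            subsample_cap = 4000, discard_frac = 0.25,
                            max_chunks = 4) {
  scheme <- match.arg(scheme)
  if (tol_mae <= 0) stop_shapecv("tol_mae must be positive",
                                 "shapecv_invalid_input")
  if (max_iterations < 1) stop_shapecv("max_iterations must be >= 1",
                                       "shapecv_invalid_input")
  structure(list(K = K, seeds = seeds, scheme = scheme, gamma = gamma,
                 h0 = h0, sigma = sigma, pace = pace, deltaE = deltaE,
                 wall_offset = wall_offset, wall_kappa = wall_kappa,
                 steps = steps, init_steps = init_steps,
                 save_every = save_every, grid_n = grid_n, tol_mae = tol_mae,
                 max_iterations = max_iterations,
                 equal_state_weights = equal_state_weights,
                 subsample_cap = subsample_cap, discard_frac = discard_frac,
                 max_chunks = max_chunks),
            class = "protocol_config")
}

# weighted LDA between two labeled sets of frames: joint frame-weighted
# Kronecker alignment, scatter matrices, solver, coordinate assembly.
# sign convention: class A (label 1) projects negative.
wlda_between <- function(frames, labels, weights = NULL,
                         equal_state_weights = FALSE, delta = 1e-6) {
  M <- n_frames(frames)
  w <- resolve_weights(weights, M)
  labels <- as.integer(labels)
  if (equal_state_weights) {
    for (k in 1:2) {
      idx <- labels == k
      w[idx] <- 0.5 * w[idx] / sum(w[idx])
    }
  }
  al <- align_ensemble(frames, covariance_N = "kronecker", weights = w,
                       delta = delta)
  sc <- weighted_scatter_matrices(al$aligned, labels, w)
  if (max(abs(sc$class_means[1, ] - sc$class_means[2, ])) < 1e-8)
    stop_shapecv("states are indistinguishable after alignment (identical orbits)",
                 "shapecv_no_discriminant")
  v <- wlda_solve(sc, n_components = 1)
  # pooled weighted within-class Kronecker covariance as alignment reference
  covN <- matrix(0, n_particles(frames), n_particles(frames))
  for (k in 1:2) {
    idx <- labels == k
    muk <- vec_to_frame(sc$class_means[k, ])
    covN <- covN + sc$class_weights[k] *
      weighted_cov_N(al$aligned$coords[idx, , , drop = FALSE], muk, w[idx])
  }
  coord <- lda_coordinate(v, ref_mean = center_frame(vec_to_frame(sc$global_mean)),
                          ref_covariance_N = covN, align = TRUE, delta = delta)
  proj <- evaluate_ld_ensemble(frames, coord)
  # orient so state A sits on the negative side
  if (sum(w[labels == 1] * proj[labels == 1]) / sum(w[labels == 1]) > 0) {
    coord$v <- -coord$v
    proj <- -proj
  }
  coord$value_range <- range(proj)
  coord
}

#' Initial LDA coordinate from two labeled state ensembles
#'
#' Uniform-weight weighted LDA between the two ensembles after joint
#' self-consistent Kronecker alignment.  The coordinate is oriented so state
#' A projects negative.
#'
#' @param state_A_frames,state_B_frames `frame_ensemble`s sampled in each
#'   state.
#' @param delta covariance ridge.
#' @return an `lda_coordinate`.
#' @export
initial_coordinate <- function(state_A_frames, state_B_frames, delta = 1e-6) {
  if (n_frames(state_A_frames) == 0 || n_frames(state_B_frames) == 0)
    stop_shapecv("both state ensembles must be non-empty",
                 "shapecv_invalid_input")
  coords <- array(0, dim = c(n_frames(state_A_frames) + n_frames(state_B_frames),
                             n_particles(state_A_frames), 3))
  coords[seq_len(n_frames(state_A_frames)), , ] <- state_A_frames$coords
  coords[n_frames(state_A_frames) + seq_len(n_frames(state_B_frames)), , ] <-
    state_B_frames$coords
  frames <- frame_ensemble(coords)
  labels <- rep(1:2, c(n_frames(state_A_frames), n_frames(state_B_frames)))
  wlda_between(frames, labels, delta = delta)
}

# stack the coordinate arrays of several trajectories
rbind_frames <- function(...) {
  trs <- list(...)
  Ms <- vapply(trs, function(t) n_frames(t$frames), integer(1))
  N <- n_particles(trs[[1]]$frames)
  out <- array(0, dim = c(sum(Ms), N, 3))
  off <- 0L
  for (t in trs) {
    m <- n_frames(t$frames)
    out[off + seq_len(m), , ] <- t$frames$coords
    off <- off + m
  }
  out
}

# Gaussian reference states from labeled frames (aligned class statistics)
reference_states <- function(frames, labels, weights = NULL, delta = 1e-6) {
  w <- resolve_weights(weights, n_frames(frames))
  refs <- vector("list", 2)
  for (k in 1:2) {
    idx <- which(labels == k)
    sub <- subset_frames(frames, idx)
    al <- align_ensemble(sub, covariance_N = "kronecker",
                         weights = w[idx], delta = delta)
    refs[[k]] <- gaussian_state(al$mean, al$covariance_N,
                                label = c("A", "B")[k])
  }
  refs
}

#' One record of the refinement loop
#'
#' Internal constructor collecting the artifacts of one iteration.
#'
#' @keywords internal
iteration_record <- function(index, coordinate, model = NULL, match = NULL,
                             fes = NULL, mae_vs_previous = NA_real_,
                             transit_count = NA_integer_, trajectory = NULL,
                             weights = NULL) {
  structure(list(index = index, coordinate = coordinate, model = model,
                 match = match, fes = fes, mae_vs_previous = mae_vs_previous,
                 transit_count = transit_count, trajectory = trajectory,
                 weights = weights),
            class = "iteration_record")
}

#' @export
print.iteration_record <- function(x, ...) {
  cat(sprintf("<iteration_record %d: %s%s%s>\n", x$index,
              if (is.null(x$model)) "initial coordinate"
              else sprintf("K = %d refit", x$model$K),
              if (is.na(x$mae_vs_previous)) ""
              else sprintf(", MAE vs prev = %.3g kcal/mol", x$mae_vs_previous),
              if (is.na(x$transit_count)) ""
              else sprintf(", %d round trips", x$transit_count)))
  invisible(x)
}

#' Run one iteration of the refinement loop
#'
#' Biases the toy system along the previous coordinate, reweights the biased
#' frames with the final bias, refits a frame-weighted shape GMM, matches the
#' new components to the reference states by Bhattacharyya distance, fits a
#' weighted LDA between the two matched clusters, and estimates the FES along
#' the fixed reference coordinate together with its MAE against the previous
#' iteration.
#'
#' @param prev the previous `iteration_record` (must carry a coordinate).
#' @param system a `toy_two_state`.
#' @param refs list of two `gaussian_state` reference states.
#' @param config a `protocol_config`.
#' @param seed seed for this iteration's sampling.
#' @return an `iteration_record`.
#' @export
run_iteration <- function(prev, system, refs, config, seed = 1) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_shapecv(sprintf("iteration stage '%s' failed: %s", what,
                           conditionMessage(e)), "shapecv_stage_error")
    })
  }
  # biased sampling, extended in chunks until the trajectory has completed
  # at least two round trips between the states (or the chunk cap is hit):
  # re-clustering on data that never left the starting basin would only
  # degrade the coordinate
  ref_coord <- reference_coordinate(system)
  thr <- 0.25 * system$separation
  chunks <- list()
  run <- NULL
  for (chunk in seq_len(config$max_chunks)) {
    run <- stage("biased sampling", run_biased_langevin(
      system, coordinate = prev$coordinate, scheme = config$scheme,
      steps = config$steps, seed = seed + 7919L * (chunk - 1L),
      x0 = if (is.null(run)) NULL else run$final,
      bias_init = if (is.null(run)) NULL else run$bias_state,
      save_every = config$save_every,
      h0 = config$h0, sigma = config$sigma, gamma = config$gamma,
      pace = config$pace, deltaE = config$deltaE,
      wall_offset = config$wall_offset))
    chunks[[chunk]] <- run$trajectory
    s_all <- evaluate_ld_ensemble(
      frame_ensemble(do.call(rbind_frames, chunks)), ref_coord)
    if (count_round_trips(s_all, -thr, thr) >= 2) break
  }
  co_all <- do.call(rbind_frames, chunks)
  traj <- trajectory(frame_ensemble(co_all),
                     cv_values = unlist(lapply(chunks, `[[`, "cv_values")),
                     bias = unlist(lapply(chunks, `[[`, "bias")))
  # drop the bias-fill transient: frames laid down before the bias was in
  # place are not equilibrated under the final bias
  M_all <- n_frames(traj$frames)
  keep <- seq(floor(config$discard_frac * M_all) + 1L, M_all)
  traj <- trajectory(subset_frames(traj$frames, keep),
                     cv_values = traj$cv_values[keep],
                     bias = traj$bias[keep])
  w <- stage("reweighting", weights_from_bias(
    run$bias_state, traj$cv_values, system$kT, walls = run$walls))

  # subsample for re-clustering (evenly strided; weights renormalized)
  M <- n_frames(traj$frames)
  idx <- if (M > config$subsample_cap)
    round(seq(1, M, length.out = config$subsample_cap)) else seq_len(M)
  frames_fit <- subset_frames(traj$frames, idx)
  w_fit <- frame_weights(w[idx])

  model <- stage("weighted clustering", weighted_em_fit(
    frames_fit, w_fit, K = config$K, seeds = config$seeds))
  match <- stage("state matching", match_states(model, refs[[1]], refs[[2]]))

  assign <- predict_assignments(model, frames_fit)
  sel <- assign$labels %in% c(match$index_A, match$index_B)
  if (!any(assign$labels == match$index_A) ||
      !any(assign$labels == match$index_B))
    stop_shapecv("a matched cluster has no assigned frames",
                 "shapecv_stage_error")
  lab2 <- ifelse(assign$labels[sel] == match$index_A, 1L, 2L)
  coord <- stage("weighted LDA", wlda_between(
    subset_frames(frames_fit, sel), lab2, weights = w_fit[sel],
    equal_state_weights = config$equal_state_weights))

  # FES along the fixed reference coordinate, final-bias reweighting
  s_ref <- evaluate_ld_ensemble(traj$frames, ref_coord)
  grid <- seq(-0.75 * system$separation, 0.75 * system$separation,
              length.out = config$grid_n)
  fes <- stage("FES estimation", reweighted_fes(s_ref, w, grid, system$kT))
  mae <- if (!is.null(prev$fes)) fes_mae(fes, prev$fes) else NA_real_
  transits <- count_round_trips(s_ref, -thr, thr)

  iteration_record(index = prev$index + 1L, coordinate = coord,
                   model = model, match = match, fes = fes,
                   mae_vs_previous = mae, transit_count = transits,
                   trajectory = traj, weights = w)
}

#' Check convergence of the refinement loop
#'
#' `TRUE` when the mean absolute error between the two most recent FES
#' estimates (reference cutoff rule of [fes_mae()]) falls below `tol`.
#'
#' @param history list of `iteration_record`s (at least two with FES
#'   profiles).
#' @param tol MAE tolerance, kcal/mol.
#' @param cutoff reference free-energy cutoff passed to [fes_mae()].
#' @export
check_convergence <- function(history, tol, cutoff = 7.5) {
  with_fes <- Filter(function(r) !is.null(r$fes), history)
  if (length(with_fes) < 2) return(FALSE)
  n <- length(with_fes)
  fes_mae(with_fes[[n]]$fes, with_fes[[n - 1]]$fes, cutoff = cutoff) < tol
}

#' Run the full iterative refinement loop on a toy system
#'
#' Generates initial unbiased data in each state, builds the initial
#' coordinate and reference states, then repeats biased sampling, weighted
#' re-clustering, state matching and weighted re-LDA until the FES along the
#' fixed reference coordinate converges or `max_iterations` is reached.
#' Per-iteration seeds are derived deterministically from `seed`, so a run
#' checkpointed into `run_dir` and resumed reproduces the uninterrupted
#' result exactly.
#'
#' @param system a `toy_two_state`.
#' @param config a `protocol_config`.
#' @param seed base seed.
#' @param run_dir optional directory for checkpoints and logs.
#' @param resume reuse existing checkpoints in `run_dir`.
#' @return list with `history` (iteration records), `converged`, the final
#'   `coordinate`, the `refs`, and the `config`.
#' @export
iterate_cv <- function(system, config = protocol_config(), seed = 1,
                       run_dir = NULL, resume = FALSE) {
  if (!is.null(run_dir) && !dir.exists(run_dir))
    dir.create(run_dir, recursive = TRUE)
  ckpt <- function(i) file.path(run_dir, sprintf("iteration_%02d.rds", i))

  # step 1: short unbiased runs from each state
  seed_init <- seed * 1000L
  runA <- run_biased_langevin(system, steps = config$init_steps,
                              seed = seed_init + 1L,
                              x0 = system$means[[1]],
                              save_every = config$save_every)
  runB <- run_biased_langevin(system, steps = config$init_steps,
                              seed = seed_init + 2L,
                              x0 = system$means[[2]],
                              save_every = config$save_every)
  framesA <- runA$trajectory$frames
  framesB <- runB$trajectory$frames

  coord0 <- initial_coordinate(framesA, framesB)
  coords_all <- array(0, dim = c(n_frames(framesA) + n_frames(framesB),
                                 system$N, 3))
  coords_all[seq_len(n_frames(framesA)), , ] <- framesA$coords
  coords_all[n_frames(framesA) + seq_len(n_frames(framesB)), , ] <-
    framesB$coords
  labels0 <- rep(1:2, c(n_frames(framesA), n_frames(framesB)))
  refs <- reference_states(frame_ensemble(coords_all), labels0)

  history <- list(iteration_record(index = 0L, coordinate = coord0))
  converged <- FALSE
  for (i in seq_len(config$max_iterations)) {
    rec <- NULL
    if (resume && !is.null(run_dir) && file.exists(ckpt(i)))
      rec <- readRDS(ckpt(i))
    if (is.null(rec)) {
      rec <- run_iteration(history[[length(history)]], system, refs, config,
                           seed = seed_init + 10L + i)
      if (!is.null(run_dir)) saveRDS(rec, ckpt(i))
    }
    history[[length(history) + 1]] <- rec
    if (check_convergence(history, config$tol_mae)) {
      converged <- TRUE
      break
    }
  }
  list(history = history, converged = converged,
       coordinate = history[[length(history)]]$coordinate,
       refs = refs, config = config)
}

#' Export a coordinate for external biased-sampling engines
#'
#' Writes the coefficient vector (one `particle_index cx cy cz` row per
#' particle), the reference mean structure as PDB, the alignment covariance
#' factor as delimited text, and a manifest recording the normalization,
#' sign convention and trained range.
#'
#' @param coordinate an `lda_coordinate`.
#' @param model optional `shape_gmm` whose metadata is noted in the manifest.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_coefficients <- function(coordinate, model = NULL, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    coefficients = file.path(out_dir, "coefficients.txt"),
    ref_mean = file.path(out_dir, "ref_mean.pdb"),
    covariance = file.path(out_dir, "sigma_N.txt"),
    manifest = file.path(out_dir, "manifest.yaml"))
  cf <- data.frame(particle_index = seq_len(nrow(coordinate$v)),
                   cx = coordinate$v[, 1], cy = coordinate$v[, 2],
                   cz = coordinate$v[, 3])
  write.table(format(cf, digits = 17), paths$coefficients, sep = " ",
              row.names = FALSE, quote = FALSE)
  write_pdb_frame(coordinate$ref_mean, paths$ref_mean)
  write.table(format(coordinate$ref_covariance_N, digits = 17),
              paths$covariance, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    norm = sqrt(sum(coordinate$v^2)),
    sign_convention = "state A projects negative",
    align = coordinate$align,
    value_range = as.numeric(coordinate$value_range),
    delta = coordinate$delta,
    # full-precision copies (the PDB is truncated to 3 decimals for
    # external engines; re-import must reproduce the coordinate exactly)
    ref_mean = as.numeric(coordinate$ref_mean),
    ref_covariance_N = as.numeric(coordinate$ref_covariance_N),
    model = if (is.null(model)) NULL else
      list(K = model$K, train_log_likelihood = model$train_log_likelihood)),
    paths$manifest, precision = 17)
  invisible(paths)
}

#' Re-import an exported coordinate
#'
#' Inverse of [export_coefficients()]; coefficients round-trip bit-exactly.
#'
#' @param out_dir directory written by [export_coefficients()].
#' @return an `lda_coordinate`.
#' @export
read_coefficients <- function(out_dir) {
  cf <- read.table(file.path(out_dir, "coefficients.txt"), header = TRUE)
  v <- as.matrix(cf[, c("cx", "cy", "cz")])
  dimnames(v) <- NULL
  man <- yaml::read_yaml(file.path(out_dir, "manifest.yaml"))
  N <- nrow(v)
  ref <- if (!is.null(man$ref_mean)) matrix(as.numeric(man$ref_mean), N, 3)
  else read_pdb_frame(file.path(out_dir, "ref_mean.pdb"))
  covN <- if (!is.null(man$ref_covariance_N))
    matrix(as.numeric(man$ref_covariance_N), N, N)
  else {
    cm <- as.matrix(read.table(file.path(out_dir, "sigma_N.txt"), sep = "\t"))
    dimnames(cm) <- NULL
    cm
  }
  lda_coordinate(v, ref_mean = ref, ref_covariance_N = covN,
                 align = man$align,
                 value_range = if (is.null(man$value_range)) NULL
                 else as.numeric(man$value_range),
                 delta = man$delta)
}
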