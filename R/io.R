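# Plain-text readers and writers: multi-frame XYZ trajectories, minimal PDB
# for single reference structures, frame-weight files, shape-GMM archives
# (YAML), hill/kernel deposit logs and FES profiles as delimited text.

#' Read a multi-frame XYZ file
#'
#' Standard XYZ layout: particle count, comment line, then one
#' `element x y z` row per particle, repeated per frame.  The element column
#' is preserved verbatim.
#'
#' @param path file path.
#' @return a `frame_ensemble`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  frames <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop_shapecv(sprintf("bad particle count at line %d", pos),
                               "shapecv_invalid_input")
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    elements <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  coords <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  frame_ensemble(coords, elements = elements)
}

#' Write a multi-frame XYZ file
#'
#' @param frames a `frame_ensemble`.
#' @param path output path.
#' @param elements element symbols (defaults to those stored on the
#'   ensemble, else `"C"`).
#' @param comment per-frame comment (recycled).
#' @export
write_xyz <- function(frames, path, elements = NULL, comment = "frame") {
  stopifnot(inherits(frames, "frame_ensemble"))
  N <- n_particles(frames)
  elements <- elements %||% frames$elements %||% rep("C", N)
  comment <- rep_len(comment, n_frames(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(frames))) {
    f <- get_frame(frames, i)
    writeLines(c(as.character(N), comment[i],
                 sprintf("%s %.10f %.10f %.10f", elements, f[, 1], f[, 2],
                         f[, 3])), con)
  }
  invisible(path)
}

# minimal single-frame PDB writer/reader for reference structures of
# synthetic particle systems (ATOM records, coordinates in Angstrom)
write_pdb_frame <- function(frame, path, elements = NULL) {
  N <- nrow(frame)
  elements <- elements %||% rep("C", N)
  lines <- sprintf(
    "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(N), substr(paste0(elements, seq_len(N)), 1, 4), "TOY",
    seq_len(N), frame[, 1], frame[, 2], frame[, 3], 1, 0,
    substr(elements, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a single reference structure from PDB
#'
#' Uses \pkg{bio3d} when available; otherwise parses ATOM/HETATM records
#' directly (fixed-column coordinates).
#'
#' @param path PDB file.
#' @return `N x 3` coordinate matrix.
#' @export
read_pdb_frame <- function(path) {
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
    return(xyz)
  }
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  t(vapply(lines, function(l) {
    c(as.numeric(substr(l, 31, 38)), as.numeric(substr(l, 39, 46)),
      as.numeric(substr(l, 47, 54)))
  }, numeric(3), USE.NAMES = FALSE))
}

#' Read / write per-frame weight files
#'
#' One weight per line; values are normalized to sum one on read.
#'
#' @param path file path.
#' @return a `frame_weights` vector.
#' @export
read_weights <- function(path) {
  frame_weights(scan(path, quiet = TRUE))
}

#' @rdname read_weights
#' @param w weights to write.
#' @export
write_weights <- function(w, path) {
  writeLines(format(as.numeric(w), digits = 17), path)
  invisible(path)
}

#' Serialize a shape GMM to a single archive file
#'
#' YAML layout with `K`, `phi`, per-component `means` and `covariances_N`
#' (row-major lists), the ridge `delta` and the training log-likelihood.
#'
#' @param model a `shape_gmm`.
#' @param path output file.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "shape_gmm"))
  yaml::write_yaml(list(
    K = model$K,
    phi = as.numeric(model$phi),
    N = nrow(model$means[[1]]),
    delta = model$delta,
    train_log_likelihood = model$train_log_likelihood,
    means = lapply(model$means, function(m) as.numeric(t(m))),
    covariances_N = lapply(model$covariances_N, as.numeric)), path,
    precision = 17)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  d <- yaml::read_yaml(path)
  N <- d$N
  means <- lapply(d$means, function(m) matrix(as.numeric(m), N, 3, byrow = TRUE))
  covs <- lapply(d$covariances_N, function(S) matrix(as.numeric(S), N, N))
  new_shape_gmm(d$K, as.numeric(d$phi), means, covs, d$delta,
                train_log_likelihood = d$train_log_likelihood)
}

#' Write / read a bias deposit log
#'
#' Append-only delimited text with one row per deposit: step, CV center,
#' height (hill height for WT-MetaD, kernel weight for OPES) and width.
#'
#' @param deposits data frame with columns `step`, `center`, `height`,
#'   `width`.
#' @param path output file.
#' @export
write_hills <- function(deposits, path) {
  write.table(format(deposits, digits = 17), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  read.table(path, header = TRUE)
}

#' Write / read a FES profile as two-column text
#'
#' @param fes a `fes_profile`.
#' @param path output file.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_profile"))
  write.table(format(as.data.frame(fes), digits = 17), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @param kT thermal energy recorded on the re-read profile.
#' @export
read_fes <- function(path, kT = 0.593) {
  df <- read.table(path, header = TRUE)
  fes_profile(df$grid, df$free_energy, kT)
}
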