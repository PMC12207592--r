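# ggplot2 display methods for the main result types.

#' @method autoplot fes_profile
#' @export
autoplot.fes_profile <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df[!is.na(df$free_energy), ],
                  ggplot2::aes(x = .data$grid, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "collective variable", y = "free energy (kcal/mol)")
}

#' @method autoplot cluster_scan
#' @export
autoplot.cluster_scan <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[is.na(df$error) | df$error == "", ]
  long <- rbind(
    data.frame(K = df$K, seed = df$seed, ll = df$train_ll, split = "train"),
    data.frame(K = df$K, seed = df$seed, ll = df$cv_ll, split = "held-out"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$ll,
                                     colour = .data$split,
                                     group = interaction(.data$split,
                                                         .data$seed))) +
    ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters K",
                  y = "weighted log-likelihood per frame")
}

#' Plot a CV time trace
#'
#' @param traj a `trajectory` with CV values.
#' @param thresholds optional pair of horizontal guide lines marking the two
#'   states.
#' @export
plot_cv_trace <- function(traj, thresholds = NULL) {
  stopifnot(inherits(traj, "trajectory"), !is.null(traj$cv_values))
  df <- data.frame(frame = seq_along(traj$cv_values), cv = traj$cv_values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$cv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "saved frame", y = "biased CV")
  if (!is.null(thresholds))
    p <- p + ggplot2::geom_hline(yintercept = thresholds, linetype = 2)
  p
}

#' @importFrom ggplot2 .data
NULL
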