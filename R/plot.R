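#' Plot a source grid with estimated and true silent regions
#'
#' Flat projection of the source grid (posterior view: x versus z) with the
#' estimated and, if given, true silent regions highlighted.
#'
#' @param grid A `source_grid`.
#' @param est Estimated silent indices.
#' @param truth Optional true silent indices.
#' @return A ggplot object.
#' @export
plot_silence <- function(grid, est, truth = NULL) {
  df <- data.frame(x = grid$positions[, 1], z = grid$positions[, 3],
                   status = "active")
  if (!is.null(truth)) df$status[truth] <- "truth"
  df$status[est] <- ifelse(!is.null(truth) & df$status[est] == "truth",
                           "both", "estimate")
  df$status[intersect(est, truth)] <- "both"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   color = .data$status)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_color_manual(values = c(
      active = "grey75", estimate = "#d7301f", truth = "#2b8cbe",
      both = "#54278f")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, + right)", y = "z (mm)",
                  color = NULL,
                  title = "Localized region of silence") +
    ggplot2::theme_minimal()
}

#' Plot per-source contribution values on the grid
#'
#' @param grid A `source_grid`.
#' @param beta A `contribution_vector` or numeric vector.
#' @return A ggplot object.
#' @export
plot_contribution <- function(grid, beta) {
  b <- contribution_values(beta)
  df <- data.frame(x = grid$positions[, 1], z = grid$positions[, 3],
                   beta = b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   color = .data$beta)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_color_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, + right)", y = "z (mm)",
                  color = "contribution") +
    ggplot2::theme_minimal()
}

#' Plot the fitted result of the localization pipeline
#'
#' Shows the fine grid with the estimated region and, when available, the
#' center-of-mass trajectory across iterations.
#'
#' @param object A `silencemap_result`.
#' @param grid The fine `source_grid` the result refers to.
#' @param truth Optional true silent indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silencemap_result <- function(object, grid, truth = NULL, ...) {
  pl <- plot_silence(grid, object$silent_set, truth)
  traj <- as.data.frame(object$com_trajectory)
  names(traj) <- c("x", "y", "z")
  pl + ggplot2::geom_path(data = traj,
                          ggplot2::aes(x = .data$x, y = .data$z),
                          inherit.aes = FALSE, linewidth = 0.4,
                          color = "black") +
    ggplot2::geom_point(data = traj,
                        ggplot2::aes(x = .data$x, y = .data$z),
                        inherit.aes = FALSE, shape = 4, size = 2)
}
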