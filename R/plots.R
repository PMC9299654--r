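#' Plot a deterministic trajectory
#'
#' One panel per trait: population mean against generation. In the stable
#' regime all three traits plateau; in the runaway regime aggression
#' plateaus at `bA / cA` while signal and body size accelerate together.
#'
#' @param object A `contest_trajectory` from [simulate_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' traj <- simulate_trajectory(population_state(0, 0, 0), contest_params(),
#'                             genetic_architecture(GSB = 0.4),
#'                             max_generations = 200)
#' autoplot(traj)
#' @export
autoplot.contest_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "generation",
                  "mean_signal", "mean_body", "mean_aggression"),
    cols = -"generation", names_to = "trait", values_to = "mean"
  )
  long$trait <- factor(long$trait,
                       levels = c("mean_signal", "mean_body",
                                  "mean_aggression"),
                       labels = c("signal", "body size", "aggression"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$mean,
                                     colour = .data$trait)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "generation", y = "population mean", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Phase-plane plot with the line of equilibria
#'
#' Mean signal against mean body size: the line of equilibria (heavy line)
#' plus, optionally, one or more trajectories approaching it (stable
#' regime) or overshooting it (runaway).
#'
#' @param params A [contest_params()] object (`cS > 0`).
#' @param trajectories A `contest_trajectory` or list of them (optional).
#' @param body_range Range of mean body size to draw the line over;
#'   defaults to the span of the trajectories, or `c(0, 10)`.
#' @return A ggplot object.
#' @examples
#' plot_phase_plane(contest_params())
#' @export
plot_phase_plane <- function(params, trajectories = NULL, body_range = NULL) {
  ln <- equilibrium_line(params)
  if (inherits(trajectories, "contest_trajectory")) {
    trajectories <- list(trajectories)
  }
  traj_tbl <- NULL
  if (!is.null(trajectories)) {
    traj_tbl <- dplyr::bind_rows(lapply(seq_along(trajectories), function(i) {
      tibble::tibble(run = factor(i),
                     mean_body = trajectories[[i]]$mean_body,
                     mean_signal = trajectories[[i]]$mean_signal)
    }))
  }
  if (is.null(body_range)) {
    body_range <- if (!is.null(traj_tbl)) range(traj_tbl$mean_body) else c(0, 10)
    if (diff(body_range) == 0) body_range <- body_range + c(-1, 1)
  }
  line_tbl <- tibble::tibble(
    mean_body = seq(body_range[1], body_range[2], length.out = 100)
  )
  line_tbl$mean_signal <- ln[["intercept"]] + ln[["slope"]] * line_tbl$mean_body
  p <- ggplot2::ggplot(line_tbl, ggplot2::aes(x = .data$mean_body,
                                              y = .data$mean_signal)) +
    ggplot2::geom_line(linewidth = 1.1) +
    ggplot2::labs(x = "mean body size", y = "mean signal size") +
    ggplot2::theme_minimal()
  if (!is.null(traj_tbl)) {
    p <- p + ggplot2::geom_path(
      data = traj_tbl,
      ggplot2::aes(x = .data$mean_body, y = .data$mean_signal,
                   colour = .data$run),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                             type = "closed"),
      inherit.aes = FALSE
    ) + ggplot2::guides(colour = "none")
  }
  p
}
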