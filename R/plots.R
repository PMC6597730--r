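#' Plot MSD curves
#'
#' Per-particle curves are drawn as thin lines; an ensemble curve (with an
#' `sem_um2` column) as mean ± s.e.m. ribbon.
#'
#' @param msd An MSD tibble from [compute_msd()] or [ensemble_msd()].
#' @param theory Optional tibble with `lag_s` and `msd_um2` to overlay (e.g.
#'   from [msd_abp_theory()]).
#' @return A ggplot object.
#' @export
plot_msd <- function(msd, theory = NULL) {
  stopifnot(is.data.frame(msd))
  p <- ggplot2::ggplot(msd, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2))
  if ("sem_um2" %in% names(msd)) {
    p <- p +
      ggplot2::geom_ribbon(
        ggplot2::aes(
          ymin = .data$msd_um2 - .data$sem_um2,
          ymax = .data$msd_um2 + .data$sem_um2
        ),
        alpha = 0.25
      ) +
      ggplot2::geom_line(linewidth = 0.8)
  } else {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = .data$particle_id),
      alpha = 0.4, linewidth = 0.3
    )
  }
  if (!is.null(theory)) {
    p <- p + ggplot2::geom_line(
      data = theory, linetype = "dashed", colour = "red"
    )
  }
  p + ggplot2::labs(
    x = "lag time (s)", y = expression(MSD ~ (mu * m^2))
  )
}

#' Plot a dose–response sweep
#'
#' Fitted mean speed ± s.e.m. against substrate (or inhibitor)
#' concentration, with the kinetic ground truth overlaid.
#'
#' @param sweep A table from [run_sweep()].
#' @param x_col Concentration column to put on the x axis
#'   (default `"substrate_mM"`).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(sweep, x_col = "substrate_mM") {
  stopifnot(is.data.frame(sweep), x_col %in% names(sweep))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[x_col]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$true_speed_um_s),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$mean_v_um_s,
      ymin = .data$mean_v_um_s - .data$sem_v_um_s,
      ymax = .data$mean_v_um_s + .data$sem_v_um_s
    )) +
    ggplot2::labs(
      x = paste0(sub("_mM$", "", x_col), " (mM)"),
      y = expression(speed ~ (mu * m ~ s^-1))
    )
}

#' @export
autoplot.speed_activity_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$activity, y = .data$speed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "red"
    ) +
    ggplot2::labs(
      x = "relative enzymatic activity",
      y = expression(speed ~ (mu * m ~ s^-1)),
      subtitle = sprintf("adj. R^2 = %.3f (n = %d)", object$r_squared_adj, object$n)
    )
}

#' @export
autoplot.propulsive_fit <- function(object, ...) {
  d <- object$lm$model
  names(d) <- c("msd_um2", "four_t", "t2")
  d$lag_s <- d$four_t / 4
  d$fit <- stats::fitted(object$lm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$msd_um2)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::labs(
      x = "lag time (s)", y = expression(MSD ~ (mu * m^2)),
      subtitle = sprintf(
        "v = %.3f um/s, D_t = %.3f um^2/s (%s)",
        object$v_um_s, object$D_t_um2_s, object$flag
      )
    )
}
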