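# QC figures. Each returns a ggplot so callers can restyle.

#' Plot a tribometer trace with phase annotations
#'
#' Shows the lateral force, the measured height with its polynomial fit, and
#' the normal force against time; the static peak and stabilization window
#' are shaded when a segmentation is supplied.
#'
#' @param object A `tribo_trace`.
#' @param segmentation Optional [segment_phases()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tribo_trace
#' @export
autoplot.tribo_trace <- function(object, segmentation = NULL, ...) {
  df <- tibble::as_tibble(object) %>%
    tidyr::pivot_longer(c("fx_mN", "h_mm", "fz_mN"),
                        names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL)
  if (!is.null(segmentation)) {
    t <- object$time_s
    w <- segmentation$stabilization_window
    shade <- tibble::tibble(xmin = t[min(w)], xmax = t[max(w)])
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.15, fill = "steelblue",
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf))
    if (!segmentation$static_missing) {
      p <- p + ggplot2::geom_vline(
        xintercept = t[segmentation$static_peak_index],
        linetype = "dashed", colour = "darkgreen")
    }
  }
  p
}

#' Plot slide friction forces with their Amonton fits
#'
#' @param batch A [batch_friction()] result.
#' @param which `"dynamic"` or `"static"`.
#' @return A ggplot of per-slide adjusted friction force vs normal load with
#'   the through-origin fit line.
#' @export
plot_amonton <- function(batch, which = c("dynamic", "static")) {
  which <- match.arg(which)
  stopifnot(inherits(batch, "friction_batch"))
  fit <- batch$fits[[which]]
  if (is.null(fit)) abort(sprintf("No %s Amonton fit available.", which))
  ggplot2::ggplot(fit$points,
                  ggplot2::aes(x = .data$F_N_mN, y = .data$F_F_mN)) +
    ggplot2::geom_abline(slope = fit$mu, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(F[N] ~ "[mN]"), y = expression(F[F] ~ "[mN]"),
      title = sprintf("%s friction: mu = %.3f", which, fit$mu))
}

#' Plot a lateral damage profile with its width estimate
#'
#' @param object A [estimate_track_width()] result.
#' @param ... Unused.
#' @return A ggplot of damage fraction against lateral offset with the
#'   half-plateau level and estimated width marked.
#' @method autoplot track_width_estimate
#' @export
autoplot.track_width_estimate <- function(object, ...) {
  if (nrow(object$profile) == 0) abort("Empty damage profile.")
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$offset_um, y = .data$damage)) +
    ggplot2::geom_col(alpha = 0.4, width = diff(object$profile$offset_um[1:2])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$damage_smooth), colour = "red") +
    ggplot2::labs(x = "lateral offset [um]", y = "damage fraction",
                  title = sprintf("track width %.1f um (%s)",
                                  object$width_um, object$method))
  if (is.finite(object$plateau)) {
    p <- p + ggplot2::geom_hline(yintercept = object$plateau / 2,
                                 linetype = "dotted")
  }
  p
}

#' Plot relative nuclei densities against normal force
#'
#' @param batch A [batch_damage()] result.
#' @return A ggplot mirroring the damage summary: per-slide open points and
#'   per-force means for the healthy, dead and removed relative densities.
#' @export
plot_damage <- function(batch) {
  stopifnot(inherits(batch, "damage_batch"))
  long <- batch$results %>%
    select("F_N_mN", "rel_blue", "rel_red", "rel_removed") %>%
    tidyr::pivot_longer(-"F_N_mN", names_to = "fraction", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$F_N_mN, y = .data$value,
                                     colour = .data$fraction)) +
    ggplot2::geom_point(shape = 1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3) +
    ggplot2::scale_colour_manual(values = c(rel_blue = "blue",
                                            rel_red = "red",
                                            rel_removed = "black")) +
    ggplot2::labs(x = expression(F[N] ~ "[mN]"),
                  y = "relative nuclei density")
}
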