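# Coordination-diagram plotting: horizontal propulsion bars on the 0-100%
# cycle axis, limbs ordered LF, LH, RF, RH from top to bottom, wrap-around
# bars split at the cycle boundary.

#' @importFrom ggplot2 .data
NULL

#' Plot a coordination diagram
#'
#' Draws the propulsion phase of each limb as a horizontal bar on the
#' percent-of-cycle axis (blank regions are the return phase). For a lap the
#' cycles are shown as facets. Rendering is deterministic given the input.
#'
#' @param x A [swim_cycle()] or [lap_recording()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_coordination <- function(x, title = NULL) {
  if (inherits(x, "swim_cycle")) {
    bars <- coordination_diagram(x)
    bars$cycle <- 1L
  } else if (inherits(x, "lap_recording")) {
    bars <- do.call(rbind, lapply(seq_along(x$cycles), function(k) {
      b <- coordination_diagram(x$cycles[[k]])
      b$cycle <- k
      b
    }))
    if (is.null(title)) {
      title <- sprintf("Horse %s, lap %d (%sHand)", x$horse_id, x$lap_index,
                       x$hand)
    }
  } else {
    stop("x must be a swim_cycle or a lap_recording")
  }
  bars$side <- ifelse(bars$limb %in% c("LF", "LH"), "left", "right")
  bars$y <- 5L - as.integer(factor(bars$limb, levels = LIMB_LEVELS))
  p <- ggplot2::ggplot(bars) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                   fill = .data$side)
    ) +
    ggplot2::scale_y_continuous(breaks = 4:1, labels = LIMB_LEVELS,
                                limits = c(0.5, 4.5)) +
    ggplot2::scale_x_continuous(limits = c(0, 100),
                                breaks = seq(0, 100, 25)) +
    ggplot2::scale_fill_manual(values = c(left = "#4477AA", right = "#CC6677"),
                               guide = "none") +
    ggplot2::labs(x = "% of swimming cycle", y = NULL, title = title) +
    ggplot2::theme_minimal()
  if (length(unique(bars$cycle)) > 1L) {
    p <- p + ggplot2::facet_wrap(~cycle, ncol = 1L,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Boxplots of coordination parameters by category
#'
#' Side-by-side boxplots of one or more per-side parameters grouped by
#' category, the standard way to compare parameter distributions between
#' coordination categories.
#'
#' @param params Data frame with a `category` column plus parameter columns
#'   (see [lap_parameters()]).
#' @param parameter_names Columns to plot.
#' @return A ggplot object.
#' @export
plot_parameters <- function(params,
                            parameter_names = c("lat_ol_left", "lat_ol_right",
                                                "diag_ol_left", "diag_ol_right")) {
  stopifnot(is.data.frame(params), "category" %in% names(params),
            all(parameter_names %in% names(params)))
  long <- do.call(rbind, lapply(parameter_names, function(pn) {
    data.frame(category = params$category, parameter = pn,
               value = params[[pn]], stringsAsFactors = FALSE)
  }))
  long$parameter <- factor(long$parameter, levels = parameter_names)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$category, y = .data$value,
                               fill = .data$category)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% of cycle") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
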