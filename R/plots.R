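#' Plot a recorded sweep set
#'
#' Voltage traces of selected sweeps, offset-free, coloured by step
#' amplitude.
#'
#' @param object A [cell_record()].
#' @param amplitudes Step amplitudes to show (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_record <- function(object, amplitudes = NULL, ...) {
  amps <- record_amplitudes(object)
  keep <- if (is.null(amplitudes)) seq_along(amps)
          else which(amps %in% amplitudes)
  df <- purrr::map_dfr(keep, function(i) {
    s <- object$sweeps[[i]]
    tibble::tibble(time = sweep_times(s), voltage = s$voltage,
                   amplitude = s$current_amplitude)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$voltage,
                                   group = .data$amplitude,
                                   colour = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  colour = "step (pA)",
                  title = object$cell_id) +
    ggplot2::theme_minimal()
}

#' Phase-plane plot of one or more APs
#'
#' dV/dt against V over the spike window, one loop per AP.
#'
#' @param sweep A [new_sweep()].
#' @param events Event table from [detect_aps()] (default: all APs of the
#'   sweep).
#' @param ... Passed to [phase_plot()].
#' @return A ggplot.
#' @export
plot_phase_plane <- function(sweep, events = detect_aps(sweep), ...) {
  df <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    pp <- phase_plot(sweep, events[i, ], ...)
    pp$ap <- events$ap[i]
    pp
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$voltage, .data$dvdt,
                                   group = .data$ap)) +
    ggplot2::geom_path(linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(x = "V (mV)", y = "dV/dt (mV/ms)") +
    ggplot2::theme_minimal()
}

#' Plot a group comparison
#'
#' Boxplots of each feature by group, annotated with the omnibus p value.
#'
#' @param object A `group_comparison` from [group_summary()].
#' @param features Feature table the comparison was computed from.
#' @param feature_cols Features to show (default: up to 8 with the smallest
#'   omnibus p).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_comparison <- function(object, features,
                                      feature_cols = NULL, ...) {
  if (is.null(feature_cols)) {
    om <- object$omnibus[order(object$omnibus$p), ]
    feature_cols <- utils::head(om$feature, 8)
  }
  long <- tidyr::pivot_longer(
    features[, c(object$group, feature_cols)],
    cols = dplyr::all_of(feature_cols),
    names_to = "feature", values_to = "value")
  labs <- stats::setNames(
    sprintf("%s (p = %.2g)", object$omnibus$feature, object$omnibus$p),
    object$omnibus$feature)
  long$feature <- factor(long$feature, levels = feature_cols,
                         labels = labs[feature_cols])
  ggplot2::ggplot(long, ggplot2::aes(.data[[object$group]], .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a morphology
#'
#' 2D projection (x against the pia axis) of the dendritic arbor, coloured
#' by compartment.
#'
#' @param object A [morphology()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morphology <- function(object, ...) {
  n <- object$nodes
  pos <- match(n$parent_id, n$id)
  seg <- tibble::tibble(
    x = n$x[pos], y = n$y[pos], xend = n$x, yend = n$y,
    compartment = n$compartment)[!is.na(pos), ]
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
      colour = .data$compartment), linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um, +pia)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
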