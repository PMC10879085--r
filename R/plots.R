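#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_boxplot facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot an elbow curve
#'
#' Within/between distance ratio against k, with the selected K marked.
#'
#' @param object An `elbow_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elbow_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$k, y = .data$ratio)) +
    geom_line() +
    geom_point(aes(colour = .data$selected), size = 2.5) +
    labs(x = "number of states k", y = "within / between distance ratio",
         colour = "selected") +
    theme_minimal()
}

#' Plot state centroids as connectivity strength profiles
#'
#' @param object A `state_model`.
#' @param ... Unused.
#' @return A ggplot of centroid Fisher-z values per pair, one facet per
#'   state.
#' @export
autoplot.state_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$pair, y = .data$z)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~ state, ncol = 1, labeller = ggplot2::label_both) +
    labs(x = "component pair (canonical order)", y = "centroid Fisher z") +
    theme_minimal()
}

#' Plot per-subject state dynamics by group
#'
#' @param dynamics Tibble from [cohort_state_dynamics()].
#' @param cohort Cohort tibble.
#' @param measure One of "occupancy", "dwell", "n_transitions".
#' @return A ggplot (boxplots per state and group).
#' @export
plot_state_dynamics <- function(dynamics, cohort,
                                measure = c("occupancy", "dwell",
                                            "n_transitions")) {
  measure <- match.arg(measure)
  d <- dplyr::left_join(dynamics, cohort[, c("subject_id", "group")],
                        by = "subject_id")
  if (measure == "n_transitions") d <- dplyr::filter(d, .data$state == 1L)
  p <- ggplot(d, aes(x = factor(.data$state), y = .data[[measure]],
                     fill = .data$group)) +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = "state (1 = low connectivity)", y = measure) +
    theme_minimal()
  if (measure == "n_transitions") p <- p + labs(x = NULL)
  p
}

#' Plot a global metric across the sparsity-threshold series
#'
#' @param curves Result of [metric_curves()].
#' @param metric One of "cp", "lp", "gamma", "lambda", "sigma".
#' @return A ggplot of the metric against sparsity.
#' @export
plot_metric_curve <- function(curves, metric = "sigma") {
  stopifnot(metric %in% c("cp", "lp", "gamma", "lambda", "sigma"))
  ggplot(curves$global, aes(x = .data$threshold, y = .data[[metric]])) +
    geom_line() + geom_point(size = 1) +
    labs(x = "sparsity (network density)", y = metric) +
    theme_minimal()
}
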