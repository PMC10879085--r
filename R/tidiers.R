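#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted state model
#'
#' One row per state x pair centroid value, in the canonical pair ordering.
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return Tibble: `state`, `pair`, `z`.
#' @export
tidy.state_model <- function(x, ...) {
  tidyr::expand_grid(state = seq_len(x$k), pair = seq_len(ncol(x$centroids))) %>%
    dplyr::mutate(z = as.vector(t(x$centroids)))
}

#' One-row summary of a fitted state model
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_windows`, `n_subjects`, `tot_within`,
#'   `state_sizes`.
#' @export
glance.state_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_windows = length(x$labels),
    n_subjects = if (is.null(x$subject_ids)) NA_integer_ else
      length(x$subject_ids),
    tot_within = x$tot_within,
    state_sizes = paste(tabulate(x$labels, x$k), collapse = "/"))
}

#' Tidy an elbow-selection result
#'
#' @param x An `elbow_result` from [elbow_select_k()].
#' @param ... Unused.
#' @return The elbow curve tibble (`k`, `within`, `between`, `ratio`) with a
#'   `selected` flag.
#' @export
tidy.elbow_result <- function(x, ...) {
  dplyr::mutate(x$elbow_curve, selected = .data$k == x$k)
}

#' Tidy a dynamic-topology summary
#'
#' @param x A `dynamic_topology`.
#' @param ... Unused.
#' @return Tibble of AUC variances: `scope` ("global"/"nodal"), `metric`,
#'   `node` (NA for global), `variance`.
#' @export
tidy.dynamic_topology <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$variance_global, scope = "global", node = NA_integer_),
    dplyr::mutate(x$variance_nodal, scope = "nodal")) %>%
    dplyr::select("scope", "metric", "node", "variance")
}
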