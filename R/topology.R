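#' Sparsity-threshold series
#'
#' Network density values at which connectivity matrices are binarised. The
#' default series runs from 0.10 to 0.38 in steps of 0.01 (29 values), the
#' range over which small-world estimation on networks of this size is
#' stable.
#'
#' @param from,to,by Range and step of the series.
#' @return Strictly increasing numeric vector in (0, 1).
#' @export
threshold_series <- function(from = 0.10, to = 0.38, by = 0.01) {
  v <- round(seq(from, to, by = by), 10)
  if (any(v <= 0 | v >= 1) || any(diff(v) <= 0)) {
    abort("thresholds must be strictly increasing within (0, 1)",
          class = "dynfc_domain_error")
  }
  v
}

#' Binarise a connectivity vector at a sparsity (density) threshold
#'
#' "Sparsity" is network density: the fraction of strongest edges kept.
#' The `round(s * P)` pairs with the largest `|z|` become edges (ties broken
#' by canonical pair order, first pair wins); everything else is 0. The
#' result is a symmetric 0/1 adjacency matrix with zero diagonal.
#'
#' @param z_vector P connectivity values in canonical pair order.
#' @param s Sparsity in (0, 1); `round(s * P)` must be >= 1.
#' @return C x C binary adjacency matrix.
#' @export
binarize_by_sparsity <- function(z_vector, s) {
  P <- length(z_vector)
  C <- as.integer(round((1 + sqrt(1 + 8 * P)) / 2))
  if (n_pairs(C) != P) abort("z_vector length is not C*(C-1)/2",
                             class = "dynfc_schema_error")
  if (s <= 0 || s >= 1) abort("sparsity must lie in (0, 1)",
                              class = "dynfc_domain_error")
  n_edges <- floor(s * P + 0.5)
  if (n_edges < 1) {
    abort(sprintf("round(s * P) = 0: threshold %g too low for %d pairs", s, P),
          class = "dynfc_domain_error")
  }
  keep <- order(-abs(z_vector), seq_len(P))[seq_len(n_edges)]
  v <- numeric(P)
  v[keep] <- 1
  pairvec_to_mat(v, C)
}

#' Nodal graph metrics
#'
#' Degree centrality (edge count at the node, unnormalised), nodal
#' clustering coefficient (`2 * triangles / (deg * (deg - 1))`, 0 when
#' degree < 2) and nodal efficiency (mean inverse shortest-path length to
#' the other nodes, with `1/Inf = 0`).
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Tibble: `node`, `degree`, `clustering`, `efficiency`.
#' @export
nodal_metrics <- function(adj) {
  g <- graph_from_adj(adj)
  C <- nrow(adj)
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  D <- igraph::distances(g)
  inv <- 1 / D
  diag(inv) <- 0
  eff <- rowSums(inv) / (C - 1)
  tibble::tibble(node = seq_len(C), degree = as.numeric(deg),
                 clustering = as.numeric(cl), efficiency = eff)
}

#' Global small-world metrics with degree-preserving nulls
#'
#' `Cp` is the mean nodal clustering coefficient and `Lp` the mean shortest
#' path length over reachable ordered pairs (finite distances only; the
#' number of unreachable pairs is reported). `Gamma = Cp / Cp_null` and
#' `Lambda = Lp / Lp_null`, where the null values are means over `n_nulls`
#' Maslov-Sneppen degree-preserving rewirings (`null_swaps` attempted edge
#' swaps each, default `10 * n_edges`); `Sigma = Gamma / Lambda` is the
#' small-worldness.
#'
#' @param adj Binary symmetric adjacency with at least one edge.
#' @param n_nulls Number of rewired null networks (default 100).
#' @param null_swaps Attempted swaps per null (default `10 * n_edges`).
#' @param seed Integer seed (NULL = current RNG stream).
#' @return One-row tibble: `cp`, `lp`, `gamma`, `lambda`, `sigma`,
#'   `unreachable_pairs`.
#' @export
global_metrics <- function(adj, n_nulls = 100L, null_swaps = NULL,
                           seed = NULL) {
  g <- graph_from_adj(adj)
  ne <- igraph::ecount(g)
  if (ne < 1L) abort("graph has no edges", class = "dynfc_domain_error")
  if (is.null(null_swaps)) null_swaps <- 10L * ne
  base <- cp_lp(g, nrow(adj))
  if (!is.finite(base$lp)) {
    abort("no reachable pairs: Lp undefined", class = "dynfc_domain_error")
  }
  run <- function() {
    nulls <- purrr::map(seq_len(n_nulls), function(i) {
      gn <- igraph::rewire(g, igraph::keeping_degseq(niter = null_swaps))
      cp_lp(gn, nrow(adj))
    })
    c(cp = mean(purrr::map_dbl(nulls, "cp")),
      lp = mean(purrr::map_dbl(nulls, "lp")))
  }
  nullv <- if (is.null(seed)) run() else withr_seed(seed, run())
  gamma <- if (nullv[["cp"]] > 0) base$cp / nullv[["cp"]] else NA_real_
  lambda <- base$lp / nullv[["lp"]]
  tibble::tibble(cp = base$cp, lp = base$lp, gamma = gamma, lambda = lambda,
                 sigma = gamma / lambda,
                 unreachable_pairs = base$unreachable)
}

graph_from_adj <- function(adj) {
  adj <- as.matrix(adj)
  stopifnot(nrow(adj) == ncol(adj))
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

cp_lp <- function(g, C) {
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  D <- igraph::distances(g)
  finite <- is.finite(D) & upper.tri(D)
  lp <- if (any(finite)) mean(D[finite]) else Inf
  list(cp = mean(cl), lp = lp,
       unreachable = sum(!is.finite(D[upper.tri(D)])))
}

#' Area under a metric-versus-threshold curve
#'
#' Trapezoidal integral of the metric over the sparsity axis.
#'
#' @param values Metric values, one per threshold.
#' @param thresholds Threshold series of equal length (>= 2).
#' @return Scalar AUC.
#' @export
auc_over_thresholds <- function(values, thresholds) {
  if (length(values) != length(thresholds) || length(values) < 2L) {
    abort("values and thresholds must have equal length >= 2",
          class = "dynfc_validation_error")
  }
  sum(diff(thresholds) * (head(values, -1) + tail(values, -1)) / 2)
}

#' Metric curves and AUCs for one connectivity vector
#'
#' Binarises the vector at every threshold and evaluates the global and
#' nodal metrics, returning per-threshold curves and their AUC.
#'
#' @param z_vector P connectivity values in canonical pair order.
#' @param thresholds Sparsity series (default [threshold_series()]).
#' @param n_nulls Null networks per threshold for the normalised global
#'   metrics (default 100; set 0 to skip Gamma/Lambda/Sigma).
#' @param seed Integer seed (NULL = current RNG stream).
#' @return List with `global` (tibble threshold x metric), `nodal` (tibble
#'   threshold x node x metric) and `auc` (tibble metric/node x auc).
#' @export
metric_curves <- function(z_vector, thresholds = threshold_series(),
                          n_nulls = 100L, seed = NULL) {
  per_thr <- purrr::map(thresholds, function(s) {
    adj <- binarize_by_sparsity(z_vector, s)
    glob <- if (n_nulls > 0L) {
      global_metrics(adj, n_nulls = n_nulls, seed = seed)
    } else {
      g <- graph_from_adj(adj)
      b <- cp_lp(g, nrow(adj))
      tibble::tibble(cp = b$cp, lp = b$lp, gamma = NA_real_,
                     lambda = NA_real_, sigma = NA_real_,
                     unreachable_pairs = b$unreachable)
    }
    list(global = dplyr::mutate(glob, threshold = s, .before = 1),
         nodal = dplyr::mutate(nodal_metrics(adj), threshold = s,
                               .before = 1))
  })
  glob <- dplyr::bind_rows(purrr::map(per_thr, "global"))
  nodal <- dplyr::bind_rows(purrr::map(per_thr, "nodal"))
  gm <- c("cp", "lp", "gamma", "lambda", "sigma")
  auc_glob <- tibble::tibble(
    metric = gm,
    auc = vapply(gm, function(m) {
      v <- glob[[m]]
      if (all(is.finite(v))) auc_over_thresholds(v, thresholds) else NA_real_
    }, numeric(1L)))
  nm <- c("degree", "clustering", "efficiency")
  auc_nodal <- nodal %>%
    tidyr::pivot_longer(dplyr::all_of(nm), names_to = "metric",
                        values_to = "value") %>%
    dplyr::group_by(.data$node, .data$metric) %>%
    dplyr::summarise(auc = auc_over_thresholds(.data$value,
                                               .env$thresholds),
                     .groups = "drop")
  list(global = glob, nodal = nodal, auc_global = auc_glob,
       auc_nodal = auc_nodal)
}

#' Dynamic graph topology: across-window variance of AUC
#'
#' For each window of a subject's windowed connectivity: binarise at every
#' threshold, compute the metrics, integrate over thresholds (AUC); then
#' summarise each metric by the population variance (divide by W) of its W
#' per-window AUC values — the variability of network organisation over
#' time.
#'
#' @param windows A `windowed_fnc` object (W >= 2 windows).
#' @param thresholds Sparsity series (default [threshold_series()]).
#' @param n_nulls Null networks per window and threshold for the normalised
#'   metrics (default 10; the reduced dynamic-analysis count).
#' @param seed Integer seed.
#' @return A `dynamic_topology` list: `subject_id`, `window_auc_global`
#'   (tibble window x metric x auc), `window_auc_nodal`, `variance_global`
#'   (tibble metric, variance), `variance_nodal` (tibble node, metric,
#'   variance).
#' @export
dynamic_topology <- function(windows, thresholds = threshold_series(),
                             n_nulls = 10L, seed = 1L) {
  stopifnot(inherits(windows, "windowed_fnc"))
  W <- nrow(windows$z)
  if (W < 2L) abort("need at least two windows", class = "dynfc_domain_error")
  per_window <- withr_seed(seed, {
    purrr::map(seq_len(W), function(w) {
      curves <- tryCatch(
        metric_curves(windows$z[w, ], thresholds, n_nulls = n_nulls),
        error = function(e) {
          abort(sprintf("window %d: %s", w, conditionMessage(e)),
                class = "dynfc_computation_error")
        })
      list(global = dplyr::mutate(curves$auc_global, window = w, .before = 1),
           nodal = dplyr::mutate(curves$auc_nodal, window = w, .before = 1))
    })
  })
  wg <- dplyr::bind_rows(purrr::map(per_window, "global"))
  wn <- dplyr::bind_rows(purrr::map(per_window, "nodal"))
  pop_var <- function(v) mean((v - mean(v))^2)
  vg <- wg %>% dplyr::group_by(.data$metric) %>%
    dplyr::summarise(variance = pop_var(.data$auc), .groups = "drop")
  vn <- wn %>% dplyr::group_by(.data$node, .data$metric) %>%
    dplyr::summarise(variance = pop_var(.data$auc), .groups = "drop")
  structure(list(subject_id = windows$subject_id,
                 window_auc_global = wg, window_auc_nodal = wn,
                 variance_global = vg, variance_nodal = vn),
            class = "dynamic_topology")
}

#' @export
print.dynamic_topology <- function(x, ...) {
  cat(sprintf("<dynamic_topology> subject %s: AUC variance over %d windows\n",
              x$subject_id, max(x$window_auc_global$window)))
  print(x$variance_global)
  invisible(x)
}
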