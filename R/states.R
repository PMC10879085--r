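#' K-means brain states under the Manhattan distance
#'
#' Clusters the stacked window vectors of all subjects into K recurring
#' connectivity states with city-block (L1) k-means: assignments minimise the
#' Manhattan distance and centroid updates are element-wise medians, the
#' exact L1-optimal centroid. Each replicate is started with k-means++
#' seeding computed under the L1 distance; the best of `n_replicates` runs by
#' total within-cluster distance is returned. Deterministic for a fixed seed.
#'
#' @param windows Either a numeric matrix of stacked window rows, or a list
#'   of `windowed_fnc` objects (rows are stacked in list order).
#' @param k Number of states (K).
#' @param max_iter Iteration cap per replicate (default 150).
#' @param n_replicates Random restarts (default 5).
#' @param seed Integer seed.
#' @param tol_changes Stop a replicate once an assignment pass changes at
#'   most this many labels (default 0: run to the exact fixed point).
#' @return A `state_model`: list with `k`, `centroids` (K x P), `labels`
#'   (one integer per stacked row), `assignments` (list of per-subject label
#'   vectors, when subject structure was supplied), `tot_within`,
#'   `subject_ids`, `n_windows`.
#' @export
kmeans_states <- function(windows, k, max_iter = 150L, n_replicates = 5L,
                          seed = 1L, tol_changes = 0L) {
  parts <- stack_windows(windows)
  X <- parts$x
  if (nrow(X) < k) abort("need at least K rows", class = "dynfc_domain_error")
  best <- NULL
  withr_seed(seed, {
    for (rep_ in seq_len(n_replicates)) {
      init <- kmeanspp_init_l1(X, k)
      fit <- cpp_kmeans_l1(X, init, max_iter, as.integer(tol_changes))
      if (is.null(best) || fit$tot_within < best$tot_within) best <- fit
    }
  })
  labels <- as.integer(best$labels)
  assignments <- NULL
  if (!is.null(parts$n_per_subject)) {
    offs <- c(0L, cumsum(parts$n_per_subject))
    assignments <- lapply(seq_along(parts$n_per_subject), function(s) {
      labels[(offs[s] + 1L):offs[s + 1L]]
    })
    names(assignments) <- parts$subject_ids
  }
  structure(list(k = as.integer(k), centroids = best$centroids,
                 labels = labels, assignments = assignments,
                 tot_within = best$tot_within,
                 subject_ids = parts$subject_ids,
                 n_windows = parts$n_per_subject,
                 seed = seed),
            class = "state_model")
}

stack_windows <- function(windows) {
  if (is.matrix(windows)) {
    return(list(x = windows, n_per_subject = NULL, subject_ids = NULL))
  }
  if (is.list(windows) && all(vapply(windows, inherits, logical(1L),
                                     "windowed_fnc"))) {
    return(list(x = do.call(rbind, lapply(windows, `[[`, "z")),
                n_per_subject = vapply(windows, function(w) nrow(w$z),
                                       integer(1L)),
                subject_ids = vapply(windows, `[[`, character(1L),
                                     "subject_id")))
  }
  abort("windows must be a matrix or a list of windowed_fnc objects",
        class = "dynfc_schema_error")
}

# k-means++ seeding under the L1 distance (uses the current RNG stream)
kmeanspp_init_l1 <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d <- cpp_l1_dist_to_point(X, centers[1L, ])
  if (k > 1L) for (c_ in 2L:k) {
    prob <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
    pick <- sample.int(n, 1L, prob = prob)
    centers[c_, ] <- X[pick, ]
    d <- pmin(d, cpp_l1_dist_to_point(X, centers[c_, ]))
  }
  centers
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> K = %d states over %d windows (P = %d); total within-cluster L1 distance %.4g\n",
              x$k, length(x$labels), ncol(x$centroids), x$tot_within))
  invisible(x)
}

#' Elbow selection of the number of states
#'
#' For each candidate k, runs [kmeans_states()] and computes the ratio of the
#' total within-cluster distance to the cluster-size-weighted distance of the
#' centroids from the pooled centroid (element-wise median of all rows). The
#' selected K maximises the discrete curvature (second difference) of this
#' ratio curve over the interior candidates. A flat curve (all second
#' differences below 1e-12) returns the smallest candidate with a warning.
#'
#' @inheritParams kmeans_states
#' @param k_range Candidate k values (default 2:8).
#' @return List with `k` (selected) and `elbow_curve` (tibble: k, within,
#'   between, ratio), class `elbow_result`.
#' @export
elbow_select_k <- function(windows, k_range = 2:8, max_iter = 150L,
                           n_replicates = 5L, seed = 1L) {
  parts <- stack_windows(windows)
  X <- parts$x
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(X)) {
    abort("k_range exceeds the number of rows", class = "dynfc_domain_error")
  }
  grand <- apply(X, 2L, median)
  rows <- lapply(seq_along(k_range), function(idx) {
    k <- k_range[idx]
    fit <- kmeans_states(X, k, max_iter = max_iter,
                         n_replicates = n_replicates, seed = seed + idx)
    sizes <- tabulate(fit$labels, nbins = k)
    between <- sum(sizes * cpp_l1_dist_to_point(fit$centroids, grand))
    tibble::tibble(k = k, within = fit$tot_within, between = between,
                   ratio = fit$tot_within / between)
  })
  curve <- dplyr::bind_rows(rows)
  r <- curve$ratio
  if (length(r) < 3L) {
    k_star <- k_range[which.min(r)]
  } else {
    d2 <- r[1:(length(r) - 2L)] - 2 * r[2:(length(r) - 1L)] + r[3:length(r)]
    if (all(!is.finite(d2)) || all(abs(d2) < 1e-12, na.rm = TRUE)) {
      warn("flat elbow curve; returning the smallest candidate k")
      k_star <- k_range[1L]
    } else {
      k_star <- k_range[which.max(d2) + 1L]
    }
  }
  structure(list(k = k_star, elbow_curve = curve), class = "elbow_result")
}

#' State-dynamics summaries for one assignment sequence
#'
#' From a subject's per-window state labels: fractional occupancy (share of
#' windows in each state), mean dwell time (average length of maximal runs,
#' in windows; 0 for unvisited states) and the number of transitions between
#' different consecutive states. Dwell time in seconds is
#' `windows * step_tr * tr`.
#'
#' @param assignment Integer vector of window labels in 1..k.
#' @param k Number of states.
#' @param step_tr,tr Optional step (TR) and TR (seconds) to add a
#'   `dwell_seconds` column.
#' @return A tibble with one row per state: `state`, `occupancy`, `dwell`
#'   (windows), optionally `dwell_seconds`, and the scalar `n_transitions`
#'   replicated down the rows.
#' @examples
#' state_dynamics(c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3), k = 3)
#' @export
state_dynamics <- function(assignment, k, step_tr = NULL, tr = NULL) {
  assignment <- as.integer(assignment)
  if (length(assignment) == 0L) abort("empty assignment sequence",
                                      class = "dynfc_domain_error")
  if (any(assignment < 1L | assignment > k)) {
    abort("labels must lie in 1..k", class = "dynfc_domain_error")
  }
  W <- length(assignment)
  occ <- tabulate(assignment, nbins = k) / W
  runs <- rle(assignment)
  dwell <- vapply(seq_len(k), function(s) {
    len <- runs$lengths[runs$values == s]
    if (length(len)) mean(len) else 0
  }, numeric(1L))
  n_trans <- sum(diff(assignment) != 0L)
  out <- tibble::tibble(state = seq_len(k), occupancy = occ, dwell = dwell,
                        n_transitions = n_trans)
  if (!is.null(step_tr) && !is.null(tr)) {
    out$dwell_seconds <- out$dwell * step_tr * tr
  }
  out
}

#' Per-subject state dynamics for a fitted state model
#'
#' @param model A `state_model` fitted on a list of `windowed_fnc` objects.
#' @param step_tr,tr Optional unit conversion (see [state_dynamics()]).
#' @return A tibble with one row per subject x state.
#' @export
cohort_state_dynamics <- function(model, step_tr = NULL, tr = NULL) {
  stopifnot(inherits(model, "state_model"))
  if (is.null(model$assignments)) {
    abort("model was fitted on a bare matrix; per-subject dynamics need subject structure",
          class = "dynfc_validation_error")
  }
  purrr::imap_dfr(model$assignments, function(a, id) {
    dplyr::mutate(state_dynamics(a, model$k, step_tr, tr),
                  subject_id = id, .before = 1)
  })
}

#' Fraction of subjects entering each state, by group
#'
#' @param model A `state_model` with per-subject assignments.
#' @param cohort Cohort tibble.
#' @return Tibble: `group`, `state`, `prevalence` (fraction of the group's
#'   subjects with at least one window in the state).
#' @export
subject_state_prevalence <- function(model, cohort) {
  stopifnot(inherits(model, "state_model"))
  cohort <- validate_cohort(cohort, require_both_groups = FALSE)
  visited <- purrr::imap_dfr(model$assignments, function(a, id) {
    tibble::tibble(subject_id = id, state = seq_len(model$k),
                   visited = seq_len(model$k) %in% a)
  })
  visited %>%
    dplyr::left_join(cohort[, c("subject_id", "group")], by = "subject_id") %>%
    dplyr::group_by(.data$group, .data$state) %>%
    dplyr::summarise(prevalence = mean(.data$visited), .groups = "drop")
}

#' Order states from low to strong mean connectivity
#'
#' Returns the permutation that sorts states by mean absolute centroid z
#' ascending, so state 1 is the most weakly connected ("low") state and
#' state K the strongest. Apply with [relabel_states()].
#'
#' @param model A `state_model`.
#' @return Integer permutation `p` such that old state `p[s]` becomes new
#'   state `s`.
#' @export
state_strength_order <- function(model) {
  stopifnot(inherits(model, "state_model"))
  order(rowMeans(abs(model$centroids)))
}

#' Relabel the states of a model by a permutation
#'
#' @param model A `state_model`.
#' @param perm Integer permutation: old state `perm[s]` becomes new state `s`.
#' @return The relabelled `state_model`.
#' @export
relabel_states <- function(model, perm) {
  stopifnot(inherits(model, "state_model"),
            sort(perm) == seq_len(model$k))
  inv <- order(perm)
  model$centroids <- model$centroids[perm, , drop = FALSE]
  model$labels <- inv[model$labels]
  if (!is.null(model$assignments)) {
    model$assignments <- lapply(model$assignments, function(a) inv[a])
  }
  model
}

#' Match estimated states to reference states
#'
#' Finds the label permutation that maximises agreement between an estimated
#' label sequence and a reference sequence (exhaustive search over the K!
#' permutations — exact for the small K used in state analysis).
#'
#' @param estimated,reference Integer label vectors of equal length.
#' @param k Number of states.
#' @return List with `perm` (apply as in [relabel_states()]: estimated state
#'   `perm[s]` corresponds to reference state `s`), and `accuracy` (fraction
#'   of positions matching after relabelling).
#' @export
match_state_labels <- function(estimated, reference, k) {
  stopifnot(length(estimated) == length(reference))
  perms <- all_permutations(k)
  best <- NULL
  for (p in perms) {
    inv <- order(p)
    acc <- mean(inv[estimated] == reference)
    if (is.null(best) || acc > best$accuracy) best <- list(perm = p, accuracy = acc)
  }
  best
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
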