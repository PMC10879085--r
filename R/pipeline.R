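#' Run the full dynamic-connectivity study pipeline
#'
#' Sequences every stage on a cohort: time-course cleaning, static
#' connectivity with ANCOVA + FDR, windowed connectivity with confound
#' regression, state decomposition (fixed K or elbow-selected) with
#' state-dynamics group tests and EDSS correlations, and (optionally)
#' dynamic graph topology with group tests. All randomness flows from
#' `seed` through named substreams; the returned `manifest` records every
#' parameter, so the seed reproduces every number in the bundle.
#'
#' @param input A `synthetic_cohort` (from [generate_cohort()]) or a
#'   directory written by [write_synthetic_cohort()] / laid out the same way
#'   (`metadata.csv`, `labels.csv`, `timecourses/<id>.tsv`,
#'   `motion/<id>.tsv`).
#' @param k Number of states, or `"auto"` for elbow selection over
#'   `k_range`.
#' @param k_range Candidate K values when `k = "auto"`.
#' @param width_tr,step_tr Sliding-window parameters (TR units).
#' @param lambda_grid Penalty grid for the windowed graphical lasso. The
#'   default `0` uses the unpenalised tapered-correlation estimator (exactly
#'   the graphical lasso at zero penalty); pass a grid such as
#'   `exp(seq(log(0.01), log(1), length.out = 10))` for held-out selection.
#' @param postproc [postproc_params()] list.
#' @param run_sfnc,run_topology Stage switches.
#' @param thresholds,topology_nulls Sparsity series and null count for the
#'   dynamic topology stage.
#' @param tr Repetition time override when reading from disk (seconds).
#' @param seed Master seed.
#' @return A `dynfc_bundle` list: `cohort`, `sfnc` (per-pair ANCOVA table or
#'   NULL), `windows`, `state_model`, `elbow`, `dynamics`,
#'   `dynamics_tests`, `edss_correlations`, `prevalence`, `topology`,
#'   `topology_tests`, `manifest`.
#' @export
run_pipeline <- function(input, k = "auto", k_range = 2:8,
                         width_tr = 30L, step_tr = 1L,
                         lambda_grid = 0,
                         postproc = postproc_params(),
                         run_sfnc = TRUE, run_topology = FALSE,
                         thresholds = threshold_series(),
                         topology_nulls = 10L,
                         tr = 2, seed = 1L) {
  data <- load_pipeline_input(input, tr)
  cohort <- validate_cohort(data$cohort)
  n <- length(data$subjects)
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for subject %s: %s", name, id,
                    conditionMessage(e)), class = "dynfc_stage_error")
    })
  }

  # --- cleaning ---
  cleaned <- purrr::imap(data$subjects, function(s, id) {
    stage("postproc", id,
          postprocess_timecourses(s$timecourses, s$motion, postproc))
  })

  # --- static connectivity + ANCOVA ---
  sfnc_table <- NULL
  if (run_sfnc) {
    zmat <- do.call(rbind, purrr::imap(cleaned, function(tc, id) {
      stage("sfnc", id, compute_sfnc(tc))$z
    }))
    ord <- match(cohort$subject_id, names(cleaned))
    zmat <- zmat[ord, , drop = FALSE]
    pi_ <- pair_index(ncol(cleaned[[1L]]$data))
    sfnc_table <- purrr::map_dfr(seq_len(ncol(zmat)), function(pp) {
      dplyr::mutate(
        ancova_group(zmat[, pp], cohort,
                     measure = sprintf("sfnc_pair_%d", pp)),
        pair = .env$pp, i = pi_$i[.env$pp], j = pi_$j[.env$pp])
    })
    sfnc_table$fdr_q <- bh_fdr(sfnc_table$p)
  }

  # --- windowed connectivity ---
  spec <- make_window_spec(nrow(cleaned[[1L]]$data), width_tr, step_tr)
  windows <- purrr::imap(cleaned, function(tc, id) {
    stage("dfnc", id,
          windowed_connectivity(tc, spec, lambda_grid = lambda_grid,
                                seed = seed + 1L))
  })
  windows <- regress_window_confounds(unname(windows), cohort)

  # --- states ---
  elbow <- NULL
  if (identical(k, "auto")) {
    elbow <- elbow_select_k(windows, k_range = k_range, seed = seed + 2L)
    k_use <- elbow$k
  } else {
    k_use <- as.integer(k)
  }
  model <- kmeans_states(windows, k_use, seed = seed + 3L)
  model <- relabel_states(model, state_strength_order(model))
  dynamics <- cohort_state_dynamics(model, step_tr = step_tr,
                                    tr = cleaned[[1L]]$tr)
  dyn_tests <- compare_state_dynamics(dynamics, cohort)
  edss_cors <- correlate_dynamics_edss(dynamics, cohort)
  prevalence <- subject_state_prevalence(model, cohort)

  # --- dynamic topology ---
  topology <- NULL
  topo_tests <- NULL
  if (run_topology) {
    topology <- purrr::map(windows, function(w) {
      stage("topology", w$subject_id,
            dynamic_topology(w, thresholds, n_nulls = topology_nulls,
                             seed = seed + 4L))
    })
    topo_tests <- compare_topology_variance(topology, cohort)
  }

  manifest <- list(
    seed = seed, n_subjects = n, k = k_use, k_mode = k,
    width_tr = width_tr, step_tr = step_tr, lambda_grid = lambda_grid,
    postproc = postproc, thresholds = if (run_topology) thresholds else NULL,
    topology_nulls = if (run_topology) topology_nulls else NULL,
    run_sfnc = run_sfnc, run_topology = run_topology,
    fd_convention = "sum-abs-diff, radius 50 mm",
    window_convention = "rectangle (*) 4-sample Gaussian (sigma 3 TR), full support",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  structure(list(cohort = cohort, sfnc = sfnc_table, windows = windows,
                 state_model = model, elbow = elbow, dynamics = dynamics,
                 dynamics_tests = dyn_tests, edss_correlations = edss_cors,
                 prevalence = prevalence, topology = topology,
                 topology_tests = topo_tests, manifest = manifest),
            class = "dynfc_bundle")
}

load_pipeline_input <- function(input, tr) {
  if (inherits(input, "synthetic_cohort")) {
    return(list(cohort = input$cohort, subjects = input$subjects))
  }
  if (is.character(input) && dir.exists(input)) {
    cohort <- read_cohort(file.path(input, "metadata.csv"))
    labels_path <- file.path(input, "labels.csv")
    subjects <- lapply(cohort$subject_id, function(id) {
      list(timecourses = read_timecourses(
        file.path(input, "timecourses", paste0(id, ".tsv")), tr = tr,
        labels_path = labels_path, subject_id = id),
        motion = read_motion(file.path(input, "motion", paste0(id, ".tsv"))))
    })
    names(subjects) <- cohort$subject_id
    return(list(cohort = cohort, subjects = subjects))
  }
  abort("input must be a synthetic_cohort or a cohort directory",
        class = "dynfc_validation_error")
}

#' Group comparison of state-dynamics measures
#'
#' Mann-Whitney tests (uncorrected, as appropriate for the three state
#' measures) of per-state fractional occupancy and mean dwell time, and of
#' the number of transitions, patients versus controls.
#'
#' @param dynamics Per-subject dynamics tibble from
#'   [cohort_state_dynamics()].
#' @param cohort Cohort tibble.
#' @return Results tibble, one row per measure.
#' @export
compare_state_dynamics <- function(dynamics, cohort) {
  cohort <- validate_cohort(cohort)
  d <- dplyr::left_join(dynamics, cohort[, c("subject_id", "group")],
                        by = "subject_id")
  k <- max(d$state)
  rows <- list()
  for (s in seq_len(k)) {
    ds <- dplyr::filter(d, .data$state == s)
    rows[[length(rows) + 1L]] <- mann_whitney(
      ds$occupancy[ds$group == "patient"], ds$occupancy[ds$group == "control"],
      measure = sprintf("occupancy_state%d", s))
    rows[[length(rows) + 1L]] <- mann_whitney(
      ds$dwell[ds$group == "patient"], ds$dwell[ds$group == "control"],
      measure = sprintf("dwell_state%d", s))
  }
  d1 <- dplyr::filter(d, .data$state == 1L)
  rows[[length(rows) + 1L]] <- mann_whitney(
    d1$n_transitions[d1$group == "patient"],
    d1$n_transitions[d1$group == "control"], measure = "n_transitions")
  dplyr::bind_rows(rows)
}

#' Spearman correlations of state-dynamics measures with EDSS (patients)
#'
#' @inheritParams compare_state_dynamics
#' @return Results tibble (rho, p) per measure, or a zero-row tibble when no
#'   patient has an EDSS score.
#' @export
correlate_dynamics_edss <- function(dynamics, cohort) {
  cohort <- validate_cohort(cohort, require_both_groups = FALSE)
  pat <- dplyr::filter(cohort, .data$group == "patient", !is.na(.data$edss))
  if (nrow(pat) < 3L) return(tibble::tibble())
  d <- dplyr::filter(dynamics, .data$subject_id %in% pat$subject_id)
  d <- dplyr::left_join(d, pat[, c("subject_id", "edss")], by = "subject_id")
  k <- max(d$state)
  rows <- list()
  for (s in seq_len(k)) {
    ds <- dplyr::filter(d, .data$state == s)
    if (sd(ds$occupancy) > 0 && sd(ds$edss) > 0) {
      rows[[length(rows) + 1L]] <- spearman(
        ds$occupancy, ds$edss, measure = sprintf("occupancy_state%d", s))
    }
    if (sd(ds$dwell) > 0 && sd(ds$edss) > 0) {
      rows[[length(rows) + 1L]] <- spearman(
        ds$dwell, ds$edss, measure = sprintf("dwell_state%d", s))
    }
  }
  d1 <- dplyr::filter(d, .data$state == 1L)
  if (sd(d1$n_transitions) > 0 && sd(d1$edss) > 0) {
    rows[[length(rows) + 1L]] <- spearman(d1$n_transitions, d1$edss,
                                          measure = "n_transitions")
  }
  dplyr::bind_rows(rows)
}

#' Group comparison of dynamic-topology AUC variance
#'
#' Global metric variances are compared uncorrected (Mann-Whitney); nodal
#' metric variances get Benjamini-Hochberg FDR across nodes within each
#' metric.
#'
#' @param topology List of `dynamic_topology` objects (one per subject).
#' @param cohort Cohort tibble.
#' @return List with `global` and `nodal` results tibbles.
#' @export
compare_topology_variance <- function(topology, cohort) {
  cohort <- validate_cohort(cohort)
  glob <- purrr::map_dfr(topology, function(tp) {
    dplyr::mutate(tp$variance_global, subject_id = tp$subject_id)
  }) %>%
    dplyr::left_join(cohort[, c("subject_id", "group")], by = "subject_id")
  safe_mw <- function(x, y, measure) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (!length(x) || !length(y)) {
      return(tibble::tibble(measure = measure, method = "mann-whitney",
                            statistic = NA_real_, p = NA_real_,
                            effect_size = NA_real_))
    }
    mann_whitney(x, y, measure = measure)
  }
  gtab <- glob %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::group_modify(~ safe_mw(
      .x$variance[.x$group == "patient"],
      .x$variance[.x$group == "control"],
      measure = paste0("var_auc_", .y$metric))) %>%
    dplyr::ungroup()
  nod <- purrr::map_dfr(topology, function(tp) {
    dplyr::mutate(tp$variance_nodal, subject_id = tp$subject_id)
  }) %>%
    dplyr::left_join(cohort[, c("subject_id", "group")], by = "subject_id")
  ntab <- nod %>%
    dplyr::group_by(.data$metric, .data$node) %>%
    dplyr::group_modify(~ safe_mw(
      .x$variance[.x$group == "patient"],
      .x$variance[.x$group == "control"],
      measure = sprintf("var_%s_node%d", .y$metric, .y$node))) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::mutate(fdr_q = bh_fdr(.data$p)) %>%
    dplyr::ungroup()
  list(global = gtab, nodal = ntab)
}

#' Human-readable report for a pipeline bundle
#'
#' Assembles the result surfaces into one list of tibbles — a Table-1-style
#' cohort table (pooled t / phi column), the per-state dynamics comparison
#' (medians, U, p, effect size), the EDSS correlation table and, when
#' present, the topology variance comparison — plus a plain-text rendering.
#' Sections whose inputs are absent are marked as such rather than dropped.
#'
#' @param bundle A `dynfc_bundle` from [run_pipeline()].
#' @return A `dynfc_report`: list with `cohort_table`, `state_table`,
#'   `correlation_table`, `topology_table`, `text`.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "dynfc_bundle"))
  cohort <- bundle$cohort
  pat <- dplyr::filter(cohort, .data$group == "patient")
  con <- dplyr::filter(cohort, .data$group == "control")
  rows <- list(
    t_test_from_summaries(x = pat$age, y = con$age, measure = "age"),
    t_test_from_summaries(x = pat$mean_fd, y = con$mean_fd,
                          measure = "mean_fd"))
  sex_tab <- rbind(table(factor(pat$sex, c("female", "male"))),
                   table(factor(con$sex, c("female", "male"))))
  if (all(colSums(sex_tab) > 0)) {
    rows[[length(rows) + 1L]] <- phi_coefficient(sex_tab, measure = "sex")
  }
  for (vol in c("gmv", "wmv", "tiv")) {
    if (all(!is.na(cohort[[vol]]))) {
      rows[[length(rows) + 1L]] <- t_test_from_summaries(
        x = pat[[vol]], y = con[[vol]], measure = vol)
    }
  }
  if (all(!is.na(cohort$gmv) & !is.na(cohort$wmv) & !is.na(cohort$tiv))) {
    bpf_p <- brain_parenchymal_fraction(pat$gmv, pat$wmv, pat$tiv)
    bpf_c <- brain_parenchymal_fraction(con$gmv, con$wmv, con$tiv)
    rows[[length(rows) + 1L]] <- t_test_from_summaries(x = bpf_p, y = bpf_c,
                                                       measure = "bpf")
  }
  cohort_table <- dplyr::bind_rows(rows)
  correlation_table <- if (nrow(bundle$edss_correlations %||% tibble::tibble())) {
    bundle$edss_correlations
  } else NULL
  topology_table <- bundle$topology_tests$global %||% NULL
  txt <- c(
    sprintf("Cohort: %d patients, %d controls", nrow(pat), nrow(con)),
    sprintf("States: K = %d%s", bundle$state_model$k,
            if (!is.null(bundle$elbow)) " (elbow-selected)" else " (fixed)"),
    "", "-- cohort table --", format_tibble(cohort_table),
    "", "-- state dynamics (patients vs controls) --",
    format_tibble(bundle$dynamics_tests),
    "", "-- EDSS correlations (patients) --",
    if (is.null(correlation_table)) "absent: no patient EDSS scores"
    else format_tibble(correlation_table),
    "", "-- dynamic topology variance --",
    if (is.null(topology_table)) "absent: topology stage not run"
    else format_tibble(topology_table))
  structure(list(cohort_table = cohort_table,
                 state_table = bundle$dynamics_tests,
                 correlation_table = correlation_table,
                 topology_table = topology_table,
                 text = paste(txt, collapse = "\n")),
            class = "dynfc_report")
}

format_tibble <- function(x) paste(utils::capture.output(print(as.data.frame(x))),
                                   collapse = "\n")

#' @export
print.dynfc_report <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
print.dynfc_bundle <- function(x, ...) {
  cat(sprintf("<dynfc_bundle> %d subjects, K = %d states; stages: postproc, %sdfnc, states%s\n",
              nrow(x$cohort), x$state_model$k,
              if (!is.null(x$sfnc)) "sfnc, " else "",
              if (!is.null(x$topology)) ", topology" else ""))
  invisible(x)
}
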