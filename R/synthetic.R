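#' Synthetic-cohort configuration
#'
#' Assembles and validates the generative assumptions behind the synthetic
#' cohort: Markov switching among `k_true` connectivity states at time-point
#' resolution, a block-structured covariance per state built from
#' network-pair correlation levels, polynomial drift, motion contamination
#' and observation noise, and a disability (EDSS-like) score coupled to the
#' true occupancy of the low-connectivity state. Every parameter here is a
#' generative stand-in chosen to mimic the statistical structure the
#' downstream analysis assumes, not an estimate from any real cohort; see the
#' methods vignette for the rationale behind each default.
#'
#' Defaults mirror the study conditions the pipeline targets: 30 patients vs
#' 45 controls, C = 43 components in 8 networks, T = 230 volumes at TR = 2 s,
#' three true states (low / moderate / strong), a patient transition matrix
#' biased toward the low state with stickier diagonals (fewer transitions),
#' and sex/age distributions matching the cohort table the analysis emulates.
#'
#' @param n_patient,n_control Group sizes.
#' @param network_sizes Named integer vector giving components per network
#'   (names from DMN, SMN, ADN, VIS, ATN, FPN, SCN, CN); sums to C.
#' @param n_timepoints,tr Series length and repetition time (seconds).
#' @param k_true Number of planted states.
#' @param block_correlations List (length `k_true`) of block-correlation
#'   specs; each is a list with `within` (named per-network or single
#'   default), `between` (default level), and optional `pairs` (named list
#'   "NETA.NETB" -> level).
#' @param transition_patient,transition_control K x K row-stochastic
#'   matrices with strictly positive diagonals.
#' @param drift_amplitude,motion_scale,observation_noise_sd Nonnegative
#'   nuisance scales.
#' @param edss_coupling Numeric `c(intercept, slope, noise_sd)`; patient
#'   EDSS = intercept + slope * (true low-state occupancy) + noise, clipped
#'   to the 0-10 half-point grid.
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_patient = 30L, n_control = 45L,
    network_sizes = c(DMN = 9L, SMN = 6L, ADN = 2L, VIS = 7L, ATN = 7L,
                      FPN = 5L, SCN = 3L, CN = 4L),
    n_timepoints = 230L, tr = 2,
    k_true = 3L,
    block_correlations = default_block_correlations(),
    transition_patient = default_transition_matrix("patient"),
    transition_control = default_transition_matrix("control"),
    drift_amplitude = 0.4, motion_scale = 0.01, observation_noise_sd = 0.2,
    edss_coupling = c(intercept = 0, slope = 6, noise_sd = 0.8),
    seed = 1L) {
  stopifnot(n_patient >= 1L, n_control >= 1L, k_true >= 1L,
            n_timepoints >= 2L, tr > 0,
            drift_amplitude >= 0, motion_scale >= 0, observation_noise_sd >= 0,
            length(edss_coupling) == 3L,
            length(block_correlations) == k_true)
  stopifnot(all(names(network_sizes) %in% RSN_NAMES))
  check_transition_matrix(transition_patient, k_true)
  check_transition_matrix(transition_control, k_true)
  labels <- rep(names(network_sizes), network_sizes)
  structure(list(
    n_patient = as.integer(n_patient), n_control = as.integer(n_control),
    network_sizes = network_sizes, network_labels = labels,
    n_components = length(labels),
    n_timepoints = as.integer(n_timepoints), tr = tr,
    k_true = as.integer(k_true),
    block_correlations = block_correlations,
    transition_patient = transition_patient,
    transition_control = transition_control,
    drift_amplitude = drift_amplitude, motion_scale = motion_scale,
    observation_noise_sd = observation_noise_sd,
    edss_coupling = as.numeric(edss_coupling),
    seed = as.integer(seed)), class = "synthetic_config")
}

check_transition_matrix <- function(P, k) {
  if (!is.matrix(P) || nrow(P) != k || ncol(P) != k) {
    abort(sprintf("transition matrix must be %d x %d", k, k),
          class = "dynfc_validation_error")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    abort("transition matrix rows must be nonnegative and sum to 1",
          class = "dynfc_validation_error")
  }
  if (any(diag(P) <= 0)) {
    abort("transition matrix needs strictly positive diagonal",
          class = "dynfc_validation_error")
  }
  invisible(P)
}

#' @rdname synthetic_config
#' @export
default_block_correlations <- function() {
  list(
    low = list(within = 0.05, between = 0),
    moderate = list(within = 0.05, between = 0,
                    within_override = c(DMN = 0.6, VIS = 0.6, ATN = 0.6)),
    strong = list(within = 0.6, between = 0.05,
                  pairs = list(VIS.FPN = -0.4, VIS.SCN = -0.4)))
}

#' @rdname synthetic_config
#' @param group `"patient"` or `"control"`.
#' @export
default_transition_matrix <- function(group = c("patient", "control")) {
  group <- match.arg(group)
  if (group == "patient") {
    # sticky, biased toward the low state (stationary ~0.70/0.17/0.13,
    # ~4 expected transitions over 230 TR)
    matrix(c(0.990, 0.007, 0.003,
             0.025, 0.962, 0.013,
             0.020, 0.013, 0.967), 3, 3, byrow = TRUE)
  } else {
    # controls favour the moderate state and switch more often
    # (stationary ~0.21/0.55/0.24, ~6 expected transitions)
    matrix(c(0.970, 0.025, 0.005,
             0.009, 0.979, 0.012,
             0.006, 0.026, 0.968), 3, 3, byrow = TRUE)
  }
}

#' Build a block-structured state covariance template
#'
#' Constructs a C x C correlation matrix with the requested level in each
#' within- and between-network block (unit diagonal). If the result is not
#' positive definite it is shrunk toward the identity by the smallest factor
#' (binary search to tolerance 1e-6) that brings the minimum eigenvalue to at
#' least 1e-6.
#'
#' @param block_correlations A list with `within` (single default level or
#'   named per-network vector), `between` (default off-block level),
#'   optional `within_override` (named per-network) and `pairs` (named list
#'   `"NETA.NETB"` -> level) for specific network pairs.
#' @param network_labels Character vector of C network labels.
#' @return A `state_template`: list with `covariance` (C x C, unit diagonal,
#'   positive definite), `shrinkage` (factor applied, 0 if none) and
#'   `label` (if present in `block_correlations`).
#' @export
build_state_covariance <- function(block_correlations, network_labels) {
  C <- length(network_labels)
  nets <- unique(network_labels)
  within_default <- block_correlations$within %||% 0
  between_default <- block_correlations$between %||% 0
  override <- block_correlations$within_override %||% c()
  pairs <- block_correlations$pairs %||% list()
  lvl <- function(a, b) {
    if (a == b) {
      if (a %in% names(override)) return(override[[a]])
      if (is.numeric(within_default) && !is.null(names(within_default)) &&
          a %in% names(within_default)) return(within_default[[a]])
      return(unname(within_default[1L]))
    }
    key1 <- paste(a, b, sep = "."); key2 <- paste(b, a, sep = ".")
    if (key1 %in% names(pairs)) return(pairs[[key1]])
    if (key2 %in% names(pairs)) return(pairs[[key2]])
    between_default
  }
  R <- matrix(0, C, C)
  for (a in nets) for (b in nets) {
    R[network_labels == a, network_labels == b] <- lvl(a, b)
  }
  diag(R) <- 1
  if (any(abs(R[upper.tri(R)]) >= 1)) {
    abort("block correlations must have absolute value < 1",
          class = "dynfc_domain_error")
  }
  shrink <- 0
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    lo <- 0; hi <- 1
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      Rm <- (1 - mid) * R + mid * diag(C)
      if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) >= 1e-6)
        hi <- mid else lo <- mid
    }
    shrink <- hi
    R <- (1 - shrink) * R + shrink * diag(C)
  }
  structure(list(covariance = R, shrinkage = shrink,
                 label = block_correlations$label),
            class = "state_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a Markov state sequence
#'
#' First state drawn from the stationary distribution of the transition
#' matrix; Markov chain thereafter. Reproducible for a fixed seed.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param n_steps Sequence length (>= 1).
#' @param seed Integer seed (NULL = use the current RNG stream).
#' @return Integer vector of states in 1..K.
#' @export
simulate_state_sequence <- function(transition_matrix, n_steps, seed = NULL) {
  P <- as.matrix(transition_matrix)
  k <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-9) || any(P < 0)) {
    abort("transition matrix rows must sum to 1", class = "dynfc_validation_error")
  }
  stopifnot(n_steps >= 1L)
  pi0 <- stationary_distribution(P)
  sim <- function() {
    s <- integer(n_steps)
    s[1L] <- sample.int(k, 1L, prob = pi0)
    if (n_steps > 1L) for (t in 2L:n_steps) {
      s[t] <- sample.int(k, 1L, prob = P[s[t - 1L], ])
    }
    s
  }
  if (is.null(seed)) sim() else withr_seed(seed, sim())
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P K x K row-stochastic matrix (irreducible).
#' @return Probability vector of length K.
#' @export
stationary_distribution <- function(P) {
  k <- nrow(P)
  e <- eigen(t(P))
  idx <- which.min(abs(e$values - 1))
  pi0 <- Re(e$vectors[, idx])
  pi0 <- abs(pi0)
  if (sum(pi0) < .Machine$double.eps) pi0 <- rep(1, k)
  pi0 / sum(pi0)
}

#' Generate one synthetic subject
#'
#' Emissions at each time point are drawn from a zero-mean multivariate
#' normal with the covariance of the current planted state; a random cubic
#' drift of amplitude `drift_amplitude` and white observation noise are
#' added. Motion columns are mean-reverting bounded random walks scaled by
#' `motion_scale`. For patients, the EDSS-like score is `intercept + slope *
#' (true low-state occupancy) + noise`, clipped to the 0-10 half-point grid;
#' controls get `NA`.
#'
#' @param config A [synthetic_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_id Identifier string.
#' @param seed Integer seed for this subject.
#' @param templates Optional precomputed list of state templates (as from
#'   [build_state_covariance()]), to avoid rebuilding per subject.
#' @return List with `timecourses` ([tc_set()]), `motion` (T x 6 matrix),
#'   `states` (true state sequence at time-point resolution), and `record`
#'   (one-row tibble of subject metadata, mean FD computed from the motion).
#' @export
generate_subject <- function(config, group, subject_id, seed,
                             templates = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            group %in% c("patient", "control"))
  if (is.null(templates)) {
    templates <- lapply(config$block_correlations, build_state_covariance,
                        network_labels = config$network_labels)
  }
  chol_list <- lapply(templates, function(tmpl) chol(tmpl$covariance))
  T_ <- config$n_timepoints
  C <- config$n_components
  P <- if (group == "patient") config$transition_patient else
    config$transition_control
  withr_seed(seed, {
    states <- simulate_state_sequence(P, T_)
    E <- matrix(rnorm(T_ * C), T_, C)
    X <- matrix(NA_real_, T_, C)
    for (s in unique(states)) {
      idx <- states == s
      X[idx, ] <- E[idx, , drop = FALSE] %*% chol_list[[s]]
    }
    # random cubic drift per component, amplitude-scaled
    tv <- seq(-1, 1, length.out = T_)
    B <- cbind(tv, tv^2, tv^3)
    X <- X + config$drift_amplitude *
      (B %*% matrix(rnorm(3L * C), 3L, C))
    X <- X + config$observation_noise_sd * matrix(rnorm(T_ * C), T_, C)
    # mean-reverting random walk motion (AR(1), phi = 0.98), bounded scale
    motion <- vapply(seq_len(6L), function(j) {
      as.numeric(stats::arima.sim(list(ar = 0.98), T_,
                                  sd = config$motion_scale))
    }, numeric(T_))
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    motion[, 4:6] <- motion[, 4:6] / 50  # rotations on a comparable arc scale
    occ_low <- mean(states == 1L)
    edss <- NA_real_
    if (group == "patient") {
      cpl <- config$edss_coupling
      raw <- cpl[1L] + cpl[2L] * occ_low + rnorm(1L, sd = cpl[3L])
      edss <- min(10, max(0, round(raw * 2) / 2))
    }
    # demographics emulating the target cohort's composition
    p_male <- if (group == "patient") 3 / 30 else 12 / 45
    sex <- if (runif(1L) < p_male) "male" else "female"
    age_mu <- if (group == "patient") 37.70 else 41.84
    age_sd <- if (group == "patient") 11.99 else 11.23
    age <- min(65, max(18, rnorm(1L, age_mu, age_sd)))
    tiv_mu <- if (group == "patient") 1341.7 else 1385.07
    gmv_mu <- if (group == "patient") 571.67 else 593.47
    wmv_mu <- if (group == "patient") 475.88 else 510.86
    tiv <- rnorm(1L, tiv_mu, 105)
    gmv <- rnorm(1L, gmv_mu, 45)
    wmv <- rnorm(1L, wmv_mu, 48)
    if (gmv + wmv > tiv) tiv <- gmv + wmv + abs(rnorm(1L, 250, 30))
  })
  tc <- tc_set(X, tr = config$tr, network_labels = config$network_labels,
               subject_id = subject_id)
  record <- tibble::tibble(
    subject_id = subject_id, group = group, age = age, sex = sex,
    mean_fd = as.numeric(mean_framewise_displacement(motion)),
    edss = edss, gmv = gmv, wmv = wmv, tiv = tiv,
    lesion_volume = NA_real_)
  list(timecourses = tc, motion = motion, states = states, record = record)
}

#' Generate a complete synthetic cohort
#'
#' Generates `n_patient + n_control` subjects with per-subject seeds derived
#' deterministically from the master seed. Optionally writes all on-disk
#' artefacts (time courses, motion, metadata CSV, labels CSV and a truth
#' file with run-length-encoded true state sequences and true occupancies).
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; created if missing.
#' @return A `synthetic_cohort`: list with `cohort` (metadata tibble),
#'   `subjects` (list of [generate_subject()] results), `truth` (tibble:
#'   subject_id, true occupancy per state, run-length-encoded sequence) and
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  templates <- lapply(config$block_correlations, build_state_covariance,
                      network_labels = config$network_labels)
  n <- config$n_patient + config$n_control
  groups <- rep(c("patient", "control"), c(config$n_patient, config$n_control))
  ids <- sprintf("%s%02d", ifelse(groups == "patient", "pat", "con"),
                 c(seq_len(config$n_patient), seq_len(config$n_control)))
  if (anyDuplicated(ids)) abort("duplicate derived subject ids",
                                class = "dynfc_internal_error")
  seeds <- (config$seed + 104729L * seq_len(n)) %% .Machine$integer.max
  subjects <- purrr::map(seq_len(n), function(i) {
    generate_subject(config, groups[i], ids[i], seed = seeds[i],
                     templates = templates)
  })
  names(subjects) <- ids
  cohort <- dplyr::bind_rows(purrr::map(subjects, "record"))
  truth <- purrr::map_dfr(subjects, function(s) {
    occ <- tabulate(s$states, nbins = config$k_true) / length(s$states)
    r <- rle(s$states)
    tibble::tibble(
      subject_id = s$record$subject_id,
      !!!setNames(as.list(occ), paste0("occupancy_", seq_len(config$k_true))),
      states_rle = paste(sprintf("%dx%d", r$values, r$lengths),
                         collapse = ";"))
  })
  out <- structure(list(cohort = cohort, subjects = subjects, truth = truth,
                        config = config, templates = templates),
                   class = "synthetic_cohort")
  if (!is.null(dir)) write_synthetic_cohort(out, dir)
  out
}

#' @rdname generate_cohort
#' @param x A `synthetic_cohort`.
#' @export
write_synthetic_cohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timecourses"), showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  write_cohort(x$cohort, file.path(dir, "metadata.csv"))
  readr::write_csv(tibble::tibble(
    component_id = x$subjects[[1L]]$timecourses$component_ids,
    network = x$subjects[[1L]]$timecourses$network_labels),
    file.path(dir, "labels.csv"))
  for (s in x$subjects) {
    id <- s$record$subject_id
    write_timecourses(s$timecourses,
                      file.path(dir, "timecourses", paste0(id, ".tsv")))
    write_matrix(s$motion, file.path(dir, "motion", paste0(id, ".tsv")))
  }
  readr::write_csv(x$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Ground-truth state labels on the window grid
#'
#' The generator switches states at time-point resolution, so a sliding
#' window can straddle a transition and has no single true state. This
#' helper labels each window placement with its modal true state, and only
#' when that state occupies at least `min_fraction` of the window (windows
#' more mixed than that get `NA`: their truth is undefined). It is the
#' reference against which window-level assignment accuracy is measured.
#'
#' @param states True state sequence at time-point resolution.
#' @param spec A [make_window_spec()] consistent with `length(states)`.
#' @param min_fraction Minimum dominant-state fraction for a window to carry
#'   a truth label (default 0.75; use 0 to label every window modally).
#' @return Integer vector of length `spec$n_windows` (NA where undefined),
#'   with attribute `dominant_fraction`.
#' @export
window_truth_states <- function(states, spec, min_fraction = 0.75) {
  stopifnot(inherits(spec, "window_spec"),
            max(spec$starts) + spec$effective_length - 1L <= length(states))
  dom <- numeric(spec$n_windows)
  lab <- integer(spec$n_windows)
  for (w in seq_len(spec$n_windows)) {
    seg <- states[spec$starts[w]:(spec$starts[w] + spec$effective_length - 1L)]
    tab <- tabulate(seg)
    lab[w] <- which.max(tab)
    dom[w] <- max(tab) / length(seg)
  }
  lab[dom < min_fraction] <- NA_integer_
  structure(lab, dominant_fraction = dom)
}

#' Decode a run-length-encoded state sequence from a truth file
#'
#' @param rle_string String of `state x length` runs, `;`-separated, e.g.
#'   `"1x12;2x5;1x3"`.
#' @return Integer state sequence.
#' @export
decode_states_rle <- function(rle_string) {
  parts <- strsplit(rle_string, ";", fixed = TRUE)[[1L]]
  m <- do.call(rbind, strsplit(parts, "x", fixed = TRUE))
  rep(as.integer(m[, 1L]), as.integer(m[, 2L]))
}
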