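test_that("block covariance templates honour requested levels and stay positive definite", {
  labels <- rep(c("DMN", "VIS"), each = 2)

  ident <- build_state_covariance(list(within = 0, between = 0), labels)
  expect_equal(ident$covariance, diag(4))

  blk <- build_state_covariance(list(within = 0.5, between = 0), labels)
  expect_equal(sort(eigen(blk$covariance, only.values = TRUE)$values),
               c(0.5, 0.5, 1.5, 1.5))
  expect_equal(blk$covariance[1, 2], 0.5)
  expect_equal(blk$covariance[1, 3], 0)

  # triangle-violating template must be shrunk to positive definiteness
  lab3 <- rep(c("DMN", "VIS", "CN"), each = 2)
  hot <- build_state_covariance(
    list(within = 0.9, between = 0,
         pairs = list(DMN.VIS = 0.9, VIS.CN = 0.9, DMN.CN = -0.9)), lab3)
  expect_gt(hot$shrinkage, 0)
  expect_gte(min(eigen(hot$covariance, only.values = TRUE)$values), 1e-6)
  expect_equal(diag(hot$covariance), rep(1, 6))

  expect_error(build_state_covariance(list(within = 1.0), labels),
               class = "dynfc_domain_error")
})

test_that("Markov state sequences reproduce dwell and occupancy structure", {
  # absorbing chain: constant sequence
  expect_equal(unique(simulate_state_sequence(diag(3), 50, seed = 1)),
               simulate_state_sequence(diag(3), 1, seed = 1))

  # uniform chain: empirical frequencies near 1/3
  P <- matrix(1 / 3, 3, 3)
  s <- simulate_state_sequence(P, 30000, seed = 2)
  expect_true(all(abs(tabulate(s, 3) / 30000 - 1 / 3) < 0.02))

  # sticky two-state chain: geometric dwell with mean 1/(1-0.9) = 10
  P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  s2 <- simulate_state_sequence(P2, 50000, seed = 3)
  expect_lt(abs(mean(rle(s2)$lengths) - 10), 0.3)

  expect_error(simulate_state_sequence(matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2), 5),
               class = "dynfc_validation_error")
})

test_that("stationarity: empirical frequencies converge to the stationary distribution", {
  P <- default_transition_matrix("control")
  s <- simulate_state_sequence(P, 1e5, seed = 11)
  expect_true(all(abs(tabulate(s, 3) / 1e5 - stationary_distribution(P)) < 0.01))
})

test_that("noise-free single-state emissions recover the template covariance", {
  cfg <- synthetic_config(
    n_patient = 1, n_control = 1,
    network_sizes = c(DMN = 3L, VIS = 3L), n_timepoints = 5000,
    k_true = 1L,
    block_correlations = list(low = list(within = 0, between = 0)),
    transition_patient = matrix(1, 1, 1),
    transition_control = matrix(1, 1, 1),
    drift_amplitude = 0, motion_scale = 0, observation_noise_sd = 0)
  sub <- generate_subject(cfg, "patient", "p1", seed = 4)
  expect_true(all(abs(cov(sub$timecourses$data) - diag(6)) < 0.1))
})

test_that("subject generation is byte-identical for a fixed seed", {
  cfg <- small_config()
  a <- generate_subject(cfg, "patient", "p1", seed = 42)
  b <- generate_subject(cfg, "patient", "p1", seed = 42)
  expect_identical(a$timecourses$data, b$timecourses$data)
  expect_identical(a$motion, b$motion)
  expect_identical(a$states, b$states)
  expect_identical(a$record, b$record)
  c_ <- generate_subject(cfg, "patient", "p1", seed = 43)
  expect_false(identical(a$timecourses$data, c_$timecourses$data))
})

test_that("zero EDSS slope decouples disability from low-state occupancy", {
  cfg <- small_config(edss_coupling = c(3, 0, 0.7))
  recs <- purrr::map_dfr(1:40, function(i) {
    s <- generate_subject(cfg, "patient", paste0("p", i), seed = 100 + i)
    tibble::tibble(edss = s$record$edss, occ = mean(s$states == 1))
  })
  expect_lt(abs(cor(recs$edss, recs$occ, method = "spearman")), 0.3)
})

test_that("positive EDSS slope induces positive occupancy-disability correlation in nearly all cohorts", {
  # 100 seeded patient batches; rho > 0 must hold in at least 95
  signs <- vapply(1:100, function(b) {
    cfg <- small_config(seed = b)
    d <- purrr::map_dfr(1:12, function(i) {
      s <- generate_subject(cfg, "patient", paste0("p", i),
                            seed = b * 1000 + i)
      tibble::tibble(edss = s$record$edss, occ = mean(s$states == 1))
    })
    cor(d$occ, d$edss, method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("cohort generation writes a complete, reproducible set of artefacts", {
  cfg <- small_config(seed = 7)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, dir = dir)
  expect_equal(nrow(co$cohort), 8)
  expect_equal(sum(co$cohort$group == "patient"), 4)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_equal(length(list.files(file.path(dir, "timecourses"))), 8)
  expect_equal(length(list.files(file.path(dir, "motion"))), 8)

  # truth file decodes to the generated sequences and occupancies
  tr <- readr::read_csv(file.path(dir, "truth.csv"),
                        show_col_types = FALSE)
  s1 <- decode_states_rle(tr$states_rle[1])
  expect_identical(s1, co$subjects[[1]]$states)
  expect_equal(tr$occupancy_1[1], mean(s1 == 1))

  # same master seed, same truth
  co2 <- generate_cohort(cfg)
  expect_identical(co$truth, co2$truth)

  # controls carry no EDSS; patients lie on the half-point grid
  expect_true(all(is.na(co$cohort$edss[co$cohort$group == "control"])))
  e <- co$cohort$edss[co$cohort$group == "patient"]
  expect_true(all(abs(e * 2 - round(e * 2)) < 1e-9))
})

test_that("minimal one-vs-one cohort generates and writes", {
  cfg <- synthetic_config(
    n_patient = 1, n_control = 1,
    network_sizes = c(DMN = 2L, VIS = 2L), n_timepoints = 40,
    block_correlations = list(low = list(within = 0.05),
                              moderate = list(within = 0.3),
                              strong = list(within = 0.6)),
    seed = 3)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, dir = dir)
  expect_equal(nrow(co$cohort), 2)
  expect_equal(length(list.files(file.path(dir, "timecourses"))), 2)
})

test_that("window truth labels mark mixed windows as undefined", {
  states <- c(rep(1L, 40), rep(2L, 40))
  spec <- make_window_spec(80, 10, 1)
  lab <- window_truth_states(states, spec, min_fraction = 0.75)
  expect_equal(lab[1], 1L)
  expect_equal(lab[length(lab)], 2L)
  # windows centred on the transition have no truth
  expect_true(anyNA(lab))
  dom <- attr(lab, "dominant_fraction")
  expect_true(all(dom >= 0.5 & dom <= 1))
  # with min_fraction 0 every window is labelled modally
  expect_false(anyNA(window_truth_states(states, spec, min_fraction = 0)))
})

test_that("long-series occupancy recovery: pipeline estimates match time-point truth within 0.05", {
  # well-separated templates (active blocks 0.6 vs background 0.05) and slow
  # switching, T = 2000: the window estimator must recover each subject's
  # per-state occupancy from the raw generated data
  P <- matrix(c(0.990, 0.005, 0.005,
                0.005, 0.990, 0.005,
                0.005, 0.005, 0.990), 3, 3, byrow = TRUE)
  cfg <- synthetic_config(n_patient = 2, n_control = 1, n_timepoints = 2000,
                          transition_patient = P, transition_control = P,
                          seed = 3)
  co <- generate_cohort(cfg)
  spec <- make_window_spec(2000, 30, 1)
  windows <- lapply(co$subjects, function(s) {
    tc <- postprocess_timecourses(s$timecourses, s$motion)
    windowed_connectivity(tc, spec, lambda_grid = 0)
  })
  m <- kmeans_states(unname(windows), 3, n_replicates = 2, seed = 5,
                     tol_changes = 3L)
  truth_modal <- unlist(lapply(co$subjects, function(s) {
    window_truth_states(s$states, spec, min_fraction = 0)
  }))
  perm <- match_state_labels(m$labels, truth_modal, 3)$perm
  m <- relabel_states(m, perm)
  offs <- c(0, cumsum(rep(spec$n_windows, length(co$subjects))))
  for (s in 1:3) {
    errs <- vapply(seq_along(co$subjects), function(i) {
      est <- mean(m$labels[(offs[i] + 1):offs[i + 1]] == s)
      est - mean(co$subjects[[i]]$states == s)
    }, numeric(1))
    expect_lte(max(abs(errs)), 0.05)
  }
})
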