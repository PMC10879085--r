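test_that("city-block k-means separates planted clouds perfectly", {
  withr::with_seed(1, {
    a <- matrix(rnorm(40 * 6), 40, 6)
    b <- matrix(rnorm(40 * 6) + 10, 40, 6)
    m <- kmeans_states(rbind(a, b), 2, seed = 7)
    first <- m$labels[1]
    expect_true(all(m$labels[1:40] == first))
    expect_true(all(m$labels[41:80] == (3 - first)))
  })
})

test_that("degenerate clusterings behave exactly", {
  withr::with_seed(2, {
    X <- matrix(rnorm(5 * 3), 5, 3)
    m <- kmeans_states(X, 5, seed = 1)
    expect_equal(m$tot_within, 0)
    expect_equal(sort(m$labels), 1:5)

    dup <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
    m1 <- kmeans_states(dup, 1, seed = 1)
    expect_equal(as.numeric(m1$centroids), c(1, 2, 3))
    expect_equal(m1$tot_within, 0)
  })
})

test_that("k-means matches the exhaustive optimum on tiny instances", {
  withr::with_seed(3, {
    for (i in 1:50) {
      n <- sample(5:8, 1)
      k <- sample(2:3, 1)
      X <- matrix(rnorm(n * 2), n, 2)
      fit <- kmeans_states(X, k, n_replicates = 50, seed = i)
      opt <- brute_force_l1_within(X, k)
      expect_lte(fit$tot_within, opt * 1.05 + 1e-9)
    }
  })
})

test_that("elbow criterion recovers three planted clusters and warns on no structure", {
  withr::with_seed(4, {
    mk_cloud <- function(center, n) {
      sweep(matrix(rnorm(n * 8, sd = 0.3), n, 8), 2, center, "+")
    }
    X <- rbind(mk_cloud(rep(0, 8), 60), mk_cloud(rep(4, 8), 60),
               mk_cloud(rep(c(0, 6), each = 4), 60))
    el <- elbow_select_k(X, k_range = 2:6, seed = 5)
    expect_equal(el$k, 3)
    expect_equal(el$elbow_curve$k, 2:6)
    expect_true(all(diff(el$elbow_curve$within) < 0))

    same <- matrix(1, 20, 4)
    expect_warning(el2 <- elbow_select_k(same, k_range = 2:4, seed = 5),
                   "flat elbow")
    expect_equal(el2$k, 2)
  })
})

test_that("state dynamics match hand-enumerated values", {
  d <- state_dynamics(c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3), k = 3)
  expect_equal(d$occupancy, c(0.2, 0.3, 0.5))
  expect_equal(d$dwell, c(2, 3, 5))
  expect_equal(unique(d$n_transitions), 2)

  const <- state_dynamics(rep(2L, 198), k = 3, step_tr = 1, tr = 2)
  expect_equal(const$occupancy, c(0, 1, 0))
  expect_equal(const$dwell, c(0, 198, 0))
  expect_equal(const$dwell_seconds, c(0, 396, 0))
  expect_equal(unique(const$n_transitions), 0)

  alt <- state_dynamics(rep(c(1L, 2L), 5), k = 2)
  expect_equal(unique(alt$n_transitions), 9)
  expect_equal(alt$dwell, c(1, 1))

  expect_error(state_dynamics(integer(0), 2), class = "dynfc_domain_error")
  expect_error(state_dynamics(c(1, 4), 3), class = "dynfc_domain_error")
})

test_that("occupancy sums to one and runs account for every window", {
  withr::with_seed(6, {
    for (i in 1:25) {
      W <- sample(5:60, 1)
      k <- sample(2:4, 1)
      a <- sample(seq_len(k), W, replace = TRUE)
      d <- state_dynamics(a, k)
      expect_equal(sum(d$occupancy), 1)
      runs <- rle(a)
      n_runs <- vapply(seq_len(k), function(s) sum(runs$values == s),
                       numeric(1))
      expect_equal(sum(d$dwell * n_runs), W)
      expect_lte(unique(d$n_transitions), W - 1)
    }
  })
})

test_that("permuting state labels permutes the dynamics and keeps transitions", {
  withr::with_seed(7, {
    a <- sample(1:3, 40, replace = TRUE)
    d <- state_dynamics(a, 3)
    perm <- c(3, 1, 2)     # old state perm[s] becomes new state s
    inv <- order(perm)
    d2 <- state_dynamics(inv[a], 3)
    expect_equal(d2$occupancy, d$occupancy[perm])
    expect_equal(d2$dwell, d$dwell[perm])
    expect_equal(unique(d2$n_transitions), unique(d$n_transitions))
  })
})

test_that("state relabelling by connectivity strength orders centroids low to strong", {
  withr::with_seed(8, {
    lows <- matrix(rnorm(30 * 5, sd = 0.1), 30, 5)
    highs <- matrix(rnorm(30 * 5, 1.5, sd = 0.1), 30, 5)
    m <- kmeans_states(rbind(highs, lows), 2, seed = 2)
    m2 <- relabel_states(m, state_strength_order(m))
    expect_lt(mean(abs(m2$centroids[1, ])), mean(abs(m2$centroids[2, ])))
    expect_true(all(m2$labels[31:60] == 1))
  })
})

test_that("label matching finds the exact best permutation", {
  truth <- c(1, 1, 2, 2, 3, 3)
  est <- c(3, 3, 1, 1, 2, 2)   # relabelled truth
  mm <- match_state_labels(est, truth, 3)
  expect_equal(mm$accuracy, 1)
  inv <- order(mm$perm)
  expect_equal(inv[est], truth)
})

test_that("per-subject prevalence counts subjects entering each state", {
  z <- matrix(rnorm(8), 4, 2)
  mk_w <- function(id, z) structure(list(subject_id = id, z = z,
                                         starts = 1:4, spec = NULL,
                                         lambda_selected = 0),
                                    class = "windowed_fnc")
  model <- structure(list(
    k = 3L, centroids = matrix(0, 3, 2),
    labels = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L),
    assignments = list(a = c(1L, 1L, 2L, 2L), b = c(1L, 1L, 1L, 1L)),
    tot_within = 0, subject_ids = c("a", "b"), n_windows = c(4L, 4L)),
    class = "state_model")
  cohort <- tibble::tibble(
    subject_id = c("a", "b"), group = c("patient", "control"),
    age = c(40, 41), sex = c("female", "male"), mean_fd = c(0.02, 0.03),
    edss = c(2, NA))
  prev <- subject_state_prevalence(model, cohort)
  expect_equal(nrow(prev), 6)
  expect_equal(prev$prevalence[prev$group == "patient"], c(1, 1, 0))
  expect_equal(prev$prevalence[prev$group == "control"], c(1, 0, 0))
})

test_that("tidiers expose the model as tibbles", {
  withr::with_seed(9, {
    m <- kmeans_states(matrix(rnorm(60), 20, 3), 2, seed = 1)
    td <- tidy(m)
    expect_equal(nrow(td), 2 * 3)
    gl <- glance(m)
    expect_equal(gl$k, 2)
    expect_equal(gl$n_windows, 20)
  })
})
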