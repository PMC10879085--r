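test_that("static connectivity yields 903 Fisher-z pairs for 43 components", {
  tc <- make_tc(T_ = 50, C = 43, seed = 2,
                labels = rep(c("DMN", "SMN", "ADN", "VIS",
                               "ATN", "FPN", "SCN", "CN"), length.out = 43))
  z <- compute_sfnc(tc)
  expect_equal(nrow(z), 903)
  expect_true(all(is.finite(z$z)))
})

test_that("static connectivity flags degenerate components", {
  withr::with_seed(3, {
    x <- rnorm(40)
    tc <- tc_set(cbind(x, x, rnorm(40)), tr = 2,
                 network_labels = c("DMN", "DMN", "VIS"))
    expect_error(compute_sfnc(tc), class = "dynfc_domain_error")
    tc0 <- tc_set(cbind(rnorm(40), rep(2, 40)), tr = 2,
                  network_labels = c("DMN", "VIS"))
    expect_error(compute_sfnc(tc0), class = "dynfc_domain_error")
  })
})

test_that("independent components give near-zero Fisher z at long T", {
  tc <- make_tc(T_ = 5000, C = 4, seed = 4)
  expect_lt(max(abs(compute_sfnc(tc)$z)), 0.05)
})

test_that("window spec reproduces the 198-window count and its edge cases", {
  spec <- make_window_spec(230, 30, 1)
  expect_equal(spec$n_windows, 198)
  expect_length(spec$taper, 33)
  expect_equal(sum(spec$taper), 1)
  expect_equal(spec$taper, rev(spec$taper))  # symmetric

  expect_equal(make_window_spec(33, 30, 1)$n_windows, 1)
  expect_error(make_window_spec(32, 30, 1), class = "dynfc_domain_error")
})

test_that("window count formula agrees with brute-force placement enumeration", {
  withr::with_seed(6, {
    for (i in 1:200) {
      T_ <- sample(34:300, 1)
      width <- sample(5:min(60, T_ - 3), 1)
      step <- sample(1:4, 1)
      eff <- width + 3
      brute <- sum(seq(1, T_, by = step) + eff - 1 <= T_)
      if (brute < 1) next
      expect_equal(make_window_spec(T_, width, step)$n_windows, brute)
    }
  })
})

test_that("graphical lasso satisfies its optimality conditions and limits", {
  withr::with_seed(10, {
    X <- matrix(rnorm(400 * 6), 400, 6)
    X[, 2] <- X[, 1] * 0.6 + rnorm(400, sd = 0.8)
    S <- cov(X)

    # huge penalty: complete shrinkage, no off-diagonal partial correlation
    f_big <- glasso_fit(S, 100)
    expect_lt(max(abs(f_big$theta[upper.tri(f_big$theta)])), 1e-8)

    # zero penalty: exact unpenalised MLE (the sample covariance)
    f0 <- glasso_fit(S, 0)
    expect_equal(f0$w, S)
    expect_lt(max(abs(f0$theta %*% S - diag(6))), 1e-8)

    # moderate penalty: KKT conditions of the graphical-lasso objective
    lam <- 0.08
    f <- glasso_fit(S, lam)
    expect_equal(diag(f$w), diag(S) + lam)
    off <- upper.tri(S)
    expect_lte(max(abs((f$w - S)[off])), lam + 1e-6)
    active <- off & abs(f$theta) > 1e-7
    if (any(active)) {
      # where theta is nonzero, |w - s| must sit on the lambda boundary
      expect_lt(max(abs(abs((f$w - S)[active]) - lam)), 1e-4)
    }
    expect_gt(min(eigen(f$theta, only.values = TRUE)$values), 0)
  })
})

test_that("windowed connectivity shrinks to zero under a huge penalty and matches the sample correlation at zero", {
  tc <- make_tc(T_ = 60, C = 4, seed = 12)
  spec <- make_window_spec(60, 20, 4)
  big <- windowed_connectivity(tc, spec, lambda_grid = 50)
  expect_lt(max(abs(big$z)), 1e-6)

  # single window spanning (almost) the series, zero penalty: the tapered
  # correlation computed directly must match
  spec1 <- make_window_spec(60, 57, 1)
  w0 <- windowed_connectivity(tc, spec1, lambda_grid = 0)
  seg <- tc$data[1:60, ]
  mu <- colSums(seg * spec1$taper)
  xc <- sweep(seg, 2, mu)
  S <- crossprod(xc * sqrt(spec1$taper))
  r <- S / tcrossprod(sqrt(diag(S)))
  expect_equal(as.numeric(w0$z[1, ]), atanh(upper_vec(r)), tolerance = 1e-10)
})

test_that("held-out likelihood selects a sensible penalty and stays reproducible", {
  cfg <- small_config(seed = 5)
  sub <- generate_subject(cfg, "control", "c1", seed = 9)
  spec <- make_window_spec(120, 30, 4)
  w1 <- windowed_connectivity(sub$timecourses, spec,
                              lambda_grid = c(0.01, 0.1, 1), seed = 3)
  w2 <- windowed_connectivity(sub$timecourses, spec,
                              lambda_grid = c(0.01, 0.1, 1), seed = 3)
  expect_identical(w1$z, w2$z)
  expect_true(w1$lambda_selected %in% c(0.01, 0.1, 1))
  # heavy penalties suppress the mean absolute connectivity
  w_heavy <- windowed_connectivity(sub$timecourses, spec, lambda_grid = 1)
  expect_lt(mean(abs(w_heavy$z)), mean(abs(w1$z)) + 1e-12)
})

test_that("windowed connectivity separates planted high- and low-connectivity segments", {
  withr::with_seed(15, {
    C <- 6
    Sig <- matrix(0.7, C, C); diag(Sig) <- 1
    hi <- matrix(rnorm(100 * C), 100, C) %*% chol(Sig)
    lo <- matrix(rnorm(100 * C), 100, C)
    tc <- tc_set(rbind(hi, lo), tr = 2,
                 network_labels = rep(c("DMN", "VIS"), each = 3))
    spec <- make_window_spec(200, 30, 1)
    w <- windowed_connectivity(tc, spec, lambda_grid = 0)
    hi_w <- rowMeans(abs(w$z[spec$starts + 32 <= 100, ]))
    lo_w <- rowMeans(abs(w$z[spec$starts >= 101, ]))
    expect_gt(mean(hi_w), mean(lo_w))
  })
})

test_that("confound regression removes covariate signal and nothing else", {
  # identical covariates: output equals input
  mk_w <- function(id, z) structure(list(subject_id = id, z = z,
                                         starts = seq_len(nrow(z)),
                                         spec = NULL, lambda_selected = 0),
                                    class = "windowed_fnc")
  cohort <- tibble::tibble(
    subject_id = c("a", "b", "c"), group = c("patient", "patient", "control"),
    age = c(40, 40, 40), sex = rep("female", 3), mean_fd = rep(0.05, 3),
    edss = c(2, 3, NA))
  withr::with_seed(20, {
    ws <- lapply(c("a", "b", "c"), function(id) mk_w(id, matrix(rnorm(40), 10, 4)))
  })
  expect_warning(out <- regress_window_confounds(ws, cohort),
                 "constant covariate")
  for (i in 1:3) expect_equal(out[[i]]$z, ws[[i]]$z, tolerance = 1e-10)

  # age-driven values: residual correlation with age ~ 0
  cohort2 <- tibble::tibble(
    subject_id = sprintf("s%d", 1:20), group = rep(c("patient", "control"), 10),
    age = seq(20, 58, 2), sex = rep(c("female", "male"), 10),
    mean_fd = runif(20, 0.02, 0.08), edss = NA_real_)
  withr::with_seed(21, {
    ws2 <- lapply(1:20, function(i) {
      mk_w(cohort2$subject_id[i],
           matrix(2 * cohort2$age[i] + rnorm(5 * 4), 5, 4))
    })
  })
  out2 <- regress_window_confounds(ws2, cohort2)
  vals <- do.call(rbind, lapply(out2, `[[`, "z"))
  ages <- rep(cohort2$age, each = 5)
  expect_lt(max(abs(cor(ages, vals))), 0.05)

  # single subject: intercept-only, unchanged
  expect_warning(out1 <- regress_window_confounds(ws[1], cohort[1, ]),
                 "constant covariate")
  expect_equal(out1[[1]]$z, ws[[1]]$z, tolerance = 1e-10)
})

test_that("window-mean connectivity approaches the static vector as the window widens", {
  tc <- make_tc(T_ = 120, C = 5, seed = 30,
                labels = c("DMN", "DMN", "VIS", "VIS", "CN"))
  sf <- compute_sfnc(tc)
  spec <- make_window_spec(120, 117, 1)  # width = T - 3: single full window
  w <- windowed_connectivity(tc, spec, lambda_grid = 0)
  expect_lt(max(abs(colMeans(w$z) - sf$z)), 0.1)
})
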