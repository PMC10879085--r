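test_that("Mann-Whitney matches exact enumeration and handles ties", {
  r <- mann_whitney(1:3, 4:6)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)          # 2 / C(6,3) extreme labelings, two-sided
  expect_equal(r$effect_size, 1)

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$effect_size, 0)

  tied <- mann_whitney(c(1, 2), c(1, 2))
  expect_match(tied$method, "normal approx")
  expect_equal(tied$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), class = "dynfc_domain_error")
})

test_that("rank-biserial effect size is bounded and equals one only under separation", {
  withr::with_seed(1, {
    for (i in 1:30) {
      x <- rnorm(sample(3:12, 1))
      y <- rnorm(sample(3:12, 1))
      r <- mann_whitney(x, y)
      expect_gte(r$effect_size, 0)
      expect_lte(r$effect_size, 1)
      separated <- max(x) < min(y) || max(y) < min(x)
      expect_equal(r$effect_size == 1, separated)
    }
  })
})

test_that("Mann-Whitney type-I error is calibrated at the study group sizes", {
  withr::with_seed(2, {
    rejections <- vapply(1:2000, function(i) {
      mann_whitney(rnorm(30), rnorm(45))$p < 0.05
    }, logical(1))
    expect_lt(abs(mean(rejections) - 0.05), 0.015)
  })
})

test_that("Spearman correlation matches hand-rank computation with exact small-sample p", {
  expect_equal(spearman(1:6, (1:6)^3)$statistic, 1)
  expect_equal(spearman(1:6, -(1:6))$statistic, -1)
  r <- spearman(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$statistic, 0.8)  # 1 - 6*2/(5*24)
  expect_match(r$method, "exact")
  # independent oracle: enumerate all 5! orderings in R
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  rhos <- vapply(perms(1:5), function(p) cor(1:5, p), numeric(1))
  expect_equal(r$p, mean(abs(rhos) >= 0.8 - 1e-12))

  big <- spearman(1:30, rnorm(30))
  expect_match(big$method, "t approx")
  expect_error(spearman(rep(1, 5), 1:5), class = "dynfc_domain_error")
})

test_that("ANCOVA isolates the group effect from covariates", {
  mk_cohort <- function(n, age) tibble::tibble(
    subject_id = sprintf("s%d", 1:n),
    group = rep(c("patient", "control"), length.out = n),
    age = age, sex = sample(c("female", "male"), n, replace = TRUE),
    mean_fd = runif(n, 0.02, 0.08), edss = NA_real_)
  withr::with_seed(3, {
    co <- mk_cohort(40, runif(40, 20, 60))
    # pure group signal: overwhelming evidence
    y <- 3 * (co$group == "patient") + rnorm(40, sd = 0.1)
    expect_lt(ancova_group(y, co)$p, 1e-6)

    # exchangeable groups: no effect
    y0 <- rnorm(40)
    expect_gt(ancova_group(y0, co)$p, 0.05)
  })
})

test_that("age-driven signal is absorbed by the covariate, not the group term", {
  withr::with_seed(4, {
    hits <- vapply(1:100, function(i) {
      n <- 40
      age <- runif(n, 20, 60)
      co <- tibble::tibble(
        subject_id = sprintf("s%d", 1:n),
        group = rep(c("patient", "control"), length.out = n),
        age = age, sex = sample(c("female", "male"), n, replace = TRUE),
        mean_fd = runif(n, 0.02, 0.08), edss = NA_real_)
      ancova_group(2 * age + rnorm(n, sd = 0.5), co)$p < 0.05
    }, logical(1))
    # a strong age effect must not inflate the group test beyond its
    # nominal 5% level (binomial headroom over 100 seeds)
    expect_lte(mean(hits), 0.10)
  })
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.5, 7)), rep(0.5, 7))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  hand <- rev(cummin(rev(pmin(1, p * 10 / seq_len(10)))))
  expect_equal(bh_fdr(p), hand)
  # never decreases a p-value, never exceeds 1, idempotent when all equal
  withr::with_seed(5, {
    q <- bh_fdr(pp <- runif(20))
    expect_true(all(q >= pp - 1e-12))
    expect_true(all(q <= 1))
  })
  expect_equal(bh_fdr(bh_fdr(rep(0.2, 5))), bh_fdr(rep(0.2, 5)))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "dynfc_domain_error")
})

test_that("summary-statistic t reproduces the cohort-table values", {
  expect_equal(round(t_test_from_summaries(37.70, 11.99, 30,
                                           41.84, 11.23, 45)$statistic, 2),
               1.52)
  expect_equal(round(t_test_from_summaries(475.88, 46.33, 30,
                                           510.86, 52.42, 45)$statistic, 2),
               2.96)
  expect_equal(t_test_from_summaries(5, 1, 10, 5, 2, 12)$statistic, 0)
})

test_that("raw-sample and summary paths of the pooled t agree to machine precision", {
  withr::with_seed(6, {
    x <- rnorm(14, 3, 2)
    y <- rnorm(19, 2.4, 1.7)
    a <- t_test_from_summaries(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y))
    b <- t_test_from_summaries(x = x, y = y)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    # and the textbook Welch-free pooled formula via t.test
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(b$statistic, abs(unname(ref$statistic)), tolerance = 1e-12)
    expect_equal(b$p, ref$p.value, tolerance = 1e-12)
  })
})

test_that("phi coefficient matches the cohort sex table and the extremes", {
  sex <- matrix(c(27, 33, 3, 12), 2)  # rows: groups; cols: female, male
  r <- phi_coefficient(sex)
  expect_equal(round(r$statistic, 2), 0.20)
  expect_equal(phi_coefficient(matrix(c(5, 0, 0, 5), 2))$statistic, 1)
  expect_equal(phi_coefficient(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(phi_coefficient(matrix(c(5, 5, 0, 0), 2)),
               class = "dynfc_domain_error")
})

test_that("KS normality check discriminates normal from exponential samples", {
  withr::with_seed(7, {
    norm_s <- ks_normality(rnorm(500))
    expect_gt(norm_s$p, 0.05)
    expect_true(norm_s$normal)
    exp_s <- ks_normality(rexp(500))
    expect_lt(exp_s$p, 0.01)
    expect_gte(exp_s$statistic, 0)
    expect_lte(exp_s$statistic, 1)
    expect_error(ks_normality(rep(2, 10)), class = "dynfc_domain_error")
  })
})
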