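#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided Mann-Whitney U. The p-value is exact (complete enumeration of
#' the U distribution) when `n1 + n2 <= 16` and the data are tie-free, and
#' uses the tie-corrected normal approximation otherwise. The effect size is
#' the absolute rank-biserial correlation `|1 - 2U/(n1*n2)|`, bounded in
#' \[0, 1\] and equal to 1 only for completely separated samples.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param measure Label for the result row.
#' @return One-row tibble: `measure`, `group1_summary`, `group2_summary`
#'   (median (IQR)), `method`, `statistic` (U for x), `p`, `effect_size`.
#' @examples
#' mann_whitney(1:3, 4:6) # exact p = 0.1, effect size 1
#' @export
mann_whitney <- function(x, y, measure = "measure") {
  if (!length(x) || !length(y)) abort("both samples must be nonempty",
                                      class = "dynfc_domain_error")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2 <= 16) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  U <- unname(wt$statistic)
  rb <- abs(1 - 2 * U / (n1 * n2))
  tibble::tibble(measure = measure,
                 group1_summary = summary_median_iqr(x),
                 group2_summary = summary_median_iqr(y),
                 method = if (exact) "mann-whitney (exact)" else
                   "mann-whitney (normal approx.)",
                 statistic = U, p = min(1, wt$p.value), effect_size = rb)
}

summary_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.3g (%.3g-%.3g)", q[2L], q[1L], q[3L])
}

summary_mean_sd <- function(x) sprintf("%.4g +/- %.3g", mean(x), sd(x))

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks. The two-sided p-value is an
#' exact permutation value (all n! orderings enumerated) for n <= 9 and the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 degrees of
#' freedom otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 3, neither constant.
#' @param measure Label for the result row.
#' @return One-row tibble: `measure`, `method`, `statistic` (rho), `p`,
#'   `effect_size` (rho).
#' @export
spearman <- function(x, y, measure = "measure") {
  n <- length(x)
  if (n != length(y) || n < 3L) abort("need paired samples with n >= 3",
                                      class = "dynfc_domain_error")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: rho undefined",
                                      class = "dynfc_domain_error")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    p <- cpp_spearman_perm_p(rx, ry)
    method <- "spearman (exact permutation)"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "spearman (t approx.)"
  }
  tibble::tibble(measure = measure, method = method, statistic = rho,
                 p = min(1, p), effect_size = rho)
}

#' ANCOVA group comparison with age, sex and mean-FD covariates
#'
#' Ordinary least squares of the measure on group (patient vs control),
#' age, sex (female = 0, male = 1) and mean FD; the reported test is the
#' two-sided t-test on the group coefficient. Collinear columns are dropped
#' with a warning.
#'
#' @param values Numeric vector, one value per subject.
#' @param cohort Cohort tibble aligned with `values` (same order).
#' @param measure Label for the result row.
#' @return One-row tibble: `measure`, `group1_summary`, `group2_summary`
#'   (mean +/- SD for patient / control), `method`, `statistic` (group t),
#'   `p`, `effect_size` (group coefficient).
#' @export
ancova_group <- function(values, cohort, measure = "measure") {
  cohort <- validate_cohort(cohort)
  stopifnot(length(values) == nrow(cohort))
  df <- data.frame(y = values,
                   group = as.integer(cohort$group == "patient"),
                   age = cohort$age,
                   sex = as.integer(cohort$sex == "male"),
                   mean_fd = cohort$mean_fd)
  if (nrow(df) < 3L + 3L) abort("need n >= covariates + 3",
                                class = "dynfc_domain_error")
  fit <- lm(y ~ group + age + sex + mean_fd, data = df)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit))) {
    warn(paste0("collinear term(s) dropped: ",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  if (!"group" %in% rownames(cf)) {
    abort("group term not estimable", class = "dynfc_computation_error")
  }
  tibble::tibble(measure = measure,
                 group1_summary = summary_mean_sd(values[df$group == 1]),
                 group2_summary = summary_mean_sd(values[df$group == 0]),
                 method = "ancova (group + age + sex + meanFD)",
                 statistic = cf["group", "t value"],
                 p = cf["group", "Pr(>|t|)"],
                 effect_size = cf["group", "Estimate"])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: monotone, each in \[0, 1\], order preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "dynfc_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Standard independent-samples t with pooled variance and
#' `df = n1 + n2 - 2`; the absolute t is reported. Raw samples may be given
#' instead of summaries.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (n >= 2, sd > 0), or
#' @param x,y raw samples (summaries are then computed from them).
#' @param measure Label for the result row.
#' @return One-row tibble: `measure`, `group1_summary`, `group2_summary`,
#'   `method`, `statistic` (|t|), `p`, `effect_size` (t with sign).
#' @examples
#' t_test_from_summaries(37.70, 11.99, 30, 41.84, 11.23, 45) # |t| = 1.52
#' @export
t_test_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  x = NULL, y = NULL, measure = "measure") {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) abort("need n >= 2 in both groups",
                              class = "dynfc_domain_error")
  if (sd1 <= 0 || sd2 <= 0) abort("sds must be > 0",
                                  class = "dynfc_domain_error")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(measure = measure,
                 group1_summary = sprintf("%.4g +/- %.3g", mean1, sd1),
                 group2_summary = sprintf("%.4g +/- %.3g", mean2, sd2),
                 method = "pooled t",
                 statistic = abs(tval),
                 p = 2 * pt(-abs(tval), df = df),
                 effect_size = tval)
}

#' Phi coefficient for a 2 x 2 table
#'
#' `phi = (n11*n22 - n12*n21) / sqrt(r1*r2*c1*c2)` with a chi-square
#' p-value on 1 degree of freedom (`chi2 = n * phi^2`, no continuity
#' correction).
#'
#' @param table 2 x 2 count matrix with positive margins.
#' @param measure Label for the result row.
#' @return One-row tibble: `measure`, `method`, `statistic` (|phi|), `p`,
#'   `effect_size` (phi with sign).
#' @examples
#' phi_coefficient(matrix(c(27, 33, 3, 12), 2)) # |phi| ~ 0.20
#' @export
phi_coefficient <- function(table, measure = "measure") {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0)) abort("counts must be nonnegative",
                            class = "dynfc_domain_error")
  r <- rowSums(table); cc <- colSums(table)
  if (any(r == 0) || any(cc == 0)) abort("zero margin",
                                         class = "dynfc_domain_error")
  phi <- (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1]) /
    sqrt(r[1] * r[2] * cc[1] * cc[2])
  phi <- unname(phi)
  n <- sum(table)
  chi2 <- n * phi^2
  tibble::tibble(measure = measure, method = "phi (chi-square, 1 df)",
                 statistic = abs(phi), p = pchisq(chi2, df = 1,
                                                  lower.tail = FALSE),
                 effect_size = phi)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' the sample's own mean and SD, with the asymptotic p-value. Used to decide
#' between reporting mean +/- SD (normal) and median (IQR) (non-normal).
#'
#' @param x Numeric sample, n >= 5, non-constant.
#' @param measure Label for the result row.
#' @return One-row tibble: `measure`, `method`, `statistic` (D), `p`, and
#'   `normal` (logical, p > 0.05).
#' @export
ks_normality <- function(x, measure = "measure") {
  if (length(x) < 5L) abort("need n >= 5", class = "dynfc_domain_error")
  if (sd(x) == 0) abort("constant sample", class = "dynfc_domain_error")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean = mean(x), sd = sd(x)))
  tibble::tibble(measure = measure, method = "one-sample KS vs fitted normal",
                 statistic = unname(kt$statistic), p = kt$p.value,
                 effect_size = NA_real_) %>%
    dplyr::mutate(normal = .data$p > 0.05)
}
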