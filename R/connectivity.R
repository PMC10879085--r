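#' Static functional network connectivity
#'
#' Pearson correlation between every pair of component time courses over the
#' full series, Fisher-z transformed (atanh). Values are returned in the
#' canonical pair ordering (see [pair_index()]); for C components there are
#' `C*(C-1)/2` pairs (903 for C = 43).
#'
#' @param tc A post-processed [tc_set()] with T >= 3.
#' @return A tibble with columns `subject_id`, `pair`, `i`, `j`, `z`.
#' @export
compute_sfnc <- function(tc) {
  stopifnot(inherits(tc, "tc_set"))
  X <- tc$data
  if (nrow(X) < 3L) abort("need T >= 3", class = "dynfc_domain_error")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance component(s): ",
                 paste(tc$component_ids[sds == 0], collapse = ", ")),
          class = "dynfc_domain_error")
  }
  r <- cor(X)
  v <- mat_to_pairvec(r)
  if (any(abs(v) >= 1 - 1e-12)) {
    # a full-series correlation of exactly +/-1 means duplicated components
    bad <- which(abs(v) >= 1 - 1e-12)[1L]
    pi_ <- pair_index(ncol(X))
    abort(sprintf("components %s and %s are perfectly correlated",
                  tc$component_ids[pi_$i[bad]], tc$component_ids[pi_$j[bad]]),
          class = "dynfc_domain_error")
  }
  dplyr::mutate(pair_index(ncol(X)), z = atanh(v),
                subject_id = tc$subject_id, .before = 1) %>%
    dplyr::relocate("subject_id")
}

#' Sliding-window specification with Gaussian-convolved taper
#'
#' The window weight vector is the full discrete convolution of a rectangle
#' of length `width_tr` (unit height) with a 4-sample Gaussian kernel
#' (standard deviation 3 TR, sampled at offsets -1.5, -0.5, 0.5, 1.5 and
#' normalised), renormalised to sum to one. The effective window length is
#' therefore `width_tr + 3`, and only full-support placements are kept:
#' `n_windows = (T - width_tr - 3) %/% step_tr + 1`. With T = 230 retained
#' volumes, width 30 TR and step 1 TR this yields 198 windows.
#'
#' @param n_timepoints Series length T.
#' @param width_tr Window width in TR (default 30).
#' @param step_tr Step between window starts in TR (default 1).
#' @return A `window_spec`: list with `width_tr`, `step_tr`, `taper`
#'   (length `width_tr + 3`, sums to 1), `n_windows`, and `starts` (1-based
#'   first sample of each placement).
#' @examples
#' make_window_spec(230, 30, 1)$n_windows # 198
#' @export
make_window_spec <- function(n_timepoints, width_tr = 30L, step_tr = 1L) {
  T_ <- as.integer(n_timepoints)
  width_tr <- as.integer(width_tr)
  step_tr <- as.integer(step_tr)
  stopifnot(width_tr >= 1L, step_tr >= 1L)
  eff <- width_tr + 3L
  if (T_ < eff) {
    abort(sprintf("need T >= width + 3 (T = %d, width = %d)", T_, width_tr),
          class = "dynfc_domain_error")
  }
  g <- exp(-c(-1.5, -0.5, 0.5, 1.5)^2 / (2 * 3^2))
  g <- g / sum(g)
  taper <- convolve_full(rep(1, width_tr), g)
  taper <- taper / sum(taper)
  n_windows <- (T_ - eff) %/% step_tr + 1L
  starts <- 1L + step_tr * (seq_len(n_windows) - 1L)
  structure(list(width_tr = width_tr, step_tr = step_tr, taper = taper,
                 n_windows = n_windows, starts = starts,
                 effective_length = eff),
            class = "window_spec")
}

# full linear convolution, small kernels
convolve_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (k in seq_along(b)) {
    idx <- seq_along(a) + k - 1L
    out[idx] <- out[idx] + a * b[k]
  }
  out
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> width %d TR + 3 taper, step %d TR, %d windows\n",
              x$width_tr, x$step_tr, x$n_windows))
  invisible(x)
}

# taper-weighted covariance of a segment (weights sum to 1)
weighted_cov <- function(seg, w) {
  mu <- colSums(seg * w)
  xc <- sweep(seg, 2L, mu)
  crossprod(xc * sqrt(w))  # sum_t w_t (x_t - mu)(x_t - mu)'
}

# covariance -> correlation with clamping for degenerate windows
cov_to_z <- function(S, clamp = 1 - 1e-7) {
  d <- sqrt(diag(S))
  r <- S / tcrossprod(d)
  v <- mat_to_pairvec(r)
  v[v > clamp] <- clamp
  v[v < -clamp] <- -clamp
  atanh(v)
}

#' Graphical lasso fit of a covariance matrix
#'
#' L1-penalised Gaussian inverse-covariance estimation by block coordinate
#' descent. With `lambda = 0` the unpenalised maximum-likelihood estimate is
#' returned (the sample covariance itself, inverted directly).
#'
#' @param S Sample covariance matrix (symmetric, C x C).
#' @param lambda Nonnegative L1 penalty.
#' @param max_iter,tol Outer-loop iteration cap and convergence tolerance on
#'   the mean absolute change of the working covariance.
#' @return List with `w` (regularised covariance), `theta` (sparse precision
#'   matrix), `iterations`, `converged`.
#' @export
glasso_fit <- function(S, lambda, max_iter = 200L, tol = 1e-5) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), lambda >= 0)
  if (lambda == 0) {
    theta <- tryCatch(solve(S), error = function(e)
      abort("sample covariance is singular; use lambda > 0",
            class = "dynfc_computation_error"))
    return(list(w = S, theta = theta, iterations = 0L, converged = TRUE))
  }
  fit <- cpp_glasso(S, lambda, max_iter, tol)
  if (!fit$converged) {
    abort(sprintf("graphical lasso did not converge (lambda = %g, %d iterations)",
                  lambda, fit$iterations), class = "dynfc_computation_error")
  }
  fit
}

#' Windowed (dynamic) functional network connectivity
#'
#' Slides the tapered window of `spec` along the series; per window, computes
#' the taper-weighted sample covariance and its graphical-lasso-regularised
#' estimate, converts the regularised covariance to correlation, and
#' Fisher-z transforms it. The L1 penalty is chosen once per subject by
#' maximising the mean held-out Gaussian log-likelihood over `n_repetitions`
#' random 80/20 splits of the windows, evaluated on the candidate grid. Window
#' correlations of exactly +/-1 (reachable with short windows) are clamped to
#' +/-(1 - 1e-7) before atanh.
#'
#' @param tc A post-processed [tc_set()].
#' @param spec A [make_window_spec()] result consistent with `nrow(tc$data)`.
#' @param lambda_grid Candidate penalties; default 10 log-spaced values in
#'   \[0.01, 1\]. A single value (including 0) skips selection and uses it
#'   directly; `lambda_grid = 0` is the fast unpenalised path (tapered
#'   correlation).
#' @param n_repetitions Number of random splits for penalty selection
#'   (default 10).
#' @param seed Integer seed for the split randomness.
#' @return A `windowed_fnc` object: list with `subject_id`, `z` (W x P
#'   matrix, canonical pair order), `starts`, `spec`, `lambda_selected`.
#' @export
windowed_connectivity <- function(tc, spec = make_window_spec(nrow(tc$data)),
                                  lambda_grid = exp(seq(log(0.01), log(1),
                                                        length.out = 10)),
                                  n_repetitions = 10L, seed = 1L) {
  stopifnot(inherits(tc, "tc_set"), inherits(spec, "window_spec"))
  X <- tc$data
  if (max(spec$starts) + spec$effective_length - 1L > nrow(X)) {
    abort("window spec is inconsistent with the series length",
          class = "dynfc_validation_error")
  }
  C <- ncol(X)
  covs <- lapply(spec$starts, function(s0) {
    weighted_cov(X[s0:(s0 + spec$effective_length - 1L), , drop = FALSE],
                 spec$taper)
  })
  lambda <- if (length(lambda_grid) == 1L) lambda_grid else {
    select_lambda(covs, lambda_grid, n_repetitions, seed)
  }
  Z <- matrix(NA_real_, spec$n_windows, n_pairs(C))
  for (w in seq_along(covs)) {
    Sw <- if (lambda > 0) glasso_fit(covs[[w]], lambda)$w else covs[[w]]
    Z[w, ] <- cov_to_z(Sw)
  }
  structure(list(subject_id = tc$subject_id, z = Z, starts = spec$starts,
                 spec = spec, lambda_selected = lambda),
            class = "windowed_fnc")
}

# held-out log-likelihood selection of the glasso penalty over window splits
select_lambda <- function(covs, lambda_grid, n_repetitions, seed) {
  W <- length(covs)
  C <- nrow(covs[[1L]])
  withr_seed(seed, {
    splits <- lapply(seq_len(n_repetitions), function(r) {
      train <- sort(sample.int(W, size = max(1L, floor(0.8 * W))))
      list(train = train, test = setdiff(seq_len(W), train))
    })
  })
  scores <- vapply(lambda_grid, function(lam) {
    ll <- vapply(splits, function(sp) {
      S_train <- Reduce(`+`, covs[sp$train]) / length(sp$train)
      S_test <- Reduce(`+`, covs[sp$test]) / length(sp$test)
      fit <- tryCatch(glasso_fit(S_train, lam), error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      theta <- fit$theta
      ld <- determinant(theta, logarithm = TRUE)
      if (ld$sign <= 0) return(-Inf)
      as.numeric(ld$modulus) - sum(theta * S_test)
    }, numeric(1L))
    mean(ll)
  }, numeric(1L))
  if (all(!is.finite(scores))) {
    abort("graphical lasso failed at every candidate penalty",
          class = "dynfc_computation_error")
  }
  lambda_grid[which.max(scores)]
}

#' @export
print.windowed_fnc <- function(x, ...) {
  cat(sprintf("<windowed_fnc> subject %s: %d windows x %d pairs, lambda = %s\n",
              x$subject_id, nrow(x$z), ncol(x$z),
              format(x$lambda_selected, digits = 3)))
  invisible(x)
}

#' Regress subject-level confounds out of window vectors
#'
#' For each connectivity pair, all subjects' window values are stacked and
#' regressed on an intercept, age, sex (female = 0, male = 1) and mean FD
#' (each subject's covariates replicated across its windows, pooled over
#' window index); values are replaced by the residual plus the fitted grand
#' intercept. Constant covariate columns are dropped with a warning.
#'
#' @param windows List of `windowed_fnc` objects, one per subject.
#' @param cohort Cohort tibble with `subject_id`, `age`, `sex`, `mean_fd`.
#' @return The list with each `z` matrix residualised (same shapes).
#' @export
regress_window_confounds <- function(windows, cohort) {
  cohort <- validate_cohort(cohort, require_both_groups = FALSE)
  ids <- vapply(windows, `[[`, character(1L), "subject_id")
  if (!all(ids %in% cohort$subject_id)) {
    abort("every windowed subject must appear in the cohort table",
          class = "dynfc_validation_error")
  }
  meta <- cohort[match(ids, cohort$subject_id), ]
  nw <- vapply(windows, function(w) nrow(w$z), integer(1L))
  covs <- cbind(age = rep(meta$age, nw),
                sex = rep(ifelse(meta$sex == "male", 1, 0), nw),
                mean_fd = rep(meta$mean_fd, nw))
  keep <- apply(covs, 2L, function(v) diff(range(v)) > 0)
  if (!all(keep)) {
    warn(paste0("constant covariate(s) dropped: ",
                paste(colnames(covs)[!keep], collapse = ", ")))
  }
  # centre covariates so the intercept is the grand mean and adding it back
  # restores values on the original connectivity scale
  covs <- scale(covs[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  X <- cbind(intercept = 1, covs)
  Y <- do.call(rbind, lapply(windows, `[[`, "z"))
  beta <- solve(crossprod(X), crossprod(X, Y))
  res <- Y - X[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE]
  offs <- c(0L, cumsum(nw))
  for (k in seq_along(windows)) {
    windows[[k]]$z <- res[(offs[k] + 1L):offs[k + 1L], , drop = FALSE]
  }
  windows
}

# run expr with a temporary RNG state seeded at `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
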