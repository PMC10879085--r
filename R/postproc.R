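#' Post-ICA time-course cleaning
#'
#' Four cleaning steps are applied to component time courses after ICA, in a
#' fixed order: polynomial detrending (linear, quadratic and cubic trends),
#' regression of the six realignment parameters and their temporal
#' derivatives, despiking, and zero-phase Butterworth band-pass filtering
#' between 0.01 and 0.15 Hz (5th order). Each step records itself in the
#' set's `history`; applying the same step twice raises an error, which keeps
#' the pipeline order honest.
#'
#' @name postproc
NULL

add_history <- function(tc, step) {
  if (step %in% tc$history) {
    abort(sprintf("step '%s' has already been applied to this set", step),
          class = "dynfc_validation_error")
  }
  tc$history <- c(tc$history, step)
  tc
}

#' Remove polynomial trends from each component
#'
#' Each column is replaced by its residual from an ordinary least-squares
#' polynomial fit of the given order (intercept included), so output columns
#' have zero mean. Order 3 removes the linear, quadratic and cubic trends.
#'
#' @param tc A [tc_set()].
#' @param order Polynomial order (0 = demean only); needs `T > order + 1`.
#' @return The detrended `tc_set`.
#' @export
detrend_polynomial <- function(tc, order = 3L) {
  stopifnot(inherits(tc, "tc_set"))
  T_ <- nrow(tc$data)
  if (T_ <= order + 1) {
    abort(sprintf("need T > order + 1 (T = %d, order = %d)", T_, order),
          class = "dynfc_domain_error")
  }
  tv <- seq_len(T_) / T_
  X <- vapply(0:order, function(k) tv^k, numeric(T_))
  tc <- add_history(tc, sprintf("detrend(order=%d)", order))
  tc$data <- stats::lm.fit(X, tc$data)$residuals
  dimnames(tc$data) <- NULL
  tc
}

#' Regress realignment parameters and their derivatives out of time courses
#'
#' The design holds an intercept, the six motion parameters and their
#' backward-difference temporal derivatives (first row 0). Collinear design
#' columns are dropped with a warning (lm.fit handles rank deficiency by
#' pivoting; dropped coefficients are NA).
#'
#' @param tc A [tc_set()].
#' @param motion T x 6 motion matrix (see [read_motion()]).
#' @return The residualised `tc_set`.
#' @export
regress_nuisance <- function(tc, motion) {
  stopifnot(inherits(tc, "tc_set"))
  motion <- as.matrix(motion)
  if (nrow(motion) != nrow(tc$data) || ncol(motion) != 6L) {
    abort("motion must be T x 6 with T matching the time courses",
          class = "dynfc_schema_error")
  }
  deriv <- rbind(0, diff(motion))
  X <- cbind(1, motion, deriv)
  fit <- stats::lm.fit(X, tc$data)
  if (fit$rank < ncol(X)) {
    warn(sprintf("nuisance design rank-deficient (%d of %d columns used)",
                 fit$rank, ncol(X)))
  }
  tc <- add_history(tc, "regress_nuisance")
  tc$data <- fit$residuals
  dimnames(tc$data) <- NULL
  tc
}

#' Despike by running-median replacement
#'
#' Points that deviate from their centred running median by more than
#' `threshold` robust standard deviations (1.4826 x the running MAD) are
#' replaced by that running median; everything else is untouched. Windows at
#' the series edges shrink symmetrically (half-width `min(t-1, T-t,
#' (window-1)/2)`), so the first and last points are never replaced. A zero
#' MAD disables replacement in that window unless the point actually deviates
#' (deviation 0 from the median never triggers).
#'
#' @param tc A [tc_set()].
#' @param window Odd window length >= 3 (default 5).
#' @param threshold MAD multiples (default 3).
#' @return The despiked `tc_set`.
#' @export
despike <- function(tc, window = 5L, threshold = 3) {
  stopifnot(inherits(tc, "tc_set"))
  if (window < 3L || window %% 2L == 0L) {
    abort("despike window must be odd and >= 3", class = "dynfc_domain_error")
  }
  tc <- add_history(tc, sprintf("despike(window=%d,threshold=%g)",
                                window, threshold))
  tc$data <- cpp_despike(tc$data, as.integer(window), threshold)
  tc
}

# plain-R reference implementation (kept as an independent oracle for tests)
despike_column <- function(x, window, threshold) {
  T_ <- length(x)
  hmax <- (window - 1L) %/% 2L
  out <- x
  for (t in seq_len(T_)) {
    h <- min(t - 1L, T_ - t, hmax)
    seg <- x[(t - h):(t + h)]
    med <- median(seg)
    mad_ <- median(abs(seg - med))
    dev <- abs(x[t] - med)
    if (dev > threshold * 1.4826 * mad_ && dev > 0) out[t] <- med
  }
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order between `low` and
#' `high` Hz (both strictly inside (0, Nyquist), Nyquist = `1/(2 tr)`) and
#' applies it forward then time-reversed, so the net phase response is zero
#' and the amplitude response is the square of the single-pass response.
#' Before filtering, each column is extended at both ends by odd-symmetric
#' (anti-reflected) padding of length `3 * order` to suppress edge
#' transients, then trimmed back to the input length.
#'
#' @param tc A [tc_set()].
#' @param low,high Pass-band edges in Hz (defaults 0.01 and 0.15).
#' @param order Butterworth order (default 5).
#' @return The filtered `tc_set` (same length).
#' @export
bandpass_butterworth <- function(tc, low = 0.01, high = 0.15, order = 5L) {
  stopifnot(inherits(tc, "tc_set"))
  nyq <- 1 / (2 * tc$tr)
  if (!(low > 0 && low < high && high < nyq)) {
    abort(sprintf("band (%g, %g) Hz must satisfy 0 < low < high < Nyquist = %g",
                  low, high, nyq), class = "dynfc_domain_error")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  pad <- 3L * order
  tc <- add_history(tc, sprintf("bandpass(%g-%g Hz,order=%d)", low, high, order))
  tc$data <- apply(tc$data, 2L, filtfilt_odd, bf = bf, pad = pad)
  tc
}

# two-pass filter with odd-symmetric end padding; the column mean is removed
# first (a band-pass has zero DC gain, and demeaning kills the slow edge
# transient the narrow low cutoff would otherwise leave)
filtfilt_odd <- function(x, bf, pad) {
  x <- x - mean(x)
  n <- length(x)
  pad <- min(pad, n - 1L)
  xe <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filter(bf, xe)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Run the full cleaning pipeline
#'
#' Applies, in order: [detrend_polynomial()], [regress_nuisance()],
#' [despike()] and [bandpass_butterworth()].
#'
#' @param tc A raw [tc_set()].
#' @param motion T x 6 motion matrix.
#' @param params List of parameters; see defaults in [postproc_params()].
#' @return The cleaned `tc_set` with a complete `history`.
#' @export
postprocess_timecourses <- function(tc, motion, params = postproc_params()) {
  tc %>%
    detrend_polynomial(order = params$detrend_order) %>%
    regress_nuisance(motion) %>%
    despike(window = params$despike_window,
            threshold = params$despike_threshold) %>%
    bandpass_butterworth(low = params$bandpass[1], high = params$bandpass[2],
                         order = params$filter_order)
}

#' @rdname postprocess_timecourses
#' @param detrend_order,bandpass,filter_order,despike_window,despike_threshold
#'   Cleaning parameters; the defaults are the conventional resting-state
#'   choices (cubic detrend, 0.01-0.15 Hz 5th-order band-pass, window-5 /
#'   3-MAD despiking).
#' @export
postproc_params <- function(detrend_order = 3L, bandpass = c(0.01, 0.15),
                            filter_order = 5L, despike_window = 5L,
                            despike_threshold = 3) {
  stopifnot(filter_order >= 1L, despike_window >= 3L,
            despike_window %% 2L == 1L, bandpass[1] > 0,
            bandpass[1] < bandpass[2])
  list(detrend_order = detrend_order, bandpass = bandpass,
       filter_order = filter_order, despike_window = despike_window,
       despike_threshold = despike_threshold)
}
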