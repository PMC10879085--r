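#' Validate a cohort metadata table
#'
#' The cohort table holds one row per participant with the columns
#' `subject_id`, `group` ("patient" or "control"), `age` (years), `sex`
#' ("female"/"male"), `mean_fd` (millimetres), `edss` (0-10 in 0.5 steps,
#' `NA` for controls) and optionally `gmv`, `wmv`, `tiv`, `lesion_volume`
#' (millilitres). Missing EDSS is encoded as `NA` (empty field on disk),
#' never 0.
#'
#' @param cohort A data frame with at least the required columns.
#' @param require_both_groups If `TRUE` (default), error unless both groups
#'   are non-empty (any group-comparison needs both).
#' @return The validated cohort as a tibble.
#' @export
validate_cohort <- function(cohort, require_both_groups = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("subject_id", "group", "age", "sex", "mean_fd", "edss")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dynfc_schema_error")
  }
  if (anyDuplicated(cohort$subject_id)) {
    abort("subject_id values must be unique", class = "dynfc_schema_error")
  }
  if (!all(cohort$group %in% c("patient", "control"))) {
    abort("group must be 'patient' or 'control'", class = "dynfc_schema_error")
  }
  if (!all(cohort$sex %in% c("female", "male"))) {
    abort("sex must be 'female' or 'male'", class = "dynfc_schema_error")
  }
  if (any(cohort$age <= 0)) abort("age must be > 0", class = "dynfc_domain_error")
  if (any(cohort$mean_fd < 0)) abort("mean_fd must be >= 0",
                                     class = "dynfc_domain_error")
  e <- cohort$edss[!is.na(cohort$edss)]
  if (length(e) && (any(e < 0 | e > 10) || any(abs(e * 2 - round(e * 2)) > 1e-9))) {
    abort("edss must lie on the 0-10 half-point grid",
          class = "dynfc_domain_error")
  }
  if (all(c("gmv", "wmv", "tiv") %in% names(cohort))) {
    full <- complete.cases(cohort[, c("gmv", "wmv", "tiv")])
    if (any(full & (cohort$gmv + cohort$wmv > cohort$tiv + 1e-9))) {
      abort("gmv + wmv must not exceed tiv", class = "dynfc_validation_error")
    }
  }
  if (require_both_groups &&
      (!any(cohort$group == "patient") || !any(cohort$group == "control"))) {
    abort("both groups must be non-empty", class = "dynfc_validation_error")
  }
  cohort
}

#' Read / write a cohort metadata table
#'
#' CSV with header `subject_id,group,age,sex,mean_fd,edss,gmv,wmv,tiv,
#' lesion_volume`; EDSS for controls is an empty field.
#'
#' @param path CSV path.
#' @param require_both_groups Passed to [validate_cohort()].
#' @return [read_cohort()]: a validated tibble. [write_cohort()]: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, require_both_groups = TRUE) {
  cohort <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), .default = readr::col_double()))
  validate_cohort(cohort, require_both_groups = require_both_groups)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(validate_cohort(cohort, require_both_groups = FALSE), path,
                   na = "")
  invisible(path)
}

#' Brain parenchymal fraction
#'
#' The fraction of the intracranial volume occupied by brain parenchyma:
#' `(GMV + WMV) / TIV`. Scale-invariant in the three volumes.
#'
#' @param gmv,wmv,tiv Gray-matter, white-matter and total intracranial
#'   volumes, millilitres, all > 0. Vectorised.
#' @return Fraction in (0, 1].
#' @examples
#' brain_parenchymal_fraction(571.67, 475.88, 1341.7) # ~0.78
#' @export
brain_parenchymal_fraction <- function(gmv, wmv, tiv) {
  if (any(tiv <= 0) || any(gmv <= 0) || any(wmv <= 0)) {
    abort("all volumes must be > 0", class = "dynfc_domain_error")
  }
  if (any(gmv + wmv > tiv + 1e-12)) {
    abort("gmv + wmv must not exceed tiv", class = "dynfc_validation_error")
  }
  (gmv + wmv) / tiv
}

#' Mean framewise displacement
#'
#' Per-frame head motion summarised as
#' `FD_t = sum(|d translations|) + 50 mm * sum(|d rotations|)` for
#' t = 2..T (backward differences), averaged over the T - 1 values. The
#' 50 mm factor converts radians of rotation to arc length on a sphere of
#' radius 50 mm, the common convention for this scalar; the convention is
#' recorded in the attribute `fd_convention` of the result.
#'
#' @param motion T x 6 numeric matrix: three translations (mm) then three
#'   rotations (radians); T >= 2.
#' @param radius Rotation-to-displacement radius in millimetres (default 50).
#' @return Mean FD in millimetres (scalar, with attribute `fd_convention`).
#' @examples
#' m <- matrix(0, 230, 6); m[100:230, 1] <- 1  # one 1 mm step, else static
#' mean_framewise_displacement(m) # 1/229
#' @export
mean_framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L) {
    abort("motion must be a T x 6 matrix with T >= 2",
          class = "dynfc_domain_error")
  }
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
  structure(mean(fd), fd_convention = sprintf("sum-abs-diff, radius %g mm", radius))
}

results_table_columns <- c("measure", "group1_summary", "group2_summary",
                           "method", "statistic", "p", "effect_size", "fdr_q")

#' Write / read a results table
#'
#' Serialises a tibble of labelled statistic records (as produced by the
#' group-comparison functions) to CSV with a fixed header, so results
#' round-trip losslessly through [read_results_table()].
#'
#' @param rows A data frame with (a subset of) the columns `measure`,
#'   `group1_summary`, `group2_summary`, `method`, `statistic`, `p`,
#'   `effect_size`, `fdr_q`. Missing columns are written as empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) > 0 && !"measure" %in% names(rows)) {
    abort("every record needs a 'measure' name", class = "dynfc_schema_error")
  }
  for (col in results_table_columns) {
    if (!col %in% names(rows)) {
      rows[[col]] <- if (col %in% c("measure", "group1_summary",
                                    "group2_summary", "method"))
        character(nrow(rows)) else NA_real_
    }
  }
  rows <- rows[, results_table_columns]
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    measure = readr::col_character(), group1_summary = readr::col_character(),
    group2_summary = readr::col_character(), method = readr::col_character(),
    .default = readr::col_double()))
}
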