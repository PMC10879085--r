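#' Component time-course sets
#'
#' A `tc_set` bundles one subject's post-ICA component time courses (a T x C
#' numeric matrix), the repetition time, component identifiers and the mapping
#' of each component to one of the eight resting-state networks (DMN, SMN,
#' ADN, VIS, ATN, FPN, SCN, CN). All cleaning and connectivity functions
#' consume and return this container.
#'
#' @param data Numeric matrix, T time points x C components, all finite.
#' @param tr Repetition time in seconds (> 0).
#' @param component_ids Character vector of C unique component ids. Defaults
#'   to `IC1..ICC`.
#' @param network_labels Character vector of C network names from the
#'   eight-network partition.
#' @param subject_id Subject identifier string.
#' @return An object of class `tc_set`: a list with elements `data`, `tr`,
#'   `component_ids`, `network_labels`, `subject_id` and a `history` character
#'   vector recording processing steps already applied.
#' @examples
#' tc <- tc_set(matrix(rnorm(40), 20, 2), tr = 2,
#'              network_labels = c("DMN", "VIS"))
#' dim(tc$data)
#' @export
tc_set <- function(data, tr, network_labels,
                   component_ids = paste0("IC", seq_len(ncol(data))),
                   subject_id = "subject") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  if (nrow(data) < 2L || ncol(data) < 2L) {
    abort("a time-course set needs T >= 2 rows and C >= 2 columns",
          class = "dynfc_domain_error")
  }
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]),
          class = "dynfc_parse_error")
  }
  if (length(network_labels) != ncol(data)) {
    abort(sprintf("expected %d network labels, got %d",
                  ncol(data), length(network_labels)),
          class = "dynfc_schema_error")
  }
  unknown <- setdiff(unique(network_labels), RSN_NAMES)
  if (length(unknown)) {
    abort(paste0("unknown network label(s): ", paste(unknown, collapse = ", ")),
          class = "dynfc_schema_error")
  }
  if (length(component_ids) != ncol(data) || anyDuplicated(component_ids)) {
    abort("component_ids must be unique and match the column count",
          class = "dynfc_schema_error")
  }
  stopifnot(is.numeric(tr), tr > 0)
  structure(
    list(data = data, tr = as.numeric(tr),
         component_ids = as.character(component_ids),
         network_labels = as.character(network_labels),
         subject_id = as.character(subject_id),
         history = character()),
    class = "tc_set")
}

#' @export
print.tc_set <- function(x, ...) {
  cat(sprintf("<tc_set> subject %s: %d time points x %d components, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  cat("networks:", paste(sprintf("%s(%d)", names(table(x$network_labels)),
                                 table(x$network_labels)), collapse = " "), "\n")
  if (length(x$history)) cat("processing:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.tc_set <- function(x) dim(x$data)

#' Read component time courses from delimited text
#'
#' Time courses are stored one subject per file as headerless delimited text
#' (tab by default, comma accepted), T rows x C numeric columns. A companion
#' labels file (CSV with header `component_id,network`) supplies the
#' component-to-network map; its row order defines the component order and
#' must match the column count of the matrix.
#'
#' @param path Path to the T x C delimited matrix.
#' @param tr Repetition time in seconds.
#' @param labels_path Path to the `component_id,network` CSV.
#' @param subject_id Subject identifier (defaults to the file stem).
#' @return A validated [tc_set()] with column order preserved.
#' @export
read_timecourses <- function(path, tr, labels_path,
                             subject_id = sub("\\.[^.]+$", "", basename(path))) {
  m <- read_matrix(path)
  labels <- readr::read_csv(labels_path, col_types = readr::cols(
    component_id = readr::col_character(), network = readr::col_character()))
  if (nrow(labels) != ncol(m)) {
    abort(sprintf("labels file has %d rows but matrix has %d columns",
                  nrow(labels), ncol(m)), class = "dynfc_schema_error")
  }
  tc_set(m, tr = tr, network_labels = labels$network,
         component_ids = labels$component_id, subject_id = subject_id)
}

#' Write component time courses (and companion labels) to delimited text
#'
#' @param tc A [tc_set()].
#' @param path Output path for the headerless T x C matrix (tab-delimited).
#' @param labels_path Optional output path for the `component_id,network` CSV.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tc, path, labels_path = NULL) {
  stopifnot(inherits(tc, "tc_set"))
  write_matrix(tc$data, path)
  if (!is.null(labels_path)) {
    readr::write_csv(tibble::tibble(component_id = tc$component_ids,
                                    network = tc$network_labels), labels_path)
  }
  invisible(path)
}

#' Read a six-column realignment-parameter series
#'
#' Motion files are headerless delimited text with T rows and the columns
#' `tx ty tz rx ry rz`: three translations in millimetres followed by three
#' rotations in radians.
#'
#' @param path Path to the T x 6 delimited file.
#' @return A T x 6 numeric matrix with those column names.
#' @export
read_motion <- function(path) {
  m <- read_matrix(path)
  if (ncol(m) != 6L) {
    abort(sprintf("motion file must have 6 columns, found %d", ncol(m)),
          class = "dynfc_schema_error")
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

# headerless numeric matrix from tab- or comma-delimited text; full precision
read_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "dynfc_io_error")
  first <- readLines(path, n = 1L)
  delim <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = delim, header = FALSE,
                          colClasses = "character", strip.white = TRUE)
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric cell at row %d, column %d of %s",
                  bad[1L], bad[2L], path), class = "dynfc_parse_error")
  }
  m
}

write_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
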