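# Representation, validation and summaries of three-level hierarchical
# survival data: patients nested within surgeons nested within centers.

#' Validate a data frame as a three-level hierarchical survival dataset
#'
#' Coerces a data frame with one row per subject into the canonical layout
#' used throughout the package: columns `time` (follow-up, non-negative),
#' `event` (1 = event, 0 = censored), `surgeon` and `center` (cluster labels,
#' stored as character), followed by the case-mix covariate columns. Strict
#' nesting is enforced: every surgeon must appear under exactly one center.
#'
#' Events recorded at time 0 are rejected (the Weibull hazard is undefined at
#' the time origin for shape < 1); censored records at time 0 carry no
#' likelihood information and are dropped with a warning. Missing covariate
#' values are rejected, since direct standardization requires a complete
#' case-mix matrix.
#'
#' @param data A data frame, one row per subject.
#' @param time,event,surgeon,center Names of the corresponding columns in
#'   `data`.
#' @param covariates Character vector of case-mix covariate columns. Defaults
#'   to every remaining numeric column, in order.
#' @return A tibble of class `survdata` with attribute `covariates`.
#' @examples
#' df <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1),
#'                  surgeon = c("s1", "s1", "s2", "s2"),
#'                  center = c("A", "A", "B", "B"), age = c(60, 70, 55, 65))
#' as_survdata(df)
#' @export
as_survdata <- function(data, time = "time", event = "event",
                        surgeon = "surgeon", center = "center",
                        covariates = NULL) {
  stopifnot(is.data.frame(data))
  wanted <- c(time = time, event = event, surgeon = surgeon, center = center)
  missing_cols <- wanted[!wanted %in% names(data)]
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(sprintf("'%s' (%s role)", missing_cols,
                               names(missing_cols)), collapse = ", ")),
          class = "mlsurvstd_schema_error")
  }
  out <- tibble(
    time = data[[time]],
    event = data[[event]],
    surgeon = as.character(data[[surgeon]]),
    center = as.character(data[[center]])
  )
  check_numeric_col(out$time, time, "time")
  check_numeric_col(out$event, event, "event")
  out$time <- as.numeric(out$time)
  out$event <- as.numeric(out$event)
  if (any(out$time < 0)) {
    abort(sprintf("Negative follow-up time at row %d.",
                  which(out$time < 0)[1]),
          class = "mlsurvstd_parse_error")
  }
  bad_event <- !out$event %in% c(0, 1)
  if (any(bad_event)) {
    abort(sprintf("Event indicator not in {0, 1} at row %d.",
                  which(bad_event)[1]),
          class = "mlsurvstd_parse_error")
  }

  if (is.null(covariates)) {
    rest <- setdiff(names(data), wanted)
    covariates <- rest[vapply(data[rest], is.numeric, logical(1))]
  } else {
    miss <- setdiff(covariates, names(data))
    if (length(miss) > 0) {
      abort(paste0("Missing covariate column(s): ",
                   paste0("'", miss, "'", collapse = ", ")),
            class = "mlsurvstd_schema_error")
    }
  }
  for (cv in covariates) {
    check_numeric_col(data[[cv]], cv, "covariate")
    out[[cv]] <- as.numeric(data[[cv]])
  }

  # Strict nesting: a surgeon label maps to exactly one center.
  map <- unique(out[, c("surgeon", "center")])
  dup <- map$surgeon[duplicated(map$surgeon)]
  if (length(dup) > 0) {
    abort(sprintf(
      "Nesting violation: surgeon '%s' appears under more than one center.",
      dup[1]), class = "mlsurvstd_nesting_error")
  }

  # Zero-time handling.
  zero_event <- out$time == 0 & out$event == 1
  if (any(zero_event)) {
    abort(sprintf("Event at time 0 (row %d): hazard undefined at the origin.",
                  which(zero_event)[1]),
          class = "mlsurvstd_parse_error")
  }
  zero_cens <- out$time == 0 & out$event == 0
  if (any(zero_cens)) {
    warn(sprintf("Dropping %d censored record(s) at time 0 (no information).",
                 sum(zero_cens)))
    out <- out[!zero_cens, , drop = FALSE]
  }

  if (anyNA(out[covariates])) {
    abort("Missing covariate values are not supported (no imputation).",
          class = "mlsurvstd_parse_error")
  }
  if (sum(out$event) < 1) {
    abort("Dataset contains no events; the likelihood is degenerate.",
          class = "mlsurvstd_parse_error")
  }

  structure(out, covariates = covariates,
            class = c("survdata", class(tibble())))
}

check_numeric_col <- function(x, name, role) {
  if (is.numeric(x)) {
    if (anyNA(x)) {
      abort(sprintf("Missing %s value in column '%s' at row %d.",
                    role, name, which(is.na(x))[1]),
            class = "mlsurvstd_parse_error")
    }
    return(invisible(TRUE))
  }
  xs <- suppressWarnings(as.numeric(x))
  if (anyNA(xs)) {
    abort(sprintf("Non-numeric %s value in column '%s' at row %d.",
                  role, name, which(is.na(xs))[1]),
          class = "mlsurvstd_parse_error")
  }
  invisible(TRUE)
}

survdata_covariates <- function(data) {
  cv <- attr(data, "covariates")
  if (is.null(cv)) {
    cv <- setdiff(names(data), c("time", "event", "surgeon", "center"))
    cv <- cv[vapply(data[cv], is.numeric, logical(1))]
  }
  cv
}

#' Read a hierarchical survival dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header, maps columns to the time / event /
#' surgeon / center roles (plus covariates) via `schema`, and validates the
#' result with [as_survdata()]. The delimiter is auto-detected from the
#' header line unless given.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list or character vector binding roles to column
#'   names: entries `time`, `event`, `surgeon`, `center`, and optionally
#'   `covariates` (character vector). Defaults to same-named columns.
#' @param delim Field delimiter; `NULL` auto-detects `","` vs `"\t"`.
#' @return A validated `survdata` tibble.
#' @export
read_survdata <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path),
          class = "mlsurvstd_schema_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  schema <- schema %||% list()
  # Convert fully numeric columns (read as character so that parse errors
  # can be reported with row numbers) except the cluster label roles.
  labels <- c(schema$surgeon %||% "surgeon", schema$center %||% "center")
  for (nm in setdiff(names(raw), labels)) {
    num <- suppressWarnings(as.numeric(raw[[nm]]))
    if (!anyNA(num) || all(is.na(num) == (raw[[nm]] %in% c("NA", "")))) {
      if (!anyNA(num)) raw[[nm]] <- num
    }
  }
  as_survdata(as.data.frame(raw, check.names = FALSE),
              time = schema$time %||% "time",
              event = schema$event %||% "event",
              surgeon = schema$surgeon %||% "surgeon",
              center = schema$center %||% "center",
              covariates = schema$covariates %||% NULL)
}

#' Write a hierarchical survival dataset to a delimited text file
#'
#' Inverse of [read_survdata()]: writing then reading back reproduces the
#' records exactly (up to double-precision text round-trip).
#'
#' @param data A `survdata` tibble (or coercible data frame).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_survdata <- function(data, path, delim = ",") {
  readr::write_delim(as.data.frame(data), path, delim = delim)
  invisible(path)
}

#' Summarize the hierarchy of a three-level survival dataset
#'
#' @param data A `survdata` tibble.
#' @return A list of class `hier_summary` with elements `n`, `K` (number of
#'   centers), `n_surgeons`, `events`, `event_fraction`, `time_quantiles`,
#'   and per-cluster tibbles `centers` (with surgeon counts `J` and subject
#'   counts) and `surgeons` (with subject counts `I`).
#' @export
summarize_hierarchy <- function(data) {
  surgeons <- data |>
    dplyr::group_by(.data$center, .data$surgeon) |>
    dplyr::summarise(I = dplyr::n(), events = sum(.data$event),
                     .groups = "drop") |>
    dplyr::arrange(.data$center, .data$surgeon)
  centers <- surgeons |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(J = dplyr::n(), n = sum(.data$I),
                     events = sum(.data$events), .groups = "drop")
  structure(list(
    n = nrow(data),
    K = nrow(centers),
    n_surgeons = nrow(surgeons),
    events = sum(data$event),
    event_fraction = mean(data$event),
    time_quantiles = quantile(data$time, c(0, 0.25, 0.5, 0.75, 1)),
    centers = centers,
    surgeons = surgeons
  ), class = "hier_summary")
}

#' @export
print.hier_summary <- function(x, ...) {
  cat(sprintf(
    "Three-level survival data: %d subjects, %d surgeons, %d centers\n",
    x$n, x$n_surgeons, x$K))
  cat(sprintf("Events: %d (%.1f%%)\n", x$events, 100 * x$event_fraction))
  cat("Follow-up quantiles:\n")
  print(round(x$time_quantiles, 3))
  invisible(x)
}
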