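#' Construct a right-censored survival dataset
#'
#' The central data container of the package: one record per subject holding a
#' non-negative follow-up time, an event indicator (0 = censored, 1 = event)
#' and an optional data frame of covariates.  All modelling functions in the
#' package accept this class.
#'
#' @param time Numeric vector of non-negative follow-up times.
#' @param status Vector of event indicators; 0 = censored, 1 = event.
#' @param covariates Optional data frame of covariate columns (numeric or
#'   factor), one row per subject.  Column names must be unique and non-empty.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `time`, `status` (integer) and `covariates` (data frame, possibly with
#'   zero columns).
#' @examples
#' ds <- survival_dataset(c(1, 2, 3), c(1, 0, 1))
#' summary(ds)
#' @export
survival_dataset <- function(time, status, covariates = NULL) {
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(time) < 1L)
    stop("a survival dataset needs at least one subject", call. = FALSE)
  if (length(status) != length(time))
    stop("`time` and `status` must have the same length", call. = FALSE)
  bad_t <- which(!is.finite(time) | time < 0)
  if (length(bad_t))
    stop("negative or non-finite follow-up time in row(s): ",
         paste(utils::head(bad_t, 5L), collapse = ", "), call. = FALSE)
  bad_s <- which(!(status %in% c(0L, 1L)))
  if (length(bad_s))
    stop("status outside {0, 1} in row(s): ",
         paste(utils::head(bad_s, 5L), collapse = ", "), call. = FALSE)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_along(time))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(time))
      stop("`covariates` must have one row per subject", call. = FALSE)
    nm <- names(covariates)
    if (anyDuplicated(nm) || any(!nzchar(nm)))
      stop("covariate names must be unique and non-empty", call. = FALSE)
  }
  structure(list(time = time, status = status, covariates = covariates),
            class = "survival_dataset")
}

#' Number of subjects in a survival dataset
#' @param ds A `survival_dataset`.
#' @return Integer subject count.
#' @export
n_subjects <- function(ds) length(ds$time)

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> ", n_subjects(x), " subjects, ",
      sum(x$status), " events (", sum(x$status == 0L), " censored)\n", sep = "")
  if (ncol(x$covariates))
    cat("covariates: ", paste(names(x$covariates), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.survival_dataset <- function(object, ...) {
  out <- list(n = n_subjects(object), events = sum(object$status),
              censored = sum(object$status == 0L),
              time_range = range(object$time),
              covariates = names(object$covariates))
  class(out) <- "summary.survival_dataset"
  out
}

#' @export
print.summary.survival_dataset <- function(x, ...) {
  cat("Subjects:  ", x$n, "\nEvents:    ", x$events,
      "\nCensored:  ", x$censored, "\nFollow-up: [",
      x$time_range[1], ", ", x$time_range[2], "]\n", sep = "")
  if (length(x$covariates))
    cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a data frame to a survival dataset
#'
#' @param data A data frame.
#' @param time_column,status_column Names of the follow-up-time and
#'   censorship-status columns.
#' @param covariate_columns Character vector of covariate column names
#'   (default: every remaining column).
#' @param event_code,censor_code Values in `status_column` coding an event and
#'   a censoring.  Any other value is a validation error.
#' @return A [survival_dataset()].
#' @export
as_survival_dataset <- function(data, time_column, status_column,
                                covariate_columns = NULL,
                                event_code = 1, censor_code = 0) {
  for (col in c(time_column, status_column, covariate_columns))
    if (!col %in% names(data))
      stop("column not present in data: '", col, "'", call. = FALSE)
  if (is.null(covariate_columns))
    covariate_columns <- setdiff(names(data), c(time_column, status_column))

  time <- suppressWarnings(as.numeric(data[[time_column]]))
  bad <- which(is.na(time) & !is.na(data[[time_column]]))
  if (length(bad))
    stop("unparseable follow-up time in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)

  raw_status <- data[[status_column]]
  status <- rep(NA_integer_, length(raw_status))
  status[raw_status == event_code] <- 1L
  status[raw_status == censor_code] <- 0L
  bad <- which(is.na(status))
  if (length(bad))
    stop("status value not in {", censor_code, ", ", event_code,
         "} in row(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop("negative or missing follow-up time in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)

  covs <- data[covariate_columns]
  covs[] <- lapply(covs, function(v) if (is.character(v)) factor(v) else v)
  # rows with missing covariate values are dropped, with a reported count
  keep <- if (ncol(covs)) stats::complete.cases(covs) else rep(TRUE, length(time))
  if (any(!keep))
    message(sum(!keep), " row(s) with missing covariate values dropped")
  survival_dataset(time[keep], status[keep], covs[keep, , drop = FALSE])
}

#' Load right-censored survival data from a CSV file
#'
#' Reads a comma-delimited file with a header row and declares which columns
#' hold the follow-up time and the censorship status; the remaining (or the
#' explicitly named) columns become covariates.  Character covariates are
#' converted to factors.  Rows with missing covariate values are dropped with
#' a message.
#'
#' @param path Path to a CSV file (RFC 4180, header required, UTF-8).
#' @inheritParams as_survival_dataset
#' @return A [survival_dataset()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = 1:3, d = c(1, 0, 1)), f, row.names = FALSE)
#' load_csv(f, "t", "d")
#' @export
load_csv <- function(path, time_column, status_column,
                     covariate_columns = NULL,
                     event_code = 1, censor_code = 0) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  as_survival_dataset(raw, time_column, status_column, covariate_columns,
                      event_code = event_code, censor_code = censor_code)
}

#' Write a survival dataset to CSV
#'
#' Inverse of [load_csv()]: writes one row per subject with columns `time`,
#' `status` and the covariates.
#'
#' @param ds A `survival_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(ds, path) {
  df <- cbind(data.frame(time = ds$time, status = ds$status), ds$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stratify a numeric covariate into labelled intervals
#'
#' Replaces a numeric covariate by a categorical one cut at the given
#' breakpoints.  The first interval is closed at both ends and every
#' subsequent interval is left-open/right-closed, so printed ranges such as
#' "39 to 45, 45 to 55" assign a boundary value (45) to the earlier stratum.
#'
#' @param ds A `survival_dataset`.
#' @param column Name of a numeric covariate.
#' @param breakpoints Strictly increasing numeric vector of interval
#'   boundaries (length = number of strata + 1).
#' @param labels Optional stratum labels (default `"1"`, `"2"`, ...).
#' @param right Logical; right-closed intervals (the default convention
#'   described above).  `FALSE` switches to left-closed/right-open intervals
#'   with the last interval closed at both ends.
#' @return The dataset with `column` replaced by a factor of strata.
#' @examples
#' ds <- survival_dataset(1:4, rep(1, 4), data.frame(age = c(40, 50, 60, 70)))
#' table(stratify(ds, "age", c(39, 45, 55, 65, 82))$covariates$age)
#' @export
stratify <- function(ds, column, breakpoints, labels = NULL, right = TRUE) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (!column %in% names(ds$covariates))
    stop("no covariate named '", column, "'", call. = FALSE)
  v <- ds$covariates[[column]]
  if (!is.numeric(v))
    stop("covariate '", column, "' is not numeric", call. = FALSE)
  if (any(diff(breakpoints) <= 0))
    stop("`breakpoints` must be strictly increasing", call. = FALSE)
  k <- length(breakpoints) - 1L
  if (is.null(labels)) labels <- as.character(seq_len(k))
  if (length(labels) != k)
    stop("need ", k, " labels, got ", length(labels), call. = FALSE)
  out_of_range <- which(v < breakpoints[1L] | v > breakpoints[k + 1L])
  if (length(out_of_range))
    stop("value(s) outside [", breakpoints[1L], ", ", breakpoints[k + 1L],
         "] in row(s): ", paste(utils::head(out_of_range, 5L), collapse = ", "),
         call. = FALSE)
  ds$covariates[[column]] <- cut(v, breaks = breakpoints, labels = labels,
                                 right = right, include.lowest = TRUE)
  ds
}

#' Merge and rename categories of a categorical covariate
#'
#' @param ds A `survival_dataset`.
#' @param column Name of a factor (or character) covariate.
#' @param merge_map Named character vector mapping old category labels to new
#'   ones, e.g. `c("2" = "More than 1", "3" = "More than 1")`.  Categories not
#'   mentioned are left unchanged; an empty map is the identity.
#' @return The dataset with the categories merged.
#' @examples
#' ds <- survival_dataset(1:3, c(1, 1, 0),
#'                        data.frame(n_tumour = factor(c("1", "2", "3"))))
#' regroup(ds, "n_tumour", c("2" = "More than 1", "3" = "More than 1"))
#' @export
regroup <- function(ds, column, merge_map) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (!column %in% names(ds$covariates))
    stop("no covariate named '", column, "'", call. = FALSE)
  v <- ds$covariates[[column]]
  if (!is.factor(v)) v <- factor(v)
  if (length(merge_map) == 0L) {
    ds$covariates[[column]] <- v
    return(ds)
  }
  if (is.null(names(merge_map)) || any(!nzchar(names(merge_map))))
    stop("`merge_map` must be a named vector (old label -> new label)",
         call. = FALSE)
  absent <- setdiff(names(merge_map), levels(v))
  if (length(absent))
    stop("category not present in '", column, "': ",
         paste(absent, collapse = ", "), call. = FALSE)
  lev <- levels(v)
  new_lev <- ifelse(lev %in% names(merge_map), merge_map[lev], lev)
  levels(v) <- new_lev
  ds$covariates[[column]] <- v
  ds
}
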