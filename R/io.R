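## Schema-validated delimited I/O for every table the pipeline consumes.

.readDelim <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.checkSchema <- function(df, required, types, file = "<table>") {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(file, ": missing column(s): ", paste(miss, collapse = ", "))
  for (col in names(types)) {
    if (!col %in% names(df)) next
    ok <- switch(types[[col]],
                 numeric = is.numeric(df[[col]]),
                 character = is.character(df[[col]]) || is.factor(df[[col]]))
    if (!ok) stop(file, ": column '", col, "' must be ", types[[col]])
  }
  df
}

#' Read and validate pipeline input tables
#'
#' Each reader checks the required columns and their types and reports the
#' offending file and column on failure. Tables are tab-delimited text with
#' a header row.
#'
#' @param path File path.
#' @return Validated data.frame (or matrix for ROI time series).
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
readTrialTable <- function(path) {
  df <- .readDelim(path)
  df <- .checkSchema(df, c("subject", "trial", "trial_type", "rt_ms",
                           "response", "correct_response", "ssd_ms"),
                     c(trial = "numeric", rt_ms = "numeric",
                       ssd_ms = "numeric", trial_type = "character",
                       response = "character"), path)
  if (any(df$rt_ms <= 0, na.rm = TRUE))
    stop(path, ": rt_ms must be positive where present")
  if (any(!is.na(df$ssd_ms) & df$trial_type != "stop"))
    stop(path, ": ssd_ms present on non-stop trials")
  df
}

#' @rdname tableIO
#' @export
readEventTable <- function(path) {
  df <- .readDelim(path)
  df <- .checkSchema(df, c("onset", "duration", "condition"),
                     c(onset = "numeric", duration = "numeric",
                       condition = "character"), path)
  if (any(df$onset < 0) || any(diff(df$onset) < 0))
    stop(path, ": onsets must be non-negative and non-decreasing")
  if (any(df$duration < 0)) stop(path, ": durations must be >= 0")
  df
}

#' @rdname tableIO
#' @export
readRoiTimeSeries <- function(path) {
  df <- .readDelim(path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(path, ": ROI time series must be numeric")
  m
}

#' @rdname tableIO
#' @export
readCohortTable <- function(path) {
  df <- .readDelim(path)
  df <- .checkSchema(df, c("subject", "phenotype"),
                     c(phenotype = "numeric", subject = "character"), path)
  dup <- df$subject[duplicated(df$subject)]
  if (length(dup)) stop(path, ": duplicate subject id(s): ",
                        paste(unique(dup), collapse = ", "))
  df
}

#' @rdname tableIO
#' @export
readItemTable <- function(path) {
  df <- .readDelim(path)
  if (!"subject" %in% names(df)) stop(path, ": missing column(s): subject")
  items <- df[setdiff(names(df), "subject")]
  if (!all(vapply(items, is.numeric, logical(1))))
    stop(path, ": item columns must be numeric")
  df
}

#' @rdname tableIO
#' @export
readWavePanel <- function(path) {
  df <- .readDelim(path)
  .checkSchema(df, c("x1", "y1", "x2", "y2", "x3", "y3"),
               setNames(rep("numeric", 6),
                        c("x1", "y1", "x2", "y2", "x3", "y3")), path)
}

#' @rdname tableIO
#' @param df Table to write.
#' @export
writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an event table as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type` with trial types `go`,
#' `stop_success`, `stop_fail`.
#'
#' @param trials Trial table from [genSstTrials].
#' @param path Output path.
#' @export
writeBidsEvents <- function(trials, path) {
  ev <- data.frame(onset = trials$onset,
                   duration = ifelse(trials$trial_type == "go", 1, 0.3),
                   trial_type = c(go = "go", stop_success = "stop_success",
                                  stop_fail = "stop_fail")[trials$outcome])
  writeTable(ev, path)
}
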