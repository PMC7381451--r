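.REQUIRED_COLS <- c("participant_id", "session_id", "condition", "face_id",
                    "dilution_pct", "test_interval", "response_interval",
                    "correct")
.OPTIONAL_COLS <- c("duration_ms", "image_size_deg", "software")

#' Read a trial-record CSV
#'
#' Reads and validates trial-level 2IFC records. The dialect is a UTF-8 CSV
#' with a header row and "." as decimal separator; required columns are
#' `participant_id`, `session_id`, `condition`, `face_id`, `dilution_pct`
#' (in \[0, 100\]), `test_interval` and `response_interval` (1 or 2), and
#' `correct` (logical, which must equal
#' `test_interval == response_interval`). Optional metadata columns
#' `duration_ms`, `image_size_deg` and `software` are carried through.
#' Validation failures name the offending row and column.
#'
#' @param path Path to a CSV file.
#' @return A validated trial tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trials(make_synthetic_study("exp1", seed = 1), f)
#' trials <- read_trials(f)
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(.REQUIRED_COLS, names(x))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  fail <- function(rows, col, why) {
    stop(sprintf("invalid value in column '%s', row %d: %s",
                 col, rows[1], why), call. = FALSE)
  }
  x$participant_id <- as.character(x$participant_id)
  x$session_id <- as.character(x$session_id)
  x$condition <- as.character(x$condition)
  x$face_id <- as.character(x$face_id)

  bad <- which(!is.finite(x$dilution_pct) | x$dilution_pct < 0 |
                 x$dilution_pct > 100)
  if (length(bad) > 0) fail(bad, "dilution_pct", "must lie in [0, 100]")
  for (col in c("test_interval", "response_interval")) {
    v <- x[[col]]
    bad <- which(!(v %in% c(1, 2)))
    if (length(bad) > 0) fail(bad, col, "must be 1 or 2")
    x[[col]] <- as.integer(v)
  }
  if (is.numeric(x$correct)) x$correct <- x$correct != 0
  if (!is.logical(x$correct))
    stop("column 'correct' must be logical (TRUE/FALSE or 0/1)", call. = FALSE)
  bad <- which(x$correct != (x$test_interval == x$response_interval))
  if (length(bad) > 0)
    fail(bad, "correct",
         "contradicts test_interval == response_interval")
  x
}

#' Write a trial-record CSV
#'
#' Writes trials in the dialect read back by [read_trials()] (comma
#' separated, header row, LF line endings). The round-trip is lossless for
#' all required and optional columns.
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  miss <- setdiff(.REQUIRED_COLS, names(trials))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- c(.REQUIRED_COLS, intersect(.OPTIONAL_COLS, names(trials)))
  readr::write_csv(trials[, keep], path, eol = "\n", progress = FALSE)
  invisible(path)
}
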