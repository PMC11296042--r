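#' Trial-level rating tables
#'
#' A rating table is a long-format tibble with one row per trial: a
#' participant, within one session, rating one stimulus on one scale with a
#' bounded slider in \[1, 7\]. Retest trials re-present a stimulus already
#' rated in the same session and are used for within-subject reliability.
#'
#' Required columns: `participant_id`, `session_id`, `domain` (one of
#' `"narrative"`, `"video"`, `"real_life"`), `stimulus_id`, `scale_id`,
#' `rating`, `trial_type` (`"main"` or `"retest"`). Optional columns:
#' `reaction_time_ms` (non-negative, `NA` for timeout), `timeout` (logical),
#' `attention_fails` (per-session count of failed attention checks), `wave`
#' (integer, real-life sampling wave).
#'
#' @param x a data frame to validate and classify.
#' @return `as_rating_table()` returns the validated tibble with class
#'   `emospace_rating_table` prepended.
#' @name rating_table
NULL

.required_cols <- c("participant_id", "session_id", "domain", "stimulus_id",
                    "scale_id", "rating", "trial_type")
.domains <- c("narrative", "video", "real_life")

#' @rdname rating_table
#' @export
as_rating_table <- function(x) {
  x <- tibble::as_tibble(x)
  validate_rating_table(x)
  class(x) <- unique(c("emospace_rating_table", class(x)))
  x
}

#' Validate a rating table
#'
#' Checks the schema, the rating range, key uniqueness and retest pairing.
#' Out-of-range ratings are reported (with offending row numbers), never
#' silently clipped.
#'
#' @param x a data frame of trial records.
#' @param check_range enforce the \[1, 7\] rating range (default `TRUE`;
#'   turned off for tables whose ratings have been stimulus-centered).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_rating_table <- function(x, check_range = TRUE) {
  missing_cols <- setdiff(.required_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("rating table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "emospace_schema_error")
  }
  if (!is.numeric(x$rating)) {
    abort("`rating` must be numeric", class = "emospace_schema_error")
  }
  bad_domain <- setdiff(unique(x$domain), .domains)
  if (length(bad_domain) > 0) {
    abort(sprintf("unknown domain(s): %s", paste(bad_domain, collapse = ", ")),
          class = "emospace_validation_error")
  }
  bad_type <- setdiff(unique(x$trial_type), c("main", "retest"))
  if (length(bad_type) > 0) {
    abort(sprintf("unknown trial_type(s): %s", paste(bad_type, collapse = ", ")),
          class = "emospace_validation_error")
  }
  out_of_range <- if (check_range) {
    which(!is.na(x$rating) & (x$rating < 1 | x$rating > 7))
  } else {
    integer(0)
  }
  if (length(out_of_range) > 0) {
    abort(sprintf(
      "%d rating(s) outside [1, 7]; first offending rows: %s",
      length(out_of_range),
      paste(head(out_of_range, 5L), collapse = ", ")),
      class = "emospace_validation_error")
  }
  key <- paste(x$session_id, x$stimulus_id, x$scale_id, x$trial_type, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf(
      "duplicated (session, stimulus, scale, trial_type) key(s); first offending rows: %s",
      paste(head(which(dup), 5L), collapse = ", ")),
      class = "emospace_validation_error")
  }
  rt <- x[x$trial_type == "retest", c("session_id", "stimulus_id", "scale_id")]
  if (nrow(rt) > 0) {
    main_key <- unique(paste(x$session_id[x$trial_type == "main"],
                             x$stimulus_id[x$trial_type == "main"],
                             x$scale_id[x$trial_type == "main"], sep = "\r"))
    rt_key <- paste(rt$session_id, rt$stimulus_id, rt$scale_id, sep = "\r")
    orphans <- which(!(rt_key %in% main_key))
    if (length(orphans) > 0) {
      abort(sprintf(
        "%d retest trial(s) have no matching main trial in the same session",
        length(orphans)),
        class = "emospace_validation_error")
    }
  }
  invisible(x)
}

#' Read a rating table from delimited text
#'
#' @param path path to a CSV (or other delimited) file with a header naming
#'   all required columns (see [rating_table]).
#' @param delim field delimiter, `","` by default.
#' @param col_map optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(participant_id = "subj")`.
#' @return a validated rating table (see [as_rating_table()]).
#' @export
read_rating_table <- function(path, delim = ",", col_map = NULL) {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(x)) {
        abort(sprintf("column mapping refers to absent column `%s`", src),
              class = "emospace_schema_error")
      }
      names(x)[names(x) == src] <- canon
    }
  }
  as_rating_table(x)
}

#' Write a rating table to delimited text
#'
#' @param x a rating table.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_rating_table <- function(x, path, delim = ",") {
  validate_rating_table(x)
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  invisible(path)
}
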