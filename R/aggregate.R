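#' Stimulus-by-scale rating matrices
#'
#' The unit of all multivariate analysis: a numeric matrix with one row per
#' stimulus (or real-life instance) and one column per scale, values in
#' \[1, 7\]. For evoked domains cells are means across raters' main trials;
#' for real-life data each single-rater instance is one raw row. The matrix
#' carries a `domain` tag, an `aggregation` tag (`"rater-mean"` or
#' `"single-rater"`) and, optionally, per-row category labels.
#'
#' @param x numeric matrix (rows = stimuli/instances, columns = scales).
#' @param domain `"narrative"`, `"video"` or `"real_life"`.
#' @param aggregation `"rater-mean"` or `"single-rater"`.
#' @param labels optional per-row category labels (e.g., intended emotion).
#' @return an object of class `emospace_rating_matrix` (a numeric matrix
#'   with attributes).
#' @export
rating_matrix <- function(x, domain, aggregation, labels = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  domain <- match.arg(domain, .domains)
  aggregation <- match.arg(aggregation, c("rater-mean", "single-rater"))
  if (!is.null(labels) && length(labels) != nrow(x)) {
    abort("`labels` must have one entry per row")
  }
  structure(x, class = c("emospace_rating_matrix", class(x)),
            domain = domain, aggregation = aggregation, labels = labels)
}

#' @export
print.emospace_rating_matrix <- function(x, ...) {
  cat(sprintf("<rating matrix: %d x %d, domain = %s, %s%s>\n",
              nrow(x), ncol(x), attr(x, "domain"), attr(x, "aggregation"),
              if (is.null(attr(x, "labels"))) "" else ", labeled"))
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

# Strip the class but keep the data; used before handing to matrix code.
as_matrix <- function(x) {
  if (inherits(x, "emospace_rating_matrix")) {
    attr_keep <- dimnames(x)
    x <- unclass(x)
    attributes(x) <- list(dim = dim(x), dimnames = attr_keep)
  }
  as.matrix(x)
}

#' Aggregate a rating table into a stimulus-by-scale matrix
#'
#' For the evoked domains (`"narrative"`, `"video"`), each cell is the mean
#' of all raters' main-trial ratings of that stimulus on that scale; retest
#' trials never enter the means. For `"real_life"`, each single-rater
#' instance is one raw row (no averaging), with the instance identified by
#' `stimulus_id`.
#'
#' @param table a post-exclusion rating table.
#' @param domain which domain to aggregate.
#' @param scales optional character vector fixing the column roster and
#'   order; defaults to the scales present in the table.
#' @return a [rating_matrix()].
#' @export
aggregate_matrix <- function(table, domain = c("narrative", "video", "real_life"),
                             scales = NULL) {
  domain <- match.arg(domain)
  validate_rating_table(table)
  sub <- table[table$domain == domain & table$trial_type == "main", , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("no main trials for domain `%s`", domain))
  scales <- scales %||% sort(unique(sub$scale_id))
  stimuli <- sort(unique(sub$stimulus_id))

  if (domain == "real_life") {
    wide <- tidyr::pivot_wider(
      sub[, c("stimulus_id", "scale_id", "rating")],
      names_from = "scale_id", values_from = "rating")
    missing_scales <- setdiff(scales, names(wide))
    if (length(missing_scales) > 0 || anyNA(wide[scales])) {
      bad <- if (length(missing_scales) > 0) missing_scales else {
        scales[vapply(wide[scales], anyNA, logical(1))]
      }
      abort(sprintf("empty (instance, scale) cell(s) for scale(s): %s",
                    paste(head(bad, 5L), collapse = ", ")),
            class = "emospace_completeness_error")
    }
    m <- as.matrix(wide[, scales, drop = FALSE])
    rownames(m) <- wide$stimulus_id
    return(rating_matrix(m, domain, "single-rater"))
  }

  m <- matrix(NA_real_, length(stimuli), length(scales),
              dimnames = list(stimuli, scales))
  means <- aggregate(rating ~ stimulus_id + scale_id, data = sub, FUN = mean)
  idx <- cbind(match(means$stimulus_id, stimuli), match(means$scale_id, scales))
  keep <- !is.na(idx[, 2])
  m[idx[keep, , drop = FALSE]] <- means$rating[keep]
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    abort(sprintf("empty (stimulus, scale) cell(s), e.g. (%s, %s)",
                  stimuli[holes[1, 1]], scales[holes[1, 2]]),
          class = "emospace_completeness_error")
  }
  rating_matrix(m, domain, "rater-mean")
}
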