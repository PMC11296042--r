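#' Within-subject test-retest reliability
#'
#' Pearson correlation between main and retest ratings of the same stimuli,
#' per session. Sessions with fewer than `min_pairs` valid pairs or zero
#' variance on either side get `NA` (undefined) and are ignored by
#' downstream medians rather than being treated as zero.
#'
#' @param table a rating table with retest trials.
#' @param min_pairs minimum number of (main, retest) pairs (default 3;
#'   Pearson r is not meaningful below that).
#' @return tibble with `session_id`, `scale_id`, `stimulus_set`, `n_pairs`,
#'   `r`.
#' @export
test_retest <- function(table, min_pairs = 3L) {
  validate_rating_table(table)
  if (!any(table$trial_type == "retest")) {
    warn("no retest trials; returning an empty result")
    return(session_reliability(table[0, ], min_pairs))
  }
  session_reliability(table, min_pairs = min_pairs)
}

#' Between-subject split-half reliability
#'
#' For each rater cohort (raters of the same scale on the same stimulus
#' set), raters are randomly split into two halves, per-stimulus mean
#' ratings are computed within each half from main trials, and the two mean
#' vectors are correlated; the split is repeated `n_rep` times.
#'
#' @param table a rating table.
#' @param n_rep number of random resplits (default 50).
#' @param seed integer seed for the resplits.
#' @return tibble with `scale_id`, `stimulus_set`, `rep`, `r`.
#' @export
split_half <- function(table, n_rep = 50, seed = 1L) {
  validate_rating_table(table)
  main <- table[table$trial_type == "main", , drop = FALSE]
  set_of <- session_stimulus_set(main)
  main$stimulus_set <- set_of[main$session_id]
  cohorts <- split(main, list(main$scale_id, main$stimulus_set), drop = TRUE)
  with_seed(seed, {
    out <- lapply(cohorts, function(co) {
      sessions <- sort(unique(co$session_id))
      n_s <- length(sessions)
      if (n_s < 2) return(NULL)
      if (n_s < 4) warn(sprintf("cohort for scale `%s` has only %d raters; halves of size < 2",
                                co$scale_id[1], n_s))
      wide <- tapply(co$rating, list(co$stimulus_id, co$session_id), mean)
      rs <- vapply(seq_len(n_rep), function(i) {
        half <- sample(sessions, floor(n_s / 2))
        m1 <- rowMeans(wide[, colnames(wide) %in% half, drop = FALSE], na.rm = TRUE)
        m2 <- rowMeans(wide[, !(colnames(wide) %in% half), drop = FALSE], na.rm = TRUE)
        safe_cor(m1, m2)
      }, numeric(1))
      tibble::tibble(scale_id = co$scale_id[1], stimulus_set = co$stimulus_set[1],
                     rep = seq_len(n_rep), r = rs)
    })
    dplyr::bind_rows(out)
  })
}

# stimulus-set id per session (sorted main-trial stimulus roster)
session_stimulus_set <- function(table) {
  sets <- tapply(table$stimulus_id, table$session_id,
                 function(s) paste(sort(unique(s)), collapse = "|"))
  setNames(as.character(sets), names(sets))
}

#' Scale-quality report
#'
#' Per-scale medians of test-retest reliability (across sessions with a
#' defined r) and split-half reliability (across resplits), the session
#' count, and optionally a readability grade for each scale definition.
#'
#' @param table a rating table.
#' @param definitions optional tibble with `scale_id` and `definition`
#'   columns (e.g., [scale_roster()]); when given, a Flesch-Kincaid grade is
#'   computed per scale.
#' @param n_rep split-half resplits.
#' @param seed seed for the resplits.
#' @return tibble with one row per scale: `median_test_retest`,
#'   `median_split_half`, `n_sessions`, and `fk_grade` when definitions are
#'   given; the readability-reliability correlations are attached as
#'   attribute `"readability_cor"`.
#' @export
scale_quality <- function(table, definitions = NULL, n_rep = 50, seed = 1L) {
  tr <- test_retest(table)
  sh <- split_half(table, n_rep = n_rep, seed = seed)
  tr_med <- dplyr::summarise(
    dplyr::group_by(tr, .data$scale_id),
    median_test_retest = median(.data$r, na.rm = TRUE),
    n_sessions = dplyr::n(), .groups = "drop")
  sh_med <- dplyr::summarise(
    dplyr::group_by(sh, .data$scale_id),
    median_split_half = median(.data$r, na.rm = TRUE), .groups = "drop")
  out <- dplyr::left_join(tr_med, sh_med, by = "scale_id")
  if (!is.null(definitions)) {
    defs <- definitions[match(out$scale_id, definitions$scale_id), ]
    out$fk_grade <- vapply(defs$definition, fk_grade, numeric(1), USE.NAMES = FALSE)
    attr(out, "readability_cor") <- c(
      test_retest = safe_cor(out$fk_grade, out$median_test_retest),
      split_half = safe_cor(out$fk_grade, out$median_split_half))
  }
  out
}

#' Flag low-quality scales
#'
#' Either an explicit exclusion roster (the default reproduces the five
#' canonical low-reliability scales, leaving 23 of 28) or reliability
#' thresholds applied to a [scale_quality()] report.
#'
#' @param report a [scale_quality()] tibble (may be `NULL` when only an
#'   explicit roster is used).
#' @param exclude explicit character vector of scale ids to flag; default
#'   the five canonical exclusions.
#' @param min_test_retest,min_split_half optional thresholds; scales whose
#'   median falls strictly below either are flagged in addition to the
#'   explicit roster.
#' @return character vector of flagged scale ids (those present in the
#'   report, when one is given).
#' @export
flag_low_quality <- function(report = NULL, exclude = .low_quality_scales,
                             min_test_retest = NULL, min_split_half = NULL) {
  flagged <- exclude %||% character(0)
  if (!is.null(report)) {
    if (!is.null(min_test_retest)) {
      flagged <- c(flagged,
                   report$scale_id[!is.na(report$median_test_retest) &
                                     report$median_test_retest < min_test_retest])
    }
    if (!is.null(min_split_half)) {
      flagged <- c(flagged,
                   report$scale_id[!is.na(report$median_split_half) &
                                     report$median_split_half < min_split_half])
    }
    flagged <- intersect(unique(flagged), report$scale_id)
  } else {
    flagged <- unique(flagged)
  }
  flagged
}

#' Flesch-Kincaid grade level
#'
#' `0.39 * (words / sentences) + 11.8 * (syllables / words) - 15.59`, with a
#' dictionary-free syllable heuristic: a syllable is a maximal vowel group
#' (`aeiouy`), minus one for a silent ending (`-e`, `-es`, `-ed`), with a
#' minimum of one syllable per word.
#'
#' @param text a character string.
#' @return the grade level (a single number; can be negative for very simple
#'   text).
#' @export
fk_grade <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  sentences <- strsplit(text, "[.!?]+")[[1]]
  sentences <- sentences[grepl("[[:alpha:]]", sentences)]
  words <- unlist(strsplit(text, "[^[:alpha:]']+"))
  words <- words[nchar(gsub("'", "", words)) > 0]
  if (length(sentences) == 0 || length(words) == 0) {
    abort("text has no sentences or words", class = "emospace_domain_error")
  }
  syllables <- vapply(words, count_syllables, numeric(1))
  0.39 * (length(words) / length(sentences)) +
    11.8 * (sum(syllables) / length(words)) - 15.59
}

count_syllables <- function(word) {
  w <- tolower(gsub("[^a-z]", "", tolower(word)))
  if (nchar(w) == 0) return(0)
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1) 0L else length(groups)
  if (n > 1 && grepl("(e|es|ed)$", w) && !grepl("(le|les|[aeiouy]ed)$", w)) {
    n <- n - 1L
  }
  max(n, 1L)
}
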