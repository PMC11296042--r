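#' Exclusion rule configuration
#'
#' Thresholds for the multi-level exclusion procedure, defaulting to the
#' pre-registered values of the evoked-emotion study design: trials are
#' dropped on timeout or when the reaction time is under 400 ms; sessions are
#' dropped when more than 1 of the 3 attention checks failed, when the
#' session's test-retest reliability falls more than 3 standard deviations
#' below the mean reliability of the same (scale, stimulus-set) rater cohort,
#' or when more than 10% of the session's trials are invalid; participants
#' are dropped after more than 3 invalid sessions.
#'
#' @param rt_min_ms minimum valid reaction time in milliseconds.
#' @param max_attention_fails maximum tolerated failed attention checks per
#'   session (strictly more fails excludes the session).
#' @param reliability_sd the z-cutoff of the cohort reliability screen;
#'   sessions strictly below mean − `reliability_sd`·SD are excluded.
#' @param max_invalid_frac maximum tolerated fraction of invalid trials per
#'   session (strictly more excludes the session).
#' @param max_invalid_sessions maximum tolerated invalid sessions per
#'   participant (strictly more excludes the participant).
#' @param min_retest_pairs minimum number of valid (main, retest) pairs for a
#'   session reliability to be defined; sessions with fewer pairs are screened
#'   only by the invalid-trial rule.
#' @return a list of class `emospace_exclusion_rules`.
#' @export
exclusion_rules <- function(rt_min_ms = 400, max_attention_fails = 1,
                            reliability_sd = 3, max_invalid_frac = 0.10,
                            max_invalid_sessions = 3, min_retest_pairs = 3) {
  out <- list(rt_min_ms = rt_min_ms, max_attention_fails = max_attention_fails,
              reliability_sd = reliability_sd, max_invalid_frac = max_invalid_frac,
              max_invalid_sessions = max_invalid_sessions,
              min_retest_pairs = min_retest_pairs)
  class(out) <- "emospace_exclusion_rules"
  out
}

#' Apply multi-level exclusions to a rating table
#'
#' Drops invalid trials, then invalid sessions, then invalid participants,
#' per [exclusion_rules()]. The cohort reliability screen (mean − 3 SD among
#' raters of the same scale and stimulus set) is iterated to a fixed point
#' within the call, so that re-applying the exclusions to the output is a
#' no-op.
#'
#' @param table a rating table (see [rating_table]); must carry
#'   `reaction_time_ms` and `attention_fails` columns for the corresponding
#'   rules (a `timeout` logical column is honored when present).
#' @param rules an [exclusion_rules()] object.
#' @return a list with elements `table` (the filtered rating table) and
#'   `report` (an exclusion report: `$drops`, a tibble of per-rule drop
#'   counts with their level and reason code, and `$counts`, per-level
#'   input/dropped/surviving tallies).
#' @export
apply_exclusions <- function(table, rules = exclusion_rules()) {
  validate_rating_table(table)
  if (!inherits(rules, "emospace_exclusion_rules")) {
    abort("`rules` must be created by exclusion_rules()", class = "emospace_config_error")
  }
  if (!is.null(rules$rt_min_ms) && !("reaction_time_ms" %in% names(table))) {
    abort("reaction-time rule configured but `reaction_time_ms` column is absent",
          class = "emospace_config_error")
  }
  if (!is.null(rules$max_attention_fails) && !("attention_fails" %in% names(table))) {
    abort("attention-check rule configured but `attention_fails` column is absent",
          class = "emospace_config_error")
  }

  n_in <- c(trial = nrow(table),
            session = dplyr::n_distinct(table$session_id),
            participant = dplyr::n_distinct(table$participant_id))
  drops <- list()
  note <- function(level, reason, n) {
    drops[[length(drops) + 1L]] <<- tibble::tibble(level = level, reason = reason,
                                                   n_dropped = as.integer(n))
  }

  ## -- trial level ----------------------------------------------------------
  timeout <- if ("timeout" %in% names(table)) {
    !is.na(table$timeout) & table$timeout
  } else {
    rep(FALSE, nrow(table))
  }
  if ("reaction_time_ms" %in% names(table)) {
    timeout <- timeout | is.na(table$reaction_time_ms)
  }
  too_fast <- if (!is.null(rules$rt_min_ms)) {
    !is.na(table$reaction_time_ms) & table$reaction_time_ms < rules$rt_min_ms
  } else {
    rep(FALSE, nrow(table))
  }
  note("trial", "timeout", sum(timeout))
  note("trial", "rt_min", sum(too_fast & !timeout))
  invalid_trial <- timeout | too_fast
  # invalid-trial fraction per session, measured against the session's full
  # trial count before any removal
  frac_invalid <- tapply(invalid_trial, table$session_id, mean)
  kept <- table[!invalid_trial, , drop = FALSE]
  # retests whose main trial was dropped can no longer be paired; drop them too
  main_key <- paste(kept$session_id, kept$stimulus_id, kept$scale_id, sep = "\r")
  is_retest <- kept$trial_type == "retest"
  orphan <- is_retest & !(main_key %in% main_key[kept$trial_type == "main"])
  note("trial", "orphan_retest", sum(orphan))
  kept <- kept[!orphan, , drop = FALSE]

  ## -- session level --------------------------------------------------------
  sess <- dplyr::distinct(kept, .data$session_id, .data$participant_id,
                          .data$scale_id)
  bad_attention <- character(0)
  if (!is.null(rules$max_attention_fails)) {
    af <- tapply(table$attention_fails, table$session_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) 0 else max(v)
    })
    bad_attention <- names(af)[af > rules$max_attention_fails]
  }
  note("session", "attention", length(intersect(bad_attention, sess$session_id)))

  bad_frac <- names(frac_invalid)[frac_invalid > rules$max_invalid_frac]
  note("session", "invalid_trials", length(setdiff(intersect(bad_frac, sess$session_id),
                                                   bad_attention)))

  kept <- kept[!(kept$session_id %in% c(bad_attention, bad_frac)), , drop = FALSE]

  # cohort reliability screen, iterated to a fixed point
  n_rel <- 0L
  if (!is.null(rules$reliability_sd)) {
    repeat {
      rel <- session_reliability(kept, min_pairs = rules$min_retest_pairs)
      rel <- rel[!is.na(rel$r), , drop = FALSE]
      if (nrow(rel) == 0) break
      grp <- split(rel, list(rel$scale_id, rel$stimulus_set), drop = TRUE)
      bad <- unlist(lapply(grp, function(g) {
        if (nrow(g) < 2) return(character(0))
        thr <- mean(g$r) - rules$reliability_sd * sd(g$r)
        g$session_id[g$r < thr]
      }), use.names = FALSE)
      if (length(bad) == 0) break
      n_rel <- n_rel + length(bad)
      kept <- kept[!(kept$session_id %in% bad), , drop = FALSE]
    }
  }
  note("session", "low_reliability", n_rel)

  ## -- participant level ----------------------------------------------------
  sessions_by_part <- tapply(table$session_id, table$participant_id,
                             function(s) length(unique(s)))
  kept_by_part <- tapply(kept$session_id, kept$participant_id,
                         function(s) length(unique(s)))
  n_invalid <- sessions_by_part
  n_invalid[names(kept_by_part)] <-
    sessions_by_part[names(kept_by_part)] - kept_by_part
  bad_part <- names(n_invalid)[n_invalid > rules$max_invalid_sessions]
  bad_part <- intersect(bad_part, kept$participant_id)
  note("participant", "invalid_sessions", length(bad_part))
  kept <- kept[!(kept$participant_id %in% bad_part), , drop = FALSE]

  counts <- tibble::tibble(
    level = c("trial", "session", "participant"),
    n_input = as.integer(n_in),
    n_surviving = c(nrow(kept), dplyr::n_distinct(kept$session_id),
                    dplyr::n_distinct(kept$participant_id))
  )
  counts$n_dropped <- counts$n_input - counts$n_surviving

  list(table = as_rating_table(kept),
       report = list(drops = dplyr::bind_rows(drops), counts = counts))
}

# Per-session test-retest reliability with the cohort key used by the
# exclusion screen. The stimulus set of a session is identified by the sorted
# roster of its main-trial stimuli (or a `stimulus_set` column when present).
session_reliability <- function(table, min_pairs = 3L) {
  if (nrow(table) == 0) {
    return(tibble::tibble(session_id = character(0), scale_id = character(0),
                          stimulus_set = character(0), n_pairs = integer(0),
                          r = numeric(0)))
  }
  by_sess <- split(table, table$session_id)
  rows <- lapply(names(by_sess), function(sid) {
    s <- by_sess[[sid]]
    set_id <- if ("stimulus_set" %in% names(s)) {
      as.character(s$stimulus_set[1])
    } else {
      main_stims <- sort(unique(s$stimulus_id[s$trial_type == "main"]))
      paste(main_stims, collapse = "|")
    }
    main <- s[s$trial_type == "main", c("stimulus_id", "scale_id", "rating")]
    re <- s[s$trial_type == "retest", c("stimulus_id", "scale_id", "rating")]
    pairs <- merge(main, re, by = c("stimulus_id", "scale_id"),
                   suffixes = c("_main", "_retest"))
    r <- if (nrow(pairs) >= min_pairs) {
      safe_cor(pairs$rating_main, pairs$rating_retest, min_pairs = min_pairs)
    } else {
      NA_real_
    }
    tibble::tibble(session_id = sid, scale_id = s$scale_id[1],
                   stimulus_set = set_id, n_pairs = nrow(pairs), r = r)
  })
  dplyr::bind_rows(rows)
}
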