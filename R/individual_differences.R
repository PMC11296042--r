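#' Center ratings on their per-stimulus means
#'
#' Subtracts from every rating the cross-participant mean of that
#' (stimulus, scale) cell (main trials), so that a participant's session
#' mean reflects their rating bias relative to the sample rather than the
#' stimuli they happened to rate. Centering is idempotent; cells rated by a
#' single participant center to zero.
#'
#' @param table an evoked-domain rating table.
#' @return the table with `rating` replaced by its centered value.
#' @export
center_by_stimulus <- function(table) {
  validate_rating_table(table, check_range = FALSE)
  key <- paste(table$stimulus_id, table$scale_id, sep = "\r")
  is_main <- table$trial_type == "main"
  cell_means <- tapply(table$rating[is_main], key[is_main], mean)
  mu <- cell_means[key]
  mu[is.na(mu)] <- 0
  table$rating <- table$rating - as.numeric(mu)
  table
}

#' Participant-by-scale mean ratings
#'
#' For evoked domains: per-session means of stimulus-centered main-trial
#' ratings (one session = one participant on one scale). For real-life
#' data: per-participant means across waves, restricted to participants
#' with complete data from all `complete_waves` waves; optionally corrected
#' by subtracting the participant's evoked-rating bias (`baseline`).
#'
#' @param table a rating table.
#' @param domain `"evoked"` (narrative + video) or `"real_life"`.
#' @param complete_waves required number of waves for real-life inclusion
#'   (default 15).
#' @param baseline optional tibble of evoked biases (`participant_id`,
#'   `bias`) subtracted from real-life means.
#' @param center for evoked data, center by stimulus first (default `TRUE`).
#' @return tibble with `participant_id`, `scale_id`, `mean_rating`, `n`.
#' @export
participant_means <- function(table, domain = c("evoked", "real_life"),
                              complete_waves = 15, baseline = NULL,
                              center = TRUE) {
  domain <- match.arg(domain)
  validate_rating_table(table, check_range = FALSE)
  if (domain == "evoked") {
    sub <- table[table$domain %in% c("narrative", "video"), , drop = FALSE]
    if (center) sub <- center_by_stimulus(sub)
    sub <- sub[sub$trial_type == "main", , drop = FALSE]
    out <- dplyr::summarise(
      dplyr::group_by(sub, .data$participant_id, .data$scale_id),
      mean_rating = mean(.data$rating), n = dplyr::n(), .groups = "drop")
    return(out)
  }
  sub <- table[table$domain == "real_life" & table$trial_type == "main", , drop = FALSE]
  if (!"wave" %in% names(sub)) abort("real-life table must carry a `wave` column",
                                     class = "emospace_config_error")
  waves_by_part <- tapply(sub$wave, sub$participant_id,
                          function(w) length(unique(w)))
  complete <- names(waves_by_part)[waves_by_part >= complete_waves]
  if (length(complete) == 0) {
    warn("no participants with complete wave data")
    return(tibble::tibble(participant_id = character(0),
                          scale_id = character(0),
                          mean_rating = numeric(0), n = integer(0)))
  }
  sub <- sub[sub$participant_id %in% complete, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$participant_id, .data$scale_id),
    mean_rating = mean(.data$rating), n = dplyr::n(), .groups = "drop")
  if (!is.null(baseline)) {
    stopifnot(all(c("participant_id", "bias") %in% names(baseline)))
    idx <- match(out$participant_id, baseline$participant_id)
    corr <- baseline$bias[idx]
    corr[is.na(corr)] <- 0
    out$mean_rating <- out$mean_rating - corr
  }
  out
}

#' Trait-association screen over participant mean ratings
#'
#' Tests every (scale, variable) pair: Pearson correlation for numeric
#' variables, Welch's two-sample t test for two-level categorical variables
#' (oriented first level minus second, by factor-level or alphabetical
#' order). Bonferroni correction is applied over the whole tested grid.
#'
#' @param means participant-by-scale means: either the tibble from
#'   [participant_means()] or a wide tibble/matrix with `participant_id`
#'   plus one column per scale.
#' @param traits tibble with `participant_id` and one column per variable.
#' @param alpha significance level (default 0.05).
#' @return tibble of class `emospace_association_table`: one row per
#'   (scale, variable) with `type` (`"pearson"`/`"welch"`), `statistic`
#'   (r or t), `p`, `p_bonferroni`, `significant_raw`,
#'   `significant_bonferroni`, `n`.
#' @export
association_screen <- function(means, traits, alpha = 0.05) {
  wide <- widen_means(means)
  stopifnot("participant_id" %in% names(traits))
  shared <- intersect(wide$participant_id, traits$participant_id)
  if (length(shared) < 3) abort("fewer than 3 participants shared between inputs")
  wide <- wide[match(shared, wide$participant_id), , drop = FALSE]
  traits <- traits[match(shared, traits$participant_id), , drop = FALSE]
  scales <- setdiff(names(wide), "participant_id")
  vars <- setdiff(names(traits), "participant_id")
  rows <- list()
  for (s in scales) {
    y <- wide[[s]]
    for (v in vars) {
      x <- traits[[v]]
      if (is.numeric(x)) {
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
        r <- cor(x[ok], y[ok])
        tt <- r * sqrt((sum(ok) - 2) / (1 - r^2))
        p <- 2 * pt(-abs(tt), df = sum(ok) - 2)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scale_id = s, variable = v, type = "pearson",
          statistic = r, p = p, n = sum(ok))
      } else {
        lv <- if (is.factor(x)) levels(droplevels(factor(x))) else sort(unique(as.character(x)))
        lv <- lv[!is.na(lv)]
        if (length(lv) != 2) next
        g1 <- y[x == lv[1] & is.finite(y)]
        g2 <- y[x == lv[2] & is.finite(y)]
        if (length(g1) < 2 || length(g2) < 2) {
          inform(sprintf("skipping %s ~ %s: a group has n < 2", s, v))
          next
        }
        wt <- t.test(g1, g2)  # Welch by default; orientation lv1 - lv2
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scale_id = s, variable = v, type = "welch",
          statistic = unname(wt$statistic), p = wt$p.value,
          n = length(g1) + length(g2))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(scale_id = character(0), variable = character(0),
                          type = character(0), statistic = numeric(0),
                          p = numeric(0), n = integer(0))
  }
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$significant_raw <- out$p < alpha
  out$significant_bonferroni <- out$p_bonferroni < alpha
  class(out) <- c("emospace_association_table", class(out))
  attr(out, "alpha") <- alpha
  out
}

widen_means <- function(means) {
  if (is.matrix(means)) {
    out <- tibble::as_tibble(as.data.frame(means))
    out <- dplyr::bind_cols(
      tibble::tibble(participant_id = rownames(means) %||%
                       as.character(seq_len(nrow(means)))), out)
    return(out)
  }
  means <- tibble::as_tibble(means)
  if (all(c("participant_id", "scale_id", "mean_rating") %in% names(means))) {
    return(tidyr::pivot_wider(means[, c("participant_id", "scale_id", "mean_rating")],
                              names_from = "scale_id",
                              values_from = "mean_rating"))
  }
  stopifnot("participant_id" %in% names(means))
  means
}
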