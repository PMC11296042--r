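#' Generate a stimulus-by-scale matrix from the latent factor model
#'
#' Draws factor scores `F ~ MVN(0, phi)`, stimulus latent means
#' `F lambda^T + unique noise`, and maps them through the bounded slider
#' (`center + gain * latent`, clipped to \[1, 7\]). The truth model is
#' returned unchanged alongside the data for parameter-recovery testing.
#'
#' @param truth a [truth_model()].
#' @param seed optional seed overriding `truth$seed`.
#' @return list with elements `matrix` (a [rating_matrix()] with the factor
#'   scores in `attr(, "scores")`), and `truth`.
#' @export
generate_latent_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "emospace_truth_model"))
  seed <- seed %||% truth$seed
  out <- with_seed(seed, draw_latent(truth))
  m <- rating_matrix(out$ratings,
                     domain = if (truth$n_raters == 1) "real_life" else "narrative",
                     aggregation = if (truth$n_raters == 1) "single-rater" else "rater-mean",
                     labels = out$labels)
  attr(m, "scores") <- out$scores
  list(matrix = m, truth = truth)
}

# Core latent draw; assumes the RNG state is already set. Factor scores are
# drawn first so that the planted-category generator at separation 0 is
# bitwise identical to the unclustered one.
draw_latent <- function(truth) {
  n <- truth$n_stimuli
  k <- truth$k_true
  z <- matrix(rnorm(n * k), n, k)
  f <- z %*% chol(truth$phi)
  labels <- NULL
  if (!is.null(truth$clusters)) {
    cs <- truth$clusters
    centroids <- cs$centroids %||% default_centroids(cs$n_categories, k)
    labels <- rep_len(seq_len(cs$n_categories), n)
    f <- cs$within_sd * f + cs$separation * centroids[labels, , drop = FALSE]
    labels <- paste0("cat_", labels)
  }
  e <- matrix(rnorm(n * truth$n_scales), n, truth$n_scales)
  e <- sweep(e, 2, sqrt(truth$psi), `*`)
  latent <- f %*% t(truth$lambda) + e
  ratings <- truth$center + truth$gain * latent
  if (truth$clip) ratings <- pmin(pmax(ratings, 1), 7)
  scales <- rownames(truth$lambda) %||% paste0("scale_", sprintf("%02d", seq_len(truth$n_scales)))
  dimnames(ratings) <- list(paste0("stim_", sprintf("%04d", seq_len(n))), scales)
  dimnames(latent) <- dimnames(ratings)
  rownames(f) <- rownames(ratings)
  colnames(f) <- colnames(truth$lambda) %||% paste0("factor_", seq_len(k))
  list(ratings = ratings, scores = f, labels = labels,
       latent = latent)
}

#' Generate a planted-category stimulus-by-scale matrix
#'
#' As [generate_latent_dataset()], but factor scores are drawn around
#' category centroids scaled by the cluster spec's `separation`; per-row
#' category labels are attached to the matrix. With `separation = 0` the
#' output is identical to the unclustered generator under the same seed.
#'
#' @inheritParams generate_latent_dataset
#' @return as [generate_latent_dataset()]; the matrix carries `labels`.
#' @export
generate_categorical_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "emospace_truth_model"))
  if (is.null(truth$clusters)) {
    abort("`truth` has no cluster spec; see cluster_spec()",
          class = "emospace_parameter_error")
  }
  generate_latent_dataset(truth, seed = seed)
}

#' Generate trial-level rater data from a truth model
#'
#' Emulates the evoked-emotion sessions: each rater rates every stimulus on
#' one assigned scale (one session per rater), `rating = stimulus latent
#' value + rater bias + trial noise`, clipped to \[1, 7\]; `n_retest`
#' randomly chosen stimuli are re-presented as retest trials with fresh
#' noise. Reaction times (log-normal) and attention-check failures are
#' simulated so the exclusion rules have something to act on; a
#' `plant_invalid` fraction of trials is planted with sub-threshold reaction
#' times for exclusion testing.
#'
#' @param truth a [truth_model()].
#' @param domain domain tag for the generated trials.
#' @param plant_invalid fraction of trials planted with reaction times below
#'   400 ms (default 0).
#' @param seed optional seed overriding `truth$seed`.
#' @return list with `table` (a rating table), `truth`, and `latent` (the
#'   stimulus-by-scale latent slider values before rater noise).
#' @export
generate_rater_ratings <- function(truth, domain = "narrative",
                                   plant_invalid = 0, seed = NULL) {
  stopifnot(inherits(truth, "emospace_truth_model"))
  if (truth$n_retest > truth$n_stimuli) {
    abort("retest count exceeds the number of stimuli",
          class = "emospace_parameter_error")
  }
  seed <- seed %||% truth$seed
  with_seed(seed, {
    base <- draw_latent(truth)
    latent_slider <- truth$center + truth$gain * base$latent  # pre-noise slider value
    n <- truth$n_stimuli
    scales <- colnames(base$ratings)
    recs <- vector("list", length(scales) * truth$n_raters)
    idx <- 0L
    for (s in seq_along(scales)) {
      for (r in seq_len(truth$n_raters)) {
        idx <- idx + 1L
        pid <- sprintf("p_%s_%02d", scales[s], r)
        sid <- sprintf("sess_%s_%02d", scales[s], r)
        bias <- rnorm(1, 0, truth$bias_sd)
        main <- latent_slider[, s] + bias + rnorm(n, 0, truth$noise_sd)
        if (truth$clip) main <- pmin(pmax(main, 1), 7)
        re_idx <- sample.int(n, truth$n_retest)
        re <- latent_slider[re_idx, s] + bias + rnorm(truth$n_retest, 0, truth$noise_sd)
        if (truth$clip) re <- pmin(pmax(re, 1), 7)
        rt <- exp(rnorm(n + truth$n_retest, log(2000), 0.35))
        attention <- rbinom(1, 3, 0.02)
        recs[[idx]] <- tibble::tibble(
          participant_id = pid, session_id = sid, domain = domain,
          stimulus_id = c(rownames(latent_slider), rownames(latent_slider)[re_idx]),
          scale_id = scales[s],
          rating = c(main, re),
          trial_type = rep(c("main", "retest"), c(n, truth$n_retest)),
          reaction_time_ms = rt,
          attention_fails = attention)
      }
    }
    table <- dplyr::bind_rows(recs)
    if (plant_invalid > 0) {
      n_bad <- round(plant_invalid * nrow(table))
      bad <- sample.int(nrow(table), n_bad)
      table$reaction_time_ms[bad] <- runif(n_bad, 50, 399)
    }
    list(table = as_rating_table(table), truth = truth, latent = latent_slider)
  })
}

#' Generate participants with planted trait-rating associations
#'
#' Draws continuous traits (standard-normal scores) and categorical group
#' labels for `n` participants, and participant-by-scale mean ratings in
#' which each planted effect links a trait to a scale's mean with a chosen
#' population correlation (continuous traits) or standardized group
#' difference (categorical variables). Traits with no planted effect are
#' independent of all rating means, so the null behavior of the association
#' screen can be calibrated.
#'
#' @param n number of participants.
#' @param scales character vector of scale ids for the rating means.
#' @param traits character vector of continuous trait names.
#' @param groups character vector of binary group variable names.
#' @param effects tibble with columns `variable`, `scale`, `effect`: the
#'   planted correlation (continuous) or Cohen's d (categorical). Default:
#'   none.
#' @param mean_sd SD of the participant mean-rating deviations.
#' @param seed integer seed.
#' @return list with `traits` (participant x variable tibble), `means`
#'   (participant x scale tibble of mean ratings), `effects` (the planted
#'   table).
#' @export
generate_participants <- function(n = 441,
                                  scales = scale_roster("real_life", TRUE)$scale_id,
                                  traits = c("extraversion", "neuroticism",
                                             "conscientiousness", "resilience"),
                                  groups = c("sex", "education", "party"),
                                  effects = NULL, mean_sd = 0.6, seed = 1L) {
  effects <- effects %||%
    tibble::tibble(variable = character(0), scale = character(0), effect = numeric(0))
  stopifnot(all(c("variable", "scale", "effect") %in% names(effects)))
  bad <- setdiff(effects$variable, c(traits, groups))
  if (length(bad) > 0) abort(sprintf("effects refer to unknown variable(s): %s",
                                     paste(bad, collapse = ", ")))
  with_seed(seed, {
    pid <- sprintf("p_%04d", seq_len(n))
    tr <- matrix(rnorm(n * length(traits)), n, length(traits),
                 dimnames = list(pid, traits))
    gr <- matrix(sample(c("a", "b"), n * length(groups), replace = TRUE),
                 n, length(groups), dimnames = list(pid, groups))
    means <- matrix(rnorm(n * length(scales), 0, 1), n, length(scales),
                    dimnames = list(pid, scales))
    for (i in seq_len(nrow(effects))) {
      v <- effects$variable[i]; s <- effects$scale[i]; ef <- effects$effect[i]
      if (!s %in% scales) abort(sprintf("effect refers to unknown scale `%s`", s))
      if (v %in% traits) {
        # plant population correlation ef between trait and mean rating
        means[, s] <- ef * tr[, v] + sqrt(max(0, 1 - ef^2)) * means[, s]
      } else {
        # plant standardized group difference ef (group "a" minus "b")
        shift <- ifelse(gr[, v] == "a", ef / 2, -ef / 2)
        means[, s] <- means[, s] + shift
      }
    }
    means <- 4 + mean_sd * means
    traits_tbl <- tibble::as_tibble(as.data.frame(tr))
    for (g in groups) traits_tbl[[g]] <- gr[, g]
    traits_tbl <- dplyr::bind_cols(tibble::tibble(participant_id = pid), traits_tbl)
    means_tbl <- dplyr::bind_cols(tibble::tibble(participant_id = pid),
                                  tibble::as_tibble(as.data.frame(means)))
    list(traits = traits_tbl, means = means_tbl, effects = effects)
  })
}
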