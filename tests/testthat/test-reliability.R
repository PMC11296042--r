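test_that("test-retest reliability matches hand-computed correlations", {
  # identical retests give r = 1
  tab <- toy_table(n_stim = 5, n_raters = 1, n_retest = 3,
                   ratings = list(c(1, 3, 5, 6, 7)))
  tr <- test_retest(tab)
  expect_equal(tr$r, 1)

  # hand-built 3-pair session: (1,7) (7,1) (4,4) -> r = -1
  main <- tibble::tibble(
    participant_id = "p1", session_id = "s1", domain = "narrative",
    stimulus_id = c("a", "b", "c"), scale_id = "happy",
    rating = c(1, 7, 4), trial_type = "main",
    reaction_time_ms = 1000, attention_fails = 0L)
  re <- dplyr::mutate(main, rating = c(7, 1, 4), trial_type = "retest")
  tr2 <- test_retest(as_rating_table(dplyr::bind_rows(main, re)))
  expect_equal(tr2$r, -1)

  # constant main ratings leave r undefined (NA), not zero
  tab3 <- toy_table(n_stim = 5, n_raters = 1, n_retest = 3,
                    ratings = list(rep(4, 5)))
  expect_true(is.na(test_retest(tab3)$r))

  # no retest trials: empty result with a warning
  tab4 <- toy_table(n_stim = 3, n_raters = 1, n_retest = 0)
  expect_warning(out <- test_retest(tab4), "no retest")
  expect_equal(nrow(out), 0L)
})

test_that("split-half reliability behaves like noisy-mean correlation", {
  # two identical raters: r = 1 for every split
  tab <- toy_table(n_stim = 6, n_raters = 2, n_retest = 0,
                   ratings = list(c(1:6), c(1:6)))
  sh <- split_half(tab, n_rep = 8, seed = 1)
  expect_true(all(sh$r > 0.999))

  # a fixed seed reproduces the whole resplit vector
  tm <- truth_model(n_stimuli = 40, n_scales = 23, n_raters = 6, seed = 5)
  rr <- generate_rater_ratings(tm)
  s1 <- split_half(rr$table, n_rep = 10, seed = 7)
  s2 <- split_half(rr$table, n_rep = 10, seed = 7)
  expect_identical(s1$r, s2$r)

  # Spearman-Brown behavior: mean split-half grows with rater count
  mean_sh <- vapply(c(4, 10, 20), function(nr) {
    tmr <- truth_model(n_stimuli = 60, n_scales = 5,
                       lambda = default_loadings(5, 2),
                       n_raters = nr, noise_sd = 1.5, seed = 9)
    rrr <- generate_rater_ratings(tmr)
    mean(split_half(rrr$table, n_rep = 10, seed = 3)$r)
  }, numeric(1))
  expect_true(all(diff(mean_sh) > 0))
})

test_that("the readability grade follows the Flesch-Kincaid formula", {
  # 6 words, 1 sentence, 6 syllables -> 0.39*6 + 11.8*1 - 15.59 = -1.45
  expect_equal(fk_grade("The cat sat on the mat."), -1.45, tolerance = 1e-12)

  # duplicating a sentence leaves the grade unchanged
  txt <- "Emotions persist over time and generalize across situations."
  expect_equal(fk_grade(txt), fk_grade(paste(txt, txt)), tolerance = 1e-12)

  # degenerate text errors
  expect_error(fk_grade("..."), class = "emospace_domain_error")

  # formula check at stated ratios: 12 words/sentence, 1.5 syllables/word
  words <- c(rep("cat", 6), rep("catfish", 6))  # 6x1 + 6x2 = 18 syllables
  expect_equal(fk_grade(paste0(paste(words, collapse = " "), ".")),
               0.39 * 12 + 11.8 * 1.5 - 15.59, tolerance = 1e-12)
})

test_that("low-quality flagging reproduces the canonical 5-scale exclusion", {
  flagged <- flag_low_quality()
  expect_setequal(flagged, c("self_relevance", "intrinsic_extrinsic",
                             "remembering", "mental_bodily", "future"))
  roster <- scale_roster()
  expect_equal(nrow(roster) - length(flagged), 23L)
  expect_equal(nrow(scale_roster("evoked", post_exclusion = TRUE)), 23L)
  expect_equal(nrow(scale_roster("real_life", post_exclusion = TRUE)), 18L)
  # the post-exclusion real-life roster is exactly the shared 18
  shared <- intersect(scale_roster("evoked", TRUE)$scale_id,
                      scale_roster("real_life", TRUE)$scale_id)
  expect_equal(length(shared), 18L)

  # threshold rule flags exactly the below-threshold scale
  report <- tibble::tibble(scale_id = c("a", "b", "c"),
                           median_test_retest = c(0.6, 0.05, 0.55),
                           median_split_half = c(0.8, 0.5, 0.7))
  expect_equal(flag_low_quality(report, exclude = NULL,
                                min_test_retest = 0.2), "b")
  # all above threshold: nothing flagged
  expect_length(flag_low_quality(report, exclude = NULL,
                                 min_test_retest = 0.01), 0L)
})

test_that("scale quality reports medians and the readability correlation", {
  tm <- truth_model(n_stimuli = 25, n_scales = 23, n_raters = 4, seed = 15)
  rr <- generate_rater_ratings(tm)
  rep_q <- scale_quality(rr$table, definitions = scale_roster(),
                         n_rep = 5, seed = 2)
  expect_equal(sort(rep_q$scale_id), sort(unique(rr$table$scale_id)))
  expect_true(all(rep_q$median_test_retest >= -1 & rep_q$median_test_retest <= 1,
                  na.rm = TRUE))
  rc <- attr(rep_q, "readability_cor")
  expect_true(all(is.finite(rc)))
})
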