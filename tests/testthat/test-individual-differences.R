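test_that("stimulus centering zeroes cell means, keeps biases, and is idempotent", {
  tm <- truth_model(n_stimuli = 20, n_scales = 23, n_raters = 4, seed = 111)
  rr <- generate_rater_ratings(tm)
  ct <- center_by_stimulus(rr$table)
  main <- ct[ct$trial_type == "main", ]
  cell_means <- tapply(main$rating, paste(main$stimulus_id, main$scale_id), mean)
  expect_lt(max(abs(cell_means)), 1e-10)

  # idempotence
  ct2 <- center_by_stimulus(ct)
  expect_equal(ct2$rating, ct$rating, tolerance = 1e-12)

  # a participant rating everything +1 above the rest keeps ~+1 mean
  set.seed(9)
  tab <- toy_table(n_stim = 12, n_raters = 5, n_retest = 0,
                   ratings = replicate(5, runif(12, 2, 5), simplify = FALSE))
  shifted <- tibble::as_tibble(tab)
  shifted$rating[shifted$participant_id == "p05"] <-
    shifted$rating[shifted$participant_id == "p01"] + 1
  shifted <- as_rating_table(shifted)
  pm <- participant_means(shifted, "evoked")
  m5 <- pm$mean_rating[pm$participant_id == "p05"]
  m1 <- pm$mean_rating[pm$participant_id == "p01"]
  expect_equal(m5 - m1, 1, tolerance = 1e-10)
})

test_that("real-life participant means honor wave completeness and baseline correction", {
  mk_rl <- function(pid, waves) {
    dplyr::bind_rows(lapply(waves, function(w) tibble::tibble(
      participant_id = pid, session_id = paste0(pid, "_w", w),
      domain = "real_life", stimulus_id = paste0("inst_", pid, "_", w),
      scale_id = "valence", rating = 4 + (w %% 3) / 2, trial_type = "main",
      reaction_time_ms = 1500, attention_fails = 0L, wave = w)))
  }
  tab <- as_rating_table(dplyr::bind_rows(mk_rl("pA", 1:15), mk_rl("pB", 1:14)))
  pm <- participant_means(tab, "real_life", complete_waves = 15)
  expect_true("pA" %in% pm$participant_id)
  expect_false("pB" %in% pm$participant_id)  # 14/15 waves -> excluded

  # a constant +1 evoked bias is removed exactly
  base <- participant_means(tab, "real_life", complete_waves = 15)
  corrected <- participant_means(
    tab, "real_life", complete_waves = 15,
    baseline = tibble::tibble(participant_id = "pA", bias = 1))
  expect_equal(corrected$mean_rating, base$mean_rating - 1)
})

test_that("the association screen computes the right statistics and corrections", {
  gp <- generate_participants(n = 120, seed = 7)
  # trait equal to a scale's means: r = 1 and Bonferroni-significant
  traits <- gp$traits
  traits$mirror <- gp$means$valence
  sc <- association_screen(gp$means, traits)
  row <- sc[sc$scale_id == "valence" & sc$variable == "mirror", ]
  expect_equal(row$statistic, 1)
  expect_true(row$significant_bonferroni)

  # identical group distributions: t = 0
  means2 <- tibble::tibble(participant_id = c("a", "b", "c", "d"),
                           happy = c(3, 5, 3, 5))
  traits2 <- tibble::tibble(participant_id = c("a", "b", "c", "d"),
                            grp = c("g1", "g1", "g2", "g2"))
  sc2 <- association_screen(means2, traits2)
  expect_equal(sc2$statistic, 0)
  expect_equal(sc2$type, "welch")

  # Bonferroni flags are a subset of raw flags
  expect_true(all(!sc$significant_bonferroni | sc$significant_raw))

  # groups with n < 2 are skipped
  traits3 <- tibble::tibble(participant_id = c("a", "b", "c", "d"),
                            grp = c("g1", "g2", "g2", "g2"))
  expect_message(sc3 <- association_screen(means2, traits3), "n < 2")
  expect_equal(nrow(sc3), 0L)
})
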