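test_that("the latent generator reproduces its own covariance structure", {
  # no unique noise, no clipping distortion: sample covariance of the
  # ratings approaches gain^2 * Lambda Phi Lambda' (Monte-Carlo vs closed
  # form)
  lam <- default_loadings(23, 3)
  tm <- truth_model(n_stimuli = 5000, lambda = lam, psi = rep(1e-6, 23),
                    gain = 0.3, seed = 11)
  m <- generate_latent_dataset(tm)$matrix
  emp <- cov(unclass(m))
  pop <- 0.3^2 * lam %*% tm$phi %*% t(lam)
  expect_lt(max(abs(emp - pop)), 0.02)

  # ratings always within the slider bounds
  tm2 <- truth_model(n_stimuli = 300, gain = 3, seed = 12)
  m2 <- generate_latent_dataset(tm2)$matrix
  expect_true(all(m2 >= 1 & m2 <= 7))

  # determinism under the seed
  expect_identical(unclass(generate_latent_dataset(tm2)$matrix),
                   unclass(generate_latent_dataset(tm2)$matrix))

  # invalid factor correlation matrix is rejected
  bad_phi <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(truth_model(k_true = 2, lambda = default_loadings(10, 2),
                           phi = bad_phi),
               class = "emospace_parameter_error")
})

test_that("planted categories reduce to the unclustered generator at s = 0", {
  tm0 <- truth_model(n_stimuli = 60, seed = 21)
  tmc <- truth_model(n_stimuli = 60, seed = 21,
                     clusters = cluster_spec(4, separation = 0))
  m0 <- unclass(generate_latent_dataset(tm0)$matrix)
  mc <- unclass(generate_categorical_dataset(tmc)$matrix)
  attr(mc, "labels") <- NULL
  expect_equal(m0, mc)

  # centroid count must match the spec
  expect_error(
    truth_model(clusters = cluster_spec(3, centroids = diag(2))),
    class = "emospace_parameter_error")

  # labels attach to the rows
  tm6 <- truth_model(n_stimuli = 66, seed = 22, clusters = cluster_spec(6))
  m6 <- generate_categorical_dataset(tm6)$matrix
  expect_equal(length(attr(m6, "labels")), 66L)
  expect_equal(dplyr::n_distinct(attr(m6, "labels")), 6L)
})

test_that("rater-level generation supports reliability and exclusion logic", {
  tm <- truth_model(n_stimuli = 30, n_scales = 23, n_raters = 3,
                    noise_sd = 0, bias_sd = 0, seed = 31)
  rr <- generate_rater_ratings(tm)
  # noiseless raters: every session's retest correlates perfectly
  tr <- test_retest(rr$table)
  expect_true(all(is.na(tr$r) | tr$r > 0.999))

  # planted invalid trials are dropped exactly by the reaction-time rule
  rr2 <- generate_rater_ratings(tm, plant_invalid = 0.1, seed = 32)
  planted <- sum(rr2$table$reaction_time_ms < 400)
  res <- apply_exclusions(rr2$table, exclusion_rules(
    max_attention_fails = NULL, reliability_sd = NULL,
    max_invalid_frac = 1, max_invalid_sessions = Inf))
  drops <- res$report$drops
  expect_equal(drops$n_dropped[drops$reason == "rt_min"], planted)

  # deterministic under seed
  expect_identical(generate_rater_ratings(tm)$table$rating,
                   generate_rater_ratings(tm)$table$rating)

  # retest count cannot exceed the stimulus count
  expect_error(generate_rater_ratings(
    truth_model(n_stimuli = 5, n_retest = 8)),
    class = "emospace_parameter_error")
})

test_that("participant generation plants recoverable trait effects", {
  eff <- tibble::tibble(variable = "extraversion", scale = "valence",
                        effect = 0.5)
  gp <- generate_participants(n = 441, effects = eff, seed = 41)
  r <- cor(gp$traits$extraversion, gp$means$valence)
  expect_lt(abs(r - 0.5), 0.1)

  # zero-effect traits are independent of the rating means
  r0 <- cor(gp$traits$neuroticism, gp$means$valence)
  expect_lt(abs(r0), 0.15)

  # deterministic under seed
  gp2 <- generate_participants(n = 441, effects = eff, seed = 41)
  expect_identical(gp$means, gp2$means)
})
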