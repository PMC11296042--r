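test_that("redundancy ordering removes the most correlated scale first", {
  # A and B duplicates, C independent: one of A/B leaves first (tie-break
  # by id -> A), C survives to the end
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 1
  colnames(r) <- rownames(r) <- c("A", "B", "C")
  ord <- redundancy_order(r)
  expect_equal(ord[1], "A")
  expect_equal(sort(ord[2:3]), c("B", "C"))

  # identity correlation: removal order is id order
  r0 <- diag(4)
  colnames(r0) <- rownames(r0) <- c("d", "a", "c", "b")
  expect_equal(redundancy_order(r0), c("a", "b", "c", "d"))

  # invariant to input row order given the tie-break
  perm <- c(3, 1, 4, 2)
  expect_equal(redundancy_order(r0[perm, perm]), redundancy_order(r0))
})

test_that("stimulus decimation keeps strong factors congruent", {
  tm <- truth_model(n_stimuli = 80, seed = 71)
  m <- generate_latent_dataset(tm)$matrix
  curves <- decimate_stimuli(m, k = 3, step = 20, n_rand = 3, seed = 1)
  expect_true(all(c("n_stimuli", "rand", "factor", "congruence") %in%
                    names(curves)))
  # down to half the stimuli the solution stays highly congruent
  big <- curves$congruence[curves$n_stimuli >= 40]
  expect_true(mean(big >= 0.9) > 0.8)
  # removing nothing is exact self-congruence
  full <- fit_efa(m, 3)
  expect_true(all(tucker_congruence(full, full)$phi >= 1 - 1e-12))
})

test_that("scale decimation matches factors one-to-one with high score correlations", {
  # truth with genuinely redundant scales: five extra scales duplicate the
  # loadings of strong indicators (independent unique noise), so the
  # redundancy ordering should shed them first and the factor scores
  # should barely move while it does
  lam <- default_loadings(23, 3)
  twins <- lam[c("valence", "arousal", "generalizability_stimuli",
                 "happy", "common"), ]
  rownames(twins) <- paste0(rownames(twins), "_twin")
  tm <- truth_model(n_stimuli = 120, lambda = rbind(lam, twins), seed = 72)
  m <- generate_latent_dataset(tm)$matrix
  curves <- decimate_scales(m, k = 3, min_scales = 22, seed = 1)
  expect_true(nrow(curves) > 0)
  # matching is a permutation at every step
  by_step <- split(curves, curves$n_scales)
  for (st in by_step) {
    expect_equal(sort(unique(st$matched_factor)), sort(st$matched_factor))
  }
  # the first removals are dominated by the planted twins
  removed <- unique(curves$removed)
  expect_gte(sum(grepl("_twin", removed) | removed %in%
                   c("valence", "arousal", "generalizability_stimuli",
                     "happy", "common")), 4)
  # removing five redundant scales barely moves the factor scores; the
  # raw-mean redundancy rule preferentially targets positively loaded
  # indicators (bipolar scales have self-cancelling mean correlations), so
  # the thin arousal factor is allowed a slightly wider margin
  keep <- curves$n_scales >= 23
  expect_gte(mean(curves$r[keep]), 0.9)
  expect_true(all(curves$r[keep] >= 0.85))
})

test_that("the linear autoencoder attains the PCA optimum and mirrors EFA", {
  tm <- truth_model(n_stimuli = 60, n_raters = 6, seed = 73)
  rr <- generate_rater_ratings(tm)
  m <- scale(unclass(aggregate_matrix(rr$table, "narrative")), scale = FALSE)

  fit <- fit_linear_autoencoder(m, 3, seed = 2)
  pc <- prcomp(m, center = FALSE)
  pca_mse <- mean((m - pc$x[, 1:3] %*% t(pc$rotation[, 1:3]))^2)
  expect_lt(abs(fit$train_mse - pca_mse), 1e-6)

  # full-width bottleneck reconstructs exactly
  fit_full <- fit_linear_autoencoder(m, ncol(m), seed = 3)
  expect_lt(fit_full$train_mse, 1e-10)

  # cross-validated curves: test error decreases from k=1 to the true k=3
  cvres <- linear_autoencoder_cv(rr$table, k_range = c(1, 3), n_iter = 3,
                                 seed = 4)
  agg <- tapply(cvres$curves$test_mse, cvres$curves$k, mean)
  expect_lt(agg["3"], agg["1"])

  # decoder weights align with the EFA loadings
  efa <- fit_efa(aggregate_matrix(rr$table, "narrative"), 3)
  cg <- tucker_congruence(efa$loadings, cvres$weights$k3)
  expect_true(mean(cg$phi) >= 0.9)
})
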