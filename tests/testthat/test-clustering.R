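test_that("the fast dip statistic agrees with the brute-force definition", {
  # frozen anchors computable by hand
  expect_equal(dip_stat(c(0, 1)), 0.25)
  expect_equal(dip_stat(1:3), 1 / 6, tolerance = 1e-12)
  expect_equal(dip_stat(rep(2, 5)), 0)

  # randomized cross-check against the LP oracle (rounded data keeps the
  # linear programs well conditioned)
  skip_if_not_installed("boot")
  set.seed(12)
  for (i in 1:12) {
    n <- sample(5:18, 1)
    x <- switch(i %% 3 + 1,
                round(rnorm(n), 2),
                round(c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4)), 2),
                round(runif(n, 0, 2), 1))
    expect_equal(dip_stat(x), dip_oracle(x), tolerance = 1e-7,
                 info = paste("case", i))
  }
})

test_that("dip p-values separate planted clusters from smooth clouds", {
  tm2 <- truth_model(n_stimuli = 100, clusters = cluster_spec(2), seed = 101)
  m2 <- generate_categorical_dataset(tm2)$matrix
  d2 <- dip_unimodality(m2, n_boot = 500, seed = 1)
  expect_lt(d2$p_value, 0.01)

  tm1 <- truth_model(n_stimuli = 100, seed = 102)
  m1 <- generate_latent_dataset(tm1)$matrix
  d1 <- dip_unimodality(m1, n_boot = 500, seed = 2)
  expect_gt(d1$p_value, 0.05)

  # degenerate input errors
  same <- rating_matrix(matrix(4, 5, 3), "narrative", "rater-mean")
  expect_error(dip_unimodality(same), "identical")
})

test_that("hierarchical clustering recovers planted partitions", {
  tm <- truth_model(n_stimuli = 80, clusters = cluster_spec(2), seed = 103)
  m <- generate_categorical_dataset(tm)$matrix
  h <- hac(m)
  expect_equal(adjusted_rand_index(attr(m, "labels"), h$cuts$k2), 1)

  # the top split separates positive from negative valence scores
  scores <- attr(m, "scores")
  val_sign <- scores[, 1] >= 0
  expect_gt(abs(cor(as.numeric(val_sign), as.numeric(h$cuts$k2 == 1))), 0.8)

  # duplicated rows merge at height zero
  mm <- unclass(m)[c(1, 1, 2, 3), ]
  h2 <- hclust(dist(mm), method = "ward.D2")
  expect_equal(min(h2$height), 0)

  # row order only permutes labels
  perm <- sample(nrow(m))
  h3 <- hac(rating_matrix(unclass(m)[perm, ], "narrative", "rater-mean"))
  expect_equal(adjusted_rand_index(h$cuts$k2[perm], h3$cuts$k2), 1)
})

test_that("K-means agreement metrics are chance-corrected and invariant", {
  tm <- truth_model(n_stimuli = 90, clusters = cluster_spec(6), seed = 104)
  m <- generate_categorical_dataset(tm)$matrix
  km <- kmeans_agreement(m, seed = 5)
  expect_gte(km$ari, 0.9)
  expect_gte(km$ami, 0.9)

  # reference equal to the clustering itself: both metrics are exactly 1
  km_self <- kmeans_agreement(m, reference = km$cluster,
                              k = length(unique(km$cluster)), seed = 5)
  expect_equal(km_self$ari, 1)
  expect_equal(km_self$ami, 1)

  # label renaming changes nothing
  ren <- c(a = "z", b = "y", c = "x", d = "w", e = "v", f = "u")
  labs <- attr(m, "labels")
  relabeled <- ren[match(labs, paste0("cat_", 1:6))]
  expect_equal(adjusted_rand_index(labs, km$cluster),
               adjusted_rand_index(relabeled, km$cluster))
  expect_equal(adjusted_mutual_info(labs, km$cluster),
               adjusted_mutual_info(relabeled, km$cluster))

  # random labels against real structure: ARI near 0
  set.seed(6)
  aris <- replicate(40, adjusted_rand_index(
    sample(labs), km$cluster))
  expect_lt(abs(mean(aris)), 0.02)

  # cross-check ARI against the established implementation
  skip_if_not_installed("mclust")
  expect_equal(km$ari, mclust::adjustedRandIndex(attr(m, "labels"),
                                                 km$cluster))
  set.seed(7)
  a <- sample(1:3, 40, TRUE); b <- sample(1:4, 40, TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("basic-emotion instance selection follows the strict perfect-example rule", {
  scales <- basic_emotion_scales()
  m <- rbind(
    perfect = c(7, 1, 1, 1, 1, 1),
    near = c(6.5, 1.5, 1, 1, 1, 1),
    boundary = c(6.0, 1, 1, 1, 1, 1),    # exactly 6: excluded (strict >)
    far = c(6.2, 4, 4, 4, 4, 4),
    other = c(1, 7, 1, 1, 1, 1))
  colnames(m) <- scales
  rm6 <- rating_matrix(m, "narrative", "rater-mean")
  sel <- select_basic_instances(rm6, per_category = 2)
  happy <- sel[sel$category == "happy", ]
  expect_equal(happy$instance, c("perfect", "near"))
  expect_equal(happy$distance[1], 0)
  expect_false("boundary" %in% sel$instance)
  surprised <- sel[sel$category == "surprised", ]
  expect_equal(surprised$instance, "other")

  # exhaustive ranking: 3 candidates at distances 0.5 < 1.0 < 2.0, keep 2
  m2 <- rbind(
    a = c(7 - 0.5, 1, 1, 1, 1, 1),
    b = c(7, 2, 1, 1, 1, 1) - c(0, 1, 0, 0, 0, 0) + c(0, 1, 0, 0, 0, 0),
    c = c(7, 1, 1, 1, 1, 3))
  m2["b", ] <- c(7, 1, 1, 1, 1, 2)
  colnames(m2) <- scales
  sel2 <- select_basic_instances(rating_matrix(m2, "narrative", "rater-mean"),
                                 per_category = 2)
  happy2 <- sel2[sel2$category == "happy", ]
  expect_equal(happy2$instance, c("a", "b"))
})
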