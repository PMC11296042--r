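test_that("rating tables round-trip through CSV and validate their schema", {
  tab <- toy_table(n_stim = 3, n_raters = 2, ratings = list(c(1, 4, 7), c(2, 3, 6)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rating_table(tab, path)
  back <- read_rating_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tab))

  # boundary ratings 1 and 7 are accepted; 8 is rejected with row numbers
  bad <- tab
  bad$rating[2] <- 8
  expect_error(as_rating_table(bad), class = "emospace_validation_error")

  # missing required column is a schema error
  expect_error(as_rating_table(tab[, setdiff(names(tab), "scale_id")]),
               class = "emospace_schema_error")

  # duplicated (session, stimulus, scale, main) key
  dup <- dplyr::bind_rows(tibble::as_tibble(tab), tibble::as_tibble(tab)[1, ])
  expect_error(as_rating_table(dup), class = "emospace_validation_error")

  # retest without a matching main trial
  orphan <- tibble::as_tibble(tab)
  orphan$trial_type[1] <- "retest"
  expect_error(as_rating_table(orphan), class = "emospace_validation_error")

  # column remapping on read
  renamed <- tibble::as_tibble(tab)
  names(renamed)[names(renamed) == "participant_id"] <- "subj"
  readr::write_csv(renamed, path)
  back2 <- read_rating_table(path, col_map = c(participant_id = "subj"))
  expect_setequal(back2$participant_id, tab$participant_id)
})

test_that("trial, session and participant exclusions follow the study rules", {
  tab <- toy_table(n_stim = 10, n_raters = 4, n_retest = 3)
  # plant one too-fast trial and one session with 2 failed attention checks
  tab$reaction_time_ms[1] <- 300
  tab$attention_fails[tab$session_id == "s03"] <- 2L
  res <- apply_exclusions(tab)
  drops <- res$report$drops
  expect_equal(drops$n_dropped[drops$reason == "rt_min"], 1L)
  expect_equal(drops$n_dropped[drops$reason == "attention"], 1L)
  expect_false("s03" %in% res$table$session_id)
  expect_false(any(res$table$reaction_time_ms < 400))

  # report counts are conserved at every level
  counts <- res$report$counts
  expect_equal(counts$n_input, counts$n_surviving + counts$n_dropped)

  # a clean table passes through unchanged with zero drops
  clean <- toy_table(n_stim = 5, n_raters = 3)
  res2 <- apply_exclusions(clean)
  expect_equal(nrow(res2$table), nrow(clean))
  expect_true(all(res2$report$drops$n_dropped == 0))

  # idempotence: excluding twice equals excluding once
  res3 <- apply_exclusions(res$table)
  expect_equal(tibble::as_tibble(res3$table), tibble::as_tibble(res$table))

  # >10% invalid trials drops the session
  tab2 <- toy_table(n_stim = 10, n_raters = 2, n_retest = 0)
  tab2$reaction_time_ms[tab2$session_id == "s01"][1:2] <- 100
  res4 <- apply_exclusions(tab2)
  expect_false("s01" %in% res4$table$session_id)
  expect_true("s02" %in% res4$table$session_id)

  # configured rule referencing an absent field errors
  no_rt <- tab[, setdiff(names(tab), "reaction_time_ms")]
  expect_error(apply_exclusions(as_rating_table(no_rt)),
               class = "emospace_config_error")
})

test_that("aggregation averages main trials only and keeps cells in range", {
  tab <- toy_table(n_stim = 2, n_raters = 2, n_retest = 0,
                   ratings = list(c(3, 2), c(5, 6)))
  m <- aggregate_matrix(tab, "narrative")
  expect_equal(unname(m["stim01", "happy"]), 4)
  expect_equal(unname(m["stim02", "happy"]), 4)
  expect_equal(attr(m, "aggregation"), "rater-mean")

  # retest trials are excluded from the means: adding extreme retests
  # leaves every cell unchanged
  with_retest <- dplyr::bind_rows(
    tibble::as_tibble(tab),
    dplyr::mutate(tibble::as_tibble(tab)[c(1, 3), ],
                  trial_type = "retest", rating = 7))
  m2 <- aggregate_matrix(as_rating_table(with_retest), "narrative")
  expect_equal(unclass(m2), unclass(m))

  # cells always lie within the contributing ratings
  set.seed(4)
  vals <- list(runif(6, 1, 7), runif(6, 1, 7), runif(6, 1, 7))
  tab3 <- toy_table(n_stim = 6, n_raters = 3, n_retest = 0, ratings = vals)
  m3 <- aggregate_matrix(tab3, "narrative")
  lo <- pmin(vals[[1]], vals[[2]], vals[[3]])
  hi <- pmax(vals[[1]], vals[[2]], vals[[3]])
  expect_true(all(m3[, 1] >= lo & m3[, 1] <= hi))

  # real-life rows pass through untouched
  rl <- toy_table(n_stim = 10, n_raters = 1, n_retest = 0,
                  domain = "real_life", scale = "valence",
                  ratings = list(seq(1, 7, length.out = 10)))
  mrl <- aggregate_matrix(rl, "real_life")
  expect_equal(dim(mrl), c(10L, 1L))
  expect_equal(sort(unname(mrl[, 1])), seq(1, 7, length.out = 10))

  # an empty (stimulus, scale) cell is a completeness error
  holey <- tibble::as_tibble(toy_table(n_stim = 2, n_raters = 1, n_retest = 0))
  holey2 <- holey
  holey2$scale_id <- "sad"
  holey2 <- holey2[-1, ]
  both <- as_rating_table(dplyr::bind_rows(holey, holey2))
  expect_error(aggregate_matrix(both, "narrative"),
               class = "emospace_completeness_error")
})
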