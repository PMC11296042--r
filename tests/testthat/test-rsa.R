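test_that("scale correlations match closed forms on constructed data", {
  set.seed(3)
  base <- rnorm(30)
  m <- cbind(a = base, b = base, c = -base + 0, d = rnorm(30))
  m <- m + matrix(rnorm(120, sd = 1e-8), 30)  # break exact constancy guards
  cs <- scale_corr(m)
  expect_equal(unname(cs["a", "b"]), 1, tolerance = 1e-6)
  expect_equal(unname(cs["a", "c"]), -1, tolerance = 1e-6)

  # constant column names the offender
  bad <- cbind(x = rep(2, 10), y = rnorm(10), z = rnorm(10))
  expect_error(scale_corr(bad), "x")

  # 3-factor synthetic data without unique noise: correlation matrix equals
  # Lambda Phi Lambda' rescaled to unit diagonal, within sampling error
  lam <- default_loadings(23, 3)
  tm <- truth_model(n_stimuli = 4000, lambda = lam, psi = rep(1e-6, 23),
                    gain = 0.3, seed = 33)
  cs3 <- scale_corr(generate_latent_dataset(tm)$matrix)
  pop <- lam %*% tm$phi %*% t(lam)
  pop <- pop / sqrt(outer(diag(pop), diag(pop)))
  expect_lt(max(abs(unclass(cs3) - pop)), 0.06)
})

test_that("seriation places correlated blocks contiguously", {
  r <- block_corr(c(3, 3), rho = 0.8)
  ord <- seriate(structure(r, class = c("emospace_corr_structure", "matrix", "array"),
                           scale_ids = colnames(r)))
  blocks <- rep(1:2, each = 3)[ord]
  expect_true(all(diff(blocks) >= 0) || all(diff(blocks) <= 0) ||
                length(rle(blocks)$lengths) == 2)

  # permuting the input scales yields the same contiguous partition
  perm <- c(4, 1, 6, 2, 5, 3)
  rp <- r[perm, perm]
  ordp <- seriate(structure(rp, class = c("emospace_corr_structure", "matrix", "array"),
                            scale_ids = colnames(rp)))
  blocksp <- rep(1:2, each = 3)[perm][ordp]
  expect_equal(length(rle(blocksp)$lengths), 2L)

  # two scales: identity or swap
  r2 <- block_corr(c(1, 1), rho = 0)
  ord2 <- seriate(structure(r2, class = c("emospace_corr_structure", "matrix", "array")))
  expect_setequal(ord2, 1:2)
})

test_that("second-order similarity is symmetric and matches constructed ranks", {
  m1 <- data_with_corr(block_corr(c(4, 4), 0.6), n = 60, seed = 5)
  m2 <- data_with_corr(block_corr(c(4, 4), 0.5), n = 60, seed = 6)
  c1 <- scale_corr(m1); c2 <- scale_corr(m2)
  expect_equal(second_order(c1, c1)$rho, 1)
  expect_equal(second_order(c1, c2)$rho, second_order(c2, c1)$rho)

  # rank reversal of the lower triangle gives rho = -1: build c2 whose
  # lower-triangle values reverse the ranks of c1's
  p <- 5
  v <- seq(0.1, 0.5, length.out = p * (p - 1) / 2)
  mk <- function(vals) {
    r <- diag(p)
    r[lower.tri(r)] <- vals
    r <- r + t(r) - diag(p)
    colnames(r) <- rownames(r) <- paste0("s", 1:p)
    structure(r, class = c("emospace_corr_structure", "matrix", "array"),
              scale_ids = colnames(r))
  }
  expect_equal(second_order(mk(v), mk(rev(v) * 0 + (0.6 - v)))$rho, -1)

  # independent noise structures: mean rho near 0
  set.seed(9)
  rhos <- replicate(40, {
    a <- scale_corr(matrix(rnorm(40 * 10), 40, 10) + 0)
    b <- scale_corr(matrix(rnorm(40 * 10), 40, 10) + 0)
    colnames(a) <- colnames(b) <- NULL
    attr(a, "scale_ids") <- attr(b, "scale_ids") <- paste0("s", 1:10)
    second_order(a, b)$rho
  })
  expect_lt(abs(mean(rhos)), 0.06)
})

test_that("the permutation test is calibrated and seed-stable", {
  # strongly structured identical matrices: no permutation beats identity
  c1 <- scale_corr(data_with_corr(block_corr(c(5, 5), 0.7), n = 80, seed = 2))
  pt <- perm_test(c1, c1, n = 500, seed = 4)
  expect_equal(pt$p, 1 / 501)
  expect_equal(pt$rho, 1)

  # consistent relabeling of both matrices leaves p unchanged
  r <- unclass(c1)
  perm <- sample(seq_len(ncol(r)))
  rp <- structure(r[perm, perm], class = class(c1),
                  scale_ids = colnames(r)[perm])
  pt2 <- perm_test(rp, rp, n = 500, seed = 4)
  expect_equal(pt2$p, pt$p)

  # few permutations warn
  expect_warning(perm_test(c1, c1, n = 50, seed = 1), "100")
})
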