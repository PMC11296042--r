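test_that("minres EFA recovers a noiseless oblique factor structure", {
  # simple-structure truth: the quartimin optimum coincides with the
  # generating loadings, so recovery should be essentially exact
  lam <- default_loadings(24, 3)
  tm <- truth_model(n_stimuli = 600, lambda = lam, psi = rep(0.02, 24),
                    gain = 0.4, seed = 51)
  m <- generate_latent_dataset(tm)$matrix
  fit <- fit_efa(m, 3)
  cg <- tucker_congruence(lam, fit$loadings)
  expect_true(all(cg$phi >= 0.99))

  # proportions of common variance sum to one
  expect_equal(sum(fit$var_prop), 1)

  # ten Berge scores reproduce the factor correlations exactly
  expect_lt(max(abs(cor(fit$scores) - fit$phi)), 1e-8)

  # residual off-diagonals shrink (in sum of squares) as k grows
  resid_ss <- vapply(1:4, function(k) {
    f <- fit_efa(m, k)
    r <- f$r - f$loadings %*% f$phi %*% t(f$loadings)
    sum(r[lower.tri(r)]^2)
  }, numeric(1))
  expect_true(all(diff(resid_ss) < 1e-8))
})

test_that("a rank-1 correlation matrix yields proportional 1-factor loadings", {
  v <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  r <- tcrossprod(v)
  diag(r) <- 1
  colnames(r) <- rownames(r) <- paste0("s", 1:5)
  m <- data_with_corr(r, n = 300, seed = 7)
  fit <- fit_efa(m, 1)
  ratio <- fit$loadings[, 1] / v
  expect_lt(diff(range(ratio)), 0.01)
  resid <- fit$r - tcrossprod(fit$loadings)
  expect_lt(max(abs(resid[lower.tri(resid)])), 0.01)
})

test_that("minres agrees with maximum-likelihood factor analysis", {
  # independent route: factanal (ML) on well-conditioned 2-factor data
  lam <- default_loadings(10, 2)
  tm <- truth_model(n_stimuli = 500, lambda = lam, seed = 52)
  m <- unclass(generate_latent_dataset(tm)$matrix)
  ours <- fit_efa(m, 2, rotate = "none")
  ml <- factanal(m, factors = 2, rotation = "none")
  cg <- tucker_congruence(loadings(ml)[], ours$unrotated)
  expect_true(all(abs(cg$phi) >= 0.98))
})

test_that("oblimin rotation reaches a criterion value no worse than random rotations", {
  lam <- default_loadings(23, 3)
  tm <- truth_model(n_stimuli = 200, seed = 53)
  m <- generate_latent_dataset(tm)$matrix
  ext <- emospace:::minres_extract(cor(unclass(m)), 3)
  rot <- emospace:::oblimin_rotate(ext$loadings, n_starts = 5, seed = 1)
  crit <- function(l) {
    l2 <- l^2
    nmat <- matrix(1, ncol(l), ncol(l)); diag(nmat) <- 0
    sum(l2 * (l2 %*% nmat)) / 4
  }
  set.seed(99)
  random_crits <- replicate(50, {
    t0 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    crit(ext$loadings %*% t(solve(t0)))
  })
  expect_lte(rot$f, min(random_crits) + 1e-8)
})

test_that("varimax PCA reproduces total variance and stays orthogonal", {
  tm <- truth_model(n_stimuli = 150, seed = 54)
  m <- generate_latent_dataset(tm)$matrix
  full <- fit_pca(m, k = 23, rotate = "none")
  expect_equal(sum(full$eigenvalues), 23, tolerance = 1e-8)

  p3 <- fit_pca(m, 3)
  # rotated loadings keep the same column space / total SS as unrotated
  expect_equal(sum(p3$loadings^2), sum(p3$unrotated^2), tolerance = 1e-8)
  expect_equal(p3$phi, diag(3))

  # PCA and EFA agree on strong 3-factor data
  e3 <- fit_efa(m, 3)
  expect_true(all(tucker_congruence(e3, p3)$phi >= 0.95))
})

test_that("Tucker congruence handles alignment, signs and unit vectors", {
  a <- default_loadings(23, 3)
  expect_true(all(tucker_congruence(a, a)$phi >= 1 - 1e-12))

  # column negation and permutation are undone by Procrustes alignment
  b <- a[, c(2, 3, 1)]
  b[, 1] <- -b[, 1]
  expect_true(all(tucker_congruence(a, b)$phi > 0.999))

  # single-column, no alignment: phi is the plain cosine
  expect_equal(unname(tucker_congruence(matrix(c(1, 0)), matrix(c(0.6, 0.8)),
                                        procrustes = FALSE)$phi), 0.6)

  # self-congruence survives any scramble (property over random scrambles)
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(3)
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    b2 <- sweep(a[, perm], 2, signs, `*`)
    expect_true(all(tucker_congruence(a, b2)$phi > 0.999))
  }

  # zero-norm column gives NA
  z <- a; z[, 2] <- 0
  expect_true(is.na(tucker_congruence(a, z, procrustes = FALSE)$phi[2]))
})
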