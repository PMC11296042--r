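#' Principal components analysis with varimax rotation
#'
#' Principal components of the correlation matrix; component loadings are
#' eigenvectors scaled by the square roots of their eigenvalues, varimax
#' rotated (orthogonal), with regression-estimated standardized component
#' scores. Shares the `emospace_factor_model` container with [fit_efa()] so
#' the two solutions can be compared directly with [tucker_congruence()].
#'
#' @inheritParams fit_efa
#' @param rotate `"varimax"` (default) or `"none"`.
#' @return an `emospace_factor_model` (with `phi` the identity).
#' @export
fit_pca <- function(matrix, k, rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  m <- as_matrix(matrix)
  p <- ncol(m)
  if (k < 1 || k > p) abort("`k` must satisfy 1 <= k <= n_scales")
  r <- cor(m)
  e <- eigen(r, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  l <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev[seq_len(k)]), k)
  if (rotate == "varimax" && k > 1) {
    vr <- varimax(l, normalize = TRUE)
    l <- l %*% vr$rotmat
  }
  rownames(l) <- colnames(r)
  ord <- order_factors(l, diag(k))
  l <- ord$lambda
  h2 <- rowSums(l^2)
  heywood <- FALSE
  z <- scale(m)
  w <- solve(r, l)           # regression weights for component scores
  scores <- z %*% w
  scores <- scale(scores)    # standardized component scores
  colnames(scores) <- colnames(l)
  ss <- colSums(l^2)
  new_factor_model(
    loadings = l, phi = diag(k), uniquenesses = pmax(1 - h2, 0),
    communalities = h2, scores = scores, var_prop = ss / sum(ss),
    method = "PCA-varimax", heywood = heywood,
    unrotated = e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(k)]), k),
    r = r, n_obs = nrow(m), eigenvalues = ev)
}
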