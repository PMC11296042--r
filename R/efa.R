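#' Exploratory factor analysis (minres extraction, oblimin rotation)
#'
#' Factors are extracted from the correlation matrix by the minimal-residual
#' method (uniquenesses chosen to minimize the sum of squared off-diagonal
#' residuals), rotated obliquely with oblimin (gamma = 0, i.e. direct
#' quartimin, by gradient projection with multiple random starts), and
#' scored with the ten Berge correlation-preserving estimator, so that the
#' factor-score correlations reproduce the factor correlation matrix.
#' Factors are ordered by explained common variance and sign-aligned so the
#' dominant loading of each factor is positive.
#'
#' @param matrix a [rating_matrix()] (or numeric matrix, rows = stimuli).
#' @param k number of factors (`1 <= k <` number of scales).
#' @param rotate `"oblimin"` (default) or `"none"`.
#' @param n_starts random rotation starts (the identity start is always
#'   included).
#' @param psi_start optional warm-start uniquenesses for the minres search
#'   (e.g., from a fit to closely related data); default: squared multiple
#'   correlations.
#' @param seed seed for the rotation starts.
#' @return an object of class `emospace_factor_model` with elements
#'   `loadings` (pattern matrix), `phi`, `uniquenesses`, `communalities`,
#'   `scores` (ten Berge), `var_prop` (per-factor share of common variance,
#'   structure-loading convention), `method`, `heywood`, `unrotated`, `r`,
#'   `n_obs`.
#' @export
fit_efa <- function(matrix, k, rotate = c("oblimin", "none"),
                    n_starts = 10, psi_start = NULL, seed = 1L) {
  rotate <- match.arg(rotate)
  m <- as_matrix(matrix)
  p <- ncol(m)
  if (k < 1 || k >= p) abort("`k` must satisfy 1 <= k < n_scales")
  r <- cor(m)
  if (any(!is.finite(r))) abort("correlation matrix has undefined entries (constant column?)")
  ext <- minres_extract(r, k, start = psi_start)
  a <- ext$loadings
  if (rotate == "oblimin" && k > 1) {
    rot <- oblimin_rotate(a, n_starts = n_starts, seed = seed)
    lambda <- rot$loadings
    phi <- rot$phi
  } else {
    lambda <- a
    phi <- diag(k)
  }
  ord <- order_factors(lambda, phi)
  lambda <- ord$lambda; phi <- ord$phi
  structure_l <- lambda %*% phi
  h2 <- diag(lambda %*% phi %*% t(lambda))
  heywood <- any(h2 > 1 + 1e-6)
  if (heywood) {
    warn("Heywood case: communality above 1; capped",
         class = "emospace_heywood")
    h2 <- pmin(h2, 1)
  }
  psi <- pmax(1 - h2, 0)
  ss_structure <- colSums(structure_l^2)
  var_prop <- ss_structure / sum(ss_structure)
  z <- scale(m)
  scores <- z %*% tenberge_weights(r, lambda, phi)
  colnames(scores) <- colnames(lambda)
  new_factor_model(
    loadings = lambda, phi = phi, uniquenesses = psi, communalities = h2,
    scores = scores, var_prop = var_prop,
    method = "EFA-minres-oblimin", heywood = heywood,
    unrotated = a, r = r, n_obs = nrow(m))
}

new_factor_model <- function(...) {
  structure(list(...), class = "emospace_factor_model")
}

#' @export
print.emospace_factor_model <- function(x, digits = 2, ...) {
  cat(sprintf("<factor model: %s, k = %d, n = %d%s>\n", x$method,
              ncol(x$loadings), x$n_obs %||% NA_integer_,
              if (isTRUE(x$heywood)) ", Heywood-flagged" else ""))
  cat("proportion of common variance:",
      paste(sprintf("%.2f", x$var_prop), collapse = " "), "\n")
  print(round(x$loadings, digits))
  invisible(x)
}

# ---- minres extraction -----------------------------------------------------

# Minimize the sum of squared off-diagonal residuals of R - LL' over the
# uniquenesses; for fixed communalities the optimal L comes from the leading
# eigenvectors of the reduced correlation matrix.
minres_extract <- function(r, k, start = NULL) {
  p <- ncol(r)
  lambda_of <- function(psi) {
    rs <- r
    diag(rs) <- 1 - psi
    e <- eigen(rs, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  }
  obj <- function(psi) minres_objective(psi, r, k)
  if (is.null(start)) {
    smc <- tryCatch(1 - 1 / diag(solve(r)), error = function(e) rep(0.5, p))
    start <- pmin(pmax(1 - smc, 0.05), 0.95)
  }
  start <- pmin(pmax(start, 1e-3), 1)
  fit <- nlminb(start, obj, lower = 1e-3, upper = 1,
                control = list(rel.tol = 1e-7, x.tol = 1e-6, iter.max = 120))
  l <- lambda_of(fit$par)
  rownames(l) <- colnames(r)
  colnames(l) <- paste0("F", seq_len(k))
  list(loadings = l, psi = fit$par, objective = fit$objective,
       converged = fit$convergence == 0)
}

# ---- oblimin (direct quartimin) rotation -----------------------------------

quartimin_vg <- function(l) {
  l2 <- l^2
  k <- ncol(l)
  m <- matrix(1, k, k); diag(m) <- 0
  list(f = sum(l2 * (l2 %*% m)) / 4, g = l * (l2 %*% m))
}

# Oblique gradient-projection rotation (quartimin criterion), restarted from
# `n_starts` random orthonormal rotation matrices; best criterion value wins.
# The inner projection loop runs in C++; `gpf_oblq()` below is the reference
# R implementation the test-suite checks it against.
oblimin_rotate <- function(a, n_starts = 10, seed = 1L, maxit = 500,
                           eps = 1e-6) {
  k <- ncol(a)
  starts <- c(list(diag(k)),
              with_seed(seed, lapply(seq_len(n_starts), function(i) {
                qr.Q(qr(matrix(rnorm(k * k), k, k)))
              })))
  best <- NULL
  for (t0 in starts) {
    res <- gpf_oblq_quartimin(a, t0, maxit, eps)
    if (is.null(best) || res$f < best$f) best <- res
  }
  dimnames(best$loadings) <- dimnames(a)
  best
}

gpf_oblq <- function(a, tmat, vg, maxit = 500, eps = 1e-6) {
  al <- 1
  l <- a %*% t(solve(tmat))
  vgq <- vg(l)
  f <- vgq$f
  g <- -t(t(l) %*% vgq$g %*% solve(tmat))
  for (iter in seq_len(maxit)) {
    gp <- g - tmat %*% diag(colSums(tmat * g), ncol(tmat))
    s <- sqrt(sum(gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:20) {
      x <- tmat - al * gp
      v <- 1 / sqrt(colSums(x^2))
      tmat_t <- x %*% diag(v, ncol(x))
      l <- a %*% t(solve(tmat_t))
      vgq_t <- vg(l)
      if (vgq_t$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    tmat <- tmat_t
    f <- vgq_t$f
    g <- -t(t(l) %*% vgq_t$g %*% solve(tmat))
  }
  list(loadings = l, phi = t(tmat) %*% tmat, rotation = tmat, f = f)
}

# Order factors by explained common variance (structure convention) and flip
# signs so each factor's dominant loading is positive.
order_factors <- function(lambda, phi) {
  structure_l <- lambda %*% phi
  ss <- colSums(structure_l^2)
  ord <- order(ss, decreasing = TRUE)
  lambda <- lambda[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  signs <- vapply(seq_len(ncol(lambda)), function(j) {
    v <- lambda[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  lambda <- sweep(lambda, 2, signs, `*`)
  phi <- diag(signs, length(signs)) %*% phi %*% diag(signs, length(signs))
  colnames(lambda) <- paste0("F", seq_len(ncol(lambda)))
  dimnames(phi) <- list(colnames(lambda), colnames(lambda))
  list(lambda = lambda, phi = phi)
}

# ---- ten Berge factor-score weights ----------------------------------------

mat_sqrt <- function(m, inverse = FALSE) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 1e-12)
  d <- if (inverse) 1 / sqrt(ev) else sqrt(ev)
  e$vectors %*% diag(d, length(d)) %*% t(e$vectors)
}

# Correlation-preserving (ten Berge) weights: with W below, the score
# correlation matrix W' R W equals phi exactly.
tenberge_weights <- function(r, lambda, phi) {
  l1 <- lambda %*% mat_sqrt(phi)
  r_inv <- solve(r)
  r_half_inv <- mat_sqrt(r, inverse = TRUE)
  c_mat <- r_half_inv %*% l1 %*% mat_sqrt(t(l1) %*% r_inv %*% l1, inverse = TRUE)
  r_half_inv %*% c_mat %*% mat_sqrt(phi)
}
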