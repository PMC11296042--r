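#' Confirmatory factor analysis by maximum likelihood
#'
#' Fits the factor model `Sigma = Lambda Phi Lambda' + Psi` under
#' multivariate normality, with the loading pattern fixed by a logical
#' matrix (`TRUE` entries free, others fixed at zero), factor correlations
#' free (unit factor variances) and uniquenesses free. The discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` is minimized with
#' `nlminb`; `chi^2 = (N - 1) F_min`.
#'
#' @param s sample correlation (or covariance) matrix of the held-out data.
#' @param pattern `p x k` logical matrix of free loadings.
#' @param n_obs number of observations behind `s`.
#' @param start optional warm start: list with `loadings`, `phi`, `psi`
#'   (e.g., from the EFA fitted to the other half).
#' @return list with `chisq`, `df`, `rmsea` (see [rmsea()]), `loadings`,
#'   `phi`, `psi`, `converged`, `objective`.
#' @export
fit_cfa <- function(s, pattern, n_obs, start = NULL) {
  p <- ncol(s)
  k <- ncol(pattern)
  pattern <- as.matrix(pattern)
  stopifnot(nrow(pattern) == p, is.logical(pattern))
  if (any(colSums(pattern) == 0)) {
    abort("a factor has no assigned items", class = "emospace_empty_factor")
  }
  n_lambda <- sum(pattern)
  n_phi <- k * (k - 1) / 2
  n_free <- n_lambda + n_phi + p
  df <- p * (p + 1) / 2 - n_free
  log_det_s <- determinant(s, logarithm = TRUE)$modulus

  unpack <- function(theta) {
    lambda <- matrix(0, p, k)
    lambda[pattern] <- theta[seq_len(n_lambda)]
    phi <- diag(k)
    if (n_phi > 0) {
      w <- diag(k)
      w[lower.tri(w)] <- theta[n_lambda + seq_len(n_phi)]
      raw <- tcrossprod(w)
      d <- 1 / sqrt(diag(raw))
      phi <- raw * outer(d, d)
    }
    psi <- exp(theta[n_lambda + n_phi + seq_len(p)])
    list(lambda = lambda, phi = phi, psi = psi)
  }
  obj <- function(theta) {
    par <- unpack(theta)
    sigma <- par$lambda %*% par$phi %*% t(par$lambda) + diag(par$psi, p)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    log_det <- 2 * sum(log(diag(ch)))
    tr_term <- sum(chol2inv(ch) * s)
    val <- log_det + tr_term - log_det_s - p
    if (!is.finite(val)) 1e10 else val
  }
  # analytic gradient: dF/dSigma = Sigma^-1 (Sigma - S) Sigma^-1, chained
  # through the loading pattern, the row-normalized Cholesky factor of phi,
  # and the log-scale uniquenesses
  grad <- function(theta) {
    par <- unpack(theta)
    sigma <- par$lambda %*% par$phi %*% t(par$lambda) + diag(par$psi, p)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(theta)))
    si <- chol2inv(ch)
    w <- si - si %*% s %*% si
    g_lambda <- 2 * (w %*% par$lambda %*% par$phi)
    out <- numeric(length(theta))
    out[seq_len(n_lambda)] <- g_lambda[pattern]
    if (n_phi > 0) {
      g_phi <- t(par$lambda) %*% w %*% par$lambda  # dF = tr(g_phi dPhi)
      wch <- diag(k)
      wch[lower.tri(wch)] <- theta[n_lambda + seq_len(n_phi)]
      m <- tcrossprod(wch)
      dm <- diag(m)
      inv_sq <- 1 / sqrt(dm)
      # dF/dM via Phi_ij = M_ij / sqrt(M_ii M_jj); diag(Phi) constant
      g_m <- g_phi * outer(inv_sq, inv_sq)
      diag(g_m) <- 0
      off <- g_phi * m * outer(inv_sq, inv_sq)  # g_phi_ij * Phi_ij
      diag(off) <- 0
      diag(g_m) <- -rowSums(off) / dm  # d/dM_ii terms (row i appears via both margins)
      g_w <- 2 * g_m %*% wch
      out[n_lambda + seq_len(n_phi)] <- g_w[lower.tri(g_w)]
    }
    out[n_lambda + n_phi + seq_len(p)] <- diag(w) * par$psi
    out
  }

  theta0 <- numeric(n_free)
  if (!is.null(start)) {
    l0 <- start$loadings
    theta0[seq_len(n_lambda)] <- l0[pattern]
    if (n_phi > 0) {
      w0 <- tryCatch(t(chol(start$phi)), error = function(e) diag(k))
      w0 <- w0 / diag(w0)
      theta0[n_lambda + seq_len(n_phi)] <- w0[lower.tri(w0)]
    }
    theta0[n_lambda + n_phi + seq_len(p)] <- log(pmax(start$psi, 1e-3))
  } else {
    theta0[seq_len(n_lambda)] <- 0.5
    theta0[n_lambda + n_phi + seq_len(p)] <- log(0.5)
  }

  fit <- tryCatch(
    nlminb(theta0, obj, gradient = grad,
           control = list(iter.max = 500, eval.max = 2000)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$objective) || fit$objective >= 1e9) {
    return(list(chisq = NA_real_, df = df, rmsea = NA_real_,
                loadings = NULL, phi = NULL, psi = NULL,
                converged = FALSE, objective = NA_real_))
  }
  par <- unpack(fit$par)
  chisq <- (n_obs - 1) * max(fit$objective, 0)
  list(chisq = chisq, df = df,
       rmsea = rmsea(chisq, df, n_obs),
       loadings = par$lambda, phi = par$phi, psi = par$psi,
       converged = fit$convergence == 0, objective = fit$objective)
}

#' Root-mean-square error of approximation
#'
#' `sqrt(max(chisq - df, 0) / (df * (N - 1)))`; 0 for a perfectly fitting
#' model.
#'
#' @param chisq model chi-square.
#' @param df model degrees of freedom (must be positive).
#' @param n_obs sample size.
#' @return the RMSEA value.
#' @export
rmsea <- function(chisq, df, n_obs) {
  if (is.na(chisq) || df <= 0) return(NA_real_)
  sqrt(max(chisq - df, 0) / (df * (n_obs - 1)))
}
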