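#' Scree-based retention indices: parallel analysis, optimal coordinate,
#' acceleration factor
#'
#' All three operate on the eigenvalues of the full correlation matrix
#' (principal-component eigenvalues). Parallel analysis retains the leading
#' run of observed eigenvalues exceeding the rank-wise `probs` quantile
#' (default 0.95, the usual centile convention; `probs = NULL` compares to
#' the rank-wise mean instead) of eigenvalues of random normal data of the
#' same size — the quantile form keeps the false-retention rate on pure
#' noise near `1 - probs`; the optimal coordinate
#' retains the leading run of eigenvalues exceeding their linear
#' extrapolation from the next eigenvalue and the last one; the acceleration
#' factor retains one fewer than the position of the sharpest elbow (the
#' maximal second difference of the scree), floored at 1.
#'
#' @param eigenvalues eigenvalues of the observed correlation matrix, sorted
#'   descending.
#' @param n_obs number of observations behind the correlation matrix.
#' @param n_sim random datasets for parallel analysis (default 50).
#' @param probs quantile of the random eigenvalue distribution used as the
#'   parallel-analysis threshold (default 0.95); `NULL` uses the mean.
#' @param seed seed for the random-data eigenvalues.
#' @return list with integer suggestions `pa`, `oc`, `af`, and the
#'   rank-wise random-eigenvalue thresholds as `random_threshold`.
#' @export
scree_indices <- function(eigenvalues, n_obs, n_sim = 50, probs = 0.95,
                          seed = 1L) {
  p <- length(eigenvalues)
  if (is.unsorted(rev(eigenvalues))) abort("eigenvalues must be sorted descending")
  if (n_obs <= p) abort("`n_obs` must exceed the number of variables")
  random_eigs <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      eigen(cor(matrix(rnorm(n_obs * p), n_obs, p)),
            symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  random_threshold <- if (is.null(probs)) {
    rowMeans(random_eigs)
  } else {
    apply(random_eigs, 1, quantile, probs = probs)
  }
  pa <- leading_run(eigenvalues > random_threshold)

  # optimal coordinate: predicted value at rank i from the line through
  # (i+1, e[i+1]) and (p, e[p])
  oc_pred <- vapply(seq_len(p - 2), function(i) {
    slope <- (eigenvalues[p] - eigenvalues[i + 1]) / (p - (i + 1))
    eigenvalues[i + 1] - slope
  }, numeric(1))
  oc <- leading_run(eigenvalues[seq_len(p - 2)] >= oc_pred)

  if (p < 3) {
    af <- NA_integer_
  } else {
    accel <- vapply(2:(p - 1), function(i) {
      eigenvalues[i + 1] - 2 * eigenvalues[i] + eigenvalues[i - 1]
    }, numeric(1))
    af <- max(1L, (which.max(accel) + 1L) - 1L)
  }
  list(pa = pa, oc = oc, af = af, random_threshold = random_threshold)
}

leading_run <- function(flags) {
  if (length(flags) == 0 || !flags[1]) return(0L)
  runs <- rle(flags)
  as.integer(runs$lengths[1])
}

#' Structure-based retention indices: VSS, Velicer's MAP, empirical BIC
#'
#' Very Simple Structure (complexity 1) keeps only each item's largest
#' absolute loading, reconstructs the correlation matrix from the
#' simplified pattern and picks the k maximizing the fit
#' `1 - SS_resid / SS_r` over the off-diagonals. Velicer's minimum average
#' partial picks the k minimizing the mean squared partial correlation after
#' partialling out the first k principal components (on a no-structure
#' matrix the minimum is at zero components; the reported convention is 1).
#' Empirical BIC picks the k minimizing `chi^2 - df log(N)` of the k-factor
#' maximum-likelihood solution.
#'
#' @param corr correlation matrix (or `emospace_corr_structure`).
#' @param n_obs observations behind `corr`.
#' @param k_max largest number of factors to examine (default 8).
#' @return list with `vss`, `map`, `ebic` (integer suggestions) and the
#'   per-k curves `vss_fit`, `map_values`, `ebic_values`.
#' @export
retention_indices <- function(corr, n_obs, k_max = 8) {
  r <- unclass(corr)
  p <- ncol(r)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warn("correlation matrix not positive-definite; ridge-regularizing")
    r <- (r + diag(1e-6, p)) / (1 + 1e-6)
  }
  k_max <- min(k_max, p - 1)
  ss_r <- sum(r[lower.tri(r)]^2)

  vss_fit <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fit <- tryCatch(efa_from_corr(r, k), error = function(e) NULL)
    if (is.null(fit)) next
    l <- fit$lambda
    simp <- matrix(0, p, k)
    jmax <- max.col(abs(l), ties.method = "first")
    simp[cbind(seq_len(p), jmax)] <- l[cbind(seq_len(p), jmax)]
    resid <- r - simp %*% fit$phi %*% t(simp)
    vss_fit[k] <- 1 - sum(resid[lower.tri(resid)]^2) / ss_r
  }
  vss <- if (all(is.na(vss_fit))) NA_integer_ else which.max(vss_fit)

  # Velicer MAP on principal components
  e <- eigen(r, symmetric = TRUE)
  map_values <- rep(NA_real_, k_max + 1)
  map_values[1] <- mean(r[lower.tri(r)]^2)
  for (k in seq_len(k_max)) {
    l <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    cstar <- r - tcrossprod(l)
    d <- diag(cstar)
    if (any(d < 1e-10)) break
    pc <- cstar / sqrt(outer(d, d))
    map_values[k + 1] <- mean(pc[lower.tri(pc)]^2)
  }
  map <- max(1L, which.min(map_values) - 1L)

  ebic_values <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    df <- ((p - k)^2 - (p + k)) / 2
    if (df <= 0) next
    fa <- tryCatch(
      suppressWarnings(factanal(covmat = r, factors = k, n.obs = n_obs,
                                rotation = "none")),
      error = function(e) NULL)
    if (is.null(fa)) next
    ebic_values[k] <- unname(fa$STATISTIC) - df * log(n_obs)
  }
  ebic <- if (all(is.na(ebic_values))) NA_integer_ else which.min(ebic_values)

  list(vss = as.integer(vss), map = as.integer(map), ebic = as.integer(ebic),
       vss_fit = vss_fit, map_values = map_values, ebic_values = ebic_values)
}

# minres + oblimin straight from a correlation matrix (no raw data)
efa_from_corr <- function(r, k, n_starts = 4, seed = 1L) {
  ext <- minres_extract(r, k)
  if (k == 1) return(list(lambda = ext$loadings, phi = diag(1)))
  rot <- oblimin_rotate(ext$loadings, n_starts = n_starts, seed = seed)
  ord <- order_factors(rot$loadings, rot$phi)
  list(lambda = ord$lambda, phi = ord$phi)
}

#' Cross-validated factor retention (EFA half, CFA half)
#'
#' For each candidate k and each iteration, the stimuli are randomly split
#' into two halves; an EFA (minres + oblimin) on half A yields the explained
#' variance and a loading pattern (items assigned to every factor crossing
#' the absolute-loading cutoff; an item crossing none is assigned to its
#' largest-loading factor); a CFA with that pattern is fitted to half B by
#' maximum likelihood and its RMSEA recorded. Iterations where a factor ends
#' up with no assigned items, or where the CFA fails, are marked invalid and
#' excluded from the mean curves. The suggested k is the largest k whose
#' mean RMSEA improves on k - 1 by more than `elbow_tol`.
#'
#' @param matrix a [rating_matrix()].
#' @param k_range candidate factor counts (default 1:8).
#' @param n_iter random half-splits per k (default 20).
#' @param cutoff absolute pattern-loading cutoff for item assignment
#'   (default 0.2).
#' @param elbow_tol minimum mean-RMSEA improvement that justifies one more
#'   factor (default 0.01).
#' @param n_starts oblimin rotation restarts per EFA fit inside the loop
#'   (default 3; the assignment pattern is robust to the rotation start).
#' @param seed integer seed.
#' @return list of class `emospace_retention`: `curves` (tibble of per-k
#'   mean explained variance and mean RMSEA with valid-iteration counts),
#'   `details` (per-iteration tibble), `chosen_k`, `justification`.
#' @export
cv_retention <- function(matrix, k_range = 1:8, n_iter = 20, cutoff = 0.2,
                         elbow_tol = 0.01, n_starts = 3, seed = 1L) {
  m <- as_matrix(matrix)
  n <- nrow(m)
  if (n < 2 * (max(k_range) + 2)) {
    warn("few rows relative to k_max; half-splits will be small")
  }
  r_full <- cor(m)
  rows <- list()
  for (k in k_range) {
    # warm-start the per-iteration minres searches from the full-data fit
    psi_full <- tryCatch(minres_extract(r_full, k)$psi,
                         error = function(e) NULL)
    for (it in seq_len(n_iter)) {
      half <- with_seed(child_seed(seed, k * 1000 + it),
                        sample.int(n, floor(n / 2)))
      a <- m[half, , drop = FALSE]
      b <- m[-half, , drop = FALSE]
      res <- withCallingHandlers(tryCatch({
        efa <- fit_efa(a, k, n_starts = n_starts, psi_start = psi_full,
                       seed = child_seed(seed, k * 1000 + it))
        expl <- sum(efa$communalities) / ncol(m)
        pattern <- abs(efa$loadings) > cutoff
        none <- rowSums(pattern) == 0
        if (any(none)) {
          jmax <- max.col(abs(efa$loadings), ties.method = "first")
          pattern[cbind(which(none), jmax[none])] <- TRUE
        }
        cfa <- fit_cfa(cor(b), pattern, nrow(b),
                       start = list(loadings = efa$loadings * pattern,
                                    phi = efa$phi,
                                    psi = efa$uniquenesses))
        tibble::tibble(k = k, iter = it, explained = expl,
                       rmsea = cfa$rmsea, chisq = cfa$chisq, df = cfa$df,
                       valid = cfa$converged && is.finite(cfa$rmsea))
      }, emospace_empty_factor = function(e) {
        tibble::tibble(k = k, iter = it, explained = NA_real_,
                       rmsea = NA_real_, chisq = NA_real_, df = NA_real_,
                       valid = FALSE)
      }, error = function(e) {
        tibble::tibble(k = k, iter = it, explained = NA_real_,
                       rmsea = NA_real_, chisq = NA_real_, df = NA_real_,
                       valid = FALSE)
      }), emospace_heywood = function(w) invokeRestart("muffleWarning"))
      rows[[length(rows) + 1L]] <- res
    }
  }
  details <- dplyr::bind_rows(rows)
  curves <- dplyr::summarise(
    dplyr::group_by(details, .data$k),
    mean_explained = mean(.data$explained[.data$valid]),
    mean_rmsea = mean(.data$rmsea[.data$valid]),
    n_valid = sum(.data$valid), .groups = "drop")
  # validity is not random: iterations that keep a k-factor CFA converging
  # are those whose half-split supported the extra structure, so a mean over
  # a filtered minority is biased low; only k with a clear majority of valid
  # iterations may be selected
  eligible <- curves$n_valid >= ceiling(0.75 * n_iter)
  chosen <- choose_k_elbow(curves$k[eligible], curves$mean_rmsea[eligible],
                           elbow_tol)
  structure(list(curves = curves, details = details, chosen_k = chosen,
                 justification = sprintf(
                   "largest k with mean RMSEA improvement over k-1 above %.3g",
                   elbow_tol)),
            class = "emospace_retention")
}

# largest k whose mean RMSEA improves on the best value at any smaller k by
# more than tol (k=1 baseline always eligible); requiring improvement over
# the running minimum (not just over k-1) stops a noisy spike at k-1 from
# promoting a k that is no better than an earlier solution. NA curves are
# skipped.
choose_k_elbow <- function(k, rmsea_means, tol) {
  ok <- is.finite(rmsea_means)
  k <- k[ok]; rmsea_means <- rmsea_means[ok]
  if (length(k) == 0) return(NA_integer_)
  chosen <- k[1]
  best <- rmsea_means[1]
  for (i in seq_along(k)[-1]) {
    if ((best - rmsea_means[i]) > tol) chosen <- k[i]
    best <- min(best, rmsea_means[i])
  }
  as.integer(chosen)
}

#' @export
print.emospace_retention <- function(x, ...) {
  cat(sprintf("<cv retention: chosen k = %s (%s)>\n", x$chosen_k,
              x$justification))
  print(x$curves)
  invisible(x)
}
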