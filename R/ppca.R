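#' Principal preserved component analysis
#'
#' Eigen-decomposition of the symmetrized cross-covariance
#' `(X'Y + Y'X) / 2` of two column-centered datasets measured on the same
#' stimuli and scales. Components are ordered by eigenvalue (descending);
#' positive eigenvalues capture structure preserved across the two
#' datasets. With `Y = X` the decomposition reduces exactly to the PCA of
#' `X'X`.
#'
#' @param x,y numeric matrices of identical dimensions (stimuli x scales).
#' @param m number of components to keep (default: all).
#' @param center column-center each dataset first (default `TRUE`).
#' @return list of class `emospace_ppca`: `weights` (scales x m eigenvector
#'   matrix), `eigenvalues`, `m`.
#' @export
fit_ppca <- function(x, y, m = NULL, center = TRUE) {
  x <- as_matrix(x); y <- as_matrix(y)
  if (!all(dim(x) == dim(y))) abort("`x` and `y` must have the same shape")
  if (center) {
    x <- scale(x, scale = FALSE)
    y <- scale(y, scale = FALSE)
  }
  cc <- (crossprod(x, y) + crossprod(y, x)) / 2
  e <- eigen(cc, symmetric = TRUE)
  m <- m %||% ncol(x)
  w <- e$vectors[, seq_len(m), drop = FALSE]
  rownames(w) <- colnames(x)
  colnames(w) <- paste0("PPC", seq_len(m))
  structure(list(weights = w, eigenvalues = e$values[seq_len(m)], m = m),
            class = "emospace_ppca")
}

#' @export
print.emospace_ppca <- function(x, ...) {
  cat(sprintf("<PPCA: %d components; leading eigenvalues %s>\n", x$m,
              paste(sprintf("%.2f", head(x$eigenvalues, 4)), collapse = " ")))
  invisible(x)
}

#' Split-half leave-one-out PPCA significance procedure
#'
#' Per repetition: raters of each stimulus are randomly assigned to two
#' sets and averaged within set; each stimulus is then held out in turn,
#' PPCA is fitted on the remaining stimuli, and the held-out row of both
#' sets is projected onto the components. The held-out component scores are
#' concatenated and correlated across the two sets, partialling out (by
#' least-squares residualization) all previous components' scores on each
#' side. Across repetitions, each component's correlations are tested for a
#' positive median with a one-tailed Wilcoxon signed-rank test at the
#' Bonferroni-corrected level `alpha / m`; the reported significant count
#' is the contiguous leading run of significant components.
#'
#' @param table a rater-level rating table.
#' @param n_rep repetitions of the rater split (default 20).
#' @param alpha family significance level before Bonferroni (default 0.05).
#' @param m number of components (default: number of scales).
#' @param domain domain to analyze.
#' @param seed integer seed.
#' @return list of class `emospace_ppca_cv`: `correlations` (rep x
#'   component matrix of partialled held-out correlations), `p_values`
#'   (per component), `alpha_bonferroni`, `n_significant` (leading run),
#'   `n_significant_total`, `weights` (from a final full-data split-half
#'   fit averaged over repetitions is not well-defined, so the weights of
#'   a fit on the full rater-mean split of the first repetition are
#'   returned for inspection).
#' @export
ppca_loocv <- function(table, n_rep = 20, alpha = 0.05, m = NULL,
                       domain = "narrative", seed = 1L) {
  validate_rating_table(table)
  main <- table[table$domain == domain & table$trial_type == "main", , drop = FALSE]
  scales <- sort(unique(main$scale_id))
  stimuli <- sort(unique(main$stimulus_id))
  m <- m %||% length(scales)
  # ratings per (stimulus, scale): list of rater values
  n_raters <- min(tapply(main$rating,
                         list(main$stimulus_id, main$scale_id),
                         length))
  if (is.na(n_raters) || n_raters < 2) {
    abort("need at least 2 ratings per (stimulus, scale) cell to split halves")
  }
  first_weights <- NULL
  cors <- matrix(NA_real_, n_rep, m)
  for (rep_i in seq_len(n_rep)) {
    halves <- with_seed(child_seed(seed, rep_i), split_rater_halves(main, scales, stimuli))
    xa <- halves$a; xb <- halves$b
    sa <- matrix(NA_real_, length(stimuli), m)
    sb <- matrix(NA_real_, length(stimuli), m)
    for (i in seq_along(stimuli)) {
      fit <- fit_ppca(xa[-i, , drop = FALSE], xb[-i, , drop = FALSE], m = m)
      ca <- colMeans(xa[-i, , drop = FALSE])
      cb <- colMeans(xb[-i, , drop = FALSE])
      sa[i, ] <- (xa[i, ] - ca) %*% fit$weights
      sb[i, ] <- (xb[i, ] - cb) %*% fit$weights
    }
    if (rep_i == 1) first_weights <- fit_ppca(xa, xb, m = m)$weights
    cors[rep_i, ] <- partialled_correlations(sa, sb)
  }
  alpha_b <- alpha / m
  p_values <- apply(cors, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3) return(NA_real_)
    suppressWarnings(wilcox.test(v, alternative = "greater")$p.value)
  })
  sig <- !is.na(p_values) & p_values < alpha_b
  structure(list(correlations = cors, p_values = p_values,
                 alpha_bonferroni = alpha_b,
                 n_significant = leading_run(sig),
                 n_significant_total = sum(sig),
                 weights = first_weights, seed = as.integer(seed)),
            class = "emospace_ppca_cv")
}

# split each (stimulus, scale) cell's raters into two halves and average
split_rater_halves <- function(main, scales, stimuli) {
  a <- matrix(NA_real_, length(stimuli), length(scales),
              dimnames = list(stimuli, scales))
  b <- a
  by_scale <- split(main, main$scale_id)
  for (s in names(by_scale)) {
    sub <- by_scale[[s]]
    sessions <- sort(unique(sub$session_id))
    half <- sample(sessions, floor(length(sessions) / 2))
    in_a <- sub$session_id %in% half
    ma <- tapply(sub$rating[in_a], sub$stimulus_id[in_a], mean)
    mb <- tapply(sub$rating[!in_a], sub$stimulus_id[!in_a], mean)
    a[names(ma), s] <- ma
    b[names(mb), s] <- mb
  }
  if (anyNA(a) || anyNA(b)) abort("a rater half has empty (stimulus, scale) cells")
  list(a = a, b = b)
}

# correlate held-out scores across sets, partialling out all previous
# components (least-squares residuals on each side)
partialled_correlations <- function(sa, sb) {
  m <- ncol(sa)
  out <- numeric(m)
  for (j in seq_len(m)) {
    va <- sa[, j]; vb <- sb[, j]
    if (j > 1) {
      za <- sa[, seq_len(j - 1), drop = FALSE]
      zb <- sb[, seq_len(j - 1), drop = FALSE]
      va <- stats::lsfit(za, va)$residuals
      vb <- stats::lsfit(zb, vb)$residuals
    }
    out[j] <- safe_cor(va, vb)
  }
  out
}

#' @export
print.emospace_ppca_cv <- function(x, ...) {
  cat(sprintf(paste0("<PPCA cross-validation: %d significant leading ",
                     "component(s) at Bonferroni alpha = %.5f>\n"),
              x$n_significant, x$alpha_bonferroni))
  invisible(x)
}
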