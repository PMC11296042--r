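#' Tidy a fitted factor model
#'
#' One row per (scale, factor) with the pattern loading, plus per-scale
#' communality and uniqueness.
#'
#' @param x an `emospace_factor_model` from [fit_efa()] or [fit_pca()].
#' @param ... unused.
#' @return a tibble with `scale_id`, `factor`, `loading`, `communality`,
#'   `uniqueness`.
#' @export
tidy.emospace_factor_model <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    scale_id = rep(rownames(l) %||% as.character(seq_len(nrow(l))), ncol(l)),
    factor = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l),
    communality = rep(x$communalities, ncol(l)),
    uniqueness = rep(x$uniquenesses, ncol(l)))
}

#' @rdname tidy.emospace_factor_model
#' @export
glance.emospace_factor_model <- function(x, ...) {
  tibble::tibble(method = x$method, k = ncol(x$loadings), n_obs = x$n_obs,
                 common_variance = sum(x$communalities) / nrow(x$loadings),
                 heywood = isTRUE(x$heywood))
}

#' Tidy a retention report
#'
#' @param x an `emospace_retention` from [cv_retention()].
#' @param ... unused.
#' @return the per-k curve tibble (mean explained variance, mean RMSEA,
#'   valid-iteration counts).
#' @export
tidy.emospace_retention <- function(x, ...) x$curves

#' @rdname tidy.emospace_retention
#' @export
glance.emospace_retention <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, justification = x$justification)
}

#' Tidy a PPCA cross-validation result
#'
#' @param x an `emospace_ppca_cv` from [ppca_loocv()].
#' @param ... unused.
#' @return a tibble with one row per component: median held-out
#'   correlation, Wilcoxon p, significance at the Bonferroni level.
#' @export
tidy.emospace_ppca_cv <- function(x, ...) {
  tibble::tibble(
    component = seq_len(ncol(x$correlations)),
    median_r = apply(x$correlations, 2, median, na.rm = TRUE),
    p = x$p_values,
    significant = !is.na(x$p_values) & x$p_values < x$alpha_bonferroni)
}

#' @rdname tidy.emospace_ppca_cv
#' @export
glance.emospace_ppca_cv <- function(x, ...) {
  tibble::tibble(n_significant = x$n_significant,
                 n_significant_total = x$n_significant_total,
                 alpha_bonferroni = x$alpha_bonferroni)
}

#' Tidy a congruence result
#'
#' @param x an `emospace_congruence` from [tucker_congruence()].
#' @param ... unused.
#' @return tibble with `factor` and `congruence`.
#' @export
tidy.emospace_congruence <- function(x, ...) {
  tibble::tibble(factor = names(x$phi), congruence = unname(x$phi))
}
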