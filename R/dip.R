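#' Hartigan's dip statistic
#'
#' The maximal distance between the empirical cdf and its closest unimodal
#' cdf. Larger values indicate stronger departure from unimodality; the
#' minimal attainable value for an all-distinct sample is `1/(2n)`.
#'
#' @param x numeric vector.
#' @return the dip statistic (a single non-negative number).
#' @export
dip_stat <- function(x) {
  x <- x[is.finite(x)]
  dip_stat_sorted(sort(x))
}

#' Dip test of unimodality
#'
#' Bootstrap p-value against the uniform null distribution (the classical
#' least-favorable unimodal reference): `n_boot` uniform samples of the same
#' size are drawn, and the p-value is the add-one-corrected fraction of
#' bootstrap dips at least as large as the observed one.
#'
#' @param x numeric vector.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return list of class `emospace_dip`: `statistic`, `p_value`, `n`,
#'   `n_boot`.
#' @export
dip_test <- function(x, n_boot = 2000, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  d_obs <- dip_stat_sorted(sort(x))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    dip_stat_sorted(sort(runif(n)))
  }, numeric(1)))
  p <- (1 + sum(boots >= d_obs)) / (n_boot + 1)
  structure(list(statistic = d_obs, p_value = p, n = n,
                 n_boot = as.integer(n_boot)),
            class = "emospace_dip")
}

#' @export
print.emospace_dip <- function(x, ...) {
  cat(sprintf("<dip test: D = %.4g, p = %.4g (n = %d, %d bootstrap reps)>\n",
              x$statistic, x$p_value, x$n, x$n_boot))
  invisible(x)
}
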