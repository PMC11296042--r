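# Internal helpers shared across modules.

# Run an expression under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed and an index, staying
# inside the 32-bit integer range.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + i * 2654435761) %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

is_symmetric_psd <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

# Pearson correlation that returns NA (instead of erroring/warning) on
# zero-variance input or fewer than `min_pairs` complete pairs.
safe_cor <- function(x, y, min_pairs = 3L, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_pairs) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

# Fisher r-to-z with clamping away from |r| = 1.
fisher_z <- function(r, warn_clamp = TRUE) {
  lim <- 1 - 1e-12
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    if (warn_clamp) warn("correlations with |r| = 1 clamped before Fisher z-transform")
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

lower_tri <- function(m) m[lower.tri(m)]

`%||%` <- function(x, y) if (is.null(x)) y else x
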