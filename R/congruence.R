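#' Tucker congruence between two loading matrices
#'
#' Column-wise Tucker congruence coefficients after (optionally) aligning
#' the comparison matrix `b` to `a` with the best orthogonal Procrustes
#' rotation (from the singular decomposition of `b' a`). The coefficient is
#' the cosine between matched columns and is invariant to per-column scaling
#' and, with alignment on, to any column permutation and sign change of `b`.
#'
#' @param a reference loading matrix (or a fitted `emospace_factor_model`).
#' @param b comparison loading matrix (or fitted model), same dimensions.
#' @param procrustes align `b` to `a` first (default `TRUE`).
#' @return list of class `emospace_congruence`: `phi` (per-factor
#'   congruence), `rotation` (the alignment rotation, identity when
#'   `procrustes = FALSE`), `aligned` (the aligned `b`).
#' @export
tucker_congruence <- function(a, b, procrustes = TRUE) {
  a <- loadings_of(a)
  b <- loadings_of(b)
  if (!all(dim(a) == dim(b))) abort("`a` and `b` must have the same dimensions")
  rot <- diag(ncol(a))
  if (procrustes) {
    if (ncol(a) > 1) {
      sv <- svd(t(b) %*% a)
      rot <- sv$u %*% t(sv$v)
    } else {
      rot <- matrix(if (sum(a * b) < 0) -1 else 1)
    }
  }
  b_al <- b %*% rot
  phi <- vapply(seq_len(ncol(a)), function(j) {
    num <- sum(a[, j] * b_al[, j])
    den <- sqrt(sum(a[, j]^2) * sum(b_al[, j]^2))
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  names(phi) <- colnames(a) %||% paste0("F", seq_len(ncol(a)))
  structure(list(phi = phi, rotation = rot, aligned = b_al),
            class = "emospace_congruence")
}

loadings_of <- function(x) {
  if (inherits(x, "emospace_factor_model")) return(x$loadings)
  as.matrix(x)
}

#' @export
print.emospace_congruence <- function(x, ...) {
  cat("<Tucker congruence:",
      paste(sprintf("%.3f", x$phi), collapse = " "), ">\n")
  invisible(x)
}
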