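#' Scale-by-scale correlation structure
#'
#' Pairwise Pearson correlations across stimuli/instances.
#'
#' @param matrix a [rating_matrix()] (or plain numeric matrix, rows =
#'   stimuli, columns = scales).
#' @return an object of class `emospace_corr_structure`: the correlation
#'   matrix with a `scale_ids` attribute.
#' @export
scale_corr <- function(matrix) {
  m <- as_matrix(matrix)
  if (nrow(m) < 3) abort("need at least 3 rows to correlate scales")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant column(s): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  r <- cor(m)
  structure(r, class = c("emospace_corr_structure", "matrix", "array"),
            scale_ids = colnames(m))
}

#' @export
print.emospace_corr_structure <- function(x, ...) {
  cat(sprintf("<correlation structure over %d scales>\n", nrow(x)))
  print(round(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))], 2))
  invisible(x)
}

#' Seriation order for correlation-matrix display
#'
#' Leaf order of an average-linkage dendrogram on correlation distance
#' (1 - r), used to sort heatmaps so correlated blocks are contiguous.
#'
#' @param c an `emospace_corr_structure` (or correlation matrix).
#' @return integer ordering of the scales.
#' @export
seriate <- function(c) {
  r <- unclass(c)
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  hc$order
}

#' Second-order similarity between two correlation structures
#'
#' Spearman rank correlation between the Fisher z-transformed lower
#' triangles of the two matrices, restricted to a shared scale roster (the
#' z-transform is monotone, so it does not change the rank correlation; it
#' is applied for comparability of the vectorized entries).
#'
#' @param c1,c2 correlation structures over (at least) the shared scales.
#' @param shared_scales character vector of scale ids present in both;
#'   default: the intersection, in `c1` order.
#' @return list of class `emospace_second_order` with `rho`,
#'   `shared_scales`, and (after [perm_test()]) `p`, `n_perm`, `seed`.
#' @export
second_order <- function(c1, c2, shared_scales = NULL) {
  v <- second_order_vectors(c1, c2, shared_scales)
  rho <- cor(v$z1, v$z2, method = "spearman")
  structure(list(rho = rho, shared_scales = v$shared, p = NA_real_,
                 n_perm = NA_integer_, seed = NA_integer_),
            class = "emospace_second_order")
}

second_order_vectors <- function(c1, c2, shared_scales = NULL) {
  ids1 <- attr(c1, "scale_ids") %||% colnames(c1)
  ids2 <- attr(c2, "scale_ids") %||% colnames(c2)
  shared <- shared_scales %||% intersect(ids1, ids2)
  if (length(shared) < 3) abort("need at least 3 shared scales")
  if (!all(shared %in% ids1) || !all(shared %in% ids2)) {
    abort("`shared_scales` must be present in both structures")
  }
  m1 <- unclass(c1)[match(shared, ids1), match(shared, ids1)]
  m2 <- unclass(c2)[match(shared, ids2), match(shared, ids2)]
  list(z1 = fisher_z(lower_tri(m1)), z2 = fisher_z(lower_tri(m2)),
       m1 = m1, m2 = m2, shared = shared)
}

#' Permutation test for second-order similarity
#'
#' The scales of one matrix are jointly row/column permuted `n` times
#' (preserving symmetry); the empirical p-value uses the add-one correction
#' `p = (1 + #\{rho_perm >= rho_obs\}) / (n + 1)`, so p is never zero.
#'
#' @inheritParams second_order
#' @param n number of permutations (default 10000).
#' @param seed integer seed.
#' @return an `emospace_second_order` with `p` filled in.
#' @export
perm_test <- function(c1, c2, shared_scales = NULL, n = 10000, seed = 1L) {
  if (n < 100) warn("fewer than 100 permutations gives a coarse p-value")
  v <- second_order_vectors(c1, c2, shared_scales)
  rho_obs <- cor(v$z1, v$z2, method = "spearman")
  p <- length(v$shared)
  z1_rank <- rank(v$z1)  # Spearman via ranks; z1 side fixed
  perm_rhos <- with_seed(seed, vapply(seq_len(n), function(i) {
    idx <- sample.int(p)
    m2p <- v$m2[idx, idx]
    cor(z1_rank, rank(fisher_z(lower_tri(m2p), warn_clamp = FALSE)))
  }, numeric(1)))
  pval <- (1 + sum(perm_rhos >= rho_obs)) / (n + 1)
  structure(list(rho = rho_obs, shared_scales = v$shared, p = pval,
                 n_perm = as.integer(n), seed = as.integer(seed),
                 perm_rhos = perm_rhos),
            class = "emospace_second_order")
}

#' @export
print.emospace_second_order <- function(x, ...) {
  cat(sprintf("<second-order similarity: rho = %.3f%s, %d shared scales>\n",
              x$rho,
              if (is.na(x$p)) "" else sprintf(", p = %.4g (%d perms)", x$p, x$n_perm),
              length(x$shared_scales)))
  invisible(x)
}
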