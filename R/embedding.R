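#' Trustworthiness of a low-dimensional embedding
#'
#' Measures how much the embedded k-neighborhoods can be trusted: each
#' point that intrudes into an embedded neighborhood without belonging to
#' the original-space neighborhood is penalized by how far down the
#' original-space ranking it sits. 1 means no intruders; values near the
#' permutation baseline mean the embedded neighborhoods are unrelated to
#' the original space.
#'
#' @param x original-space matrix (rows = instances).
#' @param e embedding (same row count, typically 2 columns).
#' @param k_nn neighborhood size (must be below `n / 2`).
#' @return trustworthiness in \[0, 1\].
#' @export
trustworthiness <- function(x, e, k_nn = 5) {
  x <- as_matrix(x); e <- as.matrix(e)
  n <- nrow(x)
  if (nrow(e) != n) abort("`x` and `e` must have the same number of rows")
  if (k_nn >= n / 2) abort("`k_nn` must be below n / 2")
  dx <- as.matrix(dist(x))
  de <- as.matrix(dist(e))
  diag(dx) <- Inf
  diag(de) <- Inf
  penalty <- 0
  for (i in seq_len(n)) {
    rank_orig <- rank(dx[i, ], ties.method = "first")
    nn_emb <- order(de[i, ])[seq_len(k_nn)]
    intruders <- nn_emb[rank_orig[nn_emb] > k_nn]
    penalty <- penalty + sum(rank_orig[intruders] - k_nn)
  }
  1 - 2 / (n * k_nn * (2 * n - 3 * k_nn - 1)) * penalty
}

#' Cross-validated neighborhood-size selection for the 2-D embedding
#'
#' For each candidate neighborhood size, rows are randomly split in half
#' (`n_split` times); the embedding is fitted on one half, the held-out
#' half is mapped through the fitted model, and two complementary metrics
#' are computed on the held-out half: trustworthiness (local structure) and
#' the Spearman correlation of pairwise Euclidean distances (global
#' structure). The chosen size maximizes the rank-sum of the two mean
#' metrics across the grid.
#'
#' @param matrix a [rating_matrix()].
#' @param grid candidate neighborhood sizes (default `c(5, 10, 15, 25, 50)`).
#' @param n_split random half-splits (default 10).
#' @param trust_k trustworthiness neighborhood size (default 5).
#' @param seed integer seed.
#' @return list of class `emospace_neighbor_cv`: `chosen`, `metrics`
#'   (per-size tibble of mean trustworthiness and distance correlation).
#' @export
select_neighbors <- function(matrix, grid = c(5, 10, 15, 25, 50),
                             n_split = 10, trust_k = 5, seed = 1L) {
  m <- as_matrix(matrix)
  n <- nrow(m)
  if (any(grid >= floor(n / 2) / 2)) {
    grid <- grid[grid < floor(n / 2) / 2]
    if (length(grid) == 0) abort("all grid values too large for n/2 rows")
  }
  rows <- list()
  for (split_i in seq_len(n_split)) {
    half <- with_seed(child_seed(seed, split_i), sample.int(n, floor(n / 2)))
    a <- m[half, , drop = FALSE]
    b <- m[-half, , drop = FALSE]
    if (any(apply(b, 1, sd) == 0)) inform("degenerate constant row in a test half")
    for (nb in grid) {
      eb <- with_seed(child_seed(seed, split_i * 1000 + nb), {
        model <- uwot::umap(a, n_neighbors = nb, n_components = 2,
                            ret_model = TRUE, n_threads = 1,
                            n_sgd_threads = 0, verbose = FALSE)
        uwot::umap_transform(b, model, n_threads = 1, n_sgd_threads = 0,
                             verbose = FALSE)
      })
      tw <- trustworthiness(b, eb, k_nn = trust_k)
      rho <- cor(as.vector(dist(b)), as.vector(dist(eb)), method = "spearman")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_neighbors = nb, split = split_i, trustworthiness = tw,
        dist_spearman = rho)
    }
  }
  details <- dplyr::bind_rows(rows)
  metrics <- dplyr::summarise(
    dplyr::group_by(details, .data$n_neighbors),
    trustworthiness = mean(.data$trustworthiness),
    dist_spearman = mean(.data$dist_spearman), .groups = "drop")
  score <- rank(metrics$trustworthiness) + rank(metrics$dist_spearman)
  chosen <- metrics$n_neighbors[which.max(score)]
  structure(list(chosen = chosen, metrics = metrics, details = details,
                 seed = as.integer(seed)),
            class = "emospace_neighbor_cv")
}

#' 2-D manifold embedding of a rating matrix
#'
#' UMAP embedding to two dimensions, deterministic under a fixed seed.
#' Factor scores and/or category labels can be attached for plotting.
#'
#' @param matrix a [rating_matrix()].
#' @param n_neighbors neighborhood size (the study presets chose 10, 15 and
#'   25 for narrative, video and real-life data).
#' @param scores optional factor-score matrix (same rows) to carry along.
#' @param seed integer seed.
#' @return list of class `emospace_embedding`: `coords` (tibble with `dim1`,
#'   `dim2`, optional score columns and `label`), `n_neighbors`, `seed`.
#' @export
embed_ratings <- function(matrix, n_neighbors = 15, scores = NULL, seed = 1L) {
  m <- as_matrix(matrix)
  if (nrow(m) < n_neighbors + 1) abort("need at least n_neighbors + 1 rows")
  coords <- with_seed(seed,
    uwot::umap(m, n_neighbors = n_neighbors, n_components = 2,
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  out <- tibble::tibble(instance = rownames(m) %||% as.character(seq_len(nrow(m))),
                        dim1 = coords[, 1], dim2 = coords[, 2])
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(nrow(scores) == nrow(m))
    for (j in seq_len(ncol(scores))) {
      out[[colnames(scores)[j] %||% paste0("score_", j)]] <- scores[, j]
    }
  }
  labels <- attr(matrix, "labels")
  if (!is.null(labels)) out$label <- labels
  structure(list(coords = out, n_neighbors = n_neighbors,
                 seed = as.integer(seed)),
            class = "emospace_embedding")
}
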