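#' Hierarchical agglomerative clustering of emotion instances
#'
#' Ward-linkage clustering on Euclidean distances between raw (explicitly
#' unstandardized) 1-7 rating profiles; the shared 1-7 range makes the
#' per-scale variances informative, so no rescaling is applied. Flat cuts
#' at 2 and 4 clusters (the valence and valence-by-arousal partitions) are
#' returned alongside the dendrogram.
#'
#' @param matrix a [rating_matrix()].
#' @param cuts cluster counts to cut at (default `c(2, 4)`).
#' @return list of class `emospace_hac`: `tree` (an `hclust`), `cuts`
#'   (named list of label vectors), `labels` (reference labels carried from
#'   the matrix, if any).
#' @export
hac <- function(matrix, cuts = c(2, 4)) {
  m <- as_matrix(matrix)
  if (nrow(m) < 2) abort("need at least 2 rows")
  tree <- hclust(dist(m), method = "ward.D2")
  cut_labels <- lapply(cuts, function(k) cutree(tree, k = min(k, nrow(m))))
  names(cut_labels) <- paste0("k", cuts)
  structure(list(tree = tree, cuts = cut_labels,
                 labels = attr(matrix, "labels")),
            class = "emospace_hac")
}

#' K-means category recovery scoring
#'
#' Runs K-means (multiple restarts, best inertia kept) with k equal to the
#' number of reference categories and scores the agreement with the
#' reference labels by the adjusted Rand index, the adjusted mutual
#' information and a contingency table.
#'
#' @param matrix a [rating_matrix()].
#' @param reference reference label vector (one per row); defaults to the
#'   matrix's attached category labels.
#' @param k number of clusters; defaults to the number of reference
#'   categories.
#' @param n_start K-means restarts (default 10).
#' @param seed integer seed.
#' @return list of class `emospace_kmeans_agreement`: `cluster` (labels),
#'   `inertia`, `ari`, `ami`, `contingency`.
#' @export
kmeans_agreement <- function(matrix, reference = NULL, k = NULL,
                             n_start = 10, seed = 1L) {
  m <- as_matrix(matrix)
  reference <- reference %||% attr(matrix, "labels")
  if (is.null(reference)) abort("no reference labels given or attached")
  stopifnot(length(reference) == nrow(m))
  k <- k %||% length(unique(reference))
  if (k > nrow(m)) abort("k exceeds the number of rows")
  km <- with_seed(seed, kmeans(m, centers = k, nstart = n_start,
                               iter.max = 100))
  structure(list(cluster = km$cluster, inertia = km$tot.withinss,
                 ari = adjusted_rand_index(reference, km$cluster),
                 ami = adjusted_mutual_info(reference, km$cluster),
                 contingency = table(reference = reference,
                                     cluster = km$cluster),
                 seed = as.integer(seed)),
            class = "emospace_kmeans_agreement")
}

#' Chance-corrected partition agreement indices
#'
#' `adjusted_rand_index()` is the Rand index corrected for chance under the
#' hypergeometric model (1 for identical partitions, about 0 for unrelated
#' ones, can be negative). `adjusted_mutual_info()` is mutual information
#' corrected by its expected value under the same model, normalized by the
#' arithmetic mean of the two entropies. Both are invariant to label
#' renaming.
#'
#' @param a,b label vectors of equal length.
#' @return a single number (at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  unname((sum_ij - expected) / (max_index - expected))
}

#' @rdname adjusted_rand_index
#' @export
adjusted_mutual_info <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  p <- tab / n
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    if (tab[i, j] > 0) {
      mi <- mi + p[i, j] * log(p[i, j] / (ai[i] * bj[j] / n^2))
    }
  }
  h_a <- -sum(ifelse(ai > 0, (ai / n) * log(ai / n), 0))
  h_b <- -sum(ifelse(bj > 0, (bj / n) * log(bj / n), 0))
  emi <- expected_mutual_info(ai, bj, n)
  denom <- (h_a + h_b) / 2 - emi
  if (abs(denom) < 1e-14) return(1)
  unname((mi - emi) / denom)
}

# E[MI] under the hypergeometric model of random contingency tables with
# fixed margins
expected_mutual_info <- function(ai, bj, n) {
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (lo > hi) next
      for (nij in lo:hi) {
        term <- (nij / n) * log(n * nij / (ai[i] * bj[j]))
        lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
          lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) -
          lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai[i] - nij + 1) -
          lgamma(bj[j] - nij + 1) - lgamma(n - ai[i] - bj[j] + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Dip test of unimodality on pairwise distances
#'
#' Computes all pairwise Euclidean distances between rows (uniformly
#' subsampled to `max_distances` when there are more) and applies the
#' Hartigan dip test; a small p-value indicates a multimodal distance
#' distribution, i.e. cluster structure in the high-dimensional space.
#'
#' @param matrix a [rating_matrix()].
#' @param n_boot bootstrap replicates for the p-value.
#' @param max_distances cap on the number of distances used (default
#'   10000).
#' @param seed integer seed.
#' @return an `emospace_dip` (see [dip_test()]) with an `n_rows` field.
#' @export
dip_unimodality <- function(matrix, n_boot = 2000, max_distances = 10000,
                            seed = 1L) {
  m <- as_matrix(matrix)
  if (nrow(m) < 3) abort("need at least 3 rows")
  d <- as.vector(dist(m))
  if (all(d == 0)) abort("all rows identical; distance distribution degenerate")
  if (length(d) > max_distances) {
    d <- with_seed(child_seed(seed, 1), sample(d, max_distances))
  }
  out <- dip_test(d, n_boot = n_boot, seed = child_seed(seed, 2))
  out$n_rows <- nrow(m)
  out
}

#' Select the clearest basic-emotion instances
#'
#' Restricted to the six basic-emotion scales, a perfect instance of a
#' category is rated 7 on its own scale and 1 on the other five. Candidates
#' must be rated strictly above 6 on the category scale; among candidates,
#' the instances closest (Euclidean) to the perfect vector are selected, up
#' to `per_category`, ties broken by instance id.
#'
#' @param matrix6 a [rating_matrix()] whose columns are exactly the six
#'   basic-emotion scales.
#' @param per_category instances to select per category (default 5).
#' @param threshold minimal rating on the category's own scale (strict;
#'   default 6).
#' @return tibble with `category`, `instance`, `distance`, ordered by
#'   category then distance; categories without candidates are absent (and
#'   reported via a message).
#' @export
select_basic_instances <- function(matrix6, per_category = 5, threshold = 6) {
  m <- as_matrix(matrix6)
  if (ncol(m) != 6) abort("matrix must have exactly the six basic-emotion scales")
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- list()
  for (j in seq_len(ncol(m))) {
    cand <- which(m[, j] > threshold)
    if (length(cand) == 0) {
      inform(sprintf("no candidates for category `%s`", colnames(m)[j]))
      next
    }
    perfect <- rep(1, 6)
    perfect[j] <- 7
    dists <- unname(sqrt(rowSums(sweep(m[cand, , drop = FALSE], 2, perfect)^2)))
    ord <- order(dists, ids[cand])
    take <- head(ord, per_category)
    out[[length(out) + 1L]] <- tibble::tibble(
      category = colnames(m)[j], instance = ids[cand][take],
      distance = dists[take])
  }
  dplyr::bind_rows(out)
}
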