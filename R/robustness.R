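#' Stimulus-decimation robustness of a factor solution
#'
#' Re-fits the k-factor EFA on progressively smaller random subsets of the
#' stimuli (removing `step` stimuli at a time, `n_rand` randomizations per
#' size) and records the per-factor Tucker congruence (with Procrustes
#' alignment) between each subset solution and the full-set solution.
#'
#' @param matrix a [rating_matrix()].
#' @param k number of factors.
#' @param step stimuli removed per decimation step (the study presets are 5
#'   for narratives, 25 for videos, 250 for real-life instances).
#' @param n_rand randomizations per size (default 20).
#' @param min_left smallest subset size to attempt (default `k + 2`; the
#'   procedure stops early, with a message, below that).
#' @param seed integer seed.
#' @return tibble with `n_stimuli`, `rand`, `factor`, `congruence`.
#' @export
decimate_stimuli <- function(matrix, k, step, n_rand = 20, min_left = NULL,
                             seed = 1L) {
  m <- as_matrix(matrix)
  stopifnot(step >= 1)
  n <- nrow(m)
  min_left <- min_left %||% (k + 2)
  full <- fit_efa(m, k, seed = seed)
  sizes <- seq(n - step, min_left, by = -step)
  if (length(sizes) == 0) {
    inform("no decimation sizes above the minimum; returning empty curves")
  }
  rows <- list()
  for (size in sizes) {
    for (rand in seq_len(n_rand)) {
      idx <- with_seed(child_seed(seed, size * 100 + rand),
                       sample.int(n, size))
      fit <- tryCatch(fit_efa(m[idx, , drop = FALSE], k,
                              seed = child_seed(seed, size * 100 + rand)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      cg <- tucker_congruence(full, fit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_stimuli = size, rand = rand,
        factor = names(cg$phi), congruence = cg$phi)
    }
  }
  dplyr::bind_rows(rows)
}

#' Redundancy-based scale removal ordering
#'
#' Iteratively removes the scale with the highest mean correlation with the
#' remaining scales (the most redundant one), recomputing the means after
#' each removal,
#' until two scales remain. Ties are broken by scale id (alphabetical),
#' making the ordering deterministic and invariant to input row order.
#'
#' @param corr a correlation structure (or correlation matrix) over at
#'   least 3 scales.
#' @return character vector: scales in removal order (the two never-removed
#'   scales are appended last, in id order).
#' @export
redundancy_order <- function(corr) {
  r <- unclass(corr)
  if (ncol(r) < 3) abort("need at least 3 scales")
  ids <- colnames(r) %||% paste0("s", seq_len(ncol(r)))
  dimnames(r) <- list(ids, ids)
  order_out <- character(0)
  while (ncol(r) > 2) {
    means <- (rowSums(r) - 1) / (ncol(r) - 1)  # raw means, self excluded
    top <- max(means)
    cand <- sort(names(means)[means >= top - 1e-12])
    drop_id <- cand[1]
    order_out <- c(order_out, drop_id)
    keep <- setdiff(colnames(r), drop_id)
    r <- r[keep, keep, drop = FALSE]
  }
  c(order_out, sort(colnames(r)))
}

#' Scale-decimation robustness of a factor solution
#'
#' Removes scales one at a time in a given (redundancy-based) order,
#' re-fits the k-factor EFA on the reduced roster, and records Pearson
#' correlations between the full-set and subset factor scores, with factors
#' matched greedily by maximal absolute correlation (a permutation: no
#' factor is matched twice) and sign-aligned.
#'
#' @param matrix a [rating_matrix()].
#' @param k number of factors.
#' @param order removal ordering, e.g. from [redundancy_order()]; default
#'   computed from the matrix's own correlation structure.
#' @param min_scales stop when this many scales remain (default 5).
#' @param seed integer seed.
#' @return tibble with `n_scales`, `removed`, `factor`, `matched_factor`,
#'   `r` (sign-aligned score correlation).
#' @export
decimate_scales <- function(matrix, k, order = NULL, min_scales = 5,
                            seed = 1L) {
  m <- as_matrix(matrix)
  order <- order %||% redundancy_order(scale_corr(m))
  full <- fit_efa(m, k, seed = seed)
  rows <- list()
  remaining <- colnames(m)
  for (i in seq_along(order)) {
    remaining <- setdiff(remaining, order[i])
    if (length(remaining) < max(min_scales, k + 1)) break
    fit <- tryCatch(fit_efa(m[, remaining, drop = FALSE], k,
                            seed = child_seed(seed, i)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    match_res <- match_factor_scores(full$scores, fit$scores)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      n_scales = length(remaining), removed = order[i],
      factor = colnames(full$scores),
      matched_factor = colnames(fit$scores)[match_res$assignment],
      r = match_res$r)
  }
  dplyr::bind_rows(rows)
}

# Greedy maximal-|r| matching between two score matrices; returns the
# assignment (a permutation) and the sign-aligned correlations.
match_factor_scores <- function(f_ref, f_new) {
  cm <- cor(f_ref, f_new)
  k <- ncol(f_ref)
  assignment <- integer(k)
  r <- numeric(k)
  free <- rep(TRUE, k)
  ord <- order(-apply(abs(cm), 1, max))
  for (i in ord) {
    j <- which.max(ifelse(free, abs(cm[i, ]), -Inf))
    assignment[i] <- j
    r[i] <- abs(cm[i, j])
    free[j] <- FALSE
  }
  list(assignment = assignment, r = r)
}
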