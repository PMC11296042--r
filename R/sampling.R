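#' Subset-size determination by PCA plateau
#'
#' For each candidate subset size, draws `n_rep` random subsets of the
#' stimulus feature matrix, and records the minimal number of principal
#' components needed to reach `var_target` cumulative variance; the plateau
#' is the smallest size whose mean PC count comes within `tol` of the
#' full-set value.
#'
#' @param feature_matrix numeric matrix (stimuli x features).
#' @param sizes candidate subset sizes (ascending).
#' @param n_rep random subsets per size (default 100).
#' @param var_target cumulative variance target in (0, 1) (default 0.80).
#' @param tol plateau tolerance in PC-count units (default 0.5).
#' @param seed integer seed.
#' @return list of class `emospace_pca_plateau`: `curve` (tibble with
#'   `size`, `mean_pcs`), `full_pcs`, `plateau_size`.
#' @export
pca_plateau <- function(feature_matrix, sizes, n_rep = 100, var_target = 0.80,
                        tol = 0.5, seed = 1L) {
  if (var_target <= 0 || var_target >= 1) {
    abort("`var_target` must lie strictly between 0 and 1")
  }
  m <- as.matrix(feature_matrix)
  n <- nrow(m)
  if (any(sizes > n)) abort("sizes exceed the number of stimuli")
  pcs_needed <- function(x) {
    vars <- prcomp(x, center = TRUE, scale. = FALSE)$sdev^2
    cum <- cumsum(vars) / sum(vars)
    which(cum >= var_target - 1e-12)[1]
  }
  full_pcs <- pcs_needed(m)
  curve <- lapply(sizes, function(s) {
    counts <- vapply(seq_len(n_rep), function(rep_i) {
      idx <- with_seed(child_seed(seed, s * 1000 + rep_i), sample.int(n, s))
      pcs_needed(m[idx, , drop = FALSE])
    }, numeric(1))
    tibble::tibble(size = s, mean_pcs = mean(counts), sd_pcs = sd(counts))
  })
  curve <- dplyr::bind_rows(curve)
  at_plateau <- curve$size[curve$mean_pcs >= full_pcs - tol]
  structure(list(curve = curve, full_pcs = full_pcs,
                 plateau_size = if (length(at_plateau)) min(at_plateau) else NA_integer_,
                 var_target = var_target),
            class = "emospace_pca_plateau")
}

#' Maximum-variation subset selection
#'
#' Greedy diverse-subset sampling: starting from every possible initial
#' stimulus in turn, each new pick maximizes the summed Euclidean distance
#' to all previously selected stimuli; the run whose final subset has the
#' largest total pairwise distance wins. Ties (in picks and between runs)
#' break lexicographically by stimulus id, so the output is deterministic.
#'
#' @param feature_matrix numeric matrix (stimuli x features) with stimulus
#'   ids as rownames (row numbers are used otherwise).
#' @param m subset size (at least 2).
#' @param criterion `"sum"` (default; maximize summed distance to the
#'   selected set) or `"maxmin"` (maximize the minimum distance).
#' @return list of class `emospace_max_variation`: `ids` (selected
#'   stimulus ids, in selection order of the winning run), `objective`
#'   (total pairwise distance of the subset), `start` (winning
#'   initialization).
#' @export
max_variation <- function(feature_matrix, m, criterion = c("sum", "maxmin")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(feature_matrix)
  n <- nrow(x)
  if (m < 2) abort("`m` must be at least 2")
  if (m > n) abort("`m` exceeds the number of stimuli")
  ids <- rownames(x) %||% sprintf("%d", seq_len(n))
  d <- as.matrix(dist(x))
  id_order <- order(ids)  # lexicographic tie-break helper
  rank_id <- integer(n)
  rank_id[id_order] <- seq_len(n)

  best <- NULL
  for (start in seq_len(n)[id_order]) {
    sel <- start
    for (step in seq_len(m - 1)) {
      score <- if (criterion == "sum") {
        colSums(d[sel, , drop = FALSE])
      } else {
        apply(d[sel, , drop = FALSE], 2, min)
      }
      score[sel] <- -Inf
      top <- max(score)
      cand <- which(score >= top - 1e-12)
      sel <- c(sel, cand[which.min(rank_id[cand])])
    }
    obj <- sum(d[sel, sel]) / 2
    if (is.null(best) || obj > best$objective + 1e-12 ||
        (abs(obj - best$objective) <= 1e-12 &&
         rank_id[start] < rank_id[best$start])) {
      best <- list(ids = ids[sel], objective = obj, start = start)
    }
  }
  structure(list(ids = best$ids, objective = best$objective,
                 start = ids[best$start], criterion = criterion),
            class = "emospace_max_variation")
}
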