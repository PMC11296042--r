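#' Linear autoencoder fitted by alternating least squares
#'
#' A single hidden layer of width k with linear activations: reconstruct
#' `X W_e W_d` from column-centered data `X`. The two weight matrices are
#' fitted by alternating exact least-squares updates from a random start;
#' at convergence the reconstruction equals the projection onto the top-k
#' principal subspace of the training data (the classical linear
#' autoencoder / PCA equivalence), which the test-suite verifies
#' numerically.
#'
#' @param x numeric matrix (rows = observations), already column-centered.
#' @param k bottleneck width.
#' @param max_iter,tol ALS iteration controls.
#' @param seed seed for the random start.
#' @return list with `encoder` (p x k), `decoder` (k x p), `train_mse`,
#'   `iterations`, `converged`.
#' @export
fit_linear_autoencoder <- function(x, k, max_iter = 500, tol = 1e-10,
                                   seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(k >= 1, k <= p)
  w_e <- with_seed(seed, matrix(rnorm(p * k, sd = 0.1), p, k))
  mse <- function(w_e, w_d) mean((x - x %*% w_e %*% w_d)^2)
  last <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    h <- x %*% w_e
    w_d <- tryCatch(solve(crossprod(h), crossprod(h, x)),
                    error = function(e) NULL)
    if (is.null(w_d)) {  # degenerate bottleneck; re-jitter
      w_e <- w_e + matrix(rnorm(p * k, sd = 0.01), p, k)
      next
    }
    w_e <- t(w_d) %*% solve(tcrossprod(w_d))
    cur <- mse(w_e, w_d)
    if (is.finite(last) && abs(last - cur) < tol * max(1, cur)) {
      converged <- TRUE
      last <- cur
      break
    }
    last <- cur
  }
  list(encoder = w_e, decoder = w_d, train_mse = last, iterations = it,
       converged = converged)
}

#' Cross-validated linear-autoencoder dimensionality curves
#'
#' For each bottleneck width k, the raters are randomly split in half, the
#' autoencoder is trained on the half-A stimulus-by-scale aggregate and its
#' reconstruction error is measured on the held-out half-B aggregate
#' (repeated `n_iter` times). Decoder weights from a final fit on the
#' full aggregate are returned per k for comparison against EFA loadings
#' with [tucker_congruence()].
#'
#' @param table a rater-level rating table (main trials are aggregated
#'   within each rater half).
#' @param k_range bottleneck widths (default 1:8).
#' @param n_iter random half-splits per k (default 10).
#' @param domain domain to aggregate.
#' @param seed integer seed.
#' @return list of class `emospace_autoencoder_cv`: `curves` (tibble with
#'   per-k, per-iteration train/test mean squared error), `weights` (list of
#'   p x k decoder weight matrices per k, from the full-data fit),
#'   `scales`.
#' @export
linear_autoencoder_cv <- function(table, k_range = 1:8, n_iter = 10,
                                  domain = "narrative", seed = 1L) {
  validate_rating_table(table)
  main <- table[table$domain == domain & table$trial_type == "main", , drop = FALSE]
  sessions <- unique(main$session_id)
  if (length(sessions) < 4) abort("need at least 4 rater sessions to half-split")
  full <- aggregate_matrix(main, domain)
  center <- colMeans(full)
  rows <- list()
  by_scale <- split(main$session_id, main$scale_id)
  for (it in seq_len(n_iter)) {
    # split raters in half within each scale so every cell stays covered
    half <- with_seed(child_seed(seed, it), unlist(lapply(by_scale, function(s) {
      s <- sort(unique(s))
      sample(s, floor(length(s) / 2))
    })))
    a <- aggregate_matrix(main[main$session_id %in% half, , drop = FALSE], domain,
                          scales = colnames(full))
    b <- aggregate_matrix(main[!(main$session_id %in% half), , drop = FALSE], domain,
                          scales = colnames(full))
    shared <- intersect(rownames(a), rownames(b))
    a <- scale(as_matrix(a)[shared, , drop = FALSE], scale = FALSE)
    b_centered <- scale(as_matrix(b)[shared, , drop = FALSE], scale = FALSE)
    for (k in k_range) {
      fit <- fit_linear_autoencoder(a, k, seed = child_seed(seed, it * 100 + k))
      test_mse <- mean((b_centered - b_centered %*% fit$encoder %*% fit$decoder)^2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        k = k, iter = it, train_mse = fit$train_mse, test_mse = test_mse,
        converged = fit$converged)
    }
  }
  x_full <- scale(as_matrix(full), scale = FALSE)
  weights <- lapply(k_range, function(k) {
    fit <- fit_linear_autoencoder(x_full, k, seed = child_seed(seed, 99000 + k))
    w <- t(fit$decoder)
    rownames(w) <- colnames(full)
    colnames(w) <- paste0("unit_", seq_len(k))
    w
  })
  names(weights) <- paste0("k", k_range)
  structure(list(curves = dplyr::bind_rows(rows), weights = weights,
                 scales = colnames(full), center = center),
            class = "emospace_autoencoder_cv")
}
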