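# Shared fixtures built in code; kept tiny so the suite stays fast.

# A minimal valid rating table: `n_stim` stimuli rated by `n_raters` raters
# on one scale, with retests duplicating the first `n_retest` stimuli.
toy_table <- function(n_stim = 4, n_raters = 2, n_retest = 2,
                      scale = "happy", domain = "narrative",
                      ratings = NULL) {
  rows <- list()
  for (r in seq_len(n_raters)) {
    vals <- if (is.null(ratings)) rep(4, n_stim) else ratings[[r]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = sprintf("p%02d", r),
      session_id = sprintf("s%02d", r),
      domain = domain,
      stimulus_id = sprintf("stim%02d", seq_len(n_stim)),
      scale_id = scale,
      rating = vals,
      trial_type = "main",
      reaction_time_ms = 2000,
      attention_fails = 0L)
    if (n_retest > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = sprintf("p%02d", r),
        session_id = sprintf("s%02d", r),
        domain = domain,
        stimulus_id = sprintf("stim%02d", seq_len(n_retest)),
        scale_id = scale,
        rating = vals[seq_len(n_retest)],
        trial_type = "retest",
        reaction_time_ms = 2000,
        attention_fails = 0L)
    }
  }
  as_rating_table(dplyr::bind_rows(rows))
}

# Block-structured correlation matrix: two perfectly separated blocks with
# within-block correlation `rho`.
block_corr <- function(sizes = c(3, 3), rho = 0.8) {
  p <- sum(sizes)
  r <- diag(p)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b] + sizes[b] - 1)
    r[idx, idx] <- rho
  }
  diag(r) <- 1
  colnames(r) <- rownames(r) <- paste0("s", sprintf("%02d", seq_len(p)))
  r
}

# Draw a data matrix whose sample correlation exactly equals `r`
# (whiten-and-recolor construction).
data_with_corr <- function(r, n = 200, seed = 1L) {
  p <- ncol(r)
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, scale = FALSE)
  z <- z %*% solve(chol(cov(z)))
  out <- z %*% chol(r)
  colnames(out) <- colnames(r)
  out
}
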