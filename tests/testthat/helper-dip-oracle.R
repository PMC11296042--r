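# Exact brute-force dip oracle, straight from the definition:
# dip(F_n) = min over unimodal cdfs G of sup_x |F_n(x) - G(x)|.
#
# A unimodal cdf is convex up to its mode and concave after it, and may jump
# at the mode. Restricting G to piecewise-linear functions with knots at the
# distinct sample locations is exact (the constraints bind only there), so
# for each candidate mode placement (in a gap between locations, or at a
# location with a jump) the minimal sup-deviation is a small linear program,
# solved here with boot::simplex. Only usable at small n; the fast
# implementation must agree with it to numerical tolerance.
dip_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2 || x[n] == x[1]) return(0)
  loc <- unique(x)
  L <- length(loc)
  first <- match(loc, x)            # a_i: first sample index at location
  last <- n + 1L - match(loc, rev(x))  # b_i
  up_c <- (first - 1) / n           # g_i - t <= up_c
  lo_c <- last / n                  # g_i + t >= lo_c
  d <- diff(loc)

  solve_lp <- function(n_g, upper_rows, lower_rows, mono_rows, curv_rows) {
    # variables: g_1..g_{n_g}, t ; minimize t
    nv <- n_g + 1
    a_obj <- c(rep(0, n_g), 1)
    A1 <- NULL; b1 <- NULL  # <=
    A2 <- NULL; b2 <- NULL  # >=
    add1 <- function(row, rhs) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    add2 <- function(row, rhs) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    for (r in upper_rows) {  # g_i - t <= rhs
      row <- rep(0, nv); row[r$i] <- 1; row[nv] <- -1; add1(row, r$rhs)
    }
    for (r in lower_rows) {  # g_i + t >= rhs
      row <- rep(0, nv); row[r$i] <- 1; row[nv] <- 1; add2(row, r$rhs)
    }
    for (i in seq_len(n_g)) {  # g_i <= 1
      row <- rep(0, nv); row[i] <- 1; add1(row, 1)
    }
    for (r in mono_rows) {  # g_i <= g_j
      row <- rep(0, nv); row[r$i] <- 1; row[r$j] <- -1; add1(row, 0)
    }
    for (r in curv_rows) {
      # d_prev * g_next - (d_prev + d_next) * g_mid + d_next * g_prev,
      # >= 0 for convex, <= 0 for concave
      row <- rep(0, nv)
      row[r$prev] <- r$d_next; row[r$mid] <- -(r$d_prev + r$d_next)
      row[r$nxt] <- r$d_prev
      if (r$convex) add2(row, 0) else add1(row, 0)
    }
    res <- boot::simplex(a = a_obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         maxi = FALSE)
    if (res$solved == 1) res$value else Inf
  }

  curv_for <- function(idx_prev, idx_mid, idx_nxt, loc_i, convex) {
    list(prev = idx_prev, mid = idx_mid, nxt = idx_nxt,
         d_prev = d[loc_i - 1], d_next = d[loc_i], convex = convex)
  }

  best <- Inf
  # mode in a gap j (0 = before all, L = after all). The slope into the
  # mode may rise and the slope out of it may fall freely, so exactly one
  # of the two flanking curvature constraints can be dropped: variant A
  # keeps convexity through location j, variant B keeps concavity through
  # location j + 1.
  for (j in 0:L) {
    for (variant in c("A", "B")) {
      conv_max <- if (variant == "A") j else j - 1      # convex at 2..conv_max
      conc_min <- if (variant == "A") j + 2 else j + 1  # concave at conc_min..L-1
      upper <- lapply(seq_len(L), function(i) list(i = i, rhs = up_c[i]))
      lower <- lapply(seq_len(L), function(i) list(i = i, rhs = lo_c[i]))
      mono <- lapply(seq_len(L - 1), function(i) list(i = i, j = i + 1))
      curv <- list()
      for (i in seq_len(L)) {
        if (i < 2 || i > L - 1) next
        if (i <= conv_max) curv[[length(curv) + 1]] <- curv_for(i - 1, i, i + 1, i, TRUE)
        if (i >= conc_min) curv[[length(curv) + 1]] <- curv_for(i - 1, i, i + 1, i, FALSE)
      }
      best <- min(best, solve_lp(L, upper, lower, mono, curv))
    }
  }
  # mode at location m with a jump: variables g_1..g_L are the convex-side
  # values, plus g_{L+1} = the post-jump value at location m
  for (m in seq_len(L)) {
    gp <- L + 1
    # pre-jump value at m only tracks the cdf's left limit; the post-jump
    # value gp tracks its right value
    upper <- c(lapply(seq_len(L), function(i) list(i = i, rhs = up_c[i])),
               list(list(i = gp, rhs = last[m] / n)))
    lower <- c(lapply(seq_len(L), function(i) {
      if (i == m) list(i = i, rhs = (first[m] - 1) / n)
      else list(i = i, rhs = lo_c[i])
    }), list(list(i = gp, rhs = lo_c[m])))
    mono <- c(
      lapply(seq_len(L - 1), function(i) {
        if (i == m) list(i = gp, j = i + 1) else list(i = i, j = i + 1)
      }),
      list(list(i = m, j = gp)))
    # the convex side ends at the pre-jump value g_m; concave rows starting
    # at m use gp as their left neighbor
    curv <- list()
    for (i in seq_len(L)) {
      if (i < 2 || i > L - 1) next
      if (i <= m - 1) curv[[length(curv) + 1]] <- curv_for(i - 1, i, i + 1, i, TRUE)
      if (i >= m + 1) {
        curv[[length(curv) + 1]] <- curv_for(
          if (i - 1 == m) gp else i - 1, i, i + 1, i, FALSE)
      }
    }
    best <- min(best, solve_lp(L + 1, upper, lower, mono, curv))
  }
  best
}
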