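# Independent oracles used by the tests.  These deliberately re-derive
# results by brute force / closed form, independent of the package code
# paths they check.

# Brute-force 4-connected component labeling by repeated flood fill,
# labels assigned in column-major raster order of first discovery (the
# package's convention).
flood_fill_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Exhaustive integer-shift search: displacement (dy, dx) of frame relative
# to ref minimizing mean squared difference on the overlap.
shift_search_oracle <- function(ref, frame, max_shift = 5L) {
  best <- c(0L, 0L); best_val <- Inf
  H <- nrow(ref); W <- ncol(ref)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    rs <- max(1, 1 + dy):min(H, H + dy)
    cs <- max(1, 1 + dx):min(W, W + dx)
    d <- frame[rs, cs] - ref[rs - dy, cs - dx]
    v <- mean(d^2)
    if (v < best_val) { best_val <- v; best <- c(dy, dx) }
  }
  c(dy = best[1], dx = best[2])
}

# Phase correlation: displacement (dy, dx) of frame relative to ref.
phase_corr_oracle <- function(ref, frame) {
  H <- nrow(ref); W <- ncol(ref)
  X <- stats::fft(ref - mean(ref)) * Conj(stats::fft(frame - mean(frame)))
  R <- X / pmax(Mod(X), 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE))
  k <- which.max(cc)
  pr <- (k - 1) %% H; pc <- (k - 1) %/% H
  sy <- if (pr > H / 2) pr - H else pr
  sx <- if (pc > W / 2) pc - W else pc
  c(dy = -sy, dx = -sx)
}

# Closed-form OLS slope via the normal equations.
ols_slope_oracle <- function(t, y) {
  X <- cbind(1, t)
  unname(solve(t(X) %*% X, t(X) %*% y)[2, 1])
}

# Closed-form Welch statistic from raw samples.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Small rendered field shared by several tests.
render_test_field <- function(n_boutons = 15, size = 96, seed = 42,
                              stage_drift = NULL, kin = kinetic_params(),
                              protocol = stim_protocol(), ...) {
  rend <- render_params(image_size = c(size, size),
                        stage_drift = stage_drift, ...)
  des <- hierarchy_design(1, 1, n_boutons, 0, 0.2, c(ctrl = 1),
                          seed = seed)
  tr <- draw_hierarchy(des, kin)
  po <- simulate_pools_multi(tr$k_exo, tr$k_endo, kin, protocol)
  out <- render_movie(po$f, rend, protocol, seed = seed + 100)
  out$pools <- po
  out$kin <- kin
  out
}
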