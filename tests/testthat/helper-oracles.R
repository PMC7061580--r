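# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each operation from its definition and share
# no code with the package internals.

# Normalized windowed convolution with reflective padding (edge sample
# excluded from the mirror), window anchored with floor((w-1)/2) samples of
# left context -- computed sample by sample.
oracle_smooth <- function(x, kernel) {
  w <- length(kernel); n <- length(x)
  k <- kernel / sum(kernel)
  L <- (w - 1) %/% 2; R <- w - 1 - L
  left  <- if (L > 0) x[(L + 1):2] else numeric(0)
  right <- if (R > 0) x[(n - 1):(n - R)] else numeric(0)
  xp <- c(left, x, right)
  vapply(seq_len(n), function(i) sum(k * xp[i:(i + w - 1)]), 0)
}

# Element-by-element finite differences (central interior, one-sided ends).
oracle_derivative <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- if (i == 1) (x[2] - x[1]) / dt
            else if (i == n) (x[n] - x[n - 1]) / dt
            else (x[i + 1] - x[i - 1]) / (2 * dt)
  }
  d
}

# Trapezoid rule summed panel by panel.
oracle_trapezoid <- function(x, dt) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + dt * (x[i] + x[i + 1]) / 2
  s
}

# Mean gray value by an explicit per-pixel loop over the circle.
oracle_mean_gray <- function(pixels, cx, cy, r) {
  tot <- 0; cnt <- 0
  for (row in seq_len(nrow(pixels))) {
    for (col in seq_len(ncol(pixels))) {
      if ((col - cx)^2 + (row - cy)^2 <= r^2) {
        tot <- tot + pixels[row, col]; cnt <- cnt + 1
      }
    }
  }
  tot / cnt
}

# Coarse grid search for the 3-parameter logistic, independent of nls: scans
# (k, t0) on a grid and solves A in closed form (linear least squares given
# the unit-amplitude curve), returning the best grid point.
oracle_logistic_grid <- function(t, y, k_grid = seq(0.3, 4, length.out = 25),
                                 t0_grid = seq(0, max(t), length.out = 25)) {
  best <- list(rss = Inf)
  for (k in k_grid) {
    for (t0 in t0_grid) {
      g <- 1 / (1 + exp(-k * (t - t0)))
      A <- sum(y * g) / sum(g * g)
      rss <- sum((y - A * g)^2)
      if (rss < best$rss) best <- list(A = A, k = k, t0 = t0, rss = rss)
    }
  }
  best
}

# Central 99% binomial band for n trials at success probability p.
binomial_band99 <- function(n, p) {
  c(lower = qbinom(0.005, n, p) / n, upper = qbinom(0.995, n, p) / n)
}

rel_err <- function(got, want) {
  abs(got - want) / pmax(abs(want), 1e-300)
}
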