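## Independent oracles and small fixture builders used across the suite.

## All-pairs Euclidean distance to the nearest opposite-label pixel, minus
## the one-pixel boundary offset. Quadratic brute force, usable up to ~16x16.
brute_force_boundary_distance <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  idx <- expand.grid(y = seq_len(h), x = seq_len(w))
  out <- matrix(NA_real_, h, w)
  for (k in seq_len(nrow(idx))) {
    y <- idx$y[k]; x <- idx$x[k]
    opp <- labels != labels[y, x]
    ys <- row(labels)[opp]; xs <- col(labels)[opp]
    out[y, x] <- min(sqrt((ys - y)^2 + (xs - x)^2)) - 1
  }
  pmax(out, 0)
}

## One-sample JZS Bayes factor by fine fixed-grid quadrature over the
## effect size itself: BF10 = Int Cauchy(delta; 0, r) * t_nu(t; ncp =
## delta sqrt(n)) ddelta / t_nu(t; 0), via the substitution
## delta = r * tan(theta). Entirely independent of the g-mixture route.
jzs_oracle <- function(t, n, r = 1, K = 40001) {
  nu <- n - 1
  th <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = K)
  delta <- r * tan(th)
  f <- suppressWarnings(dt(t, nu, ncp = delta * sqrt(n))) / pi
  m1 <- sum((f[-1] + f[-K]) / 2) * (th[2] - th[1])
  log(m1 / dt(t, nu))
}

## Scale a zero-centred sample so its one-sample t statistic is exactly
## `t_target`.
sample_with_t <- function(t_target, n, seed = 1) {
  x <- withr::with_seed(seed, rnorm(n))
  x <- x - mean(x)
  x / sd(x) + t_target / sqrt(n)
}

## Small deterministic colour population spanning L = 1..n_l uniformly.
uniform_L_population <- function(n = 1000) {
  color_population(L = seq(1, 99, length.out = n), A = rep(0, n),
                   B = rep(0, n))
}

## Patch map for a vertical half-split image: left `w_dark` columns dark.
half_split_patch_map <- function(h = 40, w = 40, w_dark = 20) {
  labels <- matrix(0, h, w)
  labels[, (w_dark + 1):w] <- 1
  list(labels = labels, dist = boundary_distance(labels))
}
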