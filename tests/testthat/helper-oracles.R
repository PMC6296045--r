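# Independent brute-force oracles used across the suite. These deliberately
# mirror the printed formulas with plain loops so they stay independent of the
# vectorized implementation paths.

angle_set <- c(0, pi / 4, pi / 2, 3 * pi / 4, pi)

fold_angle <- function(delta) {
  d <- abs(delta) %% pi
  min(d, pi - d)
}

naive_pixel_distance <- function(va, vb, ta, tb, alpha, beta,
                                 tan_cap = tan(pi / 2 - 0.01)) {
  d <- fold_angle(alpha - beta)
  ang <- if (abs(d - pi / 2) < 1e-12) tan_cap else tan(d)
  0.5 * (va - vb)^2 + 0.5 * (ta + tb + ang)
}

naive_geodesic <- function(a, b, tan_cap = tan(pi / 2 - 0.01)) {
  tot <- 0
  for (i in seq_along(a$values))
    tot <- tot + naive_pixel_distance(a$values[i], b$values[i],
                                      a$grad_mag[i], b$grad_mag[i],
                                      a$grad_angle[i], b$grad_angle[i], tan_cap)
  tot / length(a$values)
}

naive_euclidean <- function(a, b) {
  tot <- 0
  for (i in seq_along(a)) tot <- tot + (a[i] - b[i])^2
  tot / length(a)
}

naive_mse <- function(x, y) {
  tot <- 0
  for (i in seq_along(x)) tot <- tot + (x[i] - y[i])^2
  tot / length(x)
}

# grid-search minimizer of 0.5*(a - z)^2 + tau*|a|
grid_soft <- function(z, tau, step = 5e-4) {
  grid <- seq(-abs(z) - 1, abs(z) + 1, by = step)
  grid[which.min(0.5 * (grid - z)^2 + tau * abs(grid))]
}

# per-component Gaussian log-density sum with mean zero, via solve()
naive_component_scores <- function(Yc, covs) {
  vapply(covs, function(S) {
    d <- nrow(S)
    Si <- solve(S)
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    s <- 0
    for (m in seq_len(ncol(Yc))) {
      ym <- Yc[, m]
      s <- s - 0.5 * drop(t(ym) %*% Si %*% ym) - 0.5 * ld -
        0.5 * d * log(2 * pi)
    }
    s
  }, numeric(1))
}

# random feature patches on a modest gray scale (keeps double-precision
# comparisons against the vectorized path meaningful)
random_features <- function(p, seed) {
  set.seed(seed)
  list(values = matrix(runif(p * p, 0, 50), p, p),
       grad_mag = matrix(runif(p * p, 0, 10), p, p),
       grad_angle = matrix(sample(angle_set, p * p, replace = TRUE), p, p))
}

small_phantom <- function(size = 160, n = 6, radius = 12, seed = 3,
                          motif = "ring") {
  make_phantom(phantom_spec(size = size, n_particles = n, radius = radius,
                            motif = motif, seed = seed))
}
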