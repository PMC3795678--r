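# Independent oracles for the check-loss engine.  These deliberately use a
# different formulation of the pinball loss (pmax form) and different
# optimization strategies (grid search, exhaustive vertex enumeration) than
# the package's exchange algorithm.

pinball <- function(y, q, tau) {
  r <- y - q
  sum(pmax(tau * r, (tau - 1) * r))
}

# 1-D grid minimization of the check loss for intercept-only problems;
# ties resolve to the smallest grid point, i.e. the lower end of a flat
# optimum when the grid contains it
grid_quantile_oracle <- function(y, tau, n_grid = 20001L) {
  grid <- sort(unique(c(y, seq(min(y), max(y), length.out = n_grid))))
  loss <- vapply(grid, function(q) pinball(y, q, tau), numeric(1))
  grid[which.min(loss)]
}

# exhaustive enumeration of all column-subset interpolating solutions;
# returns the minimal WSAD over vertices (feasible for n <= 12)
vertex_enum_oracle <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  for (S in utils::combn(n, p, simplify = FALSE)) {
    B <- X[S, , drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    beta <- solve(B, y[S])
    w <- pinball(y, drop(X %*% beta), tau)
    if (w < best) best <- w
  }
  best
}

# LP optimality (quantile sign) property of a fitted conditional quantile
sign_property_ok <- function(y, qhat, tau, eps = 1e-7) {
  n <- length(y)
  sum(y < qhat - eps) <= n * tau + 1e-9 &&
    sum(y > qhat + eps) <= n * (1 - tau) + 1e-9
}

# random small regression instance with an almost-surely unique optimum
# (n * tau non-integer keeps the LP solution off flat faces)
random_instance <- function(seed, n_max = 40L, p_max = 4L) {
  set.seed(seed)
  repeat {
    n <- sample(15:min(39L, n_max), 1L)
    if (n %% 2L == 1L && (n * 9L) %% 10L != 0L) break
  }
  p <- sample(seq_len(p_max), 1L)
  tau <- sample(c(0.5, 0.9), 1L)
  X <- cbind(intercept = 1, matrix(rnorm(n * (p - 1L)), n))
  colnames(X) <- c("intercept", if (p > 1L) paste0("x", seq_len(p - 1L)))
  y <- rnorm(n, drop(X %*% runif(p, -2, 2)), 1)
  list(X = X, y = y, tau = tau)
}

# small complete daily series with deterministic structure, for feature and
# evaluation unit tests that do not need the full generator
toy_series <- function(n = 60L, seed = 1L, start = as.Date("1987-01-01")) {
  set.seed(seed)
  daily_series(data.frame(
    date = start + 0:(n - 1L),
    deaths = rpois(n, 14),
    tmean = 55 + 20 * cos(2 * pi * (0:(n - 1L) - 197) / 365.25) + rnorm(n),
    dptp = 45 + rnorm(n),
    o3 = 25 + rnorm(n),
    so2 = 15 + rnorm(n),
    no2 = 35 + rnorm(n),
    co = 1.5 + rnorm(n, 0, 0.1)))
}
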