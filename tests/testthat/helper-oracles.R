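# Independent oracles used across the test suite.

# Roots of the 2nd/3rd derivatives of W(t) = w_max/(1 + a exp(-k t)),
# obtained by symbolic differentiation (stats::D) plus sign-scan and uniroot.
# Independent of the closed-form expressions in growth_eigenvalues().
deriv_roots_oracle <- function(w_max, a, k, tol = 1e-10) {
  expr <- quote(w_max / (1 + a * exp(-k * t)))
  d2 <- D(D(expr, "t"), "t")
  d3 <- D(D(D(expr, "t"), "t"), "t")
  f <- function(d) function(t) {
    eval(d, list(w_max = w_max, a = a, k = k, t = t))
  }
  span <- 60 / k
  grid <- seq(-span, 4 * span, length.out = 4001L)
  find_roots <- function(fn) {
    v <- fn(grid)
    idx <- which(v[-1L] * v[-length(v)] < 0)
    vapply(idx, function(i) {
      uniroot(fn, c(grid[i], grid[i + 1L]), tol = tol)$root
    }, numeric(1))
  }
  r2 <- find_roots(f(d2))
  r3 <- find_roots(f(d3))
  stopifnot(length(r2) == 1L, length(r3) == 2L)
  list(tm = r2, t1 = min(r3), t2 = max(r3))
}

# Random valid logistic parameter triples (inflection spread widely).
random_triples <- function(n) {
  tibble::tibble(
    w_max = runif(n, 0.5, 60),
    a = exp(runif(n, -1, 20)),
    k = runif(n, 0.05, 0.15)
  )
}

# Closed-form simple linear regression via the normal equations.
ols_oracle <- function(x, y, intercept = TRUE) {
  if (intercept) {
    X <- cbind(1, x)
    b <- solve(t(X) %*% X, t(X) %*% y)
    list(intercept = b[1L], slope = b[2L])
  } else {
    list(intercept = NA_real_, slope = sum(x * y) / sum(x * x))
  }
}

# Constant-temperature weather helper.
flat_weather <- function(t_mean, start = as.Date("2020-01-01")) {
  n <- length(t_mean)
  tibble::tibble(date = start + seq_len(n) - 1L,
                 t_min = t_mean - 2, t_mean = t_mean, t_max = t_mean + 2,
                 precipitation = 0)
}
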