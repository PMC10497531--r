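# Small populations used across test files. All are deterministic.

# Three scales of 3 items, moderate saturation gradient. Three items per
# specific factor keep every block identified (a 2-item specific factor is
# under-identified in a bifactor model).
tiny_population <- function() {
  population_model(list(
    scale_spec("alpha", c(0.70, 0.65, 0.60), c(0.30, 0.32, 0.34),
               c(-1.8, -0.6, 0.6, 1.8)),
    scale_spec("beta", c(0.50, 0.48, 0.46), c(0.45, 0.47, 0.49),
               c(-1.5, -0.5, 0.5, 1.5)),
    scale_spec("gamma", c(0.30, 0.28, 0.32), c(0.60, 0.62, 0.58),
               c(-1.2, -0.4, 0.6, 1.6))
  ))
}

# Six scales of 3 items each, for combinatorial pipeline checks.
six_scale_population <- function() {
  population_model(lapply(1:6, function(t) {
    lg <- 0.35 + 0.05 * t
    scale_spec(paste0("t", t), rep(lg, 3) + c(0, 0.03, -0.03),
               rep(0.45, 3) - 0.02 * t, c(-1.8, -0.6, 0.6, 1.8))
  }))
}

# A single-scale model whose items load only on the general factor.
general_only_population <- function(loading = 0.6, n_items = 2L) {
  population_model(list(
    scale_spec("only", rep(loading, n_items), rep(0, n_items),
               c(-1.8, -0.6, 0.6, 1.8))
  ))
}

# Random positive-definite covariance matrix (for discrepancy oracles).
random_pd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(p) * 0.5
}

# Brute-force ML discrepancy, deliberately using a different code path
# (base det/solve) than the package implementation (Cholesky).
fml_bruteforce <- function(S, Sigma) {
  p <- nrow(S)
  as.numeric(
    determinant(Sigma, logarithm = TRUE)$modulus +
      sum(diag(solve(Sigma) %*% S)) -
      determinant(S, logarithm = TRUE)$modulus - p
  )
}

# Central finite-difference gradient of the discrepancy in the free
# parameters.
fml_fd_gradient <- function(par, spec, S, h = 1e-5) {
  vapply(seq_along(par), function(i) {
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (fml(S, implied_sigma(pp, spec)) - fml(S, implied_sigma(pm, spec))) / (2 * h)
  }, 0)
}

# A feasible free-parameter point near plausible bifactor values.
random_parameter_point <- function(spec, seed, sd = 0.15) {
  set.seed(seed)
  p <- spec$p; T_ <- spec$n_scales
  c(
    rnorm(p - 1L, 1, sd),                 # general loadings (marker metric)
    rnorm(p - T_, 1, sd),                 # specific loadings
    runif(p, 0.3, 0.8),                   # residual variances
    runif(T_ + 1L, 0.2, 0.6)              # factor variances
  )
}
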