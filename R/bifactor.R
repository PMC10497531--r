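#' Biased (divide-by-N) sample covariance matrix
#'
#' Covariance of the item columns with denominator `N`, the normal-theory ML
#' convention. The result is exactly symmetric.
#'
#' @param X Numeric `N x p` response matrix (`N >= 2`).
#' @return `p x p` covariance matrix carrying the column names of `X`.
#' @export
sample_covariance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / nrow(X)
  (S + t(S)) / 2
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' `F_ML = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p`, the discrepancy
#' between a sample covariance `S` and a model-implied covariance `Sigma`.
#' Nonnegative; zero iff `S == Sigma`. Tiny negative round-off is clamped to
#' zero. A `Sigma` that is not positive definite yields `Inf` (the penalty
#' sentinel the optimizer relies on); a singular `S` is a validation error
#' because the discrepancy is then undefined for every `Sigma`.
#'
#' @param S Sample covariance (symmetric positive definite).
#' @param Sigma Model-implied covariance (symmetric).
#' @return Nonnegative scalar, or `Inf` for non-PD `Sigma`.
#' @export
fml <- function(S, Sigma) {
  p <- nrow(S)
  stopifnot(is.matrix(S), is.matrix(Sigma),
            nrow(Sigma) == p, ncol(S) == p, ncol(Sigma) == p)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS)) stop("sample covariance is singular: log-determinant undefined")
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cSig)) return(Inf)
  ldet_S <- 2 * sum(log(diag(cS)))
  ldet_Sig <- 2 * sum(log(diag(cSig)))
  tr_SSi <- sum(diag(chol2inv(cSig) %*% S))
  max(0, ldet_Sig + tr_SSi - ldet_S - p)
}

#' Analytic gradient of the ML discrepancy in the free parameters
#'
#' Gradient of `fml(S, implied_sigma(par, spec))` with respect to the free
#' parameter vector, using `dF = tr(G dSigma)` with
#' `G = Sigma^-1 (Sigma - S) Sigma^-1`.
#'
#' @param par Free-parameter vector.
#' @param spec A [model_spec()].
#' @param S Sample covariance matrix.
#' @return Numeric vector of length `spec$n_free`.
#' @export
fml_gradient <- function(par, spec, S) {
  u <- unpack_parameters(par, spec)
  Sigma <- u$lambda %*% (u$psi * t(u$lambda))
  diag(Sigma) <- diag(Sigma) + u$theta
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cSig)) return(rep(NA_real_, length(par)))
  Sinv <- chol2inv(cSig)
  G <- Sinv %*% (Sigma - S) %*% Sinv
  G <- (G + t(G)) / 2
  dLambda <- 2 * (G %*% u$lambda) * rep(u$psi, each = spec$p)
  dpsi <- diag(t(u$lambda) %*% G %*% u$lambda)
  dtheta <- diag(G)
  ls_grad <- dLambda[cbind(seq_len(spec$p), spec$scale_idx + 1L)]
  c(dLambda[spec$free_lg, 1L], ls_grad[spec$free_ls], dtheta, dpsi)
}

#' Engine options for bifactor estimation
#'
#' @param max_restarts Maximum jittered restarts after a failed optimization.
#' @param maxit L-BFGS-B iteration cap per attempt.
#' @param factr L-BFGS-B relative function-value tolerance factor.
#' @param pgtol L-BFGS-B projected-gradient tolerance.
#' @param grad_tol Gradient-norm threshold (max absolute element of the
#'   analytic gradient at the solution) below which a fit counts as
#'   converged even if the optimizer stopped on its iteration cap.
#' @param seed Seed for the (lognormal, sd 0.2) start-value jitter.
#' @param n_convention `"N"` (default, matching the biased sample covariance)
#'   or `"N-1"`: multiplier turning the minimized discrepancy into chi-square.
#' @param variance_floor Lower bound on residual/factor variances, as a
#'   fraction of the relevant item variance (guards Heywood cases).
#' @return A list of class `engine_options`.
#' @export
engine_options <- function(max_restarts = 5L, maxit = 5000L, factr = 1e6,
                           pgtol = 0, grad_tol = 1e-3, seed = 1L,
                           n_convention = c("N", "N-1"),
                           variance_floor = 1e-4) {
  structure(
    list(
      max_restarts = as.integer(max_restarts), maxit = as.integer(maxit),
      factr = factr, pgtol = pgtol, grad_tol = grad_tol,
      seed = as.integer(seed),
      n_convention = match.arg(n_convention),
      variance_floor = variance_floor
    ),
    class = "engine_options"
  )
}

# Start values: general loadings from a one-component principal-axis pass on
# the correlation matrix (rescaled to the marker metric), flat 0.3 specific
# loadings, half the item variance as residual variance, marker-item
# communality for the factor variances.
starting_values <- function(S, spec) {
  p <- spec$p
  sds <- sqrt(diag(S))
  R <- stats::cov2cor(S)
  e <- eigen(R, symmetric = TRUE)
  l1 <- e$vectors[, 1L] * sqrt(max(e$values[1L], 1e-8))
  if (sum(l1) < 0) l1 <- -l1
  lg_cov <- pmax(l1, 0.1) * sds      # covariance-metric general loadings
  marker_g <- lg_cov[1L]
  lg <- lg_cov / marker_g
  psi_g <- marker_g^2
  smc <- 1 - 1 / pmax(diag(solve(R)), 1.0001)
  psi_s <- numeric(spec$n_scales)
  for (t in seq_len(spec$n_scales)) {
    m <- which(spec$scale_idx == t & spec$first_of_scale)
    psi_s[t] <- max(smc[m] * S[m, m] - lg_cov[m]^2, 0.05 * S[m, m])
  }
  theta <- 0.5 * diag(S)
  ls <- rep(0.3, p)
  c(lg[spec$free_lg], ls[spec$free_ls], theta, c(psi_g, psi_s))
}

#' Fit the orthogonal bifactor model by maximum likelihood
#'
#' Minimizes the ML discrepancy [fml()] over the free parameters of the
#' marker-identified bifactor model with a quasi-Newton (L-BFGS-B) optimizer
#' and the analytic gradient [fml_gradient()]. Residual and factor variances
#' are bounded below at a small fraction of the item variance so the implied
#' covariance stays invertible (Heywood guard; hitting the bound is flagged).
#' On failure the optimization restarts from multiplicatively jittered start
#' values (up to `options$max_restarts` times, seeded); a fit that never
#' converges is still returned with `converged = FALSE`.
#'
#' @param S Sample covariance matrix (item IDs as dimnames, optional).
#' @param n Sample size behind `S`.
#' @param spec A [model_spec()].
#' @param options An [engine_options()] list.
#' @return An object of class `bifactor_fit`: free parameters (`par`),
#'   unpacked `lambda`/`theta`/`psi`, `fml`, `chi_square`, `df`, `p_value`,
#'   `rmsea` (+ `rmsea_ci90`), `srmr`, `converged`, `n_iterations`,
#'   `n_restarts`, `heywood`, `n`, `spec`, and the implied `sigma_hat`.
#' @export
fit_bifactor <- function(S, n, spec, options = engine_options()) {
  stopifnot(inherits(spec, "model_spec"))
  S <- as.matrix(S)
  if (nrow(S) != spec$p) {
    stop(sprintf("covariance is %d x %d but the spec has %d items",
                 nrow(S), ncol(S), spec$p))
  }
  if (max(abs(S - t(S))) > 1e-8) stop("covariance matrix is not symmetric")
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) stop("covariance matrix is not positive semidefinite")
  if (ev_min < 1e-10) warning("covariance matrix is (near-)singular")
  if (n < spec$p) warning("sample size below number of items; fit may be unstable")

  floor_ <- options$variance_floor
  lower <- c(
    rep(-Inf, (spec$p - 1L) + (spec$p - spec$n_scales)),
    floor_ * diag(S),
    rep(floor_ * diag(S)[1L], spec$n_scales + 1L)
  )
  objective <- function(par) fml(S, implied_sigma(par, spec))
  gradient <- function(par) fml_gradient(par, spec, S)
  at_bound <- function(par) {
    u <- unpack_parameters(par, spec)
    any(u$theta <= floor_ * diag(S) + 1e-12) ||
      any(u$psi <= floor_ * diag(S)[1L] + 1e-12)
  }

  start0 <- starting_values(S, spec)
  best <- NULL
  n_restarts_used <- 0L
  for (attempt in 0:options$max_restarts) {
    start <- start0
    if (attempt > 0L) {
      jit_seed <- (options$seed + 7919L * attempt) %% .Machine$integer.max
      old <- globalenv()$.Random.seed
      set.seed(jit_seed)
      start <- start0 * exp(stats::rnorm(length(start0), 0, 0.2))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      n_restarts_used <- attempt
    }
    start <- pmax(start, lower)
    opt <- tryCatch(
      stats::optim(
        start, objective, gradient, method = "L-BFGS-B", lower = lower,
        control = list(maxit = options$maxit, factr = options$factr,
                       pgtol = options$pgtol)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    g <- fml_gradient(opt$par, spec, S)
    # converged if the optimizer stopped regularly or the stationarity
    # condition holds at the returned point (flat-ridge fits that exhaust
    # maxit with a vanishing gradient are solutions, not failures)
    ok <- opt$convergence == 0L ||
      (all(is.finite(g)) && max(abs(g)) <= options$grad_tol)
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$ok <- ok
    }
    # a variance pinned at its lower bound is often a spurious boundary
    # optimum: jitter and retry, keeping the best value seen
    if (ok && !at_bound(opt$par)) break
  }
  if (is.null(best)) {
    stop("optimization failed on every attempt (non-finite objective)")
  }

  u <- unpack_parameters(best$par, spec)
  sigma_hat <- implied_sigma(best$par, spec)
  dimnames(sigma_hat) <- dimnames(S)
  df <- degrees_of_freedom(spec)
  n_mult <- if (options$n_convention == "N") n else n - 1L
  chi_square <- n_mult * best$value
  idx <- fit_indices(chi_square, df, n_mult, S, sigma_hat)
  heywood <- any(u$theta <= lower[spec$offsets[["theta"]] + seq_len(spec$p)] + 1e-12) ||
    any(u$psi <= floor_ * diag(S)[1L] + 1e-12)
  structure(
    list(
      par = best$par, lambda = u$lambda, theta = u$theta, psi = u$psi,
      fml = best$value, chi_square = chi_square, df = df,
      p_value = idx$p_value, rmsea = idx$rmsea, rmsea_ci90 = idx$rmsea_ci90,
      srmr = idx$srmr, converged = isTRUE(best$ok),
      n_iterations = unname(best$counts[1L]), n_restarts = n_restarts_used,
      heywood = heywood, n = n, spec = spec, sigma_hat = sigma_hat,
      options = options
    ),
    class = "bifactor_fit"
  )
}

#' @export
print.bifactor_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Bifactor fit: %d items, %d scales\n",
           "  chi-square(%d) = %.1f, p %s\n",
           "  RMSEA = %.3f, 90%% CI [%.3f; %.3f]; SRMR = %.3f\n",
           "  converged: %s (%d iterations, %d restarts)%s\n"),
    x$spec$p, x$spec$n_scales, x$df, x$chi_square,
    if (x$p_value < .001) "< .001" else sprintf("= %.3f", x$p_value),
    x$rmsea, x$rmsea_ci90[1L], x$rmsea_ci90[2L], x$srmr,
    x$converged, x$n_iterations, x$n_restarts,
    if (x$heywood) "  [variance at lower bound]" else ""
  ))
  invisible(x)
}

#' Global fit indices of a covariance-structure model
#'
#' RMSEA with its 90 percent confidence interval (from the noncentral
#' chi-square), SRMR on the correlation metric (unique elements including the
#' diagonal), and the chi-square p-value.
#'
#' @param chi_square Observed chi-square statistic.
#' @param df Model degrees of freedom (> 0).
#' @param n Sample-size multiplier used for the chi-square.
#' @param S Sample covariance matrix.
#' @param sigma_hat Model-implied covariance matrix.
#' @return List with `rmsea`, `rmsea_ci90` (length-2 vector), `srmr`,
#'   `p_value`.
#' @export
fit_indices <- function(chi_square, df, n, S, sigma_hat) {
  if (df <= 0) stop("RMSEA undefined for df = 0")
  rmsea <- sqrt(max(0, (chi_square - df) / (df * n)))
  ci <- c(
    rmsea_ncp(chi_square, df, prob = 0.95),
    rmsea_ncp(chi_square, df, prob = 0.05)
  )
  rmsea_ci90 <- sqrt(ci / (df * n))
  rS <- stats::cov2cor(S)
  rSig <- stats::cov2cor(sigma_hat)
  resid <- (rS - rSig)[lower.tri(rS, diag = TRUE)]
  srmr <- sqrt(mean(resid^2))
  p_value <- stats::pchisq(chi_square, df, lower.tail = FALSE)
  list(rmsea = rmsea, rmsea_ci90 = rmsea_ci90, srmr = srmr, p_value = p_value)
}

# Noncentrality parameter lambda solving P(chisq_df(lambda) <= x) = prob;
# 0 when no nonnegative solution exists.
rmsea_ncp <- function(x, df, prob) {
  f <- function(ncp) stats::pchisq(x, df, ncp = ncp) - prob
  if (f(0) <= 0) return(0)
  hi <- max(x, df, 1)
  while (f(hi) > 0 && hi < 1e10) hi <- hi * 2
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}
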