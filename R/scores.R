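#' Regression-method scores for the general (D) factor
#'
#' Thurstone regression scores `Fhat = Psi Lambda' Sigma^-1 (x - xbar)`,
#' computed from the fitted loadings, factor variances and model-implied
#' covariance; the general-factor row is returned. Scores are sign-aligned:
#' if the sum of estimated general loadings is negative all general loadings
#' (and hence the scores) are flipped, so that consistently oriented models
#' yield positively correlated score vectors.
#'
#' @param X The `N x p` response matrix the model was fitted to (columns in
#'   the order of the fit's scale map).
#' @param fit A [fit_bifactor()] result.
#' @return Numeric vector of class-less D scores, length `N`, with attribute
#'   `"sign_flipped"`.
#' @export
score_general_factor <- function(X, fit) {
  stopifnot(inherits(fit, "bifactor_fit"))
  X <- as.matrix(X)
  if (ncol(X) != fit$spec$p) {
    stop(sprintf("X has %d columns but the fit expects %d", ncol(X), fit$spec$p))
  }
  if (!is.null(colnames(X)) && !is.null(fit$spec$map$item_ids) &&
      !identical(colnames(X), fit$spec$map$item_ids)) {
    stop("column names of X do not match the fitted scale map")
  }
  if (!fit$converged) {
    warning("scoring a fit that did not converge")
  }
  lg <- fit$lambda[, 1L]
  if (all(lg == 0) || fit$psi[1L] * sum(lg^2) < 1e-12) {
    stop("general factor carries no information (all general loadings zero)")
  }
  flip <- sum(lg) < 0
  sgn <- if (flip) -1 else 1
  cSig <- tryCatch(chol(fit$sigma_hat), error = function(e) {
    stop("implied covariance of the fit is singular; cannot score")
  })
  Sinv <- chol2inv(cSig)
  w <- fit$psi[1L] * as.vector(Sinv %*% lg)   # general row of Psi Lambda' Sigma^-1
  Xc <- sweep(X, 2L, colMeans(X))
  scores <- sgn * as.vector(Xc %*% w)
  attr(scores, "sign_flipped") <- flip
  scores
}

#' Explained common variance (D saturation) per trait scale
#'
#' For each scale `t`, `ECV_t = sum(l_g^2) / (sum(l_g^2) + sum(l_s^2))` over
#' the scale's items, where `l` are completely standardized loadings
#' (`loading * sqrt(factor variance) / item SD` on the model-implied metric).
#' The ECV is the proportion of a scale's common variance captured by the
#' general factor.
#'
#' @param fit A [fit_bifactor()] result.
#' @return Named numeric vector of ECV values in `[0, 1]`; `NA` (with a
#'   warning) for a scale with zero common variance.
#' @export
ecv <- function(fit) {
  stopifnot(inherits(fit, "bifactor_fit"))
  spec <- fit$spec
  sd_item <- sqrt(diag(fit$sigma_hat))
  std_g <- fit$lambda[, 1L] * sqrt(fit$psi[1L]) / sd_item
  ls <- fit$lambda[cbind(seq_len(spec$p), spec$scale_idx + 1L)]
  std_s <- ls * sqrt(fit$psi[spec$scale_idx + 1L]) / sd_item
  out <- vapply(seq_len(spec$n_scales), function(t) {
    i <- spec$scale_idx == t
    common <- sum(std_g[i]^2) + sum(std_s[i]^2)
    if (common < 1e-12) return(NA_real_)
    sum(std_g[i]^2) / common
  }, 0)
  names(out) <- spec$map$scales
  if (anyNA(out)) {
    warning("scale(s) with zero common variance: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Completely standardized loadings of a fit
#'
#' Rescales the marker-metric estimates to the metric in which items and
#' factors have unit variance: `loading * sqrt(factor variance) / item SD`.
#'
#' @param fit A [fit_bifactor()] result.
#' @return List with vectors `general` and `specific`, one entry per item.
#' @export
standardized_loadings <- function(fit) {
  stopifnot(inherits(fit, "bifactor_fit"))
  spec <- fit$spec
  sd_item <- sqrt(diag(fit$sigma_hat))
  ls <- fit$lambda[cbind(seq_len(spec$p), spec$scale_idx + 1L)]
  list(
    general = fit$lambda[, 1L] * sqrt(fit$psi[1L]) / sd_item,
    specific = ls * sqrt(fit$psi[spec$scale_idx + 1L]) / sd_item
  )
}

#' Pearson correlation between two score vectors
#'
#' Both inputs are expected to be sign-aligned upstream (see
#' [score_general_factor()]), so the signed correlation is reported — no
#' absolute value is taken.
#'
#' @param a,b Numeric vectors of equal length (>= 3), nonzero variance.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
correlate_scores <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance score vector")
  }
  stats::cor(as.numeric(a), as.numeric(b))
}
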