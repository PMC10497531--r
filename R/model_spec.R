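#' Construct a scale map
#'
#' A scale map is the ordered assignment of item columns to named trait
#' scales; it defines the bifactor loading pattern (every item loads on the
#' general factor and on its own scale's specific factor) and the marker
#' items used for identification (the first item overall for the general
#' factor, the first item of each scale for the specific factors).
#'
#' @param item_ids Character vector of unique item IDs, in column order.
#' @param scale_names Character vector, same length: the scale of each item.
#' @return An object of class `scale_map`.
#' @export
scale_map <- function(item_ids, scale_names) {
  item_ids <- as.character(item_ids)
  scale_names <- as.character(scale_names)
  if (length(item_ids) != length(scale_names)) {
    stop("item_ids and scale_names must have the same length")
  }
  if (anyDuplicated(item_ids)) {
    stop("duplicate item_id: ", item_ids[anyDuplicated(item_ids)])
  }
  scales <- unique(scale_names)
  counts <- table(factor(scale_names, levels = scales))
  if (any(counts < 2L)) {
    bad <- names(counts)[counts < 2L]
    stop("every scale needs at least 2 items; offending scale(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(
      item_ids = item_ids,
      scale_of = scale_names,
      scales = scales,
      n_items = length(item_ids),
      n_scales = length(scales)
    ),
    class = "scale_map"
  )
}

#' Scale map of a population model
#' @param model A [population_model()].
#' @return A [scale_map()].
#' @export
as_scale_map <- function(model) {
  stopifnot(inherits(model, "population_model"))
  scale_map(model$item_ids, model$scale_of)
}

#' Restrict a scale map to a subset of scales
#' @param map A [scale_map()].
#' @param scales Character vector of scale names to keep (order follows the
#'   original map).
#' @return A [scale_map()] over the kept items.
#' @export
subset_scale_map <- function(map, scales) {
  stopifnot(inherits(map, "scale_map"))
  missing <- setdiff(scales, map$scales)
  if (length(missing)) {
    stop("unknown scale(s): ", paste(missing, collapse = ", "))
  }
  keep <- map$scale_of %in% scales
  scale_map(map$item_ids[keep], map$scale_of[keep])
}

#' Bifactor model specification with marker identification
#'
#' Fixes the estimation contract: every item loads on the general factor and
#' on its own specific factor; all factors are mutually orthogonal (factor
#' covariances fixed to 0) with free variances; each factor's metric is set
#' by fixing one marker loading to 1 (first item overall for the general
#' factor, first item of each scale for its specific factor); all residual
#' variances are free; no mean structure. Free parameters therefore number
#' `(p - 1) + (p - T) + p + (T + 1)` for `p` items over `T` scales.
#'
#' @param map A [scale_map()].
#' @return An object of class `model_spec` carrying the map, the factor
#'   pattern indices and the free-parameter layout.
#' @export
model_spec <- function(map) {
  stopifnot(inherits(map, "scale_map"))
  p <- map$n_items
  T_ <- map$n_scales
  scale_idx <- match(map$scale_of, map$scales)
  first_of_scale <- !duplicated(scale_idx)
  # free-parameter layout: [general loadings | specific loadings | residual
  # variances | factor variances], markers excluded
  free_lg <- which(seq_len(p) != 1L)           # p - 1
  free_ls <- which(!first_of_scale)            # p - T
  n_free <- (p - 1L) + (p - T_) + p + (T_ + 1L)
  structure(
    list(
      map = map, p = p, n_scales = T_,
      scale_idx = scale_idx,
      first_of_scale = first_of_scale,
      free_lg = free_lg, free_ls = free_ls,
      n_free = n_free,
      offsets = c(
        lg = 0L, ls = p - 1L, theta = (p - 1L) + (p - T_),
        psi = (p - 1L) + (p - T_) + p
      )
    ),
    class = "model_spec"
  )
}

#' Degrees of freedom of the bifactor model
#'
#' Number of non-redundant covariance moments, `p(p+1)/2`, minus the number
#' of free parameters of the marker-identified orthogonal bifactor model.
#'
#' @param spec A [model_spec()].
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  as.integer(spec$p * (spec$p + 1L) / 2L - spec$n_free)
}

# Unpack a free-parameter vector into Lambda (p x (T+1), general factor
# first), theta (residual variances) and psi (factor variances).
unpack_parameters <- function(par, spec) {
  p <- spec$p; T_ <- spec$n_scales; off <- spec$offsets
  lg <- numeric(p); lg[1L] <- 1
  lg[spec$free_lg] <- par[seq_len(p - 1L)]
  ls <- numeric(p)
  ls[spec$first_of_scale] <- 1
  ls[spec$free_ls] <- par[off[["ls"]] + seq_len(p - T_)]
  theta <- par[off[["theta"]] + seq_len(p)]
  psi <- par[off[["psi"]] + seq_len(T_ + 1L)]
  L <- matrix(0, p, T_ + 1L)
  L[, 1L] <- lg
  L[cbind(seq_len(p), spec$scale_idx + 1L)] <- ls
  list(lambda = L, theta = theta, psi = psi)
}

# Inverse of unpack_parameters.
pack_parameters <- function(lambda, theta, psi, spec) {
  ls <- lambda[cbind(seq_len(spec$p), spec$scale_idx + 1L)]
  c(lambda[spec$free_lg, 1L], ls[spec$free_ls], theta, psi)
}

#' Model-implied covariance matrix
#'
#' `Sigma(theta) = Lambda Psi Lambda' + Theta` with `Lambda` in the bifactor
#' pattern (zeros outside the general column and the item's own scale
#' column), `Psi` diagonal (orthogonality) and `Theta` diagonal.
#'
#' @param par Numeric free-parameter vector (see [model_spec()] layout).
#' @param spec A [model_spec()].
#' @return Symmetric `p x p` matrix.
#' @export
implied_sigma <- function(par, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(par) != spec$n_free) {
    stop(sprintf("parameter vector has length %d, expected %d",
                 length(par), spec$n_free))
  }
  u <- unpack_parameters(par, spec)
  S <- u$lambda %*% (u$psi * t(u$lambda))
  diag(S) <- diag(S) + u$theta
  (S + t(S)) / 2
}
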