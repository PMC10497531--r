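#' Define a trait scale for the population model
#'
#' A scale is a block of Likert items that load on the general (D) factor and
#' on one scale-specific factor. Loadings are on the completely standardized
#' metric: each latent item response has unit variance, so the residual
#' variance of item i is `1 - general^2 - specific^2`, which must be positive.
#'
#' @param name Short scale label (used as prefix for item IDs).
#' @param general_loadings Numeric vector, one loading per item, each in
#'   (-1, 1): the item's loading on the general factor.
#' @param specific_loadings Numeric vector of the same length, each in
#'   (-1, 1): the item's loading on the scale-specific factor.
#' @param thresholds Either a length-4 numeric vector of strictly increasing
#'   cut-points shared by all items of the scale, or an `n_items x 4` matrix
#'   with one row of cut-points per item. Cut-points map the latent standard
#'   normal item response to the observed categories 1..5.
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(name, general_loadings, specific_loadings, thresholds) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lg <- as.numeric(general_loadings)
  ls <- as.numeric(specific_loadings)
  if (length(lg) != length(ls)) {
    stop("general and specific loadings must have the same length")
  }
  n_items <- length(lg)
  if (n_items < 1L) stop("a scale needs at least one item")
  if (any(!is.finite(lg)) || any(!is.finite(ls))) {
    stop("loadings must be finite")
  }
  if (any(abs(lg) >= 1) || any(abs(ls) >= 1)) {
    stop("standardized loadings must lie in (-1, 1)")
  }
  resid <- 1 - lg^2 - ls^2
  if (any(resid <= 0)) {
    stop(sprintf(
      "scale '%s': general^2 + specific^2 must be < 1 for every item", name
    ))
  }
  thr <- thresholds
  if (is.null(dim(thr))) {
    if (length(thr) != 4L) stop("thresholds must have 4 cut-points")
    thr <- matrix(rep(as.numeric(thr), each = n_items), nrow = n_items)
  } else {
    thr <- as.matrix(thr)
    if (!identical(dim(thr), c(n_items, 4L)) &&
        !identical(dim(thr), as.integer(c(n_items, 4)))) {
      stop("threshold matrix must be n_items x 4")
    }
  }
  if (any(apply(thr, 1L, function(z) any(diff(z) <= 0)))) {
    stop(sprintf("scale '%s': thresholds must be strictly increasing", name))
  }
  structure(
    list(
      name = name, n_items = n_items,
      general_loadings = lg, specific_loadings = ls,
      residual_variances = resid, thresholds = thr
    ),
    class = "scale_spec"
  )
}

#' Assemble a bifactor population model from scale specifications
#'
#' The population has one general factor plus one specific factor per scale,
#' all mutually orthogonal with unit variance. Items are ordered scale by
#' scale; item IDs are `"<scale>.<item#>"`.
#'
#' @param scales List of [scale_spec()] objects (order defines item order).
#' @return An object of class `population_model` with elements `scales`,
#'   `n_scales`, `n_items`, `item_ids`, and `scale_of` (scale name per item).
#' @export
population_model <- function(scales) {
  if (!length(scales) || !all(vapply(scales, inherits, TRUE, "scale_spec"))) {
    stop("scales must be a non-empty list of scale_spec objects")
  }
  nms <- vapply(scales, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("scale names must be unique")
  counts <- vapply(scales, `[[`, 0L, "n_items")
  item_ids <- unlist(lapply(scales, function(s) {
    paste(s$name, seq_len(s$n_items), sep = ".")
  }), use.names = FALSE)
  structure(
    list(
      scales = scales,
      n_scales = length(scales),
      n_items = sum(counts),
      item_counts = stats::setNames(counts, nms),
      item_ids = item_ids,
      scale_of = rep(nms, counts)
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "Bifactor population model: %d scales, %d items, %d factors (1 general + %d specific)\n",
    x$n_scales, x$n_items, x$n_scales + 1L, x$n_scales
  ))
  invisible(x)
}

# Expected observed mean of a 5-category item whose latent response is
# standard normal discretized at cut-points `thr`.
likert_mean_from_thresholds <- function(thr) {
  1 + sum(stats::pnorm(thr, lower.tail = FALSE))
}

# Shift of the symmetric base cut-points that makes the expected observed
# item mean equal `target`. Larger shifts push the distribution toward the
# scale floor (category 1).
threshold_shift_for_mean <- function(target, base = c(-1.8, -0.6, 0.6, 1.8)) {
  stats::uniroot(
    function(s) likert_mean_from_thresholds(base + s) - target,
    interval = c(-4, 4), tol = 1e-10
  )$root
}

#' Default 16-scale aversive-trait population
#'
#' Builds the population model the simulator uses to emulate a battery of 16
#' aversive trait scales (151 items in all) measured on 5-point Likert items:
#' one general aversive factor (D) plus one orthogonal specific factor per
#' scale. Scales differ in D saturation: some (e.g. the Frustralia-,
#' Machiavellianism- and Crudelia-like scales) are largely absorbed by the
#' general factor, while others (the SD3-Narcissism-, Entitlement- and
#' Greed-like scales) are dominated by specific variance. The Sadism-like
#' scale carries right-shifted thresholds producing a floor effect (expected
#' observed item mean near 1.44, against roughly 1.8-2.9 for the others).
#'
#' Loading values are stylized, not estimates from any data set: within each
#' scale they are spread evenly over a band chosen for the scale's intended
#' saturation class.
#'
#' @return A [population_model()] with 16 scales and 151 items.
#' @export
make_default_population <- function() {
  # name, item count, general-loading band, specific-loading band, target mean
  cfg <- list(
    list("crudelia",         13L, c(0.62, 0.75), c(0.20, 0.33), 2.05),
    list("egoism",           12L, c(0.48, 0.60), c(0.36, 0.48), 2.55),
    list("entitlement",       9L, c(0.27, 0.38), c(0.57, 0.68), 2.75),
    list("exploitativeness",  6L, c(0.50, 0.62), c(0.34, 0.46), 2.10),
    list("frustralia",       14L, c(0.64, 0.75), c(0.20, 0.32), 2.60),
    list("greed",             7L, c(0.26, 0.39), c(0.56, 0.69), 2.90),
    list("machiavellianism",  9L, c(0.62, 0.74), c(0.21, 0.34), 2.70),
    list("moral_diseng",      8L, c(0.46, 0.58), c(0.38, 0.50), 2.20),
    list("narcissism_sd3",    9L, c(0.25, 0.38), c(0.58, 0.70), 2.85),
    list("narcissism_narq",   6L, c(0.42, 0.54), c(0.44, 0.56), 2.45),
    list("selfishness",       8L, c(0.55, 0.67), c(0.28, 0.40), 1.95),
    list("psychopathy",       9L, c(0.56, 0.68), c(0.26, 0.38), 2.30),
    list("sadism",           10L, c(0.55, 0.67), c(0.28, 0.40), 1.44),
    list("self_centered",     4L, c(0.54, 0.64), c(0.30, 0.40), 2.15),
    list("spitefulness",     17L, c(0.50, 0.62), c(0.33, 0.45), 2.00),
    list("vengefulness",     10L, c(0.48, 0.60), c(0.35, 0.47), 2.40)
  )
  scales <- lapply(cfg, function(z) {
    n <- z[[2]]
    lg <- seq(z[[3]][1], z[[3]][2], length.out = n)
    ls <- seq(z[[4]][2], z[[4]][1], length.out = n)
    thr <- c(-1.8, -0.6, 0.6, 1.8) + threshold_shift_for_mean(z[[5]])
    scale_spec(z[[1]], lg, ls, thr)
  })
  population_model(scales)
}

#' Small planted-structure population for scaled-down pipeline studies
#'
#' An 8-scale, 4-items-per-scale population (32 items) with the same
#' qualitative structure as the default model but cheap enough for exhaustive
#' subset studies: one planted high-saturation trait (`highsat`, general
#' loadings ~0.72, weak specific loadings), one planted low-saturation trait
#' (`lowsat`, general loadings ~0.15, strong specific loadings), and six
#' intermediate traits. All thresholds are mildly right-shifted symmetric
#' cut-points except `floorish`, which emulates a floor-effect scale.
#'
#' @return A [population_model()] with 8 scales and 32 items.
#' @export
make_mini_population <- function() {
  cfg <- list(
    list("highsat",  c(0.68, 0.76), c(0.18, 0.26), 2.40),
    list("strong2",  c(0.60, 0.68), c(0.25, 0.33), 2.20),
    list("mid1",     c(0.50, 0.58), c(0.35, 0.43), 2.60),
    list("mid2",     c(0.46, 0.54), c(0.38, 0.46), 2.00),
    list("mid3",     c(0.42, 0.50), c(0.42, 0.50), 2.75),
    list("floorish", c(0.48, 0.56), c(0.34, 0.42), 1.45),
    list("weak2",    c(0.28, 0.36), c(0.55, 0.63), 2.85),
    list("lowsat",   c(0.12, 0.18), c(0.62, 0.70), 2.50)
  )
  scales <- lapply(cfg, function(z) {
    lg <- seq(z[[2]][1], z[[2]][2], length.out = 4L)
    ls <- seq(z[[3]][2], z[[3]][1], length.out = 4L)
    thr <- c(-1.8, -0.6, 0.6, 1.8) + threshold_shift_for_mean(z[[4]])
    scale_spec(z[[1]], lg, ls, thr)
  })
  population_model(scales)
}

#' Conventional named-set analogues for the mini population
#'
#' Subsets of [make_mini_population()] traits mirroring the roles of the
#' conventional aversive-trait sets: `triad_like` pairs two moderately-to-
#' well-saturated traits with the low-saturation narcissism-like trait
#' (Dark Triad analogue), `tetrad_like` adds the floor-effect sadism-like
#' trait (Dark Tetrad analogue), and `triad_swap` replaces the
#' low-saturation trait with a better-saturated variant (NARQ-style swap).
#'
#' @return Named list of character vectors of trait names.
#' @export
mini_named_sets <- function() {
  list(
    triad_like = c("strong2", "mid2", "lowsat"),
    tetrad_like = c("strong2", "mid2", "lowsat", "floorish"),
    triad_swap = c("strong2", "mid2", "mid3")
  )
}

#' Population-implied covariance matrix of the latent item responses
#'
#' Returns `Lambda %*% t(Lambda) + Theta` on the latent (pre-discretization)
#' metric, where `Lambda` stacks the general and specific loadings in the
#' bifactor pattern and `Theta` is the diagonal of residual variances. Because
#' loadings are standardized the diagonal is exactly 1.
#'
#' @param model A [population_model()].
#' @return A symmetric positive-definite `p x p` matrix with unit diagonal and
#'   dimnames equal to the item IDs.
#' @export
implied_covariance <- function(model) {
  stopifnot(inherits(model, "population_model"))
  L <- population_lambda(model)
  S <- tcrossprod(L)
  diag(S) <- 1
  dimnames(S) <- list(model$item_ids, model$item_ids)
  S
}

# p x (T+1) loading matrix of the population model, general factor first.
population_lambda <- function(model) {
  p <- model$n_items
  T_ <- model$n_scales
  L <- matrix(0, p, T_ + 1L)
  row <- 1L
  for (t in seq_len(T_)) {
    s <- model$scales[[t]]
    idx <- row:(row + s$n_items - 1L)
    L[idx, 1L] <- s$general_loadings
    L[idx, t + 1L] <- s$specific_loadings
    row <- row + s$n_items
  }
  L
}

#' True explained common variance per scale of a population model
#'
#' For each scale, the proportion of its common (factor-explained) variance
#' attributable to the general factor:
#' `sum(general^2) / (sum(general^2) + sum(specific^2))`.
#'
#' @param model A [population_model()].
#' @return Named numeric vector of ECV values in (0, 1].
#' @export
population_ecv <- function(model) {
  stopifnot(inherits(model, "population_model"))
  vapply(model$scales, function(s) {
    sum(s$general_loadings^2) /
      (sum(s$general_loadings^2) + sum(s$specific_loadings^2))
  }, 0, USE.NAMES = FALSE) |>
    stats::setNames(vapply(model$scales, `[[`, "", "name"))
}
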