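#' Simulate item responses from a bifactor population model
#'
#' Draws independent standard-normal factor scores (one general + one per
#' scale) for each respondent, forms latent item responses
#' `y* = lambda_g * F_D + lambda_s * F_t + e` with
#' `e ~ N(0, 1 - lambda_g^2 - lambda_s^2)`, and (optionally) discretizes each
#' item at its thresholds into the observed categories 1..5. The same
#' `(model, n, seed, likert)` always yields the same matrix.
#'
#' @param model A [population_model()].
#' @param n Number of respondents (>= 2).
#' @param seed Integer seed governing all randomness of the draw.
#' @param likert If `TRUE` (default), return integer categories 1..5;
#'   otherwise return the continuous latent responses.
#' @param keep_factor_scores If `TRUE`, attach the simulated factor-score
#'   matrix as attribute `"factor_scores"` (general factor in column 1) —
#'   useful for validating score recovery.
#' @return An `n x p` matrix (integer if `likert`) with item IDs as column
#'   names. In Likert mode every column is guaranteed non-constant: if a
#'   column is degenerate at the drawn sample the draw is repeated with a
#'   derived seed (at most 5 times) before erroring.
#' @export
generate_responses <- function(model, n, seed, likert = TRUE,
                               keep_factor_scores = FALSE) {
  stopifnot(inherits(model, "population_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("n must be a single number >= 2")
  }
  n <- as.integer(n)
  seed <- as.integer(seed)
  L <- population_lambda(model)
  resid_sd <- sqrt(1 - rowSums(L^2))
  if (any(!is.finite(resid_sd)) || any(resid_sd <= 0)) {
    stop("degenerate model: non-positive residual variance")
  }

  for (attempt in 0:4) {
    draw_seed <- (seed + attempt * 1000003L) %% .Machine$integer.max
    old <- globalenv()$.Random.seed
    set.seed(draw_seed)
    FF <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L))
    E <- matrix(stats::rnorm(n * nrow(L)), n, nrow(L))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    Y <- FF %*% t(L) + E * rep(resid_sd, each = n)
    colnames(Y) <- model$item_ids
    if (!likert) {
      if (keep_factor_scores) attr(Y, "factor_scores") <- FF
      return(Y)
    }
    X <- discretize_items(Y, model)
    if (all(apply(X, 2L, function(z) any(z != z[1L])))) {
      if (keep_factor_scores) attr(X, "factor_scores") <- FF
      return(X)
    }
  }
  stop("could not generate a response matrix without constant columns; ",
       "increase n or soften the thresholds")
}

# Map latent responses to categories 1..5 using each item's cut-points.
discretize_items <- function(Y, model) {
  thr <- do.call(rbind, lapply(model$scales, `[[`, "thresholds"))
  X <- matrix(1L, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (j in seq_len(ncol(Y))) {
    X[, j] <- 1L + findInterval(Y[, j], thr[j, ])
  }
  X
}

#' Write a simulated response matrix and its scale map as CSV
#'
#' The response CSV has one column per item (header = item IDs,
#' `"scale.item#"`); the companion scale map CSV has columns `item_id`,
#' `scale_name`, `reverse_coded` (all `FALSE` for simulated data, which is
#' generated consistently keyed).
#'
#' @param X Response matrix from [generate_responses()].
#' @param model The generating [population_model()].
#' @param data_path,map_path Output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_responses <- function(X, model, data_path, map_path) {
  stopifnot(inherits(model, "population_model"),
            identical(colnames(X), model$item_ids))
  utils::write.csv(as.data.frame(X), data_path, row.names = FALSE)
  map <- data.frame(
    item_id = model$item_ids,
    scale_name = model$scale_of,
    reverse_coded = FALSE
  )
  utils::write.csv(map, map_path, row.names = FALSE)
  invisible(list(data = data_path, scale_map = map_path))
}
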