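#' Enumerate all trait subsets of sizes k_min..k_max
#'
#' Every size-k subset of the trait names, for k from `k_min` to `k_max`,
#' each subset alphabetically sorted, the list ordered by size and then
#' lexicographically — a deterministic enumeration whose length is
#' `sum(choose(T, k))`.
#'
#' @param traits Character vector of unique trait names.
#' @param k_min,k_max Inclusive subset-size range (default 2..11).
#' @return List of character vectors.
#' @export
enumerate_subsets <- function(traits, k_min = 2L, k_max = 11L) {
  traits <- as.character(traits)
  if (anyDuplicated(traits)) stop("duplicate trait names")
  if (k_min < 1L || k_min > k_max || k_max > length(traits)) {
    stop("need 1 <= k_min <= k_max <= number of traits")
  }
  traits <- sort(traits)
  out <- list()
  for (k in k_min:k_max) {
    cols <- utils::combn(traits, k, simplify = FALSE)
    out <- c(out, cols)
  }
  out
}

# Deterministic per-subset seed derived from the global seed and the subset
# identity, so results do not depend on worker scheduling.
subset_seed <- function(seed, subset, all_traits) {
  idx <- match(sort(subset), sort(all_traits))
  h <- 0
  for (i in idx) h <- (h * 131 + i) %% 2147483647
  as.integer((seed %% 2147483647 + h * 7919) %% 2147483647)
}

subset_label <- function(subset) paste(sort(subset), collapse = "+")

#' Fit a reduced bifactor model on one trait subset and correlate its D with
#' the full-model D
#'
#' Restricts the response matrix to the subset's item columns, fits the
#' reduced bifactor model (general factor over the included items plus one
#' specific factor per included trait), extracts regression-method D scores,
#' and reports their Pearson correlation with the full-model scores. A
#' reduced fit that fails yields a missing `r` with `converged = FALSE`,
#' never an error.
#'
#' @param subset Character vector of trait names.
#' @param X Full response matrix.
#' @param full_scores D scores from the full model over the same `X`.
#' @param map The full [scale_map()].
#' @param options [engine_options()]; the per-subset jitter seed is derived
#'   from `options$seed` and the subset identity.
#' @return One-row `data.frame`: `subset`, `k`, `r`, `converged`, `df`,
#'   `n_restarts`, `heywood`.
#' @export
run_reduced <- function(subset, X, full_scores, map, options = engine_options()) {
  stopifnot(inherits(map, "scale_map"))
  sub_map <- subset_scale_map(map, subset)
  keep <- map$scale_of %in% subset
  Xs <- X[, keep, drop = FALSE]
  spec <- model_spec(sub_map)
  opts <- options
  opts$seed <- subset_seed(options$seed, subset, map$scales)
  res <- tryCatch({
    S <- sample_covariance(Xs)
    fit <- fit_bifactor(S, nrow(Xs), spec, opts)
    scores <- score_general_factor(Xs, fit)
    list(r = correlate_scores(scores, full_scores),
         converged = fit$converged, df = fit$df,
         n_restarts = fit$n_restarts, heywood = fit$heywood)
  }, error = function(e) {
    list(r = NA_real_, converged = FALSE, df = degrees_of_freedom(spec),
         n_restarts = NA_integer_, heywood = NA)
  })
  data.frame(
    subset = subset_label(subset), k = length(subset), r = res$r,
    converged = res$converged, df = res$df, n_restarts = res$n_restarts,
    heywood = res$heywood, stringsAsFactors = FALSE
  )
}

#' Run the full subset study
#'
#' Fits the full bifactor model once, scores D, then maps [run_reduced()]
#' over [enumerate_subsets()]. The result order is the enumeration order
#' regardless of the worker count, and per-subset seeds derive from the
#' global seed and the subset identity, so any worker count reproduces the
#' same table.
#'
#' @param X Response matrix (columns ordered as in `map`).
#' @param map A [scale_map()].
#' @param k_min,k_max Subset-size range.
#' @param options [engine_options()].
#' @param workers Parallel workers (forked; 1 = serial).
#' @param full_fit,full_scores Optionally reuse a precomputed full-model fit
#'   and its scores.
#' @return `data.frame` of [run_reduced()] rows with attributes
#'   `"manifest"` (seed, options, counts, failures) and `"full_fit"`.
#'   Completes with a warning if more than 5 percent of reduced fits failed.
#' @export
run_all <- function(X, map, k_min = 2L, k_max = 11L,
                    options = engine_options(), workers = 1L,
                    full_fit = NULL, full_scores = NULL) {
  stopifnot(inherits(map, "scale_map"))
  if (is.null(full_fit)) {
    full_fit <- fit_bifactor(sample_covariance(X), nrow(X),
                             model_spec(map), options)
  }
  if (is.null(full_scores)) {
    full_scores <- score_general_factor(X, full_fit)
  }
  subsets <- enumerate_subsets(map$scales, k_min, k_max)
  worker <- function(s) run_reduced(s, X, full_scores, map, options)
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(subsets, worker, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(subsets, worker)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_failed <- sum(!out$converged | is.na(out$r))
  if (n_failed > 0.05 * nrow(out)) {
    warning(sprintf("%d of %d reduced fits failed", n_failed, nrow(out)))
  }
  attr(out, "manifest") <- list(
    seed = options$seed, k_min = k_min, k_max = k_max,
    n_traits = map$n_scales, n_subsets = length(subsets),
    n_failed = n_failed, n_convention = options$n_convention,
    percentile_definition = "linear interpolation between order statistics (quantile type 7)"
  )
  attr(out, "full_fit") <- full_fit
  out
}

#' Summarize a subset study
#'
#' Per subset size: combination count, median correlation with full D, and
#' the 1st/5th/10th percentiles (linear-interpolation percentile definition,
#' recorded in the metadata). Per trait and size: the distribution of
#' correlations over all subsets containing that trait. Failed fits (missing
#' `r`) are excluded, with counts reported.
#'
#' @param results A [run_all()] table.
#' @return List of class `subset_summary`: `by_k`, `by_trait`,
#'   `overall_median`, `n_excluded`, `percentile_definition`.
#' @export
summarize_combinations <- function(results) {
  if (!nrow(results)) stop("empty results")
  ok <- !is.na(results$r)
  n_excluded <- sum(!ok)
  res <- results[ok, , drop = FALSE]
  qs <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
  ks <- sort(unique(results$k))
  by_k <- do.call(rbind, lapply(ks, function(k) {
    r <- res$r[res$k == k]
    all_k <- sum(results$k == k)
    if (!length(r)) {
      return(data.frame(k = k, n_combinations = all_k, n_used = 0L,
                        p01 = NA_real_, p05 = NA_real_, p10 = NA_real_,
                        median = NA_real_, all_failed = TRUE))
    }
    data.frame(k = k, n_combinations = all_k, n_used = length(r),
               p01 = qs(r, .01), p05 = qs(r, .05), p10 = qs(r, .10),
               median = stats::median(r), all_failed = FALSE)
  }))
  traits <- sort(unique(unlist(strsplit(results$subset, "+", fixed = TRUE))))
  by_trait <- do.call(rbind, lapply(traits, function(tr) {
    has <- vapply(strsplit(res$subset, "+", fixed = TRUE),
                  function(s) tr %in% s, TRUE)
    do.call(rbind, lapply(ks, function(k) {
      r <- res$r[has & res$k == k]
      if (!length(r)) return(NULL)
      data.frame(trait = tr, k = k, n = length(r),
                 median = stats::median(r),
                 q25 = qs(r, .25), q75 = qs(r, .75))
    }))
  }))
  rownames(by_k) <- rownames(by_trait) <- NULL
  structure(
    list(
      by_k = by_k, by_trait = by_trait,
      overall_median = stats::median(res$r),
      n_excluded = n_excluded,
      percentile_definition = "linear interpolation between order statistics (quantile type 7)"
    ),
    class = "subset_summary"
  )
}

#' @export
print.subset_summary <- function(x, ...) {
  cat(sprintf("Subset study: grand median r = %.3f (%d failed fits excluded)\n",
              x$overall_median, x$n_excluded))
  print(x$by_k, row.names = FALSE)
  invisible(x)
}

#' Trait composition of a correlation tail
#'
#' Restricted to subsets of one size, selects the given tail of the
#' correlation distribution (bottom or top fraction; ties at the cutoff are
#' all included) and reports, for each trait, the fraction of tail subsets
#' containing it.
#'
#' @param results A [run_all()] table.
#' @param k Subset size to restrict to.
#' @param tail Tail fraction in (0, 1].
#' @param side `"bottom"` (worst approximations) or `"top"` (best).
#' @return Named numeric vector of inclusion frequencies, plus attribute
#'   `"n_tail"`.
#' @export
tail_composition <- function(results, k, tail = 0.01,
                             side = c("bottom", "top")) {
  side <- match.arg(side)
  if (tail <= 0 || tail > 1) stop("tail must be in (0, 1]")
  res <- results[results$k == k & !is.na(results$r), , drop = FALSE]
  if (!nrow(res)) stop("no usable results at k = ", k)
  n_tail <- ceiling(tail * nrow(res))
  r_sorted <- sort(res$r, decreasing = (side == "top"))
  cutoff <- r_sorted[n_tail]
  sel <- if (side == "bottom") res$r <= cutoff else res$r >= cutoff
  members <- strsplit(res$subset[sel], "+", fixed = TRUE)
  traits <- sort(unique(unlist(strsplit(results$subset, "+", fixed = TRUE))))
  freq <- vapply(traits, function(tr) {
    mean(vapply(members, function(s) tr %in% s, TRUE))
  }, 0)
  attr(freq, "n_tail") <- sum(sel)
  freq
}

#' Evaluate named trait sets against same-size combinations
#'
#' For conventional sets such as the Dark Triad (Psychopathy,
#' Machiavellianism, Narcissism) and Dark Tetrad (plus Sadism): report each
#' set's correlation with full D, the median correlation of all same-size
#' subsets, and the median of same-size subsets containing each member trait.
#'
#' @param results A [run_all()] table.
#' @param definitions Named list of character vectors of trait names.
#' @return List with `sets` (one row per named set) and `member_medians`
#'   (one row per set x member trait).
#' @export
named_sets <- function(results, definitions) {
  if (is.null(names(definitions)) || any(!nzchar(names(definitions)))) {
    stop("definitions must be a named list")
  }
  traits <- sort(unique(unlist(strsplit(results$subset, "+", fixed = TRUE))))
  sets <- list(); members <- list()
  for (nm in names(definitions)) {
    def <- definitions[[nm]]
    unknown <- setdiff(def, traits)
    if (length(unknown)) {
      stop(sprintf("named set '%s' references unknown trait(s): %s",
                   nm, paste(unknown, collapse = ", ")))
    }
    k <- length(def)
    row <- results[results$subset == subset_label(def), , drop = FALSE]
    if (!nrow(row)) {
      stop(sprintf("named set '%s' (k = %d) is outside the enumerated range",
                   nm, k))
    }
    same_k <- results[results$k == k & !is.na(results$r), , drop = FALSE]
    sets[[nm]] <- data.frame(
      set = nm, k = k, r = row$r,
      median_same_k = stats::median(same_k$r), stringsAsFactors = FALSE
    )
    split_subsets <- strsplit(same_k$subset, "+", fixed = TRUE)
    members[[nm]] <- do.call(rbind, lapply(def, function(tr) {
      has <- vapply(split_subsets, function(s) tr %in% s, TRUE)
      data.frame(set = nm, trait = tr,
                 median_containing = stats::median(same_k$r[has]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(
    sets = do.call(rbind, c(sets, list(make.row.names = FALSE))),
    member_medians = do.call(rbind, c(members, list(make.row.names = FALSE)))
  )
}

#' Improvement of the median approximation from size k to k + 1
#'
#' The difference in per-size median correlation with full D between subsets
#' of size `k + 1` and size `k`; the quantity behind a stopping rule of the
#' form "stop adding traits once the median gain drops below a threshold".
#'
#' @param X Response matrix.
#' @param map A [scale_map()].
#' @param k Base subset size (`k + 1 <=` number of traits).
#' @param options [engine_options()].
#' @param workers Parallel workers.
#' @param results Optionally a precomputed [run_all()] table covering sizes
#'   `k` and `k + 1` (skips refitting).
#' @return Scalar median improvement, with attribute `"medians"`.
#' @export
stopping_diagnostic <- function(X, map, k, options = engine_options(),
                                workers = 1L, results = NULL) {
  if (is.null(results)) {
    if (k + 1L > map$n_scales) stop("k + 1 exceeds the number of traits")
    results <- run_all(X, map, k_min = k, k_max = k + 1L,
                       options = options, workers = workers)
  }
  r_k <- results$r[results$k == k & !is.na(results$r)]
  r_k1 <- results$r[results$k == k + 1L & !is.na(results$r)]
  if (!length(r_k) || !length(r_k1)) {
    stop("results must cover sizes k and k + 1")
  }
  meds <- c(stats::median(r_k), stats::median(r_k1))
  out <- meds[2L] - meds[1L]
  attr(out, "medians") <- stats::setNames(meds, c(k, k + 1L))
  out
}
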