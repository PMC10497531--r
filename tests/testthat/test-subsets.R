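# Crafted results table covering a full enumeration, for summary identities.
fake_results <- function(T_ = 5, k_min = 2, k_max = 3, r = NULL) {
  subsets <- enumerate_subsets(paste0("t", seq_len(T_)), k_min, k_max)
  data.frame(
    subset = vapply(subsets, paste, "", collapse = "+"),
    k = lengths(subsets),
    r = if (is.null(r)) seq(0.5, 0.9, length.out = length(subsets)) else r,
    converged = TRUE, df = 10L, n_restarts = 0L, heywood = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("enumeration counts match the binomial identities", {
  traits16 <- paste0("t", sprintf("%02d", 1:16))
  all_k <- enumerate_subsets(traits16, 2, 11)
  expect_identical(length(all_k), 63002L)
  expect_identical(length(enumerate_subsets(traits16, 8, 8)), 12870L)
  expect_identical(length(enumerate_subsets(traits16, 6, 11)), 56134L)
  expect_identical(length(enumerate_subsets(traits16, 11, 11)), 4368L)
  counts <- table(lengths(all_k))
  expect_identical(unname(c(counts)),
                   c(120L, 560L, 1820L, 4368L, 8008L, 11440L, 12870L,
                     11440L, 8008L, 4368L))

  expect_identical(
    enumerate_subsets(c("B", "A", "C"), 2, 3),
    list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"))
  )
  expect_error(enumerate_subsets(c("a", "a", "b"), 2, 2), "duplicate")
  expect_error(enumerate_subsets(letters[1:3], 2, 5), "k_max")
})

test_that("subsets are sorted and deterministically ordered", {
  subs <- enumerate_subsets(c("delta", "alpha", "charlie", "bravo"), 2, 3)
  expect_true(all(vapply(subs, function(s) !is.unsorted(s), TRUE)))
  expect_identical(subs, enumerate_subsets(c("alpha", "bravo", "charlie", "delta"), 2, 3))
})

test_that("the full trait set reproduces the full D exactly", {
  pop <- tiny_population()
  map <- as_scale_map(pop)
  X <- generate_responses(pop, 500, seed = 41)
  fit <- fit_bifactor(sample_covariance(X), 500, model_spec(map))
  full_scores <- score_general_factor(X, fit)
  row <- run_reduced(map$scales, X, full_scores, map)
  expect_true(row$converged)
  expect_gt(row$r, 1 - 1e-8)
})

test_that("run_all covers the enumeration and is worker-invariant", {
  pop <- six_scale_population()
  map <- as_scale_map(pop)
  X <- generate_responses(pop, 400, seed = 42)
  opts <- engine_options(seed = 42)
  res1 <- run_all(X, map, 2, 2, options = opts, workers = 1)
  expect_identical(nrow(res1), 15L)   # choose(6, 2)
  res2 <- run_all(X, map, 2, 2, options = opts, workers = 2)
  expect_identical(res1, res2)
  man <- attr(res1, "manifest")
  expect_identical(man$n_subsets, 15L)
  expect_identical(man$seed, 42L)
})

test_that("run_all subset counts follow the binomials on six traits", {
  pop <- six_scale_population()
  map <- as_scale_map(pop)
  X <- generate_responses(pop, 400, seed = 43)
  res <- run_all(X, map, 2, 5, options = engine_options(seed = 43), workers = 2)
  expect_identical(nrow(res), 15L + 20L + 15L + 6L)
  expect_identical(unname(c(table(res$k))), c(15L, 20L, 15L, 6L))
  # failed fits are the exception on well-behaved data
  expect_lt(sum(!res$converged | is.na(res$r)), 0.05 * nrow(res))
})

test_that("summaries collapse to the constant under constant correlations", {
  res <- fake_results(T_ = 5, r = 0.8)
  s <- summarize_combinations(res)
  expect_true(all(abs(unlist(s$by_k[, c("p01", "p05", "p10", "median")]) - 0.8) < 1e-12))
  expect_true(all(abs(s$by_trait$median - 0.8) < 1e-12))
  expect_equal(s$overall_median, 0.8)
})

test_that("summary is invariant to results order and counts subsets per trait", {
  res <- fake_results(T_ = 6, k_min = 2, k_max = 4)
  s1 <- summarize_combinations(res)
  set.seed(1)
  s2 <- summarize_combinations(res[sample(nrow(res)), ])
  expect_equal(s1$by_k, s2$by_k)
  expect_equal(s1$by_trait, s2$by_trait)
  # subsets of size k containing a fixed trait number choose(T-1, k-1)
  n_t1_k3 <- s1$by_trait$n[s1$by_trait$trait == "t1" & s1$by_trait$k == 3]
  expect_identical(n_t1_k3, 10L)   # choose(5, 2)
})

test_that("percentiles are ordered and failures are excluded with a count", {
  res <- fake_results(T_ = 6, k_min = 2, k_max = 4)
  res$r[c(3, 9)] <- NA
  s <- summarize_combinations(res)
  expect_identical(s$n_excluded, 2L)
  with(s$by_k, {
    expect_true(all(p01 <= p05 & p05 <= p10 & p10 <= median))
  })
  expect_match(s$percentile_definition, "linear interpolation")
})

test_that("tail selection honours the tie rule and the k/T identity", {
  res <- fake_results(T_ = 5, k_min = 3, k_max = 3, r = 0.7)
  # identical r: the tie rule pulls every subset into the tail
  freq <- tail_composition(res, k = 3, tail = 0.01, side = "bottom")
  expect_identical(attr(freq, "n_tail"), nrow(res))
  expect_equal(unname(c(freq)), rep(3 / 5, 5))
  # tail = 1 includes everything: inclusion frequency k/T
  res2 <- fake_results(T_ = 6, k_min = 4, k_max = 4)
  freq2 <- tail_composition(res2, k = 4, tail = 1, side = "top")
  expect_equal(unname(c(freq2)), rep(4 / 6, 6))
  expect_error(tail_composition(res2, k = 2, tail = 0.01), "no usable")
  expect_error(tail_composition(res2, k = 4, tail = 0), "in \\(0, 1\\]")
})

test_that("named sets report their rank against same-size subsets", {
  res <- fake_results(T_ = 5, k_min = 2, k_max = 3)
  best3 <- res[res$k == 3, ]
  best <- strsplit(best3$subset[which.max(best3$r)], "+", fixed = TRUE)[[1]]
  out <- named_sets(res, list(top = best))
  expect_equal(out$sets$r, max(best3$r))
  expect_gte(out$sets$r, out$sets$median_same_k)
  expect_identical(nrow(out$member_medians), 3L)
  expect_error(named_sets(res, list(bad = c("t1", "xyz"))), "xyz")
  expect_error(named_sets(res, list(c("t1", "t2"))), "named list")
})

test_that("stopping diagnostic is the difference of per-size medians", {
  res <- fake_results(T_ = 6, k_min = 3, k_max = 4, r = 0.85)
  d <- stopping_diagnostic(NULL, NULL, 3, results = res)
  expect_equal(as.numeric(d), 0)
  res$r[res$k == 4] <- 0.9
  d2 <- stopping_diagnostic(NULL, NULL, 3, results = res)
  expect_equal(as.numeric(d2), 0.05)
  expect_equal(unname(attr(d2, "medians")), c(0.85, 0.9))
  expect_error(stopping_diagnostic(NULL, NULL, 5, results = res), "cover")
})

test_that("per-subset seeds depend on the subset, not on execution order", {
  traits <- paste0("t", 1:6)
  s1 <- darkcore:::subset_seed(11, c("t2", "t5"), traits)
  s2 <- darkcore:::subset_seed(11, c("t5", "t2"), traits)
  s3 <- darkcore:::subset_seed(11, c("t2", "t6"), traits)
  expect_identical(s1, s2)
  expect_false(s1 == s3)
  expect_true(s1 >= 0 && s1 < .Machine$integer.max)
})
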