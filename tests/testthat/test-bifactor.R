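test_that("scale map validates item assignment", {
  expect_error(scale_map(c("a", "a", "b"), c("s1", "s1", "s1")),
               "duplicate item_id")
  expect_error(scale_map(c("a", "b", "c"), c("s1", "s1", "s2")),
               "at least 2 items")
  m <- scale_map(c("a", "b", "c", "d"), c("s1", "s1", "s2", "s2"))
  expect_identical(m$scales, c("s1", "s2"))
  expect_error(subset_scale_map(m, "nope"), "unknown scale")
})

test_that("degrees of freedom match hand counts and the free-parameter identity", {
  # the emulated full battery: 151 items over 16 scales
  pop <- make_default_population()
  spec <- model_spec(as_scale_map(pop))
  expect_identical(degrees_of_freedom(spec), 11023L)
  expect_identical(spec$n_free, 453L)
  expect_identical(as.integer(spec$p * (spec$p + 1L) / 2L - spec$n_free), 11023L)

  # 6 items over 2 scales of 3: 21 moments - 18 free parameters
  m <- scale_map(letters[1:6], rep(c("s1", "s2"), each = 3))
  expect_identical(degrees_of_freedom(model_spec(m)), 3L)

  # identity df = p(p+1)/2 - length(free parameters) across random specs
  set.seed(20)
  for (i in 1:20) {
    T_ <- sample(2:6, 1)
    counts <- sample(2:6, T_, replace = TRUE)
    m <- scale_map(paste0("i", seq_len(sum(counts))),
                   rep(paste0("s", seq_len(T_)), counts))
    sp <- model_spec(m)
    par <- random_parameter_point(sp, seed = i)
    expect_identical(length(par), sp$n_free)
    expect_identical(degrees_of_freedom(sp),
                     as.integer(sp$p * (sp$p + 1L) / 2L - length(par)))
  }
})

test_that("sample covariance uses the divide-by-N convention", {
  S <- sample_covariance(matrix(c(1, 3, 2, 4), 2))
  expect_equal(unname(S), matrix(1, 2, 2))
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  S2 <- sample_covariance(X)
  expect_identical(S2, t(S2))
  expect_equal(S2, cov(X) * 49 / 50, tolerance = 1e-12)
  X[, 2] <- 1
  expect_error(sample_covariance(X), "constant column.*b")
})

test_that("implied_sigma reproduces the bifactor pattern closed forms", {
  m <- scale_map(paste0("i", 1:5), c("s1", "s1", "s1", "s2", "s2"))
  spec <- model_spec(m)
  # all free loadings zero, markers 1, unit variances
  par <- c(rep(0, 4), rep(0, 3), rep(1, 5), rep(1, 3))
  Sigma <- implied_sigma(par, spec)
  # marker item 1 loads 1 on general and on s1: psi_g + psi_s1 + theta
  expect_equal(Sigma[1, 1], 3)
  expect_equal(Sigma[4, 4], 2)   # marker of s2 only: psi_s2 + theta (lg=0)
  expect_equal(Sigma[2, 2], 1)   # free item: all loadings 0
  expect_equal(Sigma[1, 4], 0)

  # off-block covariance = lg_i psi_g lg_j for items in different scales
  par2 <- random_parameter_point(spec, seed = 5)
  Sigma2 <- implied_sigma(par2, spec)
  expect_identical(Sigma2, t(Sigma2))
  lg <- c(1, par2[1:4]); psi_g <- par2[4 + 3 + 5 + 1]
  expect_equal(Sigma2[2, 5], lg[2] * psi_g * lg[5], tolerance = 1e-12)
})

test_that("fml is the ML discrepancy with its closed-form values", {
  S <- random_pd(4, seed = 1)
  expect_equal(fml(S, S), 0)
  expect_equal(fml(diag(2), 2 * diag(2)), 2 * log(2) + 1 - 2,
               tolerance = 1e-12)
  expect_error(fml(matrix(0, 2, 2), diag(2)), "singular")
  expect_identical(fml(diag(2), matrix(c(1, 2, 2, 1), 2)), Inf)
})

test_that("fml matches a brute-force evaluation and is nonnegative on random PD pairs", {
  for (i in 1:200) {
    p <- 2 + (i %% 5)
    S <- random_pd(p, seed = 2 * i)
    Sigma <- random_pd(p, seed = 2 * i + 1)
    expect_lt(abs(fml(S, Sigma) - fml_bruteforce(S, Sigma)), 1e-10)
    expect_gte(fml(S, Sigma), 0)
  }
})

test_that("analytic gradient matches central finite differences", {
  pop <- tiny_population()
  spec <- model_spec(as_scale_map(pop))
  S <- sample_covariance(generate_responses(pop, 300, seed = 8, likert = FALSE))
  for (i in 1:25) {
    par <- random_parameter_point(spec, seed = 100 + i)
    g <- fml_gradient(par, spec, S)
    fd <- fml_fd_gradient(par, spec, S)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-5)
  }
})

test_that("fitting the exact population covariance recovers the truth", {
  pop <- tiny_population()
  spec <- model_spec(as_scale_map(pop))
  fit <- fit_bifactor(implied_covariance(pop), 500, spec)
  expect_true(fit$converged)
  expect_lt(fit$fml, 1e-8)
  expect_equal(fit$chi_square, 500 * fit$fml)
  std <- standardized_loadings(fit)
  expect_lt(max(abs(std$general -
                      unlist(lapply(pop$scales, `[[`, "general_loadings")))),
            1e-3)
  expect_lt(max(abs(abs(std$specific) -
                      unlist(lapply(pop$scales, `[[`, "specific_loadings")))),
            1e-3)
})

test_that("chi-square and discrepancy are invariant under item rescaling", {
  pop <- tiny_population()
  spec <- model_spec(as_scale_map(pop))
  X <- generate_responses(pop, 400, seed = 12, likert = FALSE)
  fit1 <- fit_bifactor(sample_covariance(X), 400, spec)
  X2 <- X
  X2[, 1:3] <- 2 * X2[, 1:3]       # rescale the first scale's items
  fit2 <- fit_bifactor(sample_covariance(X2), 400, spec)
  expect_lt(abs(fit1$fml - fit2$fml), 1e-6)
  expect_lt(abs(fit1$chi_square - fit2$chi_square), 1e-3)
})

test_that("fit is invariant to scale-block ordering", {
  pop <- tiny_population()
  X <- generate_responses(pop, 400, seed = 13, likert = FALSE)
  map <- as_scale_map(pop)
  fit1 <- fit_bifactor(sample_covariance(X), 400, model_spec(map))
  perm <- c(7:9, 4:6, 1:3)         # gamma, beta, alpha
  map2 <- scale_map(map$item_ids[perm], map$scale_of[perm])
  fit2 <- fit_bifactor(sample_covariance(X[, perm]), 400, model_spec(map2))
  expect_lt(abs(fit1$fml - fit2$fml), 1e-6)
})

test_that("N convention option switches the chi-square multiplier", {
  pop <- tiny_population()
  spec <- model_spec(as_scale_map(pop))
  S <- sample_covariance(generate_responses(pop, 200, seed = 21, likert = FALSE))
  fN <- fit_bifactor(S, 200, spec, engine_options(n_convention = "N"))
  fN1 <- fit_bifactor(S, 200, spec, engine_options(n_convention = "N-1"))
  expect_equal(fN$chi_square / 200, fN1$chi_square / 199, tolerance = 1e-6)
})

test_that("fit indices reproduce closed forms", {
  I2 <- diag(2)
  idx <- fit_indices(35211, 11023, 1676, I2, I2)
  expect_equal(round(idx$rmsea, 3), 0.036)
  expect_true(idx$rmsea_ci90[1] <= idx$rmsea && idx$rmsea <= idx$rmsea_ci90[2])
  expect_lt(idx$p_value, 0.001)

  # zero noncentrality and perfect reproduction
  idx0 <- fit_indices(50, 50, 300, I2, I2)
  expect_equal(idx0$rmsea, 0)
  S <- random_pd(4, seed = 9)
  idxS <- fit_indices(120, 60, 300, S, S)
  expect_equal(idxS$srmr, 0)
  expect_error(fit_indices(10, 0, 100, I2, I2), "df = 0")
})

test_that("warnings are raised for shaky inputs, errors for invalid ones", {
  pop <- tiny_population()
  spec <- model_spec(as_scale_map(pop))
  S <- implied_covariance(pop)
  expect_warning(fit_bifactor(S, 5, spec), "below number of items")
  expect_error(fit_bifactor(S[1:4, 1:4], 100, spec), "items")
  Sb <- S; Sb[1, 2] <- Sb[1, 2] + 1e-3
  expect_error(fit_bifactor(Sb, 100, spec), "not symmetric")
})
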