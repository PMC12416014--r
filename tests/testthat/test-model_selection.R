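test_that("free-parameter count follows K*q + K + (K-1) (+ lambda)", {
  expect_equal(count_free_params(1, 3, lambda_estimated = TRUE), 5)
  expect_equal(count_free_params(6, 3, lambda_estimated = TRUE), 30)
  expect_equal(count_free_params(1, 3, lambda_estimated = FALSE), 4)
  expect_equal(count_free_params(6, 3, lambda_estimated = FALSE), 29)
})

test_that("criteria satisfy their defining identities", {
  d <- make_two_group_data(n_per = 8, seed = 2)
  X <- build_design(d, design_polynomial(1))
  fit <- fit_multistart(d, X, 2, n_restarts = 3, seed = 1)
  cs <- criteria(fit, lambda_estimated = TRUE)
  h <- count_free_params(fit$K, fit$q, TRUE)
  expect_equal(cs$h, h)
  expect_equal(cs$aic, -2 * fit$loglik + 2 * h)
  expect_equal(cs$bic, -2 * fit$loglik + log(d$N) * h)
  expect_gte(cs$icl, cs$bic - 1e-8)
  # BIC >= AIC whenever log N > 2
  expect_gte(cs$bic, cs$aic)
  expect_error(criteria(fit, N = 0), "positive")
})

test_that("ICL equals BIC exactly for crisp posteriors and exceeds it otherwise", {
  crisp <- fake_fit(-100, K = 2, q = 2, n = 10)
  cs <- criteria(crisp, lambda_estimated = FALSE)
  # crisp responsibilities with pi = 1/2: l_ICL = l - n log 2... compute both ways
  z <- posterior_classify(crisp)
  l_icl <- sum(log(crisp$pi)[z] + crisp$logdens[cbind(1:10, z)])
  expect_equal(cs$icl, -2 * l_icl + log(crisp$N) * cs$h)
  # when the mixture loglik equals the classification loglik, ICL == BIC
  crisp$loglik <- l_icl
  cs2 <- criteria(crisp, lambda_estimated = FALSE)
  expect_equal(cs2$icl, cs2$bic)
  # soft responsibilities push ICL strictly above BIC
  d <- make_two_group_data(n_per = 8, seed = 5, sd = 0.8)
  X <- build_design(d, design_polynomial(1))
  fit <- fit_multistart(d, X, 2, n_restarts = 3, seed = 1, min_prior = 0)
  soft <- criteria(fit)
  expect_gt(soft$icl, soft$bic)
})

test_that("a singleton grid profile returns that lambda", {
  d <- make_positive_data(n = 8, seed = 3)
  pr <- profile_lambda_grid(d, design_polynomial(1), K = 1, grid = 0.4,
                            n_restarts = 1, seed = 1)
  expect_equal(pr$lambda_hat, 0.4)
  expect_equal(pr$n_evals, 1)
})

test_that("grid profile matches the Jacobian-adjusted Box-Cox profile oracle", {
  # exact lognormal data: the profile should peak at the grid point nearest 0
  set.seed(21)
  n <- 40; J <- 5
  t <- (0:(J - 1)) / (J - 1)
  y <- exp(1 + 0.5 * rep(t, n) + rnorm(n * J, 0, 0.3))
  d <- longitudinal_data(rep(1:n, each = J), rep(t, n), y)
  X <- build_design(d, design_polynomial(1))
  grid <- seq(-1, 1, by = 0.25)
  pr <- profile_lambda_grid(d, design_polynomial(1), K = 1, grid = grid,
                            n_restarts = 1, seed = 1)
  # independent oracle: classic Box-Cox profile, l_bc(lambda) + N(lambda-1) log gmean
  g <- geometric_mean(d)
  oracle <- vapply(grid, function(lam)
    ols_mle_loglik(boxcox(d$y, lam), X) + d$N * (lam - 1) * log(g),
    numeric(1))
  expect_equal(pr$loglik, oracle, tolerance = 1e-6)
  expect_equal(pr$lambda_hat, grid[which.max(oracle)])
  expect_equal(pr$lambda_hat, 0)
})

test_that("optimized search uses 33 evaluations and matches a dense grid", {
  set.seed(8)
  n <- 30; J <- 4
  t <- 0:(J - 1)
  y <- exp(0.5 + 0.2 * rep(t, n) + rnorm(n * J, 0, 0.25))
  d <- longitudinal_data(rep(1:n, each = J), rep(t, n), y)
  spec <- design_polynomial(1)
  opt <- optimized_lambda_search(d, spec, K = 1, n_restarts = 1, seed = 1)
  expect_equal(opt$n_evals, 33)
  expect_gte(opt$lambda_hat, -5)
  expect_lte(opt$lambda_hat, 5)
  # dense-grid oracle at step 0.01 via the closed-form K = 1 profile
  X <- build_design(d, spec)
  g <- geometric_mean(d)
  dense <- seq(-5, 5, by = 0.01)
  ll <- vapply(dense, function(lam)
    ols_mle_loglik(scaled_boxcox(d$y, lam, g), X), numeric(1))
  expect_lte(abs(opt$lambda_hat - dense[which.max(ll)]), 0.04 + 1e-9)
})

test_that("model selection picks the true K on a two-group mixture", {
  d <- simulate_study1("M2", seed = 5)
  sel <- select_model(d, design_polynomial(2), K_range = 1:3,
                      lambda_method = "grid",
                      lambda = seq(-1, 1, by = 0.25),
                      n_restarts = 3, seed = 1)
  expect_equal(sel$selected$bic, 2)
  expect_true(all(abs(sel$table$lambda_hat) <= 0.5, na.rm = TRUE))
  # untransformed analysis of the same data over-extracts
  sel_raw <- select_model(d, design_polynomial(2), K_range = 1:4,
                          lambda_method = "fixed", lambda = 1,
                          n_restarts = 3, seed = 1)
  expect_gte(sel_raw$selected$bic, 2)
  expect_false(sel_raw$lambda_estimated)
})

test_that("K_range of one is honored and h reflects the lambda convention", {
  d <- make_positive_data(n = 10, seed = 4)
  sel <- select_model(d, design_polynomial(1), K_range = 1,
                      lambda_method = "grid", lambda = c(0, 0.5),
                      n_restarts = 1, seed = 1)
  expect_equal(sel$selected$bic, 1)
  expect_equal(sel$table$h, count_free_params(1, 2, TRUE))
  sel2 <- select_model(d, design_polynomial(1), K_range = 1,
                       lambda_method = "grid", lambda = c(0, 0.5),
                       n_restarts = 1, seed = 1, count_lambda = FALSE)
  expect_equal(sel2$table$h, count_free_params(1, 2, FALSE))
})

test_that("model selection is invariant to subject order", {
  d <- simulate_study1("M2", n = 40, seed = 9)
  perm <- c(21:40, 1:20)
  ids <- rep(perm, each = 10)
  d2 <- longitudinal_data(
    id = sprintf("s%04d", ids),
    time = rep((0:9) / 9, 40),
    y = as.vector(matrix(d$y, nrow = 10)[, perm]))
  spec <- design_polynomial(1)
  s1 <- select_model(d, spec, K_range = 1:2, lambda_method = "grid",
                     lambda = c(-0.5, 0, 0.5), n_restarts = 4, seed = 3)
  s2 <- select_model(d2, spec, K_range = 1:2, lambda_method = "grid",
                     lambda = c(-0.5, 0, 0.5), n_restarts = 4, seed = 3)
  expect_equal(s1$selected$bic, s2$selected$bic)
  expect_equal(s1$table$lambda_hat, s2$table$lambda_hat)
})
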