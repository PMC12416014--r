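test_that("component log-density matches the Gaussian formula and a dnorm oracle", {
  expect_equal(component_loglik(0.5, matrix(1), 0.5, 1), -0.5 * log(2 * pi))
  expect_equal(component_loglik(c(0, 0), cbind(c(1, 1)), 0, 1), -log(2 * pi))
  set.seed(3)
  X <- cbind(1, rnorm(6))
  y <- rnorm(6)
  th <- c(0.3, -1)
  s2 <- 0.7
  oracle <- sum(dnorm(y, drop(X %*% th), sqrt(s2), log = TRUE))
  expect_equal(component_loglik(y, X, th, s2), oracle, tolerance = 1e-10)
  expect_error(component_loglik(y, X, c(1, 2, 3), s2), "dimension")
})

test_that("E-step normalizes responsibilities and follows Bayes' rule", {
  d <- make_two_group_data(n_per = 4)
  X <- build_design(d, design_polynomial(1))
  params1 <- list(theta = cbind(c(1, 0)), sigma2 = 1, pi = 1)
  es1 <- e_step(d, X, params1)
  expect_equal(unname(es1$resp[, 1]), rep(1, d$n))
  # two identical components split responsibilities evenly
  params2 <- list(theta = cbind(c(1, 0), c(1, 0)), sigma2 = c(1, 1),
                  pi = c(0.5, 0.5))
  es2 <- e_step(d, X, params2)
  expect_equal(unname(es2$resp), matrix(0.5, d$n, 2))
  # hand-computed Bayes arithmetic on a 2-subject toy
  toy <- longitudinal_data(id = c("a", "b"), time = c(0, 0), y = c(0, 1))
  Xt <- build_design(toy, design_polynomial(0))
  pars <- list(theta = cbind(0, 1), sigma2 = c(1, 1), pi = c(0.3, 0.7))
  es <- e_step(toy, Xt, pars)
  f <- function(y, mu) dnorm(y, mu, 1)
  manual_a <- 0.3 * f(0, 0) / (0.3 * f(0, 0) + 0.7 * f(0, 1))
  manual_b <- 0.3 * f(1, 0) / (0.3 * f(1, 0) + 0.7 * f(1, 1))
  expect_equal(unname(es$resp[, 1]), c(manual_a, manual_b), tolerance = 1e-12)
  expect_equal(es$loglik,
               log(0.3 * f(0, 0) + 0.7 * f(0, 1)) +
                 log(0.3 * f(1, 0) + 0.7 * f(1, 1)), tolerance = 1e-12)
})

test_that("M-step with crisp responsibilities equals per-group least squares", {
  d <- make_two_group_data(n_per = 6)
  X <- build_design(d, design_polynomial(1))
  resp <- matrix(0, d$n, 2)
  resp[cbind(seq_len(d$n), d$true_labels)] <- 1
  pars <- m_step(d, X, resp)
  for (k in 1:2) {
    rows <- d$sidx %in% which(d$true_labels == k)
    ols <- lm.fit(X[rows, ], d$y[rows])
    expect_equal(unname(pars$theta[, k]), unname(ols$coefficients),
                 tolerance = 1e-10)
    expect_equal(pars$sigma2[k], mean(ols$residuals^2), tolerance = 1e-10)
  }
  expect_equal(pars$pi, colMeans(resp))
})

test_that("M-step with uniform responsibilities collapses to the pooled fit", {
  d <- make_two_group_data(n_per = 5)
  X <- build_design(d, design_polynomial(1))
  pars <- m_step(d, X, matrix(0.5, d$n, 2))
  pooled <- lm.fit(X, d$y)
  for (k in 1:2)
    expect_equal(unname(pars$theta[, k]), unname(pooled$coefficients),
                 tolerance = 1e-10)
  expect_equal(pars$pi, c(0.5, 0.5))
})

test_that("M-step mixing proportions are responsibility column means", {
  d <- longitudinal_data(id = c("a", "b", "c"), time = c(0, 0, 0),
                         y = c(1, 2, 3))
  X <- build_design(d, design_polynomial(0))
  resp <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(m_step(d, X, resp)$pi, c(2 / 3, 1 / 3))
})

test_that("K = 1 EM equals the closed-form Gaussian regression MLE", {
  d <- make_two_group_data(n_per = 8, seed = 9)
  X <- build_design(d, design_polynomial(1))
  fit <- fit_em(d, X, 1)
  ols <- lm.fit(X, d$y)
  expect_equal(fit$loglik, ols_mle_loglik(d$y, X), tolerance = 1e-8)
  expect_equal(unname(fit$theta[, 1]), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(fit$sigma2[1], mean(ols$residuals^2), tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and responsibilities stay normalized", {
  for (seed in 1:5) {
    d <- make_two_group_data(n_per = 8, seed = seed, sd = 0.5)
    X <- build_design(d, design_polynomial(1))
    set.seed(seed)
    fit <- fit_em(d, X, 2, min_prior = 0)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(rowSums(fit$resp), rep(1, d$n), tolerance = 1e-10)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
    expect_true(all(fit$sigma2 > 0))
  }
})

test_that("compiled and reference EM engines agree exactly", {
  d <- make_two_group_data(n_per = 10, seed = 4)
  X <- build_design(d, design_polynomial(1))
  set.seed(1)
  init <- sample(1:3, d$n, replace = TRUE)
  fc <- fit_em(d, X, 3, init = init, engine = "cpp")
  fr <- fit_em(d, X, 3, init = init, engine = "R")
  expect_equal(fc$loglik, fr$loglik, tolerance = 1e-10)
  expect_equal(fc$theta, fr$theta, tolerance = 1e-8)
  expect_equal(fc$loglik_trace, fr$loglik_trace, tolerance = 1e-8)
  expect_equal(fc$K, fr$K)
})

test_that("multistart keeps the best restart and is deterministic", {
  d <- make_two_group_data(n_per = 7, seed = 6)
  X <- build_design(d, design_polynomial(1))
  f1 <- fit_multistart(d, X, 2, n_restarts = 1, seed = 10)
  set.seed(10 + 1)
  f1b <- fit_em(d, X, 2, init = trajmix:::.random_partition(d$n, 2))
  expect_equal(f1$loglik, f1b$loglik)
  multi <- fit_multistart(d, X, 2, n_restarts = 6, seed = 10)
  for (r in 1:6) {
    set.seed(10 + r)
    single <- fit_em(d, X, 2, init = trajmix:::.random_partition(d$n, 2))
    expect_gte(multi$loglik + 1e-10, single$loglik)
  }
  again <- fit_multistart(d, X, 2, n_restarts = 6, seed = 10)
  expect_equal(multi$loglik, again$loglik)
})

test_that("multistart attains the exhaustive-partition optimum on a tiny instance", {
  d <- make_two_group_data(n_per = 3, seed = 13, sd = 0.2)
  X <- build_design(d, design_polynomial(1))
  best_ll <- -Inf
  for (code in 0:(2^d$n - 1)) {   # every crisp 2-partition, EM-refined
    z <- bitwAnd(bitwShiftR(code, 0:(d$n - 1)), 1) + 1
    if (length(unique(z)) < 2) next
    f <- tryCatch(fit_em(d, X, 2, init = z, min_prior = 0),
                  error = function(e) NULL)
    if (!is.null(f) && !f$degenerate) best_ll <- max(best_ll, f$loglik)
  }
  multi <- fit_multistart(d, X, 2, n_restarts = 20, seed = 3, min_prior = 0)
  expect_lt(abs(multi$loglik - best_ll), 1e-4)
})

test_that("posterior classification breaks ties toward the smaller component", {
  fit <- fake_fit(0, K = 2, q = 1, n = 3)
  fit$resp <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_equal(posterior_classify(fit), c(1, 2, 1))
})

test_that("component labels are canonical regardless of initialization", {
  d <- make_two_group_data(n_per = 10, seed = 8, sd = 0.2)
  X <- build_design(d, design_polynomial(1))
  z <- d$true_labels
  f_a <- fit_em(d, X, 2, init = z)
  f_b <- fit_em(d, X, 2, init = 3 - z)  # swapped labels
  expect_equal(f_a$theta, f_b$theta, tolerance = 1e-6)
  expect_equal(f_a$pi, f_b$pi, tolerance = 1e-6)
  expect_equal(posterior_classify(f_a), posterior_classify(f_b))
  # ordering is by fitted mean at the earliest time, ascending
  x0 <- X[which.min(d$time), ]
  mu0 <- drop(crossprod(f_a$theta, x0))
  expect_true(all(diff(mu0) >= 0))
})

test_that("EM recovers the generating parameters of a lognormal two-group mixture", {
  d <- simulate_study1("M2", seed = 77)
  dlog <- d
  dlog$y <- log(d$y)
  X <- build_design(dlog, design_polynomial(1))
  fit <- fit_multistart(dlog, X, 2, n_restarts = 5, seed = 2)
  # components canonically ordered by mean at x = 0 (both intercepts 1);
  # match on slope instead
  slopes <- sort(fit$theta[2, ])
  expect_lt(abs(slopes[1] - 0), 0.1)
  expect_lt(abs(slopes[2] - 1), 0.1)
  expect_lt(max(abs(fit$theta[1, ] - 1)), 0.1)
  flat <- which.min(fit$theta[2, ])
  expect_lt(abs(fit$pi[flat] - 0.6), 0.05)
  expect_lt(max(abs(sqrt(fit$sigma2) - 0.5)), 0.05)
})

test_that("degenerate requests surface as typed errors", {
  d <- longitudinal_data(id = c("a", "b"), time = c(0, 0), y = c(1, 2))
  X <- build_design(d, design_polynomial(0))
  expect_error(fit_em(d, X, 3), "at least K subjects")
  # noiseless trajectories hit the variance floor
  d2 <- longitudinal_data(id = rep(paste0("s", 1:6), each = 3),
                          time = rep(0:2, 6), y = rep(1 + 2 * (0:2), 6))
  X2 <- build_design(d2, design_polynomial(1))
  expect_error(
    fit_multistart(d2, X2, 1, n_restarts = 2, seed = 1),
    class = "trajmix_degenerate")
})
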