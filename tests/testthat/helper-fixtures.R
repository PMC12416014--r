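# shared fixtures and independent oracles

# small balanced two-group dataset with linear trends; group 1 flat at a,
# group 2 rising; deterministic given seed
make_two_group_data <- function(n_per = 10, times = 0:4, sd = 0.3,
                                a = c(1, 0), b = c(2, 1), seed = 42,
                                link = identity) {
  set.seed(seed)
  n <- 2 * n_per
  labels <- rep(1:2, each = n_per)
  J <- length(times)
  y <- numeric(n * J)
  for (i in seq_len(n)) {
    cf <- if (labels[i] == 1) a else b
    y[((i - 1) * J + 1):(i * J)] <-
      link(cf[1] + cf[2] * times + rnorm(J, 0, sd))
  }
  longitudinal_data(id = rep(sprintf("i%02d", 1:n), each = J),
                    time = rep(times, n), y = y, true_label = rep(labels, each = J))
}

# positive-response dataset for transformation tests
make_positive_data <- function(n = 12, times = 0:3, seed = 7) {
  set.seed(seed)
  J <- length(times)
  y <- exp(1 + 0.3 * rep(times, n) + rnorm(n * J, 0, 0.4))
  longitudinal_data(id = rep(paste0("s", 1:n), each = J),
                    time = rep(times, n), y = y)
}

# closed-form Gaussian regression MLE log-likelihood (K = 1 oracle)
ols_mle_loglik <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  N <- length(y)
  s2 <- sum(fit$residuals^2) / N
  -N / 2 * log(2 * pi * s2) - N / 2
}

# brute-force adjusted Rand from explicit pair counting
ari_bruteforce <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  np <- ncol(pairs)
  exp_index <- (n11 + n10) * (n11 + n01) / np
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == exp_index) return(1)
  (n11 - exp_index) / (max_index - exp_index)
}

# direct-count purity
purity_bruteforce <- function(labels, truth) {
  total <- 0
  for (cl in unique(labels)) {
    total <- total + max(table(truth[labels == cl]))
  }
  total / length(labels)
}

# minimal mixture_fit carrying a given log-likelihood, for criterion
# arithmetic on printed values
fake_fit <- function(loglik, K, q, n = 10, N = 50, crisp = TRUE) {
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), rep_len(seq_len(K), n))] <- 1
  if (!crisp) resp <- (resp + 0.5) / rowSums(resp + 0.5)
  structure(list(K = K, K_requested = K, q = q,
                 theta = matrix(0, q, K), sigma2 = rep(1, K),
                 pi = rep(1 / K, K), resp = resp,
                 logdens = matrix(0, n, K), loglik = loglik,
                 n_iter = 1L, converged = TRUE, degenerate = FALSE,
                 n = n, p = rep(N / n, n), N = N, scale = "w",
                 transform = NULL, design = NULL),
            class = "mixture_fit")
}
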