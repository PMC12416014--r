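#' Log-density of one subject under one mixture component
#'
#' The multivariate normal log-density of a subject's trajectory under the
#' conditional-independence model Sigma_ik = sigma2_k I:
#' `-(p_i/2) log(2 pi sigma2_k) - ||y_i - X_i theta_k||^2 / (2 sigma2_k)`.
#'
#' @param y_i numeric response vector of length p_i.
#' @param X_i p_i x q design matrix.
#' @param theta_k coefficient vector of length q.
#' @param sigma2_k positive residual variance.
#' @return The log-density, a scalar.
#' @export
component_loglik <- function(y_i, X_i, theta_k, sigma2_k) {
  X_i <- as.matrix(X_i)
  if (length(y_i) != nrow(X_i) || length(theta_k) != ncol(X_i))
    stop("dimension mismatch between y_i (", length(y_i), "), X_i (",
         nrow(X_i), "x", ncol(X_i), ") and theta_k (", length(theta_k), ")")
  if (sigma2_k <= 0) stop("sigma2_k must be positive")
  r <- y_i - drop(X_i %*% theta_k)
  -(length(y_i) / 2) * log(2 * pi * sigma2_k) - sum(r^2) / (2 * sigma2_k)
}

# n x K matrix of per-subject log component densities.
# y, X stacked over measurements; sidx maps rows to subjects 1..n.
.logdens_matrix <- function(y, X, sidx, n, p, theta, sigma2) {
  K <- length(sigma2)
  fitted <- X %*% theta                     # N x K
  rss <- rowsum((y - fitted)^2, sidx, reorder = FALSE)  # n x K
  # sidx is 1..n in order of first appearance so rows align with subjects
  sweep(rss, 2, -1 / (2 * sigma2), `*`) -
    outer(p / 2, log(2 * pi * sigma2))
}

.logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

#' E-step: posterior membership probabilities
#'
#' Computes the n x K responsibility matrix r_ik proportional to
#' `pi_k f_k(y_i | X_i)`, normalized per subject via log-sum-exp.
#'
#' @param data a [longitudinal_data] object.
#' @param X stacked design matrix from [build_design()].
#' @param params list with `theta` (q x K matrix), `sigma2` (length K),
#'   `pi` (length K); as held in a [mixture_fit].
#' @return List with `resp` (n x K responsibilities), `loglik` (mixture
#'   log-likelihood) and `logdens` (n x K component log-densities).
#' @export
e_step <- function(data, X, params) {
  L <- .logdens_matrix(data$y, X, data$sidx, data$n, data$p,
                       params$theta, params$sigma2)
  A <- sweep(L, 2, log(params$pi), `+`)
  lse <- .logsumexp_rows(A)
  if (any(!is.finite(lse)))
    stop("all components underflow for subject ",
         data$subjects[which(!is.finite(lse))[1]], "; try another start")
  list(resp = exp(A - lse), loglik = sum(lse), logdens = L)
}

#' M-step: weighted maximum-likelihood parameter updates
#'
#' Given responsibilities, each component's coefficients solve a weighted
#' least-squares problem in which all of subject i's rows carry the weight
#' r_ik; variances are responsibility-weighted mean squared residuals with
#' denominator `sum_i r_ik p_i`, and mixing proportions are column means
#' of the responsibilities.
#'
#' @inheritParams e_step
#' @param resp n x K responsibility matrix with rows summing to 1.
#' @return A params list (`theta`, `sigma2`, `pi`).
#' @export
m_step <- function(data, X, resp) {
  resp <- as.matrix(resp)
  K <- ncol(resp)
  q <- ncol(X)
  theta <- matrix(0, q, K)
  sigma2 <- numeric(K)
  for (k in seq_len(K)) {
    w <- resp[data$sidx, k]
    A <- crossprod(X * w, X)
    b <- crossprod(X, w * data$y)
    th <- tryCatch(solve(A, b), error = function(e)
      stop("singular weighted normal equations in component ", k,
           " (responsibility mass ", format(sum(resp[, k])), ")"))
    res2 <- (data$y - drop(X %*% th))^2
    theta[, k] <- th
    sigma2[k] <- sum(w * res2) / sum(w * 1)  # sum(w) = sum_i r_ik p_i
  }
  list(theta = theta, sigma2 = sigma2, pi = colMeans(resp))
}

# order components by fitted mean at the earliest observed time, ascending
.canonicalize <- function(fit, x0) {
  mu0 <- drop(crossprod(fit$theta, x0))
  ord <- order(mu0)
  fit$theta <- fit$theta[, ord, drop = FALSE]
  fit$sigma2 <- fit$sigma2[ord]
  fit$pi <- fit$pi[ord]
  fit$resp <- fit$resp[, ord, drop = FALSE]
  fit$logdens <- fit$logdens[, ord, drop = FALSE]
  fit
}

#' Fit a K-component trajectory mixture by EM
#'
#' Maximum-likelihood estimation of the normal mixture of linear
#' regressions with subject-level cluster membership. Starting from a
#' crisp partition of subjects (followed by one M-step), the algorithm
#' alternates E and M steps until the relative change in log-likelihood
#' falls below `tol` or `max_iter` iterations are reached. A component
#' whose prior falls below `min_prior` is dropped and the fit continues
#' with fewer components, so the effective `K` of the returned fit can be
#' smaller than requested. A fit whose smallest variance falls below a
#' floor (`var_floor_factor * var(y)`) is flagged degenerate.
#'
#' Components of the returned fit are relabeled in ascending order of the
#' fitted mean at the earliest observed time, so results are invariant to
#' internal label switching.
#'
#' @inheritParams e_step
#' @param K number of mixture components requested (1 <= K <= n).
#' @param init optional integer vector of length n: initial crisp
#'   component assignment of each subject. Default: random partition drawn
#'   from the current RNG state.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of EM iterations.
#' @param min_prior components with mixing proportion below this are
#'   dropped (set to 0 to disable).
#' @param var_floor_factor variance floor as a fraction of `var(data$y)`.
#' @param engine `"cpp"` (default) runs the compiled EM loop; `"R"` runs
#'   the reference implementation built from [e_step()] and [m_step()].
#'   Both produce identical results.
#' @return An object of class `mixture_fit`: fields `K` (effective number
#'   of components), `K_requested`, `q`, `theta` (q x K), `sigma2`, `pi`,
#'   `resp` (n x K), `logdens`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `degenerate`, `n`, `p`, `N`, `scale`, and optionally
#'   `transform` (a `transform_context`) and `design`.
#' @export
fit_em <- function(data, X, K, init = NULL, tol = 1e-6, max_iter = 200,
                   min_prior = 0.05, var_floor_factor = 1e-10,
                   engine = c("cpp", "R")) {
  stopifnot(inherits(data, "longitudinal_data"), K >= 1)
  engine <- match.arg(engine)
  if (data$n < K) stop("need at least K subjects (n = ", data$n,
                       ", K = ", K, ")")
  if (is.null(init)) init <- .random_partition(data$n, K)
  stopifnot(length(init) == data$n)
  var_floor <- var_floor_factor * stats::var(data$y)
  x0 <- X[which.min(data$time), ]

  resp <- matrix(0, data$n, max(init))
  resp[cbind(seq_len(data$n), init)] <- 1
  resp <- resp[, colSums(resp) > 0, drop = FALSE]

  res <- if (engine == "cpp")
    .em_engine(data$y, X, data$sidx, data$p, resp, tol, max_iter,
               min_prior, var_floor)
  else
    .em_loop_r(data, X, resp, tol, max_iter, min_prior, var_floor)

  fit <- structure(
    list(K = length(res$pi), K_requested = as.integer(K), q = ncol(X),
         theta = matrix(res$theta, ncol = length(res$pi)),
         sigma2 = as.numeric(res$sigma2), pi = as.numeric(res$pi),
         resp = matrix(res$resp, nrow = data$n),
         logdens = matrix(res$logdens, nrow = data$n),
         loglik = res$loglik, loglik_trace = as.numeric(res$trace),
         n_iter = res$n_iter, converged = res$converged,
         degenerate = res$degenerate,
         n = data$n, p = data$p, N = data$N, scale = "w",
         transform = NULL, design = attr(X, "spec")),
    class = "mixture_fit")
  .canonicalize(fit, x0)
}

# reference EM loop in R, built from the exported e_step / m_step
.em_loop_r <- function(data, X, resp, tol, max_iter, min_prior, var_floor) {
  params <- m_step(data, X, resp)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  iter <- 0L
  repeat {
    if (any(params$sigma2 < var_floor)) {
      degenerate <- TRUE
      params$sigma2 <- pmax(params$sigma2, var_floor)
    }
    es <- e_step(data, X, params)
    trace <- c(trace, es$loglik)
    if (degenerate) break
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- es$loglik
    params <- m_step(data, X, es$resp)
    iter <- iter + 1L
    if (min_prior > 0 && length(params$pi) > 1L &&
        any(params$pi < min_prior)) {
      keep <- params$pi >= min_prior
      if (!any(keep)) keep[which.max(params$pi)] <- TRUE
      params$theta <- params$theta[, keep, drop = FALSE]
      params$sigma2 <- params$sigma2[keep]
      params$pi <- params$pi[keep] / sum(params$pi[keep])
      ll_prev <- -Inf  # likelihood not comparable across K
    }
  }
  list(theta = params$theta, sigma2 = params$sigma2, pi = params$pi,
       resp = es$resp, logdens = es$logdens, loglik = es$loglik,
       trace = trace, n_iter = iter, converged = converged,
       degenerate = degenerate)
}

# random crisp partition of n subjects into K non-empty groups
.random_partition <- function(n, K) {
  z <- sample.int(K, n, replace = TRUE)
  for (k in seq_len(K)) {
    if (!any(z == k)) {
      # steal a subject from the largest group
      big <- which.max(tabulate(z, K))
      z[sample(which(z == big), 1L)] <- k
    }
  }
  z
}

#' Multistart EM
#'
#' Runs [fit_em()] from `n_restarts` random crisp-partition
#' initializations (deterministic given `seed`; restart r uses
#' `seed + r`) and returns the fit with the highest log-likelihood,
#' preferring non-degenerate fits.
#'
#' @inheritParams fit_em
#' @param n_restarts number of random restarts (>= 1).
#' @param seed integer base seed.
#' @param ... passed to [fit_em()].
#' @return The best `mixture_fit`.
#' @export
fit_multistart <- function(data, X, K, n_restarts = 10, seed = 1, ...) {
  stopifnot(n_restarts >= 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    fit <- fit_em(data, X, K, init = .random_partition(data$n, K), ...)
    if (is.null(best)) best <- fit
    else {
      better <- (fit$loglik > best$loglik)
      if ((best$degenerate && !fit$degenerate) ||
          (better && fit$degenerate == best$degenerate)) best <- fit
    }
  }
  if (best$degenerate)
    stop(structure(class = c("trajmix_degenerate", "error", "condition"),
                   list(message = paste0("all ", n_restarts,
                        " restarts degenerate for K = ", K),
                        call = sys.call())))
  best
}

#' Classify subjects by maximum posterior probability
#'
#' @param fit a [mixture_fit].
#' @return Integer vector of length n; ties go to the smallest component
#'   index.
#' @export
posterior_classify <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  max.col(fit$resp, ties.method = "first")
}

#' @export
print.mixture_fit <- function(x, digits = 4, ...) {
  cat("Trajectory mixture fit: K =", x$K,
      if (x$K != x$K_requested) paste0("(requested ", x$K_requested, ")"),
      " logLik =", format(x$loglik, digits = 10), "\n")
  cat("  pi:    ", paste(format(x$pi, digits = digits), collapse = "  "), "\n")
  cat("  sigma: ", paste(format(sqrt(x$sigma2), digits = digits),
                         collapse = "  "), "\n")
  cat("  theta:\n")
  print(round(x$theta, digits))
  cat("  ", x$n_iter, "EM iterations,",
      if (x$converged) "converged" else "not converged",
      if (x$degenerate) "(degenerate)", "\n")
  if (!is.null(x$transform))
    cat("  fitted on scaled Box-Cox scale, lambda =",
        x$transform$lambda, "\n")
  invisible(x)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$loglik, df = count_free_params(object$K, object$q, TRUE),
            class = "logLik")
}
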