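#' Number of free parameters of a K-component fit
#'
#' `K*q` regression coefficients, `K` variances, `K - 1` free mixing
#' proportions, plus one for the transformation parameter when lambda was
#' estimated from the data.
#'
#' @param K number of mixture components.
#' @param q number of regression coefficients per component.
#' @param lambda_estimated logical; was lambda estimated (default `TRUE`)?
#' @return Integer parameter count h.
#' @export
count_free_params <- function(K, q, lambda_estimated = TRUE) {
  stopifnot(K >= 1, q >= 1)
  as.integer(K * q + K + (K - 1) + as.integer(isTRUE(lambda_estimated)))
}

#' Information criteria for a mixture fit
#'
#' AIC = -2l + 2h, BIC = -2l + log(N) h, and ICL = -2 l_ICL + log(N) h,
#' where l is the mixture log-likelihood, N the total number of
#' measurements, h the free-parameter count from [count_free_params()],
#' and l_ICL the classification log-likelihood
#' `sum_i [log pi_{z_i} + log f_{z_i}(y_i | X_i)]` with z_i the
#' maximum-a-posteriori component of subject i. When the fit was obtained
#' on scaled Box-Cox observations the criteria are those of the
#' scaled-observation likelihood, which is comparable across lambda.
#'
#' @param fit a converged [mixture_fit].
#' @param N total number of measurements (default: taken from the fit).
#' @param lambda_estimated whether to count lambda in h. Default `TRUE`
#'   when the fit carries a transform context. Both conventions occur in
#'   applied work; see the vignette.
#' @return An object of class `criterion_set`: list with `loglik`, `h`,
#'   `N`, `aic`, `bic`, `icl`.
#' @export
criteria <- function(fit, N = fit$N,
                     lambda_estimated = !is.null(fit$transform)) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (N <= 0) stop("N must be positive")
  h <- count_free_params(fit$K, fit$q, lambda_estimated)
  z <- posterior_classify(fit)
  idx <- cbind(seq_len(fit$n), z)
  l_icl <- sum(log(fit$pi)[z] + fit$logdens[idx])
  structure(list(
    loglik = fit$loglik, h = h, N = as.integer(N),
    aic = -2 * fit$loglik + 2 * h,
    bic = -2 * fit$loglik + log(N) * h,
    icl = -2 * l_icl + log(N) * h
  ), class = "criterion_set")
}

#' @export
print.criterion_set <- function(x, ...) {
  cat("logLik =", format(x$loglik, digits = 10), " h =", x$h, " N =", x$N,
      "\n AIC =", format(x$aic, digits = 10),
      " BIC =", format(x$bic, digits = 10),
      " ICL =", format(x$icl, digits = 10), "\n")
  invisible(x)
}

# Evaluate fits over a lambda grid for several K at once, sharing the
# transformed datasets across K. Returns per-K profiles and the best fit
# per K (by scaled log-likelihood). Degenerate (all-restart-collapse)
# cells are NA.
.profile_engine <- function(data, design, Ks, lambdas, n_restarts = 10,
                            seed = 1, shift = 0, ...) {
  X <- build_design(data, design)
  nl <- length(lambdas)
  loglik <- matrix(NA_real_, length(Ks), nl,
                   dimnames = list(paste0("K", Ks), NULL))
  best <- vector("list", length(Ks))
  for (j in seq_len(nl)) {
    td <- transform_dataset(data, lambdas[j], shift = shift)
    for (m in seq_along(Ks)) {
      fit <- tryCatch(
        fit_multistart(td$data, X, Ks[m], n_restarts = n_restarts,
                       seed = seed + 7919L * m, ...),
        trajmix_degenerate = function(e) NULL)
      if (is.null(fit)) next
      fit$transform <- td$context
      loglik[m, j] <- fit$loglik
      if (is.null(best[[m]]) || fit$loglik > best[[m]]$loglik)
        best[[m]] <- fit
    }
  }
  list(Ks = Ks, lambdas = lambdas, loglik = loglik, best = best,
       n_evals = nl * length(Ks))
}

.make_profile <- function(eng, m) {
  ll <- eng$loglik[m, ]
  if (all(is.na(ll)))
    stop("no non-degenerate fit at any lambda for K = ", eng$Ks[m])
  structure(list(
    K = eng$Ks[m], lambdas = eng$lambdas, loglik = ll,
    lambda_hat = eng$lambdas[which.max(ll)],
    fit = eng$best[[m]], n_evals = length(ll)
  ), class = "lambda_profile")
}

#' Profile the transformation parameter over a grid
#'
#' For each lambda in `grid`, transforms the data with the scaled Box-Cox
#' map and fits the K-component mixture by multistart EM; because the
#' scaled transformation has unit Jacobian, the resulting log-likelihoods
#' are directly comparable and `lambda_hat` is the grid point with the
#' largest one.
#'
#' @param data a [longitudinal_data] with positive responses.
#' @param design a [design_spec].
#' @param K number of components.
#' @param grid numeric vector of candidate lambda values.
#' @param n_restarts,seed passed to [fit_multistart()].
#' @param shift additive shift applied before transforming.
#' @param ... passed to [fit_em()].
#' @return An object of class `lambda_profile`: `lambdas`, per-lambda
#'   `loglik` (NA where all restarts collapsed), `lambda_hat`, the best
#'   `fit`, and `n_evals`.
#' @export
profile_lambda_grid <- function(data, design, K, grid = seq(-2, 2, by = 0.05),
                                n_restarts = 10, seed = 1, shift = 0, ...) {
  stopifnot(length(grid) >= 1)
  eng <- .profile_engine(data, design, K, grid, n_restarts, seed, shift, ...)
  .make_profile(eng, 1L)
}

#' Optimized lambda search by successive grid refinement
#'
#' Searches `range` with three successive grids of 11 points each — step
#' 1.0 over the full range, then step 0.2 around the current best, then
#' step 0.04 around the refined best — for a total of 33 likelihood
#' evaluations and a final resolution of 0.04. On a unimodal profile the
#' result matches a dense grid search to within the final step.
#'
#' @inheritParams profile_lambda_grid
#' @param range numeric length-2 search interval for lambda.
#' @return A `lambda_profile` whose `lambdas`/`loglik` record all 33
#'   evaluated points in evaluation order.
#' @export
optimized_lambda_search <- function(data, design, K, range = c(-5, 5),
                                    n_restarts = 10, seed = 1, shift = 0,
                                    ...) {
  stopifnot(length(range) == 2, range[1] < range[2])
  window <- function(center, half, step) {
    lo <- min(max(center - half, range[1]), range[2] - 2 * half)
    lo + step * 0:10
  }
  stages <- list(seq(range[1], range[2], length.out = 11))
  all_l <- numeric(0); all_ll <- numeric(0); best_fit <- NULL
  for (s in 1:3) {
    g <- stages[[s]]
    eng <- .profile_engine(data, design, K, g, n_restarts,
                           seed = seed + 31L * s, shift = shift, ...)
    ll <- eng$loglik[1, ]
    all_l <- c(all_l, g); all_ll <- c(all_ll, ll)
    if (!is.null(eng$best[[1]]) &&
        (is.null(best_fit) || eng$best[[1]]$loglik > best_fit$loglik))
      best_fit <- eng$best[[1]]
    if (all(is.na(ll)))
      stop("no non-degenerate fit at any lambda in stage ", s,
           " for K = ", K)
    center <- g[which.max(ll)]
    if (s == 1) stages[[2]] <- window(center, 1, 0.2)
    if (s == 2) stages[[3]] <- window(center, 0.2, 0.04)
  }
  structure(list(
    K = K, lambdas = all_l, loglik = all_ll,
    lambda_hat = all_l[which.max(all_ll)],
    fit = best_fit, n_evals = length(all_l)
  ), class = "lambda_profile")
}

#' @export
print.lambda_profile <- function(x, ...) {
  cat("Lambda profile (K =", x$K, "):", x$n_evals, "evaluations,",
      "lambda_hat =", x$lambda_hat, "\n")
  invisible(x)
}

#' Joint selection of the number of components and lambda
#'
#' For each K in `K_range`, estimates lambda by the requested method
#' (held fixed, grid profile, or optimized refinement search), keeps the
#' fit at that K's maximum-likelihood lambda, and computes AIC, BIC and
#' ICL on the scaled-observation likelihood. The selected number of
#' clusters per criterion is the effective number of components of the
#' criterion-minimizing fit, with ties (within 1e-6) broken toward the
#' smaller K. Requested K whose restarts all collapse are excluded.
#'
#' @inheritParams profile_lambda_grid
#' @param K_range integer vector of candidate component counts.
#' @param lambda_method one of `"grid"`, `"fixed"`, `"optimized"`.
#' @param lambda fixed lambda value (`lambda_method = "fixed"`) or the
#'   grid (`"grid"`); ignored for `"optimized"`.
#' @param range search interval for `"optimized"`.
#' @param criterion criterion reported as `K_selected`; all three are
#'   tabulated.
#' @param count_lambda logical: count lambda as a free parameter in h when
#'   it was estimated (default `TRUE`; ignored and set `FALSE` for fixed
#'   lambda).
#' @param criterion_nobs sample size N entering the BIC/ICL penalty
#'   `log(N) h`: `"measurements"` (the default, the total number of
#'   measurements) or `"subjects"` (the number of trajectories, the
#'   convention of much group-based trajectory software). AIC is
#'   unaffected.
#' @return An object of class `model_search`: `table` (one row per
#'   requested K: effective K, lambda_hat, loglik, h, aic, bic, icl),
#'   `fits`, `selected` (named list of identified k per criterion) and
#'   `K_selected` for `criterion`.
#' @export
select_model <- function(data, design, K_range = 1:5,
                         lambda_method = c("grid", "fixed", "optimized"),
                         lambda = seq(-2, 2, by = 0.05), range = c(-5, 5),
                         criterion = c("bic", "aic", "icl"),
                         n_restarts = 10, seed = 1, shift = 0,
                         count_lambda = TRUE,
                         criterion_nobs = c("measurements", "subjects"),
                         ...) {
  lambda_method <- match.arg(lambda_method)
  criterion <- match.arg(criterion)
  criterion_nobs <- match.arg(criterion_nobs)
  N_pen <- if (criterion_nobs == "measurements") data$N else data$n
  stopifnot(length(K_range) >= 1)
  K_range <- sort(unique(as.integer(K_range)))

  lambda_estimated <- count_lambda && lambda_method != "fixed"
  profiles <- vector("list", length(K_range))
  if (lambda_method == "optimized") {
    for (m in seq_along(K_range))
      profiles[[m]] <- tryCatch(
        optimized_lambda_search(data, design, K_range[m], range = range,
                                n_restarts = n_restarts,
                                seed = seed + 104729L * m, shift = shift,
                                ...),
        error = function(e) NULL)
  } else {
    grid <- if (lambda_method == "fixed") lambda[1] else lambda
    eng <- .profile_engine(data, design, K_range, grid, n_restarts, seed,
                           shift, ...)
    for (m in seq_along(K_range))
      profiles[[m]] <- tryCatch(.make_profile(eng, m),
                                error = function(e) NULL)
  }

  rows <- lapply(seq_along(K_range), function(m) {
    pr <- profiles[[m]]
    if (is.null(pr))
      return(data.frame(K_requested = K_range[m], K = NA_integer_,
                        lambda_hat = NA_real_, loglik = NA_real_,
                        h = NA_integer_, aic = NA_real_, bic = NA_real_,
                        icl = NA_real_))
    cs <- criteria(pr$fit, N = N_pen, lambda_estimated = lambda_estimated)
    data.frame(K_requested = K_range[m], K = pr$fit$K,
               lambda_hat = pr$lambda_hat, loglik = cs$loglik, h = cs$h,
               aic = cs$aic, bic = cs$bic, icl = cs$icl)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$K)))
    stop("no non-degenerate fit for any K in K_range")

  pick <- function(values) {
    ok <- which(!is.na(values))
    best <- min(values[ok])
    cand <- ok[values[ok] <= best + 1e-6]
    as.integer(min(tab$K[cand]))
  }
  selected <- list(aic = pick(tab$aic), bic = pick(tab$bic),
                   icl = pick(tab$icl))

  structure(list(
    table = tab, fits = lapply(profiles, function(p) p$fit),
    profiles = profiles, selected = selected,
    criterion = criterion, K_selected = selected[[criterion]],
    lambda_method = lambda_method, lambda_estimated = lambda_estimated,
    criterion_nobs = criterion_nobs
  ), class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("Model search (", x$lambda_method, " lambda):\n", sep = "")
  print(transform(x$table,
                  loglik = round(loglik, 2), aic = round(aic, 2),
                  bic = round(bic, 2), icl = round(icl, 2)),
        row.names = FALSE)
  cat("Selected k:  AIC =", x$selected$aic, " BIC =", x$selected$bic,
      " ICL =", x$selected$icl, "\n")
  invisible(x)
}

#' Write a model-search table as CSV
#'
#' @param search a `model_search` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_csv <- function(search, path) {
  stopifnot(inherits(search, "model_search"))
  utils::write.csv(search$table, path, row.names = FALSE)
  invisible(path)
}
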