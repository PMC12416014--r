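#' Geometric mean of all responses
#'
#' The N-th root of the product of all N measurements, computed in log
#' space so that large N cannot overflow the product.
#'
#' @param data a [longitudinal_data] object or a numeric vector of
#'   strictly positive values.
#' @return The geometric mean, a positive scalar.
#' @export
#' @examples
#' geometric_mean(c(1, 2, 4))  # 2
geometric_mean <- function(data) {
  y <- if (inherits(data, "longitudinal_data")) data$y else as.numeric(data)
  bad <- which(y <= 0)
  if (length(bad)) {
    where <- if (inherits(data, "longitudinal_data"))
      paste0("subject ", data$subjects[data$sidx[bad[1]]],
             ", measurement row ", bad[1])
    else paste0("element ", bad[1])
    stop("nonpositive response (", y[bad[1]], ") at ", where,
         "; the geometric mean requires y > 0")
  }
  exp(mean(log(y)))
}

# lambda values closer to zero than this use the log branch; continuity of
# the transform makes the cutoff inconsequential at double precision.
.LAMBDA_EPS <- 1e-10

#' Box-Cox power transformation
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for `lambda = 0`.
#'
#' @param y strictly positive numeric values.
#' @param lambda transformation parameter.
#' @return Transformed values, same shape as `y`.
#' @export
boxcox <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox transformation requires y > 0; found ",
                        min(y))
  if (abs(lambda) < .LAMBDA_EPS) log(y)
  else (exp(lambda * log(y)) - 1) / lambda
}

#' Scaled Box-Cox transformation
#'
#' The Box-Cox transform divided by `gmean^(lambda - 1)`, where `gmean` is
#' the geometric mean of the full sample:
#' `w = (y^lambda - 1) / (lambda * gmean^(lambda - 1))` for `lambda != 0`
#' and `w = gmean * log(y)` for `lambda = 0`. The scaling absorbs the
#' Jacobian of the transformation, so Gaussian log-likelihoods of the
#' scaled observations are directly comparable across lambda values.
#'
#' @param y strictly positive numeric values.
#' @param lambda transformation parameter.
#' @param gmean positive geometric mean of the sample `y` belongs to.
#' @return Transformed values, same shape as `y`.
#' @export
#' @examples
#' scaled_boxcox(c(1, 2, 4), lambda = 2, gmean = 2)  # (y^2 - 1)/4
scaled_boxcox <- function(y, lambda, gmean) {
  if (any(y <= 0)) stop("scaled Box-Cox transformation requires y > 0; found ",
                        min(y))
  if (gmean <= 0) stop("gmean must be positive")
  if (abs(lambda) < .LAMBDA_EPS) gmean * log(y)
  else (exp(lambda * log(y)) - 1) / (lambda * exp((lambda - 1) * log(gmean)))
}

#' Transform a dataset to the scaled Box-Cox scale
#'
#' Replaces every response by its scaled Box-Cox transform, using the
#' dataset's own geometric mean; ids, times and the grouping structure are
#' unchanged. An optional additive shift `y + shift` is applied before the
#' transformation for semicontinuous responses with zeros; the shift is
#' recorded in the returned context.
#'
#' @param data a [longitudinal_data] object with (after shifting) strictly
#'   positive responses.
#' @param lambda transformation parameter.
#' @param shift additive constant applied to responses before transforming
#'   (default 0).
#' @return A list with components `data` (the transformed
#'   [longitudinal_data]) and `context` (class `transform_context`: fields
#'   `lambda`, `gmean`, `N`, `shift`).
#' @export
transform_dataset <- function(data, lambda, shift = 0) {
  stopifnot(inherits(data, "longitudinal_data"))
  y <- data$y + shift
  bad <- which(y <= 0)
  if (length(bad))
    stop("nonpositive response after shift (", y[bad[1]], ") at subject ",
         data$subjects[data$sidx[bad[1]]], ", row ", bad[1],
         "; supply a larger shift or remove zeros")
  gmean <- exp(mean(log(y)))
  w <- scaled_boxcox(y, lambda, gmean)
  out <- data
  out$y <- w
  context <- structure(
    list(lambda = lambda, gmean = gmean, N = data$N, shift = shift),
    class = "transform_context")
  list(data = out, context = context)
}

#' @export
print.transform_context <- function(x, ...) {
  cat("Scaled Box-Cox context: lambda =", x$lambda,
      " gmean =", format(x$gmean), " N =", x$N,
      if (x$shift != 0) paste(" shift =", x$shift) else "", "\n")
  invisible(x)
}

#' Convert scaled-scale estimates to the Box-Cox scale
#'
#' Mixture parameters estimated from scaled observations w(lambda) are
#' mapped back to the plain Box-Cox scale y(lambda) by the factor
#' `gmean^(lambda - 1)`: coefficients and residual standard deviations are
#' multiplied by it, mixing proportions and responsibilities are unchanged.
#' The conversion is only defined for balanced data (equal numbers of
#' measurements per subject).
#'
#' @param fit_w a [mixture_fit] estimated on the scaled (w) scale.
#' @param context the `transform_context` returned by [transform_dataset()].
#' @return A `mixture_fit` with `theta` and `sqrt(sigma2)` rescaled and a
#'   `scale` field set to `"boxcox"`.
#' @export
convert_estimates <- function(fit_w, context) {
  stopifnot(inherits(fit_w, "mixture_fit"),
            inherits(context, "transform_context"))
  if (length(unique(fit_w$p)) != 1L)
    stop("conversion to the Box-Cox scale is only supported for balanced ",
         "data (p_1 = ... = p_n); this fit has ragged measurement counts")
  fac <- exp((context$lambda - 1) * log(context$gmean))
  out <- fit_w
  out$theta <- fit_w$theta * fac
  out$sigma2 <- fit_w$sigma2 * fac^2
  out$scale <- "boxcox"
  out$transform <- context
  out
}
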