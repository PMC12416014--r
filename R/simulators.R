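#' Define a trajectory-mixture simulation scenario
#'
#' A scenario specifies component mean functions on a common time grid, the
#' mixing proportions, an error law, and a link: responses are
#' `link(mean_k(x_j) + e_ij)` where the subject's component k is drawn
#' from `prob` and the errors are i.i.d. draws from `error`. With
#' `link = "exp"` the error enters inside the exponent, so the log
#' responses are exactly distributed as `mean + error`.
#'
#' @param name scenario label.
#' @param n number of subjects.
#' @param times numeric time grid x_j shared by all subjects.
#' @param means list of mean functions of time, one per component.
#' @param prob mixing proportions (must sum to 1).
#' @param error error law: `list(dist = "normal", sd = )` or
#'   `list(dist = "gamma", shape = , scale = )`.
#' @param link `"identity"` or `"exp"`.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, n, times, means, prob,
                     error = list(dist = "normal", sd = 1),
                     link = c("identity", "exp")) {
  link <- match.arg(link)
  if (abs(sum(prob) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (length(means) != length(prob))
    stop("one mean function per mixing proportion required")
  structure(list(name = name, n = as.integer(n), times = as.numeric(times),
                 means = means, prob = prob, error = error, link = link),
            class = "scenario")
}

# registry of the built-in scenarios; eps ~ N(0, 0.5^2) inside the
# exponent for M1-M3 (lognormal trajectories, x_j = (j-1)/9, j = 1..10),
# additive Gamma(shape 2, scale 1) errors for S1-S4 (x_j = (j-1)/5,
# j = 1..6, means 1 and 1 + 2x).
.scenario_registry <- function(name, n = NULL) {
  x10 <- (0:9) / 9
  x6 <- (0:5) / 5
  norm05 <- list(dist = "normal", sd = 0.5)
  gam21 <- list(dist = "gamma", shape = 2, scale = 1)
  switch(name,
    M1 = scenario("M1", n %||% 200, x10,
                  list(function(x) 1 + 0.2 * x), 1, norm05, "exp"),
    M2 = scenario("M2", n %||% 200, x10,
                  list(function(x) 1 + 0 * x, function(x) 1 + x),
                  c(0.6, 0.4), norm05, "exp"),
    M3 = scenario("M3", n %||% 200, x10,
                  list(function(x) 1 + 0 * x, function(x) 1 + x,
                       function(x) 1 + x + x^2),
                  c(0.5, 0.3, 0.2), norm05, "exp"),
    S1 = scenario("S1", n %||% 200, x6,
                  list(function(x) 1 + 0 * x, function(x) 1 + 2 * x),
                  c(0.5, 0.5), gam21, "identity"),
    S2 = scenario("S2", n %||% 200, x6,
                  list(function(x) 1 + 0 * x, function(x) 1 + 2 * x),
                  c(0.8, 0.2), gam21, "identity"),
    S3 = scenario("S3", n %||% 500, x6,
                  list(function(x) 1 + 0 * x, function(x) 1 + 2 * x),
                  c(0.5, 0.5), gam21, "identity"),
    S4 = scenario("S4", n %||% 500, x6,
                  list(function(x) 1 + 0 * x, function(x) 1 + 2 * x),
                  c(0.8, 0.2), gam21, "identity"),
    stop("unknown scenario '", name, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a user-defined trajectory mixture
#'
#' Draws each subject's component from the scenario's mixing proportions,
#' adds i.i.d. errors to the component mean on the time grid, applies the
#' link, and returns a labeled [longitudinal_data]. All randomness comes
#' from R's default Mersenne-Twister generator seeded with `seed`, so a
#' (scenario, seed) pair reproduces the dataset exactly; labels are drawn
#' first, then the n x length(times) error matrix row by row.
#'
#' @param scn a [scenario].
#' @param seed integer seed.
#' @return A [longitudinal_data] with `true_labels`.
#' @export
simulate_custom <- function(scn, seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(seed)
  K <- length(scn$prob)
  J <- length(scn$times)
  labels <- if (K == 1L) rep(1L, scn$n)
            else sample.int(K, scn$n, replace = TRUE, prob = scn$prob)
  eps <- switch(scn$error$dist,
    normal = matrix(stats::rnorm(scn$n * J, 0, scn$error$sd),
                    scn$n, J, byrow = TRUE),
    gamma = matrix(stats::rgamma(scn$n * J, shape = scn$error$shape,
                                 scale = scn$error$scale),
                   scn$n, J, byrow = TRUE),
    stop("unknown error distribution '", scn$error$dist, "'"))
  mu <- vapply(scn$means, function(f) f(scn$times), numeric(J))  # J x K
  eta <- t(mu)[labels, , drop = FALSE] + eps                     # n x J
  y <- if (scn$link == "exp") exp(eta) else eta
  longitudinal_data(
    id = rep(sprintf("s%04d", seq_len(scn$n)), each = J),
    time = rep(scn$times, scn$n),
    y = as.vector(t(y)),
    true_label = rep(labels, each = J)
  )
}

#' Simulate lognormal trajectory mixtures (study-1 models M1-M3)
#'
#' Responses are `exp(eta_k(x_j) + e_ij)` with `e_ij ~ N(0, 0.5^2)`,
#' `x_j = (j-1)/9`, `j = 1..10`: M1 has the single mean `1 + 0.2x`; M2
#' mixes `1` and `1 + x` with proportions (0.6, 0.4); M3 mixes `1`,
#' `1 + x` and `1 + x + x^2` with proportions (0.5, 0.3, 0.2). Log
#' responses are exactly normal, so the nominal Box-Cox parameter is 0.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param n number of subjects (default 200).
#' @param seed integer seed.
#' @return A [longitudinal_data] with `true_labels`.
#' @export
simulate_study1 <- function(model = c("M1", "M2", "M3"), n = 200, seed = 1) {
  model <- match.arg(model)
  simulate_custom(.scenario_registry(model, n), seed)
}

#' Simulate skewed additive-error mixtures (study-2 setups S1-S4)
#'
#' Two-component mixtures with means `1` and `1 + 2x_j` on
#' `x_j = (j-1)/5`, `j = 1..6`, and additive `Gamma(shape 2, scale 1)`
#' errors (mean 2, variance 2 — markedly right-skewed). Setups: S1
#' (n = 200, pi = 0.5/0.5), S2 (200, 0.8/0.2), S3 (500, 0.5/0.5), S4
#' (500, 0.8/0.2).
#'
#' @param setup `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param seed integer seed.
#' @return A [longitudinal_data] with `true_labels`.
#' @export
simulate_study2 <- function(setup = c("S1", "S2", "S3", "S4"), seed = 1) {
  setup <- match.arg(setup)
  simulate_custom(.scenario_registry(setup), seed)
}
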