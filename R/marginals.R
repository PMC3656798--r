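# Collapsed Gaussian marginals: theta is integrated out analytically, so all
# likelihood evaluation reduces to marginal likelihoods of sets of values and
# predictive densities of one value given a set. Everything is computed in log
# space and only exponentiated at the user-facing boundary.

# Log marginal likelihood of a set of observations with sufficient statistics
# (n, sum, sumsq) under y_i ~ N(theta, obs_var) iid, theta ~ N(prior_mean,
# prior_var). n = 0 gives 0 (empty product). prior_var = 0 is the point-mass
# base measure.
gaussian_marginal_loglik <- function(n, sum, sumsq, model) {
  if (n == 0L) return(0)
  s2 <- model$obs_var; m0 <- model$prior_mean; s02 <- model$prior_var
  if (s02 == 0) {
    return(-n / 2 * log(2 * pi * s2) - (sumsq - 2 * m0 * sum + n * m0^2) / (2 * s2))
  }
  tau <- 1 / s2; tau0 <- 1 / s02
  A <- n * tau + tau0
  B <- tau * sum + tau0 * m0
  -n / 2 * log(2 * pi * s2) - tau * sumsq / 2 -
    0.5 * log(2 * pi * s02) - tau0 * m0^2 / 2 +
    0.5 * log(2 * pi / A) + B^2 / (2 * A)
}

suff_stats <- function(values) {
  list(n = length(values), sum = sum(values), sumsq = sum(values^2))
}

# log predictive density of g given a conditioning set with stats (n,sum,sumsq)
log_dish_predictive <- function(g, n, sum, sumsq, model) {
  gaussian_marginal_loglik(n + 1L, sum + g, sumsq + g^2, model) -
    gaussian_marginal_loglik(n, sum, sumsq, model)
}

#' Prior-predictive density of an observation
#'
#' The marginal density \eqn{\int F(g \mid \theta)\, \mu_1(\theta)\, d\theta}
#' of a single expression value with the component mean integrated out against
#' the base measure. For the Gaussian-conjugate model this is the density of
#' \eqn{N(m_0, \sigma^2 + s_0^2)} at `g`.
#'
#' @param g observation value(s); finite numeric.
#' @param model an [obs_model()].
#' @param log return the log density.
#' @return density value(s), strictly positive.
#' @examples
#' prior_predictive(0, obs_model())   # 1/sqrt(4*pi) = 0.2820948
#' @export
prior_predictive <- function(g, model = obs_model(), log = FALSE) {
  stopifnot(inherits(model, "obs_model"))
  if (any(!is.finite(g))) stop("non-finite observation value")
  dnorm(g, mean = model$prior_mean, sd = sqrt(model$obs_var + model$prior_var), log = log)
}

#' Dish-conditional predictive density
#'
#' Density of one observation `g` given the multiset `S` of observations
#' currently assigned to the same mixture component (dish), with the
#' component mean integrated out:
#' \deqn{f(g \mid S) = \frac{\int F(g\mid\theta) \prod_{g' \in S} F(g'\mid\theta)\,
#'   \mu_1(\theta)\, d\theta}{\int \prod_{g' \in S} F(g'\mid\theta)\,
#'   \mu_1(\theta)\, d\theta}.}
#' For the Gaussian-conjugate model this is the posterior-predictive Gaussian
#' whose mean and variance are the conjugate update by `S`; with empty `S` it
#' reduces to [prior_predictive()]. The value depends on `S` only through its
#' size and sum (exchangeability).
#'
#' @param g observation value (scalar).
#' @param S numeric vector (multiset) of conditioning observations, possibly
#'   empty.
#' @param model an [obs_model()].
#' @param log return the log density.
#' @return scalar density.
#' @examples
#' m <- obs_model()
#' dish_predictive(0, numeric(0), m)  # = prior_predictive(0, m)
#' dish_predictive(0, 1, m)           # posterior-predictive N(0.5, 1.5) at 0
#' @export
dish_predictive <- function(g, S, model = obs_model(), log = FALSE) {
  stopifnot(inherits(model, "obs_model"), length(g) == 1L)
  if (!is.finite(g) || any(!is.finite(S))) stop("non-finite observation value")
  st <- suff_stats(S)
  lp <- log_dish_predictive(g, st$n, st$sum, st$sumsq, model)
  if (log) lp else exp(lp)
}

#' Monte-Carlo estimate of the predictive-density integrals
#'
#' Estimates the numerator \eqn{\int F(g\mid\theta)\prod_{S} F(g'\mid\theta)
#' \mu_1(\theta) d\theta} and denominator \eqn{\int \prod_{S} F(g'\mid\theta)
#' \mu_1(\theta) d\theta} of the dish predictive by simple Monte Carlo:
#' draw \eqn{\theta \sim \mu_1} and average the likelihood products. This is
#' the stochastic integration route; the closed form ([dish_predictive()]) is
#' the production path and this estimator serves as an independent check.
#'
#' @param g target observation value.
#' @param S conditioning multiset (numeric vector, possibly empty).
#' @param model an [obs_model()] with `prior_var > 0`.
#' @param n_draws number of Monte-Carlo draws, at least 100.
#' @param seed optional integer seed.
#' @return list with `numerator`, `denominator`, `ratio` (each an estimate),
#'   `numerator_se`, `denominator_se` (standard errors of the two integral
#'   estimates) and `n_draws`.
#' @export
mc_integrate <- function(g, S, model = obs_model(), n_draws = 10000L, seed = NULL) {
  stopifnot(inherits(model, "obs_model"), length(g) == 1L, is.finite(g),
            all(is.finite(S)))
  n_draws <- as.integer(n_draws)
  if (n_draws < 100L) stop("n_draws must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  theta <- rnorm(n_draws, model$prior_mean, sqrt(model$prior_var))
  sdF <- sqrt(model$obs_var)
  # log prod_{g' in S} F(g'|theta), vectorized over theta draws
  logden <- rep(0, n_draws)
  for (v in S) logden <- logden + dnorm(v, theta, sdF, log = TRUE)
  lognum <- logden + dnorm(g, theta, sdF, log = TRUE)
  den <- exp(logden); num <- exp(lognum)
  list(numerator = mean(num),
       denominator = mean(den),
       ratio = mean(num) / mean(den),
       numerator_se = sd(num) / sqrt(n_draws),
       denominator_se = sd(den) / sqrt(n_draws),
       n_draws = n_draws)
}

# Adaptive-quadrature oracle for the same ratio; kept independent of the
# closed form (integrates the actual likelihood products over theta on
# m0 +/- 12 combined SD). Used by tests; exported for transparency.
#' Quadrature evaluation of the dish predictive (test oracle)
#'
#' Evaluates the predictive-density ratio by adaptive quadrature over the
#' component mean instead of the conjugate closed form. Intended as an
#' independent numerical check of [dish_predictive()].
#'
#' @inheritParams mc_integrate
#' @return scalar density value.
#' @export
quad_dish_predictive <- function(g, S, model = obs_model()) {
  stopifnot(inherits(model, "obs_model"), model$prior_var > 0)
  sdF <- sqrt(model$obs_var)
  width <- 12 * sqrt(model$obs_var + model$prior_var)
  lo <- model$prior_mean - width; hi <- model$prior_mean + width
  f_prod <- function(theta, extra = NULL) {
    out <- dnorm(theta, model$prior_mean, sqrt(model$prior_var))
    for (v in S) out <- out * dnorm(v, theta, sdF)
    if (!is.null(extra)) out <- out * dnorm(extra, theta, sdF)
    out
  }
  num <- integrate(f_prod, lo, hi, extra = g, rel.tol = 1e-10)$value
  den <- integrate(f_prod, lo, hi, rel.tol = 1e-10)$value
  num / den
}
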