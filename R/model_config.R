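#' Gaussian observation model with conjugate prior on the mean
#'
#' The likelihood family for a single expression value is
#' \eqn{g \mid \theta \sim N(\theta, \sigma^2)} with known observation
#' variance \eqn{\sigma^2}; the base measure over the component mean is
#' \eqn{\theta \sim N(m_0, s_0^2)}. The sampler is fully collapsed:
#' \eqn{\theta} is never instantiated and all likelihood evaluations go
#' through the marginal (prior- and posterior-predictive) densities, which are
#' available in closed form under this conjugate pair.
#'
#' `prior_var = 0` is allowed and degenerates the base measure to a point mass
#' at `prior_mean`.
#'
#' @param obs_var observation variance \eqn{\sigma^2 > 0}.
#' @param prior_mean prior mean \eqn{m_0} of the component mean.
#' @param prior_var prior variance \eqn{s_0^2 \ge 0} of the component mean.
#' @return object of class `obs_model`.
#' @examples
#' obs_model()                      # N(0,1) base measure, unit noise
#' obs_model(obs_var = 0.25)
#' @export
obs_model <- function(obs_var = 1, prior_mean = 0, prior_var = 1) {
  stopifnot(is.numeric(obs_var), length(obs_var) == 1L, is.finite(obs_var), obs_var > 0)
  stopifnot(is.numeric(prior_mean), length(prior_mean) == 1L, is.finite(prior_mean))
  stopifnot(is.numeric(prior_var), length(prior_var) == 1L, is.finite(prior_var), prior_var >= 0)
  structure(list(obs_var = obs_var, prior_mean = prior_mean, prior_var = prior_var),
            class = "obs_model")
}

#' @export
print.obs_model <- function(x, ...) {
  cat(sprintf("Gaussian observation model: F = N(theta, %.4g), theta ~ N(%.4g, %.4g)\n",
              x$obs_var, x$prior_mean, x$prior_var))
  invisible(x)
}

#' HDP concentration hyperparameters
#'
#' Concentration parameters of the two Dirichlet-process levels:
#' `alpha0` governs the propensity of a customer to open a new table within
#' its experiment row, `alpha1` the propensity of a table to order a new
#' (global) dish. Both carry a Gamma(`gamma_shape`, `gamma_rate`) prior
#' (shape-rate convention); when `resample_concentrations` is `TRUE` the
#' sampler redraws both from this prior every sweep, otherwise they stay
#' fixed — the reproducible default.
#'
#' @param alpha0 table-level concentration, > 0.
#' @param alpha1 dish-level concentration, > 0.
#' @param gamma_shape,gamma_rate Gamma prior parameters, both > 0.
#' @param resample_concentrations logical; redraw alpha0/alpha1 each sweep.
#' @return object of class `hdp_hyper`.
#' @export
hdp_hyper <- function(alpha0 = 1, alpha1 = 1, gamma_shape = 1, gamma_rate = 1,
                      resample_concentrations = FALSE) {
  stopifnot(alpha0 > 0, alpha1 > 0, gamma_shape > 0, gamma_rate > 0,
            is.logical(resample_concentrations), length(resample_concentrations) == 1L)
  structure(list(alpha0 = alpha0, alpha1 = alpha1,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 resample_concentrations = resample_concentrations),
            class = "hdp_hyper")
}

#' @export
print.hdp_hyper <- function(x, ...) {
  cat(sprintf("HDP concentrations: alpha0 = %.4g, alpha1 = %.4g (Gamma(%.4g, %.4g) prior, resampling %s)\n",
              x$alpha0, x$alpha1, x$gamma_shape, x$gamma_rate,
              if (x$resample_concentrations) "on" else "off"))
  invisible(x)
}

#' Markov chain configuration
#'
#' @param burnin number of discarded warm-up sweeps \eqn{l_0 \ge 0}.
#' @param samples number of retained posterior snapshots \eqn{L \ge 1}.
#' @param thin keep one snapshot every `thin` post-burn-in sweeps.
#' @param seed integer seed for the run, or `NULL` to leave the RNG state
#'   untouched.
#' @param sampler `"direct"` draws each discrete label exactly from its
#'   normalized finite-support conditional; `"mh"` makes one
#'   Metropolis-Hastings step per label with a symmetric uniform proposal over
#'   the same support. Both target the same stationary distribution.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(burnin = 1000L, samples = 2000L, thin = 1L, seed = NULL,
                         sampler = c("direct", "mh")) {
  sampler <- match.arg(sampler)
  burnin <- as.integer(burnin); samples <- as.integer(samples); thin <- as.integer(thin)
  stopifnot(burnin >= 0L, samples >= 1L, thin >= 1L)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(burnin = burnin, samples = samples, thin = thin,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 sampler = sampler),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("chain: %d burn-in + %d samples (thin %d), %s sampler, seed %s\n",
              x$burnin, x$samples, x$thin, x$sampler,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
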