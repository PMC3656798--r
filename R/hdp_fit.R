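#' Cluster genes with a hierarchical Dirichlet process mixture
#'
#' Fits the two-level HDP mixture to a genes-by-experiments expression
#' matrix by collapsed Chinese-restaurant-franchise Gibbs sampling and
#' returns the aggregated membership posterior together with the MAP gene
#' clustering. The number of clusters is not fixed in advance; it is inferred
#' as the number of dishes supported by the posterior.
#'
#' Each expression value \eqn{g_{ji}} (gene `i`, experiment `j`) is modeled as
#' \eqn{N(\theta_{z_{ji}}, \sigma^2)} where the component means
#' \eqn{\theta_k \sim N(m_0, s_0^2)} are shared across experiments through
#' the hierarchy and integrated out analytically. A gene's cluster is the
#' label maximizing its experiment-aggregated membership probability.
#'
#' @param x an [expression_matrix()] or numeric matrix, genes as rows.
#' @param obs_var observation variance \eqn{\sigma^2}; the default 1 suits
#'   standardized (e.g. log-scale, unit-variance) data. The string
#'   `"pooled"` uses the pooled variance of all values.
#' @param prior_mean,prior_var base-measure parameters, see [obs_model()].
#' @param alpha0,alpha1 concentration parameters, see [hdp_hyper()].
#' @param gamma_shape,gamma_rate,resample_concentrations Gamma prior on the
#'   concentrations and whether to redraw them each sweep.
#' @param burnin,samples,thin,sampler chain settings, see [chain_config()].
#' @param init initialization mode, see [init_state()].
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param engine `"cpp"` (default) or `"r"`, see [run_chain()].
#' @param verbose print sweep progress.
#' @return an object of class `hdp_fit` with components `cluster` (named
#'   integer vector, the MAP partition), `K` (number of MAP clusters),
#'   `posterior` (a `membership_posterior`), `trace` (the `hdp_trace`),
#'   `data`, `model`, `hyper`, `config` and `call`.
#' @examples
#' sim <- gen_gaussian_clusters(K = 2, sizes = c(5, 5), means = c(-3, 3),
#'                              sd = 0.5, M = 3, seed = 1)
#' fit <- hdp_cluster(sim$data, burnin = 100, samples = 200, seed = 1)
#' fit$cluster
#' rand_index(fit$cluster, sim$truth)
#' @export
hdp_cluster <- function(x, obs_var = 1, prior_mean = 0, prior_var = 1,
                        alpha0 = 1, alpha1 = 1,
                        gamma_shape = 1, gamma_rate = 1,
                        resample_concentrations = FALSE,
                        burnin = 1000L, samples = 2000L, thin = 1L,
                        sampler = c("direct", "mh"),
                        init = "each-own-table",
                        seed = NULL, engine = c("cpp", "r"), verbose = FALSE) {
  cl <- match.call()
  x <- as_expression_matrix(x)
  if (identical(obs_var, "pooled")) obs_var <- var(as.vector(x))
  model <- obs_model(obs_var = obs_var, prior_mean = prior_mean, prior_var = prior_var)
  hyper <- hdp_hyper(alpha0 = alpha0, alpha1 = alpha1,
                     gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                     resample_concentrations = resample_concentrations)
  config <- chain_config(burnin = burnin, samples = samples, thin = thin,
                         seed = seed, sampler = match.arg(sampler))
  trace <- run_chain(x, model, hyper, config, init = init,
                     engine = match.arg(engine), verbose = verbose)
  post <- aggregate_posterior(trace)
  part <- map_assignment(post)
  structure(list(cluster = part, K = length(unique(part)),
                 posterior = post, trace = trace,
                 data = x, model = model, hyper = hyper, config = config,
                 call = cl),
            class = "hdp_fit")
}

#' @export
print.hdp_fit <- function(x, ...) {
  cat("Hierarchical Dirichlet process clustering\n\n")
  cat("Call: "); print(x$call)
  cat(sprintf("\n%d genes x %d experiments; %d snapshots (%s sampler)\n",
              nrow(x$data), ncol(x$data), x$config$samples, x$config$sampler))
  cat(sprintf("MAP clustering: %d clusters\n", x$K))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' @export
summary.hdp_fit <- function(object, ...) {
  sizes <- table(cluster = object$cluster)
  centers <- t(vapply(seq_len(object$K), function(k) {
    colMeans(unclass(object$data)[object$cluster == k, , drop = FALSE])
  }, numeric(ncol(object$data))))
  rownames(centers) <- paste0("cluster", seq_len(object$K))
  maxp <- apply(object$posterior$gene, 1L, max)
  out <- list(K = object$K, sizes = sizes, centers = centers,
              dish_count_table = table(dishes = object$trace$K),
              mean_max_membership = mean(maxp),
              config = object$config, model = object$model, hyper = object$hyper)
  class(out) <- "summary.hdp_fit"
  out
}

#' @export
print.summary.hdp_fit <- function(x, ...) {
  cat(sprintf("HDP clustering summary: %d MAP clusters\n\n", x$K))
  cat("Cluster sizes:\n"); print(x$sizes)
  cat("\nCluster mean expression profiles:\n")
  print(round(x$centers, 3))
  cat("\nDishes per posterior snapshot:\n"); print(x$dish_count_table)
  cat(sprintf("\nMean max membership probability: %.3f\n", x$mean_max_membership))
  invisible(x)
}

#' @export
fitted.hdp_fit <- function(object, ...) {
  centers <- t(vapply(seq_len(object$K), function(k) {
    colMeans(unclass(object$data)[object$cluster == k, , drop = FALSE])
  }, numeric(ncol(object$data))))
  out <- centers[object$cluster, , drop = FALSE]
  dimnames(out) <- dimnames(object$data)
  out
}

#' @export
residuals.hdp_fit <- function(object, ...) {
  unclass(object$data) - fitted(object)
}

#' Plot gene expression profiles by MAP cluster
#'
#' Line plot of every gene's expression profile across experiments, colored
#' by its MAP cluster, with the cluster mean profiles overlaid in bold.
#'
#' @param x an `hdp_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hdp_fit <- function(x, ...) {
  d <- unclass(x$data)
  cols <- grDevices::hcl.colors(max(3L, x$K), "Dark 3")[x$cluster]
  graphics::matplot(t(d), type = "l", lty = 1, col = grDevices::adjustcolor(cols, 0.35),
                    xlab = "experiment", ylab = "expression", ...)
  for (k in seq_len(x$K)) {
    graphics::lines(colMeans(d[x$cluster == k, , drop = FALSE]),
                    col = grDevices::hcl.colors(max(3L, x$K), "Dark 3")[k], lwd = 3)
  }
  invisible(x)
}
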