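# Collapsed Chinese-restaurant-franchise Gibbs sampler.
#
# The unit operations below (table_weights, dish_weights, sample_table,
# sample_dish, gibbs_sweep) are the reference implementation in R, operating
# on the transparent seating_state structure; run_chain() dispatches to a C++
# engine with identical semantics for long chains (engine = "cpp", the
# default) or to these functions (engine = "r"). All weights are computed in
# log space.

logsumexp <- function(lw) {
  if (!length(lw)) return(-Inf)
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

# one draw from a categorical given unnormalized log weights
sample_log <- function(lw) {
  p <- exp(lw - max(lw))
  sample.int(length(p), 1L, prob = p)
}

#' Conditional weights for reseating one customer
#'
#' Unnormalized full-conditional weights of the table assignment of customer
#' `(j, i)` — the expression of gene `i` in experiment `j` — given everything
#' else. The customer must already be unseated (its counts and value removed
#' from the state, see [st_unseat] via [sample_table()]).
#'
#' An occupied table `t` of row `j` has weight
#' \eqn{c_{jt} \cdot f_{k(t)}(g \mid \text{dish data})}: its customer count
#' times the collapsed predictive density of the value under the table's dish.
#' The single new-table weight is
#' \eqn{\alpha_0 \left[\sum_k \frac{\sum_j d_{jk}}{\sum_{jk} d_{jk} + \alpha_1}
#' f_k(g\mid\cdot) + \frac{\alpha_1}{\sum_{jk} d_{jk} + \alpha_1}
#' p_0(g)\right]}, the dish-level Chinese-restaurant mixture over all served
#' dishes plus a fresh dish with prior-predictive density \eqn{p_0}. In an
#' empty restaurant this collapses to \eqn{\alpha_0 p_0(g)}.
#'
#' @param j experiment (row) index; @param i gene (customer) index.
#' @param state a `seating_state` with customer `(j,i)` unseated.
#' @param data the [expression_matrix()].
#' @param model an [obs_model()]; @param hyper an [hdp_hyper()].
#' @return list with `tables` (named weights per occupied table of row `j`),
#'   `new` (new-table weight), the log versions `log_tables`/`log_new`, and
#'   `log_dish_pred` (per-dish log predictive of the value, reused for the
#'   new table's dish draw).
#' @export
table_weights <- function(j, i, state, data, model, hyper) {
  if (!is.na(state$phi[j, i]))
    stop("customer (", j, ",", i, ") must be unseated before computing weights")
  g <- data[i, j]
  lp0 <- prior_predictive(g, model, log = TRUE)
  dishes <- names(state$dish_tab)
  logf <- vapply(dishes, function(kk) {
    log_dish_predictive(g, state$dish_n[[kk]], state$dish_sum[[kk]],
                        state$dish_sumsq[[kk]], model)
  }, 0)
  totd <- sum(state$dish_tab)
  log_new <- log(hyper$alpha0) +
    logsumexp(c(log(as.numeric(state$dish_tab)) + logf, log(hyper$alpha1) + lp0)) -
    log(totd + hyper$alpha1)
  tabs <- names(state$tab_dish[[j]])
  log_tabs <- vapply(tabs, function(tk) {
    log(as.numeric(state$tab_n[[j]][[tk]])) +
      logf[[as.character(state$tab_dish[[j]][[tk]])]]
  }, 0)
  list(tables = exp(log_tabs), new = exp(log_new),
       log_tables = log_tabs, log_new = log_new,
       log_dish_pred = logf, log_prior_pred = lp0)
}

#' Conditional weights for re-dishing one table
#'
#' Unnormalized full-conditional weights of the dish served at table `(j, t)`
#' given everything else. The table's block of data must already be detached
#' from its dish (see [sample_dish()]). A served dish `k` has weight
#' \eqn{(\sum_j d_{jk}) \cdot f_k(\text{table data} \mid \text{dish data})} —
#' its global table count times the collapsed predictive density of the
#' table's whole block given the dish's remaining data; the new-dish weight is
#' \eqn{\alpha_1} times the prior-predictive (marginal) density of the block.
#'
#' @inheritParams table_weights
#' @param t table label within row `j`.
#' @return list with `dishes` (named weights per served dish), `new`, and the
#'   log versions.
#' @export
dish_weights <- function(j, t, state, data, model, hyper) {
  tk <- as.character(t)
  if (!tk %in% names(state$tab_dish[[j]]))
    stop("no occupied table ", t, " in row ", j)
  if (!is.na(state$tab_dish[[j]][[tk]]))
    stop("table (", j, ",", t, ") must be detached from its dish first")
  bn <- state$tab_n[[j]][[tk]]; bs <- state$tab_sum[[j]][[tk]]
  bss <- state$tab_sumsq[[j]][[tk]]
  block_lml <- gaussian_marginal_loglik(bn, bs, bss, model)
  dishes <- names(state$dish_tab)
  log_d <- vapply(dishes, function(kk) {
    log(as.numeric(state$dish_tab[[kk]])) +
      gaussian_marginal_loglik(state$dish_n[[kk]] + bn, state$dish_sum[[kk]] + bs,
                               state$dish_sumsq[[kk]] + bss, model) -
      gaussian_marginal_loglik(state$dish_n[[kk]], state$dish_sum[[kk]],
                               state$dish_sumsq[[kk]], model)
  }, 0)
  log_new <- log(hyper$alpha1) + block_lml
  list(dishes = exp(log_d), new = exp(log_new),
       log_dishes = log_d, log_new = log_new)
}

#' Metropolis-Hastings acceptance for a proposed label
#'
#' With a symmetric proposal, a candidate with unnormalized weight
#' `candidate` is accepted against the current value with weight `current`
#' with probability \eqn{\min(1, \beta)}, \eqn{\beta =
#' \text{candidate}/\text{current}}. A zero-weight current value is always
#' left (accept any candidate with positive weight).
#'
#' `mh_accept_prob()` returns the acceptance probability; `mh_step()` draws
#' the accept/reject decision.
#'
#' @param candidate,current unnormalized non-negative weights.
#' @return `mh_accept_prob()`: probability in `[0, 1]`; `mh_step()`: logical.
#' @examples
#' mh_accept_prob(0.1483, 0.22971)  # 0.6456
#' @export
mh_accept_prob <- function(candidate, current) {
  stopifnot(candidate >= 0, current >= 0)
  if (current == 0) return(if (candidate > 0) 1 else 0)
  min(1, candidate / current)
}

#' @rdname mh_accept_prob
#' @export
mh_step <- function(candidate, current) {
  runif(1L) < mh_accept_prob(candidate, current)
}

# draw the dish of a freshly opened table holding the single value whose
# per-dish log predictives are logf (from table_weights); returns dish label
# or NA for a new dish
draw_dish_for_new_table <- function(state, logf, lp0, hyper) {
  lw <- c(log(as.numeric(state$dish_tab)) + logf, log(hyper$alpha1) + lp0)
  idx <- sample_log(lw)
  if (idx > length(state$dish_tab)) NA else as.integer(names(state$dish_tab)[idx])
}

#' Resample the table of one customer
#'
#' Unseats customer `(j, i)`, computes [table_weights()], draws the new table
#' (exactly in `"direct"` mode, or by one Metropolis-Hastings step with a
#' uniform proposal over the finite support in `"mh"` mode) and reseats the
#' customer. A customer seated at a new table triggers an immediate dish draw
#' for that table from the dish-level Chinese-restaurant weights. Emptied
#' tables and dishes are garbage-collected.
#'
#' @inheritParams table_weights
#' @param mode `"direct"` or `"mh"`.
#' @return the updated `seating_state`.
#' @export
sample_table <- function(j, i, state, data, model, hyper, mode = c("direct", "mh")) {
  mode <- match.arg(mode)
  g <- data[i, j]
  prev_t <- state$phi[j, i]
  state <- st_unseat(state, j, i, g)
  w <- table_weights(j, i, state, data, model, hyper)
  lw <- c(w$log_tables, w$log_new)
  n_opt <- length(lw)
  if (mode == "direct") {
    idx <- sample_log(lw)
  } else {
    cur <- if (as.character(prev_t) %in% names(w$tables))
      which(names(w$tables) == as.character(prev_t)) else n_opt
    cand <- sample.int(n_opt, 1L)
    idx <- if (cand == cur || mh_step(exp(lw[cand] - lw[cur]), 1)) cand else cur
  }
  if (idx > length(w$tables)) {
    k <- draw_dish_for_new_table(state, w$log_dish_pred, w$log_prior_pred, hyper)
    state <- st_open_table(state, j, i, g)
    state <- st_assign_table_dish(state, j, state$phi[j, i], k)
  } else {
    state <- st_seat_existing(state, j, i, as.integer(names(w$tables)[idx]), g)
  }
  state
}

#' Resample the dish of one table
#'
#' Detaches the block of data at table `(j, t)` from its current dish,
#' computes [dish_weights()], draws the new dish (direct or one
#' Metropolis-Hastings step with a uniform proposal) and reattaches the
#' block. A dish left with no tables is garbage-collected.
#'
#' @inheritParams dish_weights
#' @param mode `"direct"` or `"mh"`.
#' @return the updated `seating_state`.
#' @export
sample_dish <- function(j, t, state, data, model, hyper, mode = c("direct", "mh")) {
  mode <- match.arg(mode)
  tk <- as.character(t)
  if (!tk %in% names(state$tab_dish[[j]]))
    stop("no occupied table ", t, " in row ", j)
  prev_k <- state$tab_dish[[j]][[tk]]
  state <- st_detach_table(state, j, t)
  w <- dish_weights(j, t, state, data, model, hyper)
  lw <- c(w$log_dishes, w$log_new)
  n_opt <- length(lw)
  if (mode == "direct") {
    idx <- sample_log(lw)
  } else {
    cur <- if (as.character(prev_k) %in% names(w$dishes))
      which(names(w$dishes) == as.character(prev_k)) else n_opt
    cand <- sample.int(n_opt, 1L)
    idx <- if (cand == cur || mh_step(exp(lw[cand] - lw[cur]), 1)) cand else cur
  }
  k <- if (idx > length(w$dishes)) NA else as.integer(names(w$dishes)[idx])
  st_assign_table_dish(state, j, t, k)
}

#' Resample the concentration parameters
#'
#' When `resample_concentrations` is enabled, draws fresh values of
#' `alpha0` and `alpha1` independently from their Gamma(shape, rate) prior —
#' the seating configuration carries no information about them in this
#' sampler's update, so the conditional equals the prior. Disabled (the
#' default), the values pass through unchanged.
#'
#' @param hyper an [hdp_hyper()].
#' @return an [hdp_hyper()] with (possibly) updated `alpha0`, `alpha1`.
#' @export
sample_concentrations <- function(hyper) {
  if (isTRUE(hyper$resample_concentrations)) {
    hyper$alpha0 <- rgamma(1L, shape = hyper$gamma_shape, rate = hyper$gamma_rate)
    hyper$alpha1 <- rgamma(1L, shape = hyper$gamma_shape, rate = hyper$gamma_rate)
  }
  hyper
}

#' One full Gibbs sweep
#'
#' Resamples, in fixed row-major order, the table of every customer, then the
#' dish of every occupied table (rows in order, table labels ascending), then
#' the concentration parameters.
#'
#' @inheritParams sample_table
#' @param state a fully seated, valid `seating_state`.
#' @return list with the updated `state` and `hyper`.
#' @export
gibbs_sweep <- function(state, data, model, hyper, mode = c("direct", "mh")) {
  mode <- match.arg(mode)
  M <- ncol(data); N <- nrow(data)
  for (j in seq_len(M)) for (i in seq_len(N))
    state <- sample_table(j, i, state, data, model, hyper, mode)
  for (j in seq_len(M)) {
    for (t in sort(as.integer(names(state$tab_dish[[j]])))) {
      if (as.character(t) %in% names(state$tab_dish[[j]]))
        state <- sample_dish(j, t, state, data, model, hyper, mode)
    }
  }
  hyper <- sample_concentrations(hyper)
  list(state = state, hyper = hyper)
}

# Canonical relabeling: dishes renumbered 1..K in order of increasing dish
# mean (the mean of the values currently assigned to each dish) — the
# standard identifiability constraint for a univariate Gaussian mixture, so
# canonical label a means "a-th lowest component" in every snapshot. Tables
# are renumbered by first appearance within their row.
canonical_snapshot <- function(state) {
  zraw <- st_dish_matrix(state)
  labs <- as.integer(names(state$dish_tab))
  means <- as.numeric(state$dish_sum) / as.numeric(state$dish_n)
  rank_of <- integer(max(labs))
  rank_of[labs[order(means, labs)]] <- seq_along(labs)
  z <- matrix(rank_of[zraw], nrow(zraw), ncol(zraw))
  ph <- state$phi
  for (j in seq_len(nrow(ph))) ph[j, ] <- match(ph[j, ], unique(ph[j, ]))
  list(z = z, tab = ph)
}

#' Run the collapsed Gibbs sampler
#'
#' Runs `burnin` warm-up sweeps followed by `samples * thin` recorded sweeps
#' (keeping every `thin`-th), starting from [init_state()]. Every recorded
#' snapshot is stored with canonical labels — dishes renumbered `1..K` in
#' order of increasing dish mean (so canonical label `a` consistently means
#' the `a`-th lowest mixture component), tables renumbered by first
#' appearance within each row — which removes the arbitrary label component
#' before posterior aggregation (label switching).
#'
#' @param data an [expression_matrix()] (or plain matrix, genes as rows).
#' @param model an [obs_model()].
#' @param hyper an [hdp_hyper()].
#' @param config a [chain_config()].
#' @param init initialization mode, see [init_state()].
#' @param engine `"cpp"` (compiled sampler, default) or `"r"` (the reference
#'   implementation above). Both use R's RNG and target the same posterior;
#'   their draw streams differ.
#' @param verbose print progress every 100 sweeps.
#' @return an `hdp_trace`: list with `z` (samples as an `M x N x L` integer
#'   array of canonical dish labels), `tab` (table labels, same shape),
#'   `alpha0`/`alpha1`/`K` per snapshot, plus ids and configuration.
#' @export
run_chain <- function(data, model = obs_model(), hyper = hdp_hyper(),
                      config = chain_config(), init = "each-own-table",
                      engine = c("cpp", "r"), verbose = FALSE) {
  data <- as_expression_matrix(data)
  engine <- match.arg(engine)
  stopifnot(inherits(model, "obs_model"), inherits(hyper, "hdp_hyper"),
            inherits(config, "chain_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- init_state(data, init)
  M <- ncol(data); N <- nrow(data); L <- config$samples
  if (engine == "cpp") {
    z0 <- st_dish_matrix(state)
    res <- crf_run_chain(t(unclass(data)), state$phi, z0,
                         model$obs_var, model$prior_mean, model$prior_var,
                         hyper$alpha0, hyper$alpha1,
                         hyper$gamma_shape, hyper$gamma_rate,
                         hyper$resample_concentrations,
                         config$burnin, L, config$thin,
                         config$sampler == "mh", verbose)
    z <- array(res$z, dim = c(M, N, L))
    tab <- array(res$tab, dim = c(M, N, L))
    a0 <- res$alpha0; a1 <- res$alpha1; K <- res$K
  } else {
    z <- array(NA_integer_, c(M, N, L))
    tab <- array(NA_integer_, c(M, N, L))
    a0 <- numeric(L); a1 <- numeric(L); K <- integer(L)
    total <- config$burnin + L * config$thin
    rec <- 0L
    for (l in seq_len(total)) {
      sw <- gibbs_sweep(state, data, model, hyper, config$sampler)
      state <- sw$state; hyper <- sw$hyper
      if (l > config$burnin && (l - config$burnin) %% config$thin == 0L) {
        rec <- rec + 1L
        snap <- canonical_snapshot(state)
        z[, , rec] <- snap$z
        tab[, , rec] <- snap$tab
        a0[rec] <- hyper$alpha0; a1[rec] <- hyper$alpha1
        K[rec] <- n_dishes(state)
      }
      if (verbose && l %% 100L == 0L)
        message(sprintf("sweep %d/%d: %d dishes", l, total, n_dishes(state)))
    }
  }
  structure(list(z = z, tab = tab, alpha0 = a0, alpha1 = a1, K = K,
                 gene_ids = rownames(data), experiment_ids = colnames(data),
                 model = model, hyper = hyper, config = config, engine = engine),
            class = "hdp_trace")
}

#' @export
print.hdp_trace <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("hdp_trace: %d snapshots of %d experiments x %d genes (%s engine)\n",
              d[3L], d[1L], d[2L], x$engine))
  cat("dishes per snapshot: ")
  print(table(x$K))
  invisible(x)
}

#' Aggregate a trace into membership distributions
#'
#' Converts the snapshots of a chain into empirical posterior membership
#' distributions: for every customer `(j, i)` the distribution of its dish
#' label across snapshots, and for every gene `i` the experiment-aggregated
#' distribution \eqn{\sum_j P(z_{ji} = a \mid g) / M}.
#' With `joint = TRUE` the empirical frequencies of canonical (table, dish)
#' pairs per customer are also returned.
#'
#' Label frequencies across MCMC snapshots are only meaningful if label `a`
#' denotes the same mixture component in every snapshot. The default
#' `align = "rank"` relies on the stored mean-ordered canonical labels
#' (label `a` = `a`-th lowest component mean, the usual order constraint for
#' identifying a univariate Gaussian mixture). `align = "match"` instead
#' iteratively permutes each snapshot's labels to maximize co-assignment
#' overlap with the consensus of all snapshots (a greedy Stephens-style
#' relabeling); it can help when the number of components is stable but
#' their means cross.
#'
#' @param trace an `hdp_trace` from [run_chain()].
#' @param joint also tabulate (table, dish) pair frequencies.
#' @param align label alignment across snapshots, `"rank"` or `"match"`.
#' @return a `membership_posterior`: list with `P` (`M x N x K` array of
#'   per-customer probabilities), `gene` (`N x K` matrix, rows summing to 1),
#'   `labels`, `gene_ids`, and optionally `joint`.
#' @export
aggregate_posterior <- function(trace, joint = FALSE, align = c("rank", "match")) {
  stopifnot(inherits(trace, "hdp_trace"))
  align <- match.arg(align)
  d <- dim(trace$z)
  if (d[3L] < 1L) stop("empty trace")
  M <- d[1L]; N <- d[2L]; L <- d[3L]
  z <- trace$z
  if (align == "match") z <- align_labels(z)
  Kmax <- max(z)
  P <- array(0, c(M, N, Kmax))
  for (k in seq_len(Kmax))
    P[, , k] <- apply(z == k, c(1L, 2L), sum) / L
  gene <- apply(P, c(2L, 3L), sum) / M   # N x K, rows sum to 1
  out <- list(P = P, gene = gene, labels = seq_len(Kmax),
              gene_ids = trace$gene_ids)
  if (joint) {
    jt <- vector("list", M)
    for (j in seq_len(M)) {
      jt[[j]] <- vector("list", N)
      for (i in seq_len(N)) {
        key <- paste(trace$tab[j, i, ], trace$z[j, i, ], sep = ".")
        jt[[j]][[i]] <- table(key) / L
      }
    }
    out$joint <- jt
  }
  structure(out, class = "membership_posterior")
}

#' @export
print.membership_posterior <- function(x, ...) {
  cat(sprintf("membership_posterior: %d genes, %d experiments, %d labels\n",
              dim(x$P)[2L], dim(x$P)[1L], length(x$labels)))
  invisible(x)
}

#' MAP cluster assignment of genes
#'
#' Assigns each gene to the label maximizing its experiment-aggregated
#' membership probability \eqn{\sum_j P(z_{ji} = a \mid g)}; ties break to
#' the smallest canonical label. Output labels are renumbered `1..K` in order
#' of first appearance over the genes.
#'
#' @param post a `membership_posterior` from [aggregate_posterior()].
#' @return named integer vector of cluster labels (one per gene).
#' @export
map_assignment <- function(post) {
  stopifnot(inherits(post, "membership_posterior"))
  raw <- apply(post$gene, 1L, which.max)   # first max = smallest label on ties
  lab <- match(raw, unique(raw))
  names(lab) <- post$gene_ids
  lab
}

# Relabeling of an M x N x L label array across snapshots: each snapshot's
# labels are permuted to maximize cell-wise co-assignment overlap with a
# consensus membership matrix, iteratively (greedy matching against the
# aggregate, then rebuild the aggregate, until stable). Snapshot dishes that
# find no consensus partner open fresh labels. Finally, consensus labels are
# renumbered so that label usage is densest first (stable order).
align_labels <- function(z, max_iter = 5L) {
  d <- dim(z); M <- d[1L]; N <- d[2L]; L <- d[3L]
  ncell <- M * N
  zmat <- matrix(z, ncell, L)   # cells x snapshots
  Kl <- apply(zmat, 2L, max)
  # initial consensus from the stored mean-ranked labels
  counts <- matrix(0, ncell, max(Kl))
  for (l in seq_len(L))
    counts[cbind(seq_len(ncell), zmat[, l])] <- counts[cbind(seq_len(ncell), zmat[, l])] + 1
  match_one <- function(zl, counts) {
    K <- max(zl)
    O <- rowsum(counts, group = zl)           # K x A overlap
    perm <- integer(K)
    usedA <- rep(FALSE, ncol(counts))
    Ow <- O
    for (step in seq_len(min(K, ncol(counts)))) {
      idx <- arrayInd(which.max(Ow), dim(Ow))
      if (Ow[idx] <= 0) break
      perm[idx[1L]] <- idx[2L]
      usedA[idx[2L]] <- TRUE
      Ow[idx[1L], ] <- -Inf
      Ow[, idx[2L]] <- -Inf
    }
    un <- which(perm == 0L)
    if (length(un)) {
      free <- c(which(!usedA), ncol(counts) + seq_along(un))
      perm[un] <- free[seq_along(un)]
    }
    perm
  }
  for (iter in seq_len(max_iter)) {
    new_zmat <- zmat
    for (l in seq_len(L)) {
      perm <- match_one(zmat[, l], counts)
      new_zmat[, l] <- perm[zmat[, l]]
    }
    changed <- any(new_zmat != zmat)
    zmat <- new_zmat
    A <- max(zmat)
    counts <- matrix(0, ncell, A)
    for (l in seq_len(L))
      counts[cbind(seq_len(ncell), zmat[, l])] <- counts[cbind(seq_len(ncell), zmat[, l])] + 1
    if (!changed) break
  }
  # renumber labels by decreasing total usage (ties: old order) so that the
  # retained label set is compact and deterministic
  usage <- colSums(counts)
  ord <- order(-usage, seq_along(usage))
  relab <- integer(length(usage))
  relab[ord] <- seq_along(ord)
  array(relab[zmat], dim = d)
}

# ---- tiny-instance brute-force posterior oracle ---------------------------

# all set partitions of n items as restricted-growth label vectors
set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, used) {
    pos <- length(labels) + 1L
    if (pos > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (lab in seq_len(used + 1L)) recurse(c(labels, lab), max(used, lab))
  }
  recurse(integer(0), 0L)
  out
}

log_pochhammer <- function(a, n) if (n == 0L) 0 else sum(log(a + 0:(n - 1L)))

# log CRP probability of a partition with block sizes `sizes` of n items
log_crp_prob <- function(sizes, alpha) {
  n <- sum(sizes)
  length(sizes) * log(alpha) + sum(lgamma(sizes)) - log_pochhammer(alpha, n)
}

#' Exact posterior over customer partitions (brute force, tiny instances)
#'
#' Enumerates every franchise configuration of a tiny instance — all set
#' partitions of each experiment row's customers into tables crossed with all
#' set partitions of the resulting tables into dishes — scores each by its
#' Chinese-restaurant-franchise prior probability (at fixed `alpha0`,
#' `alpha1`) times the product of collapsed dish marginal likelihoods, and
#' marginalizes to the induced partition of all `M * N` customers by dish.
#' Serves as the independent oracle the chain output is checked against.
#'
#' @param data an [expression_matrix()] with at most 6 values in total.
#' @param model an [obs_model()].
#' @param hyper an [hdp_hyper()] (concentrations taken as fixed).
#' @return named numeric vector of posterior probabilities, one per customer
#'   partition; names are canonical row-major dish-label strings as produced
#'   by [partition_key()]; sorted decreasing.
#' @export
exact_posterior_small <- function(data, model = obs_model(), hyper = hdp_hyper()) {
  data <- as_expression_matrix(data)
  N <- nrow(data); M <- ncol(data)
  if (N * M > 6L) stop("instance too large for exact enumeration (N*M must be <= 6)")
  row_parts <- set_partitions(N)
  combos <- expand.grid(rep(list(seq_along(row_parts)), M))
  acc <- new.env(parent = emptyenv())
  for (ci in seq_len(nrow(combos))) {
    lp_rows <- 0
    tables <- list()  # each: list(j, values)
    for (j in seq_len(M)) {
      part <- row_parts[[combos[ci, j]]]
      sizes <- tabulate(part)
      lp_rows <- lp_rows + log_crp_prob(sizes, hyper$alpha0)
      for (b in seq_len(max(part)))
        tables[[length(tables) + 1L]] <- list(j = j, members = which(part == b))
    }
    Tn <- length(tables)
    for (dpart in set_partitions(Tn)) {
      lp_dish <- log_crp_prob(tabulate(dpart), hyper$alpha1)
      ll <- 0
      for (k in seq_len(max(dpart))) {
        vals <- unlist(lapply(which(dpart == k), function(ti)
          data[tables[[ti]]$members, tables[[ti]]$j]))
        st <- suff_stats(vals)
        ll <- ll + gaussian_marginal_loglik(st$n, st$sum, st$sumsq, model)
      }
      z <- matrix(NA_integer_, M, N)
      for (ti in seq_len(Tn))
        z[tables[[ti]]$j, tables[[ti]]$members] <- dpart[ti]
      key <- partition_key(z)
      w <- exp(lp_rows + lp_dish + ll)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
    }
  }
  keys <- ls(acc)
  p <- vapply(keys, function(k) acc[[k]], 0)
  p <- p / sum(p)
  sort(p, decreasing = TRUE)
}

#' Canonical key of a customer partition
#'
#' Encodes the partition of all customers induced by a dish-label matrix
#' `z[j, i]` as a string of canonical labels in row-major (experiment-major)
#' order. Two label matrices inducing the same partition map to the same key.
#'
#' @param z integer matrix of labels (experiments x genes).
#' @return character scalar.
#' @export
partition_key <- function(z) {
  v <- as.vector(t(z))
  paste(match(v, unique(v)), collapse = "-")
}

#' Empirical partition frequencies of a trace
#'
#' Tabulates the canonical customer-partition key of every snapshot of a
#' chain, for comparison against [exact_posterior_small()].
#'
#' @param trace an `hdp_trace`.
#' @return named numeric vector of relative frequencies, sorted decreasing.
#' @export
trace_partition_frequencies <- function(trace) {
  stopifnot(inherits(trace, "hdp_trace"))
  L <- dim(trace$z)[3L]
  keys <- vapply(seq_len(L), function(l) partition_key(trace$z[, , l]), "")
  sort(table(keys) / L, decreasing = TRUE)
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q named numeric vectors of probabilities; names are the support.
#' @return scalar in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}
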