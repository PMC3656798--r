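# Whole-chain behavior: determinism, cross-engine agreement, aggregation
# arithmetic, MAP assignment, and the brute-force posterior oracle.

test_that("chains are reproducible and snapshots well formed", {
  we <- worked_example()
  cfg <- chain_config(burnin = 50, samples = 40, seed = 9)
  for (eng in c("cpp", "r")) {
    t1 <- run_chain(we$data, we$model, we$hyper, cfg, engine = eng)
    t2 <- run_chain(we$data, we$model, we$hyper, cfg, engine = eng)
    expect_identical(t1$z, t2$z)
    expect_identical(t1$tab, t2$tab)
    expect_equal(dim(t1$z), c(2L, 2L, 40L))
    # canonical labels are contiguous 1..K in every snapshot
    for (l in 1:40) {
      zz <- t1$z[, , l]
      expect_setequal(unique(as.vector(zz)), seq_len(max(zz)))
      expect_equal(max(zz), t1$K[l])
    }
  }
  short <- run_chain(we$data, we$model, we$hyper,
                     chain_config(burnin = 0, samples = 1, seed = 2))
  expect_equal(dim(short$z)[3], 1L)
})

test_that("direct, M-H and reference-engine chains target the same posterior", {
  we <- worked_example()
  exact <- exact_posterior_small(we$data, we$model, we$hyper)
  expect_equal(sum(exact), 1, tolerance = 1e-10)
  fr_cpp <- trace_partition_frequencies(
    run_chain(we$data, we$model, we$hyper,
              chain_config(burnin = 500, samples = 8000, seed = 41)))
  fr_mh <- trace_partition_frequencies(
    run_chain(we$data, we$model, we$hyper,
              chain_config(burnin = 500, samples = 8000, seed = 42, sampler = "mh")))
  fr_r <- trace_partition_frequencies(
    run_chain(we$data, we$model, we$hyper,
              chain_config(burnin = 200, samples = 3000, seed = 43), engine = "r"))
  expect_lt(tv_distance(fr_cpp, exact), 0.05)
  expect_lt(tv_distance(fr_mh, exact), 0.05)
  expect_lt(tv_distance(fr_r, exact), 0.06)
  expect_lt(tv_distance(fr_cpp, fr_mh), 0.05)
})

test_that("posterior aggregation matches hand-counted tallies", {
  # toy trace: 3 snapshots over a 1-experiment, 2-gene instance
  z <- array(c(1L, 1L,   1L, 2L,   1L, 2L), dim = c(1, 2, 3))
  tab <- array(c(1L, 1L,  1L, 2L,  1L, 2L), dim = c(1, 2, 3))
  tr <- structure(list(z = z, tab = tab, alpha0 = rep(1, 3), alpha1 = rep(1, 3),
                       K = c(1L, 2L, 2L), gene_ids = c("a", "b"),
                       experiment_ids = "e1", config = chain_config(samples = 3),
                       engine = "manual"),
                  class = "hdp_trace")
  post <- aggregate_posterior(tr, joint = TRUE)
  expect_equal(post$P[1, 1, ], c(1, 0))          # gene a always label 1
  expect_equal(post$P[1, 2, ], c(1 / 3, 2 / 3))  # gene b: 1 once, 2 twice
  expect_equal(rowSums(post$gene), c(1, 1))
  expect_equal(unname(unclass(post$joint[[1]][[2]])[["2.2"]]), 2 / 3)
  # all snapshots identical -> hard 0/1 memberships
  zc <- array(rep(c(1L, 2L), 3), dim = c(1, 2, 3))
  trc <- tr; trc$z <- zc
  pc <- aggregate_posterior(trc)
  expect_true(all(pc$P %in% c(0, 1)))
  # alternating equally -> exact 0.5
  za <- array(c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L), dim = c(1, 2, 4))
  tra <- tr; tra$z <- za; tra$tab <- za
  tra$alpha0 <- tra$alpha1 <- rep(1, 4); tra$K <- c(1L, 2L, 1L, 2L)
  pa <- aggregate_posterior(tra)
  expect_equal(pa$P[1, 2, ], c(0.5, 0.5))
})

test_that("MAP assignment maximizes the aggregated membership with tie rules", {
  mk_post <- function(gene) {
    structure(list(P = array(0, c(2, nrow(gene), ncol(gene))), gene = gene,
                   labels = seq_len(ncol(gene)), gene_ids = rownames(gene)),
              class = "membership_posterior")
  }
  # unanimous
  expect_equal(unname(map_assignment(mk_post(rbind(c(1, 0), c(1, 0))))), c(1, 1))
  # exact tie -> smallest canonical label
  expect_equal(unname(map_assignment(mk_post(rbind(c(0.5, 0.5))))), 1)
  # per-experiment distributions (0.6, 0.4) and (0.3, 0.7): sums (0.9, 1.1)
  P <- array(0, c(2, 1, 2))
  P[1, 1, ] <- c(0.6, 0.4); P[2, 1, ] <- c(0.3, 0.7)
  post <- structure(list(P = P, gene = apply(P, c(2, 3), sum) / 2,
                         labels = 1:2, gene_ids = "g1"),
                    class = "membership_posterior")
  expect_equal(unname(map_assignment(post)), 1)  # renumbered from winning label 2
  expect_equal(unname(apply(post$gene, 1, which.max)), 2)
  # output labels renumbered by first appearance
  g <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1))
  expect_equal(unname(map_assignment(mk_post(g))), c(1, 2, 1))
})

test_that("the exact enumeration oracle behaves lawfully", {
  m <- we_model(); h <- hdp_hyper()
  one <- expression_matrix(matrix(0.2, 1, 1))
  expect_equal(unname(exact_posterior_small(one, m, h)), 1)
  # equal observations co-cluster more than distant ones
  near <- expression_matrix(matrix(c(0.5, 0.5), 2, 1))
  far <- expression_matrix(matrix(c(-3, 3), 2, 1))
  p_together <- function(d) {
    p <- exact_posterior_small(d, m, h)
    sum(p[names(p) == "1-1"])
  }
  expect_gt(p_together(near), p_together(far))
  expect_gt(p_together(near), 0.5)
  expect_error(exact_posterior_small(expression_matrix(matrix(rnorm(8), 4, 2)), m, h),
               "too large")
})

test_that("well-separated clusters are recovered from a fitted model", {
  sim <- gen_gaussian_clusters(K = 3, sizes = c(10, 10, 10),
                               means = c(-5, 0, 5), sd = 0.5, M = 4, seed = 4)
  fit <- hdp_cluster(sim$data, burnin = 300, samples = 600, seed = 4)
  expect_gte(rand_index(fit$cluster, sim$truth), 0.95)
  expect_equal(fit$K, 3L)
  # methods run
  expect_output(print(fit), "3 clusters")
  s <- summary(fit)
  expect_equal(unname(sort(as.vector(s$sizes))), c(10, 10, 10))
  expect_equal(dim(fitted(fit)), dim(sim$data))
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(unclass(sim$data)))
})

test_that("network posterior co-clustering separates the three modules", {
  net <- gen_network_data(network_spec(n_samples = 50), seed = 105)
  tr <- run_chain(net, obs_model(), hdp_hyper(),
                  chain_config(burnin = 300, samples = 600, seed = 105))
  z <- tr$z; M <- dim(z)[1]; N <- dim(z)[2]
  keep <- seq(1, dim(z)[3], by = 3)
  co <- matrix(0, N, N)
  for (l in keep) {
    zz <- z[, , l]
    for (j in seq_len(M)) co <- co + outer(zz[j, ], zz[j, ], "==")
  }
  co <- co / (M * length(keep))
  modules <- list(c(2, 4, 6), c(1, 3, 5, 7), c(8, 9, 10))
  within <- unlist(lapply(modules, function(m) co[t(combn(m, 2))]))
  crossm <- c(co[modules[[1]], modules[[3]]], co[modules[[2]], modules[[3]]],
              co[modules[[1]], modules[[2]]])
  expect_gt(mean(within), mean(crossm))
})

test_that("label alignment is stable for stable chains", {
  # identical snapshots: alignment must not alter anything but label order
  z <- array(rep(c(1L, 2L, 2L, 1L), 5), dim = c(2, 2, 5))
  za <- align_labels(z)
  expect_equal(dim(za), dim(z))
  for (l in 1:5) expect_equal(za[, , l], za[, , 1])
  expect_setequal(unique(as.vector(za)), 1:2)
})
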