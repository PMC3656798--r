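test_that("the walk-through fixture is exactly as specified", {
  we <- worked_example()
  expect_equal(unname(unclass(we$data)), matrix(c(0, 1, -1, 2), 2, 2))
  expect_length(validate_state(we$state, we$data), 0)
  # row-1 tables share one dish, row-2 tables another
  expect_equal(length(unique(we$state$tab_dish[[1]])), 1L)
  expect_equal(length(unique(we$state$tab_dish[[2]])), 1L)
  expect_equal(unname(we$state$dish_tab), c(2L, 2L))
  expect_equal(we$model$prior_mean, 0)
  expect_equal(we$model$prior_var, 1)
  expect_equal(we$model$obs_var, 1)
  expect_equal(we$hyper$alpha0, 1)
  expect_equal(we$hyper$alpha1, 1)
})

test_that("network generator follows the stated Gaussian cascade", {
  spec <- network_spec(n_samples = 500)
  x <- gen_network_data(spec, seed = 19)
  expect_equal(dim(x), c(10L, 500L))
  expect_identical(x, gen_network_data(spec, seed = 19))
  n <- 500
  # roots keep their stated means; children inherit in expectation
  expect_lt(abs(mean(x["node8", ]) - 3), 4 / sqrt(n))
  expect_lt(abs(mean(x["node2", ]) - 2), 4 / sqrt(n))
  expect_lt(abs(mean(x["node4", ]) - 2), 4 * sqrt(2) / sqrt(n))
  expect_lt(abs(mean(x["node1", ]) - 1), 4 / sqrt(n))
  # node 7 inherits node 4's location
  expect_lt(abs(mean(x["node7", ]) - 2), 0.4)
  # within-module correlations beat cross-module correlations on average
  modules <- list(c(2, 4, 6), c(1, 3, 5, 7), c(8, 9, 10))
  cc <- cor(t(unclass(x)))
  within <- unlist(lapply(modules, function(m) cc[t(combn(m, 2))]))
  crossm <- c(cc[modules[[1]], modules[[3]]], cc[modules[[2]], modules[[3]]])
  expect_gt(mean(within), mean(crossm) + 0.2)
})

test_that("network specification is validated", {
  expect_error(network_spec(edges = data.frame(parent = c(1, 3), child = c(3, 1),
                                               role = c("mean", "mean"))),
               "cyclic")
  e <- network_spec()$edges
  expect_error(network_spec(edges = rbind(e, data.frame(parent = 2, child = 3,
                                                        role = "mean"))),
               "one mean parent")
  sp <- network_spec()
  expect_setequal(sp$roots, c(1, 2, 8))
  e7 <- sp$edges[sp$edges$child == 7, ]
  expect_setequal(e7$role, c("mean", "variance"))
})

test_that("AD400-like generator has the benchmark's shape and separation", {
  ad <- gen_ad400_like(seed = 23)
  expect_equal(dim(ad$data), c(400L, 10L))
  expect_equal(unname(table(ad$truth)), rep(40L, 10L), ignore_attr = TRUE)
  expect_identical(ad$data, gen_ad400_like(seed = 23)$data)
  # distinct profiles: separation factor well above the noise level
  expect_gt(attr(ad, "separation"), 1)
  # genes scatter around their cluster profile
  per_gene_sd <- apply(unclass(ad$data) - ad$profiles[ad$truth, ], 1, sd)
  expect_equal(mean(per_gene_sd), 0.5, tolerance = 0.05)
})

test_that("Gaussian-cluster generator is exact in its degenerate limits", {
  one <- gen_gaussian_clusters(K = 1, sizes = 5, means = 2, sd = 1, M = 3, seed = 1)
  expect_equal(unname(unique(one$truth)), 1L)
  degen <- gen_gaussian_clusters(K = 2, sizes = c(3, 3), means = c(-1, 1),
                                 sd = 0, M = 2, seed = 1)
  expect_equal(unname(unclass(degen$data)[, 1]), c(-1, -1, -1, 1, 1, 1))
  expect_error(gen_gaussian_clusters(K = 2, sizes = 1:3, means = c(0, 1)),
               "length K")
  big <- gen_gaussian_clusters(K = 3, sizes = c(30, 50, 20), means = c(-2, 0, 2),
                               sd = 0.5, M = 10, seed = 2)
  grand <- mean(big$data)
  expected <- sum(c(30, 50, 20) * c(-2, 0, 2)) / 100
  expect_lt(abs(grand - expected), 4 * 1 / sqrt(1000))
})
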