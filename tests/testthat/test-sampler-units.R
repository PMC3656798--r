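# Unit-level checks of the conditional weights and single-site updates,
# on the 2x2 walk-through instance where everything can be computed by hand.

we_unseated <- function() {
  we <- worked_example()
  we$state <- st_unseat(we$state, 1L, 1L, we$data[1L, 1L])
  we
}

test_that("table weights equal occupancy times collapsed predictives", {
  we <- we_unseated()
  w <- table_weights(1, 1, we$state, we$data, we$model, we$hyper)
  # after unseating (1,1): dish 1 holds {1}, dish 2 holds {-1, 2};
  # row 1 keeps only table 2 (count 1, dish 1)
  expect_named(w$tables, "2")
  f1 <- dish_predictive(0, 1, we$model)
  f2 <- dish_predictive(0, c(-1, 2), we$model)
  p0 <- prior_predictive(0, we$model)
  expect_equal(unname(w$tables), 1 * f1, tolerance = 1e-12)
  expect_equal(f1, 0.29969, tolerance = 1e-4)
  # new-table weight mixes all served dishes plus a fresh one (3 tables left)
  expect_equal(w$new, 1 * (1 * f1 + 2 * f2 + 1 * p0) / (3 + 1), tolerance = 1e-12)
  expect_true(all(c(w$tables, w$new) >= 0) && all(is.finite(c(w$tables, w$new))))
  # weights require the customer to be unseated
  expect_error(table_weights(2, 1, we$state, we$data, we$model, we$hyper),
               "unseated")
})

test_that("an empty restaurant reduces to the prior-predictive new table", {
  x <- expression_matrix(matrix(0.4, 1, 1))
  seated <- init_state(x, "each-own-table")
  st <- st_unseat(seated, 1L, 1L, 0.4)
  w <- table_weights(1, 1, st, x, we_model(), hdp_hyper(alpha0 = 2.5))
  expect_length(w$tables, 0)
  expect_equal(w$new, 2.5 * prior_predictive(0.4, we_model()), tolerance = 1e-12)
  # and the customer deterministically reopens a table
  st2 <- sample_table(1, 1, seated, x, we_model(), hdp_hyper())
  expect_length(validate_state(st2, x), 0)
})

test_that("dish weights score whole table blocks against each menu entry", {
  we <- worked_example()
  st <- st_detach_table(we$state, 2L, 3L)   # table holding g21 = -1, dish 2
  w <- dish_weights(2, 3, st, we$data, we$model, we$hyper)
  m <- we$model
  # dish 1 still has 2 tables with data {0, 1}; dish 2 one table with {2}
  expect_equal(unname(w$dishes[["1"]]), 2 * dish_predictive(-1, c(0, 1), m),
               tolerance = 1e-12)
  expect_equal(unname(w$dishes[["2"]]), 1 * dish_predictive(-1, 2, m),
               tolerance = 1e-12)
  expect_equal(w$new, 1 * prior_predictive(-1, m), tolerance = 1e-12)
  # a table must be detached first, and must exist
  expect_error(dish_weights(1, 1, we$state, we$data, we$model, we$hyper),
               "detached")
  expect_error(dish_weights(1, 9, we$state, we$data, we$model, we$hyper),
               "no occupied table")
})

test_that("multi-customer table blocks use the joint marginal ratio", {
  # one table holding both customers of a row: its block predictive given a
  # dish equals the ratio of marginal likelihoods, here checked sequentially
  x <- expression_matrix(matrix(c(0.5, -0.5, 1.5), 3, 1))
  st <- init_state(x, "single-table")
  m <- we_model()
  st <- st_detach_table(st, 1L, 1L)
  w <- dish_weights(1, 1, st, x, m, hdp_hyper())
  # only the new-dish option exists (menu emptied by the detach)
  expect_length(w$dishes, 0)
  chain_rule <- prior_predictive(0.5, m) * dish_predictive(-0.5, 0.5, m) *
    dish_predictive(1.5, c(0.5, -0.5), m)
  expect_equal(w$new, chain_rule, tolerance = 1e-12)
})

test_that("Metropolis-Hastings acceptance follows the weight ratio", {
  expect_equal(mh_accept_prob(0.1483, 0.22971), 0.1483 / 0.22971, tolerance = 1e-12)
  expect_equal(round(mh_accept_prob(0.1483, 0.22971), 4), 0.6456)
  expect_equal(round(mh_accept_prob(0.282082, 2 * 0.22971), 3), 0.614)
  expect_equal(mh_accept_prob(2, 1), 1)
  expect_equal(mh_accept_prob(1, 0), 1)
  expect_equal(mh_accept_prob(0, 0), 0)
  expect_error(mh_accept_prob(-1, 1))
  set.seed(1)
  expect_true(all(replicate(50, mh_step(3, 1))))
})

test_that("direct draws follow the normalized conditional weights", {
  seated <- worked_example()
  we <- we_unseated()
  w <- table_weights(1, 1, we$state, we$data, we$model, we$hyper)
  p_existing <- w$tables[["2"]] / (w$tables[["2"]] + w$new)
  set.seed(31)
  ndraw <- 20000
  hit <- logical(ndraw)
  for (r in seq_len(ndraw)) {
    s2 <- sample_table(1, 1, seated$state, seated$data, seated$model, seated$hyper)
    hit[r] <- s2$phi[1, 1] == 2L
  }
  se <- sqrt(p_existing * (1 - p_existing) / ndraw)
  expect_lt(abs(mean(hit) - p_existing), 3 * se)
})

test_that("concentration limits force sharing", {
  m <- we_model()
  # alpha0 -> 0: a second identical observation joins the first's table
  x <- expression_matrix(matrix(c(1.2, 1.2), 2, 1))
  st <- init_state(x, "each-own-table")
  hyper <- hdp_hyper(alpha0 = 1e-9, alpha1 = 1e-9)
  set.seed(5)
  joined <- replicate(400, {
    s2 <- sample_table(1, 2, st, x, m, hyper)
    s2$phi[1, 2] == s2$phi[1, 1]
  })
  expect_gt(mean(joined), 0.99)
  # alpha1 -> 0: two tables with identical data share one dish
  shared <- replicate(400, {
    s2 <- sample_dish(1, 2, st, x, m, hyper)
    d <- s2$tab_dish[[1]]
    d[["1"]] == d[["2"]]
  })
  expect_gt(mean(shared), 0.99)
})

test_that("concentration resampling draws from the Gamma prior", {
  h_off <- hdp_hyper(alpha0 = 0.7, alpha1 = 1.3)
  expect_identical(sample_concentrations(h_off), h_off)
  h_on <- hdp_hyper(gamma_shape = 2, gamma_rate = 4, resample_concentrations = TRUE)
  set.seed(8)
  draws <- replicate(30000, sample_concentrations(h_on)$alpha0)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 2 / 4, tolerance = 0.02)
  expect_equal(var(draws), 2 / 16, tolerance = 0.02)
})

test_that("a sweep conserves customers and keeps the state valid", {
  we <- worked_example()
  set.seed(13)
  st <- we$state; hy <- we$hyper
  for (s in 1:5) {
    sw <- gibbs_sweep(st, we$data, we$model, hy)
    st <- sw$state; hy <- sw$hyper
    expect_length(validate_state(st, we$data), 0)
    expect_true(all(vapply(st$tab_n, sum, 0) == nrow(we$data)))
  }
  # single customer: nothing can change but labels
  one <- expression_matrix(matrix(2, 1, 1))
  s1 <- gibbs_sweep(init_state(one, "each-own-table"), one, we$model, we$hyper)$state
  expect_equal(sum(vapply(s1$tab_dish, length, 1L)), 1L)
  expect_equal(length(s1$dish_tab), 1L)
  # seeded reproducibility of the reference engine
  set.seed(77); a <- gibbs_sweep(we$state, we$data, we$model, we$hyper)$state
  set.seed(77); b <- gibbs_sweep(we$state, we$data, we$model, we$hyper)$state
  expect_identical(a, b)
})
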