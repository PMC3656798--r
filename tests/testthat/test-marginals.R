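# Closed-form collapsed predictives checked against independent quadrature
# and Monte-Carlo oracles.

test_that("prior predictive matches the Gaussian closed form and quadrature", {
  m <- we_model()
  # 1/sqrt(4*pi): marginal of N(0, sigma^2 + s0^2 = 2) at 0
  expect_equal(prior_predictive(0, m), 1 / sqrt(4 * pi), tolerance = 1e-12)
  expect_equal(prior_predictive(1, m), dnorm(1, 0, sqrt(2)), tolerance = 1e-12)
  expect_equal(prior_predictive(1, m), 0.21970, tolerance = 1e-4)
  expect_equal(prior_predictive(0, m), quad_dish_predictive(0, numeric(0), m),
               tolerance = 1e-8)
  # point-mass base measure: plain N(m0, sigma^2) density
  pm <- obs_model(obs_var = 2, prior_mean = 1.5, prior_var = 0)
  expect_equal(prior_predictive(2.5, pm), dnorm(2.5, 1.5, sqrt(2)), tolerance = 1e-12)
  expect_error(prior_predictive(NaN, m), "non-finite")
})

test_that("dish predictive equals the conjugate posterior predictive", {
  m <- we_model()
  expect_equal(dish_predictive(0, numeric(0), m), prior_predictive(0, m))
  # S = {1}: posterior N(0.5, 0.5), predictive N(0.5, 1.5)
  expect_equal(dish_predictive(0, 1, m), dnorm(0, 0.5, sqrt(1.5)), tolerance = 1e-12)
  expect_equal(dish_predictive(0, 1, m), 0.29969, tolerance = 1e-4)
  expect_equal(dish_predictive(0, 0, m), dnorm(0, 0, sqrt(1.5)), tolerance = 1e-12)
  expect_equal(dish_predictive(0, 0, m), 0.32574, tolerance = 1e-4)
})

test_that("closed form, quadrature and Monte Carlo agree on random queries", {
  set.seed(11)
  for (q in 1:20) {
    m <- obs_model(obs_var = runif(1, 0.3, 2), prior_mean = rnorm(1),
                   prior_var = runif(1, 0.2, 2))
    S <- rnorm(sample(0:6, 1), m$prior_mean, 1.5)
    g <- rnorm(1, m$prior_mean, 2)
    closed <- dish_predictive(g, S, m)
    expect_equal(closed, quad_dish_predictive(g, S, m), tolerance = 1e-8)
  }
  m <- we_model()
  mc <- mc_integrate(0, 1, m, n_draws = 2e5, seed = 7)
  # delta-method SE of the ratio is bounded by the component relative SEs
  se <- mc$ratio * (mc$numerator_se / mc$numerator + mc$denominator_se / mc$denominator)
  expect_lt(abs(mc$ratio - dish_predictive(0, 1, m)), 3 * se)
})

test_that("Monte-Carlo estimator behaves like a mean of n draws", {
  m <- we_model()
  # empty conditioning set: denominator is an average of exact ones
  mc <- mc_integrate(0.5, numeric(0), m, n_draws = 1000, seed = 1)
  expect_equal(mc$denominator, 1, tolerance = 1e-12)
  expect_equal(mc$denominator_se, 0, tolerance = 1e-12)
  # SE shrinks roughly 10x when n grows 100x
  a <- mc_integrate(0, c(1, -1), m, n_draws = 1000, seed = 2)
  b <- mc_integrate(0, c(1, -1), m, n_draws = 100000, seed = 3)
  expect_equal(a$numerator_se / b$numerator_se, 10, tolerance = 0.5)
  expect_error(mc_integrate(0, 1, m, n_draws = 10), "at least 100")
})

test_that("dish predictive is a density, exchangeable, and concentrates", {
  m <- we_model()
  S <- c(0.3, -1.2, 2.4)
  # integrates to 1 over the observation
  dens <- integrate(function(g) vapply(g, dish_predictive, 0, S = S, model = m),
                    -40, 40, rel.tol = 1e-9)
  expect_equal(dens$value, 1, tolerance = 1e-6)
  # order of the conditioning multiset is irrelevant
  expect_equal(dish_predictive(0.7, S, m), dish_predictive(0.7, rev(S), m))
  expect_equal(dish_predictive(0.7, S, m), dish_predictive(0.7, sample(S), m))
  # predictive mean approaches the repeated conditioning value
  v <- 1.7
  pred_mean <- function(n) {
    st <- suff_stats(rep(v, n))
    # conjugate posterior mean
    (m$prior_mean / m$prior_var + st$sum / m$obs_var) /
      (1 / m$prior_var + st$n / m$obs_var)
  }
  gap <- abs(vapply(c(1, 10, 100), pred_mean, 0) - v)
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.02)
})
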