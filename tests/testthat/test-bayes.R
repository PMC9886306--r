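test_that("log-likelihood normalizer and monotonicity", {
  expect_equal(log_likelihood(0, 1, 1), -0.5 * log(2 * pi))
  expect_lt(log_likelihood(2, 1.5, 4), log_likelihood(1, 1.5, 4))
  expect_error(log_likelihood(1, 0, 3))
  expect_error(log_likelihood(-1, 1, 3))
})

test_that("grid argmax matches the least-squares parameter", {
  # data simulated from y = a * x, misfit = SSE over a parameter grid
  x <- 1:10
  y <- 2.37 * x
  mis <- function(m) sum((y - m[1] * x)^2)
  post <- quadrature_posterior(mis, c(a = 1), c(a = 4), n_grid = 301,
                               sigma = 1, n_points = 10)
  ls <- sum(x * y) / sum(x^2)
  expect_lt(abs(post$mle[["a"]] - ls), (4 - 1) / 300 + 1e-12)
})

test_that("quadrature posterior normalizes and finds quadratic modes", {
  post <- quadrature_posterior(function(m) 5, c(p = 0), c(p = 1),
                               n_grid = 11, sigma = 1, n_points = 1)
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
  expect_equal(post$weights, rep(1 / 11, 11), tolerance = 1e-12)

  m0 <- 0.437
  post2 <- quadrature_posterior(function(m) (m[1] - m0)^2, c(p = 0),
                                c(p = 1), n_grid = 101, sigma = 0.05,
                                n_points = 1)
  grid <- post2$support[, 1]
  expect_equal(post2$mle[["p"]], grid[which.min(abs(grid - m0))])

  # marginal density integrates to one by the trapezoid rule
  md <- marginal_density(post2, "p")
  tz <- sum(diff(md$value) *
              (head(md$density, -1) + tail(md$density, -1)) / 2)
  expect_equal(tz, 1, tolerance = 1e-10)
})

test_that("grid misfit failures carry grid-point context", {
  expect_error(
    quadrature_posterior(function(m) if (m[1] > 0.5) NaN else 0,
                         c(p = 0), c(p = 1), n_grid = 5,
                         sigma = 1, n_points = 1),
    "grid point")
})

test_that("Metropolis-Hastings samples a standard normal", {
  post <- metropolis_hastings(function(m) -m[1]^2 / 2, c(x = 0.3),
                              proposal_sd = 1.5, n_steps = 1e5,
                              seed = 11)
  g <- fit_gaussian(post)
  expect_lt(abs(g["x", "mean"]), 0.05)
  expect_lt(abs(g["x", "sd"] - 1), 0.05)
  expect_true(post$acceptance_rate > 0.1 && post$acceptance_rate < 0.9)
})

test_that("Metropolis-Hastings is deterministic under a fixed seed and
           always accepts equal-density proposals", {
  lp <- function(m) 0  # flat target: acceptance ratio one
  p1 <- metropolis_hastings(lp, c(x = 0), 1, 500, seed = 3)
  expect_equal(p1$acceptance_rate, 1)
  p2 <- metropolis_hastings(function(m) -m[1]^2 / 2, c(x = 0.3), 1.5,
                            2000, seed = 42)
  p3 <- metropolis_hastings(function(m) -m[1]^2 / 2, c(x = 0.3), 1.5,
                            2000, seed = 42)
  expect_identical(p2$support, p3$support)
  expect_error(metropolis_hastings(function(m) NaN, c(x = 0), 1, 10,
                                   seed = 1))
})

test_that("Gaussian fits moment-match marginals", {
  two_pt <- angiocal:::new_posterior_summary(
    "grid", matrix(c(-3, 3), 2, 1, dimnames = list(NULL, "a")),
    c(0, 0), c(0.5, 0.5), c(a = -3))
  g <- fit_gaussian(two_pt)
  expect_equal(g["a", "mean"], 0)
  expect_equal(g["a", "sd"], 3)

  # round trip: a grid density that is itself Gaussian
  mu <- 2; sdv <- 0.3
  post <- quadrature_posterior(function(m) (m[1] - mu)^2,
                               c(p = 0), c(p = 4), n_grid = 401,
                               sigma = sdv, n_points = 1)
  g2 <- fit_gaussian(post)
  expect_equal(g2["p", "mean"], mu, tolerance = 0.01)
  expect_equal(g2["p", "sd"], sdv, tolerance = 0.01)

  degen <- angiocal:::new_posterior_summary(
    "grid", matrix(c(1, 1), 2, 1, dimnames = list(NULL, "a")),
    c(0, 0), c(0.5, 0.5), c(a = 1))
  expect_error(fit_gaussian(degen), "degenerate")
})

test_that("Gaussian fits print in the N(mean, sd) convention", {
  expect_equal(format_gaussian(243.0, 18.1), "N(243.0, 18.1)")
  expect_equal(format_gaussian(3.96, 0.44, digits = 2), "N(3.96, 0.44)")
})

test_that("quadrature and MH agree on a 1D ODE-model calibration", {
  # tumor growth-rate calibration on the same synthetic data
  gp <- growth_params()
  tt <- 24 * (1:5)
  y <- 5e4 * exp(gp$lambda_T_g * tt)
  sse <- function(lam) sum((y - 5e4 * exp(lam * tt))^2)
  sigma <- 0.05 * mean(y)
  post_q <- quadrature_posterior(function(m) sse(m[1]),
                                 c(lam = 5e-3), c(lam = 1.3e-2),
                                 n_grid = 301, sigma = sigma,
                                 n_points = 5)
  post_m <- metropolis_hastings(
    function(m) log_likelihood(sse(m[1]), sigma, 5),
    c(lam = 7e-3), 5e-4, 3e4, seed = 9,
    lower = 5e-3, upper = 1.3e-2)
  gq <- fit_gaussian(post_q); gm <- fit_gaussian(post_m)
  expect_equal(gq["lam", "mean"], gm["lam", "mean"], tolerance = 0.02)
})
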