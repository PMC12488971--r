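test_that("kalman_update follows the gain formula on worked cases", {
  st <- kalman_update(kalman_state(50, 10), observation = 60, obs_variance = 10)
  expect_equal(st$mu, 55)
  expect_equal(st$var, 5)
  expect_equal(st$lp, 5)

  st0 <- kalman_state(42.5, 3)
  st <- kalman_update(st0, observation = 42.5, obs_variance = 7)
  expect_equal(st$mu, 42.5)
  expect_equal(st$lp, 0)

  expect_error(kalman_update(kalman_state(), 50, obs_variance = 0), "positive")
})

test_that("kalman_update equals the conjugate-posterior oracle on random cases", {
  set.seed(41)
  for (i in 1:1000) {
    mu0 <- runif(1, 0, 100); v0 <- runif(1, 0.01, 50)
    x <- runif(1, 0, 100); s <- 10^runif(1, -1, 3)
    got <- kalman_update(kalman_state(mu0, v0), x, s)
    want <- oracle_conjugate(mu0, v0, x, s)
    expect_lt(abs(got$mu - want$mu), 1e-10)
    expect_lt(abs(got$var - want$var), 1e-10)
  }
})

test_that("posterior variance follows the closed-form precision recursion", {
  st <- kalman_state(50, 10)
  for (t in 1:25) {
    st <- kalman_update(st, 55, 100)
    expect_equal(st$var, 1 / (1 / 10 + t / 100), tolerance = 1e-12)
  }
})

test_that("expected learning progress matches its closed form and Monte Carlo", {
  lp <- expected_learning_progress(kalman_state(50, 10), 10)
  expect_equal(lp, 0.5 * sqrt(2 * 20 / pi), tolerance = 1e-12)
  expect_equal(lp, 1.784, tolerance = 1e-3)
  expect_equal(expected_learning_progress(kalman_state(50, 10), 1000),
               0.251, tolerance = 1e-2)

  ## Monte-Carlo cross-check: mean |realized update| over 1e5 draws
  set.seed(42)
  x <- rnorm(1e5, 50, sqrt(10 + 10))      # predictive draw
  mc <- mean(abs(0.5 * (x - 50)))
  expect_lt(abs(mc - lp), 0.02)

  ## K -> 0 limit
  expect_lt(expected_learning_progress(kalman_state(50, 1e-9), 10), 1e-4)
})

test_that("expected learning progress strictly decreases across updates", {
  for (s in c(0.1, 10, 1000)) {
    st <- kalman_state(50, 10)
    lps <- numeric(30)
    for (t in 1:30) {
      lps[t] <- expected_learning_progress(st, s)
      st <- kalman_update(st, 50, s)
    }
    expect_true(all(diff(lps) < 0))
  }
})

test_that("gp_posterior interpolates and shrinks to the prior", {
  one <- data.frame(row = 3, col = 4, value = 1.7)
  post <- gp_posterior(one, lengthscale = 2, dims = c(5, 5))
  expect_equal(post$pred_mean[3, 4], 1.7, tolerance = 1e-6)

  ## vanishing lengthscale: unrevealed tiles fall back to the prior mean 0
  post <- gp_posterior(one, lengthscale = 0.01, dims = c(5, 5))
  expect_lt(max(abs(post$pred_mean[-((4 - 1) * 5 + 3)])), 1e-8)

  expect_error(gp_posterior(one[0, ], 1), "at least one")
  two <- rbind(one, one)
  expect_error(gp_posterior(two, 1, dims = c(5, 5)), "duplicate")
})

test_that("gp_posterior equals the dense direct-solve oracle on 5x5 lattices", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    idx <- sample(25, n)
    rev <- data.frame(row = (idx - 1) %% 5 + 1, col = (idx - 1) %/% 5 + 1,
                      value = rnorm(n))
    lam <- sample(c(0.5, 1, 2, 4), 1)
    got <- gp_posterior(rev, lam, dims = c(5, 5))$pred_mean
    want <- oracle_gp_dense(rev, lam, dims = c(5, 5))
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("grid_prediction_error honours its contracts", {
  set.seed(44)
  g <- generate_grid(4)
  all_idx <- expand.grid(row = 1:30, col = 1:30)
  expect_equal(grid_prediction_error(g, all_idx), 0)
  expect_error(grid_prediction_error(g, all_idx[0, ]), "at least one")

  ## smooth grids are predictable from few reveals, rough grids are not
  mse_at <- function(lam, n_grids = 30, reveals = 20) {
    mean(replicate(n_grids, {
      gg <- generate_grid(lam)
      rev <- all_idx[sample(900, reveals), ]
      grid_prediction_error(gg, rev)
    }))
  }
  expect_lt(mse_at(16), mse_at(0.25))
})

test_that("standardized error scale divides by the grid value SD", {
  set.seed(45)
  g <- generate_grid(2)
  rev <- data.frame(row = c(1, 15, 30), col = c(1, 15, 30))
  raw <- grid_prediction_error(g, rev, scale = "raw")
  std <- grid_prediction_error(g, rev, scale = "standardized")
  expect_equal(std * sd(as.vector(g$values_raw))^2, raw, tolerance = 1e-4)
})
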