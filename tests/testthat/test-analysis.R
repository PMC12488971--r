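test_that("estimated and expected variance arithmetic", {
  expect_equal(estimated_variance(c(50, 50, 50)), 0)
  expect_equal(estimated_variance(c(1, 3)), 2)
  expect_error(estimated_variance(5), "at least 2")

  expect_equal(expected_variance(data.frame(est_variance = c(2, 10),
                                            n_guesses = c(3, 6))),
               (2 * 3 + 10 * 6) / 9)
  expect_equal(expected_variance(data.frame(est_variance = 7, n_guesses = 4)), 7)
  expect_equal(expected_variance(data.frame(est_variance = c(4, 8),
                                            n_guesses = c(5, 5))), 6)
  expect_error(expected_variance(data.frame(est_variance = numeric(),
                                            n_guesses = integer())), "empty")
})

test_that("estimated variance is consistent for machine emissions", {
  set.seed(71)
  x <- machine_emit(machine(50, 100), 1e4, round = FALSE)
  expect_true(estimated_variance(x) > 85 && estimated_variance(x) < 115)
})

test_that("disparity_table drops first and censored sessions and is antisymmetric", {
  sessions <- data.frame(participant = 1, session = 1:3,
                         mean = 50, variance = 10,
                         n_guesses = 3, censored = c(FALSE, FALSE, TRUE),
                         est_variance = NA)
  guesses <- data.frame(participant = 1, session = rep(1:3, each = 3),
                        trial = rep(1:3, 3), guess = 50,
                        emitted = rep(c(49, 50, 51), 3))
  log <- make_session_log(sessions, guesses)
  dt <- disparity_table(log)
  expect_identical(nrow(dt), 1L)           # session 2 only
  expect_equal(dt$session, 2)
  ## identical history and current emissions: disparity exactly 0
  expect_equal(dt$disparity, 0)
  expect_equal(dt$disparity,
               -(dt$expected_variance - dt$est_variance))

  dt_log <- disparity_table(log, scale = "log10")
  expect_equal(dt_log$disparity, 0)
})

test_that("level measures implement the stated formulas", {
  smm <- data.frame(level = 1:2, attempts = c(100, 100), clears = c(25, 80),
                    stars = c(10, 30), creator_category = c(3, 1))
  attr(smm, "schema") <- "smm"
  ms <- level_measures(smm)
  expect_equal(ms$difficulty, c(0.75, 0.20))
  expect_equal(ms$enjoyment, c(0.10, 0.30))
  expect_equal(ms$difficulty_disparity, c(0, 0))  # self-calibrating map

  rb <- data.frame(level = 1, upvotes = 30, downvotes = 10, rating = 3.2,
                   attempts = 40, clears = 10)
  expect_equal(level_measures(rb, "robozzle")$enjoyment, 0.75)

  ## zero attempts / zero votes rows are skipped with a warning
  smm0 <- rbind(smm, data.frame(level = 3, attempts = 0, clears = 0,
                                stars = 0, creator_category = 2))
  attr(smm0, "schema") <- "smm"
  expect_warning(ms0 <- level_measures(smm0), "zero attempts")
  expect_identical(nrow(ms0), 2L)
  rb0 <- data.frame(level = 1:2, upvotes = c(3, 0), downvotes = c(1, 0),
                    rating = 2, attempts = 10, clears = 5)
  expect_warning(msr <- level_measures(rb0, "robozzle"), "zero votes")
  expect_true(all(msr$enjoyment >= 0 & msr$enjoyment <= 1))
})

test_that("fit_count_quadratic recovers signs and flags degenerate input", {
  set.seed(72)
  log <- generate_guessing_cohort(60)
  ss <- log$sessions[!log$sessions$censored, ]
  ss$cond <- log10(ss$variance)
  res <- fit_count_quadratic(ss, "n_guesses", "cond",
                             predictor_ref = log10(c(0.1, 1, 10, 100, 1000)),
                             floor = 3)
  co <- res$coefficients
  expect_gt(co$estimate[co$term == "z"], 0)
  expect_lt(co$estimate[co$term == "I(z^2)"], 0)
  expect_lt(co$p[co$term == "I(z^2)"], 0.05)

  ## degenerate: response stuck at the floor
  ss$flat <- 3L
  expect_warning(dres <- fit_count_quadratic(ss, "flat", "cond", floor = 3),
                 "degenerate")
  expect_true(dres$degenerate)

  expect_error(fit_count_quadratic(ss[ss$participant == 1, ],
                                   "n_guesses", "cond"), "participants")
})

test_that("permuted condition labels rarely produce a quadratic effect", {
  set.seed(73)
  log <- generate_guessing_cohort(60)
  ss <- log$sessions[!log$sessions$censored, ]
  covered <- 0L
  nperm <- 50L
  for (i in seq_len(nperm)) {
    ss$cond <- sample(log10(ss$variance))
    res <- fit_count_quadratic(ss, "n_guesses", "cond", floor = 3,
                               method = "fixed")
    co <- res$coefficients
    q <- co[co$term == "I(z^2)", ]
    covered <- covered + as.integer(q$conf_lo <= 0 && q$conf_hi >= 0)
  }
  expect_gte(covered, 45L)   # >= 90% of permutations
})

test_that("polynomial comparison separates quadratic from cubic worlds", {
  set.seed(74)
  ## pure inverted-U on the probability scale: quadratic, no cubic gain
  tb2 <- generate_level_table(2000, "robozzle")
  cmp2 <- fit_polynomial_enjoyment(level_measures(tb2))
  expect_equal(cmp2$selected_degree, 2)

  ## low-difficulty success bonus: cubic wins
  tb3 <- generate_level_table(2000, "smm",
                              params = list(success_bonus = 0.15))
  cmp3 <- fit_polynomial_enjoyment(level_measures(tb3))
  expect_equal(cmp3$selected_degree, 3)

  ## constant enjoyment: nothing beats the intercept
  flat <- data.frame(difficulty = runif(300), enjoyment = 0.5)
  expect_equal(fit_polynomial_enjoyment(flat)$selected_degree, 0)
})

test_that("update convergence trend is negative for Kalman guessers", {
  set.seed(75)
  log <- generate_guessing_cohort(40)
  res <- update_convergence_trend(log)
  sl <- res$coefficients[res$coefficients$term == "trial", ]
  expect_lt(sl$estimate, 0)
  expect_lt(sl$p, 0.01)
})

test_that("update convergence handles degenerate logs", {
  sessions <- data.frame(participant = c(1, 2), session = 1,
                         mean = 50, variance = 1, n_guesses = 3,
                         censored = FALSE, est_variance = NA)
  guesses <- data.frame(participant = rep(c(1, 2), each = 3), session = 1,
                        trial = rep(1:3, 2), guess = 50, emitted = 50)
  res <- update_convergence_trend(make_session_log(sessions, guesses))
  expect_identical(res$coefficients$estimate, 0)

  ## single update per session at a fixed trial index: slope undefined
  g2 <- guesses[guesses$trial <= 2, ]
  sessions2 <- transform(sessions, n_guesses = 2)
  expect_error(update_convergence_trend(make_session_log(sessions2, g2)),
               "no variation")
})

test_that("manipulation check orders difficulty by variance", {
  set.seed(76)
  log <- generate_guessing_cohort(80, guess_noise_sd = 0)
  mc <- manipulation_check(log)
  expect_true(all(diff(mc$by_variance$mean_abs_error) > 0))
  expect_lt(mc$exact_cor, -0.8)
  ## low variance, integer scale: frequent exact matches after convergence
  g <- merge(log$guesses,
             log$sessions[c("participant", "session", "variance")])
  late01 <- g[g$variance == 0.1 & g$trial > 3, ]
  expect_gt(mean(late01$guess == late01$emitted), 0.5)

  ## undefined correlation is flagged
  one <- make_session_log(
    data.frame(participant = 1, session = 1:2, mean = 50, variance = 1,
               n_guesses = 3, censored = c(FALSE, FALSE), est_variance = NA),
    data.frame(participant = 1, session = rep(1:2, each = 3),
               trial = rep(1:3, 2), guess = 50, emitted = c(50, 50, 50, 50, 50, 50)))
  expect_warning(mc1 <- manipulation_check(one), "undefined")
  expect_true(is.na(mc1$exact_cor))
})
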