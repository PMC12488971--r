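#' Stopping-rule configuration
#'
#' The agent keeps interacting with an environment while its learning
#' progress per step stays above `threshold`; it is forced to take at least
#' `min_steps` interactions (3 guesses per machine, 5 tiles per grid, as in
#' the experiments) and is capped at `max_steps`.
#'
#' @param threshold Learning-progress threshold, > 0 (default 0.5).
#' @param min_steps Forced minimum interactions (default 3).
#' @param max_steps Safety cap (default 200).
#' @param mode `"deterministic"` (expected learning progress; reproducible
#'   without averaging) or `"monte-carlo"` (average stopping point of `reps`
#'   stochastic runs).
#' @param reps Monte-Carlo repetitions (default 1000).
#' @return An object of class `stopping_config`.
#' @export
stopping_config <- function(threshold = 0.5, min_steps = 3L, max_steps = 200L,
                            mode = c("deterministic", "monte-carlo"),
                            reps = 1000L) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, min_steps >= 1, max_steps > min_steps, reps >= 1)
  structure(list(threshold = threshold, min_steps = as.integer(min_steps),
                 max_steps = as.integer(max_steps), mode = mode,
                 reps = as.integer(reps)),
            class = "stopping_config")
}

## One deterministic stopping pass: iterate the expected-learning-progress
## proxy; n is the first step whose LP falls below threshold (that step's
## observation is consumed), floored and capped.
machine_stop_deterministic <- function(prior_mean, prior_var, true_var, cfg) {
  st <- kalman_state(prior_mean, prior_var)
  for (t in seq_len(cfg$max_steps)) {
    lp <- expected_learning_progress(st, true_var)
    if (lp < cfg$threshold) return(max(t, cfg$min_steps))
    st <- structure(list(mu = st$mu, var = (1 - st$var / (st$var + true_var)) * st$var,
                         lp = lp), class = "kalman_state")
  }
  warning("machine stopping cap reached at max_steps = ", cfg$max_steps)
  cfg$max_steps
}

#' Simulate engagement with one machine
#'
#' Runs the Kalman mean tracker against a machine of the given true variance
#' and returns the number of guesses before the update of the mean falls
#' below the stopping threshold. In deterministic mode learning progress is
#' the expected absolute mean update; in Monte-Carlo mode actual emissions
#' are drawn and the realized |mean update| is used, averaging the stopping
#' step over `cfg$reps` runs.
#'
#' @param prior_mean,prior_var Agent prior (simulation default 50 and 10).
#' @param true_var True machine variance driving both emissions and the gain.
#' @param cfg A [stopping_config()] (`min_steps` 3 for machines).
#' @param true_mean Machine mean used in Monte-Carlo mode (default 50).
#' @return Number of guesses (integer in deterministic mode, mean over runs
#'   in Monte-Carlo mode).
#' @export
simulate_machine_engagement <- function(prior_mean = 50, prior_var = 10,
                                        true_var, cfg = stopping_config(),
                                        true_mean = 50) {
  stopifnot(inherits(cfg, "stopping_config"), true_var > 0, prior_var > 0)
  if (cfg$mode == "deterministic")
    return(machine_stop_deterministic(prior_mean, prior_var, true_var, cfg))
  m <- machine(true_mean, true_var)
  one <- function() {
    st <- kalman_state(prior_mean, prior_var)
    for (t in seq_len(cfg$max_steps)) {
      st <- kalman_update(st, machine_emit(m, round = FALSE), true_var)
      if (st$lp < cfg$threshold) return(max(t, cfg$min_steps))
    }
    cfg$max_steps
  }
  mean(replicate(cfg$reps, one()))
}

#' Engagement sweep over priors and variances
#'
#' Computes simulated engagement for every combination of prior variance and
#' true machine variance, the summary behind the inverted-U engagement
#' curves: with a prior variance of 10 and the five design variances, the
#' longest interaction happens at an intermediate variance, and the peak
#' variance grows with the prior.
#'
#' @param prior_vars Prior variances to sweep.
#' @param variances True machine variances (default the five design values).
#' @param cfg A [stopping_config()].
#' @param prior_mean Agent prior mean.
#' @return Data frame (class `engagement_curve`) with columns `prior_var`,
#'   `variance`, `engagement`, `threshold`, `mode`.
#' @export
sweep_variance_engagement <- function(prior_vars = 10,
                                      variances = MACHINE_VARIANCES,
                                      cfg = stopping_config(),
                                      prior_mean = 50) {
  stopifnot(length(prior_vars) >= 1, length(variances) >= 1)
  out <- expand.grid(prior_var = prior_vars, variance = variances,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$prior_var, out$variance), ]
  out$engagement <- mapply(function(pv, v)
    simulate_machine_engagement(prior_mean, pv, v, cfg),
    out$prior_var, out$variance)
  out$threshold <- cfg$threshold
  out$mode <- cfg$mode
  rownames(out) <- NULL
  class(out) <- c("engagement_curve", "data.frame")
  out
}

## Fast MSE trajectory for one grid under uniformly random reveals.
## Recomputes the dense solve per step on the revealed subset; t stays small
## relative to 900 so this is cheap. Returns MSE after t = 1..horizon
## reveals (step 1 is the free tile shown when a grid appears).
grid_mse_trajectory <- function(grid, horizon, lengthscale = grid$lengthscale,
                                scale = c("raw", "standardized"),
                                jitter = 1e-8, order = NULL,
                                stop_fn = NULL) {
  scale <- match.arg(scale)
  vals <- as.vector(grid$values_raw)   # latent surface; see vignette
  if (scale == "standardized") vals <- (vals - mean(vals)) / stats::sd(vals)
  ntile <- length(vals)
  if (is.null(order)) order <- sample.int(ntile)
  horizon <- min(horizon, ntile)
  Kfull <- rbf_kernel(grid_coords(dim(grid$values)), lengthscale)
  out <- numeric(horizon)
  for (t in seq_len(horizon)) {
    obs <- order[seq_len(t)]
    ctr <- mean(vals[obs])
    U <- chol(Kfull[obs, obs, drop = FALSE] + diag(jitter, t))
    a <- backsolve(U, forwardsolve(t(U), vals[obs] - ctr))
    if (t < ntile) {
      un <- order[(t + 1L):ntile]
      pred <- ctr + drop(Kfull[un, obs, drop = FALSE] %*% a)
      out[t] <- mean((pred - vals[un])^2)
    } else out[t] <- 0
    if (!is.null(stop_fn) && stop_fn(t, out)) return(out[seq_len(t)])
  }
  out
}

#' Mean GP learning curves per lengthscale
#'
#' For each lengthscale, generates `n_grids` landscapes, reveals tiles
#' uniformly at random (the first tile free, as in the game), refits the GP
#' after every reveal and records the mean squared error over the unrevealed
#' tiles, then averages across grids. Smooth grids (large lambda) reach zero
#' error quickly, rough grids (small lambda) plateau immediately; only
#' intermediate lambdas keep learning over a long stretch.
#'
#' @param lengthscales Lambdas to sweep (default the seven design values).
#' @param n_grids Grids per lengthscale (200 is desk scale; the reference
#'   simulation used 1000).
#' @param horizon Number of reveals per grid.
#' @param scale Error scale, `"raw"` (points squared, default) or
#'   `"standardized"`.
#' @return Data frame with columns `lengthscale`, `step`, `mean_mse`,
#'   `n_grids`.
#' @export
mse_learning_curves <- function(lengthscales = GRID_LENGTHSCALES,
                                n_grids = 200L, horizon = 100L,
                                scale = "raw") {
  stopifnot(n_grids >= 1, horizon >= 1, horizon <= prod(GRID_DIM))
  res <- lapply(lengthscales, function(lam) {
    acc <- numeric(horizon)
    for (g in seq_len(n_grids))
      acc <- acc + grid_mse_trajectory(generate_grid(lam), horizon,
                                       scale = scale)
    data.frame(lengthscale = lam, step = seq_len(horizon),
               mean_mse = acc / n_grids, n_grids = n_grids)
  })
  do.call(rbind, res)
}

#' Simulate engagement with one grid
#'
#' Reveals tiles uniformly at random and stops at the first step (at or past
#' `min_steps`) where the absolute difference of the prediction error
#' between two consecutive steps falls below the threshold. Error is the GP
#' mean squared error over unrevealed tiles on the raw point scale by
#' default (see the package vignette for why the threshold of 0.5 lives on
#' this scale).
#'
#' @param grid A `grid_env`.
#' @param cfg A [stopping_config()]; use `min_steps = 5`, `max_steps = 900`.
#' @param lengthscale Learner lengthscale (defaults to the grid's, the
#'   matched-model simulation).
#' @param scale `"raw"` or `"standardized"` error scale.
#' @return Number of tiles revealed (including the free first tile).
#' @export
simulate_grid_engagement <- function(grid, cfg = stopping_config(min_steps = 5L,
                                                                 max_steps = 900L),
                                     lengthscale = grid$lengthscale,
                                     scale = "raw") {
  stopifnot(inherits(grid, "grid_env"), inherits(cfg, "stopping_config"))
  cap <- min(cfg$max_steps, prod(dim(grid$values)))
  stopped <- FALSE
  stop_fn <- function(t, mse) {
    ok <- t >= cfg$min_steps && t >= 2L &&
      abs(mse[t] - mse[t - 1L]) < cfg$threshold
    if (ok) stopped <<- TRUE
    ok
  }
  traj <- grid_mse_trajectory(grid, cap, lengthscale = lengthscale,
                              scale = scale, stop_fn = stop_fn)
  if (!stopped && length(traj) == cap && cap == cfg$max_steps)
    warning("grid stopping cap reached at max_steps = ", cfg$max_steps)
  length(traj)
}

#' Engagement sweep over lengthscales
#'
#' Mean simulated tiles opened per grid as a function of the lengthscale:
#' the inverted-U over smoothness.
#'
#' @inheritParams mse_learning_curves
#' @param cfg A [stopping_config()] with grid defaults.
#' @return Data frame (class `engagement_curve`) with columns `lengthscale`,
#'   `engagement` (mean tiles), `sd`, `n_grids`, `threshold`.
#' @export
sweep_lengthscale_engagement <- function(lengthscales = GRID_LENGTHSCALES,
                                         n_grids = 200L,
                                         cfg = stopping_config(min_steps = 5L,
                                                               max_steps = 900L),
                                         scale = "raw") {
  res <- lapply(lengthscales, function(lam) {
    n <- vapply(seq_len(n_grids), function(g)
      simulate_grid_engagement(generate_grid(lam), cfg, scale = scale),
      numeric(1))
    data.frame(lengthscale = lam, engagement = mean(n), sd = stats::sd(n),
               n_grids = n_grids, threshold = cfg$threshold)
  })
  out <- do.call(rbind, res)
  class(out) <- c("engagement_curve", "data.frame")
  out
}
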