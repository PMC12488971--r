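#' Kalman state for tracking a machine's mean
#'
#' The agent tracks the mean of the current machine with a Gaussian belief:
#' `mu` is the estimated mean, `var` the uncertainty about that mean. The
#' simulation prior is mu = 50, var = 10.
#'
#' @param mu Estimated mean (points).
#' @param var Estimated variance of the mean estimate (points squared), > 0.
#' @return An object of class `kalman_state` with elements `mu`, `var`, and
#'   `lp` (the learning progress |delta mu| of the most recent update, NA
#'   before any update).
#' @export
kalman_state <- function(mu = 50, var = 10) {
  stopifnot(is.finite(mu), is.numeric(var), var > 0)
  structure(list(mu = mu, var = var, lp = NA_real_), class = "kalman_state")
}

#' Kalman update of the mean estimate
#'
#' Standard scalar Kalman step with gain K = var / (var + obs_var):
#' mu' = mu + K (x - mu), var' = (1 - K) var. Equivalent to conjugate
#' Gaussian posterior updating (precision addition). Learning progress of the
#' step is |mu' - mu|, stored in the returned state's `lp`.
#'
#' @param state A `kalman_state`.
#' @param observation Observed number x.
#' @param obs_variance True observation variance of the machine, > 0.
#' @return Updated `kalman_state`.
#' @export
kalman_update <- function(state, observation, obs_variance) {
  stopifnot(inherits(state, "kalman_state"), is.finite(observation))
  if (!is.numeric(obs_variance) || obs_variance <= 0)
    stop("obs_variance must be positive")
  K <- state$var / (state$var + obs_variance)
  mu <- state$mu + K * (observation - state$mu)
  structure(list(mu = mu, var = (1 - K) * state$var,
                 lp = abs(mu - state$mu)),
            class = "kalman_state")
}

#' Expected learning progress of the next Kalman step
#'
#' Before observing x, the predictive distribution is
#' N(mu, var + obs_var), so the expected absolute mean update is
#' K * E|x - mu| = K * sqrt(2 (var + obs_var) / pi). This deterministic
#' proxy drives the reproducible stopping rule.
#'
#' @inheritParams kalman_update
#' @return Expected |mean update| (points).
#' @export
expected_learning_progress <- function(state, obs_variance) {
  stopifnot(inherits(state, "kalman_state"))
  if (!is.numeric(obs_variance) || obs_variance <= 0)
    stop("obs_variance must be positive")
  K <- state$var / (state$var + obs_variance)
  K * sqrt(2 * (state$var + obs_variance) / pi)
}

#' Gaussian-process posterior over a tile lattice
#'
#' Noise-free GP regression with the package's RBF kernel and zero prior
#' mean: given revealed tiles, predicts the value of every tile on the
#' lattice. A small jitter keeps the observation covariance well conditioned,
#' so predictions at revealed tiles reproduce the observations to within
#' jitter tolerance.
#'
#' @param revealed Data frame with columns `row`, `col` (1-based lattice
#'   coordinates) and `value`.
#' @param lengthscale Kernel lengthscale lambda assumed by the learner.
#' @param jitter Diagonal jitter variance (default 1e-8).
#' @param dims Lattice dimensions, default 30x30.
#' @param prior_mean Prior mean subtracted before and added back after
#'   regression (default 0).
#' @return An object of class `gp_posterior`: list with `pred_mean`
#'   (dims[1] x dims[2] matrix), `revealed`, `lengthscale`.
#' @export
gp_posterior <- function(revealed, lengthscale, jitter = 1e-8,
                         dims = GRID_DIM, prior_mean = 0) {
  if (!is.data.frame(revealed) || nrow(revealed) < 1L)
    stop("need at least one revealed tile")
  stopifnot(all(c("row", "col", "value") %in% names(revealed)))
  if (anyDuplicated(revealed[c("row", "col")]))
    stop("duplicate revealed coordinates")
  if (any(revealed$row < 1 | revealed$row > dims[1] |
          revealed$col < 1 | revealed$col > dims[2]))
    stop("revealed coordinates outside the lattice")
  X <- cbind(revealed$row - 1, revealed$col - 1)
  Xs <- as.matrix(expand.grid(row = seq_len(dims[1]) - 1L,
                              col = seq_len(dims[2]) - 1L))
  Koo <- rbf_kernel(X, lengthscale) + diag(jitter, nrow(X))
  Kso <- rbf_kernel(Xs, lengthscale, y = X)
  U <- chol(Koo)   # two triangular solves == Koo^-1 y via the factor
  a <- backsolve(U, forwardsolve(t(U), revealed$value - prior_mean))
  pred <- prior_mean + drop(Kso %*% a)
  structure(list(pred_mean = matrix(pred, dims[1], dims[2]),
                 revealed = revealed, lengthscale = lengthscale),
            class = "gp_posterior")
}

#' Mean squared prediction error on a grid
#'
#' Fits the GP posterior to the revealed tiles and returns the mean squared
#' difference between predictions and ground truth over the unrevealed tiles
#' (the model's "predictions of the values of all other tiles"). The revealed
#' values are centered at their own mean before regression, so the zero-mean
#' prior acts on residuals. `scale = "standardized"` divides the grid by its
#' own value standard deviation first, giving a per-grid unit-variance error
#' scale; the default is the raw point scale.
#'
#' @param grid A `grid_env`.
#' @param revealed Data frame with `row`, `col` (values are looked up from
#'   the grid; a `value` column, if present, is ignored).
#' @param lengthscale Learner lengthscale; defaults to the grid's own.
#' @param scale `"raw"` (points squared) or `"standardized"`.
#' @param over `"unrevealed"` (default) or `"all"` tiles.
#' @param surface `"latent"` (default): learn the continuous pre-rounding
#'   surface; `"displayed"`: learn the integer-rounded tile values. Rounding
#'   injects a noise floor that blurs the stopping rule's step decrements,
#'   so simulations run on the latent surface.
#' @param jitter Passed to [gp_posterior()].
#' @return Mean squared error (0 when every tile is revealed and
#'   `over = "unrevealed"`).
#' @export
grid_prediction_error <- function(grid, revealed,
                                  lengthscale = grid$lengthscale,
                                  scale = c("raw", "standardized"),
                                  over = c("unrevealed", "all"),
                                  surface = c("latent", "displayed"),
                                  jitter = 1e-8) {
  stopifnot(inherits(grid, "grid_env"))
  scale <- match.arg(scale)
  over <- match.arg(over)
  if (!is.data.frame(revealed) || nrow(revealed) < 1L)
    stop("need at least one revealed tile")
  vals <- switch(match.arg(surface), latent = grid$values_raw,
                 displayed = grid$values)
  if (scale == "standardized")
    vals <- (vals - mean(vals)) / stats::sd(vals)
  idx <- (revealed$col - 1L) * nrow(vals) + revealed$row
  if (anyDuplicated(idx)) stop("duplicate revealed coordinates")
  obs <- data.frame(row = revealed$row, col = revealed$col,
                    value = vals[idx])
  ctr <- mean(obs$value)
  obs$value <- obs$value - ctr
  post <- gp_posterior(obs, lengthscale, jitter = jitter,
                       dims = dim(vals))
  pred <- post$pred_mean + ctr
  target <- if (over == "all") seq_along(vals) else setdiff(seq_along(vals), idx)
  if (!length(target)) return(0)
  mean((pred[target] - vals[target])^2)
}
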