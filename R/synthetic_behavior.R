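## Design-based scalings: both experiments place their conditions on a
## log-spaced ladder, so conditions enter generating models and default
## analyses as z-scores of log10(variance) / log2(lengthscale) over the
## design values. Magnitude (max tile value) is Uniform(45, 75) by
## construction.
design_z <- function(x, ref) (x - mean(ref)) / stats::sd(ref)
Z_VAR_REF <- log10(MACHINE_VARIANCES)
Z_LAM_REF <- log2(GRID_LENGTHSCALES)
Z_MAG_MEAN <- 60
Z_MAG_SD <- 30 / sqrt(12)

#' Generating model for synthetic engagement counts
#'
#' Houses the generating analogues of the fitted engagement coefficients.
#' Counts per session are `floor + NegBin(mu, dispersion)` with
#' `log mu = intercept + linear z + quadratic z^2 + disparity_quad dz^2 +
#' magnitude z_mag + u`, where `z` is the scaled condition (log-variance or
#' log-lengthscale), `dz` the difficulty-expectation disparity divided by
#' `disparity_scale`, `z_mag` the scaled maximum tile value, and `u` a
#' participant random intercept with SD `random_sd`.
#'
#' @param intercept Log baseline count above the floor.
#' @param linear,quadratic Coefficients on the scaled condition and its
#'   square (a negative quadratic generates the inverted U).
#' @param disparity_quad Coefficient on the squared scaled disparity.
#' @param magnitude Coefficient on the scaled maximum tile value (grids).
#' @param random_sd Participant random-intercept SD.
#' @param dispersion Negative-binomial size parameter, > 0.
#' @param budget Interaction budget per participant (guesses or tiles),
#'   the count proxy for the 10-minute session.
#' @param disparity_scale Disparity units per unit of `dz` (default 1000
#'   points squared, the span of the design variances, so the largest
#'   attainable disparities contribute a few log units; use 1 with the
#'   log10 metric, where a unit is one decade of variance).
#' @param disparity_metric `"raw"` (variance difference, the main
#'   definition) or `"log10"` (difference of log10 variances; the design
#'   variances are log-spaced and estimation noise is symmetric on this
#'   scale).
#' @return An object of class `engagement_model`.
#' @export
engagement_model <- function(intercept = log(5), linear = 0.3,
                             quadratic = -0.5, disparity_quad = 0,
                             magnitude = 0, random_sd = 0.3,
                             dispersion = 8, budget = 77,
                             disparity_scale = 1000,
                             disparity_metric = c("raw", "log10")) {
  disparity_metric <- match.arg(disparity_metric)
  stopifnot(dispersion > 0, random_sd >= 0, budget >= 3,
            disparity_scale > 0)
  structure(as.list(environment()), class = "engagement_model")
}

#' Defaults for the grid exploration cohort
#'
#' Same structure as [engagement_model()] with defaults matching grid
#' sessions: baseline 31 tiles above the floor of 5 (cohort means near 36
#' tiles per grid and 40 grids per participant), a positive magnitude
#' effect, and a tile budget of 1400.
#'
#' @inheritParams engagement_model
#' @return An `engagement_model`.
#' @export
grid_engagement_model <- function(intercept = log(31), linear = 0.3,
                                  quadratic = -0.5, magnitude = 0.1,
                                  random_sd = 0.3, dispersion = 8,
                                  budget = 1400) {
  engagement_model(intercept = intercept, linear = linear,
                   quadratic = quadratic, disparity_quad = 0,
                   magnitude = magnitude, random_sd = random_sd,
                   dispersion = dispersion, budget = budget)
}

nb_count <- function(mu, size, floor_n)
  floor_n + as.integer(stats::rnbinom(1L, size = size, mu = mu))

#' Generate a synthetic guessing-game cohort
#'
#' Emulates per-participant machine sessions: machines sampled from the
#' experimental design, guesses produced by a Kalman tracker (guess =
#' rounded posterior mean plus small integer noise), emissions from the
#' machine, and per-machine guess counts drawn from the negative-binomial
#' engagement model. Sessions stop when the guess budget is exhausted; the
#' final, interrupted session is flagged censored. Every session has at
#' least three guesses.
#'
#' @param n_participants Number of participants (0 gives an empty log).
#' @param model An [engagement_model()].
#' @param guess_noise_sd SD of the integer guess jitter around the Kalman
#'   mean (default 2 points).
#' @return An object of class `session_log`: list with `sessions` (one row
#'   per machine) and `guesses` (one row per guess), plus `kind` and the
#'   generating `model`.
#' @export
generate_guessing_cohort <- function(n_participants, model = engagement_model(),
                                     guess_noise_sd = 2) {
  stopifnot(inherits(model, "engagement_model"), n_participants >= 0)
  sess <- list(); gus <- list()
  for (p in seq_len(n_participants)) {
    u <- stats::rnorm(1, 0, model$random_sd)
    used <- 0L; s <- 0L
    hist_v <- numeric(0); hist_n <- integer(0)
    while (used < model$budget) {
      s <- s + 1L
      m <- sample_machine(id = sprintf("p%d_m%d", p, s))
      z <- design_z(log10(m$variance), Z_VAR_REF)
      dz2 <- 0
      if (model$disparity_quad != 0 && length(hist_v)) {
        d <- if (model$disparity_metric == "log10") {
          lh <- log10(pmax(hist_v, 1 / 12))
          log10(m$variance) - sum(lh * hist_n) / sum(hist_n)
        } else {
          m$variance - sum(hist_v * hist_n) / sum(hist_n)
        }
        dz2 <- (d / model$disparity_scale)^2
      }
      mu <- exp(model$intercept + model$linear * z +
                  model$quadratic * z^2 + model$disparity_quad * dz2 + u)
      n <- nb_count(mu, model$dispersion, 3L)
      censored <- used + n >= model$budget
      if (censored) n <- max(3L, as.integer(model$budget - used))
      used <- used + n
      emitted <- machine_emit(m, n)
      st <- kalman_state(50, 10)
      guess <- integer(n)
      for (t in seq_len(n)) {
        g <- base::round(st$mu) + base::round(stats::rnorm(1, 0, guess_noise_sd))
        guess[t] <- min(100L, max(0L, g))
        st <- kalman_update(st, emitted[t], m$variance)
      }
      est_v <- stats::var(emitted)
      hist_v <- c(hist_v, est_v); hist_n <- c(hist_n, n)
      sess[[length(sess) + 1L]] <- data.frame(
        participant = p, session = s, mean = m$mean, variance = m$variance,
        n_guesses = n, censored = censored, est_variance = est_v)
      gus[[length(gus) + 1L]] <- data.frame(
        participant = p, session = s, trial = seq_len(n),
        guess = guess, emitted = emitted)
    }
  }
  structure(list(sessions = if (length(sess)) do.call(rbind, sess) else
                   data.frame(participant = integer(), session = integer(),
                              mean = numeric(), variance = numeric(),
                              n_guesses = integer(), censored = logical(),
                              est_variance = numeric()),
                 guesses = if (length(gus)) do.call(rbind, gus) else
                   data.frame(participant = integer(), session = integer(),
                              trial = integer(), guess = integer(),
                              emitted = numeric()),
                 kind = "guessing", model = model),
            class = "session_log")
}

#' Generate a synthetic grid-exploration cohort
#'
#' Emulates per-participant grid sessions: landscapes sampled per the
#' experimental design (lengthscale uniform over the seven design values,
#' value minimum uniform on [5, 35]), tiles revealed uniformly at random,
#' and per-grid tile counts from the negative-binomial engagement model with
#' a scaled log-lengthscale condition and a scaled magnitude (maximum tile
#' value) term. Every session opens at least five tiles; the final session
#' is censored by the tile budget.
#'
#' @param n_participants Number of participants.
#' @param model A [grid_engagement_model()].
#' @param tiles Keep the per-tile reveal rows (default TRUE)? With
#'   `tiles = FALSE` the full surfaces are never built (the rescaling pins
#'   the maximum tile value at `value_min + 40`), which is much faster for
#'   recovery studies; the random stream then differs from `tiles = TRUE`.
#' @return A `session_log` with `sessions` (one row per grid) and `tiles`
#'   (one row per reveal; empty data frame when `tiles = FALSE`).
#' @export
generate_grid_cohort <- function(n_participants, model = grid_engagement_model(),
                                 tiles = TRUE) {
  stopifnot(inherits(model, "engagement_model"), n_participants >= 0)
  sess <- list(); tl <- list()
  for (p in seq_len(n_participants)) {
    u <- stats::rnorm(1, 0, model$random_sd)
    used <- 0L; s <- 0L
    while (used < model$budget) {
      s <- s + 1L
      lam <- sample(GRID_LENGTHSCALES, 1L)
      if (tiles) {
        g <- generate_grid(lam, id = sprintf("p%d_g%d", p, s))
        vmin <- g$value_min
        vmax <- max(g$values)
      } else {
        ## the affine rescale pins max = min + 40, so the session table does
        ## not need the full surface
        vmin <- stats::runif(1, 5, 35)
        vmax <- base::round(vmin + GRID_SPAN)
      }
      z <- design_z(log2(lam), Z_LAM_REF)
      zm <- (vmax - Z_MAG_MEAN) / Z_MAG_SD
      mu <- exp(model$intercept + model$linear * z + model$quadratic * z^2 +
                  model$magnitude * zm + u)
      n <- nb_count(mu, model$dispersion, 5L)
      censored <- used + n >= model$budget
      if (censored) n <- max(5L, as.integer(model$budget - used))
      used <- used + n
      n <- min(n, prod(GRID_DIM))
      sess[[length(sess) + 1L]] <- data.frame(
        participant = p, session = s, lengthscale = lam,
        value_min = vmin, magnitude = vmax, n_tiles = n,
        censored = censored)
      if (tiles) {
        ord <- sample.int(prod(dim(g$values)), n)
        rw <- (ord - 1L) %% nrow(g$values) + 1L
        cl <- (ord - 1L) %/% nrow(g$values) + 1L
        tl[[length(tl) + 1L]] <- data.frame(
          participant = p, session = s, step = seq_len(n),
          row = rw, col = cl, value = g$values[cbind(rw, cl)])
      }
    }
  }
  structure(list(sessions = if (length(sess)) do.call(rbind, sess) else
                   data.frame(participant = integer(), session = integer(),
                              lengthscale = numeric(), value_min = numeric(),
                              magnitude = numeric(), n_tiles = integer(),
                              censored = logical()),
                 tiles = if (length(tl)) do.call(rbind, tl) else
                   data.frame(participant = integer(), session = integer(),
                              step = integer(), row = integer(),
                              col = integer(), value = numeric()),
                 kind = "grid", model = model),
            class = "session_log")
}

#' Generate a synthetic game-level table
#'
#' Emulates the schemas of the three game datasets: per-level attempt counts
#' from a heavy-tailed count law, clears binomial in a hidden true clear
#' probability, an enjoyment signal (stars, up/down votes, or awards) whose
#' probability follows a generating inverted-U in true difficulty plus an
#' optional disparity term (peaking where the creator category matches the
#' calculated difficulty) and an optional success bonus at low difficulty,
#' and a creator category assigned as a noisy quantile of true difficulty.
#' These tables are synthetic stand-ins for the real game exports, built
#' only to carry the statistical structure the analyses assume.
#'
#' @param n_levels Number of levels, >= 1.
#' @param schema `"robozzle"`, `"trackmania"` or `"smm"`.
#' @param params Named list overriding generator defaults:
#'   `attempts_mu`, `attempts_size`, `attempts_min` (attempt law; or fixed
#'   `attempts`), `enjoy_base` and `enjoy_quad` and `enjoy_peak` (linear-scale
#'   inverted U of the enjoyment probability in true difficulty),
#'   `disparity_quad` (coefficient on squared category mismatch),
#'   `success_bonus` (extra enjoyment below difficulty 0.2; generates the
#'   cubic shape seen in the platformer data), `category_sd` (probit noise
#'   of the creator category), `votes_mu` (mean votes, robozzle),
#'   `awards_mu` (mean award scale, trackmania).
#' @return Data frame of class `level_table`; `true_clear_prob` and
#'   `true_difficulty` are generator-only hidden fields.
#' @export
generate_level_table <- function(n_levels, schema = c("robozzle", "trackmania", "smm"),
                                 params = list()) {
  schema <- match.arg(schema)
  stopifnot(n_levels >= 1)
  p <- utils::modifyList(list(
    attempts_mu = 200, attempts_size = 0.7, attempts_min = 10, attempts = NULL,
    enjoy_base = 0.8, enjoy_quad = -1.6, enjoy_peak = 0.5,
    disparity_quad = 0, success_bonus = 0, category_sd = 0.4,
    votes_mu = 25, awards_mu = 30), params)
  d <- stats::runif(n_levels)                      # hidden true difficulty
  clear_prob <- 1 - d
  attempts <- if (!is.null(p$attempts)) rep(as.integer(p$attempts), n_levels)
    else p$attempts_min + stats::rnbinom(n_levels, size = p$attempts_size,
                                         mu = p$attempts_mu)
  clears <- stats::rbinom(n_levels, attempts, clear_prob)
  ## creator category: ordinal probit on true difficulty, quartile cutpoints
  lat <- stats::qnorm(pmin(pmax(d, 1e-6), 1 - 1e-6)) +
    stats::rnorm(n_levels, 0, p$category_sd)
  category <- cut(stats::pnorm(lat), breaks = c(0, .25, .5, .75, 1),
                  labels = FALSE, include.lowest = TRUE)
  expected_d <- (category - 0.5) / 4               # quartile midpoints
  enjoy <- p$enjoy_base + p$enjoy_quad * (d - p$enjoy_peak)^2 +
    p$disparity_quad * (d - expected_d)^2 +
    p$success_bonus * pmax(0, 0.2 - d) / 0.2
  enjoy <- pmin(pmax(enjoy, 0.02), 0.98)
  out <- data.frame(level = seq_len(n_levels), attempts = attempts,
                    clears = clears, creator_category = category,
                    true_clear_prob = clear_prob, true_difficulty = d)
  if (schema == "smm") {
    out$stars <- stats::rbinom(n_levels, attempts, enjoy)
  } else if (schema == "robozzle") {
    votes <- 1L + stats::rpois(n_levels, p$votes_mu)
    out$upvotes <- stats::rbinom(n_levels, votes, enjoy)
    out$downvotes <- votes - out$upvotes
    out$rating <- pmin(5, pmax(1, 1 + 4 * d + stats::rnorm(n_levels, 0, 0.05)))
  } else {
    out$awards <- stats::rpois(n_levels, p$awards_mu * enjoy)
  }
  attr(out, "schema") <- schema
  class(out) <- c("level_table", "data.frame")
  out
}
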