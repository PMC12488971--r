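#' Unbiased sample variance of a machine's emissions
#'
#' The estimated variance of the current machine, based on all the samples
#' it produced before stopping. Uses the n-1 denominator.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Sample variance (points squared).
#' @export
estimated_variance <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  stats::var(samples)
}

#' Expected variance from machine history
#'
#' Average of the estimated variances observed so far, weighted by the
#' number of guesses spent on each machine.
#'
#' @param history Data frame (or list coercible to one) with columns
#'   `est_variance` and `n_guesses`; or a two-column matrix.
#' @return Weighted mean variance (points squared).
#' @export
expected_variance <- function(history) {
  history <- as.data.frame(history)
  if (nrow(history) < 1L)
    stop("empty history: expected variance undefined for the first machine")
  stopifnot(all(c("est_variance", "n_guesses") %in% names(history)))
  sum(history$est_variance * history$n_guesses) / sum(history$n_guesses)
}

#' Difficulty-expectation disparity table
#'
#' For every non-first, non-censored machine session of each participant,
#' computes the estimated variance of that machine (sample variance of its
#' emissions), the expected variance from all machines played before it
#' (weighted by guesses), and their difference — the disparity. Estimated
#' variances are recomputed from the per-guess emissions, not read from
#' generator metadata.
#'
#' @param log A guessing-game `session_log`.
#' @param scale `"raw"` (variance difference in points squared, the
#'   main definition) or `"log10"` (difference of log10 variances; the five
#'   design variances are log-spaced). On the log scale, estimated
#'   variances are floored at 1/12 points squared — the variance of the
#'   integer display rounding, below which the machine's spread is not
#'   observable — so that a run of identical displayed numbers (sample
#'   variance 0) stays finite; and the expected variance is the
#'   guess-weighted geometric mean of the history (the arithmetic mean is
#'   dominated by the largest variance seen, which would pin the expectation
#'   to the top of the log scale).
#' @return Data frame with one row per eligible session: `participant`,
#'   `session`, `machines_played` (history size), `variance`,
#'   `est_variance`, `expected_variance`, `disparity`, `n_guesses`.
#' @export
disparity_table <- function(log, scale = c("raw", "log10")) {
  stopifnot(inherits(log, "session_log"), log$kind == "guessing")
  scale <- match.arg(scale)
  out <- list()
  for (p in unique(log$sessions$participant)) {
    ss <- log$sessions[log$sessions$participant == p, ]
    ss <- ss[order(ss$session), ]
    hist_v <- numeric(0); hist_n <- integer(0)
    for (i in seq_len(nrow(ss))) {
      g <- log$guesses[log$guesses$participant == p &
                         log$guesses$session == ss$session[i], ]
      ev <- estimated_variance(g$emitted)
      if (length(hist_v) && !ss$censored[i]) {
        if (scale == "log10") {
          lh <- log10(pmax(hist_v, 1 / 12))
          expv <- 10^(sum(lh * hist_n) / sum(hist_n))
          disp <- log10(max(ev, 1 / 12)) - log10(expv)
        } else {
          expv <- sum(hist_v * hist_n) / sum(hist_n)
          disp <- ev - expv
        }
        out[[length(out) + 1L]] <- data.frame(
          participant = p, session = ss$session[i],
          machines_played = length(hist_v), variance = ss$variance[i],
          est_variance = ev, expected_variance = expv, disparity = disp,
          n_guesses = ss$n_guesses[i])
      }
      hist_v <- c(hist_v, ev); hist_n <- c(hist_n, ss$n_guesses[i])
    }
  }
  if (!length(out))
    return(data.frame(participant = integer(), session = integer(),
                      machines_played = integer(), variance = numeric(),
                      est_variance = numeric(), expected_variance = numeric(),
                      disparity = numeric(), n_guesses = integer()))
  do.call(rbind, out)
}

#' Per-level difficulty and enjoyment measures
#'
#' Schema-appropriate measures: calculated difficulty is 1 minus the clear
#' ratio (platformer), the average player rating (puzzle game), or the
#' creator category mapped to 1-4 (racing game); enjoyment is the star
#' rate, the like-ratio (upvotes over total votes), or the award count. For
#' the platformer schema an expected difficulty per creator category is
#' derived self-calibratingly as the mean calculated difficulty of levels
#' in that category, and `difficulty_disparity` is calculated minus
#' expected difficulty. Rows with zero attempts (or zero votes for the
#' like-ratio) are skipped with a warning.
#'
#' @param table A `level_table` (or compatible data frame).
#' @param schema `"robozzle"`, `"trackmania"` or `"smm"`; defaults to the
#'   table's own schema attribute.
#' @return Data frame with columns `level`, `difficulty`, `enjoyment` and,
#'   for `"smm"`, `expected_difficulty` and `difficulty_disparity`.
#' @export
level_measures <- function(table, schema = attr(table, "schema")) {
  schema <- match.arg(schema, c("robozzle", "trackmania", "smm"))
  tb <- as.data.frame(table)
  if (schema == "smm") {
    keep <- tb$attempts > 0
    if (any(!keep)) warning(sum(!keep), " level(s) with zero attempts skipped")
    tb <- tb[keep, ]
    diff <- 1 - tb$clears / tb$attempts
    out <- data.frame(level = tb$level, difficulty = diff,
                      enjoyment = tb$stars / tb$attempts,
                      creator_category = tb$creator_category)
    expmap <- tapply(out$difficulty, out$creator_category, mean)
    out$expected_difficulty <- as.numeric(expmap[as.character(out$creator_category)])
    out$difficulty_disparity <- out$difficulty - out$expected_difficulty
  } else if (schema == "robozzle") {
    tot <- tb$upvotes + tb$downvotes
    keep <- tot > 0
    if (any(!keep)) warning(sum(!keep), " level(s) with zero votes skipped")
    tb <- tb[keep, ]
    out <- data.frame(level = tb$level, difficulty = tb$rating,
                      enjoyment = tb$upvotes / (tb$upvotes + tb$downvotes))
  } else {
    out <- data.frame(level = tb$level,
                      difficulty = as.numeric(tb$creator_category),
                      enjoyment = tb$awards)
  }
  rownames(out) <- NULL
  out
}

## Shared result wrapper for the count/linear fits below.
regression_result <- function(coefs, method_used, fallback = FALSE,
                              aic = NA_real_, loglik = NA_real_,
                              degenerate = FALSE, model = NULL) {
  structure(list(coefficients = coefs, method_used = method_used,
                 fallback = fallback, aic = aic, loglik = loglik,
                 degenerate = degenerate, model = model),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result: %s%s%s>\n", x$method_used,
              if (x$fallback) " (fallback)" else "",
              if (x$degenerate) " DEGENERATE" else ""))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

coef_table <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             conf_lo = unname(est - 1.96 * se),
             conf_hi = unname(est + 1.96 * se))
}

## Negative-binomial count fit with a participant random intercept;
## falls back to participant fixed effects when the mixed fit fails.
nb_group_fit <- function(df, fixed_terms, method = c("auto", "mixed", "fixed")) {
  method <- match.arg(method)
  if (stats::var(df$y) == 0) {
    warning("degenerate response: no variation around the floor")
    return(regression_result(NULL, "none", degenerate = TRUE))
  }
  rhs <- paste(fixed_terms, collapse = " + ")
  if (method != "fixed") {
    fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | group)"))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::glmer.nb(fml, data = df))),
      error = function(e) NULL)
    ok <- !is.null(fit) && length(fit@optinfo$conv$lme4) == 0
    if (ok) {
      co <- summary(fit)$coefficients
      return(regression_result(coef_table(co[, 1], co[, 2]), "glmer.nb",
                               aic = stats::AIC(fit),
                               loglik = as.numeric(stats::logLik(fit)),
                               model = fit))
    }
    if (method == "mixed" && is.null(fit))
      stop("mixed negative-binomial fit failed")
    message("mixed NB fit unavailable or non-converged; ",
            "falling back to participant fixed effects")
  }
  fml <- stats::as.formula(paste("y ~", rhs, "+ factor(group)"))
  fit <- tryCatch(MASS::glm.nb(fml, data = df), error = function(e) {
    ## extreme leverage can break the default IRLS start; seed it from a
    ## Poisson fit instead
    st <- stats::coef(stats::glm(fml, data = df, family = stats::poisson()))
    MASS::glm.nb(fml, data = df, start = st)
  })
  co <- summary(fit)$coefficients
  keep <- !grepl("^factor\\(group\\)", rownames(co))
  regression_result(coef_table(co[keep, 1], co[keep, 2]), "glm.nb",
                    fallback = method != "fixed", aic = stats::AIC(fit),
                    loglik = as.numeric(stats::logLik(fit)), model = fit)
}

#' Quadratic negative-binomial engagement regression
#'
#' Regresses a per-session count on the z-scored condition variable and its
#' square, optionally with extra pre-scaled linear terms, with a participant
#' random intercept (mixed NB regression; participant fixed effects as a
#' logged fallback). A negative fitted quadratic detects the inverted U.
#'
#' @param data Per-session data frame.
#' @param response Name of the count column (e.g. `"n_guesses"`).
#' @param predictor Name of the condition column; it is z-scored (against
#'   `predictor_ref` if given, else empirically) before squaring.
#' @param group Name of the grouping column (default `"participant"`).
#' @param extra Character vector of additional columns entered linearly,
#'   used as given (pre-scale them yourself).
#' @param predictor_ref Optional numeric reference values defining the
#'   scaling of the predictor (e.g. the design conditions).
#' @param floor Forced-minimum count subtracted from the response before
#'   fitting (0 reproduces the conventional raw-count fit; 3 or 5 match the
#'   synthetic generator's shifted negative binomial).
#' @param method `"auto"` (mixed with fallback), `"mixed"`, or `"fixed"`.
#' @return A `regression_result`; terms `z` and `I(z^2)` carry the linear
#'   and quadratic condition effects.
#' @export
fit_count_quadratic <- function(data, response, predictor,
                                group = "participant", extra = character(),
                                predictor_ref = NULL, floor = 0,
                                method = c("auto", "mixed", "fixed")) {
  stopifnot(all(c(response, predictor, group, extra) %in% names(data)))
  if (length(unique(data[[group]])) < 2L) stop("need >= 2 participants")
  x <- data[[predictor]]
  if (stats::var(x) == 0) stop("predictor has zero variance")
  ref <- if (is.null(predictor_ref)) x else predictor_ref
  df <- data.frame(y = data[[response]] - floor,
                   z = (x - mean(ref)) / stats::sd(ref),
                   group = data[[group]])
  if (any(df$y < 0)) stop("response below floor: counts must be >= floor")
  for (e in extra) df[[e]] <- data[[e]]
  nb_group_fit(df, c("z", "I(z^2)", extra), method = match.arg(method))
}

#' Disparity engagement regression
#'
#' Fits the number of guesses on the scaled difficulty-expectation disparity
#' and its square, controlling for the number of machines played so far,
#' with a participant random intercept. A negative quadratic with a linear
#' CI covering zero indicates an inverted U peaking at zero disparity.
#'
#' The disparity is divided by its standard deviation but deliberately NOT
#' mean-centered: in the centered parameterization a null linear term would
#' place the peak at the sample mean disparity, not at zero, which is not
#' the hypothesis of interest.
#'
#' @param dtab Output of [disparity_table()].
#' @param floor Forced-minimum guess count subtracted before fitting.
#' @inheritParams fit_count_quadratic
#' @return A `regression_result` with terms `z` (scaled disparity),
#'   `I(z^2)` and `machines_played_z`.
#' @export
fit_disparity_engagement <- function(dtab, floor = 0,
                                     method = c("auto", "mixed", "fixed")) {
  stopifnot(nrow(dtab) > 0)
  dtab$disparity_z <- dtab$disparity / stats::sd(dtab$disparity)
  dtab$machines_played_z <- as.numeric(scale(dtab$machines_played))
  fit_count_quadratic(dtab, response = "n_guesses",
                      predictor = "disparity_z",
                      predictor_ref = c(-1, 1) / sqrt(2),  # mean 0, sd 1: scale only
                      extra = "machines_played_z", floor = floor,
                      method = match.arg(method))
}

#' Polynomial enjoyment fits and model comparison
#'
#' Fits enjoyment on nested polynomials of the z-scored difficulty (degrees
#' 0 to `max_degree`) and compares them by AIC: a degree is adopted when it
#' improves on the previous degree by more than `margin`. In the game
#' datasets a quadratic was a meaningful improvement everywhere, and only
#' the platformer (with its success bonus at low difficulty) supported a
#' cubic.
#'
#' @param measures Output of [level_measures()] (needs `difficulty` and
#'   `enjoyment`).
#' @param max_degree Highest polynomial degree, 1-3.
#' @param margin AIC improvement required to adopt a higher degree
#'   (default 10).
#' @return List with `aic` (data frame of degree, aic, delta vs previous),
#'   `selected_degree`, `fits` (lm objects), `coefficients` of the selected
#'   fit.
#' @export
fit_polynomial_enjoyment <- function(measures, max_degree = 3, margin = 10) {
  stopifnot(max_degree >= 1, max_degree <= 3)
  d <- measures$difficulty
  if (length(unique(d)) < max_degree + 2)
    stop("need at least max_degree + 2 distinct difficulty values")
  df <- data.frame(y = measures$enjoyment, z = as.numeric(scale(d)))
  fits <- vector("list", max_degree + 1)
  fits[[1]] <- stats::lm(y ~ 1, data = df)
  for (k in seq_len(max_degree))
    fits[[k + 1]] <- stats::lm(y ~ poly(z, k, raw = TRUE), data = df)
  aic <- vapply(fits, stats::AIC, numeric(1))
  delta <- c(NA, -diff(aic))      # improvement over previous degree
  ## adopt a higher degree only when it improves on the best lower-degree
  ## fit by more than the margin (a flat linear term must not block a
  ## clearly better quadratic)
  sel <- 0
  for (k in seq_len(max_degree)) {
    if (aic[k + 1] < aic[sel + 1] - margin) sel <- k
  }
  list(aic = data.frame(degree = 0:max_degree, aic = aic, improvement = delta),
       selected_degree = sel, fits = fits,
       coefficients = stats::coef(fits[[sel + 1]]))
}

#' Guess-update convergence trend
#'
#' Tests whether guess updates (|current - last guess|) shrink over trials
#' within machine sessions: regresses the z-scored update on the trial index
#' with a participant random intercept. A negative slope indicates
#' convergence.
#'
#' @param log A guessing-game `session_log`.
#' @param include_censored Include censored sessions (default FALSE)?
#' @return A `regression_result` with the `trial` slope.
#' @export
update_convergence_trend <- function(log, include_censored = FALSE) {
  stopifnot(inherits(log, "session_log"), log$kind == "guessing")
  ss <- log$sessions
  if (!include_censored) ss <- ss[!ss$censored, ]
  g <- merge(log$guesses, ss[c("participant", "session")],
             by = c("participant", "session"))
  g <- g[order(g$participant, g$session, g$trial), ]
  upd <- within_session_updates(g)
  if (!nrow(upd)) stop("no session with >= 2 guesses")
  if (stats::var(upd$trial) == 0)
    stop("trial index has no variation: slope undefined")
  if (stats::sd(upd$update) == 0) {
    return(regression_result(
      data.frame(term = "trial", estimate = 0, se = NA_real_, z = NA_real_,
                 p = NA_real_, conf_lo = NA_real_, conf_hi = NA_real_),
      "constant-updates"))
  }
  upd$uz <- as.numeric(scale(upd$update))
  fit <- lme4::lmer(uz ~ trial + (1 | participant), data = upd)
  co <- summary(fit)$coefficients
  regression_result(coef_table(co[, 1], co[, 2]), "lmer",
                    aic = stats::AIC(fit),
                    loglik = as.numeric(stats::logLik(fit)), model = fit)
}

within_session_updates <- function(g) {
  sp <- split(g, list(g$participant, g$session), drop = TRUE)
  rows <- lapply(sp, function(x) {
    if (nrow(x) < 2L) return(NULL)
    data.frame(participant = x$participant[-1], session = x$session[-1],
               trial = x$trial[-1], update = abs(diff(x$guess)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(participant = integer(),
                                      session = integer(), trial = integer(),
                                      update = numeric())
  rownames(out) <- NULL
  out
}

#' Difficulty manipulation check
#'
#' Verifies that larger machine variances made guessing harder: reports the
#' mean absolute guess error per variance level, a regression of per-session
#' mean absolute error on the scaled log-variance, and the correlation
#' between the (log) variance level and the mean number of exact-match
#' guesses per session. The first guess of every session is excluded: it is
#' made before any emission is seen, so it measures the prior-to-machine
#' mismatch rather than the machine's difficulty.
#'
#' @param log A guessing-game `session_log`.
#' @param include_censored Include censored sessions (default FALSE)?
#' @return List with `by_variance` (variance, mean_abs_error,
#'   mean_exact_per_session, n_sessions), `abs_error_fit` (lm on scaled
#'   log10 variance), and `exact_cor` (NA with a warning when undefined).
#' @export
manipulation_check <- function(log, include_censored = FALSE) {
  stopifnot(inherits(log, "session_log"), log$kind == "guessing")
  ss <- log$sessions
  if (!include_censored) ss <- ss[!ss$censored, ]
  g <- merge(log$guesses,
             ss[c("participant", "session", "variance")],
             by = c("participant", "session"))
  g <- g[g$trial > 1L, ]
  g$abs_err <- abs(g$guess - g$emitted)
  g$exact <- as.integer(g$guess == g$emitted)
  per_sess <- stats::aggregate(cbind(abs_err, exact) ~ participant + session + variance,
                               data = g, FUN = function(x) c(m = mean(x), s = sum(x)))
  sess_df <- data.frame(variance = per_sess$variance,
                        mean_abs_err = per_sess$abs_err[, "m"],
                        exact_count = per_sess$exact[, "s"])
  by_var <- do.call(rbind, lapply(split(sess_df, sess_df$variance), function(x)
    data.frame(variance = x$variance[1], mean_abs_error = mean(x$mean_abs_err),
               mean_exact_per_session = mean(x$exact_count),
               n_sessions = nrow(x))))
  by_var <- by_var[order(by_var$variance), ]
  rownames(by_var) <- NULL
  sess_df$zv <- design_z(log10(sess_df$variance), Z_VAR_REF)
  fit <- stats::lm(mean_abs_err ~ zv, data = sess_df)
  exact_cor <- if (stats::sd(by_var$mean_exact_per_session) == 0 ||
                   nrow(by_var) < 2) {
    warning("exact-match correlation undefined (constant or single level)")
    NA_real_
  } else stats::cor(log10(by_var$variance), by_var$mean_exact_per_session)
  list(by_variance = by_var, abs_error_fit = fit, exact_cor = exact_cor)
}
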