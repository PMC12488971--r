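## Independent oracles, written from closed forms / brute force before the
## implementation paths they check; they deliberately avoid the package's
## internal code paths.

## Conjugate Gaussian posterior by precision addition.
oracle_conjugate <- function(mu0, v0, x, obs_var) {
  prec <- 1 / v0 + 1 / obs_var
  list(mu = (mu0 / v0 + x / obs_var) / prec, var = 1 / prec)
}

## Deterministic machine engagement by the precision recursion:
## before step t the posterior variance is 1 / (1/v0 + (t-1)/s); the
## expected |mean update| is K * sqrt(2 (v + s) / pi); n is the first step
## whose expected update falls below the threshold, floored and capped.
oracle_machine_engagement <- function(prior_var, true_var, threshold,
                                      min_steps = 3L, max_steps = 200L) {
  for (t in seq_len(max_steps)) {
    v <- 1 / (1 / prior_var + (t - 1) / true_var)
    lp <- (v / (v + true_var)) * sqrt(2 * (v + true_var) / pi)
    if (lp < threshold) return(max(t, min_steps))
  }
  max_steps
}

## Dense GP regression solve (no Cholesky): pred = K*o (Koo + jI)^-1 y.
oracle_gp_dense <- function(revealed, lengthscale, dims, jitter = 1e-8) {
  X <- cbind(revealed$row - 1, revealed$col - 1)
  Xs <- as.matrix(expand.grid(row = seq_len(dims[1]) - 1,
                              col = seq_len(dims[2]) - 1))
  k <- function(a, b) {
    d2 <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j)
      sum((a[i, ] - b[j, ])^2)))
    exp(-d2 / (2 * lengthscale^2))
  }
  Koo <- k(X, X) + diag(jitter, nrow(X))
  matrix(k(Xs, X) %*% solve(Koo, revealed$value), dims[1], dims[2])
}

## Brute-force rejection sampler for truncated machine emissions.
oracle_truncated_draws <- function(mean, variance, n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sqrt(variance))
    out <- c(out, x[x >= 1 & x <= 100])
  }
  out[seq_len(n)]
}

## Hand-built session log for degenerate analysis cases.
make_session_log <- function(sessions, guesses, kind = "guessing") {
  structure(list(sessions = sessions, guesses = guesses, kind = kind,
                 model = NULL),
            class = "session_log")
}
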