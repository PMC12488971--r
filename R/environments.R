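#' @keywords internal
"_PACKAGE"

MACHINE_VARIANCES <- c(0.1, 1, 10, 100, 1000)
GRID_LENGTHSCALES <- c(0.25, 0.5, 1, 2, 4, 8, 16)
GRID_DIM <- c(30L, 30L)
GRID_SPAN <- 40

#' Construct a number machine
#'
#' A machine emits numbers from a Gaussian distribution with a fixed mean and
#' variance; the variance defines the difficulty of guessing its next number.
#'
#' @param mean Machine mean on the 0-100 guess scale; must lie in [20, 80].
#' @param variance One of 0.1, 1, 10, 100, 1000 (points squared).
#' @param id Opaque label.
#' @return An object of class `machine`.
#' @export
machine <- function(mean, variance, id = NA_character_) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (mean < 20 || mean > 80)
    stop("machine mean must lie in [20, 80], got ", mean)
  if (!isTRUE(any(abs(variance - MACHINE_VARIANCES) < 1e-12)))
    stop("machine variance must be one of ",
         paste(MACHINE_VARIANCES, collapse = ", "))
  structure(list(mean = mean, variance = variance, id = id),
            class = "machine")
}

#' Sample a machine from the experimental design
#'
#' The mean is uniform on [20, 80]; the variance is drawn uniformly from the
#' five design values 0.1, 1, 10, 100, 1000.
#'
#' @param id Optional label.
#' @return A `machine`.
#' @export
sample_machine <- function(id = NA_character_) {
  machine(mean = stats::runif(1, 20, 80),
          variance = sample(MACHINE_VARIANCES, 1L),
          id = id)
}

#' Emit numbers from a machine
#'
#' Draws from Normal(mean, variance), resampling any draw below 1 or above
#' 100. Emissions are rounded to integers by default, matching the integer
#' display scale of the game; `round = FALSE` gives raw truncated draws for
#' oracle checks.
#'
#' @param machine A `machine`.
#' @param n Number of emissions.
#' @param round Round to integers after truncation?
#' @param max_iter Safety cap on resampling rounds.
#' @return Numeric vector of length `n`, all values in [1, 100].
#' @export
machine_emit <- function(machine, n = 1L, round = TRUE, max_iter = 1e6) {
  stopifnot(inherits(machine, "machine"), n >= 0)
  sd <- sqrt(machine$variance)
  out <- stats::rnorm(n, machine$mean, sd)
  bad <- which(out < 1 | out > 100)
  iter <- 0L
  while (length(bad)) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("machine_emit: resampling cap reached; parameters out of range?")
    out[bad] <- stats::rnorm(length(bad), machine$mean, sd)
    bad <- bad[out[bad] < 1 | out[bad] > 100]
  }
  if (round) out <- base::round(out)
  out
}

## lattice coordinates (0-based, row-major) and squared distances are fixed
## for the 30x30 board; the kernel Cholesky is cached per lengthscale since
## generating many grids per condition is the common case.
.lpe_cache <- new.env(parent = emptyenv())

grid_coords <- function(dims = GRID_DIM) {
  as.matrix(expand.grid(row = seq_len(dims[1]) - 1L,
                        col = seq_len(dims[2]) - 1L))
}

#' Radial basis function kernel matrix
#'
#' k(x, x') = exp(-||x - x'||^2 / (2 lambda^2)) over rows of two coordinate
#' matrices.
#'
#' @param x,y Coordinate matrices (one point per row); `y` defaults to `x`.
#' @param lengthscale Positive kernel lengthscale lambda.
#' @return Kernel matrix of dimension nrow(x) x nrow(y).
#' @export
rbf_kernel <- function(x, lengthscale, y = x) {
  if (!is.numeric(lengthscale) || lengthscale <= 0)
    stop("lengthscale must be positive")
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * lengthscale^2))
}

grid_kernel_chol <- function(lengthscale, jitter = 1e-8) {
  key <- sprintf("chol_%.10g", lengthscale)
  got <- get0(key, envir = .lpe_cache)
  if (!is.null(got)) return(got)
  K <- rbf_kernel(grid_coords(), lengthscale)
  L <- chol(K + diag(jitter, nrow(K)))
  assign(key, L, envir = .lpe_cache)
  L
}

## Affine rescale of a latent surface to the display scale: span exactly
## `span`, minimum at `vmin`. A flat surface cannot be stretched and raises.
rescale_span <- function(z, vmin, span = GRID_SPAN) {
  rng <- range(z)
  if (diff(rng) <= 0)
    stop("degenerate latent surface: zero span cannot be rescaled")
  (z - rng[1]) / diff(rng) * span + vmin
}

#' Generate a point landscape
#'
#' Draws a 30x30 latent surface from a zero-mean Gaussian process with an
#' RBF kernel of the given lengthscale, then rescales it affinely so the tile
#' values span exactly 40 points with the minimum uniform on [5, 35] (hence
#' all values in [5, 75]). Displayed values are rounded to integers; the
#' pre-rounding surface is kept in `values_raw`.
#'
#' @param lengthscale Kernel lengthscale lambda; the experiment used
#'   0.25, 0.5, 1, 2, 4, 8, 16 (any positive value is accepted).
#' @param id Opaque label.
#' @param round Round tile values to integers (default TRUE)?
#' @return An object of class `grid_env` with elements `values` (30x30
#'   matrix), `values_raw`, `lengthscale`, `value_min`, `id`.
#' @export
generate_grid <- function(lengthscale, id = NA_character_, round = TRUE) {
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L || lengthscale <= 0)
    stop("lengthscale must be a positive scalar")
  L <- grid_kernel_chol(lengthscale)
  z <- drop(crossprod(L, stats::rnorm(nrow(L))))
  vmin <- stats::runif(1, 5, 35)
  raw <- matrix(rescale_span(z, vmin), GRID_DIM[1], GRID_DIM[2])
  structure(list(values = if (round) base::round(raw) else raw,
                 values_raw = raw,
                 lengthscale = lengthscale,
                 value_min = vmin,
                 id = id),
            class = "grid_env")
}

#' @export
print.machine <- function(x, ...) {
  cat(sprintf("<machine %s: mean %.2f, variance %g>\n",
              ifelse(is.na(x$id), "", x$id), x$mean, x$variance))
  invisible(x)
}

#' @export
print.grid_env <- function(x, ...) {
  cat(sprintf("<grid %s: lambda %g, values %d-%d (min drawn %.2f)>\n",
              ifelse(is.na(x$id), "", x$id), x$lengthscale,
              min(x$values), max(x$values), x$value_min))
  invisible(x)
}
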