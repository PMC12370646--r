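#' Derive a child seed from a base seed and a label
#'
#' All randomness in the package is funnelled through seeds derived
#' deterministically from one base seed, so that cohorts, folds and model fits
#' are reproducible stage by stage. The derivation is a small polynomial hash
#' of the label folded into the base seed, kept below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param ... character or numeric labels identifying the consumer
#'   (e.g. `"participant"`, `17`).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  label <- paste(vapply(list(...), paste, "", collapse = "|"), collapse = "|")
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h)
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library internals do not perturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Centred moving average with shrinking edge windows
#'
#' @param x numeric vector.
#' @param n window length in samples (coerced to odd).
#' @return smoothed vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L || length(x) < 3L) return(x)
  half <- (n - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving average with window given in seconds
#' @keywords internal
smooth_ma <- function(x, fs, win_s) moving_average(x, round(win_s * fs))

#' Indices of strict local minima
#'
#' A local minimum is a sample strictly smaller than both neighbours; plateaus
#' resolve to their leftmost sample (deterministic tie-break). Endpoints are
#' never minima.
#'
#' @param x numeric vector.
#' @return integer vector of minima positions.
#' @keywords internal
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_min <- r$values[mid] < r$values[mid - 1L] & r$values[mid] < r$values[mid + 1L]
  starts[mid][is_min]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip values into an interval
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
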