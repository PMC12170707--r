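#' Derive a deterministic child seed from a root seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' root seed plus a string label (e.g. participant and session ids), so that
#' adding participants or toggling stages never perturbs existing random
#' streams.
#'
#' @param root integer root seed.
#' @param ... character or numeric labels identifying the stream.
#' @return An integer seed in [0, 2^31).
#' @export
child_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1L)
  mod <- 2147480009  # prime below 2^31
  h <- as.numeric(root) %% mod
  for (key in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(key), "|"))) {
      h <- (h * 131 + ch) %% mod
    }
  }
  as.integer(h)
}

#' Centered moving average with shrinking edge windows
#'
#' The window covers `window` consecutive samples centred on each point
#' (for even windows one extra sample on the right); at the edges the window
#' shrinks to the available samples so the output has the same length as the
#' input.
#'
#' @param x numeric vector.
#' @param window window length in samples (>= 1).
#' @return Numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("`window` must be a positive scalar")
  }
  window <- as.integer(window)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(1L, i - lo)
  b <- pmin(n, i + hi)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Rolling quantile-based scale estimate
#'
#' Half the interquartile range of `x` within a centred window of
#' `window` samples (shrinking at the edges). Used as the time-varying
#' deviation estimate in BBI artifact detection.
#'
#' @param x numeric vector.
#' @param window window length in samples (odd recommended).
#' @return Numeric vector, same length as `x`.
#' @keywords internal
rolling_iqr_scale <- function(x, window) {
  n <- length(x)
  half <- (as.integer(window) - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - half)
    b <- min(n, i + half)
    q <- stats::quantile(x[a:b], c(0.25, 0.75), names = FALSE, type = 7)
    out[i] <- (q[2] - q[1]) / 2
  }
  out
}

#' Rolling median with shrinking edge windows
#' @keywords internal
rolling_median <- function(x, window) {
  n <- length(x)
  half <- (as.integer(window) - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - half)
    b <- min(n, i + half)
    out[i] <- stats::median(x[a:b])
  }
  out
}

#' Nearest-rank empirical quantile
#'
#' `sort(x)[ceiling(p * n)]` (clamped to [1, n]); the convention used for the
#' bootstrap masking limits.
#'
#' @keywords internal
nearest_rank <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  k <- min(max(1L, as.integer(ceiling(p * n))), n)
  s[k]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
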