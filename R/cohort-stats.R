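#' Twin-pair ages of the study cohort
#'
#' Ages (years) of the six recruited twin pairs, indexed A-F; pairs A, B, C, E
#' and F are monozygotic, pair D dizygotic. Both co-twins share the pair age.
#'
#' @return Named numeric vector of six pair ages.
#' @export
twin_study_ages <- function() {
  c(A = 25, B = 63, C = 56, D = 76, E = 36, F = 54)
}

#' Descriptive statistics of an age sample
#'
#' @param values numeric vector of ages (years), all positive.
#' @param sd_mode `"sample"` for the n-1 denominator, `"population"` for n.
#'   Both conventions occur in demographic reporting; the mode used is
#'   recorded in the result.
#' @return List with `mean`, `sd`, `n`, `sd_mode`.
#' @export
describe_ages <- function(values, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (length(values) < 1L || !all(is.finite(values)) || any(values <= 0)) {
    stop("`values` must be a non-empty vector of positive ages")
  }
  n <- length(values)
  m <- mean(values)
  s <- if (sd_mode == "sample") {
    if (n < 2L) stop("sample-mode SD needs n >= 2")
    stats::sd(values)
  } else {
    sqrt(mean((values - m)^2))
  }
  list(mean = m, sd = s, n = n, sd_mode = sd_mode)
}

# Exact P(D_n >= d) for the one-sample Kolmogorov statistic
# (Marsaglia-Tsang-Wang matrix-power algorithm).
ks_exact_pvalue <- function(d, n) {
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  nd <- n * d
  k <- as.integer(ceiling(nd))
  h <- k - nd
  m <- 2L * k - 1L
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1L >= 0L) H[i, j] <- 1
    }
  }
  for (i in seq_len(m)) {
    H[i, 1] <- H[i, 1] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1)
  }
  H[m, 1] <- H[m, 1] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1L > 0L) {
        H[i, j] <- H[i, j] / factorial(i - j + 1L)
      }
    }
  }
  # H^n with scaling to avoid overflow
  Hn <- H
  eR <- 0L
  if (n > 1L) {
    for (i in 2:n) {
      Hn <- Hn %*% H
      if (Hn[k, k] > 1e140) {
        Hn <- Hn * 1e-140
        eR <- eR + 140L
      }
    }
  }
  s <- Hn[k, k]
  for (i in seq_len(n)) {
    s <- s * i / n
    if (s < 1e-140) {
      s <- s * 1e140
      eR <- eR - 140L
    }
  }
  p <- 1 - s * 10^eR
  min(max(p, 0), 1)
}

# Asymptotic Kolmogorov tail probability Q(lambda)
ks_asymptotic_pvalue <- function(d, n) {
  lambda <- sqrt(n) * d
  if (lambda < 1e-8) return(1)
  kk <- 1:100
  p <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lambda^2))
  min(max(p, 0), 1)
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests an age sample against a normal law whose mean and *population*
#' (n-denominator) standard deviation are estimated from the sample itself,
#' the convention of MATLAB's and SciPy's default normality screens. The
#' statistic is the usual two-sided ECDF sup-distance; the p-value uses the
#' exact finite-sample Kolmogorov distribution by default (appropriate at the
#' small n of a twin cohort), with the asymptotic series as an option. No
#' correction for the estimated parameters (Lilliefors) is applied.
#'
#' @param values numeric sample, n >= 3, non-degenerate.
#' @param p_method `"exact"` or `"asymptotic"`.
#' @return List with `D`, `p`, `n`, `mean`, `sd` (population).
#' @export
ks_normality <- function(values, p_method = c("exact", "asymptotic")) {
  p_method <- match.arg(p_method)
  n <- length(values)
  if (n < 3L) stop("KS normality test needs n >= 3")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma <= 0) stop("sample has zero variance")
  x <- sort(values)
  Fx <- stats::pnorm(x, mu, sigma)
  i <- seq_len(n)
  D <- max(pmax(i / n - Fx, Fx - (i - 1) / n))
  p <- switch(p_method,
    exact = ks_exact_pvalue(D, n),
    asymptotic = ks_asymptotic_pvalue(D, n)
  )
  list(D = D, p = p, n = n, mean = mu, sd = sigma)
}

#' Student t-tests for age comparisons
#'
#' Two-sample pooled-variance (equal-variance Student) test when `b` is
#' given; one-sample test against `mu0` otherwise.
#'
#' @param a,b numeric samples (each n >= 2 for the two-sample test).
#' @param mu0 null mean for the one-sample test.
#' @return List with `t`, `df`, `p`, `type`.
#' @export
age_t_test <- function(a, b = NULL, mu0 = NULL) {
  if (!is.null(b)) {
    if (length(a) < 2L || length(b) < 2L) stop("each arm needs n >= 2")
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  type = "two_sample_pooled"))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, type = "two_sample_pooled")
  } else {
    if (is.null(mu0)) stop("supply `b` or `mu0`")
    if (length(a) < 2L) stop("one-sample test needs n >= 2")
    if (stats::sd(a) == 0) stop("zero variance sample")
    ht <- stats::t.test(a, mu = mu0)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, type = "one_sample")
  }
}
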