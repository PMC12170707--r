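# Independent brute-force oracles used to validate the package's vectorized
# implementations, plus small fixture builders.

# Centered shrinking-window moving average, straight per-point loop.
oracle_moving_average <- function(x, w) {
  n <- length(x)
  lo <- (w - 1) %/% 2
  hi <- w - 1 - lo
  sapply(seq_len(n), function(i) mean(x[max(1, i - lo):min(n, i + hi)]))
}

# Two-pass covariance Pearson r per full window; unweighted mean.
oracle_windowed_pearson <- function(va, vb, window, hop) {
  n <- min(length(va), length(vb))
  starts <- seq(1, n - window + 1, by = hop)
  rs <- sapply(starts, function(s) {
    xa <- va[s:(s + window - 1)]; xb <- vb[s:(s + window - 1)]
    ma <- sum(xa) / window; mb <- sum(xb) / window
    sxx <- sum((xa - ma)^2); syy <- sum((xb - mb)^2)
    if (sxx == 0 || syy == 0) return(NA_real_)
    sum((xa - ma) * (xb - mb)) / sqrt(sxx * syy)
  })
  mean(rs[!is.na(rs)])
}

# Band averaging by explicit loops over cells and grid frequencies.
oracle_band_average <- function(pow, freqs, bands) {
  top <- which.max(sapply(bands, `[`, 2))
  out <- array(NA_real_, c(dim(pow)[1], dim(pow)[2], length(bands)))
  for (e in seq_len(dim(pow)[1])) for (ch in seq_len(dim(pow)[2])) {
    for (k in seq_along(bands)) {
      sel <- if (k == top) which(freqs >= bands[[k]][1] & freqs <= bands[[k]][2])
             else which(freqs >= bands[[k]][1] & freqs < bands[[k]][2])
      out[e, ch, k] <- mean(pow[e, ch, sel])
    }
  }
  out
}

# Sham-pair enumeration by filtering all combinations.
oracle_sham_pairs <- function(pairs_df) {
  ids <- c(pairs_df$member1, pairs_df$member2)
  pair_of <- c(pairs_df$pair_id, pairs_df$pair_id)
  names(pair_of) <- ids
  cmb <- utils::combn(ids, 2)
  keep <- apply(cmb, 2, function(p) pair_of[p[1]] != pair_of[p[2]])
  cmb[, keep, drop = FALSE]
}

# Cellwise mean of maps with NA exclusion, explicit loops.
oracle_mean_maps <- function(mats) {
  out <- mats[[1]]
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    v <- sapply(mats, function(m) m[i, j])
    v <- v[!is.na(v)]
    out[i, j] <- if (length(v)) mean(v) else NA_real_
  }
  out
}

# Direct per-epoch zero-padded complex Morlet convolution power (the
# definition wavelet_power() implements through Gram matrices).
oracle_wavelet_power <- function(x_epoch, f, cycles, fs) {
  sigma_t <- cycles / (2 * pi * f)
  half <- max(1, floor(3.5 * sigma_t * fs))
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  L <- length(x_epoch)
  conv <- sapply(seq_len(L), function(tt) {
    acc <- 0 + 0i
    for (tau in seq_len(L)) {
      k <- tt - tau
      if (abs(k) <= half) acc <- acc + x_epoch[tau] * w[k + half + 1]
    }
    acc
  })
  mean(Mod(conv)^2)
}

# Kolmogorov-Smirnov sup-distance by scanning the ECDF against a normal law.
oracle_ks_D <- function(x, mu, sigma) {
  xs <- sort(x)
  n <- length(xs)
  ec_hi <- sapply(xs, function(v) mean(x <= v))
  ec_lo <- sapply(xs, function(v) mean(x < v))
  Fx <- pnorm(xs, mu, sigma)
  max(abs(ec_hi - Fx), abs(Fx - ec_lo))
}

# Fixture: uniform BBI series from a numeric vector.
mk_series <- function(v, start = 0, id = "x", session = "1") {
  uniform_bbi(id, session, start, v)
}

# Fixture: clean tachogram at a constant rhythm.
mk_tachogram <- function(n = 60, bbi = 1000, id = "x", session = "1") {
  bt <- seq(0, by = bbi / 1000, length.out = n + 1)
  bbi_tachogram(id, session, bt, rep(bbi, n))
}
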