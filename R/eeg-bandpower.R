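# EEG band-power pipeline: cleaning, epoching, pooled rejection, Morlet
# wavelet decomposition, band averaging, coarse time-course extraction and
# within-dyad correlation.

# Per-session cache of wavelet Gram matrices (see wavelet_power).
.gram_cache <- new.env(parent = emptyenv())

#' Frequency bands of the band-power analysis
#'
#' Delta 1.5-4, theta 4-7, alpha 7-12, sigma 12-18, beta 18-30 and gamma
#' 30-50 Hz. Bands are half-open `[low, high)`; the top band is closed.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1.5, 4), theta = c(4, 7), alpha = c(7, 12),
       sigma = c(12, 18), beta = c(18, 30), gamma = c(30, 50))
}

#' Basic EEG cleaning: high-pass and line-noise notch
#'
#' Removes the per-channel mean, applies a zero-phase Butterworth high-pass
#' at `highpass` Hz and a zero-phase notch (band-stop) around `line_freq`.
#' The channel count is unchanged. If the notch band would reach the Nyquist
#' frequency the notch is skipped with a warning.
#'
#' @param rec an [eeg_recording()].
#' @param highpass high-pass edge, Hz (must be below Nyquist).
#' @param line_freq line frequency, Hz (60 for North American mains).
#' @param notch_halfwidth half-width of the stop band, Hz.
#' @return A cleaned [eeg_recording()].
#' @export
basic_clean <- function(rec, highpass = 0.5, line_freq = 60,
                        notch_halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (highpass >= nyq) stop("highpass edge must be below the Nyquist frequency")
  hp <- signal::butter(2, highpass / nyq, type = "high")
  do_notch <- line_freq + notch_halfwidth < nyq
  if (!do_notch) warning("line frequency too close to Nyquist; notch skipped")
  if (do_notch) {
    bs <- signal::butter(2, c(line_freq - notch_halfwidth,
                              line_freq + notch_halfwidth) / nyq,
                         type = "stop")
  }
  dat <- rec$data
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ] - mean(dat[ch, ])
    x <- signal::filtfilt(hp, x)
    if (do_notch) x <- signal::filtfilt(bs, x)
    dat[ch, ] <- x
  }
  eeg_recording(rec$subject, rec$condition, rec$labels, rec$srate, dat)
}

#' Equalize the lengths of two recordings
#'
#' Truncates the longer recording from the end so both have the shorter
#' length; requires matching sampling rates.
#'
#' @param a,b [eeg_recording()] objects.
#' @return List with truncated recordings `a` and `b`.
#' @export
equalize_lengths <- function(a, b) {
  stopifnot(inherits(a, "eeg_recording"), inherits(b, "eeg_recording"))
  if (a$srate != b$srate) stop("sampling rates differ")
  n <- min(ncol(a$data), ncol(b$data))
  if (n < 1) stop("zero-length recording")
  trim <- function(r) eeg_recording(r$subject, r$condition, r$labels,
                                    r$srate, r$data[, seq_len(n), drop = FALSE])
  list(a = trim(a), b = trim(b))
}

#' Sliding epoch grid over a recording
#'
#' Epoch `i` covers `[i * step, i * step + length_s)`; the number of epochs
#' is `floor((T - length_s) / step) + 1`.
#'
#' @param rec an [eeg_recording()].
#' @param length_s epoch length, seconds.
#' @param step step between epoch starts, seconds (> 0).
#' @return An [epoch_set()].
#' @export
epoch_sliding <- function(rec, length_s = 1.5, step = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (step <= 0) stop("step must be positive")
  T <- ncol(rec$data) / rec$srate
  if (T < length_s) stop("recording shorter than one epoch")
  n <- floor((T - length_s) / step + 1e-9) + 1L
  epoch_set(starts = (seq_len(n) - 1L) * step, length_s = length_s,
            step = step)
}

# Sample index matrix (epoch_len x n_epochs) for an epoch grid.
epoch_index_matrix <- function(rec, epochs, which_epochs = NULL) {
  L <- round(epochs$length_s * rec$srate)
  starts <- epochs$starts
  if (!is.null(which_epochs)) starts <- starts[which_epochs]
  s0 <- round(starts * rec$srate)
  outer(seq_len(L), s0, `+`)
}

#' Pooled probabilistic epoch rejection for a dyad
#'
#' Per subject and epoch, a joint log-improbability score is computed: for
#' every channel, the negative log of a kernel-density estimate of that
#' channel's amplitude distribution is averaged within the epoch, and the
#' per-channel values are summed. Epochs whose score exceeds
#' `z_threshold` standard deviations above the subject's mean are marked;
#' the union of both subjects' marks is removed from both recordings, so the
#' retained epoch grids stay identical.
#'
#' @param a,b [eeg_recording()] objects of equal length and epoch grid.
#' @param epochs an [epoch_set()] valid for both recordings.
#' @param z_threshold rejection threshold in z-units (default 3).
#' @return Logical keep-mask over epochs (same for both subjects).
#' @export
reject_epochs_pooled <- function(a, b, epochs, z_threshold = 3) {
  stopifnot(inherits(a, "eeg_recording"), inherits(b, "eeg_recording"))
  if (ncol(a$data) != ncol(b$data)) stop("equalize lengths first")
  score_subject <- function(rec) {
    idx <- epoch_index_matrix(rec, epochs)
    total <- numeric(length(epochs$starts))
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, ]
      kde <- stats::density(x, n = 512)
      px <- stats::approx(kde$x, kde$y, xout = x, rule = 2)$y
      nll <- -log(pmax(px, 1e-300))
      em <- matrix(nll[idx], nrow = nrow(idx))
      total <- total + colMeans(em)
    }
    total
  }
  mark <- function(score) {
    s <- stats::sd(score)
    if (s == 0) return(rep(FALSE, length(score)))
    (score - mean(score)) / s > z_threshold
  }
  bad <- mark(score_subject(a)) | mark(score_subject(b))
  if (all(bad)) stop("all epochs rejected; raise z_threshold")
  !bad
}

# Complex Morlet wavelet at frequency f with a given number of cycles,
# sampled at fs, L2-normalized, odd length.
morlet_wavelet <- function(f, cycles, fs, sd_span = 3.5) {
  sigma_t <- cycles / (2 * pi * f)
  half <- max(1L, floor(sd_span * sigma_t * fs))
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet power per epoch, channel and frequency
#'
#' Each epoch is zero-padded and convolved with complex Morlet wavelets
#' whose cycle count rises linearly from `cycles_min` at `f_min` to
#' `cycles_max` at `f_max`; power is the squared magnitude averaged over the
#' epoch samples. The per-epoch convolution is evaluated exactly through the
#' wavelet Gram matrix (`power = x' Re(W* W) x / L`), which is algebraically
#' identical to the direct convolution but runs as one matrix product per
#' channel and frequency.
#'
#' At the lowest frequencies the wavelet support exceeds a 1.5-s epoch; the
#' zero-padding then acts as a mild taper and those band estimates lean on
#' fewer effective cycles.
#'
#' @param rec an [eeg_recording()].
#' @param epochs an [epoch_set()].
#' @param f_min,f_max frequency range, Hz (`f_max` below Nyquist).
#' @param cycles_min,cycles_max wavelet cycles at the range ends.
#' @param freq_step frequency grid step, Hz.
#' @param keep_only drop epochs where `epochs$kept` is FALSE (default TRUE).
#' @return Array `epochs x channels x frequencies` with attributes `freqs`
#'   (Hz) and `times` (epoch start times, s).
#' @export
wavelet_power <- function(rec, epochs, f_min = 1.5, f_max = 50,
                          cycles_min = 3, cycles_max = 30, freq_step = 1,
                          keep_only = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(epochs, "epoch_set"))
  if (f_max >= rec$srate / 2) stop("f_max must be below the Nyquist frequency")
  freqs <- seq(f_min, f_max, by = freq_step)
  freqs <- freqs[freqs < rec$srate / 2 & freqs <= f_max]
  which_epochs <- if (keep_only) which(epochs$kept) else
    seq_along(epochs$starts)
  idx <- epoch_index_matrix(rec, epochs, which_epochs)
  L <- nrow(idx)
  n_ep <- ncol(idx)
  n_ch <- nrow(rec$data)

  # Gram matrices G_f = Re(W^H W), W the epoch-restricted convolution
  # operator of the wavelet (zero-padding outside the epoch). They depend
  # only on (srate, L, frequency grid), so they are cached across calls.
  cache_key <- paste(rec$srate, L, f_min, f_max, cycles_min, cycles_max,
                     freq_step, sep = "_")
  grams <- .gram_cache[[cache_key]]
  if (is.null(grams)) {
    dmat <- outer(seq_len(L), seq_len(L), `-`)
    grams <- lapply(freqs, function(f) {
      cyc <- cycles_min + (cycles_max - cycles_min) * (f - f_min) /
        (f_max - f_min)
      w <- morlet_wavelet(f, cyc, rec$srate)
      half <- (length(w) - 1L) %/% 2L
      W <- matrix(0i, L, L)
      inside <- abs(dmat) <= half
      W[inside] <- w[dmat[inside] + half + 1L]
      Re(Conj(t(W)) %*% W)
    })
    .gram_cache[[cache_key]] <- grams
  }

  pow <- array(0, dim = c(n_ep, n_ch, length(freqs)))
  for (ch in seq_len(n_ch)) {
    X <- matrix(rec$data[ch, ][idx], nrow = L)
    for (k in seq_along(freqs)) {
      Y <- grams[[k]] %*% X
      pow[, ch, k] <- colSums(X * Y) / L
    }
  }
  pow[pow < 0] <- 0  # clip numerical negatives of the quadratic form
  dimnames(pow) <- list(NULL, rec$labels, NULL)
  attr(pow, "freqs") <- freqs
  attr(pow, "times") <- epochs$starts[which_epochs]
  pow
}

#' Average wavelet power into frequency bands
#'
#' Mean over grid frequencies within `[low, high)` per band; the top band is
#' closed at its upper edge. An empty band (no grid frequency) is an error.
#'
#' @param pow a [wavelet_power()] array with a `freqs` attribute.
#' @param bands named list of `c(low, high)` pairs (default [eeg_bands()]).
#' @return Array `epochs x channels x bands` with attribute `times`.
#' @export
band_average <- function(pow, bands = eeg_bands()) {
  freqs <- attr(pow, "freqs")
  if (is.null(freqs)) stop("pow must carry a freqs attribute")
  top <- which.max(vapply(bands, `[`, 0, 2))
  out <- array(0, dim = c(dim(pow)[1], dim(pow)[2], length(bands)))
  for (k in seq_along(bands)) {
    lo <- bands[[k]][1]; hi <- bands[[k]][2]
    inb <- if (k == top) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
    if (!any(inb)) stop("band ", names(bands)[k], " covers no grid frequency")
    sl <- pow[, , inb, drop = FALSE]
    out[, , k] <- apply(sl, c(1, 2), mean)
  }
  dimnames(out) <- list(NULL, dimnames(pow)[[2]], names(bands))
  attr(out, "times") <- attr(pow, "times")
  attr(out, "bands") <- bands
  out
}

#' Smooth band power over time and extract a coarse time course
#'
#' Moving average of each channel-band power trace over epochs whose start
#' times fall within a `smooth_window`-second centred window, then
#' `n_points` evenly spaced samples across the smoothed course. If the
#' course is shorter than the smoothing window a single-point fallback (the
#' overall mean, replicated) is returned with a warning.
#'
#' @param bp a [band_average()] array (epochs x channels x bands) with
#'   `times` and `bands` attributes.
#' @param subject subject id for the result.
#' @param smooth_window smoothing window, seconds (default 120).
#' @param n_points number of extracted points (default 20).
#' @param log_power return log10 power instead of linear.
#' @return A [band_power_tc()].
#' @export
smooth_downsample <- function(bp, subject = "s", smooth_window = 120,
                              n_points = 20, log_power = FALSE) {
  times <- attr(bp, "times")
  bands <- attr(bp, "bands")
  n <- dim(bp)[1]
  if (n < n_points) stop("fewer epochs than requested time points")
  span <- diff(range(times))
  if (span < smooth_window) {
    warning("time course shorter than the smoothing window; single-point fallback")
    m <- apply(bp, c(2, 3), mean)
    vals <- array(rep(m, 1), dim = c(dim(bp)[2], dim(bp)[3], 1))
    tc <- band_power_tc(subject, bands, dimnames(bp)[[2]], vals,
                        times = mean(times), log_power = FALSE)
    if (log_power) {
      tc$values <- log10(pmax(tc$values, 1e-300)); tc$log_power <- TRUE
    }
    return(tc)
  }
  half <- smooth_window / 2
  lo <- vapply(times, function(t) which(times >= t - half)[1], 1L)
  hi <- vapply(times, function(t) max(which(times <= t + half)), 1L)
  sel <- round(seq(1, n, length.out = n_points))
  vals <- array(0, dim = c(dim(bp)[2], dim(bp)[3], n_points))
  for (ch in seq_len(dim(bp)[2])) for (bd in seq_len(dim(bp)[3])) {
    x <- bp[, ch, bd]
    cs <- cumsum(c(0, x))
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    vals[ch, bd, ] <- sm[sel]
  }
  tc <- band_power_tc(subject, bands, dimnames(bp)[[2]], vals,
                      times = times[sel], log_power = FALSE)
  if (log_power) {
    tc$values <- log10(pmax(tc$values, 1e-300)); tc$log_power <- TRUE
  }
  tc
}

#' Correlate two band-power time courses cell by cell
#'
#' Pearson r per (channel, band) across the coarse time points. Cells where
#' either course has zero variance are set to `NA` and flagged
#' `"undefined"`; downstream averaging and masking exclude them.
#'
#' @param tc_a,tc_b [band_power_tc()] objects with identical channels,
#'   bands and point counts.
#' @param condition condition label for the resulting map.
#' @return A [topo_map()].
#' @export
pair_correlation <- function(tc_a, tc_b, condition = "meditation") {
  stopifnot(inherits(tc_a, "band_power_tc"), inherits(tc_b, "band_power_tc"))
  if (!identical(dim(tc_a$values), dim(tc_b$values))) {
    stop("time courses must have identical shapes")
  }
  if (!identical(tc_a$channels, tc_b$channels)) stop("channel sets differ")
  nc <- dim(tc_a$values)[1]; nb <- dim(tc_a$values)[2]
  R <- matrix(NA_real_, nc, nb,
              dimnames = list(tc_a$channels, names(tc_a$bands)))
  mask <- matrix("unmasked", nc, nb, dimnames = dimnames(R))
  for (ch in seq_len(nc)) for (bd in seq_len(nb)) {
    x <- tc_a$values[ch, bd, ]; y <- tc_b$values[ch, bd, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      mask[ch, bd] <- "undefined"
    } else {
      R[ch, bd] <- stats::cor(x, y)
    }
  }
  topo_map(paste(tc_a$subject, tc_b$subject, sep = "-"), condition, R, mask)
}

#' Run the full band-power pipeline for one dyad
#'
#' Cleaning, length equalization, sliding epochs, pooled rejection, wavelet
#' decomposition, band averaging and coarse time-course extraction for both
#' subjects of a pair.
#'
#' @param rec_a,rec_b raw [eeg_recording()] objects.
#' @param epoch_length,epoch_step epoching parameters, seconds.
#' @param z_threshold pooled rejection threshold.
#' @param smooth_window,n_points time-course extraction parameters.
#' @param log_power correlate log power instead of linear.
#' @param ... passed to [wavelet_power()].
#' @return List with `tc_a`, `tc_b` (time courses), `map` (the
#'   [pair_correlation()] result) and `kept` (epoch keep-mask).
#' @export
eeg_pair_pipeline <- function(rec_a, rec_b, epoch_length = 1.5,
                              epoch_step = 0.1, z_threshold = 3,
                              smooth_window = 120, n_points = 20,
                              log_power = FALSE, ...) {
  ca <- basic_clean(rec_a)
  cb <- basic_clean(rec_b)
  eq <- equalize_lengths(ca, cb)
  ep <- epoch_sliding(eq$a, epoch_length, epoch_step)
  kept <- reject_epochs_pooled(eq$a, eq$b, ep, z_threshold)
  ep$kept <- kept
  tc <- lapply(list(eq$a, eq$b), function(r) {
    pw <- wavelet_power(r, ep, ...)
    ba <- band_average(pw)
    smooth_downsample(ba, subject = r$subject, smooth_window = smooth_window,
                      n_points = n_points, log_power = log_power)
  })
  list(tc_a = tc[[1]], tc_b = tc[[2]],
       map = pair_correlation(tc[[1]], tc[[2]], condition = rec_a$condition),
       kept = kept)
}
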