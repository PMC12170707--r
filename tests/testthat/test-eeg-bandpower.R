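mk_rec <- function(x, fs = 128, id = "s", labels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  eeg_recording(id, "meditation", labels, fs, x)
}

test_that("basic cleaning removes DC and line noise, keeps the passband", {
  fs <- 256
  t <- seq_len(20 * fs) / fs
  dc <- mk_rec(matrix(500, 1, length(t)), fs)
  out <- basic_clean(dc)
  expect_lt(abs(mean(out$data)) / 500, 1e-6)

  line <- mk_rec(sin(2 * pi * 60 * t), fs)
  out60 <- basic_clean(line)
  expect_lt(sqrt(mean(out60$data^2)) / sqrt(mean(line$data^2)), 0.05)

  alpha <- mk_rec(sin(2 * pi * 10 * t), fs)
  out10 <- basic_clean(alpha)
  expect_lt(abs(sqrt(mean(out10$data^2)) / sqrt(mean(alpha$data^2)) - 1),
            0.05)

  expect_error(basic_clean(mk_rec(rnorm(1000), 128), highpass = 70),
               "Nyquist")
})

test_that("length equalization truncates from the end and commutes with channel subsetting", {
  set.seed(3)
  a <- mk_rec(matrix(rnorm(3 * 10000), 3), id = "a")
  b <- mk_rec(matrix(rnorm(3 * 9000), 3), id = "b")
  eq <- equalize_lengths(a, b)
  expect_equal(ncol(eq$a$data), 9000)
  expect_equal(eq$a$data, a$data[, 1:9000])
  expect_equal(eq$b$data, b$data)

  same <- equalize_lengths(a, a)
  expect_identical(same$a, a)

  subset_rec <- function(r, ch) eeg_recording(r$subject, r$condition,
                                              r$labels[ch], r$srate,
                                              r$data[ch, , drop = FALSE])
  e1 <- equalize_lengths(subset_rec(a, 1:2), subset_rec(b, 1:2))
  e2 <- lapply(equalize_lengths(a, b), subset_rec, ch = 1:2)
  expect_equal(e1$a$data, e2$a$data)
  expect_equal(e1$b$data, e2$b$data)
})

test_that("sliding epochs follow the counting rule", {
  fs <- 200
  r15 <- mk_rec(rnorm(1.5 * fs), fs)
  expect_equal(length(epoch_sliding(r15)$starts), 1)

  r30 <- mk_rec(rnorm(3 * fs), fs)
  ep <- epoch_sliding(r30)
  expect_equal(length(ep$starts), 16)
  expect_equal(ep$starts[5], 4 * 0.1)  # epoch i starts at i * step
  expect_error(epoch_sliding(r30, step = 0), "positive")
})

test_that("pooled rejection removes burst epochs from both subjects symmetrically", {
  set.seed(11)
  fs <- 128
  n <- 60 * fs
  a <- matrix(rnorm(2 * n), 2)
  b <- matrix(rnorm(2 * n), 2)
  ra <- mk_rec(a, fs, "a"); rb <- mk_rec(b, fs, "b")
  ep <- epoch_sliding(ra, 1.5, 0.5)

  # clean data: false-mark rate under 1%
  kept <- reject_epochs_pooled(ra, rb, ep)
  expect_lt(mean(!kept), 0.01)

  # a 20x burst confined to one epoch of subject a is removed from both
  k <- 40
  idx <- round(ep$starts[k] * fs) + seq_len(round(1.5 * fs))
  a2 <- a; a2[1, idx] <- a2[1, idx] * 20
  kept2 <- reject_epochs_pooled(mk_rec(a2, fs, "a"), rb, ep)
  expect_false(kept2[k])

  # symmetry in the argument order
  kept3 <- reject_epochs_pooled(rb, mk_rec(a2, fs, "a"), ep)
  expect_equal(kept2, kept3)
})

test_that("wavelet power concentrates spectrally, scales as k^2, and matches direct convolution", {
  fs <- 128
  t <- seq_len(30 * fs) / fs
  rec <- mk_rec(sin(2 * pi * 10 * t), fs)
  ep <- epoch_sliding(rec, 1.5, 1)
  pw <- wavelet_power(rec, ep, f_max = 50)
  freqs <- attr(pw, "freqs")
  spec <- colMeans(pw[, 1, ])
  expect_equal(freqs[which.max(spec)], 9.5, tolerance = 1.01)
  expect_gt(spec[freqs == 9.5] + spec[freqs == 10.5],
            10 * spec[freqs == 24.5])

  z <- wavelet_power(mk_rec(numeric(30 * fs), fs), ep)
  expect_true(all(z == 0))

  k <- 3.7
  pw2 <- wavelet_power(mk_rec(k * sin(2 * pi * 10 * t), fs), ep)
  expect_equal(pw2, k^2 * pw, tolerance = 1e-9)

  expect_error(wavelet_power(rec, ep, f_max = 64), "Nyquist")

  # Gram-matrix evaluation equals the direct per-epoch convolution
  set.seed(13)
  x <- rnorm(5 * fs)
  recx <- mk_rec(x, fs)
  epx <- epoch_sliding(recx, 1.5, 1)
  pwx <- wavelet_power(recx, epx, f_min = 4, f_max = 20, freq_step = 8)
  fr <- attr(pwx, "freqs")
  L <- round(1.5 * fs)
  for (e in c(1, 3)) for (k2 in seq_along(fr)) {
    cyc <- 3 + 27 * (fr[k2] - 4) / (20 - 4)
    seg <- x[round(epx$starts[e] * fs) + seq_len(L)]
    expect_equal(unname(pwx[e, 1, k2]),
                 oracle_wavelet_power(seg, fr[k2], cyc, fs),
                 tolerance = 1e-9)
  }
})

test_that("band averaging matches the loop oracle and analytic cases", {
  set.seed(14)
  freqs <- seq(1.5, 49.5, by = 1)
  pw <- array(rexp(10 * 2 * length(freqs)), c(10, 2, length(freqs)))
  attr(pw, "freqs") <- freqs
  attr(pw, "times") <- 1:10
  ba <- band_average(pw)
  expect_equal(unname(ba[, , ]), oracle_band_average(pw, freqs, eeg_bands()),
               tolerance = 1e-12)

  flat <- array(1, c(4, 1, length(freqs)))
  attr(flat, "freqs") <- freqs; attr(flat, "times") <- 1:4
  expect_true(all(band_average(flat) == 1))

  # sum rule: band means recombine (weighted by grid count) to the grid mean
  counts <- sapply(seq_along(eeg_bands()), function(k) {
    b <- eeg_bands()[[k]]
    if (k == length(eeg_bands())) sum(freqs >= b[1] & freqs <= b[2])
    else sum(freqs >= b[1] & freqs < b[2])
  })
  recomb <- apply(ba, c(1, 2), function(v) sum(v * counts) / sum(counts))
  expect_equal(unname(recomb), unname(apply(pw, c(1, 2), mean)),
               tolerance = 1e-12)

  narrow <- pw
  attr(narrow, "freqs") <- freqs + 100
  expect_error(band_average(narrow), "no grid frequency")

  # a 10 Hz tone lands in the alpha band
  fs <- 128
  t <- seq_len(20 * fs) / fs
  rec <- mk_rec(sin(2 * pi * 10 * t), fs)
  ep <- epoch_sliding(rec, 1.5, 1)
  ba10 <- band_average(wavelet_power(rec, ep))
  expect_equal(names(which.max(colMeans(ba10[, 1, ]))), "alpha")
})

test_that("time-course extraction smooths and downsamples correctly", {
  bands <- eeg_bands()
  n <- 400
  times <- seq(0, by = 1, length.out = n)
  const <- array(7, c(n, 1, 6))
  attr(const, "times") <- times; attr(const, "bands") <- bands
  dimnames(const) <- list(NULL, "ch1", names(bands))
  tc <- smooth_downsample(const, n_points = 20)
  expect_equal(dim(tc$values), c(1, 6, 20))
  expect_true(all(tc$values == 7))

  ramp <- array(rep(2 * times + 5, 6), c(n, 1, 6))
  attr(ramp, "times") <- times; attr(ramp, "bands") <- bands
  dimnames(ramp) <- list(NULL, "ch1", names(bands))
  tcr <- smooth_downsample(ramp, n_points = 20)
  interior <- tcr$times >= min(times) + 60 & tcr$times <= max(times) - 60
  expect_true(sum(interior) > 10)
  expect_equal(tcr$values[1, 1, interior], 2 * tcr$times[interior] + 5,
               tolerance = 1e-9)

  ten <- array(1, c(10, 1, 6))
  attr(ten, "times") <- seq(0, 200, length.out = 10)
  attr(ten, "bands") <- bands
  dimnames(ten) <- list(NULL, "ch1", names(bands))
  expect_error(smooth_downsample(ten, n_points = 20), "fewer epochs")
  short <- array(1, c(30, 1, 6))
  attr(short, "times") <- seq(0, by = 1, length.out = 30)
  attr(short, "bands") <- bands
  dimnames(short) <- list(NULL, "ch1", names(bands))
  expect_warning(tc1 <- smooth_downsample(short, n_points = 20),
                 "single-point")
  expect_equal(dim(tc1$values)[3], 1)
})

test_that("pair correlation hits the exact poles and flags degenerate cells", {
  set.seed(15)
  vals <- array(exp(rnorm(4 * 6 * 20)), c(4, 6, 20))
  tc_a <- band_power_tc("a", eeg_bands(), paste0("ch", 1:4), vals, 1:20)
  m1 <- pair_correlation(tc_a, tc_a)
  expect_true(all(abs(m1$R - 1) < 1e-12))

  neg <- band_power_tc("b", eeg_bands(), paste0("ch", 1:4),
                       max(vals) + min(vals) - vals, 1:20)
  m2 <- pair_correlation(tc_a, neg)
  expect_true(all(abs(m2$R + 1) < 1e-12))

  degen <- vals; degen[1, 1, ] <- 5
  tc_d <- band_power_tc("d", eeg_bands(), paste0("ch", 1:4), degen, 1:20)
  m3 <- pair_correlation(tc_a, tc_d)
  expect_equal(m3$mask[1, 1], "undefined")
  expect_true(is.na(m3$R[1, 1]))
})

test_that("the dyad pipeline recovers strong envelope coupling", {
  prm <- eeg_coupling_params(n_channels = 3, sampling_rate = 128,
                             band_envelope_rho = rep(1, 6),
                             background_amplitude = 0)
  g <- generate_coupled_eeg(prm, 400, seed = 55)
  pl <- eeg_pair_pipeline(g$a, g$b, epoch_step = 0.5)
  expect_gt(min(pl$map$R, na.rm = TRUE), 0.95)
})

test_that("uncoupled dyads give pipeline correlations centred on zero", {
  means <- sapply(1:30, function(s) {
    prm <- eeg_coupling_params(n_channels = 2, sampling_rate = 128,
                               band_envelope_rho = rep(0, 6))
    g <- generate_coupled_eeg(prm, 330, seed = 800 + s)
    pl <- eeg_pair_pipeline(g$a, g$b, epoch_step = 1)
    mean(pl$map$R, na.rm = TRUE)
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("coupled bands exceed uncoupled bands in the correlation maps", {
  pat <- c(0.8, 0, 0.8, 0, 0.8, 0)
  gaps <- sapply(1:8, function(s) {
    prm <- eeg_coupling_params(n_channels = 2, sampling_rate = 128,
                               band_envelope_rho = pat)
    g <- generate_coupled_eeg(prm, 400, seed = 900 + s)
    pl <- eeg_pair_pipeline(g$a, g$b, epoch_step = 0.5)
    bm <- colMeans(pl$map$R, na.rm = TRUE)
    mean(bm[c(1, 3, 5)]) - mean(bm[c(2, 4, 6)])
  })
  expect_gt(mean(gaps), 0.3)
})
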