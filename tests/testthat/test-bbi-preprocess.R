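test_that("tachogram CSV I/O round-trips and validates", {
  g <- generate_coupled_bbi(bbi_coupling_params(), 600, seed = 21)
  f <- tempfile(fileext = ".csv")
  write_bbi_csv(list(g$a, g$b), f)
  back <- read_bbi_csv(f)
  expect_equal(length(back), 2)
  key <- paste(g$a$participant, g$a$session, sep = "/")
  expect_equal(back[[key]]$intervals, g$a$intervals, tolerance = 1e-9)
  expect_equal(back[[key]]$beat_times, g$a$beat_times, tolerance = 1e-9)
  # file-level round trip: write(read(x)) reproduces the table
  f2 <- tempfile(fileext = ".csv")
  write_bbi_csv(back, f2)
  expect_equal(utils::read.csv(f), utils::read.csv(f2), tolerance = 1e-12)
  # ~600 intervals parsed for a 600-s session at 1000 ms baseline
  expect_lt(abs(length(back[[key]]$intervals) - 600), 60)

  bad <- data.frame(participant = "p", session = "1",
                    t_beat_s = c(1, 2, 3), bbi_ms = c(1000, -5, 1000))
  fb <- tempfile(fileext = ".csv")
  utils::write.csv(bad, fb, row.names = FALSE)
  expect_error(read_bbi_csv(fb), "row 2")

  bad2 <- data.frame(participant = "p", session = "1",
                     t_beat_s = c(1, 3, 2), bbi_ms = rep(1000, 3))
  utils::write.csv(bad2, fb, row.names = FALSE)
  expect_error(read_bbi_csv(fb), "non-monotone")
})

test_that("artifact correction is identity on clean data and idempotent", {
  for (s in 1:5) {
    g <- generate_coupled_bbi(bbi_coupling_params(), 600, seed = 400 + s)
    cc <- detect_correct_outliers(g$a)
    expect_equal(nrow(cc$report), 0)
    expect_identical(cc$tachogram, g$a)
  }
  # idempotence on artifact-laden fixtures
  for (s in 1:5) {
    g <- generate_coupled_bbi(bbi_coupling_params(artifact_rate = 3), 600,
                              seed = 410 + s)
    c1 <- detect_correct_outliers(g$a)
    c2 <- detect_correct_outliers(c1$tachogram)
    expect_equal(nrow(c2$report), 0)
  }
  expect_error(detect_correct_outliers(mk_tachogram(8)), "11 intervals")
})

test_that("a single missed beat is found, split, and recovered", {
  g <- generate_coupled_bbi(bbi_coupling_params(), 600, seed = 2)
  tach <- g$a
  iv <- tach$intervals
  i <- 300
  iv2 <- c(iv[1:(i - 1)], iv[i] + iv[i + 1], iv[(i + 2):length(iv)])
  bt2 <- tach$beat_times[1] + c(0, cumsum(iv2) / 1000)
  merged <- bbi_tachogram(tach$participant, tach$session, bt2, iv2)

  cc <- detect_correct_outliers(merged)
  expect_equal(nrow(cc$report), 1)
  expect_equal(cc$report$rule, "missed")
  expect_equal(cc$report$old_ms, iv[i] + iv[i + 1])

  u0 <- interpolate_1hz(tach)
  u1 <- interpolate_1hz(cc$tachogram)
  ov <- intersect(bbi_times(u0), bbi_times(u1))
  rms <- sqrt(mean((u0$values[match(ov, bbi_times(u0))] -
                      u1$values[match(ov, bbi_times(u1))])^2))
  expect_lt(rms, 50)
})

test_that("correction recall and false-flag rates meet the detection target", {
  recalls <- c(); false_rates <- c()
  for (s in 1:20) {
    g <- generate_coupled_bbi(bbi_coupling_params(artifact_rate = 3), 600,
                              seed = 500 + s)
    cc <- detect_correct_outliers(g$a)
    inj <- g$artifacts$a$time
    det <- cc$report$time
    if (length(inj) == 0) next
    recalls <- c(recalls,
                 mean(sapply(inj, function(t) any(abs(det - t) < 2))))
    fd <- if (length(det)) sum(sapply(det, function(t) all(abs(inj - t) >= 2)))
          else 0
    false_rates <- c(false_rates,
                     fd / (length(g$a$intervals) - 2 * length(inj)))
  }
  expect_gte(mean(recalls), 0.8)
  expect_lte(mean(false_rates), 0.05)
})

test_that("PCHIP resampling reproduces knots, linear data, and the oracle", {
  g <- generate_coupled_bbi(bbi_coupling_params(), 120, seed = 31)
  x <- g$a$beat_times[-1]
  y <- g$a$intervals
  # knots reproduced exactly
  expect_equal(pchip_eval(x, y, x), y, tolerance = 1e-12)
  # linear data reproduced exactly
  xl <- sort(runif(20, 0, 100))
  yl <- 3 * xl + 7
  expect_equal(pchip_eval(xl, yl, seq(0, 100, by = 0.5)),
               3 * seq(0, 100, by = 0.5) + 7, tolerance = 1e-9)
  # independent dense evaluation oracle
  skip_if_not_installed("pracma")
  xo <- seq(min(x), max(x), length.out = 500)
  expect_equal(pchip_eval(x, y, xo), pracma::pchip(x, y, xo),
               tolerance = 1e-9)

  u <- interpolate_1hz(g$a)
  expect_equal(u$start, ceiling(x[1]))
  expect_equal(length(u$values),
               floor(x[length(x)]) - ceiling(x[1]) + 1)
  # segment-local no-overshoot: values within the global knot range
  expect_true(all(u$values >= min(y) & u$values <= max(y)))
  expect_error(interpolate_1hz(mk_tachogram(1)), "at least 2")
})

test_that("moving-average smoothing matches analytic cases and the oracle", {
  const <- mk_series(rep(1000, 50))
  expect_equal(smooth_moving(const)$values, rep(1000, 50))

  imp <- rep(0, 50); imp[25] <- 1
  sm <- moving_average(imp, 10)
  expect_equal(sm[25], 0.1)

  set.seed(5)
  x <- rnorm(300, 1000, 40)
  expect_equal(moving_average(x, 10), oracle_moving_average(x, 10),
               tolerance = 1e-12)
  expect_equal(moving_average(x, 7), oracle_moving_average(x, 7),
               tolerance = 1e-12)
  expect_error(smooth_moving(const, window = 0), "positive")
  expect_error(smooth_moving(mk_series(rep(1000, 5)), 10), "shorter")
})

test_that("the preprocessing pipeline preserves the mean of clean data", {
  g <- generate_coupled_bbi(bbi_coupling_params(), 900, seed = 61)
  pp <- preprocess_bbi(g$a)
  # the 1 Hz series estimates the time-average of the interval function,
  # i.e. the duration-weighted mean of the intervals
  tw_mean <- sum(g$a$intervals^2) / sum(g$a$intervals)
  expect_lt(abs(mean(pp$series$values) - tw_mean), 1)
  expect_equal(nrow(pp$report), 0)
})
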