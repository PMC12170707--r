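# BBI preprocessing: artifact correction, 1 Hz PCHIP resampling, smoothing.

#' Read BBI tachograms from CSV
#'
#' Expects columns `participant`, `session`, `t_beat_s` (time of the beat
#' ending each interval, seconds from session start) and `bbi_ms`. Returns
#' one tachogram per (participant, session); the first beat time is
#' reconstructed as `t_beat_s[1] - bbi_ms[1] / 1000`.
#'
#' @param path CSV file path.
#' @return Named list of [bbi_tachogram()] objects
#'   (`"<participant>/<session>"`).
#' @export
read_bbi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "session", "t_beat_s", "bbi_ms")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (key in unique(paste(df$participant, df$session, sep = "/"))) {
    sub <- df[paste(df$participant, df$session, sep = "/") == key, , drop = FALSE]
    bad <- which(sub$bbi_ms <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive interval at row %d (%s)",
                   as.integer(rownames(sub)[bad[1]]), key))
    }
    bad <- which(diff(sub$t_beat_s) <= 0)
    if (length(bad)) {
      stop(sprintf("non-monotone beat time at row %d (%s)",
                   as.integer(rownames(sub)[bad[1] + 1L]), key))
    }
    bt <- c(sub$t_beat_s[1] - sub$bbi_ms[1] / 1000, sub$t_beat_s)
    out[[key]] <- bbi_tachogram(sub$participant[1], sub$session[1],
                                bt, sub$bbi_ms)
  }
  out
}

#' Write BBI tachograms to CSV
#'
#' Inverse of [read_bbi_csv()]: one row per interval, timestamped by the
#' beat ending it.
#'
#' @param tachs a `bbi_tachogram` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bbi_csv <- function(tachs, path) {
  if (inherits(tachs, "bbi_tachogram")) tachs <- list(tachs)
  rows <- do.call(rbind, lapply(tachs, function(tg) {
    data.frame(participant = tg$participant, session = tg$session,
               t_beat_s = tg$beat_times[-1], bbi_ms = tg$intervals)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Detect and correct artifact beats in a tachogram
#'
#' Time-varying-threshold decision cascade in the style of modern RR artifact
#' correctors: successive interval differences (dRR) and deviations from a
#' rolling median are scaled by a rolling quantile-based deviation estimate
#' (half the local interquartile range); intervals exceeding `c_scale` times
#' that estimate are classified and corrected:
#'
#' * missed beat — interval near twice the local median: split in half
#'   (a beat is restored at the midpoint);
#' * extra beat — two adjacent intervals summing to about the local median:
#'   merged (the spurious beat is removed);
#' * ectopic beat — short-long alternation: if the pair sums to about one
#'   local median the inserted beat is removed, if to about two medians the
#'   displaced beat is moved to the midpoint;
#' * remaining isolated long/short intervals are replaced by linear
#'   interpolation from the nearest unflagged neighbours.
#'
#' Corrections that change the interval sum rebuild downstream beat times by
#' cumulative summation. A warning (not an error) is raised when the
#' corrected fraction exceeds `max_fraction`.
#'
#' @param tach a [bbi_tachogram()] with at least 11 intervals.
#' @param quantile_window rolling window, in intervals, for the median and
#'   quantile-deviation estimates.
#' @param c_scale rejection threshold in quantile-deviation units.
#' @param max_fraction corrected fraction above which a warning is raised.
#' The cascade is applied repeatedly (corrections shift the local statistics
#' slightly) until no further change occurs, so the operation is idempotent;
#' in practice a second pass rarely fires at all.
#'
#' @return List with `tachogram` (corrected) and `report` (data.frame:
#'   `index`, `time`, `old_ms`, `new_ms`, `rule`).
#' @export
detect_correct_outliers <- function(tach, quantile_window = 91,
                                    c_scale = 5.2, max_fraction = 0.2) {
  if (!inherits(tach, "bbi_tachogram")) stop("tach must be a bbi_tachogram")
  n0 <- length(tach$intervals)
  total <- NULL
  current <- tach
  for (pass in 1:5) {
    step <- correct_outliers_pass(current, quantile_window, c_scale)
    if (nrow(step$report) == 0L) break
    total <- rbind(total, step$report)
    current <- step$tachogram
  }
  if (is.null(total)) {
    total <- data.frame(index = integer(0), time = numeric(0),
                        old_ms = numeric(0), new_ms = numeric(0),
                        rule = character(0))
  }
  frac <- nrow(total) / n0
  if (frac > max_fraction) {
    warning(sprintf("corrected fraction %.1f%% exceeds %.0f%%",
                    100 * frac, 100 * max_fraction))
  }
  list(tachogram = current, report = total)
}

correct_outliers_pass <- function(tach, quantile_window, c_scale) {
  rr <- tach$intervals
  n <- length(rr)
  if (n < 11L) stop("need at least 11 intervals for artifact detection")
  t_end <- tach$beat_times[-1]

  drr <- c(0, diff(rr))
  med <- rolling_median(rr, quantile_window)
  # Floor the scale estimates at 20 ms: below wearable-PPG beat-timing
  # resolution no deviation is evidence of an artifact.
  th1 <- pmax(c_scale * rolling_iqr_scale(drr, quantile_window), 20)
  mrr <- rr - med
  th2 <- pmax(c_scale * rolling_iqr_scale(mrr, quantile_window), 20)
  nd <- drr / th1
  nm <- mrr / th2

  tol <- pmax(th2, 0.15 * med)
  report <- data.frame(index = integer(0), time = numeric(0),
                       old_ms = numeric(0), new_ms = numeric(0),
                       rule = character(0))
  # action per interval: keep / split / merge-with-next / pair-rebalance /
  # replace-by-value
  action <- rep("keep", n)
  new_val <- rr
  handled <- rep(FALSE, n)

  add_row <- function(i, old, new, rule) {
    report <<- rbind(report, data.frame(index = i, time = t_end[i] - old / 1000,
                                        old_ms = old, new_ms = new,
                                        rule = rule))
  }

  i <- 1L
  while (i <= n) {
    if (handled[i] || (abs(nd[i]) <= 1 && abs(nm[i]) <= 1)) {
      i <- i + 1L
      next
    }
    if (nm[i] > 1 && abs(rr[i] / 2 - med[i]) < tol[i]) {
      action[i] <- "split"
      add_row(i, rr[i], rr[i] / 2, "missed")
      handled[i] <- TRUE
    } else if (i < n && nm[i] < 0 && nm[i + 1L] < 0 &&
               abs(rr[i] + rr[i + 1L] - med[i]) < tol[i]) {
      action[i] <- "merge"
      add_row(i, rr[i], rr[i] + rr[i + 1L], "extra")
      handled[i] <- handled[i + 1L] <- TRUE
    } else if (i < n && abs(nd[i]) > 1 && abs(nd[i + 1L]) > 1 &&
               sign(nd[i]) != sign(nd[i + 1L]) &&
               abs(rr[i] + rr[i + 1L] - 2 * med[i]) < 2 * tol[i]) {
      action[i] <- "rebalance"  # displaced (ectopic) beat: move to midpoint
      add_row(i, rr[i], (rr[i] + rr[i + 1L]) / 2, "ectopic")
      handled[i] <- handled[i + 1L] <- TRUE
    } else if (abs(nm[i]) > 1 && abs(nd[i]) > 1) {
      # isolated long/short: replace value by interpolation from neighbours
      left <- i - 1L
      while (left >= 1L && (handled[left] || abs(nm[left]) > 1)) left <- left - 1L
      right <- i + 1L
      while (right <= n && (handled[right] || abs(nm[right]) > 1)) right <- right + 1L
      rep_val <- if (left >= 1L && right <= n) {
        rr[left] + (rr[right] - rr[left]) *
          (t_end[i] - t_end[left]) / (t_end[right] - t_end[left])
      } else if (left >= 1L) rr[left] else if (right <= n) rr[right] else med[i]
      action[i] <- "replace"
      new_val[i] <- rep_val
      add_row(i, rr[i], rep_val, "long_short")
      handled[i] <- TRUE
    }
    i <- i + 1L
  }

  if (nrow(report) == 0L) {
    return(list(tachogram = tach, report = report))
  }

  # rebuild the interval sequence
  iv <- numeric(0)
  fl <- character(0)
  i <- 1L
  while (i <= n) {
    a <- action[i]
    if (a == "keep" || a == "replace") {
      iv <- c(iv, new_val[i])
      fl <- c(fl, if (a == "keep") tach$flags[i] else "corrected")
      i <- i + 1L
    } else if (a == "split") {
      iv <- c(iv, rr[i] / 2, rr[i] / 2)
      fl <- c(fl, "corrected", "corrected")
      i <- i + 1L
    } else if (a == "merge") {
      iv <- c(iv, rr[i] + rr[i + 1L])
      fl <- c(fl, "corrected")
      i <- i + 2L
    } else {  # rebalance
      m <- (rr[i] + rr[i + 1L]) / 2
      iv <- c(iv, m, m)
      fl <- c(fl, "corrected", "corrected")
      i <- i + 2L
    }
  }
  bt <- tach$beat_times[1] + c(0, cumsum(iv) / 1000)
  list(tachogram = bbi_tachogram(tach$participant, tach$session, bt, iv, fl),
       report = report)
}

# Shape-preserving piecewise cubic Hermite (PCHIP) slopes, the
# Fritsch-Carlson weighted-harmonic-mean rule with one-sided cubic endpoints.
pchip_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  if (n == 2L) return(rep(delta, 2L))
  d <- numeric(n)
  for (k in 2:(n - 1L)) {
    if (delta[k - 1L] * delta[k] <= 0) {
      d[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1L]
      w2 <- h[k] + 2 * h[k - 1L]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1L] + w2 / delta[k])
    }
  }
  endpoint <- function(h1, h2, d1, d2) {
    dd <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(dd) != sign(d1)) dd <- 0
    else if (sign(d1) != sign(d2) && abs(dd) > 3 * abs(d1)) dd <- 3 * d1
    dd
  }
  d[1] <- endpoint(h[1], h[2], delta[1], delta[2])
  d[n] <- endpoint(h[n - 1L], h[n - 2L], delta[n - 1L], delta[n - 2L])
  d
}

#' Evaluate the shape-preserving cubic Hermite interpolant
#'
#' @param x,y knots (x strictly increasing).
#' @param xout query points inside `[min(x), max(x)]`.
#' @return Interpolated values.
#' @export
pchip_eval <- function(x, y, xout) {
  if (length(x) < 2L) stop("need at least two knots")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  d <- pchip_slopes(x, y)
  k <- findInterval(xout, x, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k >= length(x)] <- length(x) - 1L
  h <- x[k + 1L] - x[k]
  s <- (xout - x[k]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[k] + h10 * h * d[k] + h01 * y[k + 1L] + h11 * h * d[k + 1L]
}

#' Resample a tachogram to a uniform 1 Hz series
#'
#' Knots are placed at the time of the beat ending each interval, with the
#' interval value as ordinate; the shape-preserving cubic Hermite
#' interpolant is evaluated on the integer-second grid spanning
#' `[ceiling(first knot), floor(last knot)]`. Shape preservation guarantees
#' no overshoot beyond the local data range within any knot interval.
#'
#' @param tach a [bbi_tachogram()] with at least 2 intervals.
#' @return A [uniform_bbi()] series (smoothing 0).
#' @export
interpolate_1hz <- function(tach) {
  if (!inherits(tach, "bbi_tachogram")) stop("tach must be a bbi_tachogram")
  if (length(tach$intervals) < 2L) stop("need at least 2 intervals")
  x <- tach$beat_times[-1]
  y <- tach$intervals
  t0 <- ceiling(x[1])
  t1 <- floor(x[length(x)])
  if (t1 - t0 < 1) stop("covered span shorter than 2 s")
  grid <- seq(t0, t1, by = 1)
  uniform_bbi(tach$participant, tach$session, t0, pchip_eval(x, y, grid))
}

#' Smooth a uniform BBI series with a centred moving window
#'
#' @param series a [uniform_bbi()].
#' @param window window length in seconds (default 10); at the edges the
#'   window shrinks symmetrically so the output length equals the input
#'   length.
#' @return A smoothed [uniform_bbi()].
#' @export
smooth_moving <- function(series, window = 10) {
  if (!inherits(series, "uniform_bbi")) stop("series must be a uniform_bbi")
  if (window <= 0) stop("window must be positive")
  if (length(series$values) < window) stop("series shorter than window")
  uniform_bbi(series$participant, series$session, series$start,
              moving_average(series$values, window), smoothing = window)
}

#' Preprocess a raw tachogram into the 1 Hz smoothed series
#'
#' Convenience wrapper: artifact correction, PCHIP resampling to 1 Hz and
#' moving-average smoothing in sequence.
#'
#' @param tach a [bbi_tachogram()].
#' @param smooth_window smoothing window, seconds.
#' @param ... passed to [detect_correct_outliers()].
#' @return List with `series` (a [uniform_bbi()]) and `report`.
#' @export
preprocess_bbi <- function(tach, smooth_window = 10, ...) {
  corr <- detect_correct_outliers(tach, ...)
  series <- smooth_moving(interpolate_1hz(corr$tachogram), smooth_window)
  list(series = series, report = corr$report)
}
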