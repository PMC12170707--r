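#' Beat-to-beat interval tachogram
#'
#' An irregular sequence of interbeat intervals for one participant-session.
#' Interval `i` spans beat `i` to beat `i + 1` and is attributed to the beat
#' that ends it.
#'
#' @param participant,session identifiers (scalars).
#' @param beat_times beat times in seconds from session start, strictly
#'   increasing.
#' @param intervals interbeat intervals in milliseconds,
#'   `length(beat_times) - 1` of them, all positive and consistent with
#'   `diff(beat_times)`.
#' @param flags per-interval state, one of `"ok"`, `"ectopic"`, `"missed"`,
#'   `"extra"`, `"corrected"`.
#' @return Object of class `bbi_tachogram`.
#' @export
bbi_tachogram <- function(participant, session, beat_times, intervals,
                          flags = rep("ok", length(intervals))) {
  if (length(intervals) != length(beat_times) - 1L) {
    stop("need length(intervals) == length(beat_times) - 1")
  }
  if (any(diff(beat_times) <= 0)) stop("beat times must be strictly increasing")
  if (any(intervals <= 0)) stop("intervals must be positive")
  if (max(abs(diff(beat_times) * 1000 - intervals)) > 1e-6 * 1000) {
    stop("intervals inconsistent with beat time differences")
  }
  ok <- flags %in% c("ok", "ectopic", "missed", "extra", "corrected")
  if (length(flags) != length(intervals) || !all(ok)) {
    stop("invalid artifact flags")
  }
  structure(
    list(participant = as.character(participant),
         session = as.character(session),
         beat_times = as.numeric(beat_times),
         intervals = as.numeric(intervals),
         flags = as.character(flags)),
    class = "bbi_tachogram"
  )
}

#' @export
print.bbi_tachogram <- function(x, ...) {
  cat(sprintf(
    "<bbi_tachogram> %s / %s: %d intervals over %.1f s, mean %.1f ms, %d flagged\n",
    x$participant, x$session, length(x$intervals),
    diff(range(x$beat_times)), mean(x$intervals), sum(x$flags != "ok")))
  invisible(x)
}

#' Uniform 1 Hz BBI series
#'
#' @param participant,session identifiers.
#' @param start time of the first sample, seconds from session start.
#' @param values interval values in ms at exactly 1 Hz spacing, all positive.
#' @param smoothing smoothing window already applied, in seconds (0 = raw).
#' @return Object of class `uniform_bbi`.
#' @export
uniform_bbi <- function(participant, session, start, values, smoothing = 0) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("uniform series must be finite and positive")
  }
  structure(
    list(participant = as.character(participant),
         session = as.character(session),
         start = as.numeric(start),
         values = as.numeric(values),
         smoothing = as.numeric(smoothing)),
    class = "uniform_bbi"
  )
}

#' Sample times of a uniform BBI series
#' @param x a `uniform_bbi` object.
#' @return Numeric vector of times in seconds.
#' @export
bbi_times <- function(x) x$start + seq_along(x$values) - 1

#' @export
print.uniform_bbi <- function(x, ...) {
  cat(sprintf(
    "<uniform_bbi> %s / %s: %d samples @1 Hz from t=%.0f s (smoothing %g s)\n",
    x$participant, x$session, length(x$values), x$start, x$smoothing))
  invisible(x)
}

#' Multichannel EEG recording
#'
#' @param subject subject id.
#' @param condition recording condition, one of `"baseline_joint"`,
#'   `"meditation"`, `"documentary"`.
#' @param labels channel labels (10/20 names).
#' @param srate sampling rate in Hz (> 100).
#' @param data channels x samples numeric matrix, microvolts.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject, condition, labels, srate, data) {
  condition <- match.arg(condition,
                         c("baseline_joint", "meditation", "documentary"))
  if (!is.matrix(data) || nrow(data) < 1L) stop("data must be a channels x samples matrix")
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (srate <= 100) stop("sampling rate must exceed 100 Hz")
  if (!all(is.finite(data))) stop("non-finite samples")
  rownames(data) <- labels
  structure(
    list(subject = as.character(subject), condition = condition,
         labels = as.character(labels), srate = as.numeric(srate),
         data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate))
  invisible(x)
}

#' Sliding epoch grid
#'
#' @param starts epoch start times (s), uniformly spaced by `step`.
#' @param length_s epoch length in seconds.
#' @param step step between epoch starts in seconds.
#' @param kept logical keep-mask, one entry per epoch.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(starts, length_s, step, kept = rep(TRUE, length(starts))) {
  if (length(kept) != length(starts)) stop("kept mask must match starts")
  if (length(starts) > 1L) {
    sp <- diff(starts)
    if (max(abs(sp - step)) > 1e-9) stop("starts must be spaced by step")
  }
  structure(list(starts = starts, length_s = length_s, step = step,
                 kept = kept),
            class = "epoch_set")
}

#' Coarse band-power time course
#'
#' @param subject subject id.
#' @param bands named list of `c(low, high)` frequency intervals in Hz.
#' @param channels channel labels.
#' @param values channels x bands x points array of power (linear scale, >= 0).
#' @param times point times in seconds.
#' @param log_power whether `values` are log-transformed.
#' @return Object of class `band_power_tc`.
#' @export
band_power_tc <- function(subject, bands, channels, values, times,
                          log_power = FALSE) {
  stopifnot(length(dim(values)) == 3L)
  if (dim(values)[3] < 1L) stop("need at least one time point")
  if (!log_power && any(values < 0)) stop("linear power must be non-negative")
  dimnames(values) <- list(channels, names(bands), NULL)
  structure(list(subject = as.character(subject), bands = bands,
                 channels = channels, values = values, times = times,
                 log_power = log_power),
            class = "band_power_tc")
}

#' Topographic correlation map
#'
#' Channels x bands matrix of pairwise Pearson R with an optional mask state
#' per cell; masked cells carry 0 in `R` and their original value in
#' `premask`.
#'
#' @param pair_id pairing identifier.
#' @param condition recording condition.
#' @param R channels x bands correlation matrix, entries in [-1, 1] or NA.
#' @param mask character matrix, `"unmasked"`, `"masked_to_zero"` or
#'   `"undefined"`.
#' @param premask pre-mask values (defaults to `R`).
#' @return Object of class `topo_map`.
#' @export
topo_map <- function(pair_id, condition, R,
                     mask = matrix("unmasked", nrow(R), ncol(R),
                                   dimnames = dimnames(R)),
                     premask = R) {
  if (any(abs(R) > 1 + 1e-12, na.rm = TRUE)) stop("|R| must be <= 1")
  structure(list(pair_id = as.character(pair_id), condition = condition,
                 R = R, mask = mask, premask = premask),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %s [%s]: %d ch x %d bands, %d masked, %d undefined\n",
              x$pair_id, x$condition, nrow(x$R), ncol(x$R),
              sum(x$mask == "masked_to_zero"), sum(x$mask == "undefined")))
  invisible(x)
}
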