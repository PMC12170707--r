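# Synthetic dyadic cohort: rosters, coupled tachograms, coupled EEG.
#
# The generator emulates the study design this package analyzes: 21
# participants (3 MZ twin pairs, 1 DZ pair, 13 age-matched controls), 17
# group meditation sessions, within-pair coupled heart-rate dynamics and
# 32-channel EEG whose slow band-power envelopes are correlated within pairs.
# Coupling strength is a known ground-truth input, so every downstream
# statistic can be validated by parameter recovery.

#' Cohort design configuration
#'
#' Defaults reproduce the study design: 3 monozygotic pairs, 1 dizygotic
#' pair, 13 controls, 17 sessions. Twin-pair ages default to the recruited
#' pairs' ages; each pair is separated from its co-twin (one member seated
#' apart) in three of sessions 3, 4, 9, 10, 14 and 15.
#'
#' @param n_mz_pairs,n_dz_pairs,n_controls non-negative counts.
#' @param n_sessions number of meditation sessions (>= 0).
#' @param session_duration session length in seconds (> 0).
#' @param separation_sessions data.frame with columns `pair` and `session`
#'   marking sessions where the pair's second member sat apart; `NULL` for
#'   the default schedule.
#' @param ages numeric vector of per-pair ages (recycled); `NULL` for the
#'   study ages.
#' @param rng_seed integer root seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_mz_pairs = 3, n_dz_pairs = 1, n_controls = 13,
                          n_sessions = 17, session_duration = 1800,
                          separation_sessions = NULL, ages = NULL,
                          rng_seed = 1L) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_controls, n_sessions)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (session_duration <= 0) stop("session_duration must be positive")
  n_pairs <- n_mz_pairs + n_dz_pairs
  pair_ids <- if (n_pairs > 0) LETTERS[seq_len(n_pairs)] else character(0)
  if (is.null(ages)) {
    study <- c(25, 63, 56, 76, 36, 54)
    ages <- if (n_pairs <= length(study)) study[seq_len(n_pairs)] else
      rep(study, length.out = max(n_pairs, 1))[seq_len(n_pairs)]
  } else {
    ages <- rep(as.numeric(ages), length.out = max(n_pairs, 1))[seq_len(n_pairs)]
  }
  if (is.null(separation_sessions)) {
    slots <- c(3, 4, 9, 10, 14, 15)
    slots <- slots[slots <= n_sessions]
    separation_sessions <- do.call(rbind, lapply(seq_along(pair_ids), function(i) {
      mine <- slots[seq_along(slots) %% 2L == i %% 2L]
      if (length(mine) == 0) return(NULL)
      data.frame(pair = pair_ids[i], session = mine)
    }))
    if (is.null(separation_sessions)) {
      separation_sessions <- data.frame(pair = character(0), session = integer(0))
    }
  }
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 n_controls = n_controls, n_sessions = n_sessions,
                 session_duration = session_duration,
                 separation_sessions = separation_sessions,
                 ages = ages, rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

#' Generate a cohort roster and session schedule
#'
#' Builds the participant table (twins and controls with ages, sex and
#' control-pair assignments) and the per-session schedule. Every participant
#' has a recording slot in every session; the separated co-twin keeps
#' recording but is flagged out of the group meditation, which later excludes
#' that pairing-session from pairwise comparison. Under the default design
#' one control serves two pairs, as in the study cohort.
#'
#' @param config a [cohort_config()].
#' @return List of class `twin_roster` with elements `roster` (data.frame:
#'   participant, pair_id, type, age, sex, control_for), `schedule`
#'   (data.frame: participant, session, present, in_group) and `config`.
#' @export
generate_roster <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  n_pairs <- config$n_mz_pairs + config$n_dz_pairs
  pair_ids <- if (n_pairs > 0) LETTERS[seq_len(n_pairs)] else character(0)
  types <- c(rep("MZ", config$n_mz_pairs), rep("DZ", config$n_dz_pairs))
  study_sex <- c(A = "F", B = "F", C = "M", D = "F", E = "F", F = "F")

  twin_rows <- do.call(rbind, lapply(seq_along(pair_ids), function(i) {
    sex <- if (pair_ids[i] %in% names(study_sex)) study_sex[[pair_ids[i]]] else "F"
    data.frame(participant = paste0(pair_ids[i], 1:2),
               pair_id = pair_ids[i], type = types[i],
               age = config$ages[i], sex = sex, control_for = "",
               stringsAsFactors = FALSE)
  }))

  ctrl_rows <- NULL
  if (config$n_controls > 0) {
    ids <- sprintf("ctrl%02d", seq_len(config$n_controls))
    # Control-to-pair assignment. The default study design uses group sizes
    # 3 (pair A), 2 (B), 8 (C) and 1 (D), with the last of B's controls also
    # serving pair D; other configurations assign controls round-robin.
    assign_list <- stats::setNames(vector("list", config$n_controls), ids)
    group_mean <- NULL
    if (config$n_mz_pairs == 3 && config$n_dz_pairs == 1 &&
        config$n_controls == 13) {
      groups <- list(A = 1:3, B = 4:5, C = 6:13, D = 5L)
      group_mean <- c(A = 34.3, B = 64.0, C = 49.3, D = 68)
      group_sd <- c(A = 3.1, B = 5.7, C = 5.8, D = 0)
      for (p in names(groups)) for (k in groups[[p]]) {
        assign_list[[k]] <- c(assign_list[[k]], p)
      }
      age_ctrl <- numeric(config$n_controls)
      with_seed(child_seed(config$rng_seed, "control-ages"), {
        for (p in c("A", "B", "C")) {
          idx <- groups[[p]]
          z <- stats::rnorm(length(idx))
          z <- if (length(idx) > 1) (z - mean(z)) / stats::sd(z) else 0 * z
          age_ctrl[idx] <- round(group_mean[[p]] + group_sd[[p]] * z, 1)
        }
      })
    } else if (n_pairs > 0) {
      for (k in seq_len(config$n_controls)) {
        p <- pair_ids[((k - 1L) %% n_pairs) + 1L]
        assign_list[[k]] <- p
      }
      age_ctrl <- with_seed(child_seed(config$rng_seed, "control-ages"), {
        base <- config$ages[match(vapply(assign_list, `[`, "", 1), pair_ids)]
        round(base + stats::rnorm(config$n_controls, 0, 4), 1)
      })
    } else {
      age_ctrl <- with_seed(child_seed(config$rng_seed, "control-ages"),
                            round(stats::rnorm(config$n_controls, 50, 15), 1))
    }
    ctrl_sex <- vapply(assign_list, function(p) {
      if (length(p) > 0 && p[1] %in% names(study_sex)) study_sex[[p[1]]] else "F"
    }, "")
    ctrl_rows <- data.frame(participant = ids, pair_id = NA_character_,
                            type = "control", age = age_ctrl, sex = ctrl_sex,
                            control_for = vapply(assign_list, paste, "",
                                                 collapse = ","),
                            stringsAsFactors = FALSE)
  }

  roster <- rbind(twin_rows, ctrl_rows)
  if (is.null(roster)) {
    roster <- data.frame(participant = character(0), pair_id = character(0),
                         type = character(0), age = numeric(0),
                         sex = character(0), control_for = character(0))
  }
  rownames(roster) <- NULL

  if (config$n_sessions > 0 && nrow(roster) > 0) {
    schedule <- expand.grid(participant = roster$participant,
                            session = seq_len(config$n_sessions),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    schedule$present <- TRUE
    schedule$in_group <- TRUE
    sep <- config$separation_sessions
    if (!is.null(sep) && nrow(sep) > 0) {
      for (r in seq_len(nrow(sep))) {
        separated <- paste0(sep$pair[r], "2")  # second co-twin sits apart
        hit <- schedule$participant == separated &
          schedule$session == sep$session[r]
        schedule$in_group[hit] <- FALSE
      }
    }
  } else {
    schedule <- data.frame(participant = character(0), session = integer(0),
                           present = logical(0), in_group = logical(0))
  }
  structure(list(roster = roster, schedule = schedule, config = config),
            class = "twin_roster")
}

#' Count BBI recording slots in a roster
#' @param x a `twin_roster`.
#' @return Number of (participant, session) recording slots.
#' @export
recording_slots <- function(x) sum(x$schedule$present)

#' @export
print.twin_roster <- function(x, ...) {
  cat(sprintf("<twin_roster> %d participants (%d MZ pairs, %d DZ, %d controls), %d sessions, %d slots\n",
              nrow(x$roster), x$config$n_mz_pairs, x$config$n_dz_pairs,
              x$config$n_controls, x$config$n_sessions, recording_slots(x)))
  invisible(x)
}

# Band-limited unit-variance Gaussian process on a regular grid: white noise
# smoothed by a short moving average (upper cutoff) minus a long moving
# average (lower cutoff), then standardized.
band_limited_gp <- function(n, dt, band) {
  w_hi <- max(1L, round(1 / (band[2] * dt)))
  w_lo <- max(w_hi + 1L, round(1 / (band[1] * dt)))
  z <- stats::rnorm(n + 2L * w_lo)
  z <- moving_average(z, w_hi)
  z <- z - moving_average(z, w_lo)
  z <- z[w_lo + seq_len(n)]
  s <- stats::sd(z)
  if (s == 0) return(z * 0)
  (z - mean(z)) / s
}

#' Coupling parameters for synthetic twin BBI dynamics
#'
#' The two subjects' interval series share a smooth low-frequency latent
#' process scaled by `shared_amplitude`, plus independent latent processes
#' scaled by `individual_amplitude`, on top of per-subject baselines:
#' `BBI_i(t) = baseline_i + shared_amplitude * S(t) +
#' individual_amplitude * I_i(t)`. The default bandwidth (0.01-0.1 Hz)
#' matches the low-frequency band of heart-rate variability. Artifacts
#' (ectopic, missed, extra beats) are injected after beat placement at
#' `artifact_rate` events per minute.
#'
#' @param baseline_a,baseline_b mean interval per subject, ms (> 300).
#' @param shared_amplitude,individual_amplitude latent process scales, ms
#'   (>= 0).
#' @param shared_bandwidth `c(low, high)` of the latent processes, Hz.
#' @param artifact_rate injected artifacts per minute (>= 0).
#' @param artifact_mix proportions of ectopic / missed / extra artifacts.
#' @return List of class `bbi_coupling_params`.
#' @export
bbi_coupling_params <- function(baseline_a = 1000, baseline_b = 1000,
                                shared_amplitude = 40,
                                individual_amplitude = 25,
                                shared_bandwidth = c(0.01, 0.1),
                                artifact_rate = 0,
                                artifact_mix = c(ectopic = 0.4, missed = 0.3,
                                                 extra = 0.3)) {
  if (baseline_a <= 300 || baseline_b <= 300) stop("baselines must exceed 300 ms")
  if (shared_amplitude < 0 || individual_amplitude < 0) {
    stop("amplitudes must be non-negative")
  }
  if (artifact_rate < 0) stop("artifact_rate must be non-negative")
  if (length(shared_bandwidth) != 2 || shared_bandwidth[1] <= 0 ||
      shared_bandwidth[2] <= shared_bandwidth[1]) {
    stop("shared_bandwidth must be c(low, high) with 0 < low < high")
  }
  mix <- artifact_mix / sum(artifact_mix)
  structure(list(baseline_a = baseline_a, baseline_b = baseline_b,
                 shared_amplitude = shared_amplitude,
                 individual_amplitude = individual_amplitude,
                 shared_bandwidth = shared_bandwidth,
                 artifact_rate = artifact_rate, artifact_mix = mix),
            class = "bbi_coupling_params")
}

# Place beats by cumulative-interval integration of a latent interval
# function given on grid (tg, bbi_ms).
place_beats <- function(tg, bbi_ms, duration) {
  f <- stats::approxfun(tg, bbi_ms, rule = 2)
  times <- numeric(ceiling(duration / (min(bbi_ms) / 1000)) + 2L)
  times[1] <- 0
  k <- 1L
  while (times[k] < duration) {
    step <- f(times[k]) / 1000
    times[k + 1L] <- times[k] + step
    k <- k + 1L
  }
  times[seq_len(k)]
}

# Inject one artifact into (beat_times, intervals, flags) at interval index i.
inject_artifact <- function(state, type, i) {
  bt <- state$beat_times; iv <- state$intervals; fl <- state$flags
  d <- iv[i]
  if (type == "ectopic") {
    new_beat <- bt[i] + 0.35 * d / 1000
    bt <- append(bt, new_beat, after = i)
    iv <- append(iv[-i], c(0.35 * d, 0.65 * d), after = i - 1L)
    fl <- append(fl[-i], c("ectopic", "ectopic"), after = i - 1L)
  } else if (type == "extra") {
    new_beat <- bt[i] + 0.5 * d / 1000
    bt <- append(bt, new_beat, after = i)
    iv <- append(iv[-i], c(0.5 * d, 0.5 * d), after = i - 1L)
    fl <- append(fl[-i], c("extra", "extra"), after = i - 1L)
  } else {  # missed: merge intervals i and i + 1 (drop the shared beat)
    iv[i] <- iv[i] + iv[i + 1L]
    bt <- bt[-(i + 1L)]
    iv <- iv[-(i + 1L)]
    fl[i] <- "missed"
    fl <- fl[-(i + 1L)]
  }
  list(beat_times = bt, intervals = iv, flags = fl)
}

#' Generate a coupled pair of BBI tachograms with ground truth
#'
#' @param params a [bbi_coupling_params()].
#' @param duration session duration in seconds.
#' @param seed integer seed; output is bit-reproducible given
#'   `(params, duration, seed)`.
#' @param ids participant ids for the two subjects.
#' @param session session id.
#' @return List with tachograms `a` and `b`, the latent `shared` process
#'   (data.frame `time`, `value`), and `artifacts` (list of data.frames
#'   `type`, `time`, `index` per subject; `time` is the start of the
#'   modified interval).
#' @export
generate_coupled_bbi <- function(params = bbi_coupling_params(), duration,
                                 seed = 1L, ids = c("a", "b"),
                                 session = "s1") {
  if (!inherits(params, "bbi_coupling_params")) stop("invalid params")
  if (duration <= 0) stop("duration must be positive")
  with_seed(seed, {
    dt <- 0.5
    tg <- seq(0, duration + 5, by = dt)
    n <- length(tg)
    S <- band_limited_gp(n, dt, params$shared_bandwidth)
    Ia <- band_limited_gp(n, dt, params$shared_bandwidth)
    Ib <- band_limited_gp(n, dt, params$shared_bandwidth)
    bbi_a <- params$baseline_a + params$shared_amplitude * S +
      params$individual_amplitude * Ia
    bbi_b <- params$baseline_b + params$shared_amplitude * S +
      params$individual_amplitude * Ib
    if (min(bbi_a, bbi_b) <= 250) {
      stop("parameters imply non-physiological (<= 250 ms) intervals")
    }

    build <- function(bbi, id) {
      bt <- place_beats(tg, bbi, duration)
      iv <- diff(bt) * 1000
      list(beat_times = bt, intervals = iv, flags = rep("ok", length(iv)))
    }
    st_a <- build(bbi_a, ids[1])
    st_b <- build(bbi_b, ids[2])

    inject_all <- function(st) {
      n_art <- stats::rpois(1, params$artifact_rate * duration / 60)
      log <- data.frame(type = character(0), time = numeric(0),
                        index = integer(0))
      if (n_art == 0) return(list(state = st, log = log))
      types <- sample(names(params$artifact_mix), n_art, replace = TRUE,
                      prob = params$artifact_mix)
      m <- length(st$intervals)
      eligible <- seq(3L, m - 3L)
      if (length(eligible) < n_art * 3L) {
        n_art <- length(eligible) %/% 3L
        types <- types[seq_len(n_art)]
      }
      idx <- sort(sample(eligible, n_art))
      # enforce separation so artifact sites never overlap
      keep <- rep(TRUE, length(idx))
      if (length(idx) > 1) for (j in 2:length(idx)) {
        if (idx[j] - idx[max(which(keep[1:(j - 1)]))] < 3L) keep[j] <- FALSE
      }
      idx <- idx[keep]; types <- types[keep]
      # apply from the end so earlier indices stay valid
      ord <- order(idx, decreasing = TRUE)
      for (j in ord) {
        log <- rbind(log, data.frame(type = types[j],
                                     time = st$beat_times[idx[j]],
                                     index = idx[j]))
        st <- inject_artifact(st, types[j], idx[j])
      }
      log <- log[order(log$time), , drop = FALSE]
      rownames(log) <- NULL
      list(state = st, log = log)
    }
    ia <- inject_all(st_a)
    ib <- inject_all(st_b)

    list(
      a = bbi_tachogram(ids[1], session, ia$state$beat_times,
                        ia$state$intervals, ia$state$flags),
      b = bbi_tachogram(ids[2], session, ib$state$beat_times,
                        ib$state$intervals, ib$state$flags),
      shared = data.frame(time = tg, value = S),
      artifacts = list(a = ia$log, b = ib$log)
    )
  })
}

#' Convert a target coupling correlation into amplitude parameters
#'
#' Splits a total latent standard deviation into shared and individual
#' amplitudes so that the two subjects' latent interval fluctuations have
#' Pearson correlation `rho`.
#'
#' @param rho target correlation in [0, 1].
#' @param total_sd total latent fluctuation SD, ms.
#' @param ... passed on to [bbi_coupling_params()].
#' @return A `bbi_coupling_params` object.
#' @export
bbi_params_from_rho <- function(rho, total_sd = 50, ...) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  bbi_coupling_params(shared_amplitude = sqrt(rho) * total_sd,
                      individual_amplitude = sqrt(1 - rho) * total_sd, ...)
}

# Standard 32-channel 10/20-extended montage labels.
eeg_1020_labels <- function(n = 32) {
  base <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1",
            "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
            "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1",
            "Oz", "O2")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("EX%02d", seq_len(n - length(base))))
}

#' Coupling parameters for synthetic paired EEG
#'
#' Each channel is 1/f background noise plus per-band sinusoidal carriers
#' amplitude-modulated by slow (< 0.05 Hz) envelopes. Within a dyad the band
#' envelopes are a shared/independent Gaussian mixture with target Pearson
#' correlation `band_envelope_rho` per band.
#'
#' @param n_channels channel count (10/20 labels, default 32).
#' @param sampling_rate Hz, >= 100 (>= twice the highest analyzed frequency).
#' @param band_envelope_rho length-6 vector of target envelope correlations
#'   in [-1, 1] (delta..gamma order).
#' @param one_over_f_exponent spectral exponent of the background.
#' @param oscillation_center_freqs carrier frequency per band, Hz.
#' @param oscillation_amplitudes carrier amplitude per band, microvolts.
#' @param background_amplitude background SD, microvolts.
#' @return List of class `eeg_coupling_params`.
#' @export
eeg_coupling_params <- function(n_channels = 32, sampling_rate = 250,
                                band_envelope_rho = rep(0, 6),
                                one_over_f_exponent = 1,
                                oscillation_center_freqs = c(2.5, 5.5, 10, 15, 24, 40),
                                oscillation_amplitudes = c(4, 3, 5, 2.5, 2, 1.5),
                                background_amplitude = 2) {
  if (any(band_envelope_rho < -1 | band_envelope_rho > 1)) {
    stop("band_envelope_rho must lie in [-1, 1]")
  }
  if (sampling_rate < 100) stop("sampling_rate must be >= 100 Hz")
  if (sampling_rate < 2 * max(oscillation_center_freqs)) {
    stop("sampling_rate must be at least twice the highest carrier frequency")
  }
  if (n_channels < 1) stop("need at least one channel")
  k <- length(oscillation_center_freqs)
  structure(list(n_channels = n_channels, sampling_rate = sampling_rate,
                 band_envelope_rho = rep(band_envelope_rho, length.out = k),
                 one_over_f_exponent = one_over_f_exponent,
                 oscillation_center_freqs = oscillation_center_freqs,
                 oscillation_amplitudes = rep(oscillation_amplitudes,
                                              length.out = k),
                 background_amplitude = background_amplitude),
            class = "eeg_coupling_params")
}

# 1/f^a amplitude-shaped Gaussian noise via FFT phase randomization.
one_over_f_noise <- function(n, exponent) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  phases <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else (x - mean(x)) / s
}

#' Generate a coupled pair of EEG recordings with ground-truth envelopes
#'
#' @param params an [eeg_coupling_params()].
#' @param duration recording length in seconds (>= 300 recommended for
#'   stable envelope statistics; must be positive).
#' @param seed integer seed.
#' @param ids subject ids.
#' @param condition recording condition label.
#' @return List with recordings `a`, `b` and `envelopes`: list with `times`
#'   (s, 1 Hz grid) and matrices `a`, `b` (bands x time) of the amplitude
#'   envelopes actually applied.
#' @export
generate_coupled_eeg <- function(params = eeg_coupling_params(), duration,
                                 seed = 1L, ids = c("a", "b"),
                                 condition = "meditation") {
  if (!inherits(params, "eeg_coupling_params")) stop("invalid params")
  if (duration <= 0) stop("duration must be positive")
  if (duration < 300) {
    warning("durations below 300 s give noisy envelope statistics")
  }
  with_seed(seed, {
    fs <- params$sampling_rate
    n <- round(duration * fs)
    nb <- length(params$oscillation_center_freqs)
    te <- seq(0, duration, by = 1)  # envelope grid, 1 Hz
    ne <- length(te)
    env_band <- c(0.005, 0.05)
    kappa <- 0.4

    env_a <- matrix(0, nb, ne)
    env_b <- matrix(0, nb, ne)
    for (b in seq_len(nb)) {
      rho <- params$band_envelope_rho[b]
      S <- band_limited_gp(ne, 1, env_band)
      Ea <- band_limited_gp(ne, 1, env_band)
      Eb <- band_limited_gp(ne, 1, env_band)
      za <- sqrt(abs(rho)) * S + sqrt(1 - abs(rho)) * Ea
      zb <- sign(rho) * sqrt(abs(rho)) * S + sqrt(1 - abs(rho)) * Eb
      env_a[b, ] <- pmax(0, 1 + kappa * za)
      env_b[b, ] <- pmax(0, 1 + kappa * zb)
    }

    tt <- seq_len(n) / fs
    make_subject <- function(env, id) {
      dat <- matrix(0, params$n_channels, n)
      env_dense <- lapply(seq_len(nb), function(b) {
        stats::approx(te, env[b, ], xout = tt, rule = 2)$y
      })
      for (ch in seq_len(params$n_channels)) {
        x <- params$background_amplitude * one_over_f_noise(n, params$one_over_f_exponent)
        for (b in seq_len(nb)) {
          phase <- stats::runif(1, 0, 2 * pi)
          x <- x + params$oscillation_amplitudes[b] * env_dense[[b]] *
            sin(2 * pi * params$oscillation_center_freqs[b] * tt + phase)
        }
        dat[ch, ] <- x
      }
      eeg_recording(id, condition, eeg_1020_labels(params$n_channels), fs, dat)
    }
    rec_a <- make_subject(env_a, ids[1])
    rec_b <- make_subject(env_b, ids[2])
    list(a = rec_a, b = rec_b,
         envelopes = list(times = te, a = env_a, b = env_b))
  })
}
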