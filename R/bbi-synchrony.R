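# Pairwise heart-rate-dynamics similarity, pairing schemes, group statistics.

#' Sliding-window Pearson similarity of two 1 Hz BBI series
#'
#' The two series are aligned by absolute session time; windows of
#' `window` seconds start at the beginning of the overlap and advance by
#' `hop` seconds, each requiring the full `window` samples. A Pearson r is
#' computed per window; windows where either segment has zero variance are
#' skipped. The summary is the unweighted mean of retained window r values.
#'
#' @param a,b [uniform_bbi()] series from the same session.
#' @param window window length in seconds (samples at 1 Hz).
#' @param hop hop length in seconds.
#' @return List with `mean_r`, `window_r`, `n_windows` (retained), `overlap`
#'   (seconds) and `flag` (`"ok"` or `"no_windows"`). When the overlap is
#'   shorter than one window the result is flagged, not an error.
#' @export
windowed_pearson <- function(a, b, window = 300, hop = 60) {
  stopifnot(inherits(a, "uniform_bbi"), inherits(b, "uniform_bbi"))
  t0 <- max(a$start, b$start)
  t1 <- min(a$start + length(a$values) - 1, b$start + length(b$values) - 1)
  overlap <- t1 - t0 + 1
  if (!is.finite(overlap) || overlap < window) {
    return(list(mean_r = NA_real_, window_r = numeric(0), n_windows = 0L,
                overlap = max(overlap, 0), flag = "no_windows"))
  }
  va <- a$values[(t0 - a$start + 1):(t1 - a$start + 1)]
  vb <- b$values[(t0 - b$start + 1):(t1 - b$start + 1)]
  starts <- seq(1, overlap - window + 1, by = hop)
  rs <- vapply(starts, function(s) {
    xa <- va[s:(s + window - 1)]
    xb <- vb[s:(s + window - 1)]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
    stats::cor(xa, xb)
  }, numeric(1))
  kept <- rs[!is.na(rs)]
  list(mean_r = if (length(kept)) mean(kept) else NA_real_,
       window_r = rs, n_windows = length(kept), overlap = overlap,
       flag = if (length(kept)) "ok" else "no_windows")
}

#' Mean absolute BBI difference over the aligned overlap
#'
#' @param a,b [uniform_bbi()] series.
#' @return List with `mad_ms` (mean of |a(t) - b(t)| in ms, symmetric in the
#'   arguments) and `overlap` (seconds); `mad_ms` is `NA` when the overlap
#'   is empty.
#' @export
mean_abs_diff <- function(a, b) {
  stopifnot(inherits(a, "uniform_bbi"), inherits(b, "uniform_bbi"))
  t0 <- max(a$start, b$start)
  t1 <- min(a$start + length(a$values) - 1, b$start + length(b$values) - 1)
  if (t1 < t0) return(list(mad_ms = NA_real_, overlap = 0))
  va <- a$values[(t0 - a$start + 1):(t1 - a$start + 1)]
  vb <- b$values[(t0 - b$start + 1):(t1 - b$start + 1)]
  list(mad_ms = mean(abs(va - vb)), overlap = t1 - t0 + 1)
}

#' Enumerate the four pairing schemes of a twin cohort
#'
#' Builds all analyzed dyads: `T` (monozygotic co-twins), `DT` (dizygotic
#' co-twins), `CT` (each twin with each age-matched control assigned to the
#' twin's pair) and `N` (twins from different pairs). Sessions where either
#' member sat apart from the group, or that are listed in `exclusions`, are
#' flagged out for that pairing.
#'
#' @param roster a [generate_roster()] result (or compatible list with
#'   `roster` and `schedule`).
#' @param exclusions optional data.frame with columns `pairing` and
#'   `session` (additional data-quality exclusions).
#' @return List of class `pairing_scheme`: `pairings` (data.frame:
#'   `pairing`, `member1`, `member2`, `group`) and `inclusion` (logical
#'   matrix pairings x sessions).
#' @export
build_pairings <- function(roster, exclusions = NULL) {
  ros <- roster$roster
  sched <- roster$schedule
  twins <- ros[ros$type %in% c("MZ", "DZ"), , drop = FALSE]
  controls <- ros[ros$type == "control", , drop = FALSE]

  rows <- list()
  add <- function(m1, m2, group) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pairing = paste(m1, m2, sep = "-"), member1 = m1, member2 = m2,
      group = group, stringsAsFactors = FALSE)
  }
  # co-twin pairings
  for (p in unique(twins$pair_id)) {
    mem <- twins$participant[twins$pair_id == p]
    if (length(mem) == 2) {
      add(mem[1], mem[2], if (twins$type[twins$pair_id == p][1] == "MZ") "T" else "DT")
    }
  }
  # twin x matched control
  referenced <- character(0)
  for (k in seq_len(nrow(controls))) {
    pairs_for <- strsplit(controls$control_for[k], ",")[[1]]
    pairs_for <- pairs_for[nzchar(pairs_for)]
    if (length(pairs_for)) referenced <- c(referenced, controls$participant[k])
    for (p in pairs_for) {
      for (tw in twins$participant[twins$pair_id == p]) {
        add(tw, controls$participant[k], "CT")
      }
    }
  }
  if (nrow(controls) > 0 && length(referenced) < nrow(controls)) {
    warning("controls referenced by no twin pair: ",
            paste(setdiff(controls$participant, referenced), collapse = ", "))
  }
  # cross-pair twin dyads
  tp <- twins$participant
  if (length(tp) >= 2) {
    for (i in 1:(length(tp) - 1)) for (j in (i + 1):length(tp)) {
      if (twins$pair_id[i] != twins$pair_id[j]) add(tp[i], tp[j], "N")
    }
  }
  pairings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pairing = character(0), member1 = character(0),
               member2 = character(0), group = character(0))

  sessions <- sort(unique(sched$session))
  incl <- matrix(TRUE, nrow(pairings), length(sessions),
                 dimnames = list(pairings$pairing, sessions))
  if (length(sessions)) {
    ok <- function(id, s) {
      row <- sched$participant == id & sched$session == s
      any(row) && all(sched$present[row] & sched$in_group[row])
    }
    for (r in seq_len(nrow(pairings))) for (ci in seq_along(sessions)) {
      s <- sessions[ci]
      incl[r, ci] <- ok(pairings$member1[r], s) && ok(pairings$member2[r], s)
    }
  }
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (r in seq_len(nrow(exclusions))) {
      pr <- as.character(exclusions$pairing[r])
      s <- as.character(exclusions$session[r])
      if (pr %in% rownames(incl) && s %in% colnames(incl)) incl[pr, s] <- FALSE
    }
  }
  structure(list(pairings = pairings, inclusion = incl),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  tab <- table(x$pairings$group)
  cat("<pairing_scheme>", paste(names(tab), tab, sep = "=", collapse = ", "),
      sprintf("; %d sessions\n", ncol(x$inclusion)))
  invisible(x)
}

#' Pairwise similarity table for a cohort
#'
#' Computes mean windowed Pearson r and mean absolute difference for every
#' included pairing-session combination.
#'
#' @param scheme a [build_pairings()] result.
#' @param series named list of [uniform_bbi()] objects keyed
#'   `"<participant>/<session>"`.
#' @param window,hop passed to [windowed_pearson()].
#' @return data.frame: `pairing`, `group`, `session`, `mean_r`, `n_windows`,
#'   `mad_ms`, `overlap`.
#' @export
similarity_table <- function(scheme, series, window = 300, hop = 60) {
  out <- list()
  sessions <- colnames(scheme$inclusion)
  for (r in seq_len(nrow(scheme$pairings))) {
    for (s in sessions) {
      if (!scheme$inclusion[r, s]) next
      ka <- paste(scheme$pairings$member1[r], s, sep = "/")
      kb <- paste(scheme$pairings$member2[r], s, sep = "/")
      if (is.null(series[[ka]]) || is.null(series[[kb]])) next
      wp <- windowed_pearson(series[[ka]], series[[kb]], window, hop)
      md <- mean_abs_diff(series[[ka]], series[[kb]])
      out[[length(out) + 1L]] <- data.frame(
        pairing = scheme$pairings$pairing[r],
        group = scheme$pairings$group[r], session = as.integer(s),
        mean_r = wp$mean_r, n_windows = wp$n_windows,
        mad_ms = md$mad_ms, overlap = wp$overlap)
    }
  }
  if (!length(out)) {
    return(data.frame(pairing = character(0), group = character(0),
                      session = integer(0), mean_r = numeric(0),
                      n_windows = integer(0), mad_ms = numeric(0),
                      overlap = numeric(0)))
  }
  do.call(rbind, out)
}

#' Pairwise Wilcoxon rank-sum comparisons between pairing groups
#'
#' Two-sided Wilcoxon rank-sum tests (normal approximation with mid-rank tie
#' correction and continuity correction) for every pair of non-empty groups.
#' Groups with fewer than 2 observations are skipped with a notice.
#'
#' @param values numeric vector of similarity values.
#' @param groups group label per value (T/DT/CT/N).
#' @param alpha reported significance threshold (annotation only; no
#'   filtering is applied).
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `U`, `p`,
#'   `significant`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups[keep])
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least two non-empty groups")
  out <- list()
  for (i in 1:(length(gl) - 1)) for (j in (i + 1):length(gl)) {
    x <- values[groups == gl[i]]
    y <- values[groups == gl[j]]
    if (length(x) < 2 || length(y) < 2) {
      message(sprintf("skipping %s vs %s: fewer than 2 observations",
                      gl[i], gl[j]))
      next
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    out[[length(out) + 1L]] <- data.frame(
      group1 = gl[i], group2 = gl[j], n1 = length(x), n2 = length(y),
      U = unname(ht$statistic), p = ht$p.value,
      significant = ht$p.value < alpha)
  }
  do.call(rbind, out)
}

#' Mixed-effects model of absolute BBI difference over sessions
#'
#' Fits `absdiff ~ group + time + group:time` with a random intercept per
#' pairing (restricted likelihood), reference level being the control (CT)
#' group. If the fit is singular a warning is raised and a plain
#' fixed-effects regression is returned instead.
#'
#' @param tab data.frame with columns `pairing`, `group`, `session`
#'   (numeric index) and `mad_ms` (e.g. a [similarity_table()]).
#' @param reference reference group level.
#' @param time_as_factor treat session as categorical instead of numeric.
#' @return List with `coefficients` (matrix: estimate, SE, df, t, p),
#'   `model` (the fitted object) and `singular` (logical).
#' @export
fit_group_time_model <- function(tab, reference = "CT",
                                 time_as_factor = FALSE) {
  tab <- tab[!is.na(tab$mad_ms), , drop = FALSE]
  tab$group <- stats::relevel(factor(tab$group), ref = reference)
  tab$time <- if (time_as_factor) factor(tab$session) else
    as.numeric(tab$session)
  fit <- lmerTest::lmer(mad_ms ~ group * time + (1 | pairing), data = tab,
                        REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-intercept fit is singular; falling back to fixed-effects regression")
    lmfit <- stats::lm(mad_ms ~ group * time, data = tab)
    sm <- summary(lmfit)$coefficients
    co <- cbind(Estimate = sm[, 1], `Std. Error` = sm[, 2],
                df = stats::df.residual(lmfit), `t value` = sm[, 3],
                `Pr(>|t|)` = sm[, 4])
    return(list(coefficients = co, model = lmfit, singular = TRUE))
  }
  co <- summary(fit)$coefficients
  list(coefficients = co, model = fit, singular = FALSE)
}

#' Per-session group mean similarity trend
#'
#' Unweighted mean of pair-level values per group per session (the
#' session-by-session synchrony curves).
#'
#' @param tab a [similarity_table()].
#' @param metric column to average (`"mean_r"` or `"mad_ms"`).
#' @return data.frame: `group`, `session`, `mean`, `n`.
#' @export
session_trend <- function(tab, metric = "mean_r") {
  tab <- tab[!is.na(tab[[metric]]), , drop = FALSE]
  agg <- stats::aggregate(tab[[metric]],
                          by = list(group = tab$group, session = tab$session),
                          FUN = mean)
  cnt <- stats::aggregate(tab[[metric]],
                          by = list(group = tab$group, session = tab$session),
                          FUN = length)
  data.frame(group = agg$group, session = agg$session, mean = agg$x,
             n = cnt$x)
}
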