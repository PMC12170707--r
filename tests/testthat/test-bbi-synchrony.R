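test_that("windowed Pearson follows the window grammar and the oracle", {
  set.seed(8)
  a <- mk_series(1000 + cumsum(rnorm(600)))
  expect_equal(windowed_pearson(a, a)$mean_r, 1)
  expect_true(all(abs(windowed_pearson(a, a)$window_r - 1) < 1e-12))

  b660 <- mk_series(1000 + cumsum(rnorm(660)))
  c660 <- mk_series(1000 + cumsum(rnorm(660)))
  expect_equal(length(windowed_pearson(b660, c660)$window_r), 7)

  va <- 1000 + cumsum(rnorm(600)); vb <- 1000 + cumsum(rnorm(600))
  wp <- windowed_pearson(mk_series(va), mk_series(vb))
  expect_equal(wp$mean_r, oracle_windowed_pearson(va, vb, 300, 60),
               tolerance = 1e-12)

  short <- mk_series(rep(1000, 100))
  res <- windowed_pearson(short, short)
  expect_equal(res$flag, "no_windows")
  expect_true(is.na(res$mean_r))

  # zero-variance windows are skipped
  flat <- mk_series(rep(1000, 600))
  expect_equal(windowed_pearson(flat, a)$n_windows, 0)

  # shift invariance of r; alignment by absolute time
  shifted <- mk_series(va + 250)
  expect_equal(windowed_pearson(mk_series(va), shifted)$mean_r, 1)
})

test_that("mean absolute difference is exact on analytic fixtures", {
  set.seed(9)
  v <- 1000 + rnorm(600, 0, 30)
  a <- mk_series(v)
  expect_equal(mean_abs_diff(a, a)$mad_ms, 0)
  expect_equal(mean_abs_diff(a, mk_series(v + 500))$mad_ms, 500)
  expect_equal(mean_abs_diff(a, mk_series(v + 500))$mad_ms,
               mean_abs_diff(mk_series(v + 500), a)$mad_ms)

  # DZ-style baselines 1250 vs 750 with small fluctuations
  g <- generate_coupled_bbi(bbi_coupling_params(baseline_a = 1250,
                                                baseline_b = 750),
                            600, seed = 12)
  sa <- smooth_moving(interpolate_1hz(g$a))
  sb <- smooth_moving(interpolate_1hz(g$b))
  expect_lt(abs(mean_abs_diff(sa, sb)$mad_ms - 500) / 500, 0.1)

  # disjoint spans give an empty overlap, not an error
  far <- mk_series(rep(900, 50), start = 1000)
  expect_true(is.na(mean_abs_diff(a, far)$mad_ms))
})

test_that("pairing enumeration matches brute-force dyad counts", {
  r <- generate_roster()
  sch <- build_pairings(r)
  tab <- table(sch$pairings$group)
  expect_equal(unname(tab["T"]), 3)
  expect_equal(unname(tab["DT"]), 1)
  expect_equal(unname(tab["N"]), 24)  # C(8,2) - 4 co-twin pairs
  expect_equal(unname(tab["CT"]), 28) # 14 control assignments x 2 twins

  # the double-duty control appears in two pairs' CT pairings
  multi <- r$roster$participant[grepl(",", r$roster$control_for)]
  ct <- sch$pairings[sch$pairings$group == "CT", ]
  hit <- ct[ct$member2 == multi, ]
  hit_pairs <- unique(substr(hit$member1, 1, 1))
  expect_equal(length(hit_pairs), 2)

  # single twin pair: no N pairings
  r1 <- generate_roster(cohort_config(n_mz_pairs = 1, n_dz_pairs = 0,
                                      n_controls = 0, n_sessions = 2))
  s1 <- build_pairings(r1)
  expect_false("N" %in% s1$pairings$group)

  # separated sessions are excluded for co-twin pairings
  sep <- r$config$separation_sessions
  p1 <- paste0(sep$pair[1], "1-", sep$pair[1], "2")
  expect_false(sch$inclusion[p1, as.character(sep$session[1])])

  # orphan control draws a warning
  r2 <- generate_roster(cohort_config(n_mz_pairs = 1, n_dz_pairs = 0,
                                      n_controls = 1, n_sessions = 1))
  r2$roster$control_for[r2$roster$type == "control"] <- ""
  expect_warning(build_pairings(r2), "referenced by no twin")
})

test_that("group comparison uses rank-sum conventions", {
  expect_gt(compare_groups(rep(c(1, 2, 3), 2),
                           rep(c("a", "b"), each = 3))$p, 0.99)
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$U, 0)
  expect_message(
    compare_groups(c(1, 2, 3, 9), c("a", "a", "a", "b")), "fewer than 2")
  expect_error(compare_groups(1:3, rep("a", 3)), "two non-empty")
})

test_that("the mixed model recovers injected effects and falls back when singular", {
  simulate_tab <- function(seed, dt_offset = 0, dt_slope = 0, re_sd = 30) {
    set.seed(seed)
    do.call(rbind, lapply(1:24, function(pr) {
      g <- c("CT", "T", "DT", "N")[pr %% 4 + 1]
      off <- if (g == "DT") dt_offset else 0
      sl <- if (g == "DT") dt_slope else 0
      data.frame(pairing = paste0("p", pr), group = g, session = 1:17,
                 mad_ms = 200 + rnorm(1, 0, re_sd) + off + sl * (1:17) +
                   rnorm(17, 0, 20))
    }))
  }
  # reference level is CT and terms are named by group
  m <- fit_group_time_model(simulate_tab(1, dt_offset = 100, dt_slope = -9))
  co <- m$coefficients
  expect_true(all(c("groupDT", "time", "groupDT:time") %in% rownames(co)))
  expect_false(m$singular)
  expect_lt(abs(co["groupDT", "Estimate"] - 100), 3 * co["groupDT", "Std. Error"])
  expect_lt(abs(co["groupDT:time", "Estimate"] + 9),
            3 * co["groupDT:time", "Std. Error"])

  # no random-effect variance: singular fit falls back with a warning
  tab0 <- simulate_tab(1, re_sd = 0)
  expect_warning(m0 <- fit_group_time_model(tab0), "singular")
  expect_true(m0$singular)
  expect_true("groupDT:time" %in% rownames(m0$coefficients))
})

test_that("session trends average pair values per group and session", {
  tab <- data.frame(pairing = rep(c("p1", "p2"), each = 3),
                    group = "T", session = rep(1:3, 2),
                    mean_r = c(0.1, 0.2, 0.3, -0.1, -0.2, -0.3),
                    mad_ms = 1)
  tr <- session_trend(tab)
  expect_equal(tr$mean, c(0, 0, 0))
  one <- session_trend(tab[tab$pairing == "p1", ])
  expect_equal(one$mean, c(0.1, 0.2, 0.3))

  # a linearly ramped coupling produces a positive fitted trend
  slopes <- sapply(1:8, function(s) {
    vals <- sapply(1:6, function(sess) {
      rho <- 0.12 * (sess - 1)
      g <- generate_coupled_bbi(bbi_params_from_rho(rho), 600,
                                seed = child_seed(700 + s, sess))
      sa <- smooth_moving(interpolate_1hz(g$a))
      sb <- smooth_moving(interpolate_1hz(g$b))
      windowed_pearson(sa, sb)$mean_r
    })
    coef(lm(vals ~ I(1:6)))[2]
  })
  expect_gt(mean(slopes), 0)
  expect_lt(t.test(slopes, alternative = "greater")$p.value, 0.05)
})

test_that("similarity statistics are symmetric under member swap", {
  g <- generate_coupled_bbi(bbi_params_from_rho(0.5), 600, seed = 77)
  sa <- smooth_moving(interpolate_1hz(g$a))
  sb <- smooth_moving(interpolate_1hz(g$b))
  expect_equal(windowed_pearson(sa, sb)$mean_r,
               windowed_pearson(sb, sa)$mean_r, tolerance = 1e-12)
  expect_equal(mean_abs_diff(sa, sb)$mad_ms, mean_abs_diff(sb, sa)$mad_ms)
})
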