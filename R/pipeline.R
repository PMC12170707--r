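# End-to-end pipeline orchestration: simulate -> preprocess -> synchrony ->
# EEG band power -> sham mask -> demographics, with manifest-based reruns.

#' Default pipeline run configuration
#'
#' A demonstration-scale configuration: the cohort composition matches the
#' study design (3 MZ pairs, 1 DZ pair, 13 controls), while session count,
#' session duration and EEG size are scaled so a full run completes in
#' minutes on one CPU. Any element can be overridden.
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @param out_dir output directory.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("twinsync_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, bbi_prep = TRUE, bbi_sync = TRUE,
                  eeg = TRUE, sham = TRUE, demographics = TRUE),
    cohort = list(n_mz_pairs = 3, n_dz_pairs = 1, n_controls = 13,
                  n_sessions = 6, session_duration = 900),
    bbi = list(rho_T = 0.6, rho_DT = 0.4, total_sd = 50,
               artifact_rate = 1, quantile_window = 91, c_scale = 5.2,
               smooth_window = 10),
    sync = list(window = 300, hop = 60),
    eeg = list(n_channels = 8, sampling_rate = 128, duration = 330,
               rho = c(0.8, 0.6, 0.8, 0.3, 0.2, 0.1),
               epoch_length = 1.5, epoch_step = 0.25, z_threshold = 3,
               smooth_window = 120, n_points = 20),
    sham = list(n_boot = 1000, draw = 3, alpha = 0.05)
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config` returns the configuration; `write_run_config`
#'   returns `path` invisibly. Configurations round-trip losslessly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stage_done <- function(manifest, name, hash, out_dir) {
  st <- manifest$stages[[name]]
  !is.null(st) && identical(st$hash, hash) &&
    all(file.exists(file.path(out_dir, names(st$files)))) &&
    identical(unname(unlist(st$files)),
              unname(tools::md5sum(file.path(out_dir, names(st$files)))))
}

record_stage <- function(manifest, name, hash, files, out_dir) {
  manifest$stages[[name]] <- list(
    hash = hash,
    files = as.list(stats::setNames(unname(tools::md5sum(file.path(out_dir, files))),
                                    files)))
  manifest
}

#' Run the full synchrony pipeline
#'
#' Executes the enabled stages in dependency order, writing all artifacts
#' under `config$out_dir` and a `manifest.json` with per-stage parameter
#' hashes and output checksums. Re-running with an unchanged configuration
#' skips stages whose parameter hash and outputs are intact, so toggling one
#' stage never perturbs another stage's artifacts; all randomness derives
#' from the root seed.
#'
#' @param config a [default_run_config()]-style configuration.
#' @return The manifest (invisibly), listing inputs, outputs and hashes.
#' @export
run_pipeline <- function(config = default_run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = FALSE)
  } else list(stages = list())
  manifest$seed <- config$seed

  save_tsv <- function(df, file) {
    utils::write.table(df, file.path(out, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  ## ---- simulate ----
  sim_hash <- hash_obj(list(config$cohort, config$bbi, config$eeg,
                            config$seed))
  if (isTRUE(config$stages$simulate) &&
      !stage_done(manifest, "simulate", sim_hash, out)) {
    cc <- cohort_config(n_mz_pairs = config$cohort$n_mz_pairs,
                        n_dz_pairs = config$cohort$n_dz_pairs,
                        n_controls = config$cohort$n_controls,
                        n_sessions = config$cohort$n_sessions,
                        session_duration = config$cohort$session_duration,
                        rng_seed = config$seed)
    roster <- generate_roster(cc)
    utils::write.csv(roster$roster, file.path(out, "roster.csv"),
                     row.names = FALSE)
    utils::write.csv(roster$schedule, file.path(out, "schedule.csv"),
                     row.names = FALSE)

    dur <- config$cohort$session_duration
    tachs <- list()
    ros <- roster$roster
    pairs <- unique(ros$pair_id[!is.na(ros$pair_id)])
    for (s in seq_len(config$cohort$n_sessions)) {
      for (p in pairs) {
        type <- ros$type[match(p, ros$pair_id)]
        rho <- if (type == "MZ") config$bbi$rho_T else config$bbi$rho_DT
        prm <- bbi_params_from_rho(rho, config$bbi$total_sd,
                                   artifact_rate = config$bbi$artifact_rate)
        g <- generate_coupled_bbi(prm, dur,
                                  seed = child_seed(config$seed, "bbi", p, s),
                                  ids = paste0(p, 1:2), session = s)
        tachs <- c(tachs, list(g$a, g$b))
      }
      for (id in ros$participant[ros$type == "control"]) {
        prm <- bbi_coupling_params(shared_amplitude = 0,
                                   individual_amplitude = config$bbi$total_sd,
                                   artifact_rate = config$bbi$artifact_rate)
        g <- generate_coupled_bbi(prm, dur,
                                  seed = child_seed(config$seed, "bbi", id, s),
                                  ids = c(id, "unused"), session = s)
        tachs <- c(tachs, list(g$a))
      }
    }
    write_bbi_csv(tachs, file.path(out, "tachograms.csv"))
    manifest <- record_stage(manifest, "simulate", sim_hash,
                             c("roster.csv", "schedule.csv", "tachograms.csv"),
                             out)
  }

  ## ---- bbi_prep ----
  prep_hash <- hash_obj(list(sim_hash, config$bbi))
  if (isTRUE(config$stages$bbi_prep) &&
      !stage_done(manifest, "bbi_prep", prep_hash, out)) {
    if (!file.exists(file.path(out, "tachograms.csv"))) {
      stop("missing upstream artifact tachograms.csv: run the simulate stage first")
    }
    tachs <- read_bbi_csv(file.path(out, "tachograms.csv"))
    rows <- list()
    reports <- list()
    for (key in names(tachs)) {
      pp <- preprocess_bbi(tachs[[key]],
                           smooth_window = config$bbi$smooth_window,
                           quantile_window = config$bbi$quantile_window,
                           c_scale = config$bbi$c_scale)
      sr <- pp$series
      rows[[key]] <- data.frame(participant = sr$participant,
                                session = sr$session, t_s = bbi_times(sr),
                                bbi_ms = sr$values)
      if (nrow(pp$report)) {
        reports[[key]] <- cbind(participant = sr$participant,
                                session = sr$session, pp$report)
      }
    }
    utils::write.csv(do.call(rbind, rows), file.path(out, "uniform_bbi.csv"),
                     row.names = FALSE)
    rep_df <- if (length(reports)) do.call(rbind, reports) else
      data.frame(participant = character(0), session = character(0),
                 index = integer(0), time = numeric(0), old_ms = numeric(0),
                 new_ms = numeric(0), rule = character(0))
    save_tsv(rep_df, "correction_report.tsv")
    manifest <- record_stage(manifest, "bbi_prep", prep_hash,
                             c("uniform_bbi.csv", "correction_report.tsv"),
                             out)
  }

  ## ---- bbi_sync ----
  sync_hash <- hash_obj(list(prep_hash, config$sync))
  if (isTRUE(config$stages$bbi_sync) &&
      !stage_done(manifest, "bbi_sync", sync_hash, out)) {
    for (f in c("uniform_bbi.csv", "roster.csv", "schedule.csv")) {
      if (!file.exists(file.path(out, f))) {
        stop("missing upstream artifact ", f, ": run earlier stages first")
      }
    }
    udf <- utils::read.csv(file.path(out, "uniform_bbi.csv"),
                           stringsAsFactors = FALSE)
    series <- list()
    for (key in unique(paste(udf$participant, udf$session, sep = "/"))) {
      sub <- udf[paste(udf$participant, udf$session, sep = "/") == key, ]
      series[[key]] <- uniform_bbi(sub$participant[1], sub$session[1],
                                   sub$t_s[1], sub$bbi_ms,
                                   smoothing = config$bbi$smooth_window)
    }
    roster <- list(
      roster = utils::read.csv(file.path(out, "roster.csv"),
                               stringsAsFactors = FALSE),
      schedule = utils::read.csv(file.path(out, "schedule.csv"),
                                 stringsAsFactors = FALSE))
    roster$roster$control_for[is.na(roster$roster$control_for)] <- ""
    scheme <- build_pairings(roster)
    tab <- similarity_table(scheme, series, window = config$sync$window,
                            hop = config$sync$hop)
    save_tsv(tab, "similarity.tsv")
    stats_out <- list(
      pearson = compare_groups(tab$mean_r, tab$group),
      absdiff = compare_groups(tab$mad_ms, tab$group))
    mm <- tryCatch(fit_group_time_model(tab),
                   warning = function(w) suppressWarnings(fit_group_time_model(tab)))
    stats_out$mixed_model <- as.data.frame(mm$coefficients)
    stats_out$mixed_model$term <- rownames(mm$coefficients)
    stats_out$singular_fit <- mm$singular
    jsonlite::write_json(stats_out, file.path(out, "group_stats.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    save_tsv(session_trend(tab), "trend.tsv")
    manifest <- record_stage(manifest, "bbi_sync", sync_hash,
                             c("similarity.tsv", "group_stats.json",
                               "trend.tsv"), out)
  }

  ## ---- eeg (power + correlation maps) ----
  eeg_hash <- hash_obj(list(config$eeg, config$seed))
  if (isTRUE(config$stages$eeg) &&
      !stage_done(manifest, "eeg", eeg_hash, out)) {
    ec <- config$eeg
    prm <- eeg_coupling_params(n_channels = ec$n_channels,
                               sampling_rate = ec$sampling_rate,
                               band_envelope_rho = ec$rho)
    n_mz <- config$cohort$n_mz_pairs
    tcs <- list()
    maps <- list()
    for (p in LETTERS[seq_len(n_mz)]) {
      g <- generate_coupled_eeg(prm, ec$duration,
                                seed = child_seed(config$seed, "eeg", p),
                                ids = paste0(p, 1:2))
      pl <- eeg_pair_pipeline(g$a, g$b, epoch_length = ec$epoch_length,
                              epoch_step = ec$epoch_step,
                              z_threshold = ec$z_threshold,
                              smooth_window = ec$smooth_window,
                              n_points = ec$n_points)
      tcs[[paste0(p, "1")]] <- pl$tc_a
      tcs[[paste0(p, "2")]] <- pl$tc_b
      maps[[paste(p, "twin", sep = "_")]] <- pl$map
    }
    tc_rows <- do.call(rbind, lapply(names(tcs), function(id) {
      tc <- tcs[[id]]
      do.call(rbind, lapply(seq_along(tc$channels), function(ch) {
        do.call(rbind, lapply(seq_along(tc$bands), function(bd) {
          data.frame(subject = id, channel = tc$channels[ch],
                     band = names(tc$bands)[bd],
                     point = seq_along(tc$times), time_s = tc$times,
                     power = tc$values[ch, bd, ])
        }))
      }))
    }))
    save_tsv(tc_rows, "band_power_timecourses.tsv")
    map_rows <- do.call(rbind, lapply(maps, function(m) {
      data.frame(pair = m$pair_id,
                 channel = rep(rownames(m$R), ncol(m$R)),
                 band = rep(colnames(m$R), each = nrow(m$R)),
                 r = as.vector(m$R))
    }))
    save_tsv(map_rows, "twin_maps.tsv")
    saveRDS(list(tcs = tcs, maps = maps),
            file.path(out, "eeg_state.rds"), version = 2)
    manifest <- record_stage(manifest, "eeg", eeg_hash,
                             c("band_power_timecourses.tsv", "twin_maps.tsv",
                               "eeg_state.rds"), out)
  }

  ## ---- sham mask ----
  sham_hash <- hash_obj(list(eeg_hash, config$sham))
  if (isTRUE(config$stages$sham) &&
      !stage_done(manifest, "sham", sham_hash, out)) {
    if (!file.exists(file.path(out, "eeg_state.rds"))) {
      stop("missing upstream artifact eeg_state.rds: run the eeg stage first")
    }
    st <- readRDS(file.path(out, "eeg_state.rds"))
    n_mz <- config$cohort$n_mz_pairs
    pairs_df <- data.frame(pair_id = LETTERS[seq_len(n_mz)],
                           member1 = paste0(LETTERS[seq_len(n_mz)], "1"),
                           member2 = paste0(LETTERS[seq_len(n_mz)], "2"))
    shams <- enumerate_sham_pairs(pairs_df)
    sham_maps <- lapply(seq_len(nrow(shams)), function(i) {
      pair_correlation(st$tcs[[shams$member1[i]]],
                       st$tcs[[shams$member2[i]]])
    })
    mean_map <- twin_mean_map(st$maps)
    bm <- bootstrap_mask(mean_map, sham_maps, m = config$sham$draw,
                         n_boot = config$sham$n_boot,
                         alpha = config$sham$alpha,
                         seed = child_seed(config$seed, "sham"))
    long <- function(M) data.frame(channel = rep(rownames(M), ncol(M)),
                                   band = rep(colnames(M), each = nrow(M)),
                                   value = as.vector(M))
    save_tsv(cbind(long(bm$map$R),
                   mask = as.vector(bm$map$mask),
                   premask = as.vector(bm$map$premask)), "masked_map.tsv")
    save_tsv(cbind(long(bm$lo), hi = as.vector(bm$hi)), "mask_limits.tsv")
    manifest <- record_stage(manifest, "sham", sham_hash,
                             c("masked_map.tsv", "mask_limits.tsv"), out)
  }

  ## ---- demographics ----
  demo_hash <- hash_obj(list(sim_hash, "demographics"))
  if (isTRUE(config$stages$demographics) &&
      !stage_done(manifest, "demographics", demo_hash, out)) {
    if (!file.exists(file.path(out, "roster.csv"))) {
      stop("missing upstream artifact roster.csv: run the simulate stage first")
    }
    ros <- utils::read.csv(file.path(out, "roster.csv"),
                           stringsAsFactors = FALSE)
    twin_ages <- ros$age[ros$type %in% c("MZ", "DZ")]
    mz_ages <- ros$age[ros$type == "MZ"]
    demo <- list(
      twin = describe_ages(twin_ages, "sample"),
      mz = describe_ages(mz_ages, "population"),
      mz_ks = ks_normality(mz_ages))
    jsonlite::write_json(demo, file.path(out, "demographics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- record_stage(manifest, "demographics", demo_hash,
                             "demographics.json", out)
  }

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
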