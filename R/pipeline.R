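# Readers/writers for the long-format motion-table dialect, and the staged
# pipeline binding simulation, CRP, DI, determinant and synergy analyses.

TRIAL_CHANNELS <- c("hip_deg", "knee_deg", "thigh_gyro_dps",
                    "thigh_acc_x", "thigh_acc_y", "thigh_acc_z")

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_exact <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_meta <- function(path, config_hash, seed, units, n_rows) {
  meta <- c(sprintf("config_hash\t%s", config_hash),
            sprintf("seed\t%s", seed),
            sprintf("rows\t%d", n_rows),
            vapply(names(units), function(nm)
              sprintf("unit\t%s\t%s", nm, units[[nm]]), character(1L)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Write a trial in the long-format motion-table dialect
#'
#' Writes `<prefix>_data.tsv` (columns `time_s`, `side`, `channel`, `value`;
#' channels `hip_deg`, `knee_deg`, `thigh_gyro_dps`, `thigh_acc_{x,y,z}`),
#' `<prefix>_events.tsv` (`side`, `event` HS/TO, `sample_index`) and, when
#' the yaml package is available, `<prefix>_profile.yaml`. Numeric values are
#' written with 17 significant digits so re-importing reproduces the series
#' exactly.
#'
#' @param trial a [generate_trial()] object.
#' @param prefix file path prefix.
#' @return invisibly, the written file paths.
#' @export
write_trial <- function(trial, prefix) {
  stopifnot(inherits(trial, "gait_trial"))
  rows <- list()
  for (side in names(trial$sides)) {
    s <- trial$sides[[side]]
    series <- list(hip_deg = s$hip, knee_deg = s$knee,
                   thigh_gyro_dps = s$thigh_gyro,
                   thigh_acc_x = s$thigh_acc[, "x"],
                   thigh_acc_y = s$thigh_acc[, "y"],
                   thigh_acc_z = s$thigh_acc[, "z"])
    for (ch in names(series)) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = trial$time, side = side, channel = ch,
        value = series[[ch]], stringsAsFactors = FALSE)
    }
  }
  data_path <- paste0(prefix, "_data.tsv")
  write_tsv_exact(do.call(rbind, rows), data_path)
  ev <- list()
  for (side in names(trial$sides)) {
    s <- trial$sides[[side]]
    ev[[length(ev) + 1L]] <- data.frame(
      side = side,
      event = c(rep("HS", length(s$hs)), rep("TO", length(s$to))),
      sample_index = c(s$hs, s$to), stringsAsFactors = FALSE)
  }
  events_path <- paste0(prefix, "_events.tsv")
  write_tsv_exact(do.call(rbind, ev), events_path)
  paths <- c(data_path, events_path)
  if (requireNamespace("yaml", quietly = TRUE)) {
    prof <- trial$profile
    prof_list <- list(
      group_label = prof$group_label, side_roles = as.list(prof$side_roles),
      speed = prof$speed, stride_duration = prof$stride_duration,
      swing_percentage = as.list(prof$swing_percentage),
      rom_hip = as.list(prof$rom_hip), rom_knee = as.list(prof$rom_knee),
      harmonic_count = prof$harmonic_count,
      pause_spec = if (nrow(prof$pause_spec))
        lapply(seq_len(nrow(prof$pause_spec)),
               function(i) as.list(prof$pause_spec[i, ])) else list(),
      phase_offset_between_limbs = prof$phase_offset_between_limbs,
      noise_sd = prof$noise_sd, sampling_rate = prof$sampling_rate,
      seed = trial$seed)
    prof_path <- paste0(prefix, "_profile.yaml")
    yaml::write_yaml(prof_list, prof_path)
    paths <- c(paths, prof_path)
  }
  invisible(paths)
}

#' Import a motion table in the long-format dialect
#'
#' Validates the dialect (columns `time_s`, `side`, `channel`, `value`),
#' checks that required channels are present, infers the sampling rate from
#' the time column, optionally attaches events, and converts radians to
#' degrees (factor 180/pi, reported via a message) when `angle_unit =
#' "rad"`.
#'
#' @param path data table path (tab-delimited).
#' @param events_path optional events table path (`side`, `event`,
#'   `sample_index`).
#' @param angle_unit `"deg"` (native) or `"rad"`.
#' @param require_channels channels that must be present (default hip and
#'   knee angles).
#' @return a `gait_trial`-compatible list (class `gait_trial`) with the
#'   per-side series and events; `profile` is `NULL` for imported data.
#' @export
import_motion_table <- function(path, events_path = NULL,
                                angle_unit = c("deg", "rad"),
                                require_channels = c("hip_deg", "knee_deg")) {
  angle_unit <- match.arg(angle_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_s", "side", "channel", "value")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$channel), TRIAL_CHANNELS)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sides <- list()
  for (side in sort(unique(tab$side))) {
    sub <- tab[tab$side == side, ]
    got <- unique(sub$channel)
    missing_ch <- setdiff(require_channels, got)
    if (length(missing_ch))
      stop("side ", side, " is missing channel(s): ",
           paste(missing_ch, collapse = ", "), call. = FALSE)
    s <- list()
    for (ch in got) {
      v <- sub$value[sub$channel == ch]
      if (ch %in% c("hip_deg", "knee_deg") && angle_unit == "rad") {
        v <- v * 180 / pi
        message("converted ", ch, " from radians to degrees (side ", side, ")")
      }
      s[[ch]] <- v
    }
    acc <- cbind(x = s$thigh_acc_x %||% numeric(0),
                 y = s$thigh_acc_y %||% numeric(0),
                 z = s$thigh_acc_z %||% numeric(0))
    sides[[side]] <- list(hip = s$hip_deg, knee = s$knee_deg,
                          thigh_gyro = s$thigh_gyro_dps,
                          thigh_acc = if (nrow(acc)) acc else NULL,
                          hs = integer(0), to = integer(0))
  }
  tvals <- sort(unique(tab$time_s))
  fs <- 1 / stats::median(diff(tvals))
  n <- length(tvals)
  if (!is.null(events_path)) {
    ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
    for (side in names(sides)) {
      se <- ev[ev$side == side, ]
      sides[[side]]$hs <- sort(se$sample_index[se$event == "HS"])
      sides[[side]]$to <- sort(se$sample_index[se$event == "TO"])
    }
  }
  spc <- if (length(sides[[1L]]$hs) > 1L)
    as.integer(round(stats::median(diff(sides[[1L]]$hs)))) else NA_integer_
  structure(list(sampling_rate = fs, samples_per_cycle = spc,
                 n_cycles = if (is.na(spc)) NA_integer_ else
                   (length(sides[[1L]]$hs) - 1L),
                 n_samples = n, time = tvals, sides = sides,
                 profile = NULL, pause_truth = NULL, seed = NA_integer_),
            class = "gait_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' @param out_dir output directory for tables and metadata sidecars.
#' @param seed master seed for every source of randomness.
#' @param groups named integer vector: subjects per group, e.g.
#'   `c(healthy = 8, stroke = 6, amputee = 6)`.
#' @param n_cycles gait cycles per simulated trial.
#' @param stages stages to run, in dependency order, a subset of
#'   `c("simulate", "crp", "di", "determinants", "synergy")`.
#' @param crp_K smoothing harmonics for CRP preprocessing.
#' @param di_threshold pause threshold, deg/s.
#' @param synergy_task task for the synergy stage.
#' @param synergy_models models to evaluate (`"pca"`, `"lstm"`).
#' @param lstm an [lstm_config()] for the LSTM sessions.
#' @param alpha_enter,alpha_remove stepwise significance levels.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            groups = c(healthy = 8L, stroke = 6L, amputee = 6L),
                            n_cycles = 8L,
                            stages = c("simulate", "crp", "di",
                                       "determinants", "synergy"),
                            crp_K = 6L, di_threshold = 5,
                            synergy_task = "interlimb_hip",
                            synergy_models = c("pca", "lstm"),
                            lstm = lstm_config(),
                            alpha_enter = 0.1, alpha_remove = 0.1) {
  known <- c("simulate", "crp", "di", "determinants", "synergy")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single integer", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), groups = groups,
                 n_cycles = as.integer(n_cycles), stages = stages,
                 crp_K = crp_K, di_threshold = di_threshold,
                 synergy_task = synergy_task, synergy_models = synergy_models,
                 lstm = lstm, alpha_enter = alpha_enter,
                 alpha_remove = alpha_remove),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML document
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files", call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$groups)) raw$groups <- unlist(raw$groups)
  if (!is.null(raw$lstm)) raw$lstm <- do.call(lstm_config, raw$lstm)
  do.call(pipeline_config, raw)
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' cohorts: simulation, CRP quantification against the healthy reference,
#' decomposition indices, determinant (stepwise) analysis per patient group,
#' and leave-one-subject-out synergy-model evaluation. Every output table is
#' written to `out_dir` as tab-delimited text with a `.meta` sidecar carrying
#' the configuration hash, seed and column units; per-stage row counts are
#' logged via `message()`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a manifest: list of written files with row counts, plus
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  hash <- fnv1a_hash(paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n"))
  manifest <- list()
  results <- list()
  emit <- function(df, name, units) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv_exact(df, path)
    write_meta(path, hash, config$seed, units, nrow(df))
    manifest[[name]] <<- list(path = path, rows = nrow(df))
    message(sprintf("[%s] %d rows -> %s", name, nrow(df), path))
  }

  # simulate (always needed by later stages)
  cohorts <- list()
  for (g in names(config$groups)) {
    cohorts[[g]] <- make_cohort(g, config$groups[[g]],
                                n_cycles = config$n_cycles,
                                seed = child_seed(config$seed,
                                                  match(g, names(config$groups))))
  }
  results$cohorts <- cohorts
  if ("simulate" %in% config$stages) {
    for (g in names(cohorts)) {
      for (subj in names(cohorts[[g]])) {
        write_trial(cohorts[[g]][[subj]],
                    file.path(config$out_dir, paste0(g, "_", subj)))
      }
      message(sprintf("[simulate] wrote %d %s trials", length(cohorts[[g]]), g))
    }
  }

  reference <- NULL
  if (any(c("crp", "determinants") %in% config$stages)) {
    if (is.null(cohorts$healthy))
      stop("stage 'crp' needs a healthy group for the reference curves",
           call. = FALSE)
    reference <- reference_crp(cohorts$healthy, K = config$crp_K)
    results$reference <- reference
  }

  if ("crp" %in% config$stages) {
    tabs <- list()
    for (g in names(cohorts)) {
      tab <- cohort_crp_summary(cohorts[[g]], reference, K = config$crp_K)
      tab <- cbind(group = g, tab)
      tabs[[g]] <- tab
    }
    crp_tab <- do.call(rbind, tabs)
    results$crp <- crp_tab
    emit(crp_tab, "crp_summary",
         c(rmse_deg = "degrees", pcc = "dimensionless"))
  }

  if ("di" %in% config$stages) {
    tabs <- list()
    for (g in names(cohorts)) {
      tab <- cohort_di_summary(cohorts[[g]], threshold = config$di_threshold)
      tabs[[g]] <- cbind(group = g, tab)
    }
    di_tab <- do.call(rbind, tabs)
    results$di <- di_tab
    emit(di_tab, "di_summary",
         c(di_whole = "fraction", di_stance = "fraction",
           di_swing = "fraction", threshold_dps = "deg/s"))
  }

  if ("determinants" %in% config$stages) {
    preds <- c("di_stance", "di_swing", "swing_percentage",
               "rom_hip", "rom_knee", "speed")
    rows <- list()
    for (g in setdiff(names(cohorts), "healthy")) {
      for (win in c("whole", "stance", "swing")) {
        ft <- build_feature_table(cohorts[[g]], reference,
                                  pairing = "intralimb", window = win,
                                  K = config$crp_K)
        # speed is constant within a group up to jitter; keep candidates with
        # variation
        use <- preds[vapply(preds, function(p) stats::sd(ft[[p]]) > 1e-9,
                            logical(1L))]
        sw <- stepwise_select(ft, "crp_rmse", use,
                              alpha_enter = config$alpha_enter,
                              alpha_remove = config$alpha_remove)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, window = win,
          selected = paste(sw$selected, collapse = "+"),
          r_squared = sw$r_squared, stringsAsFactors = FALSE)
      }
    }
    det_tab <- do.call(rbind, rows)
    results$determinants <- det_tab
    emit(det_tab, "determinants",
         c(r_squared = "dimensionless"))
  }

  if ("synergy" %in% config$stages) {
    if (is.null(cohorts$healthy))
      stop("stage 'synergy' needs a healthy group", call. = FALSE)
    spec <- channel_spec(config$synergy_task)
    ds <- build_dataset(cohorts$healthy, spec, target_side = "L")
    rows <- list()
    for (mk in config$synergy_models) {
      rep_ <- loso_evaluate(ds, mk,
                            config = if (mk == "lstm") config$lstm else list(),
                            seed = child_seed(config$seed, 101L))
      results[[paste0("synergy_", mk)]] <- rep_
      rows[[mk]] <- cbind(model = mk, task = config$synergy_task,
                          rep_$sessions)
    }
    syn_tab <- do.call(rbind, rows)
    emit(syn_tab, "synergy_loso",
         c(rmse = "degrees", mae = "degrees", pearson = "dimensionless",
           r2 = "dimensionless"))
  }

  invisible(list(manifest = manifest, results = results,
                 config_hash = hash))
}
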