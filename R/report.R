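#' Mean indicator value per assistance system and model
#'
#' @param table Long metrics table with columns `system`, `model`,
#'   `indicator`, `value` (one row per participant, model and indicator).
#' @param indicator Indicator name to summarise.
#' @return A tibble `system`, `model`, `mean`, `n`; empty cells yield `NA`
#'   means.
#' @export
group_model_means <- function(table, indicator) {
  sub <- table[table$indicator == indicator, ]
  if (!nrow(sub)) stop("indicator not present: ", indicator)
  dplyr::summarise(
    dplyr::group_by(sub, .data$system, .data$model),
    mean = mean(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
}

#' Sample-size-weighted overall mean
#'
#' Aggregates per-group means into the "overall" row of a report table:
#' `sum(value * n) / sum(n)`.
#'
#' @param values Per-group means.
#' @param ns Per-group sample sizes.
#' @return The weighted mean (full precision; report tables round with
#'   [round_half_up()]).
#' @export
#' @examples
#' weighted_overall(c(28.02, 21.06, 23.27), c(22, 22, 21))  # 24.13
weighted_overall <- function(values, ns) {
  stopifnot(length(values) == length(ns), all(ns > 0))
  sum(values * ns) / sum(ns)
}

#' Performance summary per assistance system and model
#'
#' Mean assembly times and failure counts split by type (wrongly used parts
#' vs. wrong part orientation).
#'
#' @param performance Performance records (see [simulate_performance()]).
#' @param participants Tibble `participant_id`, `system`.
#' @return A tibble `system`, `model`, `n`, `mean_assembly_time_s`,
#'   `wrong_part`, `wrong_orientation`.
#' @export
summarize_performance <- function(performance, participants) {
  joined <- dplyr::left_join(performance, participants,
                             by = "participant_id")
  dplyr::summarise(
    dplyr::group_by(joined, .data$system, .data$model),
    n = dplyr::n(),
    mean_assembly_time_s = mean(.data$assembly_time_s),
    wrong_part = sum(.data$wrong_part),
    wrong_orientation = sum(.data$wrong_orientation),
    .groups = "drop"
  )
}

#' Compute all participant-level indicators for a cohort
#'
#' Runs the full indicator extraction per participant: RR cleaning, per-model
#' sliding heart rate, RMSSD and rrHRV, heart-rate over/underload
#' percentages, pupil preprocessing, mean pupil diameter and pupil
#' over/underload percentages, mean fixation duration and saccadic peak
#' velocity, AOI metrics, plus the performance indicators.
#'
#' @param cohort A [simulate_cohort()] result (or the same structure read
#'   back from CSV with [read_cohort()]).
#' @return A list with `metrics` (long tibble `participant_id`, `system`,
#'   `model`, `indicator`, `value`) and `aoi` (tibble of [aoi_metrics()]
#'   rows with `participant_id`, `system`, `model`).
#' @export
cohort_metrics <- function(cohort) {
  met <- list()
  aoi <- list()
  for (id in cohort$participants$participant_id) {
    sch <- cohort$schedules[[id]]
    system <- sch$system
    segs <- sch$segments
    add <- function(model, indicator, value) {
      met[[length(met) + 1]] <<- tibble::tibble(
        participant_id = id, system = system, model = model,
        indicator = indicator, value = value)
    }
    if (!is.null(cohort$rr[[id]])) {
      rr <- clean_rr(cohort$rr[[id]])
      hrt <- hr_state_table(rr, sch)
      for (s in seq_len(nrow(segs))) {
        m <- segs$model[s]
        sub <- rr[rr$t_beat_s >= segs$t_start_s[s] &
                    rr$t_beat_s <= segs$t_end_s[s], ]
        if (nrow(sub)) {
          sub$rr_ms[1] <- NA
          sub$artifact[1] <- NA
        }
        add(m, "hr", hrt$hr_bpm[hrt$model == m])
        add(m, "rmssd", suppressWarnings(rmssd(sub)))
        add(m, "rrhrv", suppressWarnings(rrhrv(sub)))
        add(m, "hr_under_pct", hrt$under_pct[hrt$model == m])
        add(m, "hr_over_pct", hrt$over_pct[hrt$model == m])
      }
    }
    if (!is.null(cohort$pupil[[id]])) {
      clean <- preprocess_pupil(cohort$pupil[[id]])
      prt <- pupil_state_table(clean, sch)
      for (m in segs$model) {
        add(m, "pr", prt$pr_mm[prt$model == m])
        add(m, "pr_under_pct", prt$under_pct[prt$model == m])
        add(m, "pr_over_pct", prt$over_pct[prt$model == m])
      }
    }
    if (!is.null(cohort$gaze[[id]])) {
      gz <- cohort$gaze[[id]]
      for (s in seq_len(nrow(segs))) {
        st <- segment_event_stats(gz, segs[s, ])
        add(segs$model[s], "fd", st$mean_fd_ms)
        add(segs$model[s], "spv", st$mean_spv_deg_s)
        am <- aoi_metrics(gz, segs[s, ])
        am$participant_id <- id
        am$system <- system
        am$model <- segs$model[s]
        aoi[[length(aoi) + 1]] <- am
      }
    }
    perf <- cohort$performance[cohort$performance$participant_id == id, ]
    for (k in seq_len(nrow(perf))) {
      add(perf$model[k], "assembly_time_s", perf$assembly_time_s[k])
      add(perf$model[k], "wrong_part", as.numeric(perf$wrong_part[k]))
      add(perf$model[k], "wrong_orientation",
          as.numeric(perf$wrong_orientation[k]))
      add(perf$model[k], "perceived_complexity",
          perf$perceived_complexity[k])
    }
  }
  list(metrics = dplyr::bind_rows(met),
       aoi = if (length(aoi)) dplyr::bind_rows(aoi) else tibble::tibble())
}

#' Read a cohort back from its CSV files
#'
#' Counterpart of [write_cohort()]. Fails fast, naming the file, when a
#' required column is missing.
#'
#' @param dir Directory holding `schedule.csv`, `participants.csv`,
#'   `performance.csv` and optionally `rr.csv`, `pupil.csv`,
#'   `gaze_events.csv`.
#' @return A list with the [simulate_cohort()] structure (no `config`).
#' @export
read_cohort <- function(dir) {
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s: missing column(s) %s", file,
                   paste(miss, collapse = ", ")))
    }
    df
  }
  rd <- function(f) readr::read_csv(file.path(dir, f),
                                    show_col_types = FALSE)
  sched <- need(rd("schedule.csv"),
                c("participant_id", "system", "model", "t_start_s",
                  "t_end_s"), "schedule.csv")
  parts <- need(rd("participants.csv"), c("participant_id", "system"),
                "participants.csv")
  perf <- need(rd("performance.csv"),
               c("participant_id", "model", "assembly_time_s",
                 "wrong_part", "wrong_orientation",
                 "perceived_complexity"), "performance.csv")
  ids <- parts$participant_id
  schedules <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    seg <- sched[sched$participant_id == id,
                 c("model", "t_start_s", "t_end_s")]
    structure(list(participant_id = id, participant_index = i,
                   system = parts$system[i],
                   gender = parts$gender[i] %||% NA_character_,
                   segments = tibble::as_tibble(seg), baseline = NULL),
              class = "mwl_schedule")
  })
  names(schedules) <- ids
  rr <- list(); pupil <- list(); gaze <- list()
  if (file.exists(file.path(dir, "rr.csv"))) {
    rrd <- need(rd("rr.csv"), c("participant_id", "t_beat_s"), "rr.csv")
    rr <- lapply(split(rrd, rrd$participant_id),
                 function(x) rr_series(x$t_beat_s))
  }
  if (file.exists(file.path(dir, "pupil.csv"))) {
    pd <- need(rd("pupil.csv"),
               c("participant_id", "t_s", "left_mm", "right_mm",
                 "left_valid", "right_valid"), "pupil.csv")
    pupil <- split(pd[-1], pd$participant_id)
  }
  if (file.exists(file.path(dir, "gaze_events.csv"))) {
    gd <- need(rd("gaze_events.csv"),
               c("participant_id", "kind", "t_start_s", "t_end_s",
                 "duration_ms", "aoi"), "gaze_events.csv")
    gaze <- split(gd[-1], gd$participant_id)
  }
  list(participants = parts, schedules = schedules, rr = rr,
       ecg = list(), pupil = pupil, gaze = gaze, performance = perf)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or loads one from CSV), extracts all indicators, fits
#' the mixed-design ANOVAs, builds the system-by-model report tables with
#' sample-size-weighted overall rows, and writes `metrics_long.csv`,
#' `aoi_metrics.csv`, `anova.csv`, `overall_tables.csv` and `report.json`
#' into `out_dir`. Identical config and seed produce byte-identical outputs.
#'
#' @param config A [sim_config()] (ignored when `data_dir` is given).
#' @param data_dir Optional directory of input CSVs (see [read_cohort()]).
#' @param out_dir Output directory.
#' @param signals Signals to simulate, passed to [simulate_cohort()].
#' @param write_inputs Also serialize the simulated cohort CSVs under
#'   `out_dir/data`.
#' @return Invisibly, a list with `metrics`, `aoi`, `anova`, `overall`.
#' @export
run_pipeline <- function(config = NULL, data_dir = NULL, out_dir,
                         signals = c("rr", "pupil", "gaze"),
                         write_inputs = FALSE) {
  if (is.null(config) && is.null(data_dir)) {
    stop("either config or data_dir is required")
  }
  cohort <- if (!is.null(data_dir)) read_cohort(data_dir)
            else simulate_cohort(config, signals = signals)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_inputs && is.null(data_dir)) {
    write_cohort(cohort, file.path(out_dir, "data"))
  }
  res <- cohort_metrics(cohort)
  readr::write_csv(res$metrics, file.path(out_dir, "metrics_long.csv"))
  if (nrow(res$aoi)) {
    readr::write_csv(res$aoi, file.path(out_dir, "aoi_metrics.csv"))
  }

  complexity_of <- c(M1 = "low", M2 = "low", M3 = "high", M4 = "high")
  anovas <- list()
  for (ind in intersect(unique(res$metrics$indicator),
                        c("hr", "rmssd", "rrhrv", "pr", "fd", "spv",
                          "hr_over_pct", "hr_under_pct",
                          "pr_over_pct", "pr_under_pct"))) {
    sub <- res$metrics[res$metrics$indicator == ind, ]
    if (anyNA(sub$value)) next
    a <- tryCatch(
      mixed_anova(sub, dv = "value", within = "model",
                  between = "system", id = "participant_id"),
      error = function(e) {
        warning(sprintf("ANOVA skipped for %s: %s", ind,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(a)) next
    a$indicator <- ind
    anovas[[length(anovas) + 1]] <- a
  }
  if ("perceived_complexity" %in% res$metrics$indicator &&
      all(table(cohort$participants$system) >= 2)) {
    sub <- res$metrics[res$metrics$indicator == "perceived_complexity", ]
    sub$complexity <- complexity_of[sub$model]
    blk <- dplyr::summarise(
      dplyr::group_by(sub, .data$participant_id, .data$system,
                      .data$complexity),
      value = mean(.data$value), .groups = "drop")
    a <- mixed_anova(blk, dv = "value", within = "complexity",
                     between = "system", id = "participant_id")
    a$indicator <- "perceived_complexity"
    anovas[[length(anovas) + 1]] <- a
  }
  anova_tab <- dplyr::bind_rows(anovas)
  readr::write_csv(anova_tab, file.path(out_dir, "anova.csv"))

  overall <- dplyr::bind_rows(lapply(unique(res$metrics$indicator),
                                     function(ind) {
    grid <- group_model_means(res$metrics, ind)
    ov <- dplyr::summarise(
      dplyr::group_by(grid, .data$model),
      mean = weighted_overall(.data$mean, .data$n),
      n = sum(.data$n), .groups = "drop")
    ov$system <- "overall"
    out <- dplyr::bind_rows(grid, ov)
    out$indicator <- ind
    out$mean <- round_half_up(out$mean, 2)
    out[, c("indicator", "system", "model", "mean", "n")]
  }))
  readr::write_csv(overall, file.path(out_dir, "overall_tables.csv"))

  report <- list(
    package = "mwlmetrics",
    version = as.character(utils::packageVersion("mwlmetrics")),
    seed = if (!is.null(config)) config$seed else NA,
    n_participants = nrow(cohort$participants),
    systems = sort(unique(cohort$participants$system)),
    files = c("metrics_long.csv",
              if (nrow(res$aoi)) "aoi_metrics.csv",
              "anova.csv", "overall_tables.csv")
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = res$metrics, aoi = res$aoi,
                 anova = anova_tab, overall = overall))
}
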