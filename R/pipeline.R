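#' Pipeline configuration
#'
#' Bundles every stage's settings plus a single global seed. The seed fans
#' out deterministically to per-stage and per-display child seeds, so any
#' stage can be rerun independently and a full rerun with the same config
#' reproduces every output bit for bit.
#'
#' @param out_dir Output directory for the run.
#' @param n_courts,displays_per_court Size of the simulated experiment.
#' @param duration,fps Per-display recording length (s) and frame rate.
#' @param use_video Render frames and track them (`TRUE`), or feed the
#'   generator's ground-truth series straight to the RQA stage (`FALSE`).
#' @param write_png Also write rendered frames as PNG directories (slow;
#'   off by default).
#' @param stages Named logical vector toggling `simulate`, `track`, `rqa`,
#'   `metrics`, `analyze`.
#' @param display Display-parameter overrides (list passed to
#'   [display_params()]).
#' @param tracker A [tracker_config()].
#' @param court Court-simulation overrides (list passed to
#'   [court_sim_params()]).
#' @param rqa_n_samples Microstate sampling budget per display.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_courts = 2, displays_per_court = 4,
                            duration = 10, fps = 30, use_video = TRUE,
                            write_png = FALSE,
                            stages = c(simulate = TRUE, track = TRUE,
                                       rqa = TRUE, metrics = TRUE,
                                       analyze = TRUE),
                            display = list(), tracker = tracker_config(),
                            court = list(), rqa_n_samples = 10000L,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, n_courts = as.integer(n_courts),
              displays_per_court = as.integer(displays_per_court),
              duration = duration, fps = fps, use_video = isTRUE(use_video),
              write_png = isTRUE(write_png),
              stages = stages, display = display, tracker = tracker,
              court = court, rqa_n_samples = as.integer(rqa_n_samples),
              seed = as.integer(seed))
  if (cfg$n_courts < 1L || cfg$displays_per_court < 1L)
    stop("court and display counts must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the arguments of [pipeline_config()]
#'   (with `tracker` given as a list of [tracker_config()] arguments).
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tracker)) y$tracker <- do.call(tracker_config, y$tracker)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

pipeline_error <- function(stage, e) {
  stop(sprintf("pipeline stage `%s` failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the display-consistency pipeline
#'
#' Executes the enabled stages in order on a fully synthetic experiment:
#' `simulate` draws the court structure and renders each display;
#' `track` extracts each display's edge-male series from the rendered
#' frames (skipped when `use_video = FALSE`, in which case the
#' ground-truth series is downsampled instead); `rqa` computes the five
#' consistency metrics per display; `metrics` adds cartwheel frequency and
#' the court-level female rates; `analyze` fits the group-size and
#' female-choice models. Every artifact is CSV or JSON under `out_dir`,
#' and `manifest.json` lists each output file with its MD5 checksum plus
#' the full configuration, so reruns can be verified bit for bit.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run `dir`, the `manifest`, and the
#'   assembled `dataset` (when the metrics stage ran).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  series_dir <- file.path(cfg$out_dir, "series")
  dir.create(series_dir, showWarnings = FALSE)
  on_stage <- function(s) isTRUE(cfg$stages[[s]])
  outputs <- character(0)

  n_disp <- cfg$n_courts * cfg$displays_per_court
  court_of <- rep(seq_len(cfg$n_courts), each = cfg$displays_per_court)

  ## ---- simulate + track: one display at a time (frames are large) ----
  layout <- NULL
  if (on_stage("simulate")) {
    layout <- tryCatch({
      withr::with_seed(derive_seed(cfg$seed, 1), {
        n_males <- sample(2:6, n_disp, replace = TRUE)
      })
      data.frame(display_id = seq_len(n_disp), court = court_of,
                 n_males = n_males)
    }, error = function(e) pipeline_error("simulate", e))
    for (i in seq_len(n_disp)) {
      dp_args <- utils::modifyList(
        list(n_males = layout$n_males[i], duration = cfg$duration,
             fps = cfg$fps, seed = derive_seed(cfg$seed, 100 + i)),
        cfg$display)
      dp <- do.call(display_params, dp_args)
      scene <- tryCatch(
        if (cfg$use_video) simulate_display_video(dp)
        else simulate_display_series(dp),
        error = function(e) pipeline_error("simulate", e))
      if (cfg$use_video && cfg$write_png)
        write_frames(scene, file.path(cfg$out_dir, "frames",
                                      sprintf("display_%03d", i)))
      series <- tryCatch({
        if (cfg$use_video && on_stage("track"))
          track_scene(scene, cfg$tracker)
        else {
          s <- if (cfg$use_video)
            display_series(scene$truth_trace, fps = cfg$fps)
          else scene$series
          if (cfg$tracker$target_fps < cfg$fps)
            downsample_series(s, cfg$tracker$target_fps) else s
        }
      }, error = function(e) pipeline_error("track", e))
      series$meta <- list(display_id = i, court = court_of[i],
                          n_males = layout$n_males[i])
      f <- file.path(series_dir, sprintf("display_%03d.csv", i))
      write_series_csv(series, f)
      outputs <- c(outputs, f, paste0(f, ".json"))
      rm(scene)
    }
    utils::write.csv(layout, file.path(cfg$out_dir, "layout.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, file.path(cfg$out_dir, "layout.csv"))
  }

  ## ---- rqa + metrics ----
  dataset <- NULL
  if (on_stage("rqa")) {
    files <- sort(list.files(series_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (!length(files))
      pipeline_error("rqa", simpleError("no series CSVs available"))
    rows <- lapply(seq_along(files), function(i) {
      series <- read_series_csv(files[[i]])
      met <- tryCatch(
        rqa_summary(series, n_samples = cfg$rqa_n_samples,
                    seed = derive_seed(cfg$seed, 200 + i)),
        error = function(e) pipeline_error("rqa", e))
      cbind(data.frame(display_id = series$meta$display_id %||% i,
                       court = series$meta$court %||% NA,
                       n_males = series$meta$n_males %||% NA),
            as.data.frame(met),
            frequency = if (on_stage("metrics"))
              cartwheel_frequency(series) else NA_real_)
    })
    dataset <- do.call(rbind, rows)
    utils::write.csv(dataset, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, file.path(cfg$out_dir, "metrics.csv"))
  }

  ## ---- metrics: court-level female rates ----
  if (on_stage("metrics") && !is.null(dataset)) {
    court_args <- utils::modifyList(
      list(n_courts = cfg$n_courts,
           displays_per_court = cfg$displays_per_court,
           seed = derive_seed(cfg$seed, 2)),
      cfg$court)
    cp <- do.call(court_sim_params, court_args)
    withr::with_seed(cp$seed, {
      visits <- stats::rpois(cfg$n_courts,
                             cp$recording_hours * exp(cp$visit_log_rate))
      cops <- stats::rpois(cfg$n_courts,
                           cp$recording_hours * exp(cp$copulation_log_rate))
    })
    courts <- data.frame(court = seq_len(cfg$n_courts),
                         recording_hours = cp$recording_hours,
                         visits = visits, copulations = cops)
    rates <- t(vapply(seq_len(cfg$n_courts), function(i)
      female_rates(list(recording_hours = courts$recording_hours[i],
                        n_visits = courts$visits[i],
                        n_copulations = courts$copulations[i])),
      c(visits_per_hour = 0, copulations_per_hour = 0)))
    courts$visit_rate <- rates[, 1]
    courts$copulation_rate <- rates[, 2]
    utils::write.csv(courts, file.path(cfg$out_dir, "courts.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, file.path(cfg$out_dir, "courts.csv"))
    ## court rates duplicated across the court's displays; the random
    ## intercept absorbs the induced dependence
    dataset <- merge(dataset, courts, by = "court", sort = TRUE)
    dataset <- dataset[order(dataset$display_id), ]
  }

  ## ---- analyze ----
  if (on_stage("analyze") && !is.null(dataset) &&
      "visit_rate" %in% names(dataset)) {
    report <- tryCatch({
      gs <- suppressWarnings(run_group_size_analysis(dataset))
      fc <- tryCatch(suppressWarnings(run_female_choice_analysis(dataset)),
                     error = function(e) list(error = conditionMessage(e)))
      list(group_size = gs$summary,
           female_choice = if (!is.null(fc$error)) fc else
             list(dropped = fc$vif$dropped,
                  visitation = fc$visitation$coefficients,
                  copulation = fc$copulation$coefficients))
    }, error = function(e) pipeline_error("analyze", e))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    outputs <- c(outputs, file.path(cfg$out_dir, "report.json"))
  }

  ## ---- manifest ----
  outputs <- unique(outputs)
  sums <- tools::md5sum(outputs)
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("tracker", "stages"))],
    tracker = unclass(cfg$tracker),
    stages = as.list(cfg$stages),
    files = data.frame(path = substring(normalizePath(outputs),
                                        nchar(normalizePath(cfg$out_dir)) + 2),
                       md5 = unname(sums)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(list(dir = cfg$out_dir,
                 manifest = manifest,
                 dataset = dataset))
}
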