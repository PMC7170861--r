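# End-to-end track pipeline: simulate (or read) -> filter -> metrics ->
# group summaries -> comparison, with a conservation-checked run report.

pipeline_allowed_keys <- list(
  top = c("out_dir", "axis", "simulate", "tracks_file", "filter", "window",
          "compare"),
  simulate = c("groups", "dt", "duration", "speed_mean", "speed_sd",
               "chemokinesis_factor", "chemokine"),
  group = c("name", "n_cells", "bias", "persistence", "seed", "chemokine"),
  filter = c("min_volume", "min_path_length", "static_displacement_threshold",
             "target_duration", "duration_tolerance", "length_measure"),
  window = c("recording_span"),
  compare = c("metric", "method")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop_input("unknown key(s) in %s: %s", where, paste(extra, collapse = ", "))
  }
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a path to a JSON file holding one)
#' with blocks `simulate` (or `tracks_file`), `filter`, optional
#' `window`, `compare`, plus `axis` and `out_dir`. Unknown keys anywhere
#' are rejected so typos cannot silently fall back to defaults. Every
#' simulated group must carry an explicit seed: there is no implicit
#' clock seeding.
#'
#' @param config Named list or JSON file path.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stop_input("config must be a named list or JSON path")
  check_keys(config, pipeline_allowed_keys$top, "config")
  if (is.null(config$axis)) stop_input("config needs `axis` (gradient direction)")
  config$axis <- unit2(as.numeric(config$axis), "axis")
  if (is.null(config$out_dir)) stop_input("config needs `out_dir`")
  has_sim <- !is.null(config$simulate)
  has_file <- !is.null(config$tracks_file)
  if (has_sim == has_file) {
    stop_input("config needs exactly one of `simulate` or `tracks_file`")
  }
  if (has_sim) {
    check_keys(config$simulate, pipeline_allowed_keys$simulate,
               "config$simulate")
    groups <- config$simulate$groups
    if (is.null(groups) || !length(groups)) {
      stop_input("config$simulate needs a non-empty `groups` list")
    }
    for (g in groups) {
      check_keys(g, pipeline_allowed_keys$group, "a simulate group")
      if (is.null(g$name) || is.null(g$seed)) {
        stop_input("each simulate group needs `name` and an explicit `seed`")
      }
    }
  }
  if (!is.null(config$filter)) {
    check_keys(config$filter, pipeline_allowed_keys$filter, "config$filter")
  }
  if (!is.null(config$window)) {
    check_keys(config$window, pipeline_allowed_keys$window, "config$window")
    if (is.null(config$window$recording_span)) {
      stop_input("config$window needs `recording_span`")
    }
  }
  if (!is.null(config$compare)) {
    check_keys(config$compare, pipeline_allowed_keys$compare,
               "config$compare")
  }
  class(config) <- c("pipeline_config", class(config))
  config
}

#' Run the track-analysis pipeline
#'
#' Executes the configured stages in order — simulate (or read) tracks,
#' exclusion filtering, optional analysis-window selection, per-track
#' metrics, per-group summaries of DMI and velocity, and a two-group
#' comparison — writing `tracks.csv`, `metrics.csv`, `summary.csv` and
#' `report.json` under `out_dir`. Record counts are conserved at every
#' stage (input = retained + rejected) and checked before the report is
#' written; identical config and seeds give identical outputs.
#'
#' @param config A [pipeline_config()] (or list / JSON path accepted by
#'   it).
#' @return The run report (named list), invisibly written as JSON.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    tool = "chemotaxkit",
    version = as.character(utils::packageVersion("chemotaxkit")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    stages = list(), seeds = list()
  )

  # stage: acquire tracks
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    tracks <- list()
    for (g in sim$groups) {
      par <- track_sim_params(
        n_cells = g$n_cells %||% 30L,
        dt = sim$dt %||% 0.75, duration = sim$duration %||% 120,
        speed_mean = sim$speed_mean %||% 6.9,
        speed_sd = sim$speed_sd %||% 1.5,
        persistence = g$persistence %||% 0.4, bias = g$bias %||% 0.3,
        chemokinesis_factor = sim$chemokinesis_factor %||% (12 / 6.9),
        chemokine = g$chemokine %||% sim$chemokine %||% TRUE,
        gradient_axis = cfg$axis, group = g$name, seed = g$seed
      )
      grp_tracks <- simulate_tracks(par)
      # keep ids unique across groups
      grp_tracks <- lapply(grp_tracks, function(tr) {
        tr$id <- paste0(g$name, "_", tr$id); tr
      })
      tracks <- c(tracks, grp_tracks)
      report$seeds[[g$name]] <- g$seed
    }
    report$stages$acquire <- list(source = "simulate", n = length(tracks))
  } else {
    tracks <- read_tracks(cfg$tracks_file)
    report$stages$acquire <- list(source = cfg$tracks_file,
                                  n = length(tracks))
  }
  write_tracks(tracks, file.path(cfg$out_dir, "tracks.csv"))

  # stage: exclusion filters
  crit <- do.call(filter_criteria, cfg$filter %||% list())
  filt <- filter_tracks(tracks, crit)
  reason_counts <- table(factor(filt$rejections$reason,
                                levels = c("volume", "static", "short")))
  report$stages$filter <- list(
    read = length(tracks), retained = length(filt$retained),
    rejected = nrow(filt$rejections),
    rejected_by_reason = as.list(reason_counts)
  )
  if (length(tracks) !=
      length(filt$retained) + nrow(filt$rejections)) {
    stop_compute("filter stage lost records: conservation violated")
  }
  kept <- filt$retained

  # stage: optional analysis window
  if (!is.null(cfg$window)) {
    span <- as.numeric(cfg$window$recording_span)
    selected <- select_analysis_window(kept, crit, span)
    report$stages$window <- list(read = length(kept),
                                 retained = length(selected),
                                 rejected = length(kept) - length(selected))
    kept <- selected
  }

  if (length(kept) == 0L) stop_compute("no tracks survive filtering")

  # stage: metrics + summaries
  metrics <- track_metrics(kept, cfg$axis)
  atomic_write(file.path(cfg$out_dir, "metrics.csv"), function(tmp) {
    utils::write.csv(format(metrics, digits = 17, trim = TRUE), tmp,
                     row.names = FALSE, quote = FALSE)
  })
  report$stages$metrics <- list(n = nrow(metrics))

  summaries <- do.call(rbind, unlist(lapply(split(metrics, metrics$group),
    function(d) {
      list(cbind(metric = "dmi",
                 summarize_group(d$dmi[!is.na(d$dmi)], d$group[1])),
           cbind(metric = "velocity_um_min",
                 summarize_group(d$velocity_um_min, d$group[1])))
    }), recursive = FALSE))
  rownames(summaries) <- NULL
  atomic_write(file.path(cfg$out_dir, "summary.csv"), function(tmp) {
    utils::write.csv(format(summaries, digits = 17, trim = TRUE), tmp,
                     row.names = FALSE, quote = FALSE)
  })
  report$summaries <- summaries

  # stage: two-group comparison
  if (!is.null(cfg$compare)) {
    metric <- cfg$compare$metric %||% "dmi"
    method <- cfg$compare$method %||% "rank_sum"
    groups <- unique(metrics$group)
    if (length(groups) != 2L) {
      stop_input("comparison needs exactly 2 groups (found %d)",
                 length(groups))
    }
    va <- metrics[[metric]][metrics$group == groups[1]]
    vb <- metrics[[metric]][metrics$group == groups[2]]
    cmp <- compare_groups(va[!is.na(va)], vb[!is.na(vb)], method)
    report$comparison <- c(list(metric = metric,
                                groups = as.list(groups)), cmp)
  }

  atomic_write(file.path(cfg$out_dir, "report.json"), function(tmp) {
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  })
  invisible(report)
}
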