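#' Run the full analysis pipeline from a configuration
#'
#' One-call orchestration: obtain activity (DAM2 files or a simulated
#' population), build the protocol, prepare the analysis day's normalized
#' activity and median profile, run the slope analysis, and write all stage
#' outputs plus figures to an output directory. Re-running with the same
#' configuration (and seed) reproduces byte-identical statistics files.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' simulate: {preset: control_LLTC, n_flies: 60, seed: 42}   # or input: {files: [...]}
#' protocol: {name: LLTC, days_ld: 2, days_constant: 3, days_tc: 6,
#'            shift_h: 5, days_free: 0, start: "2024-01-01 08:00:00"}
#' analysis: {day: TC6, bin_minutes: 30, transition_zt: 720,
#'            window_start_zt: 360, direction: uphill}
#' output:   {dir: results}
#' }
#'
#' @param config path to a YAML configuration or a list with the same shape.
#' @param outdir output directory; overrides `config$output$dir`.
#' @param figures write figure files as well (default `TRUE`).
#' @return Invisibly, a list with `matrix`, `protocol`, `prep` (the
#'   [daily_profile()] result), `analysis` (the [analyze_slopes()] result) and
#'   `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, figures = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stage("validate", {
    if (is.null(config$protocol)) stop("config needs a `protocol` section")
    if (is.null(config$simulate) && is.null(config$input)) {
      stop("config needs a `simulate` or `input` section")
    }
    if (is.null(config$analysis$day)) stop("config needs `analysis.day`")
  })
  pr <- config$protocol
  protocol <- stage("protocol", do.call(standard_protocol, c(
    list(name = pr$name %||% "LLTC"),
    pr[intersect(names(pr), c("days_ld", "days_constant", "days_tc",
                              "shift_h", "days_free", "thermophase",
                              "cryophase"))],
    if (!is.null(pr$start)) list(start = as.POSIXct(pr$start, tz = "UTC"))
  )))
  labels <- NULL
  mat <- stage("ingest", {
    if (!is.null(config$simulate)) {
      sm <- config$simulate
      cfg_args <- sm[setdiff(names(sm), c("preset", "n_flies", "seed"))]
      cfg <- if (!is.null(sm$preset)) {
        do.call(sim_preset, c(list(name = sm$preset),
                              sm[intersect(names(sm), c("n_flies", "seed"))]))
      } else {
        do.call(sim_config, c(cfg_args,
                              sm[intersect(names(sm), c("n_flies", "seed"))]))
      }
      sim <- simulate_population(cfg, protocol)
      labels <- sim$labels
      sim$matrix
    } else {
      mats <- lapply(config$input$files, read_dam2)
      m <- mats[[1]]
      for (other in mats[-1]) {
        if (!identical(as.numeric(m$timestamps),
                       as.numeric(other$timestamps))) {
          stop("monitor files do not cover identical time spans")
        }
        m <- activity_matrix(m$timestamps,
                             cbind(m$counts, other$counts),
                             valid = m$valid & other$valid,
                             fly_ids = c(m$fly_ids, other$fly_ids))
      }
      exclude_dead_flies(m)$matrix
    }
  })
  an_cfg <- config$analysis
  bin_minutes <- an_cfg$bin_minutes %||% 30
  prep <- stage("preprocess", daily_profile(
    mat, protocol, an_cfg$day, bin_minutes = bin_minutes,
    normalize_window = an_cfg$normalize_window %||% "recording"))
  direction <- an_cfg$direction %||% "uphill"
  analysis <- stage("slopes", {
    if (direction == "uphill") {
      analyze_slopes(prep$norm, prep$profile,
                     transition_zt = an_cfg$transition_zt %||% 720,
                     window_start_zt = an_cfg$window_start_zt %||%
                       ((an_cfg$transition_zt %||% 720) - 360),
                     zt_min = an_cfg$zt_min, zt_max = an_cfg$zt_max)
    } else {
      analyze_downhill(prep$norm, prep$profile,
                       window_zt = unlist(an_cfg$window_zt %||% c(0, 720)),
                       zt_min = an_cfg$zt_min, zt_max = an_cfg$zt_max)
    }
  })
  outdir <- outdir %||% config$output$dir %||% stop("no output directory given")
  stage("report", {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    norm_df <- data.frame(zt = prep$norm$zt,
                          round(prep$norm$values, 6), check.names = FALSE)
    utils::write.csv(norm_df, file.path(outdir, "normalized_activity.csv"),
                     row.names = FALSE)
    prof_df <- data.frame(zt = prep$profile$zt,
                          median_value = round(prep$profile$median_value, 6),
                          n_flies = prep$profile$n_flies)
    utils::write.csv(prof_df, file.path(outdir, "population_profile.csv"),
                     row.names = FALSE)
    res <- list(
      day = prep$day$label, direction = analysis$direction,
      zt_min = analysis$landmarks$zt_min, zt_max = analysis$landmarks$zt_max,
      act_at_min = analysis$landmarks$act_at_min,
      act_at_max = analysis$landmarks$act_at_max,
      manual_landmarks = analysis$landmarks$manual,
      slo_the = analysis$slo_the, slo_exp = analysis$slo_exp,
      ratio = analysis$ratio,
      fraction_anticipating = analysis$fraction_anticipating,
      n_flies = analysis$n_flies,
      fly_slopes = as.list(analysis$fly_slopes),
      anticipating = as.list(analysis$anticipating),
      excluded_flies = analysis$excluded_flies,
      excluded_at_normalization = prep$excluded)
    jsonlite::write_json(res, file.path(outdir, "slope_analysis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(labels)) {
      utils::write.csv(labels, file.path(outdir, "labels.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(config, file.path(outdir, "config_used.yaml"))
    writeLines(c(
      sprintf("phaseslope %s",
              as.character(utils::packageVersion("phaseslope"))),
      sprintf("day %s, %d flies, direction %s", prep$day$label,
              analysis$n_flies, analysis$direction)),
      file.path(outdir, "log.txt"))
  })
  if (figures) stage("figures", {
    plot_daily_profile(prep$profile, protocol, prep$day,
                       landmarks = analysis$landmarks,
                       file = file.path(outdir, "daily_profile.pdf"))
    full <- normalize_activity(bin_counts(mat, bin_minutes,
                                          origin = protocol$segments$start[1]))
    try(plot_actogram(full, protocol,
                      file = file.path(outdir, "actogram.pdf")),
        silent = TRUE)
    plot_slope_box(list(all = analysis$fly_slopes),
                   file = file.path(outdir, "slopes_box.pdf"))
  })
  invisible(list(matrix = mat, protocol = protocol, prep = prep,
                 analysis = analysis, labels = labels, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
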