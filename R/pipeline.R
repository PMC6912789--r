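#' Resolve a run configuration
#'
#' A run is configured by a named list or a YAML file with the same
#' structure. Exactly one of `events`/`roster` input paths or a `generator`
#' block must be present.
#'
#' Recognised fields: `profile`; either `input: list(events=, roster=)` or
#' `generator: list(...)` (arguments of [generator_config()]); `windows`
#' (integer vector, default all); `rank_cutoff` (default per profile);
#' `pls` (`n_boot`, default 5000); `out_dir`; `seed`.
#'
#' @param config list or path to a YAML file.
#' @return normalized config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen)
    stop("config needs exactly one of 'input' or 'generator'", call. = FALSE)
  config$profile <- config$profile %||% "piglet"
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "agonet-out"
  config$pls <- config$pls %||% list()
  config$pls$n_boot <- as.integer(config$pls$n_boot %||% 5000L)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic study and write its files
#'
#' Writes `events.csv`, `roster.csv` and `truth.csv` (latent dominance
#' scores) to the configured output directory. Reproducible: the same
#' config and seed give byte-identical files.
#'
#' @param config run configuration (see [run_config()]) with a `generator`
#'   block.
#' @return the simulated study, invisibly.
#' @export
run_simulate <- function(config) {
  config <- run_config(config)
  if (is.null(config$generator))
    stop("run_simulate needs a 'generator' block", call. = FALSE)
  gen_args <- config$generator
  gen_args$profile <- gen_args$profile %||% config$profile
  gen_args$seed <- gen_args$seed %||% config$seed
  cfg <- do.call(generator_config, gen_args)
  study <- simulate_study(cfg)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events(study$events, file.path(config$out_dir, "events.csv"))
  write_roster(study$roster, file.path(config$out_dir, "roster.csv"))
  utils::write.csv(study$truth, file.path(config$out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(study)
}

#' Run the full analysis pipeline
#'
#' Stages: parameter panels on rising windows, Spearman correlation series
#' (pooled and per pen), descriptive trajectories, rank-difference records
#' and Holm-adjusted contrasts against DI2, and the PLS path model with
#' bootstrap on the full-period panel. Each stage's table is written as CSV
#' under `out_dir` and returned.
#'
#' @param config run configuration; if it holds a `generator` block the
#'   study is simulated first, otherwise `input$events` / `input$roster`
#'   are read.
#' @param write whether to write CSV outputs.
#' @return list with `panels`, `series`, `trajectories`, `rank_records`,
#'   `rank_contrasts`, `pls` (or a skip reason), `meta`.
#' @export
run_analyze <- function(config, write = TRUE) {
  config <- run_config(config)
  if (!is.null(config$generator)) {
    study <- run_simulate(config)
    events <- study$events
    roster <- study$roster
  } else {
    roster <- read_roster(config$input$roster)
    events <- read_events(config$input$events, roster)
  }
  schedule <- schedule_preset(config$profile)
  windows <- config$windows %||% seq_len(total_hours(schedule))
  final_k <- max(windows)

  panels <- compute_panels(events, roster, schedule, windows = windows)
  series <- correlation_series(panels)
  traj <- descriptive_trajectories(events, roster, schedule)
  final_panel <- panels[panels$window_hours == final_k, , drop = FALSE]

  cutoff <- config$rank_cutoff %||% rank_cutoff(config$profile)
  rank_records <- rank_differences(final_panel, cutoff = cutoff)
  rank_contrasts <- if ("di2" %in% rank_records$parameter &&
                        length(unique(rank_records$pen_id)) >= 2) {
    contrast_vs_di2(rank_records)$contrasts
  } else {
    "skipped: need DI2 records from at least 2 pens"
  }

  spec <- default_pls_spec(config$profile)
  inds <- unlist(spec$blocks, use.names = FALSE)
  n_complete <- sum(stats::complete.cases(final_panel[, inds, drop = FALSE]))
  pls <- if (n_complete >= 10) {
    boot <- bootstrap_paths(final_panel, spec, n_boot = config$pls$n_boot,
                            seed = config$seed)
    list(fit = boot$fit, paths = boot$paths,
         gates = quality_gates(boot$fit),
         n_boot_failed = boot$n_boot_failed)
  } else {
    sprintf("skipped: only %d complete observations (need 10)", n_complete)
  }

  meta <- list(package_version = as.character(utils::packageVersion("agonet")),
               profile = config$profile, seed = config$seed,
               final_window = final_k,
               deviations = c(
                 "rank contrasts use fixed-effects OLS (parameter x comparison), not a mixed model",
                 "parameters standardized to [0,1] by affine mapping of the dominance indices"))

  res <- list(panels = panels, series = series, trajectories = traj,
              rank_records = rank_records, rank_contrasts = rank_contrasts,
              pls = pls, meta = meta)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(panels, file.path(config$out_dir, "panels.csv"),
                     row.names = FALSE)
    utils::write.csv(series$pooled,
                     file.path(config$out_dir, "series_pooled.csv"),
                     row.names = FALSE)
    utils::write.csv(series$per_pen,
                     file.path(config$out_dir, "series_per_pen.csv"),
                     row.names = FALSE)
    utils::write.csv(traj, file.path(config$out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(rank_records,
                     file.path(config$out_dir, "rank_records.csv"),
                     row.names = FALSE)
    if (is.data.frame(rank_contrasts))
      utils::write.csv(rank_contrasts,
                       file.path(config$out_dir, "rank_contrasts.csv"),
                       row.names = FALSE)
    if (is.list(pls))
      utils::write.csv(pls$paths, file.path(config$out_dir, "pls_paths.csv"),
                       row.names = FALSE)
  }
  res
}

#' Render figures and a text summary from analysis outputs
#'
#' Produces trajectory and correlation-series plots, a rank-difference
#' plot, and a plain-text summary of the PLS model. Stages whose outputs
#' are absent are marked absent in the summary rather than failing.
#'
#' @param results output of [run_analyze()].
#' @param out_dir directory for the PNG figures and `summary.txt`.
#' @return character vector of written file paths, invisibly.
#' @export
run_report <- function(results, out_dir = "agonet-report") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  f <- file.path(out_dir, "trajectories.png")
  grDevices::png(f, width = 900, height = 500)
  tr <- results$trajectories
  graphics::par(mfrow = c(1, 2))
  graphics::plot(tr$window_hours, tr$isolated_fraction, type = "b",
                 xlab = "window (observed h)", ylab = "isolated fraction",
                 ylim = c(0, 1), main = "Isolated animals")
  graphics::plot(tr$window_hours, tr$initiator_win_prop, type = "b",
                 xlab = "window (observed h)", ylab = "initiator win prop.",
                 ylim = c(0, 1), main = "Initiator victories")
  graphics::abline(h = 0.5, lty = 3)
  grDevices::dev.off()
  written <- c(written, f)

  f <- file.path(out_dir, "correlation_series.png")
  grDevices::png(f, width = 900, height = 600)
  s <- results$series$pooled
  s <- s[s$di == "di2", , drop = FALSE]
  cents <- unique(s$centrality)
  cols <- grDevices::hcl.colors(length(cents), "Dark 3")
  graphics::plot(NULL, xlim = range(s$window_hours), ylim = c(-1, 1),
                 xlab = "window (observed h)", ylab = "Spearman rs",
                 main = "DI2 vs centralities")
  graphics::abline(h = 0, lty = 3)
  for (i in seq_along(cents)) {
    ss <- s[s$centrality == cents[i], ]
    graphics::lines(ss$window_hours, ss$rs, col = cols[i], type = "b",
                    pch = ifelse(ss$significant, 19, 1))
  }
  graphics::legend("bottomright", legend = cents, col = cols, lty = 1,
                   cex = 0.7)
  grDevices::dev.off()
  written <- c(written, f)

  if (nrow(results$rank_records)) {
    f <- file.path(out_dir, "rank_differences.png")
    grDevices::png(f, width = 900, height = 500)
    rr <- results$rank_records
    means <- stats::aggregate(abs_diff ~ parameter + k, data = rr, FUN = mean)
    params <- unique(means$parameter)
    cols <- grDevices::hcl.colors(length(params), "Dark 3")
    graphics::plot(NULL, xlim = range(means$k),
                   ylim = c(0, max(means$abs_diff) * 1.05),
                   xlab = "comparison k:(k+1)", ylab = "mean |rank difference|",
                   main = "Subsequent-rank differences")
    for (i in seq_along(params)) {
      m <- means[means$parameter == params[i], ]
      graphics::lines(m$k, m$abs_diff, col = cols[i], type = "b")
    }
    graphics::legend("topright", legend = params, col = cols, lty = 1,
                     cex = 0.7)
    grDevices::dev.off()
    written <- c(written, f)
  }

  f <- file.path(out_dir, "summary.txt")
  con <- file(f, "w")
  on.exit(close(con))
  writeLines("agonet analysis summary", con)
  writeLines(sprintf("profile: %s, final window: %d h",
                     results$meta$profile, results$meta$final_window), con)
  if (is.list(results$pls)) {
    writeLines("", con)
    writeLines("PLS path model:", con)
    p <- results$pls$paths
    for (i in seq_len(nrow(p)))
      writeLines(sprintf("  %s -> %s: %.3f (SE %.3f, p = %.4g)", p$from[i],
                         p$to[i], p$estimate[i], p$se[i], p$p_value[i]), con)
    for (j in names(results$pls$fit$r2))
      writeLines(sprintf("  R2(%s) = %.3f [%s]", j, results$pls$fit$r2[j],
                         results$pls$gates$r2_band[j]), con)
  } else {
    writeLines(paste("PLS section absent:", results$pls), con)
  }
  if (is.data.frame(results$rank_contrasts)) {
    n_sig <- sum(results$rank_contrasts$significant)
    writeLines(sprintf("rank contrasts vs DI2: %d of %d Holm-significant",
                       n_sig, nrow(results$rank_contrasts)), con)
  } else {
    writeLines(paste("rank-contrast section absent:",
                     results$rank_contrasts), con)
  }
  written <- c(written, f)
  invisible(written)
}
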