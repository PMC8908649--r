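# Orchestration: simulate -> preprocess -> connect -> metrics -> stats,
# with a JSON config, structured run log and reproducible seeding.

#' Default run configuration
#'
#' A complete configuration with every recognized key.  Keys:
#' `seed` (master seed), `out_dir`, `run_id` (`NULL` = timestamped),
#' `stages` (subset of simulate/preprocess/connect/metrics/stats),
#' `input_dir` (cohort directory when `simulate` is disabled),
#' `write_matrices` (dump per-subject connectivity CSVs),
#' `cohort` (see [cohort_params()]),
#' `preprocess`: `discard_n`, `band_low_hz`, `band_high_hz`,
#' `detrend`, `bandpass`;
#' `sparsity`: vector of thresholds; `weighted`: also run the
#' weighted-network variant;
#' `nulls`: `n_random` (0 disables small-world ratios), `swaps_per_edge`;
#' `stats`: `alpha`.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "wmhnet_runs",
    run_id = NULL,
    stages = c("simulate", "preprocess", "connect", "metrics", "stats"),
    input_dir = NULL,
    write_matrices = FALSE,
    cohort = list(n_group_a = 64L, n_group_b = 46L, n_regions = 90L,
                  n_timepoints = 230L, tr_seconds = 2, n_modules = 6L,
                  within_module_r = 0.6, between_module_r = 0.1,
                  group_b_attenuation = 0.4, cognition_effect = 1.5,
                  noise_sd = 2),
    preprocess = list(discard_n = 10L, detrend = TRUE, bandpass = TRUE,
                      band_low_hz = 0.01, band_high_hz = 0.08),
    sparsity = seq(0.05, 0.40, by = 0.05),
    weighted = FALSE,
    nulls = list(n_random = 100L, swaps_per_edge = 10L),
    stats = list(alpha = 0.05)
  ), class = "run_config")
}

check_config_keys <- function(config, reference = default_run_config(),
                              path = "") {
  unknown <- setdiff(names(config), names(reference))
  if (length(unknown))
    stop_wmhnet("unknown config key(s): ",
                paste0(path, unknown, collapse = ", "))
  for (nm in names(config))
    if (is.list(reference[[nm]]) && !is.null(names(reference[[nm]])) &&
        is.list(config[[nm]]))
      check_config_keys(config[[nm]], reference[[nm]],
                        paste0(path, nm, "."))
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a JSON config file, rejects unknown keys (fail-fast) and merges
#' it over [default_run_config()].
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @param overrides named list applied last (e.g. from CLI flags).
#' @return A `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(default_run_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop_wmhnet("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    check_config_keys(user)
    cfg <- modifyList(cfg, user)
  }
  if (length(overrides)) {
    check_config_keys(overrides)
    cfg <- modifyList(cfg, overrides)
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, connect,
#' metrics, stats) and writes every artifact under
#' `out_dir/run_id/`: the cohort file set, per-subject metric profiles,
#' the four statistics tables, the verbatim config and a run log.
#' Re-running with an identical config and seed reproduces all CSVs
#' byte-identically.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return List of class `report_bundle`: paths of all artifacts plus
#'   the in-memory `group_analysis` (when the stats stage ran).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (!inherits(config, "run_config"))
    config <- structure(modifyList(unclass(default_run_config()), config),
                        class = "run_config")
  check_config_keys(unclass(config))
  stages <- config$stages
  run_id <- if (is.null(config$run_id))
    format(Sys.time(), "run-%Y%m%d-%H%M%S") else config$run_id
  out <- file.path(config$out_dir, run_id)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- list(config_hash = hash, stages = list())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop_wmhnet(sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e))))
    log$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    r
  }

  cohort <- NULL
  if ("simulate" %in% stages) {
    cohort <- t_stage("simulate", {
      cp <- do.call(cohort_params,
                    c(config$cohort, list(seed = config$seed)))
      co <- generate_cohort(cp)
      write_cohort(co, file.path(out, "cohort"))
      co
    })
  } else {
    if (is.null(config$input_dir))
      stop_wmhnet("simulate disabled and no input_dir given: ",
                  "supply a cohort directory via config$input_dir")
    cohort <- t_stage("load", read_cohort(config$input_dir,
                                          config$cohort$tr_seconds))
  }

  series <- cohort$timeseries
  tr <- config$cohort$tr_seconds
  if ("preprocess" %in% stages) {
    pp <- config$preprocess
    series <- t_stage("preprocess", lapply(series, function(m) {
      preprocess_timeseries(roi_timeseries(m, tr, cohort$node_labels),
                            n_discard = pp$discard_n,
                            do_detrend = pp$detrend,
                            do_bandpass = pp$bandpass,
                            low_hz = pp$band_low_hz,
                            high_hz = pp$band_high_hz)$data
    }))
  }

  zmats <- NULL
  if (any(c("connect", "metrics", "stats") %in% stages)) {
    zmats <- t_stage("connect", {
      ms <- lapply(series, function(m)
        fisher_z(pearson_matrix(roi_timeseries(m, tr,
                                               cohort$node_labels))))
      if (isTRUE(config$write_matrices)) {
        mdir <- file.path(out, "connectivity")
        dir.create(mdir, showWarnings = FALSE)
        for (id in names(ms))
          write_connectivity(ms[[id]],
                             file.path(mdir, paste0(id, "_fisherz.csv")))
      }
      ms
    })
  }

  bundle <- list(out_dir = out, config_hash = hash)
  if (any(c("metrics", "stats") %in% stages)) {
    grid <- sparsity_grid(config$sparsity)
    nulls <- if (config$nulls$n_random > 0)
      null_ensemble_params(config$nulls$n_random,
                           config$nulls$swaps_per_edge,
                           seed = config$seed) else NULL
    mdir <- file.path(out, "metrics")
    dir.create(mdir, showWarnings = FALSE)
    prof <- t_stage("metrics", {
      null_seeds <- derive_seeds(config$seed + 1L, length(zmats))
      lapply(seq_along(zmats), function(i) {
        np <- nulls
        if (!is.null(np)) np$seed <- null_seeds[i]
        gp <- global_profile(zmats[[i]], grid, np)
        npf <- nodal_profile(zmats[[i]], grid)
        id <- names(zmats)[i]
        write.csv(rbind(cbind(row = "threshold", gp$per_threshold[1:8]),
                        cbind(row = "summary",
                              data.frame(sparsity = NA,
                                         t(gp$summary)))),
                  file.path(mdir, paste0(id, "_global.csv")),
                  row.names = FALSE)
        write.csv(npf$summary,
                  file.path(mdir, paste0(id, "_nodal.csv")),
                  row.names = FALSE)
        list(global = gp, nodal = npf)
      })
    })
    bundle$metrics_dir <- mdir

    if ("stats" %in% stages) {
      ga <- t_stage("stats", {
        gs <- as.data.frame(do.call(rbind,
                                    lapply(prof, function(p) p$global$summary)))
        ne <- do.call(rbind,
                      lapply(prof, function(p) p$nodal$summary$nodal_e_mean))
        nl <- do.call(rbind,
                      lapply(prof, function(p) p$nodal$summary$nodal_eloc_mean))
        colnames(ne) <- colnames(nl) <- cohort$node_labels
        ga <- run_group_analysis(cohort$subjects, gs, ne, nl,
                                 alpha = config$stats$alpha)
        write_group_analysis(ga, file.path(out, "stats"))
        ga
      })
      bundle$stats_dir <- file.path(out, "stats")
      bundle$analysis <- ga
    }
  }

  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(bundle, class = "report_bundle")
}

cli_usage <- function() {
  keys <- default_run_config()
  cat("wmhnet pipeline\n",
      "usage: wmhnet <simulate|preprocess|connect|metrics|stats|run-all>\n",
      "              [--config FILE] [--seed INT] [--out DIR]\n\n",
      "Recognized config keys (JSON):\n", sep = "")
  show <- function(x, prefix = "  ") {
    for (nm in names(x)) {
      if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
        cat(prefix, nm, ":\n", sep = "")
        show(x[[nm]], paste0(prefix, "  "))
      } else cat(prefix, nm, " (default: ",
                 paste(format(x[[nm]]), collapse = ","), ")\n", sep = "")
    }
  }
  show(unclass(keys))
  invisible(NULL)
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `preprocess`, `connect`, `metrics`, `stats`
#' and `run-all` run the pipeline up to (and including) the named stage.
#' Flags: `--config FILE`, `--seed INT`, `--out DIR`.  A launcher script
#' is installed at `system.file("scripts", "wmhnet.R", package =
#' "wmhnet")`.
#'
#' @param args character vector of command-line arguments.
#' @return A `report_bundle`, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cli_usage()
    return(invisible(NULL))
  }
  cmd <- args[1]
  all_stages <- c("simulate", "preprocess", "connect", "metrics", "stats")
  stages <- switch(cmd,
    "run-all" = all_stages,
    "simulate" = , "preprocess" = , "connect" = , "metrics" = ,
    "stats" = all_stages[seq_len(match(cmd, all_stages))],
    stop_wmhnet("unknown subcommand: ", cmd, " (see --help)"))
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON configuration file"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "master seed (overrides config)"),
    optparse::make_option("--out", type = "character", default = NULL,
                          help = "output directory (overrides config)")))
  opts <- optparse::parse_args(parser, args = args[-1])
  overrides <- list(stages = stages)
  if (!is.null(opts$seed)) overrides$seed <- opts$seed
  if (!is.null(opts$out)) overrides$out_dir <- opts$out
  cfg <- load_run_config(opts$config, overrides)
  invisible(run_pipeline(cfg))
}
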