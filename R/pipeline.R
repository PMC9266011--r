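#' Default pipeline configuration
#'
#' A complete configuration list for [run_pipeline()]: synthetic input from
#' the reference three-source survey, shipped guideline values/weights,
#' exposure and toxicity defaults, fixed three-component retention for the
#' receptor model, and a 10,000-trial Monte Carlo block. Override any entry
#' (or supply a JSON file with the same keys).
#'
#' @param seed integer seed used by every random stage.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(schema = "gwhm-config-1",
       seed = as.integer(seed),
       data = list(synthetic = TRUE, unit = "ug/L",
                   censored_policy = "half"),
       standards = list(guideline_ug_L = as.list(default_guidelines()),
                        weights = as.list(default_weights())),
       apportionment = list(retention = "fixed", n_components = 3,
                            negative_policy = "truncate",
                            weighting = "equal"),
       exposure = default_exposure(),
       toxicity = as.list(default_toxicity()),
       monte_carlo = list(n_trials = 10000, conf_level = 95))
}

#' Read a pipeline configuration file
#'
#' @param path JSON configuration file.
#' @return configuration list (missing sections filled from
#'   [default_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), cfg)
}

config_toxicity <- function(cfg) {
  tx <- cfg$toxicity
  if (is.null(tx)) stop("config missing section 'toxicity'")
  as.data.frame(tx)
}

config_exposure <- function(cfg) {
  ex <- cfg$exposure
  if (is.null(ex)) stop("config missing section 'exposure'")
  ex
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

log_info <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[gwHMrisk] ", fmt), ...))
}

write_csv_out <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: gwhm-csv-1", con)
  write.csv(df, con, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or CSV
#' read), descriptive statistics, WQI, PEI, APCS/MLR source apportionment,
#' deterministic health risk, Monte Carlo risk, and source-oriented risk
#' apportionment. Every stage writes its outputs as plain-text files under
#' `outdir`, and a JSON run manifest records the config hash, seed,
#' package version, per-stage files and timestamps. Any stage error aborts
#' with the stage name in the message. Deterministic outputs are
#' bit-identical across reruns with the same config and seed.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   JSON config file.
#' @param outdir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @param stages character vector of stages to run; default all. Stage
#'   names: `data`, `descriptive`, `wqi`, `pei`, `apportion`, `risk`,
#'   `mc_risk`, `source_risk`.
#' @param verbose emit per-stage INFO messages.
#' @return the run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("gwhm_"),
                         seed = NULL, stages = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  all_stages <- c("data", "descriptive", "wqi", "pei", "apportion", "risk",
                  "mc_risk", "source_risk")
  if (is.null(stages)) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  timestamps <- list()
  tick <- function(stage) timestamps[[stage]] <<- format(Sys.time(), tz = "UTC")

  # required sections are validated up front so a broken config aborts
  # before any files are written
  for (sec in c("data", "standards", "exposure", "toxicity", "monte_carlo")) {
    if (is.null(config[[sec]])) stop(sprintf("config missing section '%s'", sec))
  }

  cfg_path <- file.path(outdir, "config.json")
  write_json(config, cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_hash <- unname(md5sum(cfg_path))
  files <- c(files, cfg_path)

  # --- data ------------------------------------------------------------
  truth <- NULL
  table <- stage_wrap("data", {
    d <- config$data
    if (isTRUE(d$synthetic)) {
      sim <- generate_survey(reference_synthetic_spec(), seed = config$seed)
      truth <- sim$truth
      sim$table
    } else {
      if (is.null(d$path)) stop("neither synthetic flag nor input path given")
      read_concentration_table(d$path, unit = d$unit %||% "ug/L",
                               censored_policy = d$censored_policy %||% "half")
    }
  })
  tick("data")
  f <- file.path(outdir, "concentrations.csv")
  write_concentration_table(table, f)
  files <- c(files, f)
  if (!is.null(truth)) {
    f <- file.path(outdir, "truth.json")
    write_truth(truth, f)
    files <- c(files, f)
  }
  log_info(verbose, "data: %d sites x %d metals", nrow(table$values),
           ncol(table$values))

  standards <- index_standards(unlist(config$standards$guideline_ug_L),
                               unlist(config$standards$weights))
  results <- list(table = table, truth = truth)

  if ("descriptive" %in% stages) {
    stats_df <- stage_wrap("descriptive", descriptive_stats(table))
    tick("descriptive")
    files <- c(files, write_csv_out(stats_df,
                                    file.path(outdir, "descriptive_stats.csv")))
    results$descriptive <- stats_df
  }
  if ("wqi" %in% stages) {
    wres <- stage_wrap("wqi", wqi(table, standards))
    tick("wqi")
    files <- c(files, write_csv_out(wres$per_site, file.path(outdir, "wqi.csv")))
    results$wqi <- wres
    log_info(verbose, "wqi: mean %.2f range [%.2f, %.2f]",
             mean(wres$per_site$wqi), min(wres$per_site$wqi),
             max(wres$per_site$wqi))
  }
  if ("pei" %in% stages) {
    pres <- stage_wrap("pei", pei(table, standards))
    tick("pei")
    files <- c(files, write_csv_out(pres$per_site, file.path(outdir, "pei.csv")))
    results$pei <- pres
  }
  apo <- NULL
  if ("apportion" %in% stages || "source_risk" %in% stages) {
    ap_cfg <- config$apportionment %||% list()
    apo <- stage_wrap("apportion", apportion(
      table,
      retention = ap_cfg$retention %||% "kaiser",
      n_components = ap_cfg$n_components,
      negative_policy = ap_cfg$negative_policy %||% "truncate",
      weighting = ap_cfg$weighting %||% "equal"))
    tick("apportion")
    files <- c(files,
               write_csv_out(as.data.frame(apo$pca$loadings),
                             file.path(outdir, "loadings.csv")),
               write_csv_out(as.data.frame(unclass(apo$apcs)),
                             file.path(outdir, "apcs.csv")),
               write_csv_out(as.data.frame(apo$contributions$per_metal_percent),
                             file.path(outdir, "contributions.csv")))
    f <- file.path(outdir, "overall_shares.json")
    write_json(list(schema = "gwhm-shares-1",
                    overall_percent = as.list(apo$overall)),
               f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
    results$apportion <- apo
    log_info(verbose, "apportion: %d components, overall shares %s",
             apo$pca$n_components,
             paste(sprintf("%.1f%%", apo$overall), collapse = "/"))
  }
  risk <- NULL
  if ("risk" %in% stages || "mc_risk" %in% stages || "source_risk" %in% stages) {
    tox <- config_toxicity(config)
    expo <- config_exposure(config)
    risk <- stage_wrap("risk", health_risk(table, exposure = expo, tox = tox))
    tick("risk")
    det <- do.call(rbind, lapply(names(risk), function(pn) {
      data.frame(population = pn,
                 metal = risk[[pn]]$hazard$per_metal$metal,
                 hq = risk[[pn]]$hazard$per_metal$hq,
                 HI = risk[[pn]]$hazard$HI,
                 TCR = risk[[pn]]$cancer$TCR, row.names = NULL)
    }))
    files <- c(files, write_csv_out(det,
                                    file.path(outdir, "risk_deterministic.csv")))
    results$risk <- risk
  }
  if ("mc_risk" %in% stages) {
    mc <- stage_wrap("mc_risk", {
      tox <- config_toxicity(config)
      expo <- config_exposure(config)
      conc_specs <- lapply(setNames(table$metals, table$metals), function(m) {
        v <- table$values[, m]
        v <- v[v > 0]
        if (!length(v)) stop(sprintf("no positive values for metal '%s'", m))
        fit_lognormal(v)
      })
      cfgmc <- config$monte_carlo
      run_mc_risk(conc_specs,
                  config = mc_config(cfgmc$n_trials %||% 10000,
                                     seed = config$seed,
                                     conf_level = cfgmc$conf_level %||% 95),
                  exposure = expo, tox = tox, keep_draws = FALSE)
    })
    tick("mc_risk")
    mc_df <- do.call(rbind, lapply(names(mc$populations), function(pn) {
      s <- mc$populations[[pn]]$summary
      data.frame(population = pn, quantity = rownames(s), s, row.names = NULL)
    }))
    files <- c(files, write_csv_out(mc_df, file.path(outdir, "mc_summary.csv")))
    results$mc <- mc
    log_info(verbose, "mc_risk: %d trials x %d populations",
             mc$config$n_trials, length(mc$populations))
  }
  if ("source_risk" %in% stages) {
    sr <- stage_wrap("source_risk",
                     apportion_risk(risk, apo$contributions))
    tick("source_risk")
    files <- c(files, write_csv_out(sr$table,
                                    file.path(outdir, "source_risk.csv")))
    results$source_risk <- sr
  }

  manifest <- list(schema = "gwhm-manifest-1",
                   package_version = as.character(packageVersion("gwHMrisk")),
                   seed = config$seed,
                   config_hash = cfg_hash,
                   stages = stages,
                   files = basename(files),
                   timestamps = timestamps)
  write_json(manifest, file.path(outdir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outdir <- outdir
  manifest$results <- results
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher around [run_pipeline()]:
#' `simulate | wqi | pei | apportion | risk | mc-risk | source-risk |
#' run-all`, with flags `--config <path>`, `--seed <int>`,
#' `--outdir <path>`, `--log-level info|quiet`. Each subcommand runs the
#' stages it needs (file-based stage outputs make single stages
#' independently rerunnable).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
hm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: gwhmrisk <simulate|wqi|pei|apportion|risk|mc-risk|",
                 "source-risk|run-all> [--config F] [--seed N]",
                 "[--outdir D] [--log-level info|quiet]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- list(config = NULL, seed = NULL, outdir = "gwhm_out",
               log_level = "info")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(args)) {
      message(usage); return(invisible(2L))
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  stage_map <- list(
    simulate = "data",
    wqi = c("data", "wqi"),
    pei = c("data", "pei"),
    apportion = c("data", "apportion"),
    risk = c("data", "risk"),
    `mc-risk` = c("data", "mc_risk"),
    `source-risk` = c("data", "apportion", "risk", "source_risk"),
    `run-all` = NULL)
  if (!cmd %in% names(stage_map)) { message(usage); return(invisible(2L)) }
  cfg <- if (is.null(opts$config)) default_config() else read_config(opts$config)
  status <- tryCatch({
    run_pipeline(cfg, outdir = opts$outdir,
                 seed = if (is.null(opts$seed)) NULL else as.integer(opts$seed),
                 stages = stage_map[[cmd]],
                 verbose = identical(opts$log_level, "info"))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
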