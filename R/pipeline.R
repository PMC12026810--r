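# End-to-end orchestration: configuration, ingestion (raw graphs or
# pre-tabulated metrics), scoring, and the report bundle.  Logging goes to
# standard error; results go to files only.

#' Pipeline run configuration
#'
#' Two ingestion modes exist because CAM measurements are often tabulated
#' by hand: `"metrics"` starts from the per-embryo metrics CSV, `"graphs"`
#' starts from vectorized vessel networks listed in a manifest CSV
#' (`embryo_id`, `group`, `day`, `path`; JSON or GraphML by file
#' extension) and measures them with [compute_metrics()].
#'
#' @param mode `"metrics"` or `"graphs"`.
#' @param metrics_csv per-embryo metrics CSV (metrics mode).
#' @param graphs_manifest manifest CSV (graphs mode).
#' @param survival_csv survival CSV (see [read_survival_csv()]).
#' @param thickness_csv optional thickness CSV.
#' @param roi a [ring_roi()], required in graphs mode.
#' @param control control group name.
#' @param treatments treatment groups to score; `NULL` means every
#'   non-control group.
#' @param day target day of the headline index (default 7).
#' @param out_dir output directory for the report bundle.
#' @param parameters AAI parameter set (default: the six scored ones).
#' @param verbose log progress to standard error.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("metrics", "graphs"),
                       metrics_csv = NULL, graphs_manifest = NULL,
                       survival_csv = NULL, thickness_csv = NULL,
                       roi = NULL, control = "control", treatments = NULL,
                       day = 7, out_dir = "camAAI-out",
                       parameters = AAI_PARAMETERS, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "metrics" && is.null(metrics_csv))
    cam_abort("metrics mode requires metrics_csv", "camAAI_schema_error")
  if (mode == "graphs" && (is.null(graphs_manifest) || is.null(roi)))
    cam_abort("graphs mode requires graphs_manifest and roi",
              "camAAI_schema_error")
  if (is.null(survival_csv))
    cam_abort("a survival CSV is required", "camAAI_schema_error")
  if (!length(parameters))
    cam_abort("the AAI parameter set must be non-empty", "camAAI_schema_error")
  structure(list(mode = mode, metrics_csv = metrics_csv,
                 graphs_manifest = graphs_manifest,
                 survival_csv = survival_csv, thickness_csv = thickness_csv,
                 roi = roi, control = control, treatments = treatments,
                 day = day, out_dir = out_dir, parameters = parameters,
                 verbose = verbose),
            class = "run_config")
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[camAAI] ", ...)
}

read_graph_any <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) read_graph_graphml(path)
  else read_graph_json(path)$graph
}

metrics_from_manifest <- function(manifest_path, roi) {
  man <- read_table_checked(manifest_path,
                            c("embryo_id", "group", "day", "path"), "manifest")
  base <- dirname(manifest_path)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    g <- read_graph_any(p)
    metrics_row(man$embryo_id[i], man$group[i], man$day[i],
                compute_metrics(g, roi))
  })
  do.call(rbind, rows)
}

#' Run the CAM scoring pipeline
#'
#' Ingests the inputs, assembles the cohort, builds the angiogenic profile
#' of every requested treatment group, and writes the report bundle to
#' `config$out_dir`: `metrics.csv` (the measured or ingested metrics),
#' `profile_<treatment>.csv`, `aai_report.json`, `survival_summary.csv`
#' (per-group product-limit curves and pairwise log-rank tests against the
#' control) and `run_log.txt` (every design decision applied, and any
#' parameter exclusions).  Degenerate parameters warn and are excluded;
#' schema violations abort with a diagnostic naming the offending embryo
#' or column.
#'
#' @param config a [run_config()].
#' @return named list of `aai_profile` objects, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_msg(config, "ingesting inputs (mode: ", config$mode, ")")
  metrics <- if (config$mode == "metrics") read_metrics_csv(config$metrics_csv)
  else metrics_from_manifest(config$graphs_manifest, config$roi)
  survival_df <- read_survival_csv(config$survival_csv)
  thickness <- if (!is.null(config$thickness_csv))
    read_thickness_csv(config$thickness_csv)
  cohort <- cohort_dataset(metrics, survival_df, thickness,
                           control = config$control)
  treatments <- config$treatments %||% setdiff(cohort$groups, cohort$control)
  if (!length(treatments))
    cam_abort("no treatment groups to score", "camAAI_empty_group")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics_csv(cohort$metrics, file.path(config$out_dir, "metrics.csv"))

  profiles <- list()
  for (tr in treatments) {
    log_msg(config, "scoring ", tr, " vs ", cohort$control)
    pr <- build_angiogenic_profile(cohort, tr, day = config$day,
                                   parameters = config$parameters)
    for (i in seq_len(nrow(pr$excluded)))
      warning("parameter '", pr$excluded$parameter[i], "' excluded for ",
              tr, ": ", pr$excluded$reason[i], call. = FALSE)
    write_profile_csv(pr, file.path(config$out_dir,
                                    paste0("profile_", tr, ".csv")))
    profiles[[tr]] <- pr
  }

  # survival summary: per-group curves + log-rank vs control
  curves <- lapply(cohort$groups, function(g) {
    cv <- group_curve(cohort, g)
    data.frame(group = g, time = cv$time, n_risk = cv$n_risk,
               n_event = cv$n_event, surv = signif(cv$surv, 6L))
  })
  surv_tab <- do.call(rbind, curves)
  ctrl_sv <- cohort$survival[cohort$survival$group == cohort$control, ]
  lr <- lapply(treatments, function(tr) {
    sv <- cohort$survival[cohort$survival$group == tr, ]
    res <- logrank_test(ctrl_sv$last_day_alive, ctrl_sv$status,
                        sv$last_day_alive, sv$status)
    data.frame(group = tr, time = NA, n_risk = NA, n_event = NA, surv = NA,
               logrank_chisq = signif(res$chisq, 6L), logrank_p = signif(res$p, 6L))
  })
  surv_tab$logrank_chisq <- NA_real_; surv_tab$logrank_p <- NA_real_
  surv_tab <- rbind(surv_tab, do.call(rbind, lr))
  write.csv(surv_tab, file.path(config$out_dir, "survival_summary.csv"),
            row.names = FALSE, quote = FALSE, na = "")

  report <- list(format = "camAAI-report", version = 1L,
                 control = cohort$control, day = config$day,
                 profiles = lapply(profiles, function(pr) list(
                   treatment = pr$treatment,
                   indices = as.list(signif(pr$indices, 6L)),
                   n_parameters = pr$n,
                   final_aai = signif(pr$final_aai, 6L),
                   excluded = pr$excluded)),
                 metadata = profiles[[1L]]$metadata)
  jsonlite::write_json(report, file.path(config$out_dir, "aai_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  log_lines <- c(
    paste0("camAAI run, mode=", config$mode, ", control=", cohort$control,
           ", day=", config$day),
    paste0("design: ", names(profiles[[1L]]$metadata), " = ",
           unlist(lapply(profiles[[1L]]$metadata, as.character))),
    unlist(lapply(profiles, function(pr)
      if (nrow(pr$excluded))
        paste0("excluded [", pr$treatment, "] ", pr$excluded$parameter, ": ",
               pr$excluded$reason)
      else character())))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  log_msg(config, "report written to ", config$out_dir)
  invisible(profiles)
}

# ---------------------------------------------------------------------------
# command-line interface (thin layer over the functions above)

cli_opts <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_usage <- function() {
  cat(file = stderr(),
      "usage: camaai <simulate|metrics|profile|report> [options]\n",
      "  simulate --out DIR [--seed N] [--config FILE.json] [--graphs]\n",
      "  metrics  --manifest FILE --roi FILE.json --out FILE.csv\n",
      "  profile|report --metrics FILE --survival FILE [--thickness FILE]\n",
      "           [--control NAME] [--day N] --out DIR [--verbose]\n", sep = "")
}

cli_simulate <- function(o) {
  cfg <- if (!is.null(o$config)) {
    j <- jsonlite::read_json(o$config, simplifyVector = TRUE)
    if (!is.null(j$roi))
      j$roi <- ring_roi(j$roi$center, j$roi$inner_radius_um, j$roi$outer_radius_um)
    do.call(simulation_config, j)
  } else simulation_config()
  if (!is.null(o$seed)) cfg$seed <- as.integer(o$seed)
  out <- o$out %||% "camAAI-sim"
  cohort <- simulate_cohort(cfg, keep_graphs = isTRUE(o$graphs))
  write_cohort_csv(cohort, out)
  if (isTRUE(o$graphs)) {
    gdir <- file.path(out, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    graphs <- attr(cohort, "graphs")
    man <- list()
    for (eid in names(graphs)) for (d in names(graphs[[eid]])) {
      p <- file.path(gdir, sprintf("%s_day%s.graphml", eid, d))
      write_graph_graphml(graphs[[eid]][[d]], p)
      grp <- cohort$survival$group[cohort$survival$embryo_id == eid]
      man[[length(man) + 1L]] <- data.frame(embryo_id = eid, group = grp,
                                            day = as.numeric(d), path = p)
    }
    write.csv(do.call(rbind, man), file.path(out, "manifest.csv"),
              row.names = FALSE, quote = FALSE)
  }
  eo <- expected_outcome(cfg)
  jsonlite::write_json(list(ar = eo$ar, aai = eo$aai, final = eo$final,
                            excluded = eo$excluded),
                       file.path(out, "expected_outcome.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message("[camAAI] simulated cohort written to ", out)
  0L
}

cli_metrics <- function(o) {
  roi <- read_graph_json_roi(o$roi)
  metrics <- metrics_from_manifest(o$manifest, roi)
  write_metrics_csv(metrics, o$out %||% "metrics.csv")
  message("[camAAI] metrics written to ", o$out %||% "metrics.csv")
  0L
}

read_graph_json_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- j$roi %||% j
  ring_roi(unlist(r$center), r$inner_radius_um, r$outer_radius_um)
}

cli_profile <- function(o) {
  cfg <- run_config(mode = "metrics", metrics_csv = o$metrics,
                    survival_csv = o$survival, thickness_csv = o$thickness,
                    control = o$control %||% "control",
                    day = as.numeric(o$day %||% 7),
                    out_dir = o$out %||% "camAAI-out",
                    verbose = isTRUE(o$verbose))
  profiles <- run_pipeline(cfg)
  for (pr in profiles) print(pr)
  0L
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort bundle plus its
#' expected outcome), `metrics` (measure a manifest of graph files into a
#' metrics CSV), `profile` / `report` (run the full scoring pipeline).
#' Installed alongside the package as the `inst/cli/camaai` Rscript.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return integer exit status, invisibly.
#' @export
cam_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- cli_opts(args)
  cmd <- if (length(parsed$pos)) parsed$pos[1L] else ""
  status <- tryCatch(
    switch(cmd,
           simulate = cli_simulate(parsed$opts),
           metrics = cli_metrics(parsed$opts),
           profile = ,
           report = cli_profile(parsed$opts),
           { cli_usage(); 2L }),
    camAAI_error = function(e) {
      message("[camAAI] error: ", conditionMessage(e)); 1L
    })
  invisible(status)
}
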