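# File formats.
#
# Vessel graphs travel as a documented JSON schema (nodes, edges with
# polylines, roots, optional ROI) or as GraphML (via igraph; polylines are
# serialized as "x,y;x,y" strings).  Tabular data are RFC-4180 CSV with a
# header row.  All floating-point CSV/JSON report output is serialized at 6
# significant digits; internal computation is full precision.

GRAPH_SCHEMA_VERSION <- 1L

#' Write / read a vessel graph as JSON
#'
#' The schema (version 1) is an object with `format`, `version`, `nodes`
#' (`id`, `x`, `y`), `edges` (`id`, `from`, `to`, `length_um`, `polyline` as
#' an n-by-2 array), `roots`, and optionally `roi` (`center`,
#' `inner_radius_um`, `outer_radius_um`).
#'
#' @param graph a [vessel_graph()].
#' @param path file path.
#' @param roi optional [ring_roi()] stored alongside the graph.
#' @return `write_graph_json` returns `path` invisibly; `read_graph_json`
#'   returns a list with elements `graph` and `roi` (`NULL` when absent).
#' @export
write_graph_json <- function(graph, path, roi = NULL) {
  stopifnot(inherits(graph, "vessel_graph"))
  obj <- list(
    format = "camAAI-graph", version = GRAPH_SCHEMA_VERSION,
    nodes = graph$nodes,
    edges = lapply(seq_len(nrow(graph$edges)), function(i) list(
      id = graph$edges$id[i], from = graph$edges$from[i],
      to = graph$edges$to[i], length_um = graph$edges$length[i],
      polyline = unname(graph$polylines[[i]]))),
    roots = graph$roots)
  if (!is.null(roi))
    obj$roi <- list(center = roi$center, inner_radius_um = roi$inner_radius,
                    outer_radius_um = roi$outer_radius)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "camAAI-graph"))
    cam_abort(paste0(path, ": not a camAAI graph JSON file"),
              "camAAI_schema_error")
  nodes <- do.call(rbind, lapply(obj$nodes, function(n)
    data.frame(id = n$id, x = n$x, y = n$y, stringsAsFactors = FALSE)))
  if (is.null(nodes)) nodes <- data.frame(id = character(), x = double(), y = double())
  edges <- do.call(rbind, lapply(obj$edges, function(e)
    data.frame(id = e$id, from = e$from, to = e$to, length = e$length_um,
               stringsAsFactors = FALSE)))
  polylines <- lapply(obj$edges, function(e)
    do.call(rbind, lapply(e$polyline, function(p) c(p[[1]], p[[2]]))))
  if (is.null(edges)) {
    edges <- data.frame(id = character(), from = character(), to = character())
    polylines <- NULL
  } else {
    names(polylines) <- edges$id
  }
  roi <- NULL
  if (!is.null(obj$roi))
    roi <- ring_roi(unlist(obj$roi$center), obj$roi$inner_radius_um,
                    obj$roi$outer_radius_um)
  list(graph = vessel_graph(nodes, edges, polylines,
                            roots = unlist(obj$roots) %||% character()),
       roi = roi)
}

format_polyline <- function(p)
  paste(apply(p, 1L, function(r) paste0(r[1], ",", r[2])), collapse = ";")

parse_polyline <- function(s) {
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ",", fixed = TRUE)
  do.call(rbind, lapply(pts, function(p) as.numeric(p)))
}

#' Write / read a vessel graph as GraphML
#'
#' Node attributes `x`, `y`; edge attributes `length_um`, `polyline`
#' (semicolon-separated `x,y` pairs) and `root` (0/1).
#'
#' @inheritParams write_graph_json
#' @return `write_graph_graphml` returns `path` invisibly;
#'   `read_graph_graphml` returns a [vessel_graph()].
#' @export
write_graph_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$from, to = graph$edges$to,
                   id = graph$edges$id,
                   # igraph may normalize endpoint order; keep the
                   # polyline-oriented endpoints as explicit attributes
                   src = graph$edges$from, dst = graph$edges$to,
                   length_um = graph$edges$length,
                   polyline = vapply(graph$polylines, format_polyline, ""),
                   root = as.integer(graph$edges$id %in% graph$roots),
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, x = graph$nodes$x,
                          y = graph$nodes$y, stringsAsFactors = FALSE))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graph_graphml
#' @export
read_graph_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vs <- igraph::as_data_frame(ig, what = "vertices")
  es <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(id = vs$name, x = vs$x, y = vs$y, stringsAsFactors = FALSE)
  polylines <- lapply(es$polyline, parse_polyline)
  names(polylines) <- es$id
  vessel_graph(nodes,
               data.frame(id = es$id, from = es$src, to = es$dst,
                          length = es$length_um, stringsAsFactors = FALSE),
               polylines, roots = es$id[es$root == 1])
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path))
    cam_abort(paste0(what, " file not found: ", path), "camAAI_schema_error")
  if (file.size(path) == 0)
    cam_abort(paste0(what, " file is empty: ", path), "camAAI_schema_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    cam_abort(paste0(path, ": missing required column(s): ",
                     paste(miss, collapse = ", ")), "camAAI_schema_error")
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(path, ": ignoring unknown column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  df
}

#' Read / write the per-embryo metrics table
#'
#' CSV schema: one row per embryo and observation day with columns
#' `embryo_id`, `group`, `day`, `junctions`, `segments`, `total_length_um`,
#' `mean_length_um`, `density_um_per_mm2`, `n1`..`n4`, `hierarchy_ratio`.
#'
#' @param path CSV file path.
#' @param metrics a metrics data frame in the schema above.
#' @return the data frame (read) or `path` invisibly (write).
#' @export
read_metrics_csv <- function(path) {
  read_table_checked(path, c("embryo_id", "group", "day", METRIC_COLUMNS),
                     "metrics")
}

#' @rdname read_metrics_csv
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- metrics
  num <- vapply(out, is.numeric, NA)
  out[num] <- lapply(out[num], signif, digits = 6L)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read the survival and thickness tables
#'
#' Survival CSV: `embryo_id`, `group`, `last_day_alive`, `status` (1 =
#' found dead at that day, 0 = censored).  Thickness CSV: `embryo_id`,
#' `group`, `thickness_um`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_survival_csv <- function(path) {
  read_table_checked(path, c("embryo_id", "group", "last_day_alive", "status"),
                     "survival")
}

#' @rdname read_survival_csv
#' @export
read_thickness_csv <- function(path) {
  read_table_checked(path, c("embryo_id", "group", "thickness_um"), "thickness")
}

#' Read / write a whole cohort as a CSV bundle
#'
#' `write_cohort_csv` writes `metrics.csv`, `survival.csv` and (when
#' present) `thickness.csv` into a directory; `read_cohort_csv` re-reads
#' them into a [cohort_dataset()].
#'
#' @param cohort a [cohort_dataset()].
#' @param dir directory path.
#' @param control control group name used when re-reading.
#' @return the directory (write, invisibly) or a `cam_cohort` (read).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics_csv(cohort$metrics, file.path(dir, "metrics.csv"))
  sv <- cohort$survival
  write.csv(sv, file.path(dir, "survival.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$thickness)) {
    th <- cohort$thickness
    th$thickness_um <- signif(th$thickness_um, 6L)
    write.csv(th, file.path(dir, "thickness.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir, control = "control") {
  thp <- file.path(dir, "thickness.csv")
  cohort_dataset(read_metrics_csv(file.path(dir, "metrics.csv")),
                 read_survival_csv(file.path(dir, "survival.csv")),
                 if (file.exists(thp)) read_thickness_csv(thp),
                 control = control)
}

#' Write an angiogenic profile as CSV and JSON
#'
#' The CSV holds the long profile table (`group`, `parameter`, `day`, `AR`,
#' `SD`, `n`, `AAI_i` filled on target-day treatment rows); the JSON report
#' additionally carries the per-parameter indices, the final AAI, the
#' exclusions and the applied design-decision metadata.
#'
#' @param profile an `aai_profile` from [build_angiogenic_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  tab <- profile$profile
  tab$AAI_i <- NA_real_
  for (p in names(profile$indices)) {
    hit <- tab$group == profile$treatment & tab$parameter == p &
      tab$day == if (p == "thickness") max(tab$day) else profile$day
    tab$AAI_i[hit] <- profile$indices[[p]]
  }
  num <- vapply(tab, is.numeric, NA)
  tab[num] <- lapply(tab[num], signif, digits = 6L)
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(format = "camAAI-profile", version = 1L,
              treatment = profile$treatment, control = profile$control,
              day = profile$day,
              indices = as.list(signif(profile$indices, 6L)),
              n_parameters = profile$n,
              final_aai = signif(profile$final_aai, 6L),
              excluded = profile$excluded,
              profile = {
                tab <- profile$profile
                num <- vapply(tab, is.numeric, NA)
                tab[num] <- lapply(tab[num], signif, digits = 6L)
                tab
              },
              metadata = profile$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
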