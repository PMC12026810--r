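# Vessel-network data model and morphometrics.
#
# A CAM vessel network is represented as a planar skeleton graph: nodes carry
# 2D coordinates in micrometres, edges carry a polyline (the vessel
# centerline) and its Euclidean length.  All morphometric parameters measured
# on the CAM (junctions, total/mean vessel length, density, branch hierarchy)
# are derived from this graph after canonicalization, which makes "segment"
# well defined: a maximal path between nodes of graph-degree != 2.

polyline_length <- function(points) {
  if (is.null(points) || nrow(points) < 2L) return(0)
  d <- points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE]
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

#' Construct a vessel network graph
#'
#' @param nodes data frame with columns `id`, `x`, `y`; coordinates in
#'   micrometres, origin arbitrary.
#' @param edges data frame with columns `id`, `from`, `to` and optionally
#'   `length` (micrometres).  When `length` is missing it is computed from the
#'   polyline.
#' @param polylines named list (by edge id) of two-column matrices tracing
#'   each vessel centerline from `from` to `to`.  `NULL` means straight
#'   segments between the endpoint node coordinates.
#' @param roots character vector of edge ids designated as first-degree
#'   feeder vessels entering the region of interest.  May be empty; see
#'   [assign_branch_degrees()] for the fallback used then.
#' @param validate check invariants (endpoints exist, no self-loops, stated
#'   lengths agree with polyline lengths to 1e-6 relative tolerance).
#'   Internal callers that construct graphs programmatically may skip this.
#'
#' @return An object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes = data.frame(id = character(), x = double(), y = double()),
                         edges = data.frame(id = character(), from = character(), to = character()),
                         polylines = NULL, roots = character(), validate = TRUE) {
  nodes <- data.frame(id = as.character(nodes$id), x = as.numeric(nodes$x),
                      y = as.numeric(nodes$y), stringsAsFactors = FALSE)
  ne <- nrow(edges)
  ed <- data.frame(id = as.character(edges$id), from = as.character(edges$from),
                   to = as.character(edges$to), stringsAsFactors = FALSE)
  if (is.null(polylines)) {
    fi <- match(ed$from, nodes$id)
    ti <- match(ed$to, nodes$id)
    if (validate && (anyNA(fi) || anyNA(ti)))
      cam_abort("edge endpoint not present in node table", "camAAI_schema_error")
    polylines <- lapply(seq_len(ne), function(i)
      rbind(c(nodes$x[fi[i]], nodes$y[fi[i]]), c(nodes$x[ti[i]], nodes$y[ti[i]])))
    names(polylines) <- ed$id
  } else {
    polylines <- polylines[ed$id]
  }
  plen <- if (!is.null(edges$length)) as.numeric(edges$length) else
    vapply(polylines, polyline_length, 0)
  ed$length <- plen
  g <- structure(list(nodes = nodes, edges = ed, polylines = polylines,
                      roots = as.character(roots)), class = "vessel_graph")
  if (validate) validate_vessel_graph(g)
  g
}

validate_vessel_graph <- function(g) {
  ed <- g$edges
  if (anyDuplicated(g$nodes$id))
    cam_abort("duplicated node ids", "camAAI_schema_error")
  if (anyDuplicated(ed$id))
    cam_abort("duplicated edge ids", "camAAI_schema_error")
  bad <- setdiff(c(ed$from, ed$to), g$nodes$id)
  if (length(bad))
    cam_abort(paste0("edge endpoints missing from node table: ",
                     paste(head(bad, 5L), collapse = ", ")), "camAAI_schema_error")
  if (any(ed$from == ed$to))
    cam_abort("self-loop edges are not allowed", "camAAI_schema_error")
  if (nrow(ed)) {
    pl <- vapply(g$polylines, polyline_length, 0)
    if (any(ed$length <= 0))
      cam_abort("every edge must have positive length", "camAAI_schema_error")
    rel <- abs(ed$length - pl) / pmax(pl, .Machine$double.eps)
    if (any(rel > 1e-6))
      cam_abort(paste0("stated edge length disagrees with polyline length for edge ",
                       ed$id[which.max(rel)]), "camAAI_schema_error")
    # polyline ends must sit on the endpoint nodes
    fi <- match(ed$from, g$nodes$id); ti <- match(ed$to, g$nodes$id)
    for (i in seq_len(nrow(ed))) {
      p <- g$polylines[[i]]
      d1 <- sqrt(sum((p[1L, ] - c(g$nodes$x[fi[i]], g$nodes$y[fi[i]]))^2))
      d2 <- sqrt(sum((p[nrow(p), ] - c(g$nodes$x[ti[i]], g$nodes$y[ti[i]]))^2))
      if (max(d1, d2) > 1e-6 * max(1, ed$length[i]))
        cam_abort(paste0("polyline of edge ", ed$id[i],
                         " does not terminate on its endpoint nodes"),
                  "camAAI_schema_error")
    }
  }
  if (length(g$roots) && length(setdiff(g$roots, ed$id)))
    cam_abort("root ids must refer to existing edges", "camAAI_schema_error")
  invisible(g)
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat("<vessel_graph> ", nrow(x$edges), " edges, ", nrow(x$nodes), " nodes, ",
      length(x$roots), " roots; total length ",
      format(sum(x$edges$length), digits = 6), " um\n", sep = "")
  invisible(x)
}

# node id -> incident edge indices (each edge contributes once per endpoint)
node_incidence <- function(g) {
  ne <- nrow(g$edges)
  split(rep.int(seq_len(ne), 2L), c(g$edges$from, g$edges$to))
}

#' Node degrees of a vessel graph
#'
#' @param graph a [vessel_graph()].
#' @return named integer vector of graph degrees (isolated nodes included
#'   with degree 0).
#' @export
node_degrees <- function(graph) {
  inc <- node_incidence(graph)
  deg <- setNames(integer(nrow(graph$nodes)), graph$nodes$id)
  deg[names(inc)] <- lengths(inc)
  deg
}

#' Canonicalize a vessel graph
#'
#' Merges chains of degree-2 nodes so that every remaining edge is a maximal
#' vessel segment between junctions and/or endpoints.  Polylines are
#' concatenated along the chain and total length is conserved exactly.  The
#' operation is idempotent, drops isolated nodes, and never produces
#' self-loop edges: a closed loop (all nodes of degree 2, which does not
#' occur in tree-like CAM networks) is kept as two arcs meeting at two
#' deterministic anchor nodes.
#'
#' The id of a merged edge is the lexicographically smallest constituent id;
#' a merged edge is a root if any constituent was.
#'
#' @param graph a [vessel_graph()].
#' @return a canonical [vessel_graph()].
#' @export
canonicalize <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  ne <- nrow(graph$edges)
  if (ne == 0L)
    return(vessel_graph(validate = FALSE))
  inc <- node_incidence(graph)
  deg <- lengths(inc)
  used <- graph$nodes$id %in% names(inc)
  if (!any(deg == 2L)) {
    if (all(used)) return(graph)
    g2 <- graph
    g2$nodes <- graph$nodes[used, , drop = FALSE]
    return(g2)
  }
  from <- graph$edges$from; to <- graph$edges$to; ids <- graph$edges$id
  lens <- graph$edges$length
  visited <- logical(ne)
  pieces <- list()   # each: integer vector of edge indices ordered along walk
  starts <- character(); ends <- character()

  walk <- function(node, e) {
    # follow a chain of degree-2 nodes starting with edge e out of `node`
    chain <- integer()
    repeat {
      visited[e] <<- TRUE
      chain <- c(chain, e)
      nxt <- if (from[e] == node) to[e] else from[e]
      if (deg[[nxt]] != 2L) return(list(chain = chain, end = nxt))
      cand <- inc[[nxt]]
      e2 <- cand[cand != e]
      if (length(e2) != 1L || visited[e2]) return(list(chain = chain, end = nxt))
      node <- nxt
      e <- e2
    }
  }
  anchors <- names(inc)[deg != 2L]
  for (a in anchors) {
    for (e in inc[[a]]) {
      if (visited[e]) next
      w <- walk(a, e)
      pieces[[length(pieces) + 1L]] <- w$chain
      starts <- c(starts, a); ends <- c(ends, w$end)
    }
  }
  # remaining edges are pure cycles (every node degree 2)
  while (any(!visited)) {
    rem <- which(!visited)
    cyc_nodes <- unique(c(from[rem], to[rem]))
    # deterministic anchor: smallest node id in this cycle component reachable
    a <- sort(cyc_nodes)[1L]
    e0 <- sort(inc[[a]])[1L]
    w <- walk(a, e0)
    pieces[[length(pieces) + 1L]] <- w$chain
    starts <- c(starts, a); ends <- c(ends, w$end)
  }

  out_from <- character(); out_to <- character(); out_id <- character()
  out_len <- double(); out_poly <- list(); out_root <- logical()
  emit <- function(chain, a, b) {
    # orient polylines along the walk and concatenate
    node <- a
    pts <- NULL
    for (e in chain) {
      p <- graph$polylines[[e]]
      if (from[e] != node) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      pts <- if (is.null(pts)) p else rbind(pts, p[-1L, , drop = FALSE])
      node <- if (from[e] == node) to[e] else from[e]
    }
    i <- length(out_id) + 1L
    out_from[i] <<- a; out_to[i] <<- b
    out_id[i] <<- min(ids[chain])
    out_len[i] <<- sum(lens[chain])
    out_poly[[i]] <<- pts
    out_root[i] <<- any(ids[chain] %in% graph$roots)
  }
  for (k in seq_along(pieces)) {
    chain <- pieces[[k]]
    if (starts[k] == ends[k] && length(chain) >= 2L) {
      # loop anchored at a single node: keep first edge, merge the rest,
      # so that no self-loop is created
      e1 <- chain[1L]
      mid <- if (from[e1] == starts[k]) to[e1] else from[e1]
      emit(chain[1L], starts[k], mid)
      emit(chain[-1L], mid, ends[k])
    } else {
      emit(chain, starts[k], ends[k])
    }
  }
  keep <- graph$nodes$id %in% c(out_from, out_to)
  names(out_poly) <- out_id
  vessel_graph(nodes = graph$nodes[keep, , drop = FALSE],
               edges = data.frame(id = out_id, from = out_from, to = out_to,
                                  length = out_len, stringsAsFactors = FALSE),
               polylines = out_poly,
               roots = sort(unique(out_id[out_root])),
               validate = FALSE)
}

#' Count vessel junctions
#'
#' A junction is a node of graph-degree >= 3 after canonicalization, the
#' reproducible counterpart of the visually counted branch points.
#'
#' @param graph a canonical [vessel_graph()].
#' @return nonnegative integer.
#' @export
count_junctions <- function(graph) {
  sum(node_degrees(graph) >= 3L)
}

#' Total, segment count and mean vessel length
#'
#' @param graph a canonical [vessel_graph()].
#' @return list with `total_length` (um), `segments`, `mean_length` (um;
#'   `NA` for an empty graph).
#' @export
length_metrics <- function(graph) {
  n <- nrow(graph$edges)
  tot <- sum(graph$edges$length)
  list(total_length = tot, segments = n,
       mean_length = if (n > 0L) tot / n else NA_real_)
}

#' Ring region of interest
#'
#' The plastic ring placed on the CAM delimits the scored region.  Radii are
#' in micrometres; the area is reported in mm^2 (1 mm^2 = 1e6 um^2).
#'
#' @param center numeric length-2, ring center (um).
#' @param inner_radius inner radius in um (0 for a full disk).
#' @param outer_radius outer radius in um; must exceed `inner_radius`.
#' @return object of class `ring_roi` with fields `center`, `inner_radius`,
#'   `outer_radius` and `area` (mm^2).
#' @export
ring_roi <- function(center = c(0, 0), inner_radius = 0, outer_radius) {
  if (!(is.numeric(outer_radius) && outer_radius > inner_radius && inner_radius >= 0))
    cam_abort("ring ROI requires outer_radius > inner_radius >= 0", "camAAI_invalid_roi")
  structure(list(center = as.numeric(center),
                 inner_radius = as.numeric(inner_radius),
                 outer_radius = as.numeric(outer_radius),
                 area = pi * (outer_radius^2 - inner_radius^2) / 1e6),
            class = "ring_roi")
}

#' @export
print.ring_roi <- function(x, ...) {
  cat("<ring_roi> center (", x$center[1], ", ", x$center[2], ") um, radii ",
      x$inner_radius, "-", x$outer_radius, " um, area ",
      format(x$area, digits = 6), " mm^2\n", sep = "")
  invisible(x)
}

#' Vessel density
#'
#' Defined as total vessel length per unit ROI area, in um of vessel per
#' mm^2 — the standard morphometric convention adopted by this package
#' (recorded in the output metadata of [build_angiogenic_profile()]).
#'
#' @param graph a canonical [vessel_graph()] lying inside the ROI.
#' @param roi a [ring_roi()].
#' @return density in um/mm^2.
#' @export
vessel_density <- function(graph, roi) {
  stopifnot(inherits(roi, "ring_roi"))
  if (!is.finite(roi$area) || roi$area <= 0)
    cam_abort("ROI has zero or invalid area", "camAAI_invalid_roi")
  sum(graph$edges$length) / roi$area
}

resolve_roots <- function(graph, roots = NULL, roi = NULL, boundary_tol = 0.01) {
  roots <- intersect((roots %||% graph$roots), graph$edges$id)
  if (length(roots)) return(roots)
  if (nrow(graph$edges) == 0L) return(character())
  if (!is.null(roi)) {
    # fallback 1: segments touching the ROI outer boundary are feeders
    thr <- roi$outer_radius * (1 - boundary_tol)
    hit <- vapply(graph$polylines, function(p) {
      r <- sqrt((p[, 1L] - roi$center[1L])^2 + (p[, 2L] - roi$center[2L])^2)
      any(r >= thr)
    }, NA)
    if (any(hit)) return(graph$edges$id[hit])
  }
  # fallback 2: longest segment
  graph$edges$id[which.max(graph$edges$length)]
}

#' Assign branch degrees (generation order) to vessel segments
#'
#' Branch degree is the generation order along a breadth-first traversal of
#' segments from designated root (feeder) segments: roots have degree 1, a
#' segment's degree is its predecessor's degree plus one, capped at
#' `max_degree` (first- to fourth-degree sprouts are scored).  Ties in the
#' traversal are broken by ascending edge id, so the assignment is
#' deterministic.
#'
#' When `roots` is empty the fallback is applied: segments whose polyline
#' touches the ROI outer boundary (within `boundary_tol`, a fraction of the
#' outer radius) are taken as roots; if none touch it, the longest segment
#' is.  Segments in components unreachable from any root raise a warning and
#' receive `max_degree` (the smallest-vessel class) so that branch counts
#' still sum to the segment count.
#'
#' @param graph a canonical [vessel_graph()].
#' @param roots character vector of root edge ids; defaults to
#'   `graph$roots`.
#' @param roi optional [ring_roi()] enabling the boundary fallback.
#' @param max_degree cap on the branching degree (default 4).
#' @param boundary_tol boundary detection tolerance (fraction of the outer
#'   radius).
#' @return named integer vector mapping edge id to degree in
#'   `1:max_degree`.
#' @export
assign_branch_degrees <- function(graph, roots = NULL, roi = NULL,
                                  max_degree = 4L, boundary_tol = 0.01) {
  ne <- nrow(graph$edges)
  if (ne == 0L) return(setNames(integer(), character()))
  ids <- graph$edges$id
  roots <- resolve_roots(graph, roots, roi, boundary_tol)
  if (!length(roots))
    cam_abort("no root segments available for branch-degree assignment",
              "camAAI_schema_error")
  inc <- node_incidence(graph)
  from <- graph$edges$from; to <- graph$edges$to
  degree <- setNames(rep.int(NA_integer_, ne), ids)
  queue <- sort(match(roots, ids))
  degree[queue] <- 1L
  qpos <- 1L
  while (qpos <= length(queue)) {
    e <- queue[qpos]; qpos <- qpos + 1L
    nb <- c(inc[[from[e]]], inc[[to[e]]])
    nb <- nb[is.na(degree[nb])]
    if (length(nb)) {
      nb <- unique(nb[order(ids[nb])])
      degree[nb] <- min(degree[e] + 1L, max_degree)
      queue <- c(queue, nb)
    }
  }
  if (anyNA(degree)) {
    warning("disconnected network: ", sum(is.na(degree)),
            " segment(s) unreachable from roots assigned degree ", max_degree,
            call. = FALSE)
    degree[is.na(degree)] <- max_degree
  }
  degree
}

#' Branch hierarchy ratio
#'
#' The ratio of third- and fourth-degree branch counts to first- and
#' second-degree branch counts, summarizing how much of the network sits in
#' the finer generations.  Undefined (returns `NA`) when no first- or
#' second-degree branches exist.
#'
#' @param branch_counts numeric vector of length 4 of nonnegative counts for
#'   degrees 1 to 4.
#' @return nonnegative number, or `NA` when the denominator is zero.
#' @export
hierarchy_ratio <- function(branch_counts) {
  stopifnot(length(branch_counts) == 4L, all(branch_counts >= 0))
  den <- branch_counts[1L] + branch_counts[2L]
  if (den == 0) return(NA_real_)
  (branch_counts[3L] + branch_counts[4L]) / den
}

#' Construct a per-embryo vessel-metrics record
#'
#' @param junctions,segments nonnegative integer counts.
#' @param total_length_um,mean_length_um lengths in um (`mean_length_um` is
#'   `NA` when `segments` is 0).
#' @param density_um_per_mm2 vessel density (um/mm^2).
#' @param branch_counts length-4 vector of branch counts for degrees 1-4,
#'   or `NULL` when degrees were not assigned.
#' @param hierarchy_ratio see [hierarchy_ratio()].
#' @param validate check the record invariants.
#' @return object of class `vessel_metrics`.
#' @export
vessel_metrics <- function(junctions, segments, total_length_um, mean_length_um,
                           density_um_per_mm2, branch_counts = NULL,
                           hierarchy_ratio = NA_real_, validate = TRUE) {
  m <- structure(list(junctions = as.integer(junctions),
                      segments = as.integer(segments),
                      total_length_um = as.numeric(total_length_um),
                      mean_length_um = as.numeric(mean_length_um),
                      density_um_per_mm2 = as.numeric(density_um_per_mm2),
                      branch_counts = if (is.null(branch_counts)) NULL else
                        as.integer(branch_counts),
                      hierarchy_ratio = as.numeric(hierarchy_ratio)),
                 class = "vessel_metrics")
  if (validate) {
    stopifnot(m$junctions >= 0L, m$segments >= 0L, m$total_length_um >= 0)
    if (!is.null(m$branch_counts) && sum(m$branch_counts) != m$segments)
      cam_abort("branch counts must sum to the segment count", "camAAI_schema_error")
    if (m$segments > 0L) {
      rel <- abs(m$mean_length_um * m$segments - m$total_length_um) /
        max(m$total_length_um, .Machine$double.eps)
      if (rel > 1e-9)
        cam_abort("mean length times segment count must equal total length",
                  "camAAI_schema_error")
    }
  }
  m
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat("<vessel_metrics> junctions ", x$junctions, ", segments ", x$segments,
      ", total ", format(x$total_length_um, digits = 6), " um, density ",
      format(x$density_um_per_mm2, digits = 6), " um/mm^2", sep = "")
  if (!is.null(x$branch_counts))
    cat(", branches (", paste(x$branch_counts, collapse = ", "), "), hierarchy ",
        format(x$hierarchy_ratio, digits = 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Compute all vessel-network morphometrics for one embryo and day
#'
#' Canonicalizes the graph and composes [count_junctions()],
#' [length_metrics()], [vessel_density()], [assign_branch_degrees()] and
#' [hierarchy_ratio()] into a single [vessel_metrics()] record.
#'
#' @inheritParams assign_branch_degrees
#' @param roi a [ring_roi()] containing the network.
#' @return a [vessel_metrics()] record.
#' @export
#' @examples
#' nodes <- data.frame(id = c("a", "b", "c", "d"),
#'                     x = c(0, 100, 150, 150), y = c(0, 0, 40, -40))
#' edges <- data.frame(id = c("e1", "e2", "e3"),
#'                     from = c("a", "b", "b"), to = c("b", "c", "d"))
#' g <- vessel_graph(nodes, edges, roots = "e1")
#' compute_metrics(g, ring_roi(outer_radius = 1000))
compute_metrics <- function(graph, roi, roots = NULL, max_degree = 4L,
                            boundary_tol = 0.01) {
  # designate roots before canonicalization so that chain merging carries
  # root membership onto the merged segment
  if (!is.null(roots)) graph$roots <- roots
  g <- canonicalize(graph)
  lm <- length_metrics(g)
  dens <- vessel_density(g, roi)
  if (lm$segments == 0L)
    return(vessel_metrics(0L, 0L, 0, NA_real_, 0,
                          branch_counts = c(0L, 0L, 0L, 0L),
                          hierarchy_ratio = NA_real_, validate = FALSE))
  degs <- assign_branch_degrees(g, roots = NULL, roi = roi,
                                max_degree = max_degree,
                                boundary_tol = boundary_tol)
  bc <- tabulate(degs, nbins = max_degree)
  vessel_metrics(junctions = count_junctions(g),
                 segments = lm$segments,
                 total_length_um = lm$total_length,
                 mean_length_um = lm$mean_length,
                 density_um_per_mm2 = dens,
                 branch_counts = bc,
                 hierarchy_ratio = hierarchy_ratio(bc))
}
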