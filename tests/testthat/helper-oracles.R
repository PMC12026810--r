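# Independent brute-force oracles and fixture builders.  Everything here is
# deliberately naive and shares no code with the package implementation.

# --- brute-force vessel morphometrics ---------------------------------------

pick1 <- function(x) x[sample.int(length(x), 1L)]

bf_polyline_length <- function(p) {
  tot <- 0
  for (i in seq_len(nrow(p) - 1L))
    tot <- tot + sqrt((p[i + 1L, 1L] - p[i, 1L])^2 + (p[i + 1L, 2L] - p[i, 2L])^2)
  tot
}

# merge degree-2 chains one node at a time (quadratic, obviously correct);
# root membership survives merging
bf_canonical <- function(edges, polylines, roots = character()) {
  repeat {
    ends <- c(edges$from, edges$to)
    deg <- table(ends)
    cand <- names(deg)[deg == 2L]
    merged <- FALSE
    for (v in cand) {
      inc <- which(edges$from == v | edges$to == v)
      if (length(inc) != 2L) next
      a <- inc[1L]; b <- inc[2L]
      oa <- if (edges$from[a] == v) edges$to[a] else edges$from[a]
      ob <- if (edges$from[b] == v) edges$to[b] else edges$from[b]
      if (oa == ob) next   # merging would create a self-loop; keep both arcs
      pa <- polylines[[a]]
      if (edges$to[a] != v) pa <- pa[rev(seq_len(nrow(pa))), , drop = FALSE]
      pb <- polylines[[b]]
      if (edges$from[b] != v) pb <- pb[rev(seq_len(nrow(pb))), , drop = FALSE]
      newp <- rbind(pa, pb[-1L, , drop = FALSE])
      if (edges$id[b] %in% roots) roots <- union(roots, edges$id[a])
      edges$from[a] <- oa; edges$to[a] <- ob
      polylines[[a]] <- newp
      edges <- edges[-b, , drop = FALSE]
      polylines <- polylines[-b]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  list(edges = edges, polylines = polylines, roots = intersect(roots, edges$id))
}

bf_junctions <- function(edges) {
  deg <- table(c(edges$from, edges$to))
  sum(deg >= 3L)
}

# branch degrees by fixed-point relaxation of hop distance from the roots
bf_branch_degrees <- function(edges, root_ids, cap = 4L) {
  n <- nrow(edges)
  d <- rep(Inf, n)
  d[edges$id %in% root_ids] <- 1L
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      share <- length(intersect(c(edges$from[i], edges$to[i]),
                                c(edges$from[j], edges$to[j]))) > 0L
      if (share && d[i] + 1 < d[j]) { d[j] <- d[i] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  d[!is.finite(d)] <- cap
  pmin(d, cap)
}

bf_metrics <- function(graph, roi, root_ids = graph$roots) {
  can <- bf_canonical(graph$edges, graph$polylines, root_ids)
  lens <- vapply(can$polylines, bf_polyline_length, 0)
  n <- nrow(can$edges)
  degs <- if (n) bf_branch_degrees(can$edges, can$roots) else integer()
  bc <- tabulate(degs, 4L)
  list(junctions = bf_junctions(can$edges),
       segments = n,
       total_length = sum(lens),
       mean_length = if (n) sum(lens) / n else NA_real_,
       density = sum(lens) / roi$area,
       branch_counts = bc,
       hierarchy = if (bc[1L] + bc[2L] > 0)
         (bc[3L] + bc[4L]) / (bc[1L] + bc[2L]) else NA_real_)
}

# --- random vessel-graph fixtures -------------------------------------------

# random tree with multi-point polylines plus inserted degree-2 nodes
random_vessel_graph <- function(n_segments = 10L, n_split = 3L, radius = 800) {
  nid <- function(i) sprintf("n%03d", i)
  eid <- function(i) sprintf("e%03d", i)
  nx <- runif(1, -radius, radius); ny <- runif(1, -radius, radius)
  nodes <- data.frame(id = nid(1L), x = nx, y = ny, stringsAsFactors = FALSE)
  edges <- data.frame(id = character(), from = character(), to = character(),
                      stringsAsFactors = FALSE)
  polylines <- list()
  for (i in seq_len(n_segments)) {
    at <- pick1(seq_len(nrow(nodes)))
    newx <- nodes$x[at] + runif(1, -150, 150)
    newy <- nodes$y[at] + runif(1, -150, 150)
    nodes <- rbind(nodes, data.frame(id = nid(nrow(nodes) + 1L),
                                     x = newx, y = newy))
    k <- pick1(0:2)
    mid <- if (k > 0)
      cbind(seq(nodes$x[at], newx, length.out = k + 2L)[2:(k + 1L)] + runif(k, -20, 20),
            seq(nodes$y[at], newy, length.out = k + 2L)[2:(k + 1L)] + runif(k, -20, 20))
    p <- rbind(c(nodes$x[at], nodes$y[at]), mid, c(newx, newy))
    id <- eid(i)
    edges <- rbind(edges, data.frame(id = id, from = nodes$id[at],
                                     to = nodes$id[nrow(nodes)]))
    polylines[[id]] <- p
  }
  # split some edges at an interior polyline vertex -> degree-2 nodes
  for (s in seq_len(n_split)) {
    cand <- which(vapply(polylines[edges$id], nrow, 0L) >= 3L)
    if (!length(cand)) break
    i <- pick1(cand)
    p <- polylines[[edges$id[i]]]
    cut <- pick1(2:(nrow(p) - 1L))
    vid <- nid(nrow(nodes) + 1L)
    nodes <- rbind(nodes, data.frame(id = vid, x = p[cut, 1L], y = p[cut, 2L]))
    id2 <- eid(nrow(edges) + 1L)
    polylines[[id2]] <- p[cut:nrow(p), , drop = FALSE]
    edges <- rbind(edges, data.frame(id = id2, from = vid, to = edges$to[i]))
    edges$to[i] <- vid
    polylines[[edges$id[i]]] <- p[1:cut, , drop = FALSE]
  }
  roots <- edges$id[pick1(seq_len(nrow(edges)))]
  vessel_graph(nodes, edges, polylines, roots = roots)
}

# --- survival oracles --------------------------------------------------------

# hand product-limit estimator
bf_km <- function(time, status) {
  tt <- sort(unique(time[status == 1]))
  s <- 1; out <- numeric(0)
  for (t in tt) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  list(time = tt, surv = out)
}

bf_km_at <- function(time, status, day) {
  km <- bf_km(time, status)
  idx <- which(km$time <= day)
  if (!length(idx)) 1 else km$surv[max(idx)]
}

# hand Mantel-Cox statistic
bf_logrank <- function(t1, s1, t2, s2) {
  time <- c(t1, t2); status <- c(s1, s2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  tt <- sort(unique(time[status == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in tt) {
    n <- sum(time >= t); n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O1 - E1)^2 / V
}

# --- deterministic cohort fixtures ------------------------------------------

# one metrics row with internally consistent derived columns
fixture_metrics_row <- function(embryo_id, group, day, junctions, total_length,
                                bc, area_mm2 = 1) {
  segments <- sum(bc)
  data.frame(embryo_id = embryo_id, group = group, day = day,
             junctions = junctions, segments = segments,
             total_length_um = total_length,
             mean_length_um = total_length / segments,
             density_um_per_mm2 = total_length / area_mm2,
             n1 = bc[1], n2 = bc[2], n3 = bc[3], n4 = bc[4],
             hierarchy_ratio = (bc[3] + bc[4]) / (bc[1] + bc[2]),
             stringsAsFactors = FALSE)
}

# cohort in which every baseline-corrected treatment response is exactly
# double the control's, in every scored parameter (17 embryos per group,
# one control death and two treatment deaths at day 4)
make_doubling_cohort <- function(n = 17L) {
  specs <- list(
    control = list(j = c(16, 17, 18, 20), L = c(1024, 1088, 1152, 1280),
                   bc = list(c(2, 2, 1, 1), c(2, 2, 1, 2), c(2, 2, 2, 2), c(2, 2, 2, 2)),
                   deaths = 1L, thick = 50),
    treatment = list(j = c(16, 18, 20, 24), L = c(1024, 1152, 1280, 1536),
                     bc = list(c(2, 2, 1, 1), c(2, 2, 2, 2), c(2, 2, 3, 3), c(2, 2, 3, 3)),
                     deaths = 2L, thick = 100))
  days <- c(0, 2, 4, 7)
  mrows <- list(); srows <- list(); trows <- list()
  for (g in names(specs)) {
    sp <- specs[[g]]
    for (i in seq_len(n)) {
      eid <- sprintf("%s-%02d", g, i)
      dead <- i > n - sp$deaths            # these die at day 4
      drange <- if (dead) 1:2 else 1:4
      for (k in drange)
        mrows[[length(mrows) + 1L]] <-
          fixture_metrics_row(eid, g, days[k], sp$j[k], sp$L[k], sp$bc[[k]])
      srows[[length(srows) + 1L]] <- data.frame(
        embryo_id = eid, group = g,
        last_day_alive = if (dead) 4 else 7,
        status = if (dead) 1L else 0L, stringsAsFactors = FALSE)
      if (!dead)
        trows[[length(trows) + 1L]] <- data.frame(
          embryo_id = eid, group = g, thickness_um = sp$thick,
          stringsAsFactors = FALSE)
    }
  }
  cohort_dataset(do.call(rbind, mrows), do.call(rbind, srows),
                 do.call(rbind, trows), control = "control")
}

# tiny Y-shaped graph: 100 um root splitting into two 50 um children
make_y_graph <- function() {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 100, 100 + 50 * cos(0.6), 100 + 50 * cos(-0.6)),
                      y = c(0, 0, 50 * sin(0.6), 50 * sin(-0.6)))
  edges <- data.frame(id = c("e1", "e2", "e3"),
                      from = c("a", "b", "b"), to = c("b", "c", "d"))
  vessel_graph(nodes, edges, roots = "e1")
}
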