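# Vessel-network morphometrics: canonicalization, junctions, lengths,
# density, branch degrees and the composed metrics record.

test_that("canonicalization merges degree-2 chains and conserves length", {
  nodes <- data.frame(id = c("A", "B", "C"), x = c(0, 3, 3), y = c(0, 0, 4))
  edges <- data.frame(id = c("e1", "e2"), from = c("A", "B"), to = c("B", "C"))
  g <- canonicalize(vessel_graph(nodes, edges))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length, 7)
  expect_setequal(c(g$edges$from, g$edges$to), c("A", "C"))
  expect_equal(g$edges$id, "e1")
  # polyline keeps the interior geometry
  expect_equal(nrow(g$polylines[[1]]), 3L)
})

test_that("canonicalization is idempotent and keeps already-canonical graphs", {
  y <- make_y_graph()
  g1 <- canonicalize(y)
  expect_equal(g1$edges[order(g1$edges$id), ], y$edges[order(y$edges$id), ])
  g2 <- canonicalize(g1)
  expect_identical(g1$edges, g2$edges)

  set.seed(42)
  for (i in 1:10) {
    g <- random_vessel_graph(n_segments = sample(5:20, 1))
    c1 <- canonicalize(g)
    c2 <- canonicalize(c1)
    expect_equal(c1$edges[order(c1$edges$id), ], c2$edges[order(c2$edges$id), ])
    expect_equal(sum(c1$edges$length), sum(g$edges$length), tolerance = 1e-12)
    expect_false(any(c1$edges$from == c1$edges$to))
    expect_equal(count_junctions(c1), count_junctions(g))
  }
})

test_that("degree-2 node insertion does not change any metric", {
  roi <- ring_roi(outer_radius = 2000)
  set.seed(7)
  for (i in 1:10) {
    g <- random_vessel_graph(n_segments = 10L, n_split = 5L)
    # the same network without the splits, rebuilt by canonicalization
    ref <- canonicalize(g)
    m1 <- compute_metrics(g, roi, roots = g$roots)
    m2 <- compute_metrics(ref, roi, roots = ref$roots)
    expect_identical(m1$junctions, m2$junctions)
    expect_identical(m1$segments, m2$segments)
    expect_equal(m1$total_length_um, m2$total_length_um, tolerance = 1e-12)
  }
})

test_that("junction counting matches enumerated node degrees", {
  nodes <- data.frame(id = "a", x = 0, y = 0)
  edges <- data.frame(id = character(), from = character(), to = character())
  expect_equal(count_junctions(canonicalize(vessel_graph())), 0L)
  # single segment
  g <- vessel_graph(data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 0)),
                    data.frame(id = "e1", from = "a", to = "b"))
  expect_equal(count_junctions(g), 0L)
  expect_equal(count_junctions(make_y_graph()), 1L)
  # binary tree with 7 segments: root + 3 branchings -> 3 junctions
  nodes <- data.frame(id = letters[1:8],
                      x = c(0, 1, 2, 2, 3, 3, 3, 3),
                      y = c(0, 0, 1, -1, 1.5, 0.5, -0.5, -1.5))
  edges <- data.frame(id = paste0("e", 1:7),
                      from = c("a", "b", "b", "c", "c", "d", "d"),
                      to = c("b", "c", "d", "e", "f", "g", "h"))
  expect_equal(count_junctions(vessel_graph(nodes, edges)), 3L)
})

test_that("length metrics sum segments and handle the empty graph", {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 100, 300, 600), y = 0)
  edges <- data.frame(id = c("e1", "e2", "e3"),
                      from = c("a", "b", "c"), to = c("b", "c", "d"))
  # three disconnected-by-id segments would merge; use a star instead
  edges <- data.frame(id = c("e1", "e2", "e3"),
                      from = c("a", "a", "a"), to = c("b", "c", "d"))
  g <- vessel_graph(nodes, edges)
  lm <- length_metrics(g)
  expect_equal(lm$total_length, 100 + 300 + 600)
  expect_equal(lm$segments, 3L)
  expect_equal(lm$mean_length, 1000 / 3)
  lm0 <- length_metrics(vessel_graph())
  expect_equal(lm0$total_length, 0)
  expect_equal(lm0$segments, 0L)
  expect_true(is.na(lm0$mean_length))
})

test_that("vessel density is total length over ROI area and is homogeneous", {
  roi <- ring_roi(outer_radius = sqrt(2e6 / pi))   # 2 mm^2
  expect_equal(roi$area, 2, tolerance = 1e-12)
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1000), y = 0)
  g <- vessel_graph(nodes, data.frame(id = "e1", from = "a", to = "b"))
  expect_equal(vessel_density(g, roi), 500)
  expect_equal(vessel_density(vessel_graph(), roi), 0)
  # doubling every length doubles density
  g2 <- vessel_graph(data.frame(id = c("a", "b"), x = c(0, 2000), y = 0),
                     data.frame(id = "e1", from = "a", to = "b"))
  expect_equal(vessel_density(g2, roi), 2 * vessel_density(g, roi))
})

test_that("ring ROI validates geometry and area conversion", {
  roi <- ring_roi(c(0, 0), 1000, 3000)
  expect_equal(roi$area, pi * (3000^2 - 1000^2) / 1e6, tolerance = 1e-12)
  expect_error(ring_roi(c(0, 0), 3000, 3000), class = "camAAI_invalid_roi")
  expect_error(ring_roi(c(0, 0), -1, 3000), class = "camAAI_invalid_roi")
})

test_that("branch degrees follow generation order with a cap of four", {
  y <- make_y_graph()
  expect_equal(unname(assign_branch_degrees(y)[c("e1", "e2", "e3")]), c(1, 2, 2))
  # linear chain of 6 segments from a root, each a new generation: degrees
  # 1,2,3,4,4,4 -- built as a caterpillar so no chain merging applies
  nodes <- data.frame(id = c(paste0("n", 0:6), paste0("s", 1:6)),
                      x = c(0:6, 1:6 + 0.1), y = c(rep(0, 7), rep(1, 6)))
  edges <- rbind(
    data.frame(id = paste0("e", 1:6), from = paste0("n", 0:5), to = paste0("n", 1:6)),
    data.frame(id = paste0("t", 1:6), from = paste0("n", 1:6), to = paste0("s", 1:6)))
  g <- vessel_graph(nodes, edges, roots = "e1")
  deg <- assign_branch_degrees(g)
  expect_equal(unname(deg[paste0("e", 1:6)]), c(1, 2, 3, 4, 4, 4))

  # balanced binary tree of depth 5: generation counts with cap match the
  # brute-force relaxation oracle
  nid <- 0L
  nodes <- data.frame(id = "r", x = 0, y = 0)
  edges <- data.frame(id = character(), from = character(), to = character())
  level <- data.frame(id = "r", x = 0, y = 0)
  for (d in 1:5) {
    nxt <- list()
    for (i in seq_len(nrow(level))) {
      for (s in c(-1, 1)) {
        nid <- nid + 1L
        child <- data.frame(id = sprintf("v%03d", nid),
                            x = level$x[i] + 1, y = 2 * level$y[i] + s / d)
        nodes <- rbind(nodes, child)
        edges <- rbind(edges, data.frame(id = sprintf("e%03d", nid),
                                         from = level$id[i], to = child$id))
        nxt[[length(nxt) + 1L]] <- child
      }
    }
    level <- do.call(rbind, nxt)
  }
  g <- vessel_graph(nodes, edges, roots = c("e001", "e002"))
  deg <- assign_branch_degrees(g)
  oracle <- bf_branch_degrees(g$edges, g$roots)
  expect_equal(unname(deg[g$edges$id]), oracle)
  expect_equal(tabulate(deg, 4), tabulate(oracle, 4))
})

test_that("unreachable components warn and land in the smallest-vessel class", {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 100, 500, 600), y = 0)
  edges <- data.frame(id = c("e1", "e2"), from = c("a", "c"), to = c("b", "d"))
  g <- vessel_graph(nodes, edges, roots = "e1")
  expect_warning(deg <- assign_branch_degrees(g), "disconnected")
  expect_equal(unname(deg[c("e1", "e2")]), c(1, 4))
  expect_equal(sum(tabulate(deg, 4)), nrow(g$edges))
})

test_that("root fallback uses the ROI boundary, then the longest segment", {
  roi <- ring_roi(outer_radius = 1000)
  # feeder touching the boundary
  nodes <- data.frame(id = c("a", "b", "c"), x = c(1000, 600, 200), y = 0)
  edges <- data.frame(id = c("e2", "e1"), from = c("a", "b"), to = c("b", "c"))
  g <- vessel_graph(nodes, edges, roots = character())
  deg <- suppressWarnings(assign_branch_degrees(g, roi = roi))
  expect_equal(unname(deg[c("e2", "e1")]), c(1, 2))
  # no boundary contact: longest segment becomes the root
  nodes2 <- data.frame(id = c("a", "b", "c"), x = c(500, 100, 50), y = 0)
  g2 <- vessel_graph(nodes2, edges, roots = character())
  deg2 <- assign_branch_degrees(g2, roi = roi)
  expect_equal(unname(deg2[c("e2", "e1")]), c(1, 2))
})

test_that("hierarchy ratio is (n3+n4)/(n1+n2) with an undefined flag", {
  expect_equal(hierarchy_ratio(c(2, 4, 6, 8)), 14 / 6)
  expect_equal(hierarchy_ratio(c(1, 1, 0, 0)), 0)
  expect_true(is.na(hierarchy_ratio(c(0, 0, 3, 3))))
})

test_that("compute_metrics composes the parts (hand-checked Y graph)", {
  roi <- ring_roi(outer_radius = sqrt(1e6 / pi))   # 1 mm^2
  m <- compute_metrics(make_y_graph(), roi)
  expect_equal(m$junctions, 1L)
  expect_equal(m$segments, 3L)
  expect_equal(m$total_length_um, 200)
  expect_equal(m$mean_length_um, 200 / 3)
  expect_equal(m$density_um_per_mm2, 200, tolerance = 1e-9)
  expect_equal(m$branch_counts, c(1L, 2L, 0L, 0L))
  expect_equal(m$hierarchy_ratio, 0)

  m0 <- compute_metrics(vessel_graph(), roi)
  expect_equal(m0$junctions, 0L)
  expect_equal(m0$segments, 0L)
  expect_equal(m0$total_length_um, 0)
  expect_true(is.na(m0$mean_length_um))
  expect_true(is.na(m0$hierarchy_ratio))
})

test_that("compute_metrics agrees with the brute-force oracle on random graphs", {
  roi <- ring_roi(outer_radius = 3000)
  set.seed(101)
  for (i in 1:30) {
    g <- random_vessel_graph(n_segments = sample(5:25, 1),
                             n_split = sample(0:5, 1))
    m <- compute_metrics(g, roi, roots = g$roots)
    o <- bf_metrics(g, roi)
    expect_identical(m$junctions, as.integer(o$junctions))
    expect_identical(m$segments, as.integer(o$segments))
    expect_equal(m$total_length_um, o$total_length, tolerance = 1e-9)
    expect_equal(m$density_um_per_mm2, o$density, tolerance = 1e-9)
    expect_equal(m$branch_counts, as.integer(o$branch_counts))
    expect_equal(sum(m$branch_counts), m$segments)
    expect_equal(m$mean_length_um * m$segments, m$total_length_um,
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant under rigid motion of the coordinates", {
  roi <- ring_roi(outer_radius = 3000)
  set.seed(11)
  g <- random_vessel_graph(n_segments = 15L, n_split = 3L)
  theta <- 0.73; shift <- c(120, -340)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  nodes2 <- g$nodes
  xy <- as.matrix(g$nodes[, c("x", "y")]) %*% t(rot)
  nodes2$x <- xy[, 1L] + shift[1L]; nodes2$y <- xy[, 2L] + shift[2L]
  poly2 <- lapply(g$polylines, function(p)
    sweep(p %*% t(rot), 2L, -shift))
  g2 <- vessel_graph(nodes2, g$edges[, c("id", "from", "to")], poly2,
                     roots = g$roots)
  m1 <- compute_metrics(g, roi, roots = g$roots)
  m2 <- compute_metrics(g2, roi, roots = g$roots)
  expect_identical(m1$junctions, m2$junctions)
  expect_identical(m1$branch_counts, m2$branch_counts)
  expect_equal(m1$total_length_um, m2$total_length_um, tolerance = 1e-6)
  expect_equal(m1$mean_length_um, m2$mean_length_um, tolerance = 1e-6)
})

test_that("vessel_graph validation rejects malformed input", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 0))
  expect_error(vessel_graph(nodes, data.frame(id = "e1", from = "a", to = "z")),
               class = "camAAI_schema_error")
  expect_error(vessel_graph(nodes, data.frame(id = "e1", from = "a", to = "a")),
               class = "camAAI_schema_error")
  expect_error(
    vessel_graph(nodes, data.frame(id = "e1", from = "a", to = "b", length = 5)),
    class = "camAAI_schema_error")  # stated length disagrees with polyline
})
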