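# Synthetic cohort generator and its closed-form oracle.

small_config <- function(...) {
  simulation_config(n_embryos = 5L, n_roots = 3L,
                    gen_lengths_um = c(300, 220, 160), ...)
}

test_that("zero sprouting freezes the network across days", {
  cfg <- simulation_config(groups = data.frame(
    name = c("control", "frozen"), sprout_mult = c(1, 0),
    elong_mult = c(1, 0), thickness_shift_um = c(0, 0),
    hazard = c(0, 0)), n_embryos = 2L, seed = 5L)
  g <- simulate_vessel_timecourse(cfg, "frozen", seed = 77L)
  expect_identical(g[["0"]]$edges, g[["7"]]$edges)
  expect_identical(g[["0"]]$nodes, g[["7"]]$nodes)
})

test_that("the time course is deterministic per seed and nested over days", {
  cfg <- simulation_config()
  g1 <- simulate_vessel_timecourse(cfg, "treatment-A", seed = 123L)
  g2 <- simulate_vessel_timecourse(cfg, "treatment-A", seed = 123L)
  expect_identical(g1, g2)
  # nesting: every earlier edge persists with identical geometry
  for (k in 1:3) {
    a <- g1[[k]]$edges; b <- g1[[k + 1L]]$edges
    expect_true(all(a$id %in% b$id))
    expect_identical(a, b[seq_len(nrow(a)), ])
  }
})

test_that("day-0 networks realize the deterministic base morphometry", {
  cfg <- simulation_config()
  g0 <- simulate_vessel_timecourse(cfg, "control", seed = 9L)[["0"]]
  m <- compute_metrics(g0, cfg$roi)
  base <- camAAI:::base_network_summary(cfg)
  expect_identical(m$segments, as.integer(base$S0))
  expect_identical(m$junctions, as.integer(base$J0))
  expect_equal(m$total_length_um, base$L0, tolerance = 1e-9)
  expect_equal(m$branch_counts, as.integer(base$n0))
})

test_that("generator branch generations agree with the BFS degree assignment", {
  cfg <- small_config(seed = 31L)
  gs <- simulate_vessel_timecourse(cfg, "treatment-B", seed = 31L)
  g7 <- gs[["7"]]
  deg <- assign_branch_degrees(canonicalize(g7))
  o <- bf_metrics(g7, cfg$roi)
  expect_equal(tabulate(deg, 4), o$branch_counts)
})

test_that("control junction fold change matches the closed-form mean", {
  cfg <- simulation_config()
  eo <- expected_outcome(cfg)
  expected <- eo$ar$expected_ar[eo$ar$group == "control" &
                                  eo$ar$parameter == "junctions"]
  n <- 120L
  fcs <- vapply(seq_len(n), function(i) {
    g <- simulate_vessel_timecourse(cfg, "control", seed = 5000L + i)
    j0 <- count_junctions(g[["0"]]); j7 <- count_junctions(g[["7"]])
    j7 / j0
  }, 0)
  se <- sd(fcs) / sqrt(n)
  expect_lt(abs(mean(fcs) - expected), 3 * se)
})

test_that("moment recursion matches exact enumeration of the tip process", {
  # brute-force joint distribution of (T, C) over the observation intervals
  enum <- function(t0, rate, intervals) {
    states <- list(list(t = t0, c = 0, p = 1))
    for (delta in intervals) {
      q <- 1 - exp(-rate * delta)
      nxt <- list()
      for (s in states) for (b in 0:s$t) {
        p <- s$p * dbinom(b, s$t, q)
        if (p == 0) next
        key <- paste(s$t + b, s$c + b)
        if (is.null(nxt[[key]]))
          nxt[[key]] <- list(t = s$t + b, c = s$c + b, p = p)
        else nxt[[key]]$p <- nxt[[key]]$p + p
      }
      states <- nxt
    }
    cs <- vapply(states, `[[`, 0, "c")
    ps <- vapply(states, `[[`, 0, "p")
    list(EC = sum(cs * ps), VarC = sum(cs^2 * ps) - sum(cs * ps)^2)
  }
  for (rate in c(0.05, 0.3)) {
    ex <- enum(3, rate, c(2, 2, 3))
    mo <- camAAI:::tip_moments(3, rate, c(2, 2, 3))
    expect_equal(mo$EC, ex$EC, tolerance = 1e-12)
    expect_equal(mo$VarC, ex$VarC, tolerance = 1e-12)
  }
})

test_that("simulated cohorts satisfy the cohort and metrics invariants", {
  cfg <- small_config(seed = 8L)
  cfg$groups$hazard <- c(0.05, 0.05, 0.05)
  co <- simulate_cohort(cfg)
  expect_silent(camAAI:::validate_cohort(co))
  m <- co$metrics
  expect_true(all(m$n1 + m$n2 + m$n3 + m$n4 == m$segments))
  expect_equal(m$mean_length_um * m$segments, m$total_length_um,
               tolerance = 1e-9)
  expect_equal(m$density_um_per_mm2, m$total_length_um / cfg$roi$area,
               tolerance = 1e-9)
  # every embryo alive at day 0 has a day-0 record
  expect_setequal(unique(m$embryo_id[m$day == 0]), co$survival$embryo_id)
})

test_that("zero hazard keeps every embryo alive to the final day", {
  cfg <- small_config(seed = 21L)
  cfg$groups$hazard <- 0
  co <- simulate_cohort(cfg)
  expect_true(all(co$survival$status == 0L))
  expect_true(all(co$survival$last_day_alive == 7))
  expect_equal(nrow(co$thickness), nrow(co$survival))
})

test_that("cohort simulation is reproducible and embryo streams are stable", {
  cfg <- small_config(seed = 77L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$metrics, co2$metrics)
  expect_identical(co1$thickness, co2$thickness)
  # adding embryos must not perturb existing ones
  cfg2 <- cfg; cfg2$n_embryos <- cfg$n_embryos + 2L
  co3 <- simulate_cohort(cfg2)
  shared <- unique(co1$metrics$embryo_id)
  sub <- co3$metrics[co3$metrics$embryo_id %in% shared, ]
  rownames(sub) <- NULL; rownames(co1$metrics) <- NULL
  expect_equal(co1$metrics, sub)
})

test_that("expected outcome reproduces the definitional identities", {
  # identical groups -> ideal AAI 0 everywhere that is defined
  cfg <- simulation_config(groups = data.frame(
    name = c("control", "same"), sprout_mult = c(1, 1), elong_mult = c(1, 1),
    thickness_shift_um = c(0, 0), hazard = c(0.015, 0.015)))
  eo <- expected_outcome(cfg)
  expect_true(all(abs(eo$aai$ideal) < 1e-12))
  expect_equal(eo$final$expected_final_aai, 0, tolerance = 1e-12)
  # the default calibration reproduces the worked junction example
  eo2 <- expected_outcome(simulation_config())
  jA <- eo2$aai$ideal[eo2$aai$treatment == "treatment-A" &
                        eo2$aai$parameter == "junctions"]
  expect_equal(jA, 4.63, tolerance = 0.01)
  # zero hazard excludes the survival parameter, mirroring the pipeline
  cfg3 <- simulation_config()
  cfg3$groups$hazard <- 0
  eo3 <- expected_outcome(cfg3)
  expect_true("survival" %in% eo3$excluded$parameter)
  expect_true(all(is.na(eo3$aai$ideal[eo3$aai$parameter == "survival"])))
})

test_that("a doubled expected response in every parameter gives expected AAI 1", {
  # choose a treatment whose expected baseline-corrected change doubles the
  # control's: solve the sprouting rate for 2x expected bifurcations, set
  # elongation so the expected added length doubles, double the thickness
  # shift pathway and the death probability pathway
  cfg <- simulation_config()
  mo_c <- camAAI:::tip_moments(48, cfg$sprout_rate, diff(cfg$days))
  f <- function(m) camAAI:::tip_moments(48, cfg$sprout_rate * m,
                                        diff(cfg$days))$EC - 2 * mo_c$EC
  m2 <- uniroot(f, c(1, 10), tol = 1e-12)$root
  e2 <- mo_c$EC / camAAI:::tip_moments(48, cfg$sprout_rate * m2,
                                       diff(cfg$days))$EC * 2
  hz_c <- 0.015
  s_c <- (1 - hz_c)^7
  hz_t <- 1 - (2 * s_c - 1)^(1 / 7)       # S_t - 1 = 2 (S_c - 1)
  cfg$groups <- data.frame(
    name = c("control", "double"), sprout_mult = c(1, m2),
    elong_mult = c(1, e2), thickness_shift_um = c(0, cfg$thickness_base_um),
    hazard = c(hz_c, hz_t))
  eo <- expected_outcome(cfg)
  expect_equal(eo$aai$ideal, rep(1, 6), tolerance = 1e-9)
  expect_equal(eo$final$expected_final_aai, 1, tolerance = 1e-9)
})

test_that("identical-group cohorts score a final AAI distributed around zero", {
  cfg <- simulation_config(groups = data.frame(
    name = c("control", "null-treatment"), sprout_mult = c(1, 1),
    elong_mult = c(1, 1), thickness_shift_um = c(0, 0),
    hazard = c(0.015, 0.015)))
  finals <- vapply(1:60, function(s) {
    cfg$seed <- 40000L + s
    co <- simulate_cohort(cfg)
    suppressWarnings(build_angiogenic_profile(co, "null-treatment"))$final_aai
  }, 0)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals)), 3 * se)
})

test_that("cohort CSV bundles round-trip losslessly through the readers", {
  cfg <- small_config(seed = 15L)
  co <- simulate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort_csv(co, dir)
  co2 <- read_cohort_csv(dir)
  expect_equal(co2$metrics$junctions, co$metrics$junctions)
  expect_equal(co2$metrics$total_length_um,
               signif(co$metrics$total_length_um, 6L))
  expect_equal(as.numeric(co2$survival$last_day_alive),
               as.numeric(co$survival$last_day_alive))
  expect_equal(as.integer(co2$survival$status), as.integer(co$survival$status))
  # and the scoring pipeline accepts the re-read cohort
  pr <- suppressWarnings(build_angiogenic_profile(co2, "treatment-A"))
  expect_true(is.finite(pr$final_aai))
})
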