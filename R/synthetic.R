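# Synthetic CAM cohorts with closed-form expected outcomes.
#
# The growth model is a tip-bifurcation branching process, a deliberately
# simple stand-in for CAM neovascularization (not a biophysical model): the
# day-0 network is a deterministic radial arrangement of feeder trees
# (random in orientation only), and between observation days every terminal
# segment sprouts a bifurcation with probability 1 - exp(-rate x multiplier
# x elapsed days).  A bifurcation adds one junction, two child segments of
# log-normal length, and two new tips one generation deeper (capped at
# degree 4).  Because day-0 metrics are deterministic and growth increments
# are linear in the bifurcation count, every day-0-normalized fold change
# has an exact closed-form expectation - the analytic oracle used by the
# parameter-recovery tests.

#' Simulation configuration for synthetic CAM cohorts
#'
#' The default configuration emulates the study conditions of a 3-group CAM
#' experiment: a medium control plus two secretome treatments, 17 embryos
#' per group, observed on treatment days 0, 2, 4 and 7.  The default group
#' effect multipliers are calibration constants chosen so that the expected
#' day-7 fold changes bracket typical control/treated CAM responses
#' (junctions about 1.2 vs 2.1 and 2.5; total vessel length about 1.1 vs
#' 1.4); they live here in the config, not in code.
#'
#' @param groups data frame with columns `name`, `sprout_mult` (nonnegative
#'   sprouting hazard multiplier), `elong_mult` (nonnegative new-sprout
#'   length multiplier), `thickness_shift_um`, `hazard` (daily death hazard
#'   in `[0,1)`).
#'   Must contain a group named `control` with both multipliers 1 and zero
#'   thickness shift.
#' @param n_embryos embryos per group (default 17).
#' @param days observation days (default 0, 2, 4, 7).
#' @param n_roots number of first-degree feeder trees entering the ROI.
#' @param gen_lengths_um deterministic day-0 segment length per generation
#'   (um); its length sets the tree depth (>= 3 for the closed-form
#'   hierarchy expectation to hold).
#' @param sprout_rate per-tip daily sprouting hazard of the control group.
#' @param sprout_meanlog,sprout_sdlog log-normal parameters of new sprout
#'   lengths (um) before the group elongation multiplier.
#' @param branch_angle,angle_jitter bifurcation half-angle and its jitter SD
#'   (radians); geometry only, no effect on any scored metric.
#' @param thickness_base_um,thickness_sd_um final-day CAM thickness mean of
#'   the control group and common SD (normal, truncated at 0).
#' @param roi a [ring_roi()] delimiting the scored region.
#' @param seed integer seed; every embryo derives independent substreams
#'   (growth, death, thickness) from it, so adding embryos or groups does
#'   not perturb existing ones.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(groups = data.frame(
                                name = c("control", "treatment-A", "treatment-B"),
                                sprout_mult = c(1, 5.27, 7.46),
                                elong_mult = c(1, 0.60, 0.48),
                                thickness_shift_um = c(0, 17.2, 21.5),
                                hazard = c(0.015, 0.015, 0.015),
                                stringsAsFactors = FALSE),
                              n_embryos = 17L,
                              days = c(0, 2, 4, 7),
                              n_roots = 6L,
                              gen_lengths_um = c(400, 300, 220, 160),
                              sprout_rate = 0.0232,
                              sprout_meanlog = log(120),
                              sprout_sdlog = 0.35,
                              branch_angle = 0.5,
                              angle_jitter = 0.12,
                              thickness_base_um = 59,
                              thickness_sd_um = 8,
                              roi = ring_roi(c(0, 0), 0, 3000),
                              seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("name", "sprout_mult", "elong_mult", "thickness_shift_um",
                  "hazard") %in% names(groups)),
            n_embryos >= 1L, length(days) >= 2L, all(diff(days) > 0),
            days[1] == 0, n_roots >= 1L, length(gen_lengths_um) >= 3L,
            all(gen_lengths_um > 0), sprout_rate >= 0,
            all(groups$hazard >= 0 & groups$hazard < 1),
            all(groups$sprout_mult >= 0), all(groups$elong_mult >= 0),
            inherits(roi, "ring_roi"))
  ctrl <- groups[groups$name == "control", , drop = FALSE]
  if (nrow(ctrl) != 1L ||
      ctrl$sprout_mult != 1 || ctrl$elong_mult != 1 ||
      ctrl$thickness_shift_um != 0)
    cam_abort(paste0("config must contain exactly one 'control' group with ",
                     "unit multipliers and zero thickness shift"),
              "camAAI_schema_error")
  structure(list(groups = groups, n_embryos = as.integer(n_embryos),
                 days = days, n_roots = as.integer(n_roots),
                 gen_lengths_um = gen_lengths_um, sprout_rate = sprout_rate,
                 sprout_meanlog = sprout_meanlog, sprout_sdlog = sprout_sdlog,
                 branch_angle = branch_angle, angle_jitter = angle_jitter,
                 thickness_base_um = thickness_base_um,
                 thickness_sd_um = thickness_sd_um,
                 roi = roi, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$groups), " groups x ", x$n_embryos,
      " embryos, days ", paste(x$days, collapse = ", "), ", ",
      x$n_roots, " feeder trees of depth ", length(x$gen_lengths_um),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# per-embryo substream seeds derived from the config seed; purposes:
# 1 growth, 2 death, 3 thickness
stream_seed <- function(seed, key, purpose) {
  as.integer((as.numeric(seed) + 1000003 * key + 999331 * purpose) %% 2147483629)
}

group_params <- function(config, group) {
  g <- config$groups[config$groups$name == group, , drop = FALSE]
  if (nrow(g) != 1L)
    cam_abort(paste0("group '", group, "' not in configuration"),
              "camAAI_schema_error")
  g
}

#' Simulate one embryo's vessel-network time course
#'
#' Grows the tip-bifurcation model from the deterministic day-0 feeder
#' trees and returns one canonical [vessel_graph()] per observation day.
#' Graphs are nested over time (growth only appends) and the whole time
#' course is reproducible from the seed.
#'
#' @param config a [simulation_config()].
#' @param group group name (selects the sprouting/elongation multipliers).
#' @param seed integer seed for this embryo's growth stream; defaults to
#'   the config seed.
#' @return named list of `vessel_graph` objects, one per day.
#' @export
simulate_vessel_timecourse <- function(config, group = "control", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gp <- group_params(config, group)
  set.seed(seed %||% config$seed)
  depth <- length(config$gen_lengths_um)
  R <- config$roi$outer_radius
  cx <- config$roi$center[1L]; cy <- config$roi$center[2L]

  nx <- double(); ny <- double()
  e_from <- integer(); e_to <- integer(); e_len <- double()
  e_gen <- integer(); e_dir <- double(); e_term <- logical()
  add_node <- function(x, y) { nx[length(nx) + 1L] <<- x; ny[length(ny) + 1L] <<- y; length(nx) }
  add_edge <- function(from, to, len, gen, dir, term) {
    i <- length(e_from) + 1L
    e_from[i] <<- from; e_to[i] <<- to; e_len[i] <<- len
    e_gen[i] <<- gen; e_dir[i] <<- dir; e_term[i] <<- term
    i
  }

  rotation <- runif(1, 0, 2 * pi)
  for (r in seq_len(config$n_roots)) {
    theta <- rotation + 2 * pi * (r - 1) / config$n_roots
    start <- add_node(cx + R * cos(theta), cy + R * sin(theta))
    # build the complete binary feeder tree generation by generation
    queue <- list(list(node = start, dir = theta + pi, gen = 1L))
    while (length(queue)) {
      item <- queue[[1L]]; queue <- queue[-1L]
      g <- item$gen
      len <- config$gen_lengths_um[g]
      end <- add_node(nx[item$node] + len * cos(item$dir),
                      ny[item$node] + len * sin(item$dir))
      add_edge(item$node, end, len, min(g, 4L), item$dir, g == depth)
      if (g < depth) {
        spread <- config$branch_angle * 0.85^(g - 1)
        jit <- rnorm(2, 0, config$angle_jitter)
        queue <- c(queue, list(
          list(node = end, dir = item$dir + spread + jit[1L], gen = g + 1L),
          list(node = end, dir = item$dir - spread + jit[2L], gen = g + 1L)))
      }
    }
  }
  snapshots <- list(c(edges = length(e_from), nodes = length(nx)))

  rate <- config$sprout_rate * gp$sprout_mult
  for (k in seq_along(config$days)[-1L]) {
    delta <- config$days[k] - config$days[k - 1L]
    q <- 1 - exp(-rate * delta)
    tips <- which(e_term)
    bif <- runif(length(tips)) < q
    for (t in tips[bif]) {
      lens <- rlnorm(2, config$sprout_meanlog, config$sprout_sdlog) * gp$elong_mult
      jit <- rnorm(2, 0, config$angle_jitter)
      dirs <- e_dir[t] + c(config$branch_angle, -config$branch_angle) + jit
      gen <- min(e_gen[t] + 1L, 4L)
      for (i in 1:2) {
        end <- add_node(nx[e_to[t]] + lens[i] * cos(dirs[i]),
                        ny[e_to[t]] + lens[i] * sin(dirs[i]))
        add_edge(e_to[t], end, lens[i], gen, dirs[i], TRUE)
      }
      e_term[t] <- FALSE
    }
    snapshots[[k]] <- c(edges = length(e_from), nodes = length(nx))
  }

  node_ids <- sprintf("n%05d", seq_along(nx))
  edge_ids <- sprintf("e%05d", seq_along(e_from))
  roots <- edge_ids[seq_len(snapshots[[1L]]["edges"])][
    e_gen[seq_len(snapshots[[1L]]["edges"])] == 1L]
  graphs <- lapply(seq_along(config$days), function(k) {
    ne <- snapshots[[k]]["edges"]; nn <- snapshots[[k]]["nodes"]
    vessel_graph(
      nodes = data.frame(id = node_ids[seq_len(nn)], x = nx[seq_len(nn)],
                         y = ny[seq_len(nn)], stringsAsFactors = FALSE),
      edges = data.frame(id = edge_ids[seq_len(ne)],
                         from = node_ids[e_from[seq_len(ne)]],
                         to = node_ids[e_to[seq_len(ne)]],
                         length = e_len[seq_len(ne)],
                         stringsAsFactors = FALSE),
      roots = roots, validate = FALSE)
  })
  names(graphs) <- as.character(config$days)
  graphs
}

metrics_row <- function(embryo_id, group, day, vm) {
  data.frame(embryo_id = embryo_id, group = group, day = day,
             junctions = vm$junctions, segments = vm$segments,
             total_length_um = vm$total_length_um,
             mean_length_um = vm$mean_length_um,
             density_um_per_mm2 = vm$density_um_per_mm2,
             n1 = vm$branch_counts[1L], n2 = vm$branch_counts[2L],
             n3 = vm$branch_counts[3L], n4 = vm$branch_counts[4L],
             hierarchy_ratio = vm$hierarchy_ratio,
             stringsAsFactors = FALSE)
}

#' Simulate a full CAM cohort
#'
#' Simulates every embryo's vessel time course, measures it with
#' [compute_metrics()], draws whole-day deaths (per-interval hazard
#' `1 - (1 - hazard)^days`), and draws final-day CAM thickness for the
#' survivors.  Embryos that die at an observation day have no metric record
#' on or after that day.
#'
#' @param config a [simulation_config()].
#' @param keep_graphs attach the per-embryo graph lists as the `graphs`
#'   attribute (off by default; they are large).
#' @return a [cohort_dataset()].
#' @export
simulate_cohort <- function(config, keep_graphs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  days <- config$days
  final_day <- days[length(days)]
  mrows <- list(); srows <- list(); trows <- list(); all_graphs <- list()
  for (gi in seq_len(nrow(config$groups))) {
    gname <- config$groups$name[gi]
    hz <- config$groups$hazard[gi]
    shift <- config$groups$thickness_shift_um[gi]
    for (j in seq_len(config$n_embryos)) {
      key <- (gi - 1L) * 1000L + j
      eid <- sprintf("%s-%02d", gname, j)

      set.seed(stream_seed(config$seed, key, 2L))
      death_day <- NA_real_
      for (k in seq_along(days)[-1L]) {
        p <- 1 - (1 - hz)^(days[k] - days[k - 1L])
        if (runif(1) < p) { death_day <- days[k]; break }
      }

      graphs <- simulate_vessel_timecourse(config, gname,
                                           seed = stream_seed(config$seed, key, 1L))
      alive_days <- if (is.na(death_day)) days else days[days < death_day]
      for (d in alive_days)
        mrows[[length(mrows) + 1L]] <-
          metrics_row(eid, gname, d,
                      compute_metrics(graphs[[as.character(d)]], config$roi))

      srows[[length(srows) + 1L]] <- data.frame(
        embryo_id = eid, group = gname,
        last_day_alive = if (is.na(death_day)) final_day else death_day,
        status = if (is.na(death_day)) 0L else 1L, stringsAsFactors = FALSE)

      if (is.na(death_day)) {
        set.seed(stream_seed(config$seed, key, 3L))
        repeat {
          th <- rnorm(1, config$thickness_base_um + shift, config$thickness_sd_um)
          if (th > 0) break
        }
        trows[[length(trows) + 1L]] <- data.frame(
          embryo_id = eid, group = gname, thickness_um = th,
          stringsAsFactors = FALSE)
      }
      if (keep_graphs) all_graphs[[eid]] <- graphs
    }
  }
  cohort <- cohort_dataset(do.call(rbind, mrows), do.call(rbind, srows),
                           if (length(trows)) do.call(rbind, trows),
                           control = "control", validate = FALSE)
  if (keep_graphs) attr(cohort, "graphs") <- all_graphs
  cohort
}

# Exact moments of the tip-bifurcation process for one group.
# State per interval: T = number of terminal segments, C = cumulative number
# of bifurcations, B | T ~ Binomial(T, q).  All first and second moments are
# linear in the current moments, so the recursion is exact.
tip_moments <- function(t0, rate, intervals) {
  ET <- t0; ET2 <- t0^2; EC <- 0; EC2 <- 0; ECT <- 0
  for (delta in intervals) {
    q <- 1 - exp(-rate * delta)
    ET2n <- (1 + q)^2 * ET2 + q * (1 - q) * ET
    ECTn <- (1 + q) * ECT + q * (1 + q) * ET2 + q * (1 - q) * ET
    EC2n <- EC2 + 2 * q * ECT + q * (1 - q) * ET + q^2 * ET2
    ECn <- EC + q * ET
    ETn <- (1 + q) * ET
    ET <- ETn; ET2 <- ET2n; EC <- ECn; EC2 <- EC2n; ECT <- ECTn
  }
  list(ET = ET, EC = EC, VarC = EC2 - EC^2)
}

base_network_summary <- function(config) {
  depth <- length(config$gen_lengths_um)
  gen_counts <- 2^(seq_len(depth) - 1L)
  deg <- pmin(seq_len(depth), 4L)
  n0 <- vapply(1:4, function(k) config$n_roots * sum(gen_counts[deg == k]), 0)
  list(depth = depth,
       S0 = config$n_roots * sum(gen_counts),
       J0 = config$n_roots * (2^(depth - 1L) - 1L),
       T0 = config$n_roots * 2^(depth - 1L),
       L0 = config$n_roots * sum(gen_counts * config$gen_lengths_um),
       n0 = n0)
}

#' Closed-form expected outcome of a simulation configuration
#'
#' Computes, without sampling, the expected day-0-normalized angiogenic
#' responses of every group at the final observation day and the expected
#' per-parameter and final AAI of every treatment group.  Two values are
#' reported per index:
#'
#' * `ideal` - the index evaluated at the exact expectations of the growth
#'   process (the population-level value; 0 for identical groups);
#' * `sampling_mean` - the expected value of the cohort estimator itself at
#'   the configured group size, which differs from `ideal` because the
#'   index is a ratio of group means: fold-change parameters carry a
#'   second-order delta-method correction using the exact process
#'   variances, and the survival index is evaluated by exact binomial
#'   enumeration conditional on a nondegenerate control (the estimator's
#'   finite-sample mean, matched by the parameter-recovery tests).
#'
#' A parameter whose control change is degenerate under the configuration
#' (for instance survival with zero hazard) is reported as excluded,
#' mirroring the scoring pipeline.
#'
#' @param config a [simulation_config()].
#' @return object of class `expected_outcome` with elements `ar` (data
#'   frame of expected responses), `aai` (data frame with `ideal` and
#'   `sampling_mean` per treatment and parameter), `final` (expected final
#'   AAI per treatment, ideal scale) and `excluded`.
#' @export
expected_outcome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base <- base_network_summary(config)
  if (base$depth < 3L)
    cam_abort("closed-form hierarchy expectation needs tree depth >= 3",
              "camAAI_schema_error")
  intervals <- diff(config$days)
  span <- sum(intervals)
  n34_0 <- base$n0[3L] + base$n0[4L]
  ell <- function(em) em * exp(config$sprout_meanlog + config$sprout_sdlog^2 / 2)
  vell <- function(em) em^2 * (exp(config$sprout_sdlog^2) - 1) *
    exp(2 * config$sprout_meanlog + config$sprout_sdlog^2)

  gs <- config$groups
  mom <- lapply(seq_len(nrow(gs)), function(i)
    tip_moments(base$T0, config$sprout_rate * gs$sprout_mult[i], intervals))
  names(mom) <- gs$name
  surv <- setNames((1 - gs$hazard)^span, gs$name)

  ar <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i) {
    EC <- mom[[i]]$EC
    EL <- base$L0 + 2 * EC * ell(gs$elong_mult[i])
    ES <- base$S0 + 2 * EC
    data.frame(group = gs$name[i],
               parameter = c("junctions", "hierarchy", "total_length",
                             "density", "mean_length", "survival", "thickness"),
               expected_ar = c(1 + EC / base$J0,
                               1 + 2 * EC / n34_0,
                               EL / base$L0,
                               EL / base$L0,
                               (EL / ES) / (base$L0 / base$S0),
                               surv[[i]],
                               (config$thickness_base_um +
                                  gs$thickness_shift_um[i]) /
                                 config$thickness_base_um),
               stringsAsFactors = FALSE)
  }))

  ci <- which(gs$name == "control")
  EC_c <- mom[[ci]]$EC; VarC_c <- mom[[ci]]$VarC
  hz_c <- gs$hazard[ci]
  p_c <- 1 - (1 - hz_c)^span
  n <- config$n_embryos
  m_eff <- n * (1 - hz_c)^span   # expected control survivors with final-day records
  ell_c <- ell(1); vell_c <- vell(1)

  treatments <- gs$name[gs$name != "control"]
  aai_rows <- list(); excl <- list(); finals <- list()
  for (tr in treatments) {
    ti <- which(gs$name == tr)
    EC_t <- mom[[ti]]$EC
    ideal <- c(junctions = NA_real_, hierarchy = NA_real_,
               total_length = NA_real_, density = NA_real_,
               survival = NA_real_, thickness = NA_real_)
    samp <- ideal
    # junctions and hierarchy indices are both ratios of expected
    # bifurcation counts under this growth model
    if (EC_c > 0) {
      a <- (EC_t - EC_c) / EC_c
      relvar <- VarC_c / (m_eff * EC_c^2)
      ideal[c("junctions", "hierarchy")] <- a
      samp[c("junctions", "hierarchy")] <- a + (1 + a) * relvar
      dLt <- 2 * EC_t * ell(gs$elong_mult[ti])
      dLc <- 2 * EC_c * ell_c
      al <- (dLt - dLc) / dLc
      varLi <- 2 * EC_c * vell_c + 4 * VarC_c * ell_c^2
      relvarL <- varLi / (m_eff * dLc^2)
      ideal[c("total_length", "density")] <- al
      samp[c("total_length", "density")] <- al + (1 + al) * relvarL
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        treatment = tr,
        parameter = c("junctions", "hierarchy", "total_length", "density"),
        reason = "degenerate control: zero expected sprouting")
    }
    if (p_c > 0) {
      s_t <- surv[[ti]]; s_c <- surv[[ci]]
      ideal["survival"] <- (s_t - s_c) / (s_c - 1)
      p_t <- 1 - (1 - gs$hazard[ti])^span
      k <- seq_len(n)
      einv <- sum(dbinom(k, n, p_c) / k) / (1 - dbinom(0, n, p_c))
      samp["survival"] <- n * p_t * einv - 1
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        treatment = tr, parameter = "survival",
        reason = "degenerate control: zero death hazard")
    }
    ideal["thickness"] <- gs$thickness_shift_um[ti] / config$thickness_base_um
    samp["thickness"] <- ideal["thickness"]
    aai_rows[[length(aai_rows) + 1L]] <- data.frame(
      treatment = tr, parameter = names(ideal),
      ideal = unname(ideal), sampling_mean = unname(samp),
      stringsAsFactors = FALSE)
    finals[[length(finals) + 1L]] <- data.frame(
      treatment = tr, expected_final_aai = mean(ideal, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  structure(list(day = config$days[length(config$days)],
                 base = base,
                 ar = ar,
                 aai = do.call(rbind, aai_rows),
                 final = do.call(rbind, finals),
                 excluded = if (length(excl)) do.call(rbind, excl) else
                   data.frame(treatment = character(), parameter = character(),
                              reason = character())),
            class = "expected_outcome")
}

#' @export
print.expected_outcome <- function(x, ...) {
  cat("<expected_outcome> day ", x$day, "\n", sep = "")
  print(x$aai, row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("Excluded:\n"); print(x$excluded, row.names = FALSE)
  }
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' Simulate a scratch-assay measurement series
#'
#' Draws noisy wound areas and five-position widths around configured
#' per-condition closure and remaining-width percentages.  Baseline (0 h)
#' measurements are the configured references, so with zero noise the
#' computed percentages reproduce the configured effects exactly.
#'
#' @param conditions data frame with columns `condition`, `lps`, `time_h`,
#'   `closure_pct`, `width_pct` (remaining width as percent of baseline).
#' @param n_samples independent scratches per condition.
#' @param area0_um2,width0_um baseline scratch area and width.
#' @param noise_sd_pct measurement noise SD as percent of the baseline.
#' @param seed integer seed.
#' @return data frame with columns `sample`, `condition`, `lps_flag`,
#'   `time_h`, `area`, `w1`..`w5` (compatible with [summarize_scratch()]).
#' @export
simulate_scratch_series <- function(conditions = data.frame(
                                      condition = rep(c("control", "adsc", "mixed"), each = 2),
                                      lps = FALSE,
                                      time_h = rep(c(6, 24), 3),
                                      closure_pct = c(30, 73.7, 41.8, 90, 25.6, 78.4),
                                      width_pct = c(65, 17.1, 55, 29.0, 70, 46.7),
                                      stringsAsFactors = FALSE),
                                    n_samples = 8L, area0_um2 = 3e5,
                                    width0_um = 800, noise_sd_pct = 6,
                                    seed = 1L) {
  stopifnot(all(c("condition", "lps", "time_h", "closure_pct", "width_pct") %in%
                  names(conditions)))
  set.seed(seed)
  out <- list()
  combos <- unique(conditions[, c("condition", "lps")])
  for (i in seq_len(nrow(combos))) {
    cond <- combos$condition[i]; lps <- combos$lps[i]
    rows <- conditions[conditions$condition == cond & conditions$lps == lps, ,
                       drop = FALSE]
    for (s in seq_len(n_samples)) {
      sid <- sprintf("%s%s-%02d", cond, if (lps) "+lps" else "", s)
      out[[length(out) + 1L]] <- data.frame(
        sample = sid, condition = cond, lps_flag = lps, time_h = 0,
        area = area0_um2, w1 = width0_um, w2 = width0_um, w3 = width0_um,
        w4 = width0_um, w5 = width0_um, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(rows))) {
        a <- area0_um2 * (1 - rows$closure_pct[r] / 100) +
          rnorm(1, 0, noise_sd_pct / 100 * area0_um2)
        w <- width0_um * rows$width_pct[r] / 100 +
          rnorm(5, 0, noise_sd_pct / 100 * width0_um)
        a <- max(a, 0); w <- pmax(w, 0)
        out[[length(out) + 1L]] <- data.frame(
          sample = sid, condition = cond, lps_flag = lps,
          time_h = rows$time_h[r], area = a,
          w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4], w5 = w[5],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a qPCR CT table
#'
#' Generates target and housekeeping threshold cycles for a control and a
#' treated condition with configured per-gene log2 fold changes; with zero
#' noise the estimated fold change versus control equals `2^log2_fc`
#' exactly.
#'
#' @param genes data frame with columns `gene`, `dct_control` (control
#'   delta-CT versus the housekeeping gene) and `log2_fc` (treated log2
#'   fold change versus control).
#' @param n_samples biological replicates per condition.
#' @param hk_ct housekeeping threshold cycle.
#' @param noise_sd_ct measurement noise SD on the CT scale (cycles).
#' @param seed integer seed.
#' @return data frame with columns `sample`, `condition`, `gene`, `ct`,
#'   `housekeeping_ct` (compatible with [summarize_ct()]).
#' @export
simulate_ct_table <- function(genes = data.frame(
                                gene = c("MMP9", "TIMP1", "COL1A1"),
                                dct_control = c(8, 6, 2),
                                log2_fc = c(2, 1.2, -1),
                                stringsAsFactors = FALSE),
                              n_samples = 4L, hk_ct = 15,
                              noise_sd_ct = 0.15, seed = 1L) {
  stopifnot(all(c("gene", "dct_control", "log2_fc") %in% names(genes)))
  set.seed(seed)
  out <- list()
  for (cond in c("control", "treated")) for (s in seq_len(n_samples))
    for (g in seq_len(nrow(genes))) {
      dct <- genes$dct_control[g] -
        if (cond == "treated") genes$log2_fc[g] else 0
      out[[length(out) + 1L]] <- data.frame(
        sample = sprintf("%s-%02d", cond, s), condition = cond,
        gene = genes$gene[g],
        ct = hk_ct + dct + rnorm(1, 0, noise_sd_ct),
        housekeeping_ct = hk_ct, stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
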