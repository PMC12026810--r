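# Cohort bookkeeping, day-0-normalized fold changes, survival analysis and
# the angiogenic activity index (AAI).
#
# The AAI compares the baseline-corrected angiogenic response AR of a
# treatment group with the control group, per scored parameter:
#
#   AAI_i = ((AR_t,d - AR_t,0) - (AR_c,d - AR_c,0)) / (AR_c,d - AR_c,0)
#
# and the final AAI is the arithmetic mean of the per-parameter indices.
# An AAI of 0 means control-level activity; 1 means the treatment's
# baseline-corrected change is double the control's.

METRIC_COLUMNS <- c("junctions", "segments", "total_length_um",
                    "mean_length_um", "density_um_per_mm2",
                    "n1", "n2", "n3", "n4", "hierarchy_ratio")

# parameter name -> metrics-table column for plain fold-change parameters
PARAMETER_COLUMNS <- c(junctions = "junctions",
                       segments = "segments",
                       total_length = "total_length_um",
                       mean_length = "mean_length_um",
                       density = "density_um_per_mm2")

AAI_PARAMETERS <- c("survival", "junctions", "hierarchy", "total_length",
                    "density", "thickness")

#' Assemble a CAM cohort dataset
#'
#' Bundles the per-embryo, per-day vessel metrics with the survival record
#' and the final-day CAM thickness measurements.
#'
#' @param metrics data frame with one row per embryo and observation day,
#'   columns `embryo_id`, `group`, `day`, `junctions`, `segments`,
#'   `total_length_um`, `mean_length_um`, `density_um_per_mm2`, `n1`..`n4`,
#'   `hierarchy_ratio`.
#' @param survival data frame with columns `embryo_id`, `group`,
#'   `last_day_alive`, `status`.  `status` 1 means the embryo was found dead
#'   at `last_day_alive` (the event time; no metric record exists on or
#'   after that day); `status` 0 means alive through `last_day_alive`
#'   (censored there).
#' @param thickness optional data frame with columns `embryo_id`, `group`,
#'   `thickness_um` (final-day CAM thickness).
#' @param control name of the control group (exactly one group is the
#'   reference).
#' @param validate check the cohort invariants (a day-0 record per embryo,
#'   no records after death, control present).
#' @return object of class `cam_cohort`.
#' @export
cohort_dataset <- function(metrics, survival, thickness = NULL,
                           control = "control", validate = TRUE) {
  need <- c("embryo_id", "group", "day", METRIC_COLUMNS)
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    cam_abort(paste0("metrics table is missing required column(s): ",
                     paste(miss, collapse = ", ")), "camAAI_schema_error")
  miss <- setdiff(c("embryo_id", "group", "last_day_alive", "status"),
                  names(survival))
  if (length(miss))
    cam_abort(paste0("survival table is missing required column(s): ",
                     paste(miss, collapse = ", ")), "camAAI_schema_error")
  metrics$embryo_id <- as.character(metrics$embryo_id)
  metrics$group <- as.character(metrics$group)
  survival$embryo_id <- as.character(survival$embryo_id)
  survival$group <- as.character(survival$group)
  if (!is.null(thickness)) {
    miss <- setdiff(c("embryo_id", "group", "thickness_um"), names(thickness))
    if (length(miss))
      cam_abort(paste0("thickness table is missing required column(s): ",
                       paste(miss, collapse = ", ")), "camAAI_schema_error")
    thickness$embryo_id <- as.character(thickness$embryo_id)
    thickness$group <- as.character(thickness$group)
  }
  cohort <- structure(list(metrics = metrics, survival = survival,
                           thickness = thickness, control = control,
                           groups = sort(unique(survival$group)),
                           days = sort(unique(metrics$day))),
                      class = "cam_cohort")
  if (validate) validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  if (!(cohort$control %in% cohort$groups))
    cam_abort(paste0("control group '", cohort$control,
                     "' not present in the cohort"), "camAAI_schema_error")
  d0 <- unique(cohort$metrics$embryo_id[cohort$metrics$day == 0])
  missing0 <- setdiff(cohort$survival$embryo_id, d0)
  if (length(missing0))
    cam_abort(paste0("embryo(s) without a day-0 metrics record: ",
                     paste(head(missing0, 5L), collapse = ", ")),
              "camAAI_schema_error")
  sv <- cohort$survival
  for (i in seq_len(nrow(sv))) {
    lim <- sv$last_day_alive[i]
    rows <- cohort$metrics$embryo_id == sv$embryo_id[i]
    bad <- if (sv$status[i] == 1)
      any(cohort$metrics$day[rows] >= lim)
    else
      any(cohort$metrics$day[rows] > lim)
    if (bad)
      cam_abort(paste0("embryo ", sv$embryo_id[i],
                       " has metric records after its death/censoring day"),
                "camAAI_schema_error")
  }
  invisible(cohort)
}

#' @export
print.cam_cohort <- function(x, ...) {
  cat("<cam_cohort> ", nrow(x$survival), " embryos in ",
      length(x$groups), " group(s) [control: ", x$control, "], days ",
      paste(x$days, collapse = ", "), "; ", nrow(x$metrics),
      " metric records\n", sep = "")
  invisible(x)
}

#' Relabel a copy of one group as another
#'
#' Duplicates every record of group `from` under the new group label `to`
#' (embryo ids prefixed to stay unique).  Cloning the control group gives
#' the null reference against which the AAI must be exactly zero.
#'
#' @param cohort a [cohort_dataset()].
#' @param from existing group name.
#' @param to new group name.
#' @return a `cam_cohort` with the extra group.
#' @export
clone_group <- function(cohort, from, to) {
  stopifnot(from %in% cohort$groups, !(to %in% cohort$groups))
  rekey <- function(df) {
    df <- df[df$group == from, , drop = FALSE]
    df$group <- to
    df$embryo_id <- paste0(to, ":", df$embryo_id)
    df
  }
  cohort_dataset(rbind(cohort$metrics, rekey(cohort$metrics)),
                 rbind(cohort$survival, rekey(cohort$survival)),
                 if (!is.null(cohort$thickness))
                   rbind(cohort$thickness, rekey(cohort$thickness)),
                 control = cohort$control, validate = FALSE)
}

#' Day-0-normalized fold change
#'
#' @param value_day measurement at the queried treatment day.
#' @param value_day0 measurement before the start of treatment (day 0);
#'   must be positive.
#' @return `value_day / value_day0`.
#' @export
fold_change <- function(value_day, value_day0) {
  if (!all(is.finite(value_day0)) || any(value_day0 <= 0))
    cam_abort("fold change requires a positive day-0 baseline",
              "camAAI_invalid_baseline")
  value_day / value_day0
}

#' Group-level angiogenic response for one parameter and day
#'
#' For the plain metric parameters (`junctions`, `segments`,
#' `total_length`, `mean_length`, `density`) the angiogenic response AR is
#' the group mean of per-embryo fold changes versus day 0; embryos dead
#' before the queried day (no record) are excluded, and embryos with a
#' nonpositive baseline are dropped with a warning.
#'
#' For `hierarchy` the group-level ratio is computed from branch counts
#' summed across the embryos with a record at the queried day — robust to
#' per-embryo undefined ratios — and AR is its fold change over the same
#' embryos' summed day-0 counts; the reported dispersion is the SD of the
#' per-embryo fold changes where defined.
#'
#' @param cohort a [cohort_dataset()].
#' @param group group name.
#' @param parameter one of `junctions`, `segments`, `total_length`,
#'   `mean_length`, `density`, `hierarchy`.
#' @param day observation day.
#' @return list with `group`, `parameter`, `day`, `AR`, `sd`, `n`
#'   (embryos contributing).
#' @export
group_response <- function(cohort, group, parameter, day) {
  stopifnot(inherits(cohort, "cam_cohort"))
  if (!(group %in% cohort$groups))
    cam_abort(paste0("unknown group '", group, "'"), "camAAI_empty_group")
  m <- cohort$metrics
  m0 <- m[m$group == group & m$day == 0, , drop = FALSE]
  md <- m[m$group == group & m$day == day, , drop = FALSE]
  both <- intersect(m0$embryo_id, md$embryo_id)
  if (!length(both))
    cam_abort(paste0("no embryos of group '", group, "' with records at day 0 and day ",
                     day), "camAAI_empty_group")
  m0 <- m0[match(both, m0$embryo_id), , drop = FALSE]
  md <- md[match(both, md$embryo_id), , drop = FALSE]

  if (parameter == "hierarchy") {
    num_d <- sum(md$n3 + md$n4); den_d <- sum(md$n1 + md$n2)
    num_0 <- sum(m0$n3 + m0$n4); den_0 <- sum(m0$n1 + m0$n2)
    h_d <- if (den_d > 0) num_d / den_d else NA_real_
    h_0 <- if (den_0 > 0) num_0 / den_0 else NA_real_
    ar <- if (is.na(h_d) || is.na(h_0) || h_0 == 0) NA_real_ else h_d / h_0
    fc0 <- (m0$n3 + m0$n4) / (m0$n1 + m0$n2)
    fcd <- (md$n3 + md$n4) / (md$n1 + md$n2)
    fcs <- ifelse(is.finite(fc0) & fc0 > 0 & is.finite(fcd), fcd / fc0, NA_real_)
    return(list(group = group, parameter = parameter, day = day,
                AR = if (day == 0 && !is.na(ar)) 1 else ar,
                sd = if (sum(!is.na(fcs)) > 1) sd(fcs, na.rm = TRUE) else NA_real_,
                n = length(both)))
  }

  col <- PARAMETER_COLUMNS[[parameter]]
  if (is.null(col))
    cam_abort(paste0("unknown parameter '", parameter, "'"), "camAAI_schema_error")
  v0 <- m0[[col]]; vd <- md[[col]]
  ok <- is.finite(v0) & v0 > 0 & is.finite(vd)
  if (any(!ok))
    warning(sum(!ok), " embryo(s) with nonpositive or missing baseline excluded ",
            "from ", parameter, " fold change in group '", group, "'",
            call. = FALSE)
  if (!any(ok))
    cam_abort(paste0("no valid baselines for parameter '", parameter,
                     "' in group '", group, "'"), "camAAI_empty_group")
  fcs <- vd[ok] / v0[ok]
  list(group = group, parameter = parameter, day = day,
       AR = mean(fcs),
       sd = if (length(fcs) > 1) sd(fcs) else 0,
       n = sum(ok))
}

#' Per-parameter angiogenic activity index
#'
#' The baseline-corrected change of the treatment group relative to the
#' control group's change:
#' `((AR_t_day - AR_t_day0) - (AR_c_day - AR_c_day0)) / (AR_c_day - AR_c_day0)`.
#' 0 marks control-level activity; 1 marks a doubling of the
#' baseline-corrected response.  Depends only on the ratio of differences,
#' so it is invariant under any common affine rescaling of the responses.
#'
#' @param ar_treat_day,ar_treat_day0 treatment-group responses at the
#'   queried day and at day 0 (1 by construction for fold-change
#'   parameters).
#' @param ar_ctrl_day,ar_ctrl_day0 control-group responses.
#' @param eps degenerate-control tolerance: a control change smaller than
#'   this in absolute value raises a `camAAI_degenerate_control` condition
#'   (the parameter is then excluded from the final AAI).
#' @return signed dimensionless index.
#' @export
aai_parameter <- function(ar_treat_day, ar_treat_day0, ar_ctrl_day, ar_ctrl_day0,
                          eps = CAM_EPS_DEGENERATE) {
  dc <- ar_ctrl_day - ar_ctrl_day0
  if (!is.finite(dc) || abs(dc) < eps)
    cam_abort("degenerate control: control change is zero within tolerance",
              "camAAI_degenerate_control")
  dt <- ar_treat_day - ar_treat_day0
  if (!is.finite(dt))
    cam_abort("treatment response is not finite", "camAAI_empty_group")
  (dt - dc) / dc
}

#' CAM thickness index
#'
#' CAM thickness is measured once, at the final day, so its index is the
#' relative difference of the group medians:
#' `(median_treat - median_ctrl) / median_ctrl`.
#'
#' @param thickness_treat,thickness_ctrl group median thicknesses (um);
#'   the control median must be positive.
#' @return signed dimensionless index.
#' @export
thickness_index <- function(thickness_treat, thickness_ctrl) {
  if (!is.finite(thickness_ctrl) || thickness_ctrl <= 0)
    cam_abort("thickness index requires a positive control median",
              "camAAI_invalid_baseline")
  (thickness_treat - thickness_ctrl) / thickness_ctrl
}

#' Kaplan-Meier product-limit survival curve
#'
#' Thin wrapper over [survival::survfit()] returning the ordered event
#' times, risk sets and survival probabilities.  Censored embryos reduce
#' the risk set without a survival drop.
#'
#' @param time nonnegative event/censoring times (days).
#' @param status 1 = death, 0 = censored.
#' @return object of class `survival_curve` with fields `time`, `n_risk`,
#'   `n_event`, `surv` and `n`.
#' @export
km_estimator <- function(time, status) {
  if (!length(time))
    cam_abort("empty survival input", "camAAI_empty_group")
  stopifnot(length(time) == length(status), all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           data = data.frame(time = time, status = status))
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, n = length(time)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> n = ", x$n, "\n", sep = "")
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = x$surv))
  invisible(x)
}

#' Survival probability at a day, as an angiogenic response
#'
#' Returns `S(day)` from a product-limit curve; `S(0) = 1` serves as the
#' day-0 response of the survival parameter.
#'
#' @param curve a [km_estimator()] result.
#' @param day observation day.
#' @return survival probability in `[0, 1]`.
#' @export
survival_response <- function(curve, day) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- which(curve$time <= day)
  if (!length(idx)) return(1)
  curve$surv[max(idx)]
}

#' Mantel-Cox log-rank test for two groups
#'
#' Thin wrapper over [survival::survdiff()] (1 degree of freedom).  With no
#' deaths in either group the statistic is 0 and p = 1 by convention.
#'
#' @param time_a,status_a times and statuses of group A.
#' @param time_b,status_b times and statuses of group B.
#' @return list with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(time_a, status_a, time_b, status_b) {
  if (!length(time_a) || !length(time_b))
    cam_abort("both groups must be nonempty for the log-rank test",
              "camAAI_empty_group")
  if (sum(status_a) + sum(status_b) == 0)
    return(list(chisq = 0, df = 1L, p = 1))
  df <- data.frame(time = c(time_a, time_b),
                   status = c(status_a, status_b),
                   grp = rep(c("a", "b"), c(length(time_a), length(time_b))))
  sdf <- survival::survdiff(survival::Surv(time, status) ~ grp, data = df)
  list(chisq = unname(sdf$chisq), df = 1L,
       p = pchisq(unname(sdf$chisq), df = 1, lower.tail = FALSE))
}

group_curve <- function(cohort, group) {
  sv <- cohort$survival[cohort$survival$group == group, , drop = FALSE]
  km_estimator(sv$last_day_alive, sv$status)
}

#' Final angiogenic activity index from per-parameter indices
#'
#' @param indices named numeric vector of included per-parameter indices.
#' @param excluded optional data frame (`parameter`, `reason`) of excluded
#'   parameters.
#' @return object of class `aai_profile` with `indices`, `n`, `final_aai`
#'   and `excluded`.
#' @export
final_aai <- function(indices, excluded = NULL) {
  indices <- indices[is.finite(indices)]
  if (!length(indices))
    cam_abort("no valid parameters: every AAI parameter was excluded",
              "camAAI_no_valid_parameters")
  structure(list(indices = indices, n = length(indices),
                 final_aai = mean(indices),
                 excluded = excluded %||%
                   data.frame(parameter = character(), reason = character())),
            class = "aai_profile")
}

#' Build the angiogenic profile and AAI for a treatment group
#'
#' Computes the angiogenic response AR of each scored parameter for the
#' control and treatment groups on every observation day, applies the
#' per-parameter index at the target day (survival through the
#' product-limit estimate, CAM thickness through the median-based
#' [thickness_index()]), and averages the included parameters into the
#' final AAI.  Parameters with a degenerate control change or without
#' eligible embryos are excluded with a logged reason rather than aborting
#' the profile.
#'
#' @param cohort a [cohort_dataset()].
#' @param treatment name of the treatment group to score against the
#'   cohort's control.
#' @param day target day for the index (default 7, the headline day).
#' @param parameters parameters entering the final AAI; defaults to the six
#'   scored ones (survival, junctions, hierarchy, total vessel length,
#'   vessel density, CAM thickness).  Mean vessel length is tabulated in
#'   the profile but not averaged into the AAI.
#' @param eps degenerate-control tolerance passed to [aai_parameter()].
#' @return object of class `aai_profile` with the per-day profile table
#'   (`profile`), the per-parameter indices (`indices`), exclusions,
#'   `final_aai` and the applied-design metadata.
#' @export
build_angiogenic_profile <- function(cohort, treatment, day = 7,
                                     parameters = AAI_PARAMETERS,
                                     eps = CAM_EPS_DEGENERATE) {
  stopifnot(inherits(cohort, "cam_cohort"), length(parameters) >= 1L)
  control <- cohort$control
  if (!(treatment %in% cohort$groups))
    cam_abort(paste0("treatment group '", treatment, "' not in cohort"),
              "camAAI_empty_group")
  if (treatment == control)
    cam_abort("treatment group must differ from the control group",
              "camAAI_schema_error")
  days <- sort(unique(c(cohort$days, day)))
  final_day <- max(days)
  metric_pars <- c("junctions", "hierarchy", "total_length", "density",
                   "mean_length")

  rows <- list()
  add_row <- function(group, parameter, d, ar, s, n)
    rows[[length(rows) + 1L]] <<- data.frame(group = group, parameter = parameter,
                                             day = d, AR = ar, SD = s, n = n)
  for (grp in c(control, treatment)) {
    for (p in metric_pars) for (d in days) {
      gr <- tryCatch(group_response(cohort, grp, p, d),
                     camAAI_empty_group = function(e) NULL)
      if (!is.null(gr)) add_row(grp, p, d, gr$AR, gr$sd, gr$n)
    }
    curve <- group_curve(cohort, grp)
    for (d in days)
      add_row(grp, "survival", d, survival_response(curve, d), NA_real_, curve$n)
    if (!is.null(cohort$thickness)) {
      th <- cohort$thickness$thickness_um[cohort$thickness$group == grp]
      if (length(th)) {
        thc <- cohort$thickness$thickness_um[cohort$thickness$group == control]
        add_row(grp, "thickness", final_day,
                if (length(thc)) median(th) / median(thc) else NA_real_,
                NA_real_, length(th))
      }
    }
  }
  profile <- do.call(rbind, rows)

  get_ar <- function(grp, p, d) {
    hit <- profile$group == grp & profile$parameter == p & profile$day == d
    if (!any(hit)) NA_real_ else profile$AR[which(hit)[1L]]
  }

  idx <- setNames(rep(NA_real_, length(parameters)), parameters)
  excl_par <- character(); excl_reason <- character()
  exclude <- function(p, why) {
    excl_par <<- c(excl_par, p); excl_reason <<- c(excl_reason, why)
  }
  for (p in parameters) {
    val <- tryCatch({
      if (p == "thickness") {
        if (is.null(cohort$thickness))
          cam_abort("no thickness measurements in cohort", "camAAI_empty_group")
        tt <- cohort$thickness$thickness_um[cohort$thickness$group == treatment]
        tc <- cohort$thickness$thickness_um[cohort$thickness$group == control]
        if (!length(tt) || !length(tc))
          cam_abort("thickness missing for a group", "camAAI_empty_group")
        thickness_index(median(tt), median(tc))
      } else if (p == "survival") {
        st <- survival_response(group_curve(cohort, treatment), day)
        sc <- survival_response(group_curve(cohort, control), day)
        aai_parameter(st, 1, sc, 1, eps = eps)
      } else {
        art <- get_ar(treatment, p, day)
        arc <- get_ar(control, p, day)
        if (is.na(art) || is.na(arc))
          cam_abort(paste0("group response undefined for '", p, "'"),
                    "camAAI_empty_group")
        aai_parameter(art, 1, arc, 1, eps = eps)
      }
    },
    camAAI_degenerate_control = function(e) { exclude(p, conditionMessage(e)); NA_real_ },
    camAAI_empty_group = function(e) { exclude(p, conditionMessage(e)); NA_real_ },
    camAAI_invalid_baseline = function(e) { exclude(p, conditionMessage(e)); NA_real_ })
    idx[[p]] <- val
  }
  excluded <- data.frame(parameter = excl_par, reason = excl_reason,
                         stringsAsFactors = FALSE)
  out <- final_aai(idx[!is.na(idx)], excluded = excluded)
  out$treatment <- treatment
  out$control <- control
  out$day <- day
  out$parameters <- parameters
  out$profile <- profile
  out$metadata <- list(
    density_definition = "total vessel length per ROI area (um/mm^2)",
    junction_definition = "node of graph degree >= 3 after canonicalization",
    branch_degree = "generation order by BFS from root segments, capped at 4",
    hierarchy = "(n3 + n4) / (n1 + n2), group level from summed branch counts",
    thickness_rule = "relative difference of final-day group medians",
    aggregation = "fold changes averaged within group; index applied to group means",
    degenerate_control_eps = eps)
  out
}

#' @export
print.aai_profile <- function(x, ...) {
  if (!is.null(x$treatment))
    cat("Angiogenic profile: ", x$treatment, " vs ", x$control,
        " (day ", x$day, ")\n", sep = "")
  cat("Per-parameter AAI:\n")
  for (p in names(x$indices))
    cat(sprintf("  %-13s %8.4f\n", p, x$indices[[p]]))
  if (nrow(x$excluded))
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  %-13s excluded: %s\n", x$excluded$parameter[i],
                  x$excluded$reason[i]))
  cat(sprintf("Final AAI (mean of %d parameter%s): %.4f\n", x$n,
              if (x$n == 1) "" else "s", x$final_aai))
  invisible(x)
}
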