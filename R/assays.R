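# In vitro assay arithmetic: scratch wound-healing readouts (closure by
# area, width at five positions) and relative qPCR expression by the
# delta-CT method.

#' Wound closure percentage from scratch areas
#'
#' The reduction in scratch area is inversely proportional to wound
#' closure: `(1 - area_t / area_t0) * 100`.  Negative values mean the wound
#' widened.
#'
#' @param area_t0 scratch area at time 0 (must be positive; any consistent
#'   unit).
#' @param area_t scratch area at the later time point.
#' @return percent closure.
#' @export
wound_closure_percent <- function(area_t0, area_t) {
  if (!all(is.finite(area_t0)) || any(area_t0 <= 0))
    cam_abort("wound closure requires a positive baseline area",
              "camAAI_invalid_baseline")
  (1 - area_t / area_t0) * 100
}

#' Remaining scratch width as percent of baseline
#'
#' The scratch width is measured at five positions distributed over the
#' image; the five measurements are summarized by their arithmetic mean and
#' the later mean is expressed as a percentage of the baseline mean
#' (remaining width).  100% means no narrowing, 0% complete closure.  The
#' complementary reduction is `100 - width_percent_of_baseline(...)`.
#'
#' @param widths_t0 five baseline width measurements (um).
#' @param widths_t five later width measurements (um).
#' @return remaining width as percent of baseline.
#' @export
width_percent_of_baseline <- function(widths_t0, widths_t) {
  stopifnot(length(widths_t0) == 5L, length(widths_t) == 5L,
            all(widths_t0 >= 0), all(widths_t >= 0))
  b <- mean(widths_t0)
  if (!is.finite(b) || b <= 0)
    cam_abort("remaining-width percentage requires a positive baseline width",
              "camAAI_invalid_baseline")
  mean(widths_t) / b * 100
}

#' Relative expression by the -dCT method
#'
#' `2^-(CT_target - CT_housekeeping)`, the expression of a target gene
#' relative to the housekeeping gene.
#'
#' @param ct_target,ct_housekeeping threshold cycles.
#' @return dimensionless relative expression.
#' @export
rel_expression_neg_dct <- function(ct_target, ct_housekeeping) {
  2^(-(ct_target - ct_housekeeping))
}

#' Expression fold change versus a control condition
#'
#' `2^-(dCT_treated - dCT_control)`: the fold change of a treated sample's
#' housekeeping-normalized expression over the control condition (control
#' maps to 1).
#'
#' @param dct_treated,dct_control delta-CT values (CT_target -
#'   CT_housekeeping) of the treated and control conditions.
#' @return dimensionless fold change.
#' @export
fold_change_vs_control <- function(dct_treated, dct_control) {
  2^(-(dct_treated - dct_control))
}

#' Summarize a scratch-assay measurement table
#'
#' For every sample the time-0 row is the baseline; each later time point
#' is reported as percent wound closure (by area) and as remaining /
#' reduced width (percent of the baseline mean of the five positions).
#'
#' @param scratch data frame with columns `sample`, `condition`,
#'   `lps_flag`, `time_h`, `area`, `w1`..`w5`, containing a `time_h == 0`
#'   row per sample.
#' @return tidy data frame with one row per sample and later time point:
#'   `closure_pct`, `width_remaining_pct`, `width_reduction_pct`.
#' @export
summarize_scratch <- function(scratch) {
  need <- c("sample", "condition", "lps_flag", "time_h", "area",
            paste0("w", 1:5))
  miss <- setdiff(need, names(scratch))
  if (length(miss))
    cam_abort(paste0("scratch table is missing column(s): ",
                     paste(miss, collapse = ", ")), "camAAI_schema_error")
  wcols <- paste0("w", 1:5)
  out <- list()
  for (s in unique(scratch$sample)) {
    rows <- scratch[scratch$sample == s, , drop = FALSE]
    b <- rows[rows$time_h == 0, , drop = FALSE]
    if (nrow(b) != 1L)
      cam_abort(paste0("sample ", s, " must have exactly one time-0 row"),
                "camAAI_schema_error")
    for (i in which(rows$time_h > 0)) {
      wrem <- width_percent_of_baseline(as.numeric(b[1, wcols]),
                                        as.numeric(rows[i, wcols]))
      out[[length(out) + 1L]] <- data.frame(
        sample = s, condition = rows$condition[i], lps_flag = rows$lps_flag[i],
        time_h = rows$time_h[i],
        closure_pct = wound_closure_percent(b$area, rows$area[i]),
        width_remaining_pct = wrem,
        width_reduction_pct = 100 - wrem)
    }
  }
  do.call(rbind, out)
}

#' Summarize a CT table into relative expression
#'
#' Technical replicates (rows sharing `sample` and `gene`) are averaged on
#' the CT scale before the delta-CT computation.
#'
#' @param ct data frame with columns `sample`, `gene`, `ct`,
#'   `housekeeping_ct` (optionally `condition`).
#' @return data frame with one row per sample and gene: `dct` and
#'   `rel_expression` (`2^-dct`).
#' @export
summarize_ct <- function(ct) {
  miss <- setdiff(c("sample", "gene", "ct", "housekeeping_ct"), names(ct))
  if (length(miss))
    cam_abort(paste0("CT table is missing column(s): ",
                     paste(miss, collapse = ", ")), "camAAI_schema_error")
  key <- interaction(ct$sample, ct$gene, drop = TRUE)
  agg <- lapply(split(ct, key), function(d) {
    mct <- mean(d$ct); mhk <- mean(d$housekeeping_ct)
    data.frame(sample = d$sample[1], gene = d$gene[1],
               condition = if ("condition" %in% names(d)) d$condition[1] else NA,
               dct = mct - mhk,
               rel_expression = rel_expression_neg_dct(mct, mhk))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
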