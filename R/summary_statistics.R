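# Detection-rate and detected-mean summaries for left-censored survey data.
#
# "Detected" means the censoring flag is FALSE, even when the printed
# value is 0.0 (the survey's own detection counts include such entries);
# the mean over detected values additionally requires value > 0, which is
# the rule that reproduces the printed group means.

split_groups <- function(records, group_by) {
  if (is.null(group_by) || !length(group_by)) {
    return(list(`all` = records))
  }
  missing_cols <- setdiff(group_by, names(records))
  if (length(missing_cols)) {
    stop("unknown grouping column(s): ", paste(missing_cols, collapse = ", "))
  }
  split(records, interaction(records[group_by], drop = TRUE, sep = "."),
        drop = TRUE)
}

group_frame <- function(records, group_by) {
  if (is.null(group_by) || !length(group_by)) return(data.frame(row.names = 1))
  unique(records[1, group_by, drop = FALSE])
}

#' Detection rate per group
#'
#' Fraction of records whose measurement is not left-censored, overall
#' or per group (e.g. by `water_type` and/or `season`).
#'
#' @param records Concentration records.
#' @param analyte Analyte to summarise.
#' @param group_by Character vector of grouping columns, or `NULL` for a
#'   single overall group.
#' @return data.frame with the grouping columns plus `n_total`,
#'   `n_detected` and `detection_rate` (an exact fraction; use
#'   [format_percent()] for the survey's truncated one-decimal style).
#' @export
#' @examples
#' elements <- rbind(load_fixture("table2"), load_fixture("table3"))
#' detection_rate(elements, "Ba")  # 23 of 30 brands
detection_rate <- function(records, analyte, group_by = NULL) {
  sub <- records[records$analyte == analyte, , drop = FALSE]
  if (!nrow(sub)) stop("no records for analyte: ", analyte)
  out <- lapply(split_groups(sub, group_by), function(g) {
    cbind(group_frame(g, group_by),
          data.frame(analyte = analyte, n_total = nrow(g),
                     n_detected = sum(!g$censored),
                     detection_rate = sum(!g$censored) / nrow(g)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean over detected values per group
#'
#' Arithmetic mean over records that are detected (not censored) and
#' strictly positive. Groups with no qualifying value get `NA` (an
#' explicitly undefined mean, never zero).
#'
#' @inheritParams detection_rate
#' @return data.frame with grouping columns plus `n_used` and
#'   `mean_detected`.
#' @export
mean_detected <- function(records, analyte, group_by = NULL) {
  sub <- records[records$analyte == analyte, , drop = FALSE]
  if (!nrow(sub)) stop("no records for analyte: ", analyte)
  out <- lapply(split_groups(sub, group_by), function(g) {
    v <- g$value[!g$censored & g$value > 0]
    cbind(group_frame(g, group_by),
          data.frame(analyte = analyte, n_used = length(v),
                     mean_detected = if (length(v)) mean(v) else NA_real_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concentration range per group
#'
#' Maximum over all values and minimum over detected values; when a
#' group holds censored records below every detection the minimum is
#' annotated as below the detection limit.
#'
#' @inheritParams detection_rate
#' @return data.frame with grouping columns plus `min_detected`, `max`
#'   and `min_below_lod` (TRUE when the true minimum is a censored
#'   "<LOD" bound).
#' @export
concentration_range <- function(records, analyte, group_by = NULL) {
  sub <- records[records$analyte == analyte, , drop = FALSE]
  if (!nrow(sub)) stop("no records for analyte: ", analyte)
  out <- lapply(split_groups(sub, group_by), function(g) {
    det <- g$value[!g$censored]
    cen <- g$value[g$censored]
    min_det <- if (length(det)) min(det) else NA_real_
    below <- length(cen) > 0 && (!length(det) || min(cen) <= min(det))
    cbind(group_frame(g, group_by),
          data.frame(analyte = analyte,
                     min_detected = min_det, max = max(g$value),
                     min_below_lod = below))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Grouped summary table
#'
#' One row per analyte and group combining detection counts, detected
#' mean and range; within each group, rows are ordered by descending
#' mean concentration expressed in a common unit (ug/L), which
#' reproduces the survey's "ascendant trend" orderings.
#'
#' @param records Concentration records.
#' @param registry Analyte registry.
#' @param group_by Character vector of grouping columns, or `NULL`.
#' @return data.frame with grouping columns plus `analyte`, `unit`,
#'   `n_total`, `n_detected`, `detection_rate`, `mean_detected`,
#'   `min_detected`, `max`, `min_below_lod`.
#' @export
summarize_concentrations <- function(records, registry = analyte_registry(),
                                     group_by = NULL) {
  if (!nrow(records)) {
    return(data.frame(analyte = character(), unit = character(),
                      n_total = integer(), n_detected = integer(),
                      detection_rate = numeric(), mean_detected = numeric(),
                      min_detected = numeric(), max = numeric(),
                      min_below_lod = logical()))
  }
  rows <- lapply(sort(unique(records$analyte)), function(a) {
    dr <- detection_rate(records, a, group_by)
    md <- mean_detected(records, a, group_by)
    rg <- concentration_range(records, a, group_by)
    dr$n_used <- NULL
    cbind(dr, md[, c("n_used", "mean_detected"), drop = FALSE],
          rg[, c("min_detected", "max", "min_below_lod"), drop = FALSE])
  })
  res <- do.call(rbind, rows)
  res$unit <- registry$unit[match(res$analyte, registry$analyte)]
  # order within group by descending mean on a common scale
  mean_ugl <- ifelse(is.na(res$mean_detected), -Inf,
                     ifelse(res$unit == "mg/L", res$mean_detected * 1000,
                            res$mean_detected))
  grp <- if (is.null(group_by)) rep("all", nrow(res)) else {
    interaction(res[group_by], drop = TRUE)
  }
  res <- res[order(grp, -mean_ugl), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Format a fraction in the survey's percent style
#'
#' Truncated (not rounded) to one decimal, as the survey prints
#' detection rates (14/15 -> "93.3 %").
#'
#' @param frac Fraction in \[0, 1\].
#' @return Character vector.
#' @export
format_percent <- function(frac) {
  sprintf("%.1f %%", floor(frac * 1000) / 10)
}
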