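# Regulatory-limit and bottle-label compliance checks.
#
# Both comparisons use a strict ">" (a measurement exactly at the limit
# complies): the survey's single regulatory violation is nitrite 0.13
# against the 0.1 mg/L national limit.

#' Check measurements against regulatory limits
#'
#' Compares every detected measurement with the requested source's
#' maximum allowable concentration and returns the violations. Censored
#' records never violate; analytes without a limit from that source are
#' skipped with a message.
#'
#' @param records Concentration records.
#' @param registry Analyte registry carrying `inso_limit` / `who_limit`
#'   in each analyte's declared unit.
#' @param source `"INSO"` (Iran National Standards Organization) or
#'   `"WHO"`.
#' @return data.frame of findings: `brand`, `season`, `analyte`,
#'   `measured`, `limit`, `source`, `exceeds` (all `TRUE`). Zero rows
#'   when everything complies.
#' @export
#' @examples
#' check_regulatory(load_fixture("table1"), source = "INSO")
check_regulatory <- function(records, registry = analyte_registry(),
                             source = c("INSO", "WHO")) {
  source <- match.arg(source)
  col <- if (source == "INSO") "inso_limit" else "who_limit"
  findings <- empty_findings(source)
  if (!nrow(records)) return(findings)
  for (a in unique(records$analyte)) {
    limit <- registry[[col]][registry$analyte == a]
    if (!length(limit)) stop("analyte not in registry: ", a)
    if (is.na(limit)) {
      message("no ", source, " limit for ", a, "; skipped")
      next
    }
    sub <- records[records$analyte == a & !records$censored &
                     records$value > limit, , drop = FALSE]
    if (nrow(sub)) {
      findings <- rbind(findings,
                        data.frame(brand = sub$brand, season = sub$season,
                                   analyte = a, measured = sub$value,
                                   limit = limit, source = source,
                                   exceeds = TRUE))
    }
  }
  rownames(findings) <- NULL
  findings
}

empty_findings <- function(source) {
  data.frame(brand = character(), season = character(), analyte = character(),
             measured = numeric(), limit = numeric(),
             source = character(), exceeds = logical())
}

#' Check measurements against bottle-label claims
#'
#' Compares brand-level measured concentrations with the values claimed
#' on the bottle label. Labels are in mg/L; measurements are converted
#' from the registry unit before comparison. Brands whose label carries
#' no value for an analyte are excluded from that analyte's denominator.
#' A "less than" claim is exceeded when the measurement exceeds its
#' bound. Censored measurements never exceed.
#'
#' @param records Concentration records.
#' @param labels Label entries from [read_label_table()].
#' @param aggregation How multi-season measurements map to one
#'   comparison value per brand: `"brand_max"` (default: a brand
#'   exceeds if any season does), `"brand_mean"`, or `"per_season"`
#'   (one comparison, and possible finding, per season).
#' @param registry Analyte registry.
#' @return List with `findings` (a data.frame like
#'   [check_regulatory()]'s with `label_qualifier` added) and
#'   `exceedance` (per analyte: `n_labeled` brands in the denominator,
#'   `n_exceeding`, `fraction`).
#' @export
check_labels <- function(records, labels,
                         aggregation = c("brand_max", "brand_mean", "per_season"),
                         registry = analyte_registry()) {
  aggregation <- match.arg(aggregation)
  unknown <- setdiff(unique(labels$brand), unique(records$brand))
  if (length(unknown)) {
    stop("label for unknown brand(s): ", paste(unknown, collapse = ", "))
  }
  findings <- cbind(empty_findings("label"), label_qualifier = character())
  exceedance <- data.frame(analyte = character(), n_labeled = integer(),
                           n_exceeding = integer(), fraction = numeric())
  for (a in unique(labels$analyte)) {
    lab_a <- labels[labels$analyte == a & labels$qualifier != "absent", ,
                    drop = FALSE]
    unit <- registry$unit[registry$analyte == a]
    if (!length(unit)) stop("analyte not in registry: ", a)
    rec_a <- records[records$analyte == a & !records$censored, , drop = FALSE]
    n_lab <- 0L
    exceeding_brands <- character()
    for (i in seq_len(nrow(lab_a))) {
      b <- lab_a$brand[i]
      claim <- lab_a$labeled_value[i]
      meas <- rec_a[rec_a$brand == b, , drop = FALSE]
      if (!nrow(meas)) next
      n_lab <- n_lab + 1L
      mgL <- convert_units(meas$value, unit, "mg/L")
      cmp <- switch(aggregation,
                    brand_max = data.frame(season = "pooled", value = max(mgL)),
                    brand_mean = data.frame(season = "pooled", value = mean(mgL)),
                    per_season = data.frame(season = meas$season, value = mgL))
      hit <- cmp[cmp$value > claim, , drop = FALSE]
      if (nrow(hit)) {
        exceeding_brands <- c(exceeding_brands, b)
        findings <- rbind(findings,
                          data.frame(brand = b, season = hit$season,
                                     analyte = a, measured = hit$value,
                                     limit = claim, source = "label",
                                     exceeds = TRUE,
                                     label_qualifier = lab_a$qualifier[i]))
      }
    }
    exceedance <- rbind(exceedance,
                        data.frame(analyte = a, n_labeled = n_lab,
                                   n_exceeding = length(unique(exceeding_brands)),
                                   fraction = if (n_lab) {
                                     length(unique(exceeding_brands)) / n_lab
                                   } else NA_real_))
  }
  rownames(findings) <- rownames(exceedance) <- NULL
  list(findings = findings, exceedance = exceedance)
}
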