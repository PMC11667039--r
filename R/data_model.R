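#' Analyte registry
#'
#' Loads the registry of analytes measured in the bottled-water survey:
#' declared unit, limit of detection (LOD) and quantification (LOQ), oral
#' reference dose (RfD, mg/kg/day) where one exists, and the INSO and WHO
#' maximum allowable concentrations in the analyte's declared unit.
#'
#' Units follow the survey tables: nitrate, nitrite, Ca, K, Mg and Na in
#' mg/L; Ba, Be, Fe, Li, Mn and Mo in ug/L. RfDs exist exactly for the
#' eight analytes carried into risk assessment (nitrate, nitrite, Ba, Be,
#' Fe, Li, Mn, Mo).
#'
#' @param path Optional path to a registry JSON file; defaults to the
#'   packaged registry.
#' @return A data.frame of class `analyte_registry` with one row per
#'   analyte and columns `analyte`, `unit`, `lod`, `loq`, `rfd`,
#'   `inso_limit`, `who_limit`.
#' @export
#' @examples
#' reg <- analyte_registry()
#' reg[reg$analyte == "nitrite", "lod"]  # 0.001 mg/L
analyte_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "registry.json", package = "aquarisk",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  reg <- do.call(rbind, lapply(names(raw), function(a) {
    e <- raw[[a]]
    data.frame(analyte = a, unit = normalize_unit(e$unit),
               lod = as.numeric(e$lod), loq = as.numeric(e$loq),
               rfd = num_or_na(e$rfd),
               inso_limit = num_or_na(e$inso_limit),
               who_limit = num_or_na(e$who_limit),
               stringsAsFactors = FALSE)
  }))
  validate_registry(reg)
  class(reg) <- c("analyte_registry", "data.frame")
  reg
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg),
            all(c("analyte", "unit", "lod", "loq") %in% names(reg)))
  if (anyDuplicated(reg$analyte)) stop("duplicate analyte in registry")
  if (any(reg$lod <= 0) || any(reg$loq <= 0)) stop("LOD/LOQ must be positive")
  bad <- reg$analyte[reg$loq <= reg$lod]
  if (length(bad)) stop("LOQ must exceed LOD for: ", paste(bad, collapse = ", "))
  if (any(!is.na(reg$rfd) & reg$rfd <= 0)) stop("RfD must be positive")
  invisible(reg)
}

#' Exposure profiles
#'
#' Ingestion-exposure parameter sets for the population groups assessed:
#' water ingestion rate IR (L/day), exposure frequency EF (days/year),
#' exposure duration ED (years), body weight BW (kg) and averaging time
#' AT (days). For non-carcinogenic assessment AT = ED x EF, which makes
#' the chronic daily intake reduce to C x IR / BW.
#'
#' Defaults are the surveyed Iranian consumer groups: children
#' (IR 1 L/day, BW 15 kg, ED 4 y) and adults (IR 2 L/day, BW 70 kg,
#' ED 40 y), both with EF 365 days/year.
#'
#' @param path Optional path to a profiles JSON file; defaults to the
#'   packaged profiles.
#' @return A data.frame with columns `group`, `ir`, `ef`, `ed`, `bw`, `at`.
#' @export
exposure_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "profiles.json", package = "aquarisk",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path)
  prof <- do.call(rbind, lapply(names(raw), function(g) {
    e <- raw[[g]]
    exposure_profile(g, e$ir, e$ef, e$ed, e$bw,
                     if (is.null(e$at)) e$ed * e$ef else e$at)
  }))
  prof
}

#' Construct a single exposure profile
#'
#' @param group Group name (e.g. "children", "adults").
#' @param ir Ingestion rate, L/day.
#' @param ef Exposure frequency, days/year.
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param at Averaging time, days; defaults to `ed * ef` (the
#'   non-carcinogenic convention) and must equal it.
#' @return One-row data.frame.
#' @export
exposure_profile <- function(group, ir, ef, ed, bw, at = ed * ef) {
  vals <- c(ir = ir, ef = ef, ed = ed, bw = bw, at = at)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("exposure profile fields must be strictly positive")
  }
  if (abs(at - ed * ef) > 1e-8 * ed * ef) {
    stop("averaging time must equal ED x EF (non-carcinogenic convention)")
  }
  data.frame(group = group, ir = ir, ef = ef, ed = ed, bw = bw, at = at,
             stringsAsFactors = FALSE)
}

normalize_unit <- function(unit) {
  u <- trimws(unit)
  u[u %in% c("\u00b5g/L", "\u03bcg/L", "ug/L")] <- "ug/L"  # micro/mu aliases
  if (!all(u %in% c("mg/L", "ug/L"))) {
    stop("unsupported unit: ", paste(setdiff(u, c("mg/L", "ug/L")), collapse = ", "))
  }
  u
}

#' Convert concentrations between mg/L and ug/L
#'
#' @param value Numeric vector of concentrations.
#' @param from_unit,to_unit `"mg/L"` or `"ug/L"` (micro sign accepted).
#' @return Converted numeric vector.
#' @export
#' @examples
#' convert_units(12.32, "mg/L", "ug/L")  # 12320
convert_units <- function(value, from_unit, to_unit) {
  from <- normalize_unit(from_unit)
  to <- normalize_unit(to_unit)
  if (from == to) return(value)
  if (from == "mg/L" && to == "ug/L") return(value * 1000)
  value / 1000
}

brand_water_type <- function(brand) {
  ok <- grepl("^(BDW|BMW)[0-9]+$", brand)
  if (!all(ok)) {
    stop("malformed brand code(s): ", paste(unique(brand[!ok]), collapse = ", "))
  }
  substr(brand, 1, 3)
}

#' Read a long-format concentration table
#'
#' Parses the package's CSV dialect: comma-separated, UTF-8, one header
#' row with columns `brand,season,analyte,value,sd`. A value written as
#' `<x` marks a left-censored measurement (below the detection limit);
#' the record is stored with `censored = TRUE` and its value set to the
#' registry LOD for that analyte (the censoring bound, not an
#' observation).
#'
#' @param file Path or connection to the CSV.
#' @param registry An [analyte_registry()] data.frame.
#' @return A data.frame of concentration records with columns `brand`,
#'   `water_type` (derived from the brand prefix), `season`, `analyte`,
#'   `value`, `censored`, `sd`.
#' @export
read_concentration_table <- function(file, registry = analyte_registry()) {
  raw <- utils::read.csv(file, colClasses = "character", strip.white = TRUE)
  need <- c("brand", "season", "analyte", "value")
  if (!all(need %in% names(raw))) {
    stop("header must declare columns: ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0) return(empty_records())
  unknown <- setdiff(unique(raw$analyte), registry$analyte)
  if (length(unknown)) {
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "))
  }
  censored <- startsWith(raw$value, "<")
  value <- suppressWarnings(as.numeric(sub("^<", "", raw$value)))
  if (any(is.na(value))) {
    stop("non-numeric value in row(s): ",
         paste(which(is.na(value)), collapse = ", "))
  }
  if (any(value[!censored] < 0)) {
    stop("negative concentration in row(s): ",
         paste(which(!censored & value < 0), collapse = ", "))
  }
  # censored entries carry the registry LOD, tolerating rounded printed bounds
  lod <- registry$lod[match(raw$analyte, registry$analyte)]
  value[censored] <- lod[censored]
  sd <- if ("sd" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$sd))
  } else {
    rep(NA_real_, nrow(raw))
  }
  if (any(!is.na(sd) & sd < 0)) stop("negative replicate sd")
  key <- paste(raw$brand, raw$season, raw$analyte, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (brand, season, analyte): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rec <- data.frame(brand = raw$brand,
                    water_type = brand_water_type(raw$brand),
                    season = raw$season, analyte = raw$analyte,
                    value = value, censored = censored, sd = sd,
                    stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

empty_records <- function() {
  data.frame(brand = character(), water_type = character(),
             season = character(), analyte = character(),
             value = numeric(), censored = logical(), sd = numeric(),
             stringsAsFactors = FALSE)
}

validate_records <- function(records) {
  stopifnot(all(c("brand", "water_type", "season", "analyte",
                  "value", "censored", "sd") %in% names(records)))
  if (any(records$value < 0)) stop("concentrations must be non-negative")
  if (!all(records$water_type == substr(records$brand, 1, 3))) {
    stop("brand prefix must agree with water_type")
  }
  if (!all(records$season %in% c("summer", "winter", "pooled"))) {
    stop("season must be summer, winter or pooled")
  }
  invisible(records)
}

#' Write a concentration table
#'
#' Inverse of [read_concentration_table()]: censored records are written
#' back as `<LOD`. A write-then-read round trip reproduces the records.
#'
#' @param records Concentration records.
#' @param file Destination path or connection.
#' @return `records`, invisibly.
#' @export
write_concentration_table <- function(records, file) {
  value <- ifelse(records$censored,
                  paste0("<", format(records$value, trim = TRUE,
                                     scientific = FALSE, drop0trailing = TRUE)),
                  format(records$value, trim = TRUE, scientific = FALSE,
                         drop0trailing = TRUE))
  sd <- ifelse(is.na(records$sd), "",
               format(records$sd, trim = TRUE, scientific = FALSE,
                      drop0trailing = TRUE))
  out <- data.frame(brand = records$brand, season = records$season,
                    analyte = records$analyte, value = value, sd = sd)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' Read a bottle-label claims table
#'
#' CSV with columns `brand,analyte,label`, where `label` is a number in
#' mg/L, `<x` for a "less than" claim, or `NA` when the label carries no
#' value for that analyte.
#'
#' @param file Path or connection.
#' @return A data.frame with columns `brand`, `analyte`, `labeled_value`
#'   (mg/L; `NA` when absent) and `qualifier` (`"exact"`, `"less_than"`
#'   or `"absent"`).
#' @export
read_label_table <- function(file) {
  raw <- utils::read.csv(file, colClasses = "character", strip.white = TRUE,
                         na.strings = NULL)
  if (!all(c("brand", "analyte", "label") %in% names(raw))) {
    stop("header must declare columns: brand, analyte, label")
  }
  brand_water_type(raw$brand)  # validates codes
  qualifier <- ifelse(raw$label == "NA", "absent",
                      ifelse(startsWith(raw$label, "<"), "less_than", "exact"))
  value <- suppressWarnings(as.numeric(sub("^<", "", raw$label)))
  value[qualifier == "absent"] <- NA_real_
  if (any(is.na(value) & qualifier != "absent")) stop("non-numeric label value")
  if (any(!is.na(value) & value < 0)) stop("labels must be non-negative")
  data.frame(brand = raw$brand, analyte = raw$analyte,
             labeled_value = value, qualifier = qualifier,
             stringsAsFactors = FALSE)
}

#' Load a packaged survey fixture
#'
#' The packaged fixtures transcribe the two-season survey of 30 bottled
#' water brands (15 bottled drinking water, BDW; 15 bottled mineral
#' water, BMW): `table1` the per-season nitrate/nitrite measurements
#' (120 records), `table2`/`table3` the season-pooled element
#' concentrations of the BDW and BMW brands, `table4` the bottle-label
#' claims, plus the analyte `registry` and exposure `profiles`.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table4"`,
#'   `"registry"`, `"profiles"`.
#' @return Concentration records, label entries, registry or profiles,
#'   according to `name`.
#' @export
#' @examples
#' anions <- load_fixture("table1")
#' nrow(anions)  # 120
load_fixture <- function(name) {
  known <- c("table1", "table2", "table3", "table4", "registry", "profiles")
  if (length(name) != 1 || !name %in% known) {
    stop("unknown fixture; available: ", paste(known, collapse = ", "))
  }
  if (name == "registry") return(analyte_registry())
  if (name == "profiles") return(exposure_profiles())
  path <- system.file("extdata", paste0(name, ".csv"), package = "aquarisk",
                      mustWork = TRUE)
  if (name == "table4") return(read_label_table(path))
  read_concentration_table(path, analyte_registry())
}

#' Load the full fixture concentration dataset
#'
#' Convenience: `table1` (anions, per season) plus `table2` and `table3`
#' (elements, season-pooled) bound into one record set.
#'
#' @return Concentration records (420 rows).
#' @export
load_survey <- function() {
  rbind(load_fixture("table1"), load_fixture("table2"), load_fixture("table3"))
}

#' Substitute left-censored values
#'
#' Maps a set of concentration records for one analyte to a plain
#' numeric vector, applying the chosen censoring rule: `half_lod`
#' replaces censored entries by LOD/2, `lod` by the LOD itself, `drop`
#' removes them.
#'
#' @param records Concentration records (single analyte).
#' @param registry Analyte registry (supplies the LOD).
#' @param censor_rule `"half_lod"`, `"lod"` or `"drop"`.
#' @return Numeric vector of concentrations in the analyte's unit.
#' @export
substitute_censored <- function(records, registry = analyte_registry(),
                                censor_rule = c("half_lod", "lod", "drop")) {
  censor_rule <- match.arg(censor_rule)
  a <- unique(records$analyte)
  if (length(a) != 1) stop("records must cover exactly one analyte")
  lod <- registry$lod[registry$analyte == a]
  if (!length(lod)) stop("analyte not in registry: ", a)
  v <- records$value
  cen <- records$censored
  switch(censor_rule,
         half_lod = {
           v[cen] <- lod / 2
           v
         },
         lod = {
           v[cen] <- lod
           v
         },
         drop = v[!cen])
}
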