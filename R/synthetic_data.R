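# Synthetic survey generator: lognormal concentrations with brand and
# season effects, left-censored at a configurable detection limit, so
# every pipeline stage can be exercised against known ground truth.

#' Synthetic survey configuration
#'
#' Describes the generative world: per-analyte lognormal parameters on
#' the log scale, a per-brand lognormal random effect, a summer
#' multiplier, and the censoring limit. Defaults emulate the packaged
#' survey's structure: 15 brands per water type, two seasons, a
#' nitrate-like analyte spanning two orders of magnitude with LOD
#' 0.14 mg/L, a nitrite-like trace anion censored in a sizeable
#' fraction of samples, and a Ba-like element.
#'
#' @param analytes data.frame with columns `analyte`, `meanlog`,
#'   `sdlog`, `lod`, `unit`, `rfd` (NA for no reference dose).
#' @param n_brands Brands per water type (>= 1).
#' @param brand_sd Standard deviation of the per-brand effect on the
#'   log scale (0 disables brand effects).
#' @param season_multiplier Multiplicative summer effect (> 0; 1
#'   disables it).
#' @param seasons Character vector of seasons to generate.
#' @param seed Integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(analytes = default_synthetic_analytes(),
                             n_brands = 15, brand_sd = 0.5,
                             season_multiplier = 1.3,
                             seasons = c("summer", "winter"), seed = 1) {
  stopifnot(is.data.frame(analytes),
            all(c("analyte", "meanlog", "sdlog", "lod", "unit", "rfd")
                %in% names(analytes)))
  if (any(analytes$sdlog <= 0)) stop("sdlog must be positive")
  if (any(analytes$lod < 0)) stop("lod must be non-negative")
  if (n_brands < 1) stop("need at least one brand per water type")
  if (brand_sd < 0) stop("brand_sd must be non-negative")
  if (season_multiplier <= 0) stop("season multiplier must be positive")
  structure(list(analytes = analytes, n_brands = as.integer(n_brands),
                 brand_sd = brand_sd, season_multiplier = season_multiplier,
                 seasons = seasons, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_synthetic_analytes <- function() {
  data.frame(
    analyte = c("nitrate", "nitrite", "Ba"),
    meanlog = c(log(4), log(0.004), log(5)),
    sdlog = c(1.0, 1.2, 1.3),
    lod = c(0.14, 0.001, 0.098),
    unit = c("mg/L", "mg/L", "ug/L"),
    rfd = c(1.6, 0.1, 0.2),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic concentration dataset
#'
#' Concentrations are drawn per analyte as
#' `exp(meanlog + brand_effect + summer_shift + N(0, sdlog))`; draws
#' below the analyte's LOD are emitted as censored records carrying the
#' LOD as bound. Fixed seed implies identical output.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (concentration records),
#'   `registry` (an analyte registry for the synthetic analytes, with
#'   LOQ set to 3 x LOD and no regulatory limits) and `truth` (the
#'   generative parameters, including the realized per-brand effects).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  an <- config$analytes
  brands <- c(paste0("BDW", seq_len(config$n_brands)),
              paste0("BMW", seq_len(config$n_brands)))
  with_seed(config$seed, {
    brand_eff <- matrix(stats::rnorm(length(brands) * nrow(an), 0,
                                     config$brand_sd),
                        nrow = length(brands),
                        dimnames = list(brands, an$analyte))
    rows <- list()
    for (j in seq_len(nrow(an))) {
      for (b in seq_along(brands)) {
        for (s in config$seasons) {
          mu <- an$meanlog[j] + brand_eff[b, j] +
            if (s == "summer") log(config$season_multiplier) else 0
          v <- stats::rlnorm(1, mu, an$sdlog[j])
          cen <- v < an$lod[j]
          rows[[length(rows) + 1L]] <- data.frame(
            brand = brands[b], water_type = substr(brands[b], 1, 3),
            season = s, analyte = an$analyte[j],
            value = if (cen) an$lod[j] else v, censored = cen,
            sd = NA_real_, stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, rows)
  })
  registry <- data.frame(analyte = an$analyte, unit = normalize_unit(an$unit),
                         lod = an$lod, loq = 3 * an$lod, rfd = an$rfd,
                         inso_limit = NA_real_, who_limit = NA_real_,
                         stringsAsFactors = FALSE)
  class(registry) <- c("analyte_registry", "data.frame")
  validate_records(records)
  list(records = records, registry = registry,
       truth = list(config = config, brand_effects = brand_eff))
}

#' Generate synthetic bottle-label claims
#'
#' Labels each brand x analyte with `brand mean x bias x noise`, where
#' the brand mean is taken over its detected records and the noise is
#' lognormal with log-scale standard deviation `noise_sd`. A
#' configurable fraction of labels is set to absent; brands with no
#' detected record get an absent label.
#'
#' @param records Concentration records.
#' @param bias Multiplicative label bias (> 0; < 1 understates, so
#'   measurements tend to exceed the label).
#' @param noise_sd Log-scale noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param na_fraction Fraction of labels set to absent.
#' @param registry Optional analyte registry; when supplied, label
#'   values are converted from the analyte's unit to mg/L (the label
#'   convention [check_labels()] expects). When `NULL` labels stay in
#'   the records' native unit.
#' @return Label entries as from [read_label_table()].
#' @export
generate_labels <- function(records, bias = 1, noise_sd = 0, seed = 1,
                            na_fraction = 0, registry = NULL) {
  if (bias <= 0) stop("bias must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  combos <- unique(records[, c("brand", "analyte")])
  with_seed(seed, {
    out <- lapply(seq_len(nrow(combos)), function(i) {
      sub <- records[records$brand == combos$brand[i] &
                       records$analyte == combos$analyte[i] &
                       !records$censored, , drop = FALSE]
      if (!nrow(sub)) {
        return(data.frame(brand = combos$brand[i],
                          analyte = combos$analyte[i],
                          labeled_value = NA_real_, qualifier = "absent"))
      }
      m <- mean(sub$value)
      if (!is.null(registry)) {
        u <- registry$unit[registry$analyte == combos$analyte[i]]
        if (length(u)) m <- convert_units(m, u, "mg/L")
      }
      lab <- m * bias * exp(stats::rnorm(1, 0, noise_sd))
      data.frame(brand = combos$brand[i], analyte = combos$analyte[i],
                 labeled_value = lab, qualifier = "exact",
                 stringsAsFactors = FALSE)
    })
    labels <- do.call(rbind, out)
    if (na_fraction > 0) {
      drop <- stats::runif(nrow(labels)) < na_fraction
      labels$labeled_value[drop] <- NA_real_
      labels$qualifier[drop] <- "absent"
    }
  })
  labels
}
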