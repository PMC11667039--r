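# Non-carcinogenic ingestion risk: chronic daily intake (CDI), hazard
# quotient (HQ = CDI / RfD), and Monte-Carlo percentile estimates with an
# explicit concentration distribution model for left-censored data.

#' Chronic daily intake via drinking-water ingestion
#'
#' CDI = C x IR x EF x ED / (BW x AT), in mg/kg body weight/day, for a
#' concentration C in mg/L. With the non-carcinogenic averaging-time
#' convention AT = ED x EF this reduces to C x IR / BW; both forms are
#' computed and must agree.
#'
#' @param c_mgL Concentration(s), mg/L.
#' @param profile One-row exposure profile ([exposure_profile()]).
#' @return CDI, mg/kg bw/day (vectorized over `c_mgL`).
#' @export
#' @examples
#' children <- exposure_profile("children", ir = 1, ef = 365, ed = 4, bw = 15)
#' chronic_daily_intake(38.87, children)  # 2.5913...
chronic_daily_intake <- function(c_mgL, profile) {
  if (any(c_mgL < 0)) stop("concentration must be non-negative")
  if (profile$bw <= 0 || profile$at <= 0) {
    stop("body weight and averaging time must be positive")
  }
  full <- c_mgL * profile$ir * profile$ef * profile$ed / (profile$bw * profile$at)
  short <- c_mgL * profile$ir / profile$bw
  stopifnot(all(abs(full - short) <= 1e-9 * pmax(short, 1)))
  # the reduced form: exactly invariant to joint ED/EF changes under AT = ED x EF
  short
}

#' Hazard quotient
#'
#' HQ = CDI / RfD; values above 1 indicate potential non-carcinogenic
#' health effects.
#'
#' @param cdi Chronic daily intake, mg/kg bw/day.
#' @param rfd Oral reference dose, mg/kg/day; must be positive.
#' @return HQ (dimensionless), with attribute `"flagged"` TRUE when any
#'   HQ exceeds 1.
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (length(rfd) != 1 || is.na(rfd)) {
    stop("missing RfD")
  }
  if (rfd <= 0) stop("RfD must be positive")
  hq <- cdi / rfd
  attr(hq, "flagged") <- any(hq > 1)
  hq
}

#' Linear-interpolation percentile
#'
#' Order-statistic percentile with linear interpolation at position
#' h = (n - 1) p / 100 + 1 (the convention also known as quantile
#' type 7).
#'
#' @param samples Non-empty numeric vector.
#' @param p Percentile(s) strictly between 0 and 100.
#' @return Numeric vector, one value per `p`.
#' @export
#' @examples
#' percentile(1:100, 95)  # 95.05
percentile <- function(samples, p) {
  if (!length(samples) || any(is.na(samples))) {
    stop("samples must be non-empty and free of NA")
  }
  if (any(p <= 0 | p >= 100)) stop("percentiles must lie in (0, 100)")
  s <- sort(samples)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Fit a concentration distribution model
#'
#' Builds the sampling model the Monte-Carlo simulation draws from.
#' Censored values are first substituted per `censor_rule` (see
#' [substitute_censored()]); then:
#' \describe{
#'   \item{empirical_bootstrap}{stores the substituted value multiset and
#'     samples it with replacement (the default elsewhere: it assumes no
#'     parametric family);}
#'   \item{lognormal}{maximum-likelihood fit of (meanlog, sdlog) on the
#'     log scale of the strictly positive values;}
#'   \item{normal}{moment fit; sampling is truncated at zero so drawn
#'     concentrations are non-negative;}
#'   \item{degenerate}{a single constant (returned automatically
#'     whenever all substituted values are equal, whatever family was
#'     requested).}
#' }
#'
#' @param values Numeric concentrations, or concentration records (then
#'   `censored`/`lod` are taken from the records and `registry`).
#' @param censored Logical vector marking censored entries (recycled
#'   FALSE if omitted).
#' @param lod Detection limit used for substitution of censored entries.
#' @param family Distribution family (see above).
#' @param censor_rule `"half_lod"`, `"lod"` or `"drop"`.
#' @param registry Registry used when `values` is a record data.frame.
#' @return Object of class `dist_model`.
#' @export
fit_distribution <- function(values, censored = NULL, lod = NULL,
                             family = c("empirical_bootstrap", "lognormal",
                                        "normal", "degenerate"),
                             censor_rule = c("half_lod", "lod", "drop"),
                             registry = analyte_registry()) {
  family <- match.arg(family)
  censor_rule <- match.arg(censor_rule)
  if (is.data.frame(values)) {
    v <- substitute_censored(values, registry, censor_rule)
  } else {
    censored <- if (is.null(censored)) rep(FALSE, length(values)) else censored
    stopifnot(length(censored) == length(values))
    if (any(censored) && censor_rule != "drop" && is.null(lod)) {
      stop("lod required to substitute censored values")
    }
    v <- values
    if (censor_rule == "drop") {
      v <- v[!censored]
    } else if (any(censored)) {
      v[censored] <- if (censor_rule == "half_lod") lod / 2 else lod
    }
  }
  if (!length(v)) stop("no values remain after censoring treatment")
  if (any(v < 0)) stop("concentrations must be non-negative")
  if (length(unique(v)) == 1) {
    return(structure(list(family = "degenerate", params = list(value = v[1]),
                          censor_rule = censor_rule, values = v),
                     class = "dist_model"))
  }
  if (family == "degenerate") stop("degenerate family requires all values equal")
  params <- switch(family,
    empirical_bootstrap = list(),
    lognormal = {
      pos <- v[v > 0]
      if (length(unique(pos)) < 3) stop("lognormal fit needs >= 3 distinct positive values")
      list(meanlog = mean(log(pos)), sdlog = stats::sd(log(pos)) *
             sqrt((length(pos) - 1) / length(pos)))
    },
    normal = {
      if (length(unique(v)) < 3) stop("normal fit needs >= 3 distinct values")
      list(mean = mean(v), sd = stats::sd(v))
    })
  structure(list(family = family, params = params, censor_rule = censor_rule,
                 values = v),
            class = "dist_model")
}

#' Draw concentrations from a fitted distribution model
#'
#' @param model A `dist_model` from [fit_distribution()].
#' @param n Number of draws.
#' @return Non-negative numeric vector of length `n`.
#' @export
draw_concentrations <- function(model, n) {
  stopifnot(inherits(model, "dist_model"), n >= 1)
  switch(model$family,
    degenerate = rep(model$params$value, n),
    empirical_bootstrap = sample(model$values, n, replace = TRUE),
    lognormal = stats::rlnorm(n, model$params$meanlog, model$params$sdlog),
    normal = {
      # inverse-CDF truncation at zero keeps draws non-negative
      p0 <- stats::pnorm(0, model$params$mean, model$params$sd)
      stats::qnorm(stats::runif(n, p0, 1), model$params$mean, model$params$sd)
    })
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Monte-Carlo hazard-quotient simulation
#'
#' Draws `n_iter` concentrations from the model, maps each through the
#' CDI and HQ equations, and reports the requested percentiles of both.
#' Deterministic for a fixed seed. Because HQ is CDI divided by a
#' constant RfD, every HQ percentile equals the matching CDI percentile
#' divided by RfD.
#'
#' @param model A `dist_model`; its values must be in mg/L.
#' @param profile One-row exposure profile.
#' @param rfd Oral reference dose, mg/kg/day.
#' @param n_iter Iterations (default 10000).
#' @param seed Integer seed recorded in the result.
#' @param percentiles Percentiles to report, in (0, 100).
#' @param analyte Optional analyte name carried into the result.
#' @return Object of class `mc_result`: list with `analyte`, `group`,
#'   `n_iter`, `seed`, `cdi_percentiles`, `hq_percentiles`, `mean_hq`,
#'   `flagged` (95th-style: any reported HQ percentile > 1).
#' @export
simulate_hq <- function(model, profile, rfd, n_iter = 10000, seed = 1,
                        percentiles = c(5, 50, 95), analyte = NA_character_) {
  stopifnot(n_iter >= 1)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie in (0, 100)")
  }
  conc <- with_seed(seed, draw_concentrations(model, n_iter))
  cdi <- chronic_daily_intake(conc, profile)
  hq <- hazard_quotient(cdi, rfd)
  cdi_p <- if (n_iter == 1) stats::setNames(rep(cdi, length(percentiles)),
                                            percentiles)
           else stats::setNames(percentile(cdi, percentiles), percentiles)
  hq_p <- cdi_p / rfd
  structure(list(analyte = analyte, group = profile$group,
                 n_iter = n_iter, seed = seed,
                 cdi_percentiles = cdi_p, hq_percentiles = hq_p,
                 mean_hq = mean(hq), flagged = any(hq_p > 1)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo HQ result: %s, %s (n_iter=%d, seed=%d)\n",
              x$analyte, x$group, x$n_iter, x$seed))
  cat("  CDI percentiles:",
      paste(sprintf("p%s=%.3g", names(x$cdi_percentiles), x$cdi_percentiles),
            collapse = ", "), "\n")
  cat("  HQ percentiles: ",
      paste(sprintf("p%s=%.3g", names(x$hq_percentiles), x$hq_percentiles),
            collapse = ", "), "\n")
  cat(sprintf("  mean HQ %.3g%s\n", x$mean_hq,
              if (x$flagged) "  ** HQ > 1 **" else ""))
  invisible(x)
}

#' Full risk-assessment table
#'
#' Runs the Monte-Carlo HQ simulation for every analyte that has an
#' oral reference dose and at least one detected (non-censored) record
#' — analytes never detected (Be, Mo in the packaged survey) are
#' skipped with a message — crossed with every exposure profile.
#' Concentrations are pooled across water types and seasons and
#' converted to mg/L before fitting.
#'
#' @param records Concentration records.
#' @param registry Analyte registry.
#' @param profiles Exposure profiles data.frame.
#' @param n_iter,percentiles,family,censor_rule Simulation settings,
#'   passed to [fit_distribution()] / [simulate_hq()].
#' @param seed Base seed; each analyte x group simulation uses a
#'   distinct deterministic offset of it.
#' @param analytes Optional subset of analytes.
#' @return data.frame, one row per analyte x group, with CDI and HQ
#'   percentile columns (`cdi_p95`, `hq_p95`, ...), `mean_hq` and
#'   `flagged`.
#' @export
risk_report <- function(records, registry = analyte_registry(),
                        profiles = exposure_profiles(),
                        n_iter = 10000, seed = 1, percentiles = c(5, 50, 95),
                        family = "empirical_bootstrap",
                        censor_rule = "half_lod", analytes = NULL) {
  cand <- registry$analyte[!is.na(registry$rfd)]
  cand <- intersect(cand, unique(records$analyte))
  if (!is.null(analytes)) cand <- intersect(cand, analytes)
  rows <- list()
  k <- 0L
  for (a in cand) {
    sub <- records[records$analyte == a, , drop = FALSE]
    if (!any(!sub$censored)) {
      message("no detected values for ", a, "; risk not calculated")
      next
    }
    unit <- registry$unit[registry$analyte == a]
    rfd <- registry$rfd[registry$analyte == a]
    sub$value <- convert_units(sub$value, unit, "mg/L")
    lod_mgL <- convert_units(registry$lod[registry$analyte == a], unit, "mg/L")
    model <- fit_distribution(sub$value, sub$censored, lod = lod_mgL,
                              family = family, censor_rule = censor_rule)
    for (g in seq_len(nrow(profiles))) {
      k <- k + 1L
      res <- simulate_hq(model, profiles[g, , drop = FALSE], rfd,
                         n_iter = n_iter, seed = seed + k,
                         percentiles = percentiles, analyte = a)
      row <- data.frame(analyte = a, group = res$group,
                        n_iter = n_iter, seed = res$seed,
                        rfd = rfd, mean_hq = res$mean_hq,
                        flagged = res$flagged)
      for (p in seq_along(percentiles)) {
        row[[paste0("cdi_p", percentiles[p])]] <- res$cdi_percentiles[[p]]
        row[[paste0("hq_p", percentiles[p])]] <- res$hq_percentiles[[p]]
      }
      rows[[k]] <- row
    }
  }
  if (!length(rows)) {
    return(data.frame(analyte = character(), group = character(),
                      n_iter = integer(), seed = integer(), rfd = numeric(),
                      mean_hq = numeric(), flagged = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
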