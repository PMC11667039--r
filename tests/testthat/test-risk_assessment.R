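children <- exposure_profile("children", ir = 1, ef = 365, ed = 4, bw = 15)
adults <- exposure_profile("adults", ir = 2, ef = 365, ed = 40, bw = 70)

test_that("chronic daily intake follows the ingestion equation", {
  expect_equal(chronic_daily_intake(38.87, children), 38.87 / 15)
  expect_equal(chronic_daily_intake(0, children), 0)
  # children-to-adult ratio is fixed at (1/15)/(2/70) = 7/3
  c_any <- c(0.01, 1.11 * 15, 16.65)
  ratio <- chronic_daily_intake(c_any, children) /
    chronic_daily_intake(c_any, adults)
  expect_equal(ratio, rep(7 / 3, 3))
  # the printed CDI pair 1.11 / 4.76E-1 matches that ratio at its rounding
  expect_equal(1.11 / (7 / 3), 0.476, tolerance = 2e-3)  # printed rounding
  bad <- children
  bad$bw <- 0
  expect_error(chronic_daily_intake(1, bad), "positive")
})

test_that("CDI is independent of ED and EF under the AT = ED x EF constraint", {
  alt <- exposure_profile("children", ir = 1, ef = 180, ed = 11, bw = 15)
  expect_identical(chronic_daily_intake(c(0.3, 16.65), alt),
                   chronic_daily_intake(c(0.3, 16.65), children))
})

test_that("hazard quotient divides CDI by RfD and flags HQ > 1", {
  expect_equal(round(as.numeric(hazard_quotient(1.11, 1.6)), 2), 0.69)
  expect_equal(as.numeric(hazard_quotient(3.84e-3, 0.2)), 1.92e-2)
  expect_equal(as.numeric(hazard_quotient(0, 0.1)), 0)
  expect_false(attr(hazard_quotient(0.5, 1), "flagged"))
  expect_true(attr(hazard_quotient(1.5, 1), "flagged"))
  expect_error(hazard_quotient(1, NA_real_), "missing RfD")
  expect_error(hazard_quotient(1, -1), "positive")
})

test_that("percentile is the linear-interpolation order statistic", {
  expect_equal(percentile(1:100, 95), 95.05)  # h = 99*0.95 + 1 = 95.05
  expect_equal(percentile(7, 50), 7)
  expect_equal(percentile(rep(3.2, 10), c(5, 95)), c(3.2, 3.2))
  set.seed(11)
  x <- rlnorm(57)
  p <- c(2.5, 5, 50, 95, 97.5)
  expect_equal(percentile(x, p),
               unname(stats::quantile(x, p / 100, type = 7)))
  expect_error(percentile(numeric(0), 50), "non-empty")
  expect_error(percentile(1:5, 100), "0, 100")
})

test_that("distribution fitting applies censoring rules and degenerates", {
  m <- fit_distribution(c(5, 5, 5), family = "lognormal")
  expect_equal(m$family, "degenerate")
  expect_equal(m$params$value, 5)

  m <- fit_distribution(c(0.5, 0.14, 0.9), censored = c(FALSE, TRUE, FALSE),
                        lod = 0.14)
  expect_true(0.07 %in% m$values)  # half-LOD substitution entered the set
  expect_equal(m$family, "empirical_bootstrap")

  expect_error(fit_distribution(c(0.14, 0.14), censored = c(TRUE, TRUE),
                                lod = 0.14, censor_rule = "drop"),
               "no values")
  expect_error(fit_distribution(c(1, 2), family = "degenerate"), "equal")
})

test_that("lognormal fit recovers known parameters within 3 standard errors", {
  mu <- 1; sigma <- 0.5; n <- 5000
  x <- with(list(), {set.seed(2024); rlnorm(n, mu, sigma)})
  m <- fit_distribution(x, family = "lognormal")
  se_mu <- sigma / sqrt(n)
  se_sigma <- sigma / sqrt(2 * n)
  expect_lt(abs(m$params$meanlog - mu), 3 * se_mu)
  expect_lt(abs(m$params$sdlog - sigma), 3 * se_sigma)
})

test_that("simulate_hq is deterministic, monotone and exact on constants", {
  m <- fit_distribution(c(16.65, 16.65), censored = c(FALSE, FALSE))
  res <- simulate_hq(m, children, rfd = 1.6, n_iter = 500, seed = 3)
  expect_equal(unname(res$hq_percentiles), rep(0.69375, 3))
  expect_false(res$flagged)

  m2 <- fit_distribution(c(0.3, 1.2, 5.4, 9.8, 20.1, 38.9))
  a <- simulate_hq(m2, children, 1.6, n_iter = 2000, seed = 9,
                   percentiles = c(5, 25, 50, 75, 95))
  b <- simulate_hq(m2, children, 1.6, n_iter = 2000, seed = 9,
                   percentiles = c(5, 25, 50, 75, 95))
  expect_identical(a, b)                     # fixed seed, bit-identical
  expect_false(is.unsorted(a$hq_percentiles))  # monotone in the percentile
  expect_equal(unname(a$hq_percentiles),
               unname(a$cdi_percentiles) / 1.6)  # HQ_p = CDI_p / RfD
  expect_error(simulate_hq(m2, children, 1.6, percentiles = c(50, 101)),
               "0, 100")
})

test_that("simulated 95th percentile matches the lognormal closed form", {
  mu <- log(5); sigma <- 0.5; rfd <- 1.6; n_iter <- 10000
  m <- structure(list(family = "lognormal",
                      params = list(meanlog = mu, sdlog = sigma),
                      censor_rule = "half_lod", values = numeric()),
                 class = "dist_model")
  res <- simulate_hq(m, children, rfd, n_iter = n_iter, seed = 5)
  k <- children$ir / children$bw / rfd
  q95 <- exp(mu + qnorm(0.95) * sigma)
  se <- sqrt(0.95 * 0.05 / n_iter) / dlnorm(q95, mu, sigma) * k
  expect_lt(abs(res$hq_percentiles[["95"]] - q95 * k), 3 * se)
})

test_that("normal-family draws are truncated at zero", {
  m <- fit_distribution(c(0.1, 0.5, 1.1, -0.0), family = "normal")
  x <- local({set.seed(8); draw_concentrations(m, 5000)})
  expect_true(all(x >= 0))
})

test_that("risk_report covers analytes with RfD and flags forced HQ > 1", {
  survey <- load_survey()
  rr <- suppressMessages(risk_report(survey, n_iter = 2000, seed = 1))
  expect_equal(nrow(rr), 12)  # 6 analytes x 2 groups; Be and Mo skipped
  expect_setequal(unique(rr$analyte),
                  c("nitrate", "nitrite", "Ba", "Fe", "Li", "Mn"))
  expect_false(any(rr$flagged))
  expect_message(risk_report(survey, n_iter = 10, analytes = c("Be", "nitrate")),
                 "no detected values for Be")

  tiny_rfd <- analyte_registry()
  tiny_rfd$rfd[tiny_rfd$analyte == "nitrate"] <- 1e-6
  forced <- suppressMessages(
    risk_report(survey, tiny_rfd, n_iter = 500, analytes = "nitrate"))
  expect_true(all(forced$flagged))

  empty <- suppressMessages(risk_report(survey, analytes = character(0)))
  expect_equal(nrow(empty), 0)
})
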