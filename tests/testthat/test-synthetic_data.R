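one_analyte <- function(meanlog, sdlog, lod, rfd = 1.6) {
  data.frame(analyte = "nitrate", meanlog = meanlog, sdlog = sdlog,
             lod = lod, unit = "mg/L", rfd = rfd, stringsAsFactors = FALSE)
}

test_that("censoring of generated data follows the configured LOD", {
  # LOD far above the distribution: everything censored
  high <- synthetic_config(one_analyte(0, 0.3, lod = exp(0 + 4 * 0.3)),
                           n_brands = 20, brand_sd = 0, season_multiplier = 1,
                           seasons = "summer", seed = 4)
  ds <- generate_dataset(high)
  expect_equal(detection_rate(ds$records, "nitrate")$detection_rate, 0)
  expect_true(all(ds$records$value == high$analytes$lod))
  # LOD zero: everything detected
  zero <- synthetic_config(one_analyte(0, 0.3, lod = 0), n_brands = 20,
                           brand_sd = 0, season_multiplier = 1,
                           seasons = "summer", seed = 4)
  expect_equal(detection_rate(generate_dataset(zero)$records,
                              "nitrate")$detection_rate, 1)
})

test_that("generated means recover the lognormal moment", {
  mu <- 2; sigma <- 0.6; n <- 1000
  cfg <- synthetic_config(one_analyte(mu, sigma, lod = 0), n_brands = n / 2,
                          brand_sd = 0, season_multiplier = 1,
                          seasons = "summer", seed = 12)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$records), n)
  m <- mean_detected(ds$records, "nitrate")$mean_detected
  target <- exp(mu + sigma^2 / 2)
  se <- target * sqrt(exp(sigma^2) - 1) / sqrt(n)
  expect_lt(abs(m - target), 3 * se)
})

test_that("identical config gives byte-identical CSV output", {
  cfg <- synthetic_config(seed = 77, n_brands = 8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(generate_dataset(cfg)$records, f1)
  write_concentration_table(generate_dataset(cfg)$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed changes it
  cfg2 <- synthetic_config(seed = 78, n_brands = 8)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(generate_dataset(cfg2)$records, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("generated records pass the reader's validation round trip", {
  cfg <- synthetic_config(seed = 5, n_brands = 6)
  ds <- generate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(ds$records, path)
  back <- read_concentration_table(path, ds$registry)
  expect_equal(back, ds$records)
})

test_that("label bias drives exceedances as constructed", {
  cfg <- synthetic_config(one_analyte(1, 0.5, lod = 0), n_brands = 10,
                          brand_sd = 0.4, season_multiplier = 1,
                          seasons = "summer", seed = 31)
  ds <- generate_dataset(cfg)
  # bias 1, no noise: labels equal the brand means, strict > finds nothing
  fair <- generate_labels(ds$records, bias = 1, noise_sd = 0, seed = 1)
  res <- check_labels(ds$records, fair, "brand_mean", ds$registry)
  expect_equal(nrow(res$findings), 0)
  # bias 0.5: every labelled brand exceeds
  under <- generate_labels(ds$records, bias = 0.5, noise_sd = 0, seed = 1)
  res <- check_labels(ds$records, under, "brand_mean", ds$registry)
  expect_equal(res$exceedance$fraction, 1)
  # absent labels leave the denominator
  sparse <- generate_labels(ds$records, bias = 0.5, noise_sd = 0, seed = 2,
                            na_fraction = 0.5)
  res <- check_labels(ds$records, sparse, "brand_mean", ds$registry)
  expect_equal(res$exceedance$n_labeled, sum(sparse$qualifier != "absent"))
})

test_that("noisy label exceedance matches its closed-form probability", {
  bias <- 0.9; noise_sd <- 0.2
  # exceed iff noise < log(1/bias): probability pnorm(log(1/bias)/noise_sd)
  p_exp <- pnorm(log(1 / bias) / noise_sd)
  n <- 400
  cfg <- synthetic_config(one_analyte(1, 0.5, lod = 0), n_brands = n / 2,
                          brand_sd = 0.3, season_multiplier = 1,
                          seasons = "summer", seed = 8)
  ds <- generate_dataset(cfg)
  labels <- generate_labels(ds$records, bias = bias, noise_sd = noise_sd,
                            seed = 9)
  res <- check_labels(ds$records, labels, "brand_mean", ds$registry)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(res$exceedance$fraction - p_exp), 3 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_brands = 0), "at least one brand")
  expect_error(synthetic_config(season_multiplier = 0), "positive")
  bad <- default_synthetic_analytes()
  bad$sdlog[1] <- -1
  expect_error(synthetic_config(bad), "sdlog")
  expect_error(generate_labels(fixture_anions(), bias = 0), "positive")
})
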