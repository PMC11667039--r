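# Shared fixtures and independent oracles for the test suite.

fixture_elements <- function() {
  rbind(load_fixture("table2"), load_fixture("table3"))
}

fixture_anions <- function() load_fixture("table1")

# build small record sets in code
make_records <- function(brand, season, analyte, value, censored = FALSE,
                         sd = NA_real_) {
  data.frame(brand = brand, water_type = substr(brand, 1, 3),
             season = season, analyte = analyte, value = value,
             censored = censored, sd = sd, stringsAsFactors = FALSE)
}

toy_registry <- function(analyte = "nitrate", unit = "mg/L", lod = 0.14,
                         loq = 0.42, rfd = 1.6, inso = 50, who = 50) {
  reg <- data.frame(analyte = analyte, unit = unit, lod = lod, loq = loq,
                    rfd = rfd, inso_limit = inso, who_limit = who,
                    stringsAsFactors = FALSE)
  class(reg) <- c("analyte_registry", "data.frame")
  reg
}

# Independent Mann-Whitney oracle: U by pairwise counting, exact
# two-sided p by enumerating every reassignment of the pooled values.
mwu_bruteforce <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = p)
}
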