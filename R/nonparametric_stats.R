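# Rank-based group comparisons and the normality gate.
#
# Implemented directly (not via stats::wilcox.test et al.) because the
# required combination — midrank handling of ties in the exact
# permutation null, tie-corrected normal approximation without
# continuity correction, asymptotic one-sample KS with estimated
# parameters — is not available from any single stock routine. Only
# distribution functions from stats:: are used.

np_result <- function(statistic, p_value, method, n, ties, exact = NA) {
  structure(list(statistic = statistic, p_value = min(max(p_value, 0), 1),
                 method = method, n_per_group = n,
                 tie_correction_applied = ties, exact = exact),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = ", "),
              if (isTRUE(x$tie_correction_applied)) ", tie-corrected" else ""))
  invisible(x)
}

midranks <- function(x) rank(x, ties.method = "average")

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups. For small
#' groups (both sizes at most `exact_max`) the p-value is computed by
#' exact enumeration of the permutation null over the pooled midranks;
#' otherwise by the normal approximation with tie correction and no
#' continuity correction. The U statistic reported is for the first
#' sample.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param exact Force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact iff both groups have at most
#'   `exact_max` values.
#' @param exact_max Group-size threshold for the exact path (default 10).
#' @return An `np_test` with `statistic` (U), `p_value`, sizes and
#'   whether ties were corrected.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 10) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  pooled <- c(x, y)
  r <- midranks(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- max(n1, n2) <= exact_max
  if (exact) {
    # enumerate all assignments of n1 of the pooled midranks to group x
    sums <- utils::combn(length(pooled), n1,
                         FUN = function(idx) sum(r[idx]))
    u_all <- sums - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- mean(abs(u_all - mu) >= abs(u - mu) - eps)
    return(np_result(u, p, "mann_whitney_u", c(n1, n2), has_ties, TRUE))
  }
  nn <- n1 + n2
  tie_term <- if (has_ties) {
    t_sizes <- table(pooled)
    sum(t_sizes^3 - t_sizes) / (nn * (nn - 1))
  } else 0
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
  if (sigma == 0) return(np_result(u, 1, "mann_whitney_u", c(n1, n2), TRUE, FALSE))
  z <- (u - mu) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  np_result(u, p, "mann_whitney_u", c(n1, n2), has_ties, FALSE)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of two or more independent groups: H statistic
#' with tie correction, referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups List of at least two numeric vectors, each with at
#'   least 2 values.
#' @return An `np_test` with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs at least 2 values")
  pooled <- unlist(groups, use.names = FALSE)
  nn <- length(pooled)
  r <- midranks(pooled)
  idx <- rep(seq_along(groups), n)
  rank_sums <- tapply(r, idx, sum)
  h <- 12 / (nn * (nn + 1)) * sum(rank_sums^2 / n) - 3 * (nn + 1)
  has_ties <- anyDuplicated(pooled) > 0
  if (has_ties) {
    t_sizes <- table(pooled)
    corr <- 1 - sum(t_sizes^3 - t_sizes) / (nn^3 - nn)
    if (corr == 0) return(np_result(0, 1, "kruskal_wallis", n, TRUE))
    h <- h / corr
  }
  p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  np_result(h, p, "kruskal_wallis", n, has_ties)
}

#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS distance between the empirical distribution and a
#' normal with the sample mean and standard deviation, with the
#' asymptotic KS p-value. Because the reference parameters are
#' estimated from the same sample, the p-value is anti-conservative
#' (a Lilliefors correction would reject more often); it is used here
#' only as the gate that motivates rank-based tests.
#'
#' @param x Numeric vector, n >= 4, non-constant.
#' @return An `np_test` with `statistic` (D) and `p_value`.
#' @export
ks_normality <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  if (length(unique(x)) == 1) stop("constant sample")
  s <- sort(x)
  f <- stats::pnorm(s, mean(x), stats::sd(x))
  d_plus <- max(seq_len(n) / n - f)
  d_minus <- max(f - (seq_len(n) - 1) / n)
  d <- max(d_plus, d_minus)
  lambda <- sqrt(n) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  np_result(d, p, "ks_normality", n, FALSE)
}

#' Survey-style group comparisons
#'
#' Runs the comparisons behind the survey's significance stars: for
#' every analyte, bottled drinking water (BDW) versus bottled mineral
#' water (BMW) by Mann-Whitney U; for per-season analytes additionally
#' summer versus winter by Kruskal-Wallis; and the KS normality gate on
#' the pooled values. Elements (season-pooled records) are compared on
#' brand values; anions on brand x season values. Censored values enter
#' at half the detection limit, so ties among them are handled by the
#' tie correction.
#'
#' @param records Concentration records.
#' @param registry Analyte registry.
#' @return data.frame: `analyte`, `comparison`, `method`, `statistic`,
#'   `p_value`, `n1`, `n2`, `significant` (p < 0.05).
#' @export
compare_groups <- function(records, registry = analyte_registry()) {
  out <- list()
  for (a in sort(unique(records$analyte))) {
    sub <- records[records$analyte == a, , drop = FALSE]
    vals <- substitute_censored(sub, registry, "half_lod")
    add <- function(comparison, res, n1, n2) {
      out[[length(out) + 1L]] <<- data.frame(
        analyte = a, comparison = comparison, method = res$method,
        statistic = res$statistic, p_value = res$p_value,
        n1 = n1, n2 = n2, significant = res$p_value < 0.05)
    }
    x <- vals[sub$water_type == "BDW"]
    y <- vals[sub$water_type == "BMW"]
    if (length(x) >= 2 && length(y) >= 2 &&
        length(unique(c(x, y))) > 1) {
      add("BDW_vs_BMW", mann_whitney_u(x, y), length(x), length(y))
    }
    if (all(sub$season %in% c("summer", "winter"))) {
      s <- vals[sub$season == "summer"]
      w <- vals[sub$season == "winter"]
      if (length(s) >= 2 && length(w) >= 2 && length(unique(c(s, w))) > 1) {
        add("summer_vs_winter", kruskal_wallis(list(s, w)), length(s), length(w))
      }
    }
    if (length(vals) >= 4 && length(unique(vals)) > 1) {
      add("normality", ks_normality(vals), length(vals), NA_integer_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
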