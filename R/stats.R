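# Statistical toolkit used by the study pipeline: exact Fisher tests for
# r x 2 tables by full enumeration, differences of proportions with binomial
# CIs, Wilcoxon rank-sum with the Hodges-Lehmann shift estimate, Lin's
# concordance correlation coefficient with a percentile bootstrap, and
# median/IQR descriptives.

#' Construct a test-result container
#'
#' Uniform return shape for the toolkit: point estimate, confidence bounds
#' and p-value may each be absent (`NA`), and `method` names the exact
#' procedure (including the exact/approximate branch taken and any
#' resampling seed) so every number in a report is traceable.
#'
#' @param estimate,ci_low,ci_high,p_value Numeric scalars or `NA`.
#' @param method Character description of the procedure.
#' @param ... Further metadata fields (e.g. `n_resamples`, `seed`).
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        method = "", ...) {
  if (!is.na(ci_low) && !is.na(ci_high) && !is.na(estimate))
    stopifnot(ci_low <= estimate + 1e-9, estimate <= ci_high + 1e-9)
  structure(c(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                   p_value = p_value, method = method), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$method, "\n")
  if (!is.na(x$estimate)) cat(sprintf("  estimate: %.4g", x$estimate))
  if (!is.na(x$ci_low)) cat(sprintf("  [%.4g, %.4g]", x$ci_low, x$ci_high))
  if (!is.na(x$p_value)) cat(sprintf("  p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

# enumerate all first-column count vectors compatible with the margins of an
# r x 2 table; returns a matrix with one row per table
.enum_col1 <- function(rows, c1) {
  r <- length(rows)
  rec <- function(i, left) {
    if (i == r) {
      if (left <= rows[i]) return(matrix(left, 1, 1)) else return(NULL)
    }
    lo <- max(0L, left - sum(rows[(i + 1):r]))
    hi <- min(rows[i], left)
    if (lo > hi) return(NULL)
    out <- lapply(lo:hi, function(k) {
      sub <- rec(i + 1L, left - k)
      if (is.null(sub)) return(NULL)
      cbind(k, sub)
    })
    do.call(rbind, out)
  }
  rec(1L, c1)
}

#' Fisher's exact test for an r x 2 table by full enumeration
#'
#' Enumerates every table sharing the observed margins and sums the
#' multivariate hypergeometric point probabilities of those no more likely
#' than the observed table (the point-probability rule for two-sidedness,
#' with a 1e-7 relative guard against floating-point ties).
#'
#' @param table Non-negative integer matrix with 2 columns and at least 2
#'   rows, total at most `max_total`.
#' @param max_total Enumeration guard on the table total (default 500).
#' @return A [stat_result()] with the two-sided p-value; a table with a
#'   zero row or column margin returns p = 1 with the convention noted in
#'   `method`.
#' @export
fisher_exact <- function(table, max_total = 500) {
  x <- as.matrix(table)
  if (ncol(x) != 2 || nrow(x) < 2)
    stop("fisher_exact requires an r x 2 table with r >= 2")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  N <- sum(x)
  if (N > max_total) stop("table total ", N, " exceeds enumeration guard ", max_total)
  rows <- rowSums(x)
  c1 <- sum(x[, 1])
  if (any(rows == 0) || c1 == 0 || c1 == N)
    return(stat_result(p_value = 1,
                       method = "Fisher exact (full enumeration); zero margin, p = 1 by convention"))
  if (nrow(x) == 2) {
    lo <- max(0L, c1 - rows[2]); hi <- min(rows[1], c1)
    k <- lo:hi
    p <- exp(lchoose(rows[1], k) + lchoose(rows[2], c1 - k) - lchoose(N, c1))
  } else {
    ks <- .enum_col1(rows, c1)
    # log point probability: prod_i C(rows_i, k_i) / C(N, c1)
    logp <- apply(ks, 1, function(kk) sum(lchoose(rows, kk))) - lchoose(N, c1)
    p <- exp(logp)
  }
  p_obs <- exp(sum(lchoose(rows, x[, 1])) - lchoose(N, c1))
  pval <- min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
  stat_result(p_value = pval, method = "Fisher exact (full enumeration)")
}

#' Difference between two proportions with a binomial CI
#'
#' Point estimate in percentage points, oriented as group 2 minus group 1.
#' The CI method is pluggable: `"wald"` (normal approximation on the
#' difference) or `"newcombe"` (Newcombe's hybrid Wilson-score method).
#'
#' @param k1,n1 Successes and size in group 1.
#' @param k2,n2 Successes and size in group 2.
#' @param method `"wald"` or `"newcombe"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A [stat_result()]; estimate and CI are in percentage points.
#' @export
proportion_difference <- function(k1, n1, k2, n2,
                                  method = c("wald", "newcombe"),
                                  conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  d <- p2 - p1
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wald") {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    lo <- d - z * se; hi <- d + z * se
  } else {
    wilson <- function(k, n) {
      ph <- k / n
      den <- 1 + z^2 / n
      ctr <- (ph + z^2 / (2 * n)) / den
      hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
      c(ctr - hw, ctr + hw)
    }
    w1 <- wilson(k1, n1); w2 <- wilson(k2, n2)
    lo <- d - sqrt((p2 - w2[1])^2 + (w1[2] - p1)^2)
    hi <- d + sqrt((w2[2] - p2)^2 + (p1 - w1[1])^2)
  }
  lo <- max(-1, lo); hi <- min(1, hi)
  stat_result(estimate = 100 * d, ci_low = 100 * lo, ci_high = 100 * hi,
              method = paste0("difference of proportions (", method,
                              " binomial CI), group2 - group1"))
}

.use_exact_wilcoxon <- function(x, y, exact_max_n = 25) {
  !anyDuplicated(c(x, y)) && (length(x) + length(y)) <= exact_max_n
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test of a location difference between two independent samples.
#' The p-value is exact (full rank-sum distribution) when the combined
#' sample size is at most `exact_max_n` and there are no ties; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' The branch taken is recorded in `method`.
#'
#' @param x,y Non-empty numeric samples (orientation `y` vs `x`).
#' @param exact_max_n Exact-enumeration cutoff on the combined size.
#' @return A [stat_result()] with the p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 25) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- .use_exact_wilcoxon(x, y, exact_max_n)
  ht <- suppressWarnings(stats::wilcox.test(y, x, exact = exact,
                                            correct = TRUE))
  stat_result(p_value = ht$p.value,
              method = if (exact) "Wilcoxon rank-sum (exact distribution)"
                       else "Wilcoxon rank-sum (tie-corrected normal approximation)")
}

#' Hodges-Lehmann estimate of the between-group shift
#'
#' The median of all pairwise differences `y - x` (group 2 minus group 1),
#' with a confidence interval obtained by inverting the Mann-Whitney
#' distribution (exact for small tie-free samples, normal-approximate
#' otherwise).
#'
#' @param x,y Non-empty numeric samples; the estimate is oriented `y - x`.
#' @param conf_level Confidence level, default 0.95.
#' @param exact_max_n Exact cutoff, as in [wilcoxon_rank_sum()].
#' @return A [stat_result()] with estimate, CI and the rank-sum p-value.
#' @export
hodges_lehmann <- function(x, y, conf_level = 0.95, exact_max_n = 25) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  est <- stats::median(as.vector(outer(y, x, "-")))
  exact <- .use_exact_wilcoxon(x, y, exact_max_n)
  ht <- suppressWarnings(stats::wilcox.test(y, x, exact = exact, correct = TRUE,
                                            conf.int = TRUE,
                                            conf.level = conf_level))
  ci <- as.numeric(ht$conf.int)
  stat_result(estimate = est, ci_low = min(ci[1], est),
              ci_high = max(ci[2], est), p_value = ht$p.value,
              method = paste0("Hodges-Lehmann shift (y - x), ",
                              if (exact) "exact Mann-Whitney inversion"
                              else "normal-approximate Mann-Whitney inversion"))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements, penalising both imperfect
#' correlation and location/scale shift:
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with population (1/n) moments. Equals the Pearson correlation exactly
#' when the two samples share mean and variance; lies in \[-1, 1\].
#'
#' @param x,y Paired numeric vectors of equal length at least 2.
#' @return A [stat_result()] with the CCC as estimate (no CI; see
#'   [bootstrap_ci()]).
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom <= .Machine$double.eps)
    stop("concordance undefined: both samples are the same constant")
  stat_result(estimate = 2 * sxy / denom,
              method = "Lin's concordance correlation coefficient (population moments)")
}

#' Percentile bootstrap CI for a paired statistic
#'
#' Case-resamples the pairs, recomputes `statistic` on each resample and
#' returns the percentile bounds. Reproducible given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param statistic `function(x, y) -> numeric scalar`, e.g.
#'   `function(x, y) lin_ccc(x, y)$estimate`.
#' @param x,y Paired numeric vectors.
#' @param n_resamples Number of bootstrap resamples, at least 100;
#'   default 2000.
#' @param seed Integer seed for the resampling generator.
#' @param conf_level Confidence level, default 0.95.
#' @return A [stat_result()] with the plug-in estimate and percentile CI.
#'   Errors if the statistic is undefined on more than 10% of resamples.
#' @export
bootstrap_ci <- function(statistic, x, y, n_resamples = 2000, seed = 1,
                         conf_level = 0.95) {
  stopifnot(length(x) == length(y), n_resamples >= 100)
  n <- length(x)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  vals <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(as.numeric(statistic(x[idx], y[idx])), error = function(e) NA_real_)
  }, numeric(1))
  bad <- mean(is.na(vals))
  if (bad > 0.10)
    stop(sprintf("statistic undefined on %.0f%% of resamples", 100 * bad))
  qs <- stats::quantile(vals, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  est <- as.numeric(statistic(x, y))
  stat_result(estimate = est, ci_low = min(qs[1], est), ci_high = max(qs[2], est),
              method = sprintf("percentile bootstrap, %d resamples, seed %d",
                               n_resamples, seed),
              n_resamples = n_resamples, seed = seed)
}

#' Median and interquartile range
#'
#' Quantiles use R's type-2 rule (inverse empirical CDF with averaging at
#' discontinuities, the convention of the SAS default), recorded in report
#' metadata.
#'
#' @param x Non-empty numeric vector (NAs dropped).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 2, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}
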