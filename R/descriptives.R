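#' Binomial proportion with a normal-approximation confidence interval
#'
#' Wald interval `p +/- z sqrt(p (1 - p) / n)` (default) or the Wilson
#' score interval, reported in percent; rounding is left to the caller.
#' A degenerate interval (0 or n successes under Wald) triggers a
#' warning.
#'
#' @param count successes.
#' @param n total.
#' @param level coverage (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @return Named numeric vector `c(proportion, lower, upper)`, in
#'   percent.
#' @export
#' @examples
#' proportion_ci(1191, 96218)   # 1.24 (1.17, 1.31)
proportion_ci <- function(count, n, level = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n <= 0 || count < 0 || count > n)
    sn_stop("sn_validation_error", "count must lie in [0, n], n > 0")
  phat <- count / n
  if (method == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    se <- sqrt(phat * (1 - phat) / n)
    if (se == 0) warning("degenerate interval at a boundary proportion")
    ci <- c(phat - z * se, phat + z * se)
  } else {
    ci <- stats::prop.test(count, n, conf.level = level,
                           correct = FALSE)$conf.int
  }
  100 * c(proportion = phat, lower = ci[1], upper = ci[2])
}

#' Pearson chi-square test of independence on a contingency table
#'
#' The classical `sum (O - E)^2 / E` statistic with expected counts from
#' the product of the marginals, no continuity correction, and
#' `df = (r - 1)(c - 1)`.
#'
#' @param counts r x c matrix of non-negative integer counts, at least
#'   2 rows and columns, all marginals positive.
#' @return List with `statistic`, `df` and `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    sn_stop("sn_validation_error", "need at least a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    sn_stop("sn_validation_error", "counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    sn_stop("sn_validation_error", "zero marginal; test undefined")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs between- and within-group sums of squares from group
#' sizes, means and standard deviations; with exact summaries this
#' equals the raw-data one-way ANOVA.
#'
#' @param n,mean,sd equal-length vectors of per-group size (each `>= 2`),
#'   mean and standard deviation (denominator `n - 1`).
#' @return List with `F`, `df1`, `df2` and `p`.
#' @export
#' @examples
#' anova_from_summary(c(1191, 1272, 3479), c(11.25, 7.92, 6.91),
#'                    c(6.35, 5.19, 4.92))
anova_from_summary <- function(n, mean, sd) {
  if (length(n) < 2 || length(mean) != length(n) || length(sd) != length(n))
    sn_stop("sn_validation_error", "need >= 2 groups with n, mean, sd")
  if (any(sd < 0)) sn_stop("sn_validation_error", "negative sd")
  if (any(n < 2)) sn_stop("sn_validation_error", "each group needs n >= 2")
  grand <- sum(n * mean) / sum(n)
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- length(n) - 1
  df2 <- sum(n) - length(n)
  Fval <- (ssb / df1) / (ssw / df2)
  list(F = Fval, df1 = df1, df2 = df2, p = pf(Fval, df1, df2,
                                              lower.tail = FALSE))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total))`, with
#' sample variances (denominator `n - 1`).
#'
#' @param items `n x k` numeric matrix of item scores, `k >= 2`,
#'   `n >= 2`.
#' @return Alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2 || nrow(items) < 2)
    sn_stop("sn_validation_error", "need >= 2 items and >= 2 respondents")
  vt <- var(rowSums(items))
  if (vt == 0)
    sn_stop("sn_validation_error", "zero total-score variance")
  k <- ncol(items)
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / vt)
}

#' Group summaries of instrument sum scores, Table-1 style
#'
#' Per group and instrument: n, mean and SD of the sum score, plus the
#' one-way ANOVA F and p across groups (via [anova_from_summary()]) and
#' Cronbach's alpha per instrument on the pooled sample.
#'
#' @param data a [symptom_dataset()] with at least two groups.
#' @return List with `summaries` (data.frame) and `alpha` (named vector).
#' @export
describe_groups <- function(data) {
  stopifnot(inherits(data, "symptom_dataset"))
  if (nlevels(data$group) < 2)
    sn_stop("sn_usage_error", "need at least two groups")
  out <- NULL
  alphas <- c()
  for (instr in unique(data$items$instrument)) {
    cols <- data$items$name[data$items$instrument == instr]
    tot <- rowSums(data$scores[, cols, drop = FALSE])
    ns <- tapply(tot, data$group, length)
    ms <- tapply(tot, data$group, mean)
    sds <- tapply(tot, data$group, sd)
    a <- anova_from_summary(as.numeric(ns), as.numeric(ms),
                            as.numeric(sds))
    out <- rbind(out, data.frame(instrument = instr,
                                 group = names(ns), n = as.numeric(ns),
                                 mean = as.numeric(ms),
                                 sd = as.numeric(sds),
                                 F = a$F, p = a$p, row.names = NULL))
    alphas[instr] <- cronbach_alpha(data$scores[, cols, drop = FALSE])
  }
  list(summaries = out, alpha = alphas)
}
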