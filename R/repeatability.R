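#' Absolute test-retest variability
#'
#' The primary repeatability index: the absolute difference between the two
#' sessions divided by their mean, in percent. Scale invariant.
#'
#' @param x1,x2 paired values (vectorized); `(x1 + x2)/2` must be > 0.
#' @return percent variability, `100 |x1 - x2| / ((x1 + x2)/2)`.
#' @examples
#' abs_var(3, 1)  # 100
#' @export
abs_var <- function(x1, x2) {
  m <- (x1 + x2) / 2
  if (any(m <= 0)) stop_input("pair mean must be > 0")
  100 * abs(x1 - x2) / m
}

#' Pair test and retest values from a long quantification table
#'
#' @param quant_long output of [quantify_study()] for a two-session study.
#' @return data frame: `subject_id`, `region`, `parameter`, `test_value`,
#'   `retest_value`.
#' @export
paired_values <- function(quant_long) {
  if (!all(c("test", "retest") %in% quant_long$session))
    stop_input("need both test and retest sessions")
  te <- quant_long[quant_long$session == "test", ]
  re <- quant_long[quant_long$session == "retest", ]
  m <- merge(te[, c("subject_id", "region", "parameter", "value")],
             re[, c("subject_id", "region", "parameter", "value")],
             by = c("subject_id", "region", "parameter"),
             suffixes = c("_test", "_retest"))
  data.frame(subject_id = m$subject_id, region = m$region,
             parameter = m$parameter,
             test_value = m$value_test, retest_value = m$value_retest)
}

# Core two-session variance decomposition on paired vectors.
# sigma2_intra = Var(within-subject differences)/2 (df = N-1);
# sigma2_inter = max(0, total variance - sigma2_intra), clipped at 0 when
# random fluctuation makes it negative.
decompose_one <- function(test, retest) {
  n <- length(test)
  if (n < 2L) stop_input("need >= 2 subjects for the decomposition")
  all_vals <- c(test, retest)
  m <- mean(all_vals)
  s2_total <- stats::var(all_vals)          # df = 2N - 1
  s2_intra <- stats::var(test - retest) / 2 # df = N - 1
  s2_inter_raw <- s2_total - s2_intra
  s2_inter <- max(0, s2_inter_raw)
  av <- abs_var(test, retest)
  ci <- ci95(m, sqrt(s2_total), 2 * n)
  ev_den <- s2_intra + s2_inter
  list(mean = m, sd = sqrt(s2_total),
       ci95_low = ci[1], ci95_high = ci[2],
       absvar_mean = mean(av), absvar_sd = stats::sd(av),
       cv_intra = 100 * sqrt(s2_intra) / m,
       cv_inter = 100 * sqrt(s2_inter) / m,
       ev_intra = if (ev_den > 0) 100 * s2_intra / ev_den else NA_real_,
       ev_inter = if (ev_den > 0) 100 * s2_inter / ev_den else NA_real_,
       sigma2_intra = s2_intra, sigma2_inter = s2_inter,
       sigma2_inter_raw = s2_inter_raw,
       n_subjects = n)
}

#' Test-retest variability decomposition
#'
#' For every (parameter, region) cell: grand mean and SD over all 2N
#' values, 95% CI (lower bound clipped at 0), group absolute variability
#' (mean +/- SD over subjects), and the split of the total variance into
#' intra-subject (from paired differences) and inter-subject (total minus
#' intra, clipped at 0 when random fluctuation drives it negative)
#' components, expressed as CV% of the grand mean and as explained-variance
#' shares.
#'
#' @param quant_long long quantification table ([quantify_study()]) of a
#'   test-retest study, or a paired table from [paired_values()].
#' @return data frame, one row per (parameter, region), with columns
#'   `parameter`, `region`, `mean`, `sd`, `ci95_low`, `ci95_high`,
#'   `absvar_mean`, `absvar_sd`, `cv_intra`, `cv_inter`, `ev_intra`,
#'   `ev_inter`, `n_subjects`.
#' @export
decompose_variability <- function(quant_long) {
  pairs <- if (all(c("test_value", "retest_value") %in% names(quant_long)))
    quant_long else paired_values(quant_long)
  cells <- unique(pairs[, c("parameter", "region")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- pairs[pairs$parameter == cells$parameter[i] &
                 pairs$region == cells$region[i], ]
    d <- decompose_one(sub$test_value, sub$retest_value)
    data.frame(parameter = cells$parameter[i], region = cells$region[i],
               mean = d$mean, sd = d$sd,
               ci95_low = d$ci95_low, ci95_high = d$ci95_high,
               absvar_mean = d$absvar_mean, absvar_sd = d$absvar_sd,
               cv_intra = d$cv_intra, cv_inter = d$cv_inter,
               ev_intra = d$ev_intra, ev_inter = d$ev_inter,
               n_subjects = d$n_subjects)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 95% confidence interval with non-negative lower bound
#'
#' mean +/- t(0.975, n-1) x sd, with a negative lower limit clipped to 0
#' (outcome parameters are non-negative quantities).
#'
#' @param mean,sd summary statistics; `sd >= 0`.
#' @param n number of values behind the SD, >= 2.
#' @return c(low, high).
#' @examples
#' ci95(20.6, 10.1, 12)  # upper ~42.8, lower clipped to 0
#' @export
ci95 <- function(mean, sd, n) {
  if (n < 2) stop_input("n must be >= 2")
  if (sd < 0) stop_input("sd must be >= 0")
  tq <- stats::qt(0.975, df = n - 1)
  c(max(0, mean - tq * sd), mean + tq * sd)
}

#' Sample size for a desired precision of the mean
#'
#' n = ceil((t x s / a)^2) with a = precision x mean, floored at 1.
#'
#' @param mean population mean estimate, > 0.
#' @param s population SD estimate, >= 0.
#' @param precision acceptable relative imprecision of the mean (default
#'   0.20).
#' @param t_coef coefficient of confidence (default 1.96 for a 5% alpha
#'   risk).
#' @return A `sample_size_result` list: `mean`, `s`, `precision`, `t_coef`,
#'   `n_required`.
#' @examples
#' sample_size(20.6, 10.1)$n_required  # 24
#' @export
sample_size <- function(mean, s, precision = 0.20, t_coef = 1.96) {
  if (mean <= 0) stop_input("mean must be > 0")
  if (s < 0) stop_input("s must be >= 0")
  a <- precision * mean
  n <- max(1L, as.integer(ceiling((t_coef * s / a)^2)))
  structure(list(mean = mean, s = s, precision = precision,
                 t_coef = t_coef, n_required = n),
            class = "sample_size_result")
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' rho is the Pearson correlation of mid-ranked values. For n <= 8 the
#' two-sided p-value is exact, by full enumeration of the n! orderings of
#' one margin; for larger n the usual t approximation on
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} is used.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A `correlation_result` list: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop_input("need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("rank correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    P <- all_perms(n)                      # n! x n index matrix
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.numeric(matrix(ryc[P], nrow = nrow(P)) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "correlation_result")
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided p-value of the signed-rank statistic. Zero differences are
#' dropped; ties in |d| receive mid-ranks. For N <= 12 non-zero
#' differences the p-value is exact, by enumeration of all 2^N sign
#' assignments (the null distribution is symmetric, so the two-sided
#' p-value counts assignments at least as far from the null mean as the
#' observed statistic); beyond that a normal approximation is used.
#'
#' @param x,y paired vectors (or give differences in `x` and leave `y`
#'   zero).
#' @return A `wilcoxon_result` list: `statistic` (W+), `p_value`, `n_used`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = 0) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) stop_input("need >= 2 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  E <- sum(r) / 2
  if (n <= 12L) {
    sums <- 0
    for (ri in r) sums <- c(sums + ri, sums - ri)   # 2^N signed sums of ranks
    dev <- abs(sums) / 2                            # |W - E| per assignment
    p <- mean(dev >= abs(W - E) - 1e-9)
    method <- "exact enumeration"
  } else {
    sdW <- sqrt(sum(r^2) / 4)
    z <- (W - E) / sdW
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = W, p_value = p, n_used = n, method = method),
            class = "wilcoxon_result")
}

#' Spearman correlation matrix between outcome parameters
#'
#' Correlates the outcome parameters across all (subject, session, region)
#' values with pairwise-complete observations, the usual way such
#' cross-parameter agreement tables are built.
#'
#' @param quant_long long quantification table.
#' @param parameters which parameters to include (default: the five
#'   outcome parameters).
#' @return list with matrices `rho` and `p_value`.
#' @export
parameter_correlations <- function(quant_long,
                                   parameters = c("cmrglu", "suv", "suv_gly",
                                                  "suvr_pons", "suvr_cerebellum")) {
  sub <- quant_long[quant_long$parameter %in% parameters, ]
  wide <- stats::reshape(sub, direction = "wide",
                         idvar = c("subject_id", "session", "region"),
                         timevar = "parameter")
  names(wide) <- sub("^value\\.", "", names(wide))
  k <- length(parameters)
  rho <- matrix(NA_real_, k, k, dimnames = list(parameters, parameters))
  pv <- rho
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { rho[i, j] <- 1; pv[i, j] <- 0; next }
    xi <- wide[[parameters[i]]]; xj <- wide[[parameters[j]]]
    ok <- stats::complete.cases(xi, xj)
    # parameters that never co-occur (or are degenerate) get NA, not an error
    if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
    r <- spearman_cor(xi[ok], xj[ok])
    rho[i, j] <- r$rho; pv[i, j] <- r$p_value
  }
  list(rho = rho, p_value = pv)
}

#' Robustness check: CI membership of an independent group
#'
#' For each parameter, the fraction of (animal x region) values of an
#' independent single-scan group that fall inside the 95% CI built from
#' the test-retest decomposition.
#'
#' @param decomp output of [decompose_variability()].
#' @param new_quant long quantification table of the independent group.
#' @return A `robustness_report`: data frame per parameter with `within`,
#'   `total`, `fraction`, plus attribute `"by_region"` with per-region
#'   counts.
#' @export
robustness_check <- function(decomp, new_quant) {
  params <- unique(decomp$parameter)
  per_region <- list()
  rows <- lapply(params, function(p) {
    dref <- decomp[decomp$parameter == p, ]
    vals <- new_quant[new_quant$parameter == p, ]
    if (!all(unique(vals$region) %in% dref$region))
      stop_input(sprintf("regions of the new study not covered by the decomposition for %s", p))
    m <- merge(vals, dref[, c("region", "ci95_low", "ci95_high")], by = "region")
    inside <- m$value >= m$ci95_low & m$value <= m$ci95_high
    per_region[[p]] <<- stats::aggregate(inside, by = list(region = m$region),
                                         FUN = function(z) c(sum(z), length(z)))
    data.frame(parameter = p, within = sum(inside), total = length(inside),
               fraction = mean(inside))
  })
  out <- do.call(rbind, rows)
  attr(out, "by_region") <- per_region
  class(out) <- c("robustness_report", "data.frame")
  out
}

#' Variance-additivity audit of a printed summary table
#'
#' Checks, for every row with a positive inter-subject CV, that the
#' reconstruction \eqn{\sqrt{cv_{intra}^2 + cv_{inter}^2}} agrees with the
#' total CV implied by the printed mean and SD. Because published tables
#' round mean and SD (typically to one decimal), the audit also computes
#' the half-width of the total-CV interval compatible with that rounding
#' and reports the rounding-adjusted gap
#' `max(0, |reconstructed - printed| - half_width)`.
#'
#' @param summary_df data frame with columns `mean`, `sd`, `cv_intra`,
#'   `cv_inter` (percent), e.g. [reference_summary()].
#' @param printed_ulp rounding unit of the printed mean/SD (default 0.1).
#' @return the input with added columns `cv_total_printed`,
#'   `cv_total_reconstructed`, `gap`, `rounding_half_width`,
#'   `adjusted_gap`, restricted to rows with `cv_inter > 0`.
#' @export
audit_variance_additivity <- function(summary_df, printed_ulp = 0.1) {
  rows <- summary_df[summary_df$cv_inter > 0, , drop = FALSE]
  h <- printed_ulp / 2
  rows$cv_total_printed <- 100 * rows$sd / rows$mean
  rows$cv_total_reconstructed <- sqrt(rows$cv_intra^2 + rows$cv_inter^2)
  rows$gap <- abs(rows$cv_total_reconstructed - rows$cv_total_printed)
  hi <- 100 * (rows$sd + h) / pmax(rows$mean - h, 1e-9)
  lo <- 100 * (rows$sd - h) / (rows$mean + h)
  rows$rounding_half_width <- (hi - lo) / 2
  rows$adjusted_gap <- pmax(0, rows$gap - rows$rounding_half_width)
  rows
}

#' Published macaque FDG test-retest reference summary
#'
#' Regional summary statistics (mean, SD, 95% CI, absolute variability,
#' intra-/inter-subject CVs and explained-variance shares; n = 12 scans
#' from 6 animals) for the five FDG outcome parameters, transcribed from a
#' published cynomolgus macaque test-retest study. Used by the
#' reconstruction audits and as the calibration surface for the synthetic
#' generator.
#'
#' @return data frame with columns `parameter`, `region`, `mean`, `sd`,
#'   `n`, `ci_low`, `ci_high`, `absvar_mean`, `absvar_sd`, `cv_intra`,
#'   `ev_intra`, `cv_inter`, `ev_inter`.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "reference_trt_summary.csv",
                      package = "fdgrepeat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
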