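#' Coefficient of variation
#'
#' Sample SD (n-1 denominator) divided by the mean; scale-invariant under
#' positive rescaling.
#'
#' @param values numeric, n >= 2, non-zero mean
#' @return SD/mean
#' @examples
#' coefVar(c(1, 2, 3)) # 0.5
#' @export
coefVar <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CoV undefined")
  stats::sd(values) / m
}

#' Levene's test on group-mean-normalized values
#'
#' Each group is divided by its own mean (yielding relative deviations, so
#' groups on different scales become comparable), then Levene's test --
#' one-way ANOVA on absolute deviations from the group centre -- is applied
#' to the normalized groups. Mean centring by default, median optionally.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2)
#' @param center `"mean"` (default) or `"median"`
#' @return list: `statistic` (F), `df1`, `df2`, `p.value`, `center`
#' @export
leveneMeanNormalized <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  means <- vapply(groups, mean, numeric(1))
  if (any(means == 0)) stop("degenerate group with zero mean")
  z <- mapply(function(g, m) g / m, groups, means, SIMPLIFY = FALSE)
  centerFun <- if (center == "mean") mean else stats::median
  d <- unlist(lapply(z, function(g) abs(g - centerFun(g))))
  f <- factor(rep(seq_along(z), vapply(z, length, 1L)))
  a <- stats::anova(stats::lm(d ~ f))
  list(statistic = a[1, "F value"], df1 = a[1, "Df"], df2 = a[2, "Df"],
       p.value = a[1, "Pr(>F)"], center = center)
}

#' Weight-group comparison of blood SUVs
#'
#' Independent two-sample t-test (Welch by default) of blood SUV between
#' patients above and below a weight threshold (85 kg), per sample moment
#' and normalization.
#'
#' @param suvTable data.frame with columns `weight` (kg), `time_min`,
#'   `normalization`, `suv` (one row per scan x moment x normalization)
#' @param threshold kg, default 85
#' @param welch use Welch's unequal-variance test (default); `FALSE` for
#'   Student's
#' @return data.frame: one row per (`time_min`, `normalization`) with group
#'   means, `t`, `df`, `p`, `test_kind`
#' @export
weightGroupTTest <- function(suvTable, threshold = 85, welch = TRUE) {
  combos <- unique(suvTable[, c("time_min", "normalization")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sel <- suvTable$time_min == combos$time_min[r] &
      suvTable$normalization == combos$normalization[r]
    x <- suvTable$suv[sel & suvTable$weight > threshold]
    y <- suvTable$suv[sel & suvTable$weight <= threshold]
    if (length(x) < 2 || length(y) < 2) stop("empty or degenerate weight stratum")
    tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      # identical constant groups: no evidence of a difference
      list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
           p.value = 1)
    } else stats::t.test(x, y, var.equal = !welch)
    data.frame(time_min = combos$time_min[r],
               normalization = combos$normalization[r],
               mean_above = mean(x), mean_below = mean(y),
               n_above = length(x), n_below = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               test_kind = if (welch) "welch" else "student",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation with an R-squared confidence interval
#'
#' Pearson r and r^2 with a 95% interval on r^2 obtained by the Fisher-z
#' interval on r with endpoints squared (0 replaces the lower endpoint when
#' the r interval spans zero). Zero variance in either argument is reported
#' as an explicit degenerate result rather than NaN.
#'
#' @param x,y numeric vectors, n >= 3
#' @param conf confidence level (default 0.95)
#' @return list: `r`, `r_squared`, `ci_low`, `ci_high` (on r^2), `n`, `p`,
#'   `degenerate`
#' @export
pearsonR2 <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n = n, p = NA_real_, degenerate = TRUE))
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  rlo <- tanh(z - q * se); rhi <- tanh(z + q * se)
  ci <- if (rlo <= 0 && rhi >= 0) c(0, max(rlo^2, rhi^2))
        else sort(c(rlo^2, rhi^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, r_squared = r^2, ci_low = ci[1], ci_high = ci[2], n = n,
       p = 2 * stats::pt(-abs(tstat), n - 2), degenerate = FALSE)
}

#' Williams' test for two dependent overlapping correlations
#'
#' Tests H0: rho(X1,X2) = rho(X1,X3) when X2 and X3 are themselves
#' correlated, via the determinant form of Williams' t (Steiger's
#' presentation) with n-3 degrees of freedom:
#' `t = (r12 - r13) * sqrt((n-1)(1+r23) /
#'      (2 |R| (n-1)/(n-3) + rbar^2 (1-r23)^3))`
#' with `|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23` and
#' `rbar = (r12 + r13)/2`. Triples that do not form a positive-semidefinite
#' correlation matrix are rejected.
#'
#' @param r12,r13 the two correlations sharing variable X1
#' @param r23 correlation between the two competing variables
#' @param n sample size, >= 4
#' @return list: `t_stat`, `df`, `p`, `r12`, `r13`, `r23`, `n`
#' @export
williamsTest <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) > 1)) stop("correlations must lie in [-1, 1]")
  if (n < 4) stop("need n >= 4")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12) stop("correlation triple is not positive semidefinite")
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  tStat <- if (denom <= 0) 0 else (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  list(t_stat = tStat, df = n - 3, p = 2 * stats::pt(-abs(tStat), n - 3),
       r12 = r12, r13 = r13, r23 = r23, n = n)
}

#' Longitudinal ratio analysis of Ki against SUV
#'
#' Per lesion, forms follow-up/baseline ratios of Ki and of SUV and
#' correlates the two ratio vectors (Pearson r^2) per metric, normalization
#' and time window. Degenerate ratio sets (zero variance, e.g. no treatment
#' effect and no noise) are reported via the `degenerate` flag rather than
#' crashing.
#'
#' @param lesionTable data.frame with one row per lesion x timepoint x SUV
#'   record: columns `lesion_id`, `timepoint` (`"baseline"`/`"week12"`),
#'   `ki`, `metric`, `normalization`, `time_window`, `suv`
#' @return data.frame: per (`metric`, `normalization`, `time_window`) the
#'   number of pairs, `r_squared`, `ci_low`, `ci_high`, `p`, `degenerate`
#' @export
longitudinalRatioAnalysis <- function(lesionTable) {
  combos <- unique(lesionTable[, c("metric", "normalization", "time_window")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sel <- lesionTable$metric == combos$metric[r] &
      lesionTable$normalization == combos$normalization[r] &
      lesionTable$time_window == combos$time_window[r]
    sub <- lesionTable[sel, ]
    bl <- sub[sub$timepoint == "baseline", ]
    fu <- sub[sub$timepoint == "week12", ]
    common <- intersect(bl$lesion_id, fu$lesion_id)
    if (length(common) < 3)
      stop("need at least 3 baseline/follow-up pairs")
    bl <- bl[match(common, bl$lesion_id), ]
    fu <- fu[match(common, fu$lesion_id), ]
    if (any(bl$ki == 0) || any(bl$suv == 0)) stop("zero baseline values")
    rKi <- fu$ki / bl$ki
    rSuv <- fu$suv / bl$suv
    pr <- pearsonR2(rKi, rSuv)
    data.frame(combos[r, ], n_pairs = length(common),
               r_squared = pr$r_squared, ci_low = pr$ci_low,
               ci_high = pr$ci_high, p = pr$p, degenerate = pr$degenerate,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Treatment-covariate regression of Ki on SUV
#'
#' Ordinary least squares `Ki ~ SUV + therapy` with therapy as a binary
#' covariate; reports the therapy coefficient, its SE and p-value (a test
#' for a residual treatment effect on Ki beyond what SUV carries).
#'
#' @param lesionTable data.frame with columns `ki`, `suv`, `therapy` (two
#'   levels, both present)
#' @return list: `coef` (full coefficient table), `therapy_coef`,
#'   `therapy_se`, `therapy_p`, `rank_deficient`
#' @export
treatmentRegression <- function(lesionTable) {
  th <- factor(lesionTable$therapy)
  if (nlevels(th) != 2) stop("both therapy groups must be represented")
  fit <- stats::lm(ki ~ suv + th, data = data.frame(ki = lesionTable$ki,
                                                    suv = lesionTable$suv, th = th))
  rankDef <- fit$rank < 3
  co <- summary(fit)$coefficients
  thRow <- grep("^th", rownames(co))
  list(coef = co,
       therapy_coef = if (rankDef || length(thRow) == 0) NA_real_ else co[thRow, 1],
       therapy_se = if (rankDef || length(thRow) == 0) NA_real_ else co[thRow, 2],
       therapy_p = if (rankDef || length(thRow) == 0) NA_real_ else co[thRow, 4],
       rank_deficient = rankDef)
}

#' Bland-Altman agreement
#'
#' Bias = mean(a - b) and 95% limits of agreement bias +/- 1.96 SD(a - b);
#' with `logScale = TRUE` the analysis is on log(a) - log(b) (ratio
#' agreement, used for follow-up/baseline ratio comparisons).
#'
#' @param a,b numeric vectors of equal length, n >= 2
#' @param logScale analyse log-differences
#' @return list: `bias`, `loa_low`, `loa_high`, `sd`, `n`, `log_scale`
#' @export
blandAltman <- function(a, b, logScale = FALSE) {
  if (length(a) != length(b)) stop("a and b differ in length")
  if (length(a) < 2) stop("need n >= 2")
  d <- if (logScale) log(a) - log(b) else a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(a), log_scale = logScale)
}
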