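test_that("coefficient of variation is SD/mean and scale-invariant", {
  expect_equal(coefVar(c(1, 2, 3)), 0.5)
  expect_equal(coefVar(rep(4, 10)), 0)
  x <- rlnorm(50, 0, 0.3)
  expect_equal(coefVar(7.3 * x), coefVar(x))
  expect_error(coefVar(1), "at least two")
  expect_error(coefVar(c(-1, 1)), "zero")
})

test_that("mean-normalized Levene is invariant to per-group rescaling", {
  a <- c(1.1, 2.3, 0.7, 1.9, 1.4, 0.8)
  lv <- leveneMeanNormalized(list(a, 3 * a))
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p.value, 1)
  expect_error(leveneMeanNormalized(list(a)), "two groups")
  expect_error(leveneMeanNormalized(list(a, c(-1, 1))), "zero mean")
})

test_that("mean-normalized Levene matches the reference implementation exactly", {
  skip_if_not_installed("car")
  set.seed(31)
  # two groups with CoV ~0.22 and ~0.14, n = 92 each
  g1 <- rlnorm(92, log(3.5), sqrt(log(1 + 0.22^2)))
  g2 <- rlnorm(92, log(2.4), sqrt(log(1 + 0.14^2)))
  lv <- leveneMeanNormalized(list(g1, g2))
  z <- c(g1 / mean(g1), g2 / mean(g2))
  ref <- car::leveneTest(z ~ factor(rep(1:2, each = 92)), center = mean)
  expect_lt(abs(lv$statistic - ref[1, "F value"]), 1e-10)
  expect_lt(abs(lv$p.value - ref[1, "Pr(>F)"]), 1e-10)
})

test_that("mean-normalized Levene holds its type-I error under the null", {
  set.seed(77)
  rej <- mean(vapply(1:1000, function(i) {
    # same distribution on different scales in the two groups
    leveneMeanNormalized(list(stats::rnorm(50, 10, 2),
                              stats::rnorm(50, 30, 6)))$p.value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("weight-group t-test separates what differs and only that", {
  st <- generateStudy(46, 1, seed = 1)
  v <- venousSuvTable(st)
  res <- weightGroupTTest(v)
  expect_equal(nrow(res), 12) # 3 moments x 4 normalizations
  expect_true(all(res$p[res$normalization == "BW"] < 0.01))
  expect_true(all(res$p[res$normalization == "LBM"] > 0.05))
  # all-equal SUVs give t = 0
  flat <- data.frame(weight = c(70, 70, 95, 95), time_min = 5,
                     normalization = "BW", suv = 1)
  expect_equal(weightGroupTTest(flat)$t, 0)
  expect_error(weightGroupTTest(data.frame(weight = c(70, 71, 72),
                                           time_min = 5, normalization = "BW",
                                           suv = 1:3)), "stratum")
})

test_that("Pearson R2 agrees with a brute-force covariance ratio", {
  x <- c(0.8, 1.4, 2.2, 2.9, 3.1, 4.4, 5.0, 5.8, 6.3, 7.7)
  y <- c(1.1, 0.9, 2.5, 2.4, 3.9, 3.8, 5.6, 5.1, 7.0, 7.4)
  pr <- pearsonR2(x, y)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(pr$r - rHand), 1e-12)
  expect_equal(pr$r_squared, rHand^2)
  expect_true(pr$ci_low <= pr$r_squared && pr$r_squared <= pr$ci_high)
  # exact linear relation
  expect_equal(pearsonR2(x, 2 * x)$r_squared, 1)
  # independent draws decorrelate
  set.seed(5)
  pr0 <- pearsonR2(rnorm(1000), rnorm(1000))
  expect_lt(pr0$r_squared, 0.01)
  # degenerate input is flagged, not NaN
  d <- pearsonR2(rep(1, 5), 1:5)
  expect_true(d$degenerate)
  expect_error(pearsonR2(1:2, 1:2), "n >= 3")
})

test_that("Williams' test is zero under symmetry and rejects invalid triples", {
  w <- williamsTest(0.6, 0.6, 0.4, 50)
  expect_equal(w$t_stat, 0)
  expect_equal(w$p, 1)
  expect_equal(w$df, 47)
  expect_error(williamsTest(0.95, -0.95, 0.95, 50), "semidefinite")
  expect_error(williamsTest(1.2, 0.5, 0.5, 50), "lie in")
  expect_error(williamsTest(0.5, 0.4, 0.3, 3), "n >= 4")
})

test_that("Williams' test holds its type-I error against a trivariate-normal oracle", {
  skip_if_not_installed("MASS")
  set.seed(11)
  S <- matrix(c(1, .6, .6, .6, 1, .5, .6, .5, 1), 3)
  rej <- mean(vapply(1:2000, function(i) {
    X <- MASS::mvrnorm(100, rep(0, 3), S)
    r <- stats::cor(X)
    williamsTest(r[1, 2], r[1, 3], r[2, 3], 100)$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Williams' test detects the study-sized correlation contrast", {
  skip_if_not_installed("MASS")
  set.seed(13)
  # r = .88 vs .72 sharing one variable, n = 43 (the R^2 .77 vs .52 contrast)
  S <- matrix(c(1, .88, .72, .88, 1, .85, .72, .85, 1), 3)
  pow <- mean(vapply(1:400, function(i) {
    X <- MASS::mvrnorm(43, rep(0, 3), S)
    r <- stats::cor(X)
    williamsTest(r[1, 2], r[1, 3], r[2, 3], 43)$p < 0.01
  }, logical(1)))
  expect_gt(pow, 0.5)
})

test_that("treatment regression is null-calibrated and symmetric", {
  set.seed(21)
  n <- 60
  suv <- rlnorm(n, 1, 0.4)
  ki <- 0.03 * suv + rnorm(n, 0, 0.01)
  therapy <- rep(c("anti-TNF", "IL-17A"), each = n / 2)
  tab <- data.frame(ki = ki, suv = suv, therapy = therapy)
  res <- treatmentRegression(tab)
  expect_false(res$rank_deficient)
  # duplicated data with the flag flipped: therapy coefficient exactly 0
  tab2 <- rbind(tab, transform(tab, therapy = rev(therapy)))
  res2 <- treatmentRegression(tab2)
  expect_lt(abs(res2$therapy_coef), 1e-12)
  # therapy independent of Ki|SUV stays non-significant ~95% of the time
  rej <- mean(vapply(1:300, function(i) {
    tt <- tab
    tt$therapy <- sample(tt$therapy)
    treatmentRegression(tt)$therapy_p < 0.05
  }, logical(1)))
  expect_lt(rej, 0.1)
  expect_error(treatmentRegression(data.frame(ki = 1:4, suv = 1:4,
                                              therapy = "IL-17A")), "both")
})

test_that("Bland-Altman bias and limits of agreement", {
  a <- c(1, 2, 3, 4)
  expect_equal(blandAltman(a, a), list(bias = 0, loa_low = 0, loa_high = 0,
                                       sd = 0, n = 4, log_scale = FALSE))
  shifted <- blandAltman(a, a + 1)
  expect_equal(shifted$bias, -1)
  expect_equal(shifted$sd, 0)
  set.seed(8)
  d <- rnorm(10000, 0.5, 1)
  ba <- blandAltman(d, rep(0, 10000))
  expect_equal(ba$bias, 0.5, tolerance = 0.05)
  expect_equal(ba$loa_low, -1.46, tolerance = 0.06)
  expect_equal(ba$loa_high, 2.46, tolerance = 0.06)
  # ratio analysis on the log scale
  bl <- blandAltman(c(1, 2), c(2, 4), logScale = TRUE)
  expect_equal(bl$bias, -log(2))
  expect_error(blandAltman(1:3, 1:4), "length")
})

test_that("longitudinal ratio analysis flags degenerate ratios instead of crashing", {
  mk <- function(kiBl, kiFu, suvBl, suvFu) {
    data.frame(lesion_id = rep(sprintf("L%d", seq_along(kiBl)), 2),
               timepoint = rep(c("baseline", "week12"), each = length(kiBl)),
               ki = c(kiBl, kiFu), metric = "mean", normalization = "LBM",
               time_window = "25-30min", suv = c(suvBl, suvFu))
  }
  # no treatment effect, no noise: all ratios 1 -> degenerate, not NaN-crash
  tab <- mk(c(.02, .03, .04), c(.02, .03, .04), c(1, 2, 3), c(1, 2, 3))
  res <- longitudinalRatioAnalysis(tab)
  expect_true(res$degenerate)
  # proportional changes give r^2 = 1
  tab2 <- mk(c(.02, .03, .04), c(.01, .03, .06), c(1, 2, 3), c(0.5, 2, 4.5))
  expect_equal(longitudinalRatioAnalysis(tab2)$r_squared, 1)
  expect_error(longitudinalRatioAnalysis(mk(c(0, .03, .04), c(.02, .03, .04),
                                            c(1, 2, 3), c(1, 2, 3))), "zero")
})
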