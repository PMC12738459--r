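test_that("cohort marginals match the emulated population", {
  cohort <- generateCohort(1000, seed = 42)
  expect_equal(nrow(cohort), 1000)
  expect_true(all(cohort$weight > 0 & cohort$height > 0 &
                    cohort$injected_activity > 0))
  expect_lt(abs(mean(cohort$weight) - 86.2), 2)
  expect_lt(abs(mean(cohort$height) - 172.9), 1)
  expect_lt(abs(mean(cohort$sex == "female") - 0.48), 0.05)
  expect_lt(abs(mean(cohort$therapy == "anti-TNF") - 0.38), 0.05)
  expect_lt(abs(mean(cohort$injected_activity) - 100.5), 0.6)
})

test_that("cohort generation is deterministic and extension-stable", {
  a <- generateCohort(20, seed = 7)
  b <- generateCohort(20, seed = 7)
  expect_identical(a, b)
  expect_error(generateCohort(0, seed = 1), "at least 1")
  one <- generateCohort(1, seed = 3)
  expect_equal(nrow(one), 1)
  # growing the cohort leaves existing patients untouched
  big <- generateCohort(30, seed = 7)
  expect_identical(big[1:20, ], a)
})

test_that("input function scales with injected activity and lean mass only", {
  p1 <- testPatient(weight = 85, height = 173)
  ifnA <- simulateInputFunction(p1, scaleFactor = 1)
  # same lean mass, different weight: identical expected curve (adipose
  # fraction 0)
  lbm <- lbmJanmahasatian(85, 173, "male")
  h2 <- 160
  # solve the weight giving the same LBM at height 160 (numeric inversion)
  w2 <- uniroot(function(w) lbmJanmahasatian(w, h2, "male") - lbm,
                c(60, 200), tol = 1e-10)$root
  ifnB <- simulateInputFunction(testPatient(weight = w2, height = h2),
                                scaleFactor = 1)
  expect_equal(ifnB@activity, ifnA@activity, tolerance = 1e-9)
  # doubling injected activity doubles Cp everywhere
  ifnC <- simulateInputFunction(testPatient(injected = 200), scaleFactor = 1)
  expect_equal(ifnC@activity, 2 * ifnA@activity)
  # Cp non-negative and decreasing after the bolus peak
  pk <- which.max(ifnA@activity)
  expect_true(all(diff(ifnA@activity[pk:length(ifnA@activity)]) <= 1e-12))
})

test_that("population-mean blood SUV-LBM sits on the venous-table scale", {
  cohort <- generateCohort(200, seed = 5)
  suvLbm <- vapply(seq_len(200), function(i) {
    pat <- cohort[i, ]
    ifn <- simulateInputFunction(pat, seed = 10000 + i)
    lbmG <- lbmJanmahasatian(pat$weight, pat$height, pat$sex) * 1000
    plasmaActivity(ifn, 5) * lbmG / (pat$injected_activity * 1000)
  }, numeric(1))
  expect_gt(mean(suvLbm), 2.07)
  expect_lt(mean(suvLbm), 2.81)
})

test_that("venous sampling reproduces Cp exactly at zero noise and its CV at 3%", {
  w <- noiseFreeWorld()
  s0 <- sampleVenous(w$ifn, noiseCV = 0, seed = 1)
  expect_identical(s0@time, c(5, 15, 25))
  expect_equal(s0@activity, plasmaActivity(w$ifn, c(5, 15, 25)))
  expect_error(sampleVenous(w$ifn, times = c(5, 120)), "outside")
  ratios <- unlist(lapply(1:2000, function(i)
    sampleVenous(w$ifn, noiseCV = 0.03, seed = i)@activity / s0@activity))
  expect_equal(sd(ratios) / mean(ratios), 0.03, tolerance = 0.005)
})

test_that("IDIF is the frame-averaged Cp up to its scale error", {
  w <- noiseFreeWorld()
  base <- simulateIdif(w$ifn, w$schedule, scaleError = 0, noiseCV = 0, seed = 1)
  up <- simulateIdif(w$ifn, w$schedule, scaleError = 0.10, noiseCV = 0, seed = 1)
  expect_equal(up@activity, 1.10 * base@activity)
  # frame averaging: a constant input stays constant
  flat <- simulateIdif(constantInput(7), w$schedule, scaleError = 0,
                       noiseCV = 0, seed = 1)
  expect_equal(flat@activity, rep(7, 25))
})

test_that("noise-free lesions equal the forward model exactly", {
  w <- noiseFreeWorld()
  tac <- simulateLesion(w$params, w$ifn, w$schedule, noiseScale = 0)
  expect_equal(tac@activity, modelTac(w$params, w$ifn, w$schedule)@activity)
  zero <- simulateLesion(kineticParams(0, 0.3, 0.1, 0), w$ifn, w$schedule,
                         noiseScale = 0)
  expect_equal(zero@activity, rep(0, 25))
})

test_that("static patches place the blob and respond to jitter", {
  w <- noiseFreeWorld()
  cfg0 <- noiseFreeConfig()
  patch <- simulateStaticPatch(w$params, w$ifn, jitterVox = 0, seed = 1,
                               config = cfg0)
  d <- dim(patch@values)
  expect_equal(unname(arrayInd(which.max(patch@values), d)[1, ]), c(8, 8, 8))
  # near-point-source limit: mean strictly below max
  cfgTight <- cfg0
  cfgTight$fwhmMm <- 0.5
  tight <- simulateStaticPatch(w$params, w$ifn, jitterVox = 0, seed = 1,
                               config = cfgTight)
  voi <- placeVoi(tight, 1.2)
  inVoi <- tight@values[voi@mask]
  expect_lt(mean(inVoi), max(inVoi))
  expect_error(simulateStaticPatch(w$params, w$ifn, tStatic = 99), "grid")
})

test_that("VOI jitter inflates the variance of extracted SUV-peak", {
  w <- noiseFreeWorld()
  cfg <- defaultGeneratorConfig()
  f <- testFactors()
  peakAt <- function(j, i) {
    patch <- simulateStaticPatch(w$params, w$ifn, jitterVox = j,
                                 seed = 5000 + i, config = cfg)
    s <- suvMetrics(patch, placeVoi(patch, 1.2), 100, f)
    s$value[s$metric == "peak" & s$normalization == "LBM"]
  }
  v0 <- var(vapply(1:200, function(i) peakAt(0, i), numeric(1)))
  v1 <- var(vapply(1:200, function(i) peakAt(1, i), numeric(1)))
  expect_gt(v1, v0)
})

test_that("study generation is deterministic and honours followupFraction", {
  cfg <- defaultGeneratorConfig()
  a <- generateStudy(6, 0.5, seed = 9, config = cfg)
  b <- generateStudy(6, 0.5, seed = 9, config = cfg)
  expect_identical(
    lapply(studyScans(a), function(s) s[c("patient_id", "timepoint")]),
    lapply(studyScans(b), function(s) s[c("patient_id", "timepoint")]))
  expect_equal(studyScans(a)[[2]]$venous@activity,
               studyScans(b)[[2]]$venous@activity)
  noFu <- generateStudy(5, 0, seed = 9)
  expect_false(any(vapply(studyScans(noFu), `[[`, "", "timepoint") == "week12"))
  allFu <- generateStudy(4, 1, seed = 9)
  expect_equal(sum(vapply(studyScans(allFu), `[[`, "", "timepoint") == "week12"), 4)
  # weight constant across timepoints (one cohort row per patient)
  expect_equal(nrow(studyCohort(allFu)), 4)
})

test_that("a degenerate treatment-effect distribution gives Ki ratios of one", {
  cfg <- defaultGeneratorConfig()
  cfg$treatmentEffectMeanlog <- 0
  cfg$treatmentEffectSdlog <- 0
  st <- generateStudy(3, 1, seed = 2, config = cfg)
  ratios <- vapply(seq(2, 6, by = 2), function(i) {
    bl <- studyScans(st)[[i - 1]]$truth$lesions[[1]]$ki
    fu <- studyScans(st)[[i]]$truth$lesions[[1]]$ki
    fu / bl
  }, numeric(1))
  expect_equal(ratios, rep(1, 3))
})

test_that("blood SUV-BW tracks weight while SUV-LBM does not", {
  st <- generateStudy(46, 1, seed = 1)
  v <- venousSuvTable(st)
  at5 <- v[v$time_min == 5, ]
  rBW <- cor(at5$suv[at5$normalization == "BW"], at5$weight[at5$normalization == "BW"])
  rLBM <- cor(at5$suv[at5$normalization == "LBM"], at5$weight[at5$normalization == "LBM"])
  expect_gt(rBW, 0.3)
  expect_lt(abs(rLBM), 0.2)
  # mean blood SUV decreases monotonically over the sample moments for
  # every normalization
  vs <- venousSummary(v)
  for (nm in unique(vs$normalization)) {
    m <- vs$mean[vs$normalization == nm][order(vs$time_min[vs$normalization == nm])]
    expect_true(all(diff(m) < 0))
  }
})
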