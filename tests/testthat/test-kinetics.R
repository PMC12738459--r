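test_that("Ki follows K1*k3/(k2+k3) with its limits", {
  expect_equal(kiFromMicro(kineticParams(0.12, 0.30, 0.10)), 0.030)
  expect_equal(kiFromMicro(kineticParams(0.12, 0.30, 0)), 0)
  expect_equal(kiFromMicro(kineticParams(0.12, 0, 0.10)), 0.12)
  expect_equal(kiFromMicro(kineticParams(0.5, 0, 0)), 0)
})

test_that("numerical model matches the constant-input closed form across a grid", {
  ifn <- constantInput(cp = 10, tMax = 32)
  i30 <- which.min(abs(ifn@time - 30))
  for (K1 in c(0.05, 0.12, 0.2))
    for (k2 in c(0.1, 0.3, 0.6))
      for (k3 in c(0.02, 0.1, 0.2)) {
        num <- modelCurve(kineticParams(K1, k2, k3, 0), ifn)[i30]
        ana <- closedFormConstCp(K1, k2, k3, 10, 30)
        expect_lt(abs(num / ana - 1), 1e-3)
      }
  # the worked value: K1=0.12, k2=0.30, k3=0.10, Cp=10, t=30 -> 11.25
  expect_equal(modelCurve(kineticParams(0.12, 0.3, 0.1, 0), ifn)[i30],
               11.25, tolerance = 1e-3)
})

test_that("model limits: zero delivery, reversible plateau, blood fraction", {
  ifn <- constantInput(10, 40)
  sched <- defaultFrameSchedule()
  expect_equal(modelTac(kineticParams(0, 0.3, 0.1, 0), ifn, sched)@activity,
               rep(0, 25))
  # k3 = 0: C_T plateaus at K1 c / k2
  plateau <- modelCurve(kineticParams(0.12, 0.3, 0, 0), ifn)
  expect_equal(plateau[length(plateau)], 0.12 * 10 / 0.3, tolerance = 1e-4)
  # vb = 1 limit is forbidden, vb mixes in Cp linearly
  half <- modelCurve(kineticParams(0, 0.3, 0.1, 0.5), ifn)
  expect_equal(half[1000], 5, tolerance = 1e-9)
  expect_error(modelTac(kineticParams(0.1, 0.3, 0.1), constantInput(10, 20),
                        sched), "past")
})

test_that("model is linear in Cp amplitude and in K1", {
  w <- noiseFreeWorld()
  base <- modelTac(w$params, w$ifn, w$schedule)@activity
  ifn2 <- inputFunction(w$ifn@time, 2 * w$ifn@activity)
  expect_equal(modelTac(w$params, ifn2, w$schedule)@activity, 2 * base,
               tolerance = 1e-12)
  pK <- kineticParams(2 * w$params@K1, w$params@k2, w$params@k3, 0)
  expect_equal(modelTac(pK, w$ifn, w$schedule)@activity, 2 * base,
               tolerance = 1e-12)
})

test_that("IDIF calibration averages per-sample ratios and preserves shape", {
  sched <- defaultFrameSchedule()
  flat <- timeActivityCurve(sched, rep(1, 25))
  samples <- new("VenousSamples", time = c(5, 15, 25),
                 activity = c(0.9, 1.1, 1.1))
  cal <- calibrateIdif(flat, samples)
  expect_equal(cal$perSample, c(0.9, 1.1, 1.1))
  expect_equal(cal$factor, mean(c(0.9, 1.1, 1.1)))
  expect_equal(cal$tac@activity, rep(cal$factor, 25))
  # samples equal to the IDIF leave it unchanged
  same <- calibrateIdif(flat, new("VenousSamples", time = c(5, 15, 25),
                                  activity = rep(1, 3)))
  expect_equal(same$factor, 1)
  # IDIF uniformly 2x the samples halves
  cal2 <- calibrateIdif(timeActivityCurve(sched, rep(2, 25)),
                        new("VenousSamples", time = c(5, 15, 25),
                            activity = rep(1, 3)))
  expect_equal(cal2$factor, 0.5)
  expect_error(calibrateIdif(flat, new("VenousSamples", time = 45,
                                       activity = 1)), "outside")
})

test_that("calibration is scale-equivariant and inverts the IDIF scale error", {
  w <- noiseFreeWorld()
  samples <- sampleVenous(w$ifn, noiseCV = 0, seed = 1)
  idif <- simulateIdif(w$ifn, w$schedule, scaleError = 0.1, noiseCV = 0, seed = 1)
  cal <- calibrateIdif(idif, samples)
  # scaling the IDIF by any c > 0 leaves the calibrated curve unchanged
  idif3 <- timeActivityCurve(w$schedule, 3 * idif@activity)
  cal3 <- calibrateIdif(idif3, samples)
  expect_equal(cal3$tac@activity, cal$tac@activity, tolerance = 1e-12)
  # round trip: calibrated curve recovers frame-averaged Cp closely
  trueFrames <- simulateIdif(w$ifn, w$schedule, scaleError = 0, noiseCV = 0,
                             seed = 1)@activity
  expect_lt(max(abs(cal$tac@activity / trueFrames - 1)), 0.005)
})

test_that("noise-free fits recover the generating parameters", {
  w <- noiseFreeWorld(0.12, 0.3, 0.1, vb = 0.05)
  tac <- modelTac(w$params, w$ifn, w$schedule)
  fit <- fit2t3k(tac, w$ifn)
  expect_true(fit@converged)
  expect_lt(abs(fit@ki / kiFromMicro(w$params) - 1), 0.01)
  expect_lt(abs(fit@params@vb - 0.05), 0.01)
  # all-zero TAC short-circuits to the exact zero fit
  z <- fit2t3k(timeActivityCurve(w$schedule, rep(0, 25)), w$ifn)
  expect_equal(z@ki, 0)
  expect_true(z@converged)
  # vb can be pinned to zero
  fit0 <- fit2t3k(tac, w$ifn, fitVb = FALSE)
  expect_equal(fit0@params@vb, 0)
})

test_that("fits are invariant to joint rescaling of TAC and input", {
  w <- noiseFreeWorld(0.15, 0.25, 0.08)
  tac <- simulateLesion(w$params, w$ifn, w$schedule, noiseScale = 0.2, seed = 3)
  fit1 <- fit2t3k(tac, w$ifn)
  c0 <- 4.7
  tac2 <- timeActivityCurve(w$schedule, c0 * tac@activity)
  ifn2 <- inputFunction(w$ifn@time, c0 * w$ifn@activity)
  fit2 <- fit2t3k(tac2, ifn2)
  expect_equal(fit2@ki, fit1@ki, tolerance = 1e-5)
})

test_that("Patlak recovers slope and intercept of the constant-input closed form", {
  ifn <- constantInput(10, 40)
  sched <- defaultFrameSchedule()
  tac <- modelTac(kineticParams(0.12, 0.3, 0.1, 0), ifn, sched)
  pk <- patlakKi(tac, ifn)
  # asymptotics: slope Ki = 0.030, intercept K1 k2/(k2+k3)^2 = 0.225,
  # y(30) = 1.125
  expect_equal(pk$slope, 0.030, tolerance = 0.01)
  expect_equal(pk$intercept, 0.225, tolerance = 0.02)
  expect_equal(pk$slope * 30 + pk$intercept, 1.125, tolerance = 0.01)
  # k3 = 0: slope collapses to 0
  tac0 <- modelTac(kineticParams(0.12, 0.3, 0, 0), ifn, sched)
  expect_lt(abs(patlakKi(tac0, ifn)$slope), 1e-3)
  expect_error(patlakKi(tac, ifn, tStar = 29), "at least 3")
})

test_that("Patlak and the 2t3k fit agree on noise-free lesions", {
  w <- noiseFreeWorld()
  tac <- modelTac(w$params, w$ifn, w$schedule)
  fit <- fit2t3k(tac, w$ifn)
  pk <- patlakKi(tac, w$ifn)
  expect_lt(abs(pk$slope - fit@ki) / fit@ki, 0.05)
})
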