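#' Default configuration of the synthetic-data generator
#'
#' One list holding every tunable of the generator. The defaults emulate the
#' study conditions the analysis assumes: cohort anthropometrics (height
#' normal 172.9 (6.9) cm, weight lognormal mean 86.2 SD 20.1 kg, 48%
#' female), therapy split 38/62% anti-TNF/IL-17A, injected activity normal
#' 100.5 (5.0) MBq at baseline and 101.5 (5.4) MBq at week 12, a
#' tri-exponential plasma curve whose amplitude scales as injected activity
#' over a distribution volume proportional to lean body mass (adipose
#' fraction 0, encoding negligible fluoride uptake in fat), venous samples
#' at 5/15/25 min with 3% lognormal error, an aorta IDIF with a uniform
#' +/-10% scale miscalibration, frame-statistics TAC noise, lesion 2t3k
#' kinetics drawn lognormal around fluoride-literature values (K1 0.12
#' mL/cm^3/min, k2 0.30 /min, k3 0.10 /min medians), and a week-12
#' treatment effect multiplying K1 (hence Ki) lognormal with median 0.8.
#'
#' @return named list of generator settings
#' @export
defaultGeneratorConfig <- function() {
  list(
    # cohort marginals
    heightMean = 172.9, heightSd = 6.9,
    weightMean = 86.2, weightSd = 20.1,
    pFemale = 0.48, pAntiTnf = 0.38, pAxSpA = 0.57,
    injectedMean = 100.5, injectedSd = 5.0,
    injectedMeanFu = 101.5, injectedSdFu = 5.4,
    # plasma input function
    shape = defaultInputShape(),
    tissueDensity = 1.0,     # g/mL, converts lean mass to distribution volume
    adiposeFraction = 0,     # fraction of fat mass contributing to v_d
    patientScaleCV = 0.15,   # between-patient biological scale variability
    scanScaleCV = 0.05,      # scan-to-scan (within-patient) variability
    gridTMax = 48, gridDt = 1 / 60,
    # venous sampling and IDIF
    venousTimes = c(5, 15, 25), venousNoiseCV = 0.03,
    idifScaleErrorRange = 0.10, idifNoiseCV = 0.02,
    # lesion kinetics truth
    k1Median = 0.12, k1Sdlog = 0.35,
    k2Median = 0.30, k2Sdlog = 0.30,
    k3Median = 0.10, k3Sdlog = 0.35,
    vbTruth = 0,
    treatmentEffectMeanlog = log(0.8), treatmentEffectSdlog = 0.25,
    lesionsPerScan = 1,
    # dynamic TAC noise: SD = tacNoiseScale * sqrt(value / duration_min)
    tacNoiseScale = 0.2,
    # static patch
    tStatic = 45, patchDim = 15, voxelSizeMm = 4, fwhmMm = 8,
    backgroundFraction = 0.25, patchNoiseFraction = 0.05, jitterVox = 1,
    # skeletal volume stand-in
    svPerKgLbm = 28, svNoiseCV = 0.05, svFactor = 1.80
  )
}

#' Zero-noise variant of a generator configuration
#'
#' Sets every stochastic perturbation (venous/IDIF/TAC/patch noise, IDIF
#' scale error, VOI jitter, scan-to-scan input variability, skeletal-volume
#' noise) to zero while keeping the biological between-patient and
#' between-lesion variability. Used for the noise-closure identities.
#'
#' @param config a generator configuration
#' @return the modified configuration
#' @export
noiseFreeConfig <- function(config = defaultGeneratorConfig()) {
  config$venousNoiseCV <- 0
  config$idifNoiseCV <- 0
  config$idifScaleErrorRange <- 0
  config$tacNoiseScale <- 0
  config$patchNoiseFraction <- 0
  config$jitterVox <- 0
  config$scanScaleCV <- 0
  config$svNoiseCV <- 0
  config
}

#' Generate a synthetic patient cohort
#'
#' Reproducible given `(n, seed, config)`; each patient draws from an
#' independent derived stream, so enlarging the cohort never reshuffles
#' existing patients.
#'
#' @param n number of patients, >= 1
#' @param seed integer master seed
#' @param config generator configuration
#' @return data.frame: `id`, `sex`, `weight` (kg), `height` (cm),
#'   `diagnosis`, `therapy`, `injected_activity` (MBq), `timepoint`
#' @export
generateCohort <- function(n, seed, config = defaultGeneratorConfig()) {
  if (length(n) != 1 || !is.finite(n) || n < 1) stop("n must be at least 1")
  n <- as.integer(n)
  rows <- lapply(seq_len(n), function(i) {
    withSeed(deriveSeed(seed, "patient", i), {
      sex <- if (stats::runif(1) < config$pFemale) "female" else "male"
      height <- max(stats::rnorm(1, config$heightMean, config$heightSd), 120)
      weight <- rlnormMeanSd(1, config$weightMean, config$weightSd)
      diagnosis <- if (stats::runif(1) < config$pAxSpA) "axSpA" else "PsA"
      therapy <- if (stats::runif(1) < config$pAntiTnf) "anti-TNF" else "IL-17A"
      injected <- max(stats::rnorm(1, config$injectedMean, config$injectedSd), 1)
      data.frame(id = sprintf("P%03d", i), sex = sex, weight = weight,
                 height = height, diagnosis = diagnosis, therapy = therapy,
                 injected_activity = injected, timepoint = "baseline",
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Simulate a patient's plasma input function
#'
#' Tri-exponential bolus scaled as injected activity over the tracer
#' distribution volume `v_d = (LBM + adiposeFraction * (BW - LBM)) / density`
#' (grams -> mL), times a multiplicative biological scale factor. With the
#' default adipose fraction of 0, two patients with equal lean mass share
#' the same expected curve regardless of weight, and the population-mean
#' blood SUV-LBM reproduces the venous-table values at the sample times.
#'
#' @param patient one-row cohort data.frame (or list with the same fields)
#' @param seed integer seed (used only when `scaleFactor` is `NULL`)
#' @param config generator configuration
#' @param scaleFactor biological scale multiplier; `NULL` draws one lognormal
#'   factor with CV `sqrt(patientScaleCV^2 + scanScaleCV^2)`
#' @param injectedMBq injected activity override (defaults to the patient's)
#' @return an [InputFunction-class]
#' @export
simulateInputFunction <- function(patient, seed = 1,
                                  config = defaultGeneratorConfig(),
                                  scaleFactor = NULL, injectedMBq = NULL) {
  if (is.null(injectedMBq)) injectedMBq <- patient$injected_activity
  lbmG <- lbmJanmahasatian(patient$weight, patient$height, patient$sex) * 1000
  bwG <- patient$weight * 1000
  vd <- (lbmG + config$adiposeFraction * (bwG - lbmG)) / config$tissueDensity
  if (is.null(scaleFactor)) {
    cv <- sqrt(config$patientScaleCV^2 + config$scanScaleCV^2)
    scaleFactor <- withSeed(seed, rlnormMean1Cv(1, cv))
  }
  scale <- injectedMBq * 1000 / vd * scaleFactor
  triExpInputFunction(scale, config$shape, tMax = config$gridTMax,
                      dt = config$gridDt)
}

#' Draw venous samples from an input function
#'
#' Activities are `Cp(t)` times multiplicative lognormal noise with the given
#' CV (mean-one noise); `noiseCV = 0` reproduces Cp exactly.
#'
#' @param ifn an [InputFunction-class]
#' @param times sample times, minutes (default 5, 15, 25)
#' @param noiseCV fractional measurement error (default 0.03)
#' @param seed integer seed
#' @return a [VenousSamples-class]
#' @export
sampleVenous <- function(ifn, times = c(5, 15, 25), noiseCV = 0.03, seed = 1) {
  cp <- plasmaActivity(ifn, times) # errors if outside grid
  noise <- withSeed(seed, rlnormMean1Cv(length(times), noiseCV))
  new("VenousSamples", time = times, activity = cp * noise)
}

#' Simulate an image-derived input function
#'
#' The true plasma curve frame-averaged on the dynamic schedule, multiplied
#' by `(1 + scaleError)` (a systematic blood-pool VOI miscalibration from
#' partial-volume and cross-calibration effects) and per-frame multiplicative
#' lognormal noise. Shape is preserved up to the noise.
#'
#' @param ifn the true [InputFunction-class]
#' @param schedule a [FrameSchedule-class]
#' @param scaleError systematic fractional error, > -1; `NULL` draws uniform
#'   from `+/- config$idifScaleErrorRange`
#' @param noiseCV per-frame fractional noise
#' @param seed integer seed
#' @param config generator configuration
#' @return a [TimeActivityCurve-class]
#' @export
simulateIdif <- function(ifn, schedule = defaultFrameSchedule(),
                         scaleError = NULL, noiseCV = 0.02, seed = 1,
                         config = defaultGeneratorConfig()) {
  withSeed(seed, {
    if (is.null(scaleError)) {
      r <- config$idifScaleErrorRange
      scaleError <- if (r > 0) stats::runif(1, -r, r) else 0
    }
    if (scaleError <= -1) stop("scaleError must exceed -1")
    base <- frameAverage(ifn@activity, ifn@time, schedule) * (1 + scaleError)
    noise <- rlnormMean1Cv(length(base), noiseCV)
    timeActivityCurve(schedule, base * noise)
  })
}

#' Simulate a noisy lesion time-activity curve
#'
#' The noise-free curve is exactly [modelTac()]; frame noise is zero-mean
#' Gaussian with SD `noiseScale * sqrt(value / duration_min)`, the standard
#' count-statistics weighting of dynamic PET (short, hot frames are noisy).
#' Negative excursions are clipped at zero.
#'
#' @param params true [KineticParams-class]
#' @param ifn the true [InputFunction-class]
#' @param schedule a [FrameSchedule-class]
#' @param noiseScale noise level (kBq/mL per sqrt(kBq/mL/min)); 0 gives the
#'   exact forward model
#' @param seed integer seed
#' @return a [TimeActivityCurve-class]
#' @export
simulateLesion <- function(params, ifn, schedule = defaultFrameSchedule(),
                           noiseScale = 0.2, seed = 1) {
  tac <- modelTac(params, ifn, schedule)
  if (noiseScale > 0) {
    sdv <- noiseScale * sqrt(pmax(tac@activity, 0) / frameDurations(schedule, "min"))
    eps <- withSeed(seed, stats::rnorm(length(sdv), 0, 1)) * sdv
    tac@activity <- pmax(tac@activity + eps, 0)
  }
  tac
}

#' Simulate a static-scan voxel patch around one lesion
#'
#' A cube of isotropic voxels holding one lesion rendered as an isotropic
#' Gaussian intensity profile (FWHM emulating partial-volume blur) whose
#' amplitude above background equals the model tissue curve evaluated at the
#' static scan time, on a constant bone-background level, plus Gaussian
#' voxel noise. The lesion centre is displaced from the patch centre by a
#' continuous uniform offset of up to `jitterVox` voxels per axis, emulating
#' VOI re-placement between scans.
#'
#' @param params true [KineticParams-class]
#' @param ifn the true [InputFunction-class]
#' @param tStatic static acquisition time, minutes (within the grid)
#' @param jitterVox maximum displacement, voxels
#' @param seed integer seed
#' @param config generator configuration (patch geometry and noise)
#' @return a [VoxelPatch-class]
#' @export
simulateStaticPatch <- function(params, ifn, tStatic = 45, jitterVox = 1,
                                seed = 1, config = defaultGeneratorConfig()) {
  if (tStatic > max(ifn@time) + 1e-9) stop("tStatic outside the input-function grid")
  amp <- stats::approx(ifn@time, modelCurve(params, ifn), xout = tStatic)$y
  d <- config$patchDim
  sigmaVox <- (config$fwhmMm / 2.35482) / config$voxelSizeMm
  withSeed(seed, {
    centre <- rep((d + 1) / 2, 3)
    if (jitterVox > 0) centre <- centre + stats::runif(3, -jitterVox, jitterVox)
    ax <- seq_len(d)
    g1 <- function(c0) exp(-(ax - c0)^2 / (2 * sigmaVox^2))
    blob <- outer(outer(g1(centre[1]), g1(centre[2])), g1(centre[3]))
    vals <- config$backgroundFraction * amp + amp * blob
    if (config$patchNoiseFraction > 0)
      vals <- vals + stats::rnorm(length(vals), 0, config$patchNoiseFraction * amp)
    new("VoxelPatch", values = array(pmax(vals, 0), dim = c(d, d, d)),
        voxelSize = config$voxelSizeMm)
  })
}

#' Generate a full synthetic study
#'
#' Bundles, per patient, a baseline scan and (for the leading
#' `followupFraction` of the cohort) a week-12 scan: true input function,
#' venous samples, IDIF, lesion TACs, static patches and the generating
#' ground truth. The week-12 lesion Ki equals the baseline Ki times a
#' lognormal treatment effect (applied to K1, so the whole tissue curve
#' scales); body weight is held constant between timepoints.
#'
#' Ground truth (true input function, kinetic parameters, treatment effect)
#' lives only under each scan's `$truth` element; estimation code must not
#' read it.
#'
#' @param nPatients number of patients
#' @param followupFraction fraction of patients with a week-12 scan, in [0,1]
#' @param seed integer master seed
#' @param config generator configuration
#' @param schedule dynamic [FrameSchedule-class]
#' @return a [StudyData-class]
#' @export
generateStudy <- function(nPatients, followupFraction = 0.6, seed = 1,
                          config = defaultGeneratorConfig(),
                          schedule = defaultFrameSchedule()) {
  if (followupFraction < 0 || followupFraction > 1)
    stop("followupFraction must lie in [0, 1]")
  cohort <- generateCohort(nPatients, seed, config)
  cohort$partial_sv_ml <- vapply(seq_len(nPatients), function(i)
    synthPartialSkeletalVolume(cohort[i, ], deriveSeed(seed, "sv", i),
                               perKgLbm = config$svPerKgLbm,
                               noiseCV = config$svNoiseCV), numeric(1))
  nFu <- round(followupFraction * nPatients)

  scans <- list()
  for (i in seq_len(nPatients)) {
    pat <- cohort[i, ]
    etaPat <- withSeed(deriveSeed(seed, "eta", i),
                       rlnormMean1Cv(1, config$patientScaleCV))
    truthLesions <- lapply(seq_len(config$lesionsPerScan), function(l) {
      withSeed(deriveSeed(seed, "truth", i, l), {
        K1 <- stats::rlnorm(1, log(config$k1Median), config$k1Sdlog)
        k2 <- stats::rlnorm(1, log(config$k2Median), config$k2Sdlog)
        k3 <- stats::rlnorm(1, log(config$k3Median), config$k3Sdlog)
        eff <- stats::rlnorm(1, config$treatmentEffectMeanlog,
                             config$treatmentEffectSdlog)
        list(params = kineticParams(K1, k2, k3, config$vbTruth),
             treatmentEffect = eff)
      })
    })
    tps <- if (i <= nFu) c("baseline", "week12") else "baseline"
    for (tp in tps) {
      injected <- if (tp == "baseline") pat$injected_activity else
        withSeed(deriveSeed(seed, "inj", i, tp),
                 max(stats::rnorm(1, config$injectedMeanFu, config$injectedSdFu), 1))
      etaScan <- withSeed(deriveSeed(seed, "scan-eta", i, tp),
                          rlnormMean1Cv(1, config$scanScaleCV))
      ifn <- simulateInputFunction(pat, config = config,
                                   scaleFactor = etaPat * etaScan,
                                   injectedMBq = injected)
      venous <- sampleVenous(ifn, config$venousTimes, config$venousNoiseCV,
                             deriveSeed(seed, "venous", i, tp))
      idif <- simulateIdif(ifn, schedule, scaleError = NULL,
                           noiseCV = config$idifNoiseCV,
                           seed = deriveSeed(seed, "idif", i, tp),
                           config = config)
      lesions <- lapply(seq_len(config$lesionsPerScan), function(l) {
        tru <- truthLesions[[l]]
        p <- tru$params
        if (tp == "week12")
          p <- kineticParams(p@K1 * tru$treatmentEffect, p@k2, p@k3, p@vb)
        tac <- simulateLesion(p, ifn, schedule, config$tacNoiseScale,
                              deriveSeed(seed, "tac", i, tp, l))
        patch <- simulateStaticPatch(p, ifn, config$tStatic, config$jitterVox,
                                     deriveSeed(seed, "patch", i, tp, l), config)
        list(lesion_id = sprintf("%s_L%d", pat$id, l), tac = tac, patch = patch,
             truthParams = p)
      })
      scans[[length(scans) + 1]] <- list(
        patient_id = pat$id, timepoint = tp, injected_mbq = injected,
        venous = venous, idif = idif,
        lesions = lapply(lesions, function(x) x[c("lesion_id", "tac", "patch")]),
        truth = list(ifn = ifn, etaScan = etaPat * etaScan,
                     lesions = lapply(lesions, function(x)
                       list(lesion_id = x$lesion_id, params = x$truthParams,
                            ki = kiFromMicro(x$truthParams)))))
    }
  }
  new("StudyData", cohort = cohort, scans = scans, config = config,
      seed = as.numeric(seed))
}

#' @rdname generateStudy
#' @param study a [StudyData-class]
#' @export
studyCohort <- function(study) study@cohort

#' @rdname generateStudy
#' @export
studyScans <- function(study) study@scans
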