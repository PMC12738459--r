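#' @import methods
NULL

#' Dynamic PET frame schedule
#'
#' Ordered, contiguous acquisition frames of a dynamic PET scan. Frame starts
#' and durations are stored in seconds with the scan clock starting at tracer
#' injection (t = 0).
#'
#' @slot start numeric, frame start times in seconds.
#' @slot duration numeric, frame durations in seconds.
#'
#' @seealso [frameSchedule()], [defaultFrameSchedule()], [validateFrames()]
#' @exportClass FrameSchedule
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric"),
  validity = function(object) {
    s <- object@start; d <- object@duration
    if (length(s) != length(d)) return("start and duration differ in length")
    if (length(s) == 0) return("schedule has no frames")
    if (any(d <= 0)) return("frame durations must be positive")
    if (is.unsorted(s, strictly = TRUE)) return("frame starts must be strictly increasing")
    ends <- s + d
    if (length(s) > 1 && any(abs(s[-1] - ends[-length(ends)]) > 1e-9))
      return("frames must be contiguous and non-overlapping")
    TRUE
  })

#' Plasma input function
#'
#' Arterial/plasma tracer concentration Cp(t), the input of the two-tissue
#' compartment model, held as a densely sampled grid (uniform spacing,
#' at most 1 s) plus the generating parameters when known.
#'
#' @slot time numeric, minutes post injection (uniform grid from 0).
#' @slot activity numeric, Cp in kBq/mL; non-negative.
#' @slot params list, generating parameters (may be empty for empirical curves).
#'
#' @seealso [inputFunction()], [triExpInputFunction()], [plasmaActivity()]
#' @exportClass InputFunction
setClass("InputFunction",
  representation(time = "numeric", activity = "numeric", params = "list"),
  prototype(params = list()),
  validity = function(object) {
    t <- object@time; a <- object@activity
    if (length(t) != length(a)) return("time and activity differ in length")
    if (length(t) < 2) return("input function needs at least two grid points")
    dt <- diff(t)
    if (any(dt <= 0)) return("time grid must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9) return("time grid must be uniform")
    if (max(dt) > 1 / 60 + 1e-9) return("grid spacing must be at most 1 s")
    if (abs(t[1]) > 1e-12) return("grid must start at t = 0")
    if (any(a < -1e-12)) return("Cp must be non-negative")
    TRUE
  })

#' Venous blood samples
#'
#' Manually drawn venous samples used to calibrate the image-derived input
#' function; by default three samples at 5, 15 and 25 min post injection.
#'
#' @slot time numeric, sample times in minutes.
#' @slot activity numeric, measured activity concentration in kBq/mL.
#' @exportClass VenousSamples
setClass("VenousSamples",
  representation(time = "numeric", activity = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@activity))
      return("time and activity differ in length")
    if (length(object@time) == 0) return("no samples")
    if (any(object@activity <= 0)) return("sample activities must be positive")
    if (is.unsorted(object@time, strictly = TRUE))
      return("sample times must be strictly increasing")
    TRUE
  })

#' Time-activity curve
#'
#' Frame-duration-averaged activity concentration of a region over a dynamic
#' frame schedule; the fitting target of the compartment model.
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot activity numeric, kBq/mL, one value per frame.
#' @seealso [timeActivityCurve()], [modelTac()], [fit2t3k()]
#' @exportClass TimeActivityCurve
setClass("TimeActivityCurve",
  representation(schedule = "FrameSchedule", activity = "numeric"),
  validity = function(object) {
    if (length(object@activity) != length(object@schedule@start))
      return("one activity value per frame required")
    TRUE
  })

#' Three-dimensional voxel patch
#'
#' A small cube of reconstructed PET voxels around one lesion, on the scanner's
#' isotropic grid (default 4 mm), used for static-scan SUV extraction.
#'
#' @slot values 3-D numeric array, kBq/mL.
#' @slot voxelSize numeric scalar, edge length in mm.
#' @exportClass VoxelPatch
setClass("VoxelPatch",
  representation(values = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3) return("values must be a 3-D array")
    if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
      return("voxelSize must be a positive scalar")
    if (any(object@values < 0)) return("voxel values must be non-negative")
    TRUE
  })

#' Spherical volume of interest
#'
#' A fixed-volume sphere on a voxel grid, included-voxel mask computed by the
#' centre-in-sphere rule.
#'
#' @slot center integer triple, voxel index of the sphere centre.
#' @slot radiusMm numeric, sphere radius in mm.
#' @slot mask logical 3-D array aligned to the source patch.
#' @seealso [makeSphereMask()], [placeVoi()], [suvMetrics()]
#' @exportClass SphereVOI
setClass("SphereVOI",
  representation(center = "numeric", radiusMm = "numeric", mask = "array"),
  validity = function(object) {
    if (length(object@center) != 3) return("center must be an index triple")
    if (object@radiusMm <= 0) return("radius must be positive")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (sum(object@mask) == 0) return("mask is empty")
    TRUE
  })

#' Micro-parameters of the irreversible two-tissue compartment model
#'
#' K1 (mL cm^-3 min^-1), k2 and k3 (min^-1) and the fractional blood volume
#' vb. The derived net influx rate is Ki = K1*k3/(k2+k3) (0 when k2+k3 = 0).
#'
#' @slot K1,k2,k3 numeric rate constants, all >= 0.
#' @slot vb numeric blood volume fraction in [0, 1).
#' @seealso [kineticParams()], [kiFromMicro()]
#' @exportClass KineticParams
setClass("KineticParams",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric", vb = "numeric"),
  prototype(vb = 0),
  validity = function(object) {
    for (nm in c("K1", "k2", "k3", "vb"))
      if (length(slot(object, nm)) != 1) return(sprintf("%s must be scalar", nm))
    if (object@K1 < 0 || object@k2 < 0 || object@k3 < 0)
      return("rate constants must be non-negative")
    if (object@vb < 0 || object@vb >= 1) return("vb must lie in [0, 1)")
    TRUE
  })

#' Result of a compartment-model fit
#'
#' @slot params fitted [KineticParams-class].
#' @slot ki derived net influx rate, min^-1.
#' @slot weightedRSS weighted residual sum of squares at the optimum.
#' @slot converged logical, honest optimizer convergence flag.
#' @slot nIter iteration count of the winning start.
#' @slot covarianceDiag per-parameter variance estimates (K1, k2, k3, vb);
#'   NA when the Jacobian is singular.
#' @seealso [fit2t3k()]
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "KineticParams", ki = "numeric", weightedRSS = "numeric",
                 converged = "logical", nIter = "numeric", covarianceDiag = "numeric"),
  validity = function(object) {
    ki0 <- kiFromMicro(object@params)
    if (abs(object@ki - ki0) > 1e-12 * max(1, abs(ki0)))
      return("ki inconsistent with micro-parameters")
    TRUE
  })

#' Synthetic study dataset
#'
#' Everything one simulated cohort produces: the cohort table, per-scan
#' observables (venous samples, IDIF, lesion TACs, static patches) and the
#' generating ground truth, kept in a separate slot so that estimation code
#' can be audited never to touch it.
#'
#' @slot cohort data.frame, one row per patient.
#' @slot scans list of per-scan records (see [generateStudy()]).
#' @slot config list, the full generator configuration.
#' @slot seed integer master seed.
#' @exportClass StudyData
setClass("StudyData",
  representation(cohort = "data.frame", scans = "list", config = "list",
                 seed = "numeric"))

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.0f s total (%.1f min)\n",
              length(object@start), sum(object@duration), sum(object@duration) / 60))
})

setMethod("show", "InputFunction", function(object) {
  cat(sprintf("InputFunction: %d grid points over 0-%.1f min, peak %.2f kBq/mL\n",
              length(object@time), max(object@time), max(object@activity)))
})

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve: %d frames, last frame %.3f kBq/mL\n",
              length(object@activity), object@activity[length(object@activity)]))
})

setMethod("show", "VoxelPatch", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelPatch: %dx%dx%d voxels of %.1f mm, max %.3f kBq/mL\n",
              d[1], d[2], d[3], object@voxelSize, max(object@values)))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: K1=%.4f k2=%.4f k3=%.4f vb=%.3f (Ki=%.5f /min)\n",
              object@K1, object@k2, object@k3, object@vb, kiFromMicro(object)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("2t3k fit: Ki=%.5f /min, wRSS=%.4g, converged=%s (%d iter)\n",
              object@ki, object@weightedRSS, object@converged, object@nIter))
  show(object@params)
})

setMethod("show", "StudyData", function(object) {
  cat(sprintf("StudyData: %d patients, %d scans (seed %d)\n",
              nrow(object@cohort), length(object@scans), object@seed))
})
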