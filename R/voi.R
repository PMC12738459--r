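#' Spherical VOI mask on a voxel grid
#'
#' Radius is `(3 V / 4 pi)^(1/3)`; a voxel belongs to the sphere iff its
#' centre lies within the radius of the sphere centre (centre-in-sphere
#' rule). A 1.2 cm^3 request on the 4-mm grid, centred on a voxel centre,
#' yields 19 voxels (realized volume 1.216 mL); 1.7 cm^3 yields 27.
#'
#' @param patch a [VoxelPatch-class]
#' @param center numeric index triple (may be fractional)
#' @param targetVolume cm^3
#' @return a [SphereVOI-class]
#' @examples
#' p <- new("VoxelPatch", values = array(0, c(15, 15, 15)), voxelSize = 4)
#' sum(makeSphereMask(p, c(8, 8, 8), 1.2)@mask) # 19
#' @export
makeSphereMask <- function(patch, center, targetVolume) {
  d <- dim(patch@values)
  if (any(center < 1) || any(center > d)) stop("center outside the patch")
  radius <- (3 * targetVolume * 1000 / (4 * pi))^(1 / 3) # mm
  rVox <- radius / patch@voxelSize
  if (any(center - rVox < 0.5) || any(center + rVox > d + 0.5))
    stop("sphere exceeds the patch bounds")
  ax <- lapply(1:3, function(k) (seq_len(d[k]) - center[k])^2)
  dist2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  mask <- dist2 <= rVox^2 + 1e-12
  new("SphereVOI", center = center, radiusMm = radius, mask = mask)
}

#' Place a fixed-volume VOI on the hottest voxel
#'
#' The sphere centre is the patch's maximum voxel; ties break to the lowest
#' linear (column-major) index, deterministically.
#'
#' @param patch a [VoxelPatch-class]
#' @param targetVolume cm^3 (default 1.2, the lesion VOI)
#' @return a [SphereVOI-class]
#' @export
placeVoi <- function(patch, targetVolume = 1.2) {
  idx <- which.max(patch@values) # lowest linear index on ties
  center <- arrayInd(idx, dim(patch@values))[1, ]
  makeSphereMask(patch, center, targetVolume)
}

#' SUV metrics of a VOI on a voxel patch
#'
#' `SUVmax` is the hottest voxel inside the VOI, `SUVmean` the mean over the
#' VOI, and `SUVpeak` the highest mean of a small movable sphere (default
#' 1.0 cm^3) centred on any voxel inside the VOI whose sphere fits in the
#' patch. Each concentration is converted to SUV under all four
#' normalizations via [suvValue()].
#'
#' @param patch a [VoxelPatch-class]
#' @param voi a [SphereVOI-class] aligned to `patch`
#' @param injectedActivity MBq
#' @param factors one-row normalization-factor table (see
#'   [normalizationFactors()])
#' @param timeWindow label stored in the records (default `"45min"`)
#' @param peakVolume movable-sphere volume for SUVpeak, cm^3
#' @return data.frame of SUV records: `metric`, `normalization`,
#'   `time_window`, `concentration`, `value`
#' @export
suvMetrics <- function(patch, voi, injectedActivity, factors,
                       timeWindow = "45min", peakVolume = 1.0) {
  vals <- patch@values
  if (!all(dim(voi@mask) == dim(vals))) stop("VOI is not aligned to the patch")
  inVoi <- vals[voi@mask]
  if (length(inVoi) == 0) stop("empty VOI")
  cMax <- max(inVoi)
  cMean <- mean(inVoi)
  # movable peak sphere over candidate centres inside the VOI
  rPeak <- (3 * peakVolume * 1000 / (4 * pi))^(1 / 3) / patch@voxelSize
  offs <- expand.grid(i = -floor(rPeak):floor(rPeak),
                      j = -floor(rPeak):floor(rPeak),
                      k = -floor(rPeak):floor(rPeak))
  offs <- offs[offs$i^2 + offs$j^2 + offs$k^2 <= rPeak^2 + 1e-12, ]
  d <- dim(vals)
  centres <- arrayInd(which(voi@mask), d)
  cPeak <- -Inf
  for (r in seq_len(nrow(centres))) {
    cc <- centres[r, ]
    ii <- cc[1] + offs$i; jj <- cc[2] + offs$j; kk <- cc[3] + offs$k
    if (any(ii < 1 | ii > d[1] | jj < 1 | jj > d[2] | kk < 1 | kk > d[3])) next
    m <- mean(vals[cbind(ii, jj, kk)])
    if (m > cPeak) cPeak <- m
  }
  if (!is.finite(cPeak)) cPeak <- cMean # no candidate sphere fits
  conc <- c(max = cMax, peak = cPeak, mean = cMean)
  out <- expand.grid(metric = names(conc),
                     normalization = c("BW", "LBM", "BSA", "SV"),
                     stringsAsFactors = FALSE)
  out$time_window <- timeWindow
  out$concentration <- conc[out$metric]
  out$value <- vapply(seq_len(nrow(out)), function(r)
    suvValue(out$concentration[r], injectedActivity, factors,
             out$normalization[r]), numeric(1))
  out
}

#' SUV from the last dynamic frame (25-30 min window)
#'
#' Uses the final 300-s frame of the default dynamic schedule as the
#' concentration and converts it to SUV under all four normalizations. At
#' region level the TAC is already a VOI mean, so the record is the
#' region-level equivalent of SUVmean/SUVpeak; a voxelwise maximum is not
#' available without a dynamic patch.
#'
#' @param tac a [TimeActivityCurve-class] whose schedule ends at 1800 s
#' @param injectedActivity MBq
#' @param factors one-row normalization-factor table
#' @return data.frame of SUV records labelled `time_window = "25-30min"`,
#'   `metric = "mean"`
#' @export
lastFrameSuv <- function(tac, injectedActivity, factors) {
  sched <- tac@schedule
  k <- nFrames(sched)
  if (abs(sched@start[k] + sched@duration[k] - 1800) > 1e-6)
    stop("schedule does not end with a frame at 1800 s")
  conc <- tac@activity[k]
  out <- data.frame(metric = "mean",
                    normalization = c("BW", "LBM", "BSA", "SV"),
                    time_window = "25-30min", concentration = conc,
                    stringsAsFactors = FALSE)
  out$value <- vapply(seq_len(nrow(out)), function(r)
    suvValue(conc, injectedActivity, factors, out$normalization[r]), numeric(1))
  out
}
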