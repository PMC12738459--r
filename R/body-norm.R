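#' Lean body mass by the Janmahasatian fat-free-mass equations
#'
#' `male: 9270 W / (6680 + 216 BMI)`, `female: 9270 W / (8780 + 244 BMI)`
#' with `BMI = W / (H/100)^2`. Monotone increasing in weight at fixed height
#' and always below total body weight.
#'
#' @param weight kg, > 0 (vectorized)
#' @param height cm, > 0
#' @param sex `"male"` or `"female"`
#' @return lean body mass, kg
#' @examples
#' lbmJanmahasatian(85, 173, "male")   # ~61.5 kg
#' lbmJanmahasatian(60, 165, "female") # ~39.3 kg
#' @export
lbmJanmahasatian <- function(weight, height, sex) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  sex <- rep_len(sex, length(weight))
  bmi <- weight / (height / 100)^2
  ifelse(sex == "male",
         9270 * weight / (6680 + 216 * bmi),
         9270 * weight / (8780 + 244 * bmi))
}

#' Body surface area
#'
#' DuBois-DuBois by default: `0.007184 * W^0.425 * H^0.725` (W kg, H cm);
#' Mosteller (`sqrt(W*H/3600)`) available as alternative.
#'
#' @param weight kg, > 0 (vectorized)
#' @param height cm, > 0
#' @param formula `"dubois"` (default) or `"mosteller"`
#' @return body surface area, m^2
#' @examples
#' bodySurfaceArea(85, 173) # ~1.99 m^2
#' @export
bodySurfaceArea <- function(weight, height, formula = c("dubois", "mosteller")) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  formula <- match.arg(formula)
  switch(formula,
         dubois = 0.007184 * weight^0.425 * height^0.725,
         mosteller = sqrt(weight * height / 3600))
}

#' Scale a partial skeletal volume to total skeletal volume
#'
#' The bones visible in a whole-body scan (spine, ribs, pelvis, humeri,
#' scapulae, clavicles, sternum) represent a fixed fraction of the full
#' skeleton; their combined volume times 1.80 estimates total skeletal
#' volume.
#'
#' @param partialBoneVolume mL, > 0 (vectorized)
#' @param factor scaling factor, default 1.80
#' @return total skeletal volume, mL
#' @examples
#' estimateSkeletalVolume(9500) # 17100 mL
#' @export
estimateSkeletalVolume <- function(partialBoneVolume, factor = 1.80) {
  if (any(partialBoneVolume <= 0)) stop("partial bone volume must be positive")
  factor * partialBoneVolume
}

#' Synthetic partial skeletal volume
#'
#' Synthetic stand-in for the CT-segmented partial bone volume, which no
#' generator of image-free data can measure. Drawn proportional to lean body
#' mass (skeletal volume tracks fat-free mass closely in vivo) times
#' multiplicative lognormal noise: `partial = perKgLbm * LBM * exp(noise)`.
#' Deterministic at `noiseCV = 0`; the default 28 mL per kg LBM puts the
#' implied total skeletal volume (x 1.80) at ~50 mL/kg LBM, about 3 L for an
#' average adult.
#'
#' @param patient one-row data.frame (or list) with `weight`, `height`, `sex`
#' @param seed integer seed
#' @param perKgLbm mL of partial bone volume per kg lean mass
#' @param noiseCV lognormal coefficient of variation
#' @return partial skeletal volume, mL
#' @export
synthPartialSkeletalVolume <- function(patient, seed, perKgLbm = 28, noiseCV = 0.05) {
  lbm <- lbmJanmahasatian(patient$weight, patient$height, patient$sex)
  base <- perKgLbm * lbm
  if (noiseCV > 0) {
    sdlog <- sqrt(log(1 + noiseCV^2))
    base <- base * withSeed(seed, stats::rlnorm(length(base), -sdlog^2 / 2, sdlog))
  }
  base
}

#' Normalization factors for one cohort
#'
#' Vectorized table transform: cohort in, one row of normalization factors per
#' patient out. Units follow the conventions of [suvValue()].
#'
#' @param cohort data.frame with columns `id`, `sex`, `weight` (kg), `height`
#'   (cm) and either `partial_sv_ml` or `sv_ml`
#' @param bsaFormula passed to [bodySurfaceArea()]
#' @param svFactor passed to [estimateSkeletalVolume()]
#' @return data.frame: `patient_id`, `bw_kg`, `lbm_kg`, `bsa_m2`, `sv_ml`
#' @export
normalizationFactors <- function(cohort, bsaFormula = "dubois", svFactor = 1.80) {
  sv <- if (!is.null(cohort$sv_ml)) cohort$sv_ml
        else estimateSkeletalVolume(cohort$partial_sv_ml, svFactor)
  data.frame(patient_id = cohort$id,
             bw_kg = cohort$weight,
             lbm_kg = lbmJanmahasatian(cohort$weight, cohort$height, cohort$sex),
             bsa_m2 = bodySurfaceArea(cohort$weight, cohort$height, bsaFormula),
             sv_ml = sv,
             stringsAsFactors = FALSE)
}

#' Standardized uptake value
#'
#' `SUV = C / (A / NF)` with the activity concentration `C` in kBq/mL, the
#' injected activity `A` in MBq and the normalization factor `NF` fixed by
#' convention so reported values sit on the printed scales of the study
#' tables:
#' \itemize{
#'  \item `BW`: body weight in g (1 g is taken as 1 mL of tissue),
#'  \item `LBM`: lean body mass in g,
#'  \item `BSA`: body surface area in cm^2 / 10 (i.e. m^2 x 10^3), so values
#'    are read as "SUV_BSA x 10^2",
#'  \item `SV`: skeletal volume in mL, read as "SUV_SV x 10^2".
#' }
#' All four SUVs of one measurement are exact ratios of their normalization
#' factors; no hidden state.
#'
#' @param concentration kBq/mL, >= 0 (vectorized)
#' @param injectedActivity MBq, > 0
#' @param factors one-row data.frame/list with `bw_kg`, `lbm_kg`, `bsa_m2`,
#'   `sv_ml` (see [normalizationFactors()]), recycled against `concentration`
#' @param normalization `"BW"`, `"LBM"`, `"BSA"` or `"SV"`
#' @return dimensionless SUV (on the printed scale of the chosen convention)
#' @examples
#' f <- list(bw_kg = 85, lbm_kg = 61.5, bsa_m2 = 1.99, sv_ml = 3100)
#' suvValue(2.0, 100, f, "BW") # 1.70
#' @export
suvValue <- function(concentration, injectedActivity, factors,
                     normalization = c("BW", "LBM", "BSA", "SV")) {
  if (any(injectedActivity <= 0)) stop("injected activity must be positive")
  normalization <- match.arg(normalization)
  nf <- switch(normalization,
               BW = factors$bw_kg * 1000,
               LBM = factors$lbm_kg * 1000,
               BSA = factors$bsa_m2 * 1000,
               SV = factors$sv_ml)
  if (any(nf <= 0)) stop("normalization factor must be positive")
  concentration * nf / (injectedActivity * 1000)
}
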