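#' Blood SUV table of a synthetic study
#'
#' Converts every venous sample of every scan to SUV under all four
#' normalizations. One row per scan x sample moment x normalization.
#'
#' @param study a [StudyData-class]
#' @return data.frame: `patient_id`, `timepoint`, `weight`, `time_min`,
#'   `normalization`, `suv`
#' @export
venousSuvTable <- function(study) {
  nf <- normalizationFactors(study@cohort, svFactor = study@config$svFactor)
  rows <- lapply(study@scans, function(scan) {
    f <- nf[nf$patient_id == scan$patient_id, ]
    w <- study@cohort$weight[study@cohort$id == scan$patient_id]
    grid <- expand.grid(time_min = scan$venous@time,
                        normalization = c("BW", "LBM", "BSA", "SV"),
                        stringsAsFactors = FALSE)
    grid$suv <- vapply(seq_len(nrow(grid)), function(r) {
      conc <- scan$venous@activity[match(grid$time_min[r], scan$venous@time)]
      suvValue(conc, scan$injected_mbq, f, grid$normalization[r])
    }, numeric(1))
    data.frame(patient_id = scan$patient_id, timepoint = scan$timepoint,
               weight = w, grid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean and CoV of blood SUVs per normalization and sample moment
#'
#' The venous-table analogue: population mean and coefficient of variation
#' of the blood SUV for each normalization at each sample moment.
#'
#' @param suvTable output of [venousSuvTable()]
#' @return data.frame: `normalization`, `time_min`, `n`, `mean`, `cov`
#' @export
venousSummary <- function(suvTable) {
  combos <- unique(suvTable[, c("normalization", "time_min")])
  combos <- combos[order(combos$normalization, combos$time_min), ]
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    v <- suvTable$suv[suvTable$normalization == combos$normalization[r] &
                        suvTable$time_min == combos$time_min[r]]
    data.frame(normalization = combos$normalization[r],
               time_min = combos$time_min[r], n = length(v),
               mean = mean(v), cov = coefVar(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate and fit every lesion of a study
#'
#' For each scan the IDIF is calibrated against the venous samples, promoted
#' to a dense input function, and each lesion TAC is fitted with the 2t3k
#' model; the Patlak slope is computed as cross-check. Only observed data
#' enter: the ground-truth slot of the scans is never read.
#'
#' @param study a [StudyData-class]
#' @param calibration passed to [calibrateIdif()] (`"midpoint"` default)
#' @param fitVb fit the blood volume fraction (default TRUE)
#' @param tStar Patlak start time, minutes
#' @return data.frame: `patient_id`, `lesion_id`, `timepoint`, `K1`, `k2`,
#'   `k3`, `vb`, `Ki`, `patlak_ki`, `weighted_rss`, `converged`,
#'   `calibration_factor`
#' @export
fitStudy <- function(study, calibration = "midpoint", fitVb = TRUE, tStar = 10) {
  rows <- lapply(study@scans, function(scan) {
    cal <- calibrateIdif(scan$idif, scan$venous, method = calibration)
    ifnCal <- tacToInputFunction(cal$tac, tMax = study@config$gridTMax,
                                 dt = study@config$gridDt)
    do.call(rbind, lapply(scan$lesions, function(les) {
      fit <- fit2t3k(les$tac, ifnCal, fitVb = fitVb)
      pk <- patlakKi(les$tac, ifnCal, tStar = tStar)
      p <- fit@params
      data.frame(patient_id = scan$patient_id, lesion_id = les$lesion_id,
                 timepoint = scan$timepoint, K1 = p@K1, k2 = p@k2, k3 = p@k3,
                 vb = p@vb, Ki = fit@ki, patlak_ki = pk$slope,
                 weighted_rss = fit@weightedRSS, converged = fit@converged,
                 calibration_factor = cal$factor, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Lesion SUV table (dynamic 25-30 min window and 45-min static scan)
#'
#' Per lesion and scan: the last-dynamic-frame SUV (region level, metric
#' `"mean"`) and the static-patch SUVmax/peak/mean, each under all four
#' normalizations. The static VOI is placed on the hottest voxel of the
#' patch (1.2 cm^3 sphere).
#'
#' @param study a [StudyData-class]
#' @return data.frame: `patient_id`, `lesion_id`, `timepoint`, `metric`,
#'   `normalization`, `time_window`, `concentration`, `value`
#' @export
studySuvTable <- function(study) {
  nf <- normalizationFactors(study@cohort, svFactor = study@config$svFactor)
  rows <- lapply(study@scans, function(scan) {
    f <- nf[nf$patient_id == scan$patient_id, ]
    do.call(rbind, lapply(scan$lesions, function(les) {
      dyn <- lastFrameSuv(les$tac, scan$injected_mbq, f)
      voi <- placeVoi(les$patch, 1.2)
      stat <- suvMetrics(les$patch, voi, scan$injected_mbq, f, "45min")
      out <- rbind(dyn, stat)
      data.frame(patient_id = scan$patient_id, lesion_id = les$lesion_id,
                 timepoint = scan$timepoint, out, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-sectional correlations of SUV metrics with Ki
#'
#' Pearson R^2 (with Fisher-z interval) between fitted Ki and each SUV
#' metric x normalization x time window, pooling lesions across scans as the
#' study design does.
#'
#' @param fits output of [fitStudy()]
#' @param suvTable output of [studySuvTable()]
#' @return data.frame: per combination `n`, `r`, `r_squared`, `ci_low`,
#'   `ci_high`, `p`
#' @export
crossSectionalCorrelations <- function(fits, suvTable) {
  key <- function(d) paste(d$lesion_id, d$timepoint)
  suvTable$ki <- fits$Ki[match(key(suvTable), key(fits))]
  combos <- unique(suvTable[, c("metric", "normalization", "time_window")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sel <- suvTable$metric == combos$metric[r] &
      suvTable$normalization == combos$normalization[r] &
      suvTable$time_window == combos$time_window[r]
    pr <- pearsonR2(suvTable$ki[sel], suvTable$value[sel])
    data.frame(combos[r, ], n = pr$n, r = pr$r, r_squared = pr$r_squared,
               ci_low = pr$ci_low, ci_high = pr$ci_high, p = pr$p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default end-to-end run configuration
#'
#' Cohort size and follow-up fraction mirror the image-analysis arm of the
#' emulated study design (27 patients with lesions in the dynamic field of
#' view, 16 of them with follow-up), on top of [defaultGeneratorConfig()].
#'
#' @param seed master seed
#' @return list with `nPatients`, `followupFraction`, `seed`, `generator`,
#'   `calibration`, `fitVb`, `tStar`
#' @export
defaultRunConfig <- function(seed = 1) {
  list(nPatients = 27, followupFraction = 16 / 27, seed = seed,
       generator = defaultGeneratorConfig(),
       calibration = "midpoint", fitVb = TRUE, tStar = 10)
}

#' Run the full synthetic study pipeline
#'
#' simulate -> calibrate -> fit -> SUV -> statistics, in one reproducible
#' call. Emits the venous summary (mean/CoV per normalization and moment),
#' the mean-normalized Levene comparison across normalizations, the 85-kg
#' weight-group t-tests, the cross-sectional correlation table at both time
#' windows, the longitudinal ratio table, Bland-Altman summaries (fit vs
#' Patlak Ki; longitudinal ratio agreement on the log scale) and the
#' treatment-covariate regression. Every output carries the master seed and
#' a hash of the full configuration. Stage failures abort with a
#' stage-labelled error.
#'
#' @param config a run configuration, see [defaultRunConfig()]
#' @param outDir optional directory; when given, all tables are written as
#'   CSV plus a plain-text report
#' @return list of tables and summaries (see Details) plus `meta`
#' @export
runStudy <- function(config = defaultRunConfig(), outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  meta <- list(seed = config$seed, config_hash = configHash(config))

  study <- stage("simulate",
    generateStudy(config$nPatients, config$followupFraction, config$seed,
                  config$generator))
  vsuv <- stage("venous", venousSuvTable(study))
  vsum <- stage("venous", venousSummary(vsuv))
  lev <- stage("venous", {
    do.call(rbind, lapply(unique(vsuv$time_min), function(tm) {
      groups <- lapply(c("BW", "LBM", "BSA", "SV"), function(nm)
        vsuv$suv[vsuv$normalization == nm & vsuv$time_min == tm])
      lv <- leveneMeanNormalized(groups)
      data.frame(time_min = tm, statistic = lv$statistic, df1 = lv$df1,
                 df2 = lv$df2, p = lv$p.value)
    }))
  })
  wgt <- stage("venous", weightGroupTTest(vsuv))
  fits <- stage("fit", fitStudy(study, config$calibration, config$fitVb,
                                config$tStar))
  suv <- stage("suv", studySuvTable(study))
  xsec <- stage("analyze", crossSectionalCorrelations(fits, suv))

  lesTab <- stage("analyze", {
    key <- function(d) paste(d$lesion_id, d$timepoint)
    data.frame(patient_id = suv$patient_id,
               lesion_id = suv$lesion_id, timepoint = suv$timepoint,
               ki = fits$Ki[match(key(suv), key(fits))],
               metric = suv$metric, normalization = suv$normalization,
               time_window = suv$time_window, suv = suv$value,
               stringsAsFactors = FALSE)
  })
  hasPairs <- sum(fits$timepoint == "week12") >= 3
  longitudinal <- stage("analyze", {
    if (!hasPairs) {
      out <- data.frame(metric = character(), normalization = character(),
                        time_window = character(), n_pairs = integer(),
                        r_squared = numeric(), ci_low = numeric(),
                        ci_high = numeric(), p = numeric(),
                        degenerate = logical())
      attr(out, "note") <- "no follow-up scans: longitudinal analysis empty"
      out
    } else longitudinalRatioAnalysis(lesTab)
  })
  ba <- stage("analyze", {
    out <- list(fit_vs_patlak = blandAltman(fits$patlak_ki, fits$Ki))
    if (hasPairs) {
      for (w in unique(lesTab$time_window)) {
        sub <- lesTab[lesTab$time_window == w &
                        lesTab$normalization == "LBM" &
                        lesTab$metric == lesTab$metric[lesTab$time_window == w][1], ]
        bl <- sub[sub$timepoint == "baseline", ]
        fu <- sub[sub$timepoint == "week12", ]
        common <- intersect(bl$lesion_id, fu$lesion_id)
        bl <- bl[match(common, bl$lesion_id), ]
        fu <- fu[match(common, fu$lesion_id), ]
        out[[paste0("ratio_", w)]] <-
          blandAltman(fu$suv / bl$suv, fu$ki / bl$ki, logScale = TRUE)
      }
    }
    out
  })
  reg <- stage("analyze", {
    sub <- lesTab[lesTab$time_window == "25-30min" &
                    lesTab$normalization == "LBM", ]
    sub$therapy <- study@cohort$therapy[match(sub$patient_id, study@cohort$id)]
    if (length(unique(sub$therapy)) == 2) treatmentRegression(sub) else NULL
  })

  result <- list(study = study, venous_suv = vsuv, venous_summary = vsum,
                 levene = lev, weight_group = wgt, fits = fits,
                 suv_table = suv, cross_sectional = xsec,
                 longitudinal = longitudinal, bland_altman = ba,
                 treatment_regression = reg, meta = meta)
  if (!is.null(outDir)) writeRunReport(result, outDir)
  result
}

# Write the run's tables as CSV plus a plain-text report.
writeRunReport <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$seed <- result$meta$seed
    df$config_hash <- result$meta$config_hash
    df
  }
  for (nm in c("venous_summary", "levene", "weight_group", "fits",
               "cross_sectional", "longitudinal")) {
    utils::write.csv(stamp(result[[nm]]),
                     file.path(outDir, paste0(nm, ".csv")), row.names = FALSE)
  }
  rep <- c(sprintf("fluorkin run (seed %s, config %s)", result$meta$seed,
                   result$meta$config_hash),
           "",
           sprintf("scans: %d, lesions fitted: %d, converged: %d",
                   length(result$study@scans), nrow(result$fits),
                   sum(result$fits$converged)),
           sprintf("venous SUV CoV range: %.3f-%.3f",
                   min(result$venous_summary$cov),
                   max(result$venous_summary$cov)),
           if (nrow(result$longitudinal) == 0)
             "longitudinal: no follow-up scans (table empty)"
           else sprintf("longitudinal r^2 (25-30 min, LBM): %.3f",
                        result$longitudinal$r_squared[
                          result$longitudinal$time_window == "25-30min" &
                            result$longitudinal$normalization == "LBM"][1]))
  writeLines(rep, file.path(outDir, "report.txt"))
  invisible(outDir)
}
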