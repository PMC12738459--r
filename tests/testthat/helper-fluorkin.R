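# Shared fixtures, all built in code.

testPatient <- function(weight = 85, height = 173, sex = "male",
                        injected = 100, id = "P001") {
  data.frame(id = id, sex = sex, weight = weight, height = height,
             diagnosis = "axSpA", therapy = "IL-17A",
             injected_activity = injected, timepoint = "baseline",
             stringsAsFactors = FALSE)
}

# constant plasma concentration, the closed-form oracle's input
constantInput <- function(cp = 10, tMax = 40) {
  n <- tMax * 60 + 1
  inputFunction(seq(0, tMax, by = 1 / 60), rep(cp, n))
}

# closed-form 2t3k tissue curve for constant Cp = c and vb = 0:
# C_T(t) = K1 c [k3 t/(k2+k3) + k2/(k2+k3)^2 (1 - exp(-(k2+k3) t))]
closedFormConstCp <- function(K1, k2, k3, cp, t) {
  th <- k2 + k3
  K1 * cp * (k3 * t / th + k2 / th^2 * (1 - exp(-th * t)))
}

# a noise-free lesion world: patient, true input function, default schedule
noiseFreeWorld <- function(K1 = 0.12, k2 = 0.3, k3 = 0.1, vb = 0) {
  pat <- testPatient()
  ifn <- simulateInputFunction(pat, scaleFactor = 1)
  list(patient = pat, ifn = ifn, schedule = defaultFrameSchedule(),
       params = kineticParams(K1, k2, k3, vb))
}

uniformPatch <- function(value = 1, d = 15, voxel = 4) {
  new("VoxelPatch", values = array(value, c(d, d, d)), voxelSize = voxel)
}

testFactors <- function() {
  list(bw_kg = 85, lbm_kg = 61.489, bsa_m2 = 1.991, sv_ml = 3100)
}
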