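#' Construct an input function from an explicit grid
#'
#' @param time numeric, minutes, uniform grid starting at 0 with spacing <= 1 s.
#' @param activity numeric, Cp in kBq/mL.
#' @param params optional list of generating parameters.
#' @return an [InputFunction-class]
#' @examples
#' # a constant plasma concentration of 10 kBq/mL over 0-40 min
#' ifn <- inputFunction(seq(0, 40, by = 1/60), rep(10, 40 * 60 + 1))
#' @export
inputFunction <- function(time, activity, params = list()) {
  new("InputFunction", time = as.numeric(time), activity = as.numeric(activity),
      params = params)
}

#' Default plasma shape of the fluoride input function
#'
#' Dimensionless tri-exponential bolus shape expressed on the blood SUV-LBM
#' scale: a linear rise from 0 to the bolus peak at `peakTime`, then
#' `sum(amplitudes * exp(-rates * (t - peakTime)))`. With the default rates
#' (4, 0.25, 0.02 min^-1) the two slower amplitudes are solved so the shape
#' passes exactly through blood SUV-LBM 2.44 at 5 min and 1.34 at 25 min;
#' the value at 15 min is then 1.67 (the fast bolus term has fully decayed
#' by 5 min, so only two amplitudes remain free at the sample times).
#'
#' @param rates decay constants (min^-1), fastest first.
#' @param peakAmplitude amplitude of the fast bolus term (SUV-LBM units).
#' @param peakTime bolus peak time, minutes.
#' @param anchorTimes,anchorValues two (time, value) anchors the two slow
#'   amplitudes are solved against.
#' @return list with `amplitudes`, `rates`, `peakTime`
#' @export
defaultInputShape <- function(rates = c(4, 0.25, 0.02), peakAmplitude = 20,
                              peakTime = 1,
                              anchorTimes = c(5, 25),
                              anchorValues = c(2.44, 1.34)) {
  ts <- anchorTimes - peakTime
  fast <- peakAmplitude * exp(-rates[1] * ts)
  M <- cbind(exp(-rates[2] * ts), exp(-rates[3] * ts))
  slow <- solve(M, anchorValues - fast)
  if (any(slow <= 0)) stop("anchor values inconsistent with the chosen rates")
  list(amplitudes = c(peakAmplitude, slow), rates = rates, peakTime = peakTime)
}

#' Evaluate a tri-exponential bolus shape
#'
#' @param t minutes
#' @param shape list as returned by [defaultInputShape()]
#' @return dimensionless shape values
#' @export
evalInputShape <- function(t, shape) {
  tp <- shape$peakTime
  peak <- sum(shape$amplitudes)
  out <- numeric(length(t))
  rising <- t < tp & t >= 0
  out[rising] <- peak * t[rising] / tp
  post <- t >= tp
  if (any(post)) {
    tt <- t[post] - tp
    out[post] <- drop(exp(outer(tt, -shape$rates)) %*% shape$amplitudes)
  }
  out
}

#' Build a tri-exponential input function on a dense grid
#'
#' @param scale kBq/mL per shape unit (injected activity / distribution volume).
#' @param shape list from [defaultInputShape()].
#' @param tMax grid extent, minutes.
#' @param dt grid spacing, minutes (default 1 s).
#' @return an [InputFunction-class]
#' @export
triExpInputFunction <- function(scale = 1, shape = defaultInputShape(),
                                tMax = 48, dt = 1 / 60) {
  t <- seq(0, tMax, by = dt)
  inputFunction(t, scale * evalInputShape(t, shape),
                params = c(shape, list(scale = scale)))
}

#' Interpolate Cp at arbitrary times
#'
#' Linear interpolation on the dense grid; times outside the grid are an error.
#'
#' @param ifn an [InputFunction-class]
#' @param t numeric, minutes
#' @return Cp values, kBq/mL
#' @export
plasmaActivity <- function(ifn, t) {
  if (any(t < min(ifn@time) - 1e-9) || any(t > max(ifn@time) + 1e-9))
    stop("requested times fall outside the input-function grid")
  stats::approx(ifn@time, ifn@activity, xout = t, rule = 2)$y
}

# grid spacing in minutes (validated uniform)
ifnDt <- function(ifn) ifn@time[2] - ifn@time[1]

# cumulative trapezoid of y on a uniform grid with spacing dt
cumTrapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

# Average dense grid values over each frame of a schedule (trapezoid /
# duration). The grid must cover every frame; frame boundaries are snapped
# to the nearest grid point (grid spacing 1 s vs integer-second frames).
frameAverage <- function(values, timeMin, schedule) {
  dt <- timeMin[2] - timeMin[1]
  startIdx <- round(schedule@start / 60 / dt) + 1
  endIdx <- round((schedule@start + schedule@duration) / 60 / dt) + 1
  if (max(endIdx) > length(values))
    stop("schedule extends past the input-function grid")
  vapply(seq_along(startIdx), function(i) {
    v <- values[startIdx[i]:endIdx[i]]
    (sum(v) - (v[1] + v[length(v)]) / 2) / (length(v) - 1)
  }, numeric(1))
}
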