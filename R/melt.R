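# Two-state UV melting-curve simulation and inflection-point Tm estimation.
# The unfolding equilibrium is modeled with a van't Hoff two-state law:
# K(T) = exp(-(dH/R) (1/T - 1/Tm)) in kelvin, unfolded fraction f = K/(1+K),
# absorbance = folded baseline * (1 - f) + unfolded baseline * f.

.GAS_CONSTANT <- 8.314  # J/(mol K)

#' TwoStateParams: van't Hoff parameters of a melting transition
#'
#' @slot tm melting temperature, degrees C (midpoint: f(Tm) = 1/2).
#' @slot dh van't Hoff enthalpy, kJ/mol (> 0).
#' @slot baselineFolded,baselineUnfolded numeric c(intercept, slope) of the
#'   linear absorbance baselines (absorbance units, per degree C). The
#'   unfolded plateau must be at least the folded plateau at Tm
#'   (hyperchromicity: absorbance rises on melting).
#' @export
setClass("TwoStateParams", representation(
  tm = "numeric", dh = "numeric",
  baselineFolded = "numeric", baselineUnfolded = "numeric"
))

setValidity("TwoStateParams", function(object) {
  if (object@dh <= 0) return("van't Hoff enthalpy dh must be > 0")
  bf <- object@baselineFolded
  bu <- object@baselineUnfolded
  if (length(bf) != 2L || length(bu) != 2L) return("baselines must be c(intercept, slope)")
  if (bu[1] + bu[2] * object@tm < bf[1] + bf[2] * object@tm) {
    return("unfolded plateau must be >= folded plateau (hyperchromicity)")
  }
  TRUE
})

#' @rdname TwoStateParams-class
#' @param tm,dh,baselineFolded,baselineUnfolded see slots.
#' @export
TwoStateParams <- function(tm, dh, baselineFolded = c(1, 0),
                           baselineUnfolded = c(1.3, 0)) {
  new("TwoStateParams", tm = tm, dh = dh,
      baselineFolded = baselineFolded, baselineUnfolded = baselineUnfolded)
}

setMethod("show", "TwoStateParams", function(object) {
  cat("TwoStateParams: Tm =", object@tm, "degC, dH =", object@dh, "kJ/mol\n")
})

#' MeltingCurve: a temperature-absorbance trace
#'
#' @slot temperature strictly increasing grid in degrees C.
#' @slot absorbance absorbance values (arbitrary units), same length.
#' @export
setClass("MeltingCurve", representation(
  temperature = "numeric", absorbance = "numeric"
))

setValidity("MeltingCurve", function(object) {
  if (length(object@temperature) != length(object@absorbance)) {
    return("temperature and absorbance must have equal length")
  }
  if (is.unsorted(object@temperature, strictly = TRUE)) {
    return("temperature grid must be strictly increasing")
  }
  TRUE
})

#' @rdname MeltingCurve-class
#' @param temperature,absorbance see slots.
#' @export
MeltingCurve <- function(temperature, absorbance) {
  new("MeltingCurve", temperature = temperature, absorbance = absorbance)
}

#' @rdname MeltingCurve-class
#' @param x a \linkS4class{MeltingCurve}.
#' @export
curveTemperature <- function(x) x@temperature

#' @rdname MeltingCurve-class
#' @export
curveAbsorbance <- function(x) x@absorbance

setMethod("show", "MeltingCurve", function(object) {
  cat("MeltingCurve:", length(object@temperature), "points,",
      min(object@temperature), "-", max(object@temperature), "degC\n")
})

#' Unfolded fraction of the two-state model
#'
#' @param params a \linkS4class{TwoStateParams}.
#' @param temperature degrees C (vectorized).
#' @return fraction unfolded in (0, 1); exactly 0.5 at Tm.
#' @export
unfoldedFraction <- function(params, temperature) {
  tK <- temperature + 273.15
  tmK <- params@tm + 273.15
  K <- exp(-(params@dh * 1000 / .GAS_CONSTANT) * (1 / tK - 1 / tmK))
  K / (1 + K)
}

#' Simulate a two-state melting curve
#'
#' @param params a \linkS4class{TwoStateParams}.
#' @param temperature grid in degrees C within 0-110 (default 25-90 at
#'   0.5 degC steps, the acquisition ramp of a typical UV melting run).
#' @param noiseSd standard deviation of additive Gaussian absorbance noise
#'   (0 = noise-free).
#' @param seed optional RNG seed for the noise, making traces reproducible
#'   without touching the caller's RNG state.
#' @return a \linkS4class{MeltingCurve}.
#' @examples
#' cv <- simulateMeltingCurve(TwoStateParams(70, 200))
#' estimateTmInflection(cv)
#' @export
simulateMeltingCurve <- function(params, temperature = seq(25, 90, by = 0.5),
                                 noiseSd = 0, seed = NULL) {
  stopifnot(is(params, "TwoStateParams"))
  if (any(temperature < 0 | temperature > 110)) {
    stop("temperature grid must lie within 0-110 degC")
  }
  f <- unfoldedFraction(params, temperature)
  bf <- params@baselineFolded[1] + params@baselineFolded[2] * temperature
  bu <- params@baselineUnfolded[1] + params@baselineUnfolded[2] * temperature
  y <- bf * (1 - f) + bu * f
  if (noiseSd > 0) {
    noise <- if (is.null(seed)) rnorm(length(y), 0, noiseSd)
             else .withSeed(seed, rnorm(length(y), 0, noiseSd))
    y <- y + noise
  }
  MeltingCurve(temperature, y)
}

# Smoothed van't Hoff derivative: dA/d(-1/T_K) = dA/dT * T_K^2, the
# coordinate in which a two-state transition is symmetric about Tm, so its
# maximum falls exactly at the midpoint rather than ~RT^2/dH below it.
.vhDerivative <- function(y, temp, step, smoothWindow, smoothDegree) {
  n <- length(y)
  win <- min(as.integer(smoothWindow), if (n %% 2L == 0L) n - 1L else n)
  if (win %% 2L == 0L) win <- win - 1L
  dy <- signal::sgolayfilt(y, p = smoothDegree, n = win, m = 1, ts = step)
  list(vh = dy * (temp + 273.15)^2, win = win)
}

# Interior argmax of the derivative trace, refined by a quadratic fit over
# the upper part of the peak in the 1/T coordinate, where a two-state
# transition peak is exactly symmetric about 1/Tm: the vertex is then the
# midpoint, and averaging over the peak region makes it stable under noise.
# Localization uses an extra smoothing pass so the argmax does not jump to
# noise bumps.
.derivPeak <- function(vh, temp, step, win) {
  n <- length(vh)
  locWin <- min(21L, if (n %% 2L == 0L) n - 1L else n)
  if (locWin %% 2L == 0L) locWin <- locWin - 1L
  loc <- if (locWin >= 5L) signal::sgolayfilt(vh, p = 2, n = locWin) else vh
  edge <- max(2L, min(win, n %/% 3L))   # ignore filter edge artifacts
  inner <- seq.int(edge, n + 1L - edge)
  i <- inner[which.max(loc[inner])]
  if (vh[i] <= 0 || loc[i] <= 0) {
    .stopWithClass("tRNAcp_no_transition",
                   "no positive absorbance slope: no melting transition")
  }
  if (i <= edge || i >= n + 1L - edge) {
    .stopWithClass("tRNAcp_no_transition",
                   "derivative maximum on the grid edge: transition not spanned")
  }
  thr <- 0.70 * loc[i]
  lo <- i
  while (lo > 1L && loc[lo - 1L] >= thr) lo <- lo - 1L
  hi <- i
  while (hi < n && loc[hi + 1L] >= thr) hi <- hi + 1L
  idx <- lo:hi
  tm <- if (length(idx) >= 5L) {
    x <- 1 / (temp[idx] + 273.15) - 1 / (temp[i] + 273.15)
    fit <- coef(lm(vh[idx] ~ x + I(x^2)))
    if (is.na(fit[3]) || fit[3] >= 0) temp[i]
    else {
      vertex <- -fit[2] / (2 * fit[3])
      lim <- diff(range(x))
      vertex <- max(min(vertex, lim), -lim)
      1 / (vertex + 1 / (temp[i] + 273.15)) - 273.15
    }
  } else {
    dm <- vh[max(i - 1L, 1L)]; d0 <- vh[i]; dp <- vh[min(i + 1L, n)]
    denom <- dm - 2 * d0 + dp
    off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (dm - dp) / denom
    temp[i] + max(min(off, 1), -1) * step
  }
  list(index = i, tm = unname(tm))
}

#' Inflection-point Tm estimation
#'
#' Tm is the temperature of the maximum first derivative of the melting
#' trace. The trace is smoothed with a Savitzky-Golay filter and its first
#' derivative is taken against inverse absolute temperature (equivalently,
#' dA/dT scaled by T_K^2): in that coordinate a two-state transition is
#' symmetric about its midpoint, so the derivative maximum sits exactly at
#' Tm instead of slightly below it. The grid maximum is refined by
#' quadratic interpolation of the three surrounding derivative values.
#'
#' With \code{baselineCorrect = TRUE} (default) linear pre- and
#' post-transition baselines are fitted first and their midline is
#' subtracted, which removes the bias sloped baselines would impose on the
#' derivative maximum. The fit windows are placed transition-aware: a first
#' derivative pass locates the transition and its half-width, and baseline
#' points are taken at least two half-widths away from the midpoint
#' (falling back to the outer 15% of points on the folded side; if the
#' unfolded plateau is not reached within the grid, only the folded
#' baseline is subtracted and the baselines are assumed parallel). The
#' estimate is invariant to affine rescaling of the absorbance.
#'
#' @param curve a \linkS4class{MeltingCurve} with at least 20 samples
#'   spanning the transition and grid spacing at most 1 degC.
#' @param smoothWindow odd Savitzky-Golay window length (points).
#' @param smoothDegree polynomial degree of the filter.
#' @param baselineCorrect logical; subtract fitted linear baselines first.
#' @return Tm in degrees C. A curve with no transition (flat or with the
#'   derivative maximum on the grid edge) raises a condition of class
#'   \code{tRNAcp_no_transition}.
#' @export
estimateTmInflection <- function(curve, smoothWindow = 11L, smoothDegree = 3L,
                                 baselineCorrect = TRUE) {
  stopifnot(is(curve, "MeltingCurve"))
  temp <- curve@temperature
  y <- curve@absorbance
  n <- length(y)
  if (n < 20L) stop("need at least 20 samples spanning the transition")
  dT <- diff(temp)
  if (max(dT) > 1 + 1e-9) stop("grid spacing must be <= 1 degC")
  if (diff(range(y)) == 0) {
    .stopWithClass("tRNAcp_no_transition", "flat curve: no melting transition")
  }
  amp <- diff(range(y))
  y <- (y - min(y)) / amp               # affine-invariant working scale
  step <- mean(dT)
  d0 <- .vhDerivative(y, temp, step, smoothWindow, smoothDegree)
  peak0 <- .derivPeak(d0$vh, temp, step, d0$win)
  if (!baselineCorrect) return(peak0$tm)
  # Provisional two-state transition from the derivative peak itself: on the
  # unit-amplitude scale the van't Hoff derivative maximum equals c/4 with
  # c = dH/R, so c and the midpoint are read off the first pass. Subtracting
  # this provisional sigmoid exposes the baseline trend, which is then
  # fitted as a single line over all points (equivalent to the midline of
  # the two baselines, whose residual slope error cancels at the midpoint
  # to first order). With flat baselines the fitted trend is ~zero and the
  # correction is benign even when the transition spans the whole grid.
  tK <- temp + 273.15
  cHat <- 4 * d0$vh[peak0$index]
  fHat <- 1 / (1 + exp(cHat * (1 / tK - 1 / (peak0$tm + 273.15))))
  resid <- y - fHat                     # ~ folded baseline below the
  foldIdx <- which(fHat < 0.25)         # transition, ~ unfolded - span above
  unfIdx <- which(fHat > 0.75)
  base <- if (length(foldIdx) >= 5L && length(unfIdx) >= 5L) {
    bLo <- coef(lm(resid[foldIdx] ~ temp[foldIdx]))
    bHi <- coef(lm(resid[unfIdx] ~ temp[unfIdx]))
    # midline of the two baselines: its residual slope error cancels at the
    # midpoint to first order
    (bLo[1] + bHi[1]) / 2 + (bLo[2] + bHi[2]) / 2 * temp
  } else {
    trend <- coef(lm(resid ~ temp))
    trend[1] + trend[2] * temp
  }
  d1 <- .vhDerivative(y - base, temp, step, smoothWindow, smoothDegree)
  .derivPeak(d1$vh, temp, step, d1$win)$tm
}

#' Tm difference between two constructs
#'
#' @param curveModified,curveUnmodified \linkS4class{MeltingCurve}s for the
#'   modified and unmodified constructs.
#' @param ... passed to [estimateTmInflection()].
#' @return Tm(modified) - Tm(unmodified), degrees C.
#' @export
deltaTm <- function(curveModified, curveUnmodified, ...) {
  estimateTmInflection(curveModified, ...) -
    estimateTmInflection(curveUnmodified, ...)
}
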