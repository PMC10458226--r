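# Peak detection, Lorentzian line fitting and subtraction of interfering
# atomic emission from simultaneous-mode Raman spectra.

spectrum_parts <- function(spectrum) {
  if (inherits(spectrum, "spectrum")) {
    list(x = spectrum$axis$values, y = spectrum$intensities)
  } else {
    stop_data("expected a spectrum object")
  }
}

# prominence of a local maximum: height above the higher of the two valley
# minima separating it from the nearest higher ground on each side
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i
  while (j > 1) {
    j <- j - 1
    if (y[j] < left_min) left_min <- y[j]
    if (y[j] > y[i]) break
  }
  if (j == 1 && y[1] <= y[i]) left_min <- min(left_min, min(y[1:i]))
  right_min <- y[i]
  j <- i
  while (j < n) {
    j <- j + 1
    if (y[j] < right_min) right_min <- y[j]
    if (y[j] > y[i]) break
  }
  y[i] - max(left_min, right_min)
}

#' Detect peaks in a spectrum
#'
#' Local maxima whose prominence is at least `min_prominence` times the
#' maximum intensity, with sub-channel refinement of each center by a
#' 3-point parabolic interpolation (the channel quantization of a 0.33 nm
#' grid would otherwise dominate line-position estimates).
#'
#' @param spectrum a [new_spectrum()].
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   intensity. Default 0.05.
#' @return numeric vector of peak centers (axis units), sorted ascending.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05) {
  sp <- spectrum_parts(spectrum)
  x <- sp$x; y <- sp$y
  if (length(y) < 3) stop_data("spectrum too short for peak detection")
  if (diff(range(y)) == 0) return(numeric(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  thr <- min_prominence * max(y)
  centers <- c()
  for (i in cand) {
    if (peak_prominence(y, i) < thr) next
    # parabolic refinement through (i-1, i, i+1)
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom != 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    step <- if (delta >= 0) x[min(i + 1, length(x))] - x[i] else x[i] - x[i - 1]
    centers <- c(centers, x[i] + delta * step)
  }
  sort(centers)
}

#' Fit a Lorentzian line in a window
#'
#' Nonlinear least-squares fit of a Lorentzian (center, FWHM, amplitude)
#' plus a constant local background over a narrow axis window,
#' initialized from [detect_peaks()]. Used to model atomic emission lines,
#' e.g. the Na 588.9 nm line before subtracting it from simultaneous-mode
#' Raman spectra.
#'
#' @param spectrum a [new_spectrum()].
#' @param window numeric `c(lo, hi)` axis interval containing one peak and
#'   at least 7 channels.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return an object of class `fitted_line` with the fitted `model`
#'   ([peak_model()]), the constant `background`, the `window`, and
#'   `residual_rms`.
#' @export
fit_lorentzian <- function(spectrum, window, max_iter = 200) {
  sp <- spectrum_parts(spectrum)
  sel <- sp$x >= window[1] & sp$x <= window[2]
  if (sum(sel) < 7) stop_data("window must contain at least 7 channels")
  x <- sp$x[sel]; y <- sp$y[sel]
  win_spec <- new_spectrum(spectral_axis(x, spectrum$axis$kind,
                                         spectrum$axis$excitation_nm %||% 532),
                           y, spectrum$modality)
  centers <- detect_peaks(win_spec, min_prominence = 0.05)
  if (length(centers) == 0) stop_data("no peak in window")
  # initialize at the most central detected peak
  c0 <- centers[which.min(abs(centers - mean(window)))]
  b0 <- min(y)
  a0 <- max(y) - b0
  # FWHM guess from half-maximum crossings
  above <- x[y - b0 >= a0 / 2]
  w0 <- max(diff(range(above)), 2 * stats::median(diff(x)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * (w / 2)^2 / ((x - cc)^2 + (w / 2)^2),
      start = list(b = b0, a = a0, w = w0, cc = c0),
      lower = c(b = -Inf, a = 0, w = 1e-6 * w0, cc = window[1]),
      upper = c(b = Inf, a = Inf, w = Inf, cc = window[2]),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) stop_data("Lorentzian fit failed: %s", conditionMessage(e))
  )
  est <- coef(fit)
  structure(list(
    model = peak_model(unname(est["cc"]), unname(est["w"]), unname(est["a"]),
                       "lorentzian"),
    background = unname(est["b"]),
    window = window,
    residual_rms = sqrt(mean(stats::resid(fit)^2)),
    converged = fit$convInfo$isConv %||% TRUE
  ), class = "fitted_line")
}

#' @export
print.fitted_line <- function(x, ...) {
  cat(sprintf("<fitted_line> center %.4g, fwhm %.4g, amplitude %.4g, residual RMS %.3g\n",
              x$model$center, x$model$fwhm, x$model$amplitude, x$residual_rms))
  invisible(x)
}

#' Subtract a fitted emission line from a spectrum
#'
#' Subtracts the evaluated Lorentzian (not the constant background term)
#' inside the fitted window, clipping the result at zero; channels outside
#' the window are untouched. Subtraction is done in raw intensity space,
#' where the line model is additive, i.e. before the preprocessing chain.
#'
#' @param spectrum a [new_spectrum()] on the same axis the line was fitted
#'   on (or, for a shift-axis spectrum, the nm-fitted line is mapped
#'   through the excitation wavelength).
#' @param line a `fitted_line` from [fit_lorentzian()].
#' @return the spectrum with the line removed.
#' @export
subtract_line <- function(spectrum, line) {
  stopifnot(inherits(line, "fitted_line"))
  sp <- spectrum_parts(spectrum)
  x <- sp$x
  if (spectrum$axis$kind == "raman_shift_cm1" && line$window[2] < min(x)) {
    # line fitted in wavelength space; evaluate it at the channels'
    # wavelength positions
    x <- shift_to_wavelength(x, spectrum$axis$excitation_nm)
  }
  sel <- x >= line$window[1] & x <= line$window[2]
  if (!any(sel) &&
      (line$model$center < min(x) || line$model$center > max(x))) {
    stop_data("fitted line window does not intersect the spectrum axis; axis mismatch?")
  }
  y <- sp$y
  y[sel] <- pmax(y[sel] - eval_peak(line$model, x[sel]), 0)
  out <- spectrum
  out$intensities <- y
  out
}
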