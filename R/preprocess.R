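# Conditioning chain: baseline elimination (Raman), denoising,
# normalization, and a variance-stabilizing transform, in that order.

as_intensity_matrix <- function(x) {
  if (inherits(x, "spectrum")) {
    matrix(x$intensities, nrow = 1)
  } else if (inherits(x, "spectral_dataset")) {
    x$matrix
  } else if (is.matrix(x)) {
    x
  } else {
    matrix(as.numeric(x), nrow = 1)
  }
}

rewrap_like <- function(x, mat) {
  if (inherits(x, "spectrum")) {
    out <- x
    out$intensities <- drop(mat)
    out
  } else if (inherits(x, "spectral_dataset")) {
    out <- x
    out$matrix <- mat
    out
  } else if (is.matrix(x)) {
    mat
  } else {
    drop(mat)
  }
}

#' Asymmetric least squares baseline estimation
#'
#' Estimates the smooth background under a spectrum by iteratively
#' reweighted penalized least squares (Whittaker smoother with a
#' second-difference penalty): points above the current baseline get the
#' small weight `asymmetry`, points below get `1 - asymmetry`, so the fit
#' hugs the lower envelope while peaks are ignored. Used for the Raman
#' fluorescence background; LIBS spectra get a constant-offset subtraction
#' instead (see [preprocess_spectra()]).
#'
#' @param x a numeric vector, matrix (spectra in rows), [new_spectrum()] or
#'   [spectral_dataset()]. At least 10 channels.
#' @param smoothness penalty weight on the squared second differences
#'   (larger = stiffer baseline). Default `1e5`.
#' @param asymmetry weight given to points above the baseline, in (0, 1).
#'   Default 0.01.
#' @param iters number of reweighting iterations. Default 10.
#' @return the estimated baseline, same shape as the input intensities.
#' @export
estimate_baseline <- function(x, smoothness = 1e5, asymmetry = 0.01,
                              iters = 10) {
  mat <- as_intensity_matrix(x)
  if (any(!is.finite(mat))) stop_data("non-finite intensities")
  if (ncol(mat) < 10) stop_data("baseline estimation needs >= 10 channels")
  if (!(asymmetry > 0 && asymmetry < 1)) {
    stop_data("asymmetry must lie strictly in (0, 1)")
  }
  if (smoothness <= 0) stop_data("smoothness must be positive")
  z <- .als_baseline_cpp(mat, smoothness, asymmetry, as.integer(iters))
  if (is.matrix(x)) z else drop(z)
}

#' Savitzky-Golay denoising
#'
#' Least-squares local polynomial smoothing: polynomial inputs of degree
#' `<= order` pass through unchanged, white noise is attenuated.
#'
#' @param x numeric vector, matrix (rows = spectra), [new_spectrum()] or
#'   [spectral_dataset()].
#' @param window odd filter length, `> order` and `<=` number of channels.
#' @param order polynomial order.
#' @return smoothed object of the same shape/class.
#' @export
denoise <- function(x, window = 11, order = 3) {
  mat <- as_intensity_matrix(x)
  if (window %% 2 == 0) stop_data("window must be odd")
  if (window <= order) stop_data("window must exceed the polynomial order")
  if (window > ncol(mat)) stop_data("window exceeds the number of channels")
  sm <- t(apply(mat, 1, function(row) {
    signal::sgolayfilt(row, p = order, n = window)
  }))
  if (nrow(mat) == 1) sm <- matrix(sm, nrow = 1)
  rewrap_like(x, sm)
}

#' Total-intensity normalization
#'
#' Scales each spectrum so its intensities sum to one, removing the global
#' multiplicative shot-to-shot (plasma/laser power) factor. Invariant under
#' positive rescaling of the input.
#'
#' @param x numeric vector, matrix (rows = spectra), [new_spectrum()] or
#'   [spectral_dataset()].
#' @return normalized object of the same shape/class.
#' @export
normalize_spectrum <- function(x) {
  mat <- as_intensity_matrix(x)
  tot <- rowSums(mat)
  pos <- apply(mat > 0, 1, any)
  if (any(!pos | tot <= 0)) {
    stop_data("normalization needs at least one strictly positive intensity and a positive total (row %d violates this)",
              which(!pos | tot <= 0)[1])
  }
  rewrap_like(x, mat / tot)
}

#' Variance-stabilizing transform
#'
#' Channel-wise square root by default (monotone, order-preserving per
#' channel), further damping residual multiplicative fluctuation after
#' normalization. Negative residuals (possible after baseline subtraction)
#' are clipped to zero with a warning before the square root. `"identity"`
#' and `"log1p"` are available as alternatives.
#'
#' @param x numeric vector, matrix (rows = spectra), [new_spectrum()] or
#'   [spectral_dataset()].
#' @param method `"sqrt"` (default), `"identity"` or `"log1p"`.
#' @return transformed object of the same shape/class.
#' @export
transform_spectrum <- function(x, method = c("sqrt", "identity", "log1p")) {
  method <- match.arg(method)
  mat <- as_intensity_matrix(x)
  if (method == "identity") return(rewrap_like(x, mat))
  if (any(mat < 0)) {
    warning(sprintf("%d negative intensities clipped to zero before '%s' transform",
                    sum(mat < 0), method))
    mat[mat < 0] <- 0
  }
  mat <- if (method == "sqrt") sqrt(mat) else log1p(mat)
  rewrap_like(x, mat)
}

#' Full preprocessing chain
#'
#' Applies, in order: baseline elimination (asymmetric least squares for
#' Raman; per-spectrum minimum subtraction for LIBS), Savitzky-Golay
#' denoising, total-intensity normalization, and the variance-stabilizing
#' transform. Each step can be skipped.
#'
#' @param x a [new_spectrum()] or [spectral_dataset()] (modality is taken
#'   from the object), or a numeric vector/matrix with `modality` given.
#' @param modality `"raman"` or `"libs"`; only needed for bare
#'   vectors/matrices.
#' @param baseline_smoothness,baseline_asymmetry ALS parameters
#'   (see [estimate_baseline()]).
#' @param sg_window,sg_order Savitzky-Golay parameters (see [denoise()]).
#' @param transform transform method (see [transform_spectrum()]).
#' @param skip character vector among
#'   `c("baseline", "denoise", "normalize", "transform")`.
#' @return preprocessed object of the same class as `x`.
#' @export
preprocess_spectra <- function(x, modality = NULL,
                               baseline_smoothness = 1e5,
                               baseline_asymmetry = 0.01,
                               sg_window = 11, sg_order = 3,
                               transform = "sqrt", skip = character()) {
  if (is.null(modality)) {
    modality <- if (inherits(x, c("spectrum", "spectral_dataset"))) {
      x$modality
    } else {
      stop_data("modality must be given for bare vectors/matrices")
    }
  }
  out <- x
  if (!"baseline" %in% skip) {
    mat <- as_intensity_matrix(out)
    if (modality == "raman") {
      bl <- estimate_baseline(mat, baseline_smoothness, baseline_asymmetry)
      mat <- mat - bl
    } else {
      mat <- sweep(mat, 1, apply(mat, 1, min), `-`)
    }
    out <- rewrap_like(out, mat)
  }
  if (!"denoise" %in% skip) out <- denoise(out, sg_window, sg_order)
  if (!"normalize" %in% skip) {
    # negative residuals left by baseline subtraction carry no signal;
    # clip before normalizing so totals stay positive and comparable
    mat <- as_intensity_matrix(out)
    mat[mat < 0] <- 0
    out <- normalize_spectrum(rewrap_like(out, mat))
  }
  if (!"transform" %in% skip) {
    out <- suppressWarnings(transform_spectrum(out, transform))
  }
  out
}
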