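#' Spectral axis
#'
#' A spectral axis is either an absolute wavelength grid (nm) or a Raman
#' shift grid (cm^-1) relative to a fixed excitation line. Values must be
#' finite and strictly increasing; Raman shifts must be non-negative.
#' Vacuum-wavelength convention is used throughout: no air refractive-index
#' correction is applied (a sub-0.02% effect, negligible at the 0.33 nm
#' resolution of the compact spectrometer the package targets).
#'
#' @param values numeric vector, strictly increasing and finite.
#' @param kind `"wavelength_nm"` or `"raman_shift_cm1"`.
#' @param excitation_nm excitation laser wavelength in nm; required (and
#'   only meaningful) for shift axes. Default 532 (a common DPSS/CW line).
#' @return an object of class `spectral_axis` with fields `kind`, `values`
#'   and `excitation_nm`.
#' @examples
#' ax <- raman_axis()
#' range(ax$values)  # 750 .. 2800 cm^-1
#' @export
spectral_axis <- function(values, kind = c("wavelength_nm", "raman_shift_cm1"),
                          excitation_nm = 532) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop_data("axis values must be finite and non-empty")
  }
  if (length(values) > 1L && any(diff(values) <= 0)) {
    stop_data("axis values must be strictly increasing")
  }
  if (kind == "raman_shift_cm1") {
    if (!is.finite(excitation_nm) || excitation_nm <= 0) {
      stop_data("excitation_nm must be a positive number for a shift axis")
    }
    if (any(values < 0)) stop_data("Raman shift values must be non-negative")
  } else {
    excitation_nm <- NA_real_
    if (any(values <= 0)) stop_data("wavelengths must be positive")
  }
  structure(list(kind = kind, values = values, excitation_nm = excitation_nm),
            class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  unit <- if (x$kind == "wavelength_nm") "nm" else "cm^-1"
  cat(sprintf("<spectral_axis> %s, %d channels, %.1f-%.1f %s",
              x$kind, length(x$values), min(x$values), max(x$values), unit))
  if (!is.na(x$excitation_nm)) cat(sprintf(", excitation %g nm", x$excitation_nm))
  cat("\n")
  invisible(x)
}

#' Instrument-native axes
#'
#' The compact spectrometer registers LIBS on a uniform 2000-channel
#' wavelength grid over 350-625 nm and Raman on a uniform 600-channel shift
#' grid over 750-2800 cm^-1 (about 555-625 nm at 532 nm excitation).
#'
#' @param n_channels number of uniformly spaced channels.
#' @param range_nm,range_cm1 axis endpoints.
#' @param excitation_nm excitation wavelength for the Raman axis.
#' @return a [spectral_axis()].
#' @export
libs_axis <- function(n_channels = 2000, range_nm = c(350, 625)) {
  spectral_axis(seq(range_nm[1], range_nm[2], length.out = n_channels),
                "wavelength_nm")
}

#' @rdname libs_axis
#' @export
raman_axis <- function(n_channels = 600, range_cm1 = c(750, 2800),
                       excitation_nm = 532) {
  spectral_axis(seq(range_cm1[1], range_cm1[2], length.out = n_channels),
                "raman_shift_cm1", excitation_nm = excitation_nm)
}

#' Convert between wavelength and Raman shift
#'
#' Stokes-side conversion relative to an excitation line at
#' `excitation_nm`: `shift = 1e7 * (1/excitation_nm - 1/lambda_nm)` with
#' wavelengths in nm and shifts in cm^-1. `shift_to_wavelength()` is the
#' exact inverse. Both are vectorized and strictly increasing.
#'
#' @param lambda_nm scattered wavelength(s) in nm, `>= excitation_nm`.
#' @param shift_cm1 Raman shift(s) in cm^-1, `>= 0` and
#'   `< 1e7 / excitation_nm`.
#' @param excitation_nm excitation wavelength in nm.
#' @return numeric vector of shifts (cm^-1) or wavelengths (nm).
#' @examples
#' wavelength_to_shift(588.9, 532)   # sodium D line near 1816 cm^-1
#' shift_to_wavelength(2800, 532)    # red edge of the Raman range, ~625 nm
#' @export
wavelength_to_shift <- function(lambda_nm, excitation_nm = 532) {
  check_excitation(excitation_nm)
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop_data("lambda_nm must be finite and positive")
  }
  bad <- lambda_nm < excitation_nm
  if (any(bad)) {
    stop_data("anti-Stokes wavelength %.6g nm is below the excitation line (%g nm)",
              lambda_nm[which(bad)[1]], excitation_nm)
  }
  1e7 * (1 / excitation_nm - 1 / lambda_nm)
}

#' @rdname wavelength_to_shift
#' @export
shift_to_wavelength <- function(shift_cm1, excitation_nm = 532) {
  check_excitation(excitation_nm)
  if (any(!is.finite(shift_cm1)) || any(shift_cm1 < 0)) {
    stop_data("shift_cm1 must be finite and non-negative")
  }
  bad <- shift_cm1 >= 1e7 / excitation_nm
  if (any(bad)) {
    stop_data("shift %.6g cm^-1 is at or beyond the 1e7/excitation_nm pole",
              shift_cm1[which(bad)[1]])
  }
  1 / (1 / excitation_nm - shift_cm1 / 1e7)
}

check_excitation <- function(excitation_nm) {
  if (length(excitation_nm) != 1L || !is.finite(excitation_nm) ||
      excitation_nm <= 0) {
    stop_data("excitation_nm must be a single positive number")
  }
  invisible(excitation_nm)
}

#' Wavelength overlap of a LIBS axis and a Raman axis
#'
#' Maps the Raman shift span onto absolute wavelength via its excitation
#' line and intersects it with the LIBS wavelength span. In simultaneous
#' acquisition this is the region where plasma emission lines can
#' contaminate the Raman spectrum.
#'
#' @param libs_axis a wavelength-kind [spectral_axis()].
#' @param raman_axis a shift-kind [spectral_axis()] with excitation set.
#' @return named numeric vector `c(lo, hi)` in nm; both `NA` when the spans
#'   do not intersect (an empty overlap is signalled, not an error).
#' @examples
#' overlap_interval(libs_axis(), raman_axis())  # ~554.1 .. 625 nm
#' @export
overlap_interval <- function(libs_axis, raman_axis) {
  if (!inherits(libs_axis, "spectral_axis") ||
      libs_axis$kind != "wavelength_nm") {
    stop_data("libs_axis must be a wavelength-kind spectral_axis")
  }
  if (!inherits(raman_axis, "spectral_axis") ||
      raman_axis$kind != "raman_shift_cm1" || is.na(raman_axis$excitation_nm)) {
    stop_data("raman_axis must be a shift-kind spectral_axis with excitation set")
  }
  raman_nm <- shift_to_wavelength(range(raman_axis$values),
                                  raman_axis$excitation_nm)
  lo <- max(min(libs_axis$values), raman_nm[1])
  hi <- min(max(libs_axis$values), raman_nm[2])
  if (lo > hi) return(c(lo = NA_real_, hi = NA_real_))
  c(lo = lo, hi = hi)
}
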