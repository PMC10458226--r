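#' Single spectrum container
#'
#' One acquisition: an axis, one intensity per channel, the modality it was
#' recorded with, and an optional class label plus free-form metadata
#' (spot, specimen, session, ...).
#'
#' @param axis a [spectral_axis()].
#' @param intensities numeric vector, one finite value per axis channel.
#' @param modality `"raman"`, `"libs"` or `"hybrid"`.
#' @param label optional class label (character scalar or `NA`).
#' @param meta named list of metadata.
#' @return an object of class `spectrum`.
#' @export
new_spectrum <- function(axis, intensities,
                         modality = c("raman", "libs", "hybrid"),
                         label = NA_character_, meta = list()) {
  modality <- match.arg(modality)
  if (!inherits(axis, "spectral_axis")) stop_data("axis must be a spectral_axis")
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis$values)) {
    stop_data("intensities length (%d) must match axis length (%d)",
              length(intensities), length(axis$values))
  }
  if (any(!is.finite(intensities))) stop_data("intensities must be finite")
  structure(list(axis = axis, intensities = intensities, modality = modality,
                 label = label, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d channels", x$modality,
              length(x$intensities)))
  if (!is.na(x$label)) cat(sprintf(", label '%s'", x$label))
  cat("\n")
  print(x$axis)
  invisible(x)
}

#' Labelled spectral dataset
#'
#' A matrix of spectra (rows = samples, columns = channels) with a shared
#' axis, class labels and modality. Hybrid (fused) datasets carry a
#' `channel_map` recording each column's origin modality and native
#' coordinate instead of a single axis.
#'
#' @param matrix numeric matrix, samples in rows.
#' @param axis a [spectral_axis()] (single-modality) or a list with
#'   elements `libs` and `raman` (hybrid).
#' @param labels class labels, one per row (coerced to factor).
#' @param modality `"raman"`, `"libs"` or `"hybrid"`.
#' @param channel_map for hybrid data, a data.frame with columns `modality`
#'   and `coordinate`, one row per matrix column.
#' @param meta optional per-sample data.frame (e.g. specimen ids).
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(matrix, axis, labels,
                             modality = c("raman", "libs", "hybrid"),
                             channel_map = NULL, meta = NULL) {
  modality <- match.arg(modality)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != length(labels)) {
    stop_data("row count (%d) must equal label count (%d)",
              nrow(matrix), length(labels))
  }
  if (nrow(matrix) > 0 && any(!is.finite(matrix))) {
    stop_data("dataset contains missing or non-finite values")
  }
  if (modality == "hybrid") {
    if (is.null(channel_map) || nrow(channel_map) != ncol(matrix)) {
      stop_data("hybrid dataset needs a channel_map with one row per column")
    }
  } else {
    if (!inherits(axis, "spectral_axis")) stop_data("axis must be a spectral_axis")
    if (length(axis$values) != ncol(matrix)) {
      stop_data("axis length (%d) must match channel count (%d)",
                length(axis$values), ncol(matrix))
    }
  }
  structure(list(matrix = matrix, axis = axis,
                 labels = factor(labels), modality = modality,
                 channel_map = channel_map, meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %s: %d spectra x %d channels, %d classes\n",
              x$modality, nrow(x$matrix), ncol(x$matrix),
              nlevels(x$labels)))
  invisible(x)
}

#' Extract one spectrum from a dataset
#'
#' @param dataset a [spectral_dataset()] (single modality).
#' @param i row index.
#' @return a [new_spectrum()] object.
#' @export
dataset_spectrum <- function(dataset, i) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$modality == "hybrid") {
    stop_data("cannot extract a single-axis spectrum from a hybrid dataset")
  }
  new_spectrum(dataset$axis, dataset$matrix[i, ], dataset$modality,
               label = as.character(dataset$labels[i]))
}

#' Feature mask
#'
#' Indices of channels surviving a selection stage, with provenance.
#'
#' @param indices integer channel indices (1-based, unique, within range);
#'   stored sorted ascending.
#' @param provenance `"anova"`, `"enet"` or `"manual"`.
#' @param source_dims channel count of the parent matrix.
#' @return an object of class `feature_mask`.
#' @export
feature_mask <- function(indices, provenance = c("anova", "enet", "manual"),
                         source_dims) {
  provenance <- match.arg(provenance)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop_data("mask indices must be unique")
  if (length(indices) &&
      (min(indices) < 1L || max(indices) > source_dims)) {
    stop_data("mask indices must lie in [1, %d]", source_dims)
  }
  structure(list(indices = sort(indices), provenance = provenance,
                 source_dims = as.integer(source_dims)),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d / %d channels (%s)\n",
              length(x$indices), x$source_dims, x$provenance))
  invisible(x)
}
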