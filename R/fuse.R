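# Two fusion strategies for paired LIBS/Raman data:
#  - early fusion: full spectra combined into one hybrid vector before any
#    selection (one joint ANOVA + elastic-net stage afterwards);
#  - late fusion: each modality filtered and selected independently, the
#    selected features then concatenated.

check_paired <- function(a, b) {
  if (nrow(a$matrix) != nrow(b$matrix)) {
    stop_data("datasets have different numbers of spectra (%d vs %d)",
              nrow(a$matrix), nrow(b$matrix))
  }
  la <- as.character(a$labels); lb <- as.character(b$labels)
  bad <- which(la != lb)
  if (length(bad)) {
    stop_data("label mismatch at row %d ('%s' vs '%s'); rows must be paired specimens",
              bad[1], la[bad[1]], lb[bad[1]])
  }
  invisible(TRUE)
}

#' Early (spectrum-level) fusion
#'
#' Combines the paired LIBS and Raman matrices into one hybrid dataset of
#' width `n_libs_channels + n_raman_channels` (LIBS block first). The
#' composite channel map records each column's origin modality and native
#' coordinate. Rows remain paired; both inputs should already be
#' preprocessed (per-modality normalization keeps either block from
#' dominating by raw scale).
#'
#' @param libs,raman paired [spectral_dataset()]s with identical label
#'   sequences.
#' @param coadd_overlap additionally sum the Raman signal (interpolated to
#'   wavelength) onto the LIBS channels inside the spectral overlap
#'   interval before concatenating - the "coaddition" reading of early
#'   fusion. Off by default: plain co-assembly reproduces the documented
#'   fused channel counts; the coadded variant is provided for sensitivity
#'   analysis.
#' @return a hybrid [spectral_dataset()].
#' @examples
#' # 2000-channel LIBS + 600-channel Raman -> 2600-channel hybrid
#' @export
fuse_early <- function(libs, raman, coadd_overlap = FALSE) {
  stopifnot(inherits(libs, "spectral_dataset"),
            inherits(raman, "spectral_dataset"))
  check_paired(libs, raman)
  libs_mat <- libs$matrix
  if (coadd_overlap && ncol(libs_mat) && ncol(raman$matrix)) {
    ov <- overlap_interval(libs$axis, raman$axis)
    if (!any(is.na(ov))) {
      wl_l <- libs$axis$values
      wl_r <- shift_to_wavelength(raman$axis$values,
                                  raman$axis$excitation_nm)
      sel <- wl_l >= ov["lo"] & wl_l <= ov["hi"]
      for (i in seq_len(nrow(libs_mat))) {
        libs_mat[i, sel] <- libs_mat[i, sel] +
          stats::approx(wl_r, raman$matrix[i, ], xout = wl_l[sel],
                        rule = 2)$y
      }
    }
  }
  mat <- cbind(libs_mat, raman$matrix)
  cmap <- data.frame(
    modality = c(rep("libs", ncol(libs$matrix)),
                 rep("raman", ncol(raman$matrix))),
    coordinate = c(if (ncol(libs$matrix)) libs$axis$values else numeric(0),
                   if (ncol(raman$matrix)) raman$axis$values else numeric(0)),
    stringsAsFactors = FALSE
  )
  spectral_dataset(mat, list(libs = libs$axis, raman = raman$axis),
                   libs$labels, "hybrid", channel_map = cmap,
                   meta = libs$meta)
}

#' Late (feature-level) fusion
#'
#' Concatenates the mask-selected features of independently processed
#' modalities. The combined width equals the sum of the mask sizes, and the
#' combined channel map records `(modality, channel)` provenance for every
#' column.
#'
#' @param parts named list of per-modality `list(mask = , dataset = )`
#'   pairs, e.g. `list(libs = list(mask, dataset), raman = list(mask,
#'   dataset))`. Masks index into their own modality's channels.
#' @return list with the fused feature `matrix`, the per-column provenance
#'   `channel_map` (modality, channel index, native coordinate), and the
#'   shared `labels`.
#' @export
fuse_late <- function(parts) {
  if (length(parts) < 1) stop_data("fuse_late needs at least one modality")
  names(parts) <- names(parts) %||% vapply(parts, function(p) p$dataset$modality,
                                           character(1))
  ref <- parts[[1]]$dataset
  blocks <- list(); maps <- list()
  for (nm in names(parts)) {
    p <- parts[[nm]]
    mask <- p$mask; ds <- p$dataset
    stopifnot(inherits(mask, "feature_mask"),
              inherits(ds, "spectral_dataset"))
    check_paired(ref, ds)
    if (length(mask$indices) && max(mask$indices) > ncol(ds$matrix)) {
      stop_data("mask index %d out of range for '%s' (%d channels)",
                max(mask$indices), nm, ncol(ds$matrix))
    }
    blocks[[nm]] <- ds$matrix[, mask$indices, drop = FALSE]
    maps[[nm]] <- data.frame(
      modality = rep(nm, length(mask$indices)),
      channel = mask$indices,
      coordinate = if (inherits(ds$axis, "spectral_axis")) {
        ds$axis$values[mask$indices]
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  list(matrix = do.call(cbind, blocks),
       channel_map = do.call(rbind, c(maps, list(make.row.names = FALSE))),
       labels = ref$labels)
}
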