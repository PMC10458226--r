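# Readers/writers for spectral tables, run configuration, and the
# end-to-end pipeline orchestrator.

#' Write a spectral dataset to CSV
#'
#' Wide layout (the primary interchange format): metadata comment lines
#' (`# modality=`, `# axis=`, `# excitation_nm=`), then one row per
#' spectrum with a `label` column followed by one column per channel named
#' by its axis value.
#'
#' @param dataset a single-modality [spectral_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$modality == "hybrid") {
    stop_data("hybrid datasets are written per modality; split first")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality=%s", dataset$modality), con)
  writeLines(sprintf("# axis=%s", dataset$axis$kind), con)
  if (!is.na(dataset$axis$excitation_nm)) {
    writeLines(sprintf("# excitation_nm=%g", dataset$axis$excitation_nm), con)
  }
  df <- data.frame(label = as.character(dataset$labels),
                   dataset$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("label", format(dataset$axis$values, trim = TRUE,
                                    digits = 10))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_meta_comments <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  n_comment <- 0
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    n_comment <- n_comment + 1
    kv <- strsplit(sub("^#\\s*", "", line), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  list(meta = meta, skip = n_comment)
}

#' Read a spectral dataset from CSV
#'
#' @param path file written by [write_dataset()] (wide layout) or a long
#'   table with columns `sample_id, axis_value, intensity, label`.
#' @param layout `"wide"` or `"long"`.
#' @return a [spectral_dataset()].
#' @export
read_dataset <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_data("file not found: %s", path)
  hdr <- read_meta_comments(path)
  kind <- hdr$meta$axis %||% "wavelength_nm"
  modality <- hdr$meta$modality %||%
    if (kind == "raman_shift_cm1") "raman" else "libs"
  excitation <- as.numeric(hdr$meta$excitation_nm %||% 532)
  if (kind == "raman_shift_cm1" && is.na(excitation)) {
    stop_data("shift-axis file must declare excitation_nm")
  }
  df <- read.csv(path, skip = hdr$skip, check.names = FALSE)
  if (layout == "wide") {
    if (!"label" %in% colnames(df)) stop_data("missing 'label' column")
    mat <- as.matrix(df[, setdiff(colnames(df), "label"), drop = FALSE])
    storage.mode(mat) <- "double"
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_data("non-finite intensity at row %d, channel %d",
                bad[1, 1], bad[1, 2])
    }
    vals <- as.numeric(colnames(mat))
    if (any(is.na(vals))) stop_data("channel columns must be named by axis values")
    if (is.unsorted(vals, strictly = TRUE)) {
      warning("axis columns were not sorted; reordering")
      o <- order(vals)
      vals <- vals[o]
      mat <- mat[, o, drop = FALSE]
    }
    ax <- spectral_axis(vals, kind, excitation_nm = excitation)
    spectral_dataset(mat, ax, df$label, modality)
  } else {
    need <- c("sample_id", "axis_value", "intensity", "label")
    if (!all(need %in% colnames(df))) {
      stop_data("long layout needs columns: %s", paste(need, collapse = ", "))
    }
    if (any(!is.finite(df$intensity))) {
      stop_data("non-finite intensity at row %d", which(!is.finite(df$intensity))[1])
    }
    ids <- unique(df$sample_id)
    vals <- sort(unique(df$axis_value))
    mat <- matrix(NA_real_, length(ids), length(vals),
                  dimnames = list(ids, NULL))
    lab <- character(length(ids))
    for (i in seq_along(ids)) {
      sub <- df[df$sample_id == ids[i], ]
      mat[i, match(sub$axis_value, vals)] <- sub$intensity
      lab[i] <- as.character(sub$label[1])
    }
    if (any(is.na(mat))) stop_data("long table does not cover a full grid")
    ax <- spectral_axis(vals, kind, excitation_nm = excitation)
    spectral_dataset(mat, ax, lab, modality)
  }
}

#' Run configuration
#'
#' A complete, serializable description of a pipeline run. Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param family dataset family for the simulator.
#' @param sim named list of [sim_config()] overrides (e.g.
#'   `replicates_per_class`, `noise_sd`, `mode`, `seed`).
#' @param preprocess named list of [preprocess_spectra()] overrides.
#' @param inputs input settings to evaluate, subset of
#'   `c("raman", "libs", "fusion1", "fusion2")`.
#' @param classifiers subset of `c("enet", "svm")`.
#' @param select named list of [pipeline_config()] overrides (tuning grid,
#'   `keep_n`, ...).
#' @param k,sessions,seed_base cross-validation protocol; session seeds are
#'   `seed_base + 0:(sessions-1)`.
#' @param outdir optional output directory for summary tables, confusion
#'   matrices and the run manifest.
#' @return a list of class `run_config`.
#' @export
run_config <- function(family = "coffee7", sim = list(), preprocess = list(),
                       inputs = c("raman", "libs", "fusion1", "fusion2"),
                       classifiers = "enet", select = list(),
                       k = 10, sessions = 10, seed_base = 1,
                       outdir = NULL) {
  inputs <- match.arg(inputs, several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("enet", "svm"), several.ok = TRUE)
  if (sessions < 1) stop_data("sessions must be >= 1")
  if (k < 2) stop_data("k must be >= 2")
  structure(list(family = family, sim = sim, preprocess = preprocess,
                 inputs = inputs, classifiers = classifiers, select = select,
                 k = k, sessions = sessions, seed_base = seed_base,
                 outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full classification pipeline
#'
#' Simulate (or accept) paired LIBS/Raman data, preprocess each modality,
#' subtract the interfering Na plasma line from simultaneous-mode Raman
#' spectra, build the configured input settings (single modalities, late
#' fusion, early fusion), and evaluate each with repeated stratified
#' k-fold cross-validation. Optionally writes a summary table, per-session
#' confusion matrices, and a JSON manifest (config + seeds + package
#' version) from which the run can be reproduced exactly.
#'
#' @param config a [run_config()].
#' @param data optional list with preprocessed-ready `libs` and `raman`
#'   [spectral_dataset()]s; when omitted the simulator is used.
#' @return named list: one `cv_result` per (classifier, input) pair, plus
#'   `summary` (the method x setting table) and `manifest`.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) {
    sc <- do.call(sim_config, c(list(family = config$family), config$sim))
    data <- generate_dataset(sc)
  } else {
    sc <- NULL
  }
  message(sprintf("stage simulate/load: libs %d x %d, raman %d x %d",
                  nrow(data$libs$matrix), ncol(data$libs$matrix),
                  nrow(data$raman$matrix), ncol(data$raman$matrix)))
  raman_raw <- data$raman
  if (!is.null(sc) && sc$mode == "simultaneous") {
    raman_raw <- subtract_na_line(raman_raw)
    message("stage subtract-line: Na plasma line removed from Raman block")
  }
  pp <- function(ds) do.call(preprocess_spectra, c(list(ds), config$preprocess))
  libs <- pp(data$libs)
  raman <- pp(raman_raw)
  message("stage preprocess: done")
  hybrid <- fuse_early(libs, raman)
  message(sprintf("stage fuse: hybrid %d x %d", nrow(hybrid$matrix),
                  ncol(hybrid$matrix)))

  seeds <- config$seed_base + seq_len(config$sessions) - 1
  results <- list()
  for (cls in config$classifiers) {
    for (input in config$inputs) {
      pc <- do.call(pipeline_config,
                    c(list(classifier = cls,
                           fusion = if (input == "fusion1") "late" else "none"),
                      config$select))
      dat <- switch(input,
                    raman = raman, libs = libs, fusion2 = hybrid,
                    fusion1 = list(libs = libs, raman = raman))
      res <- repeated_cv(dat, pc, k = config$k, sessions = config$sessions,
                         seeds = seeds)
      results[[cls]][[input]] <- res
      message(sprintf("stage evaluate [%s/%s]: macro %.2f%% (SD %.2f)",
                      cls, input, 100 * res$mean_accuracy,
                      100 * res$sd_accuracy))
    }
  }
  tab <- cv_summary_table(results)
  manifest <- list(config = unclass(config), seeds = seeds,
                   package_version = as.character(packageVersion("ramlibs")))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(config$outdir, "summary.csv"), row.names = FALSE)
    for (cls in names(results)) {
      for (input in names(results[[cls]])) {
        r <- results[[cls]][[input]]
        for (s in seq_along(r$confusion)) {
          write.csv(as.data.frame.matrix(r$confusion[[s]]),
                    file.path(config$outdir,
                              sprintf("confusion_%s_%s_session%02d.csv",
                                      cls, input, s)))
        }
      }
    }
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(results, list(summary = tab, manifest = manifest))
}

# fit and subtract the Na 588.9 nm plasma line from every Raman spectrum of
# a simultaneous-mode dataset (raw intensity space, +-2 nm window)
subtract_na_line <- function(raman, center_nm = 588.9, half_window_nm = 2) {
  stopifnot(inherits(raman, "spectral_dataset"))
  exc <- raman$axis$excitation_nm
  win_nm <- c(center_nm - half_window_nm, center_nm + half_window_nm)
  wl <- shift_to_wavelength(raman$axis$values, exc)
  out <- raman
  for (i in seq_len(nrow(raman$matrix))) {
    sp <- dataset_spectrum(raman, i)
    sp_nm <- new_spectrum(spectral_axis(wl, "wavelength_nm"),
                          sp$intensities, "raman")
    line <- tryCatch(fit_lorentzian(sp_nm, win_nm), error = function(e) NULL)
    if (is.null(line)) next
    out$matrix[i, ] <- subtract_line(sp, line)$intensities
  }
  out
}
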