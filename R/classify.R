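# Final classifiers and the evaluation protocol: independent sessions of
# stratified k-fold cross-validation, every data-dependent step (ANOVA
# filter, elastic-net tuning/selection, classifier training) refit inside
# each training fold, fold predictions pooled into one confusion matrix per
# session, and mean/SD of the confusion diagonal across sessions.

#' Elastic-net classifier on selected features
#'
#' Thin wrapper around [enet_fit()]: in this pipeline the elastic-net model
#' is both the feature selector and the classifier (prediction = argmax of
#' the class scores).
#'
#' @param X numeric matrix of already mask-selected features.
#' @param y class labels.
#' @param alpha,lambda elastic-net parameters.
#' @param ... passed to [enet_fit()].
#' @return an `enet_fit`.
#' @export
train_enet_classifier <- function(X, y, alpha = 0.5, lambda, ...) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop_data("empty feature set")
  enet_fit(X, y, alpha = alpha, lambda = lambda, ...)
}

#' Linear SVM benchmark
#'
#' One-vs-one linear maximum-margin classifier (libsvm via e1071), the
#' conventional benchmark against which the elastic-net classifier is
#' compared. Deterministic given the data and cost.
#'
#' @param X numeric feature matrix.
#' @param y class labels (>= 2 classes).
#' @param C soft-margin cost.
#' @return an object of class `svm_benchmark` wrapping the e1071 fit, with
#'   the same `predict` interface as the elastic-net classifier.
#' @export
train_svm_benchmark <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_data("SVM benchmark needs at least 2 classes")
  if (ncol(X) == 0) stop_data("empty feature set")
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE)
  structure(list(fit = fit, levels = levels(y), C = C),
            class = "svm_benchmark")
}

#' @export
predict.svm_benchmark <- function(object, newx, ...) {
  factor(as.character(predict(object$fit, as.matrix(newx))),
         levels = object$levels)
}

#' Pipeline configuration for cross-validated evaluation
#'
#' @param keep_n ANOVA filter size (set `Inf` to skip the filter).
#' @param alpha_grid,nlambda,lambda_min_ratio elastic-net tuning grid.
#' @param inner_folds,inner_repeats stratified CV used for tuning inside
#'   each training fold.
#' @param inner_eval_folds folds actually evaluated per tuning repeat (see
#'   [enet_select()]'s `eval_folds`); `1` gives cheap holdout tuning.
#' @param classifier `"enet"` (the tuned elastic-net model itself) or
#'   `"svm"` (linear SVM on the elastic-net-selected features).
#' @param svm_cost_grid costs tuned by inner 5-fold CV when
#'   `classifier = "svm"`.
#' @param fusion `"none"` (input is one dataset/matrix) or `"late"` (input
#'   is a list of modalities, each filtered and selected independently, the
#'   selected features then concatenated before the final classifier).
#' @param thresh,maxit solver controls.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(keep_n = 200,
                            alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                            nlambda = 50, lambda_min_ratio = 1e-4,
                            inner_folds = 3, inner_repeats = 1,
                            inner_eval_folds = NULL,
                            classifier = c("enet", "svm"),
                            svm_cost_grid = c(0.1, 1, 10),
                            fusion = c("none", "late"),
                            thresh = 1e-6, maxit = 1e4) {
  structure(list(keep_n = keep_n, alpha_grid = alpha_grid, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 inner_folds = inner_folds, inner_repeats = inner_repeats,
                 inner_eval_folds = inner_eval_folds,
                 classifier = match.arg(classifier),
                 svm_cost_grid = svm_cost_grid, fusion = match.arg(fusion),
                 thresh = thresh, maxit = maxit),
            class = "pipeline_config")
}

# fit the in-fold pipeline on training data and predict the test rows;
# returns predictions plus the fitted masks (for leakage instrumentation)
fit_fold <- function(Xtr, ytr, Xte, config, fold_seed) {
  masks <- list()
  keep_n <- min(config$keep_n, ncol(Xtr))
  amask <- if (keep_n < ncol(Xtr)) {
    anova_filter(Xtr, ytr, keep_n)
  } else {
    feature_mask(seq_len(ncol(Xtr)), "manual", ncol(Xtr))
  }
  masks$anova <- amask
  Xa <- Xtr[, amask$indices, drop = FALSE]
  sel <- enet_select(Xa, ytr, alpha_grid = config$alpha_grid,
                     nlambda = config$nlambda,
                     lambda_min_ratio = config$lambda_min_ratio,
                     folds = config$inner_folds, repeats = config$inner_repeats,
                     eval_folds = config$inner_eval_folds,
                     seed = fold_seed, thresh = config$thresh,
                     maxit = config$maxit, allow_empty = TRUE)
  masks$enet <- sel$mask
  Xte_a <- Xte[, amask$indices, drop = FALSE]
  if (config$classifier == "enet" || length(sel$mask$indices) == 0) {
    # the tuned elastic-net model is itself the classifier; with an empty
    # active set it degrades to the intercept-only (prior) model
    pred <- predict(sel$fit, Xte_a, type = "class")
  } else {
    Xsel <- Xa[, sel$mask$indices, drop = FALSE]
    cost <- tune_svm_cost(Xsel, ytr, config$svm_cost_grid, fold_seed)
    svm <- train_svm_benchmark(Xsel, ytr, C = cost)
    pred <- predict(svm, Xte_a[, sel$mask$indices, drop = FALSE])
  }
  list(pred = pred, masks = masks)
}

tune_svm_cost <- function(X, y, cost_grid, seed, folds = 5) {
  if (length(cost_grid) == 1) return(cost_grid)
  folds <- min(folds, min(table(y)))
  if (folds < 2) return(cost_grid[1])
  acc <- numeric(length(cost_grid))
  with_seed(seed + 1L, {
    fold <- stratified_folds(y, folds)
    for (ci in seq_along(cost_grid)) {
      ok <- 0
      for (f in seq_len(folds)) {
        tr <- fold != f
        m <- train_svm_benchmark(X[tr, , drop = FALSE], y[tr], cost_grid[ci])
        ok <- ok + sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
      }
      acc[ci] <- ok
    }
  })
  cost_grid[which.max(acc)]
}

fit_fold_late <- function(parts_tr, ytr, parts_te, config, fold_seed) {
  masks <- list()
  sel_tr <- list(); sel_te <- list()
  for (nm in names(parts_tr)) {
    Xtr <- parts_tr[[nm]]
    keep_n <- min(config$keep_n, ncol(Xtr))
    amask <- if (keep_n < ncol(Xtr)) {
      anova_filter(Xtr, ytr, keep_n)
    } else {
      feature_mask(seq_len(ncol(Xtr)), "manual", ncol(Xtr))
    }
    Xa <- Xtr[, amask$indices, drop = FALSE]
    sel <- enet_select(Xa, ytr, alpha_grid = config$alpha_grid,
                       nlambda = config$nlambda,
                       lambda_min_ratio = config$lambda_min_ratio,
                       folds = config$inner_folds,
                       repeats = config$inner_repeats,
                       eval_folds = config$inner_eval_folds,
                       seed = fold_seed, thresh = config$thresh,
                       maxit = config$maxit, allow_empty = TRUE)
    masks[[nm]] <- list(anova = amask, enet = sel$mask)
    sel_tr[[nm]] <- Xa[, sel$mask$indices, drop = FALSE]
    sel_te[[nm]] <- parts_te[[nm]][, amask$indices, drop = FALSE][
      , sel$mask$indices, drop = FALSE]
  }
  Xtr2 <- do.call(cbind, sel_tr)
  Xte2 <- do.call(cbind, sel_te)
  if (ncol(Xtr2) == 0) {
    # nothing survived in any modality: prior-only prediction
    lev <- levels(ytr)
    maj <- lev[which.max(tabulate(ytr))]
    return(list(pred = factor(rep(maj, nrow(Xte2)), levels = lev),
                masks = masks))
  }
  if (config$classifier == "svm") {
    cost <- tune_svm_cost(Xtr2, ytr, config$svm_cost_grid, fold_seed)
    model <- train_svm_benchmark(Xtr2, ytr, C = cost)
    pred <- predict(model, Xte2)
  } else {
    # final classifier on the concatenated selected features: elastic-net
    # tuned once more (lightly) on the reduced feature set
    sel2 <- enet_select(Xtr2, ytr, alpha_grid = config$alpha_grid,
                        nlambda = config$nlambda,
                        lambda_min_ratio = config$lambda_min_ratio,
                        folds = config$inner_folds,
                        repeats = config$inner_repeats,
                        eval_folds = config$inner_eval_folds,
                        seed = fold_seed + 7L, thresh = config$thresh,
                        maxit = config$maxit, allow_empty = TRUE)
    pred <- predict(sel2$fit, Xte2, type = "class")
  }
  list(pred = pred, masks = masks)
}

#' Repeated cross-validated evaluation
#'
#' Runs `sessions` independent evaluation sessions. Each session draws
#' stratified k folds from its own seed; within every training fold the
#' whole data-dependent pipeline (ANOVA filter, elastic-net tuning and
#' selection, classifier training) is refit from scratch, so no selection
#' information leaks into the held-out fold. Fold predictions are pooled
#' into one confusion matrix per session; the summary reports the mean and
#' SD over the session-level macro accuracies (mean of the per-class
#' recalls, i.e. the normalized confusion diagonal).
#'
#' @param data a [spectral_dataset()] (single modality or hybrid), a
#'   numeric matrix with `labels`, or - for late fusion - a named list of
#'   paired datasets/matrices.
#' @param config a [pipeline_config()].
#' @param labels class labels; taken from `data` when it is a dataset.
#' @param k folds per session (default 10).
#' @param sessions number of independent sessions (default 10).
#' @param seeds one seed per session (default `1:sessions`).
#' @param folds optional list of precomputed fold assignments (one integer
#'   vector per session), overriding the seeded stratified draw; intended
#'   for instrumentation.
#' @param collect_masks store the per-fold fitted masks (diagnostics).
#' @return an object of class `cv_result`.
#' @export
repeated_cv <- function(data, config = pipeline_config(), labels = NULL,
                        k = 10, sessions = 10, seeds = NULL, folds = NULL,
                        collect_masks = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (sessions < 1) stop_data("sessions must be >= 1")
  late <- config$fusion == "late"
  if (late) {
    if (!is.list(data) || inherits(data, "spectral_dataset")) {
      stop_data("late fusion expects a named list of per-modality datasets")
    }
    parts <- lapply(data, function(d) {
      if (inherits(d, "spectral_dataset")) d$matrix else as.matrix(d)
    })
    if (is.null(labels)) {
      first <- data[[1]]
      labels <- if (inherits(first, "spectral_dataset")) first$labels else
        stop_data("labels must be supplied for bare matrices")
      for (d in data[-1]) {
        if (inherits(d, "spectral_dataset")) check_paired(data[[1]], d)
      }
    }
    X <- NULL
    n <- nrow(parts[[1]])
  } else {
    if (inherits(data, "spectral_dataset")) {
      X <- data$matrix
      if (is.null(labels)) labels <- data$labels
    } else {
      X <- as.matrix(data)
      if (is.null(labels)) stop_data("labels must be supplied for bare matrices")
    }
    n <- nrow(X)
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop_data("evaluation needs at least 2 classes")
  small <- names(which(table(y) < k))
  if (length(small)) {
    stop_data("class '%s' has fewer than k = %d members", small[1], k)
  }
  seeds <- seeds %||% seq_len(sessions)
  if (length(seeds) != sessions) stop_data("need one seed per session")
  if (anyDuplicated(seeds)) warning("duplicate session seeds")
  K <- nlevels(y)
  lev <- levels(y)
  confusions <- vector("list", sessions)
  per_class <- matrix(NA_real_, sessions, K, dimnames = list(NULL, lev))
  mask_log <- if (collect_masks) vector("list", sessions) else NULL

  for (s in seq_len(sessions)) {
    fold <- if (!is.null(folds)) {
      folds[[s]]
    } else {
      with_seed(seeds[s], stratified_folds(y, k))
    }
    fold_seeds <- with_seed(seeds[s], sample.int(.Machine$integer.max - 1, k))
    pred <- factor(rep(lev[1], n), levels = lev)
    smasks <- vector("list", k)
    for (f in seq_len(k)) {
      te <- fold == f
      res <- if (late) {
        fit_fold_late(lapply(parts, function(m) m[!te, , drop = FALSE]),
                      y[!te],
                      lapply(parts, function(m) m[te, , drop = FALSE]),
                      config, fold_seeds[f])
      } else {
        fit_fold(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                 config, fold_seeds[f])
      }
      pred[te] <- res$pred
      if (collect_masks) smasks[[f]] <- res$masks
    }
    cm <- table(truth = y, predicted = pred)
    confusions[[s]] <- cm
    per_class[s, ] <- diag(cm) / rowSums(cm)
    if (collect_masks) mask_log[[s]] <- smasks
  }
  macro <- rowMeans(per_class)
  micro <- vapply(confusions, function(cm) sum(diag(cm)) / sum(cm), numeric(1))
  structure(list(
    confusion = confusions,
    per_class_accuracy = per_class,
    macro_accuracy = macro,
    micro_accuracy = micro,
    mean_accuracy = mean(macro),
    sd_accuracy = stats::sd(macro),
    seeds = seeds, k = k, sessions = sessions,
    settings = config,
    masks = mask_log
  ), class = "cv_result")
}

#' Assemble a cv_result from per-session confusion matrices
#'
#' Mostly useful for tests and for summarizing externally computed
#' confusion matrices with the same conventions.
#'
#' @param confusions list of K x K confusion count matrices (truth in
#'   rows).
#' @param seeds,settings optional bookkeeping.
#' @return a `cv_result`.
#' @export
cv_result <- function(confusions, seeds = seq_along(confusions),
                      settings = NULL) {
  if (length(confusions) == 0) stop_data("empty session list")
  per_class <- t(vapply(confusions, function(cm) diag(cm) / rowSums(cm),
                        numeric(nrow(confusions[[1]]))))
  macro <- rowMeans(per_class)
  structure(list(
    confusion = confusions, per_class_accuracy = per_class,
    macro_accuracy = macro,
    micro_accuracy = vapply(confusions, function(cm) sum(diag(cm)) / sum(cm),
                            numeric(1)),
    mean_accuracy = mean(macro), sd_accuracy = stats::sd(macro),
    seeds = seeds, k = NA_integer_, sessions = length(confusions),
    settings = settings, masks = NULL
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d sessions, macro accuracy %.2f%% (SD %.2f)\n",
              x$sessions, 100 * x$mean_accuracy,
              100 * (x$sd_accuracy %||% NA_real_)))
  invisible(x)
}

#' Summarize a cross-validation result
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data.frame with macro and micro accuracy (percent), their
#'   across-session SDs, and the `"mean (SD)"` display string used in the
#'   report tables.
#' @export
summary.cv_result <- function(object, ...) {
  if (length(object$confusion) == 0) stop_data("empty result")
  macro <- 100 * object$macro_accuracy
  micro <- 100 * object$micro_accuracy
  data.frame(
    metric = c("macro", "micro"),
    mean_pct = c(mean(macro), mean(micro)),
    sd_pct = c(stats::sd(macro), stats::sd(micro)),
    display = c(sprintf("%.2f (%.2f)", mean(macro), stats::sd(macro)),
                sprintf("%.2f (%.2f)", mean(micro), stats::sd(micro))),
    stringsAsFactors = FALSE
  )
}

#' Tabulate several evaluation runs side by side
#'
#' Builds the method x input-setting summary table (mean (SD) percent of
#' the confusion diagonal) in the layout of the classification report
#' tables.
#'
#' @param results named list (input setting -> `cv_result`), or a named
#'   list of such lists (method -> setting -> result).
#' @return data.frame, one row per method, one column per input setting.
#' @export
cv_summary_table <- function(results) {
  if (inherits(results[[1]], "cv_result")) results <- list(result = results)
  rows <- lapply(names(results), function(m) {
    vals <- vapply(results[[m]], function(r) summary(r)$display[1], character(1))
    cbind(data.frame(method = m, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
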