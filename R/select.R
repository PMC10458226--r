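# Feature selection: univariate one-way ANOVA filtering and multivariate
# elastic-net multinomial logistic regression (selection and classification
# in one model).

get_xy <- function(X, y) {
  if (inherits(X, "spectral_dataset")) {
    if (is.null(y)) y <- X$labels
    X <- X$matrix
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(y))
  if (nrow(X) != length(y)) stop_data("X rows and y length differ")
  list(X = X, y = y)
}

#' One-way ANOVA F statistics per channel
#'
#' Between-class over within-class mean squares for every channel, used as
#' a univariate filter to drop channels with very small effect sizes before
#' the multivariate stage.
#'
#' @param X a [spectral_dataset()] or numeric matrix (samples in rows).
#' @param y class labels (taken from the dataset when omitted).
#' @return numeric vector of F statistics, one per channel. Channels with
#'   zero within-class variance but non-zero between-class variance get
#'   `Inf` (with a warning); completely constant channels get 0.
#' @export
anova_f <- function(X, y = NULL) {
  d <- get_xy(X, y)
  X <- d$X; y <- d$y
  K <- nlevels(y); n <- nrow(X)
  if (K < 2) stop_data("ANOVA filtering needs at least 2 classes")
  if (any(table(y) < 2)) stop_data("every class needs at least 2 samples")
  counts <- as.numeric(table(y))
  gm <- rowsum(X, y) / counts               # class means, K x p
  overall <- colMeans(X)
  ssb <- colSums(counts * sweep(gm, 2, overall, `-`)^2)
  sst <- colSums(sweep(X, 2, overall, `-`)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (K - 1)
  msw <- ssw / (n - K)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  if (any(is.infinite(f))) {
    warning(sprintf("%d channel(s) have zero within-class variance; F set to Inf",
                    sum(is.infinite(f))))
  }
  f
}

#' Univariate ANOVA channel filter
#'
#' Keeps the `keep_n` channels with the largest one-way F statistics, ties
#' broken by lower channel index for reproducibility.
#'
#' @inheritParams anova_f
#' @param keep_n number of channels to keep (default 200).
#' @return a [feature_mask()] with provenance `"anova"`.
#' @export
anova_filter <- function(X, y = NULL, keep_n = 200) {
  d <- get_xy(X, y)
  p <- ncol(d$X)
  if (keep_n > p) stop_data("keep_n (%d) exceeds channel count (%d)", keep_n, p)
  f <- anova_f(d$X, d$y)
  keep <- order(-f, seq_along(f))[seq_len(keep_n)]
  feature_mask(keep, "anova", p)
}

# class indicator matrix n x K
class_indicator <- function(y) {
  K <- nlevels(y)
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

standardize_columns <- function(X) {
  center <- colMeans(X)
  sc <- sqrt(colMeans(X^2) - center^2)     # 1/n variance, glmnet convention
  constant <- sc < .Machine$double.eps^0.5
  sc[constant] <- 1                         # constant channels get zero weight
  Xs <- sweep(sweep(X, 2, center, `-`), 2, sc, `/`)
  list(Xs = Xs, center = center, scale = sc, constant = constant)
}

#' Penalized multinomial objective
#'
#' The elastic-net multinomial negative log-likelihood
#' \deqn{-\frac1n \sum_i \sum_k 1(y_i = k)\,
#'   \log\frac{e^{x_i^\top \beta_k}}{\sum_l e^{x_i^\top \beta_l}}
#'   + \lambda \sum_k \big[\alpha \|\beta_k\|_1
#'   + \tfrac12 (1-\alpha)\|\beta_k\|_2^2\big]}
#' with the penalty summed over classes and intercepts unpenalized.
#' Pure function; used by the solver tests and diagnostics.
#'
#' @param X numeric matrix (n x p) of predictors.
#' @param y class labels (factor-coercible, K levels).
#' @param coefficients p x K coefficient matrix (one column per class).
#' @param intercepts length-K intercept vector.
#' @param alpha elastic-net mixing weight in \[0, 1\] (1 = lasso).
#' @param lambda penalty strength, `>= 0`.
#' @return the penalized negative log-likelihood (a single number).
#' @export
enet_objective <- function(X, y, coefficients, intercepts, alpha, lambda) {
  d <- get_xy(X, y)
  if (any(!is.finite(coefficients)) || any(!is.finite(intercepts))) {
    stop_data("coefficients and intercepts must be finite")
  }
  eta <- sweep(d$X %*% coefficients, 2, intercepts, `+`)
  eta <- eta - apply(eta, 1, max)
  logp <- eta - log(rowSums(exp(eta)))
  nll <- -mean(logp[cbind(seq_len(nrow(d$X)), as.integer(d$y))])
  nll + lambda * (alpha * sum(abs(coefficients)) +
                    0.5 * (1 - alpha) * sum(coefficients^2))
}

#' Smallest penalty with an all-zero solution
#'
#' Closed-form threshold from the null-model gradient: with features
#' standardized and intercepts at the null fit (class log-proportions),
#' every coefficient is zero iff
#' `lambda >= max_{j,k} |<x_j, y_k - p_k>| / (n * alpha)`.
#'
#' @inheritParams enet_objective
#' @param standardize standardize columns first (as the solver does).
#' @return the lasso-null threshold `lambda_max`.
#' @export
lambda_max <- function(X, y, alpha = 1, standardize = TRUE) {
  d <- get_xy(X, y)
  Xs <- if (standardize) standardize_columns(d$X)$Xs else d$X
  Y <- class_indicator(d$y)
  props <- colMeans(Y)
  Rnull <- sweep(Y, 2, props, `-`)
  g <- crossprod(Xs, Rnull) / nrow(Xs)
  max(abs(g)) / max(alpha, 1e-3)
}

#' Fit the elastic-net multinomial model
#'
#' Cyclic coordinate descent on the objective of [enet_objective()]:
#' classes are cycled with a quadratic majorizer of the partial likelihood
#' (curvature 1/4 per observation) and coordinates updated by
#' soft-thresholding, so the objective never increases across outer
#' iterations. Features are standardized internally (zero mean, unit 1/n
#' variance) and coefficients are reported on the standardized scale;
#' intercepts are unpenalized. Convergence is declared when the largest
#' coefficient change in an outer cycle falls below `thresh`.
#'
#' @inheritParams enet_objective
#' @param lambda a single penalty value, or a decreasing sequence (the fit
#'   at each value warm-starts the next; the returned object holds the last
#'   value, `path = TRUE` returns the whole path).
#' @param standardize standardize columns internally (default `TRUE`).
#' @param thresh convergence threshold on the maximum coefficient change.
#' @param maxit maximum outer iterations per lambda.
#' @param path return the full `enet_path` instead of the final fit.
#' @param trace_objective record the objective after every outer iteration
#'   (diagnostic; slows the solver).
#' @param curvature `"newton"` (default): per-observation curvature
#'   `p(1-p)` floored at 1e-5, the fast standard choice; `"mm"`: the fixed
#'   upper bound 1/4, which makes every block update a majorize-minimize
#'   step so the objective provably never increases (debug mode).
#' @param strict error (rather than flag) on non-convergence.
#' @return an object of class `enet_fit`: `coefficients` (p x K, on the
#'   standardized scale), `intercepts`, `alpha`, `lambda`, `n_iter`,
#'   `converged`, the standardization (`center`, `scale`) and class
#'   `levels`. With `path = TRUE`, class `enet_path` holding one
#'   coefficient slab per lambda.
#' @export
enet_fit <- function(X, y, alpha = 0.5, lambda, standardize = TRUE,
                     thresh = 1e-6, maxit = 1e4, path = FALSE,
                     trace_objective = FALSE,
                     curvature = c("newton", "mm"), strict = FALSE) {
  curvature <- match.arg(curvature)
  d <- get_xy(X, y)
  if (nlevels(d$y) < 2) stop_data("need at least 2 classes")
  if (alpha < 0 || alpha > 1) stop_data("alpha must lie in [0, 1]")
  if (any(lambda < 0)) stop_data("lambda must be non-negative")
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  st <- if (standardize) {
    standardize_columns(d$X)
  } else {
    list(Xs = d$X, center = rep(0, ncol(d$X)), scale = rep(1, ncol(d$X)))
  }
  Y <- class_indicator(d$y)
  res <- .enet_mn_path_cpp(st$Xs, Y, alpha, lambda, thresh, as.integer(maxit),
                           trace_objective, curvature == "mm")
  if (strict && !all(res$converged)) {
    stop_data("elastic-net solver did not converge within %d iterations", maxit)
  }
  p <- ncol(d$X); K <- nlevels(d$y)
  mk <- function(l) {
    structure(list(
      coefficients = matrix(res$beta[, , l], p, K,
                            dimnames = list(colnames(d$X), levels(d$y))),
      intercepts = res$b0[, l],
      alpha = alpha, lambda = lambda[l],
      n_iter = res$niter[l], converged = res$converged[l],
      center = st$center, scale = st$scale,
      levels = levels(d$y),
      objective_trace = if (trace_objective) res$objective_trace[[l]] else NULL
    ), class = "enet_fit")
  }
  if (path) {
    structure(list(fits = lapply(seq_along(lambda), mk), lambda = lambda,
                   alpha = alpha),
              class = "enet_path")
  } else {
    mk(length(lambda))
  }
}

#' @export
print.enet_fit <- function(x, ...) {
  nz <- sum(rowSums(abs(as.matrix(x$coefficients))) > 0)
  cat(sprintf("<enet_fit> K = %d classes, %d features (%d active), alpha = %g, lambda = %.4g%s\n",
              length(x$levels), length(x$center), nz, x$alpha, x$lambda,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict from an elastic-net multinomial fit
#'
#' @param object an `enet_fit`.
#' @param newx numeric matrix of raw (unstandardized) predictors.
#' @param type `"class"`, `"probability"` or `"link"`.
#' @param ... unused.
#' @return factor of predicted classes, a probability matrix (rows sum to
#'   1), or the linear predictor matrix.
#' @export
predict.enet_fit <- function(object, newx,
                             type = c("class", "probability", "link"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  Xs <- sweep(sweep(newx, 2, object$center, `-`), 2, object$scale, `/`)
  eta <- sweep(Xs %*% as.matrix(object$coefficients), 2, object$intercepts, `+`)
  colnames(eta) <- object$levels
  if (type == "link") return(eta)
  em <- exp(eta - apply(eta, 1, max))
  prob <- em / rowSums(em)
  if (type == "probability") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Channels with any nonzero coefficient
#'
#' @param fit an `enet_fit`.
#' @param provenance recorded provenance of the resulting mask.
#' @return a [feature_mask()] over the fit's feature space.
#' @export
active_features <- function(fit, provenance = "enet") {
  co <- as.matrix(fit$coefficients)
  feature_mask(which(rowSums(abs(co)) > 0), provenance, nrow(co))
}

default_lambda_path <- function(lmax, nlambda = 50, lambda_min_ratio = 1e-4) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

multinomial_deviance <- function(prob, y) {
  p <- prob[cbind(seq_along(y), as.integer(y))]
  -2 * mean(log(pmax(p, 1e-12)))
}

#' Tune and fit the elastic-net selector by repeated cross-validation
#'
#' Grid-searches the mixing weight `alpha` and the penalty `lambda`
#' (warm-started descending path per alpha) by repeated stratified k-fold
#' cross-validated multinomial deviance, refits on all data at the winning
#' pair (minimum mean deviance; ties go to the sparser, i.e. larger,
#' lambda), and returns the channels with any nonzero coefficient as the
#' selected feature mask.
#'
#' @inheritParams enet_fit
#' @param alpha_grid candidate mixing weights.
#' @param nlambda number of path points per alpha (log-spaced from
#'   `lambda_max` down to `lambda_min_ratio * lambda_max`).
#' @param lambda_min_ratio smallest path value relative to `lambda_max`.
#' @param lambda_path optional explicit lambda sequence overriding the
#'   automatic path (shared across alphas).
#' @param folds,repeats stratified CV folds and repeats for tuning.
#' @param eval_folds how many of the `folds` folds to actually hold out and
#'   evaluate per repeat (default all). `eval_folds = 1` gives single
#'   holdout-split tuning: train on `(folds-1)/folds` of the data, validate
#'   on the remaining fold - a cheaper protocol for large grids.
#' @param seed RNG seed for the fold draws.
#' @param allow_empty return an intercept-only result instead of erroring
#'   when no features survive at the winner.
#' @return list with `mask` (a [feature_mask()], provenance `"enet"`),
#'   `fit` (the full-data refit, an `enet_fit`), `best`
#'   (`list(alpha, lambda)`) and `cv_deviance` (the tuning grid).
#' @export
enet_select <- function(X, y = NULL, alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                        nlambda = 50, lambda_min_ratio = 1e-4,
                        lambda_path = NULL, folds = 10, repeats = 3,
                        eval_folds = NULL, seed = 1, thresh = 1e-6,
                        maxit = 1e4, allow_empty = FALSE) {
  d <- get_xy(X, y)
  if (nlevels(d$y) < 2) stop_data("need at least 2 classes")
  n <- nrow(d$X)
  paths <- lapply(alpha_grid, function(a) {
    lambda_path %||% default_lambda_path(lambda_max(d$X, d$y, a),
                                         nlambda, lambda_min_ratio)
  })
  nl <- length(paths[[1]])
  eval_folds <- min(eval_folds %||% folds, folds)
  dev_sum <- matrix(0, length(alpha_grid), nl)
  wt_sum <- 0
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(d$y, folds)
      for (f in seq_len(eval_folds)) {
        tr <- fold != f
        for (ai in seq_along(alpha_grid)) {
          pf <- enet_fit(d$X[tr, , drop = FALSE], d$y[tr],
                         alpha = alpha_grid[ai], lambda = paths[[ai]],
                         thresh = thresh, maxit = maxit, path = TRUE)
          for (li in seq_len(nl)) {
            prob <- predict(pf$fits[[li]], d$X[!tr, , drop = FALSE],
                            type = "probability")
            dev_sum[ai, li] <- dev_sum[ai, li] +
              multinomial_deviance(prob, d$y[!tr]) * sum(!tr)
          }
        }
        wt_sum <- wt_sum + sum(!tr)
      }
    }
  })
  dev_mean <- dev_sum / wt_sum
  # winner: minimum deviance; ties resolved toward the sparser model
  best_idx <- which(dev_mean == min(dev_mean), arr.ind = TRUE)[1, ]
  best_alpha <- alpha_grid[best_idx[1]]
  best_lambda <- paths[[best_idx[1]]][best_idx[2]]
  fit <- enet_fit(d$X, d$y, alpha = best_alpha,
                  lambda = paths[[best_idx[1]]][seq_len(best_idx[2])],
                  thresh = thresh, maxit = maxit)
  mask <- active_features(fit)
  if (length(mask$indices) == 0 && !allow_empty) {
    stop_data("no features survived the elastic-net selection")
  }
  list(mask = mask, fit = fit,
       best = list(alpha = best_alpha, lambda = best_lambda),
       cv_deviance = dev_mean)
}
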