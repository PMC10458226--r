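# Independent oracle implementations and small fixtures used across tests.
# These deliberately use naive, transparent algorithms (dense solves, plain
# gradient descent, two-loop sums) so they stay independent of the package
# code paths they check.

# brute-force one-way ANOVA F statistics, column by column, two loops
anova_f_oracle <- function(X, y) {
  y <- as.factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    grand <- mean(v)
    ssb <- 0
    ssw <- 0
    for (cl in levels(y)) {
      g <- v[y == cl]
      ssb <- ssb + length(g) * (mean(g) - grand)^2
      ssw <- ssw + sum((g - mean(g))^2)
    }
    msb <- ssb / (K - 1)
    msw <- ssw / (n - K)
    if (msw > 0) msb / msw else if (msb > 0) Inf else 0
  }, numeric(1))
}

# dense alternating-weights asymmetric least squares (reference for the
# banded solver), feasible only for short spectra
als_oracle <- function(y, smoothness, asymmetry, iters = 10) {
  m <- length(y)
  D <- diff(diag(m), differences = 2)
  DtD <- crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(iters)) {
    z <- solve(diag(w) + smoothness * DtD, w * y)
    w <- ifelse(y > z, asymmetry, 1 - asymmetry)
  }
  z
}

# plain full-gradient descent on the unpenalized multinomial negative
# log-likelihood (deviance oracle for the lambda -> 0 limit)
multinom_gd_oracle <- function(X, y, iters = 40000, lr = 0.5) {
  y <- as.factor(y)
  n <- nrow(X)
  K <- nlevels(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, ncol(X), K)
  b0 <- rep(0, K)
  for (t in seq_len(iters)) {
    eta <- sweep(X %*% B, 2, b0, `+`)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta)
    P <- P / rowSums(P)
    B <- B - lr * crossprod(X, P - Y) / n
    b0 <- b0 - lr * colMeans(P - Y)
  }
  eta <- sweep(X %*% B, 2, b0, `+`)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  dev <- -2 * mean(log(P[cbind(seq_len(n), as.integer(y))]))
  list(B = B, b0 = b0, deviance = dev)
}

mean_deviance <- function(prob, y) {
  -2 * mean(log(prob[cbind(seq_along(y), as.integer(as.factor(y)))]))
}

# small custom class profiles for cheap generator-based tests; includes a
# Na-named LIBS line so simultaneous-mode injection is exercised
tiny_profiles <- function(n_classes = 3, seed = 7, spread = 0.3) {
  set.seed(seed)
  lapply(seq_len(n_classes), function(ci) {
    ml <- stats::rlnorm(3, 0, spread)
    mr <- stats::rlnorm(2, 0, spread)
    structure(list(
      class_id = sprintf("T%d", ci),
      libs_peaks = list(
        peak_model(420, 1.5, 60 * ml[1], "lorentzian", "Ca_I"),
        peak_model(516.2, 1.5, 35 * ml[2], "lorentzian", "C2"),
        peak_model(588.9, 1.5, 45 * ml[3], "lorentzian", "Na")
      ),
      raman_peaks = list(
        peak_model(1000, 20, 50 * mr[1], "gaussian", "bandA"),
        peak_model(1450, 20, 35 * mr[2], "gaussian", "bandB")
      ),
      multipliers = list(libs = ml, raman = mr),
      strong_modality = "libs"
    ), class = "class_profile")
  })
}

tiny_sim_config <- function(replicates = 12, noise_sd = 0.01,
                            fluctuation_sd = 0.05, mode = "sequential",
                            seed = 1, n_classes = 3, ...) {
  sim_config("custom",
             profiles = tiny_profiles(n_classes),
             replicates_per_class = replicates,
             noise_sd = noise_sd, fluctuation_sd = fluctuation_sd,
             mode = mode, seed = seed,
             libs_axis = libs_axis(160, c(380, 620)),
             raman_axis = raman_axis(120, c(800, 2000)),
             baseline = list(raman_coef = c(6, -4, 1, 0.3),
                             libs_offset = 1), ...)
}

# reduced tuning settings used by generator-scale evaluation tests
fast_pipeline_config <- function(...) {
  pipeline_config(alpha_grid = c(0.1, 0.5, 1), nlambda = 20,
                  lambda_min_ratio = 1e-2, inner_folds = 2,
                  inner_eval_folds = 1, thresh = 1e-3, maxit = 50, ...)
}
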