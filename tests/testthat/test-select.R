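test_that("ANOVA F statistics equal the brute-force two-loop oracle", {
  set.seed(31)
  # several instances up to 100 samples x 50 channels, 3-5 classes
  for (rep in 1:4) {
    n <- sample(c(30, 60, 100), 1)
    p <- sample(c(5, 20, 50), 1)
    K <- sample(3:5, 1)
    y <- factor(rep_len(seq_len(K), n))
    X <- matrix(rnorm(n * p), n) + outer(as.integer(y), seq_len(p)) * 0.05
    expect_equal(anova_f(X, y), anova_f_oracle(X, y), tolerance = 1e-10)
  }
  # the 5-channel, 3-class, n = 12 instance pinned exactly
  set.seed(7)
  X <- matrix(rnorm(60), 12)
  y <- factor(rep(1:3, each = 4))
  expect_equal(anova_f(X, y), anova_f_oracle(X, y), tolerance = 1e-10)
})

test_that("ANOVA filter keeps the top-F channels with index tie-breaks", {
  set.seed(32)
  y <- factor(rep(1:3, each = 10))
  X <- matrix(rnorm(30 * 20), 30)
  X[, 4] <- X[, 4] + as.integer(y) * 2      # strong channel
  X[, 9] <- 5                                # constant channel: F = 0
  m <- anova_filter(X, y, keep_n = 10)
  expect_s3_class(m, "feature_mask")
  expect_length(m$indices, 10)
  expect_true(4 %in% m$indices)
  expect_false(9 %in% m$indices)
  expect_error(anova_filter(X, y, keep_n = 21), "exceeds")
  expect_error(anova_f(X, factor(rep(1, 30))), "2 classes")
  # duplicated channels tie exactly; lower index wins
  X2 <- cbind(X[, 4], X[, 4], X[, 1:3])
  m2 <- anova_filter(X2, y, keep_n = 1)
  expect_equal(m2$indices, 1L)
  # zero within-class variance with between-class signal -> Inf and kept
  X3 <- cbind(as.numeric(y), matrix(rnorm(90), 30))
  expect_warning(f3 <- anova_f(X3, y), "zero within-class")
  expect_true(is.infinite(f3[1]))
})

test_that("the penalized objective matches hand computation", {
  # all-zero coefficients on balanced classes: uniform softmax -> log K
  set.seed(41)
  X <- matrix(rnorm(18 * 4), 18)
  y <- factor(rep(1:3, each = 6))
  expect_equal(enet_objective(X, y, matrix(0, 4, 3), rep(0, 3), 0.5, 0),
               log(3), tolerance = 1e-12)

  # 3-sample instance, hand-computed log-softmax
  Xs <- matrix(c(1, 0, -1, 0, 2, 1), 3, 2)
  ys <- factor(c("u", "v", "u"))
  B <- matrix(c(0.5, -0.2, -0.5, 0.2), 2, 2)
  b0 <- c(0.1, -0.1)
  eta <- sweep(Xs %*% B, 2, b0, `+`)
  hand <- -mean(log(exp(eta[cbind(1:3, c(1, 2, 1))]) / rowSums(exp(eta))))
  expect_equal(enet_objective(Xs, ys, B, b0, 1, 0), hand, tolerance = 1e-12)

  # penalty is linear in lambda and mixes l1/l2 as printed
  pen1 <- enet_objective(Xs, ys, B, b0, 0.3, 0.2) - hand
  pen2 <- enet_objective(Xs, ys, B, b0, 0.3, 0.4) - hand
  expect_equal(pen2, 2 * pen1, tolerance = 1e-12)
  expect_equal(pen1, 0.2 * (0.3 * sum(abs(B)) + 0.35 * sum(B^2)),
               tolerance = 1e-12)
  expect_error(enet_objective(Xs, ys, B * NA, b0, 0.5, 0.1), "finite")
})

test_that("the lasso null threshold zeroes every coefficient", {
  set.seed(42)
  X <- matrix(rnorm(90 * 12), 90)
  y <- factor(rep(1:3, each = 30))
  X[, 1] <- X[, 1] + as.integer(y)
  lmx <- lambda_max(X, y, alpha = 1)
  f_at <- enet_fit(X, y, alpha = 1, lambda = lmx * (1 + 1e-8))
  expect_true(all(f_at$coefficients == 0))
  f_below <- enet_fit(X, y, alpha = 1, lambda = lmx * 0.9)
  expect_gt(sum(f_below$coefficients != 0), 0)
})

test_that("the lambda -> 0 limit approaches the unpenalized deviance", {
  # tiny separable 2-class instance; oracle is plain gradient descent
  X <- matrix(c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2,
                0.3, -0.2, 0.1, 0.2, -0.1, 0.3, -0.3, 0.1), 8, 2)
  y <- factor(rep(c("lo", "hi"), each = 4))
  st <- scale(X, center = colMeans(X),
              scale = sqrt(colMeans(X^2) - colMeans(X)^2))
  gd <- multinom_gd_oracle(st, y, iters = 60000, lr = 1)
  f <- enet_fit(X, y, alpha = 0.5, lambda = 1e-8, thresh = 1e-9,
                maxit = 1e5)
  prob <- predict(f, X, type = "probability")
  expect_equal(mean_deviance(prob, y), gd$deviance, tolerance = 1e-4)
})

test_that("KKT subgradient conditions hold at convergence", {
  set.seed(43)
  for (rep in 1:3) {
    n <- 80; p <- 12; K <- 3
    y <- factor(rep_len(1:K, n))
    X <- matrix(rnorm(n * p), n) + outer(as.integer(y), rep(0.4, p))
    X[, 1:4] <- X[, 1:4] + matrix(rnorm(K * 4), K)[as.integer(y), ]
    alpha <- sample(c(0.3, 0.7, 1), 1)
    lam <- 0.02
    f <- enet_fit(X, y, alpha = alpha, lambda = lam, thresh = 1e-9,
                  maxit = 1e5)
    Xs <- scale(X, center = f$center, scale = f$scale)
    Y <- diag(K)[as.integer(y), ]
    eta <- sweep(Xs %*% f$coefficients, 2, f$intercepts, `+`)
    P <- exp(eta - apply(eta, 1, max))
    P <- P / rowSums(P)
    G <- crossprod(Xs, Y - P) / n          # p x K gradient of -loglik
    zero <- f$coefficients == 0
    expect_true(all(abs(G[zero]) <= lam * alpha + 1e-6))
    act <- !zero
    if (any(act)) {
      resid <- G[act] - lam * (1 - alpha) * f$coefficients[act] -
        lam * alpha * sign(f$coefficients[act])
      expect_true(all(abs(resid) < 1e-5))
    }
    # intercept stationarity
    expect_true(all(abs(colMeans(Y - P)) < 1e-6))
  }
})

test_that("objective decreases monotonically in the guaranteed-descent mode", {
  set.seed(44)
  n <- 60; p <- 10
  y <- factor(rep(1:3, each = 20))
  X <- matrix(rnorm(n * p), n) + matrix(rnorm(3 * p), 3)[as.integer(y), ]
  for (alpha in c(0.2, 1)) {
    f <- enet_fit(X, y, alpha = alpha, lambda = 0.05, curvature = "mm",
                  trace_objective = TRUE)
    expect_true(all(diff(f$objective_trace) <= 1e-12))
  }
})

test_that("warm-started path solutions match cold starts", {
  set.seed(45)
  n <- 90; p <- 15
  y <- factor(rep(1:3, each = 30))
  X <- matrix(rnorm(n * p), n) + matrix(rnorm(3 * p, sd = 0.7), 3)[as.integer(y), ]
  lmx <- lambda_max(X, y, 0.8)
  path <- lmx * c(1, 0.5, 0.2, 0.08, 0.03)
  warm <- enet_fit(X, y, alpha = 0.8, lambda = path, path = TRUE,
                   thresh = 1e-8)
  Xs <- scale(X, center = warm$fits[[1]]$center,
              scale = warm$fits[[1]]$scale)
  for (i in seq_along(path)) {
    cold <- enet_fit(X, y, alpha = 0.8, lambda = path[i], thresh = 1e-8)
    ow <- enet_objective(Xs, y, warm$fits[[i]]$coefficients,
                         warm$fits[[i]]$intercepts, 0.8, path[i])
    oc <- enet_objective(Xs, y, cold$coefficients, cold$intercepts,
                         0.8, path[i])
    expect_lt(abs(ow - oc), 1e-6)
  }
})

test_that("solutions agree with an independent elastic-net implementation", {
  skip_if_not_installed("glmnet")
  set.seed(46)
  n <- 150; p <- 25; K <- 4
  y <- factor(rep_len(1:K, n))
  X <- matrix(rnorm(n * p), n) + matrix(rnorm(K * p, sd = 0.8), K)[as.integer(y), ]
  for (alpha in c(1, 0.5, 0.1)) {
    for (lam in c(0.1, 0.02)) {
      f <- enet_fit(X, y, alpha = alpha, lambda = lam, thresh = 1e-8)
      Xs <- scale(X, center = f$center, scale = f$scale)
      o_mine <- enet_objective(Xs, y, f$coefficients, f$intercepts,
                               alpha, lam)
      g <- glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                          lambda = lam, thresh = 1e-12, maxit = 1e6)
      cg <- do.call(cbind, lapply(glmnet::coef.glmnet(g),
                                  function(m) as.numeric(m)[-1]))
      ig <- vapply(glmnet::coef.glmnet(g),
                   function(m) as.numeric(m)[1], numeric(1))
      o_ref <- enet_objective(Xs, y, cg * f$scale,
                              ig + colSums(cg * f$center), alpha, lam)
      expect_equal(o_mine, o_ref, tolerance = 1e-6)
    }
  }
})

test_that("mask size is non-increasing in lambda on a coarse lasso grid", {
  set.seed(47)
  n <- 120; p <- 30
  y <- factor(rep(1:4, each = 30))
  X <- matrix(rnorm(n * p), n) + matrix(rnorm(4 * p, sd = 0.5), 4)[as.integer(y), ]
  lmx <- lambda_max(X, y, 1)
  path <- lmx * c(0.9, 0.5, 0.25, 0.1, 0.04)
  pf <- enet_fit(X, y, alpha = 1, lambda = path, path = TRUE)
  sizes <- vapply(pf$fits, function(f) length(active_features(f)$indices),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))  # path is stored descending in lambda
})

test_that("cross-validated selection recovers a planted sparse support", {
  set.seed(48)
  n <- 200; p <- 40; K <- 4
  y <- factor(rep_len(1:K, n))
  X <- matrix(rnorm(n * p), n)
  informative <- c(2, 5, 9, 13, 17, 22, 26, 31, 35, 39)
  # every informative channel gets well-separated class means (a shuffled
  # ladder), so the planted support is identifiable by construction
  shift <- vapply(seq_along(informative),
                  function(j) sample(seq(-2.25, 2.25, length.out = K)),
                  numeric(K))
  X[, informative] <- X[, informative] + shift[as.integer(y), ]
  sel <- enet_select(X, y, alpha_grid = 1, nlambda = 30,
                     lambda_min_ratio = 1e-2, folds = 5, repeats = 1,
                     seed = 3)
  expect_true(all(informative %in% sel$mask$indices))
  expect_lte(length(setdiff(sel$mask$indices, informative)), 5)
  # determinism: the same seed reproduces the mask exactly
  sel2 <- enet_select(X, y, alpha_grid = 1, nlambda = 30,
                      lambda_min_ratio = 1e-2, folds = 5, repeats = 1,
                      seed = 3)
  expect_identical(sel$mask$indices, sel2$mask$indices)
})

test_that("a lambda_max-only path leaves no features and errors", {
  set.seed(49)
  X <- matrix(rnorm(60 * 8), 60)
  y <- factor(rep(1:3, each = 20))
  lmx <- lambda_max(X, y, 1)
  expect_error(
    enet_select(X, y, alpha_grid = 1, lambda_path = lmx * 1.001,
                folds = 3, repeats = 1),
    "no features survived")
})
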