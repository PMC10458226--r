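test_that("the elastic-net classifier separates a clean two-class problem", {
  set.seed(51)
  n <- 40
  y <- factor(rep(c("lo", "hi"), each = n / 2))
  X <- cbind(ifelse(y == "hi", 5, -5) + rnorm(n, sd = 0.1),
             rnorm(n))
  m <- train_enet_classifier(X, y, alpha = 0.5, lambda = 0.01)
  expect_equal(mean(predict(m, X) == y), 1)
  prob <- predict(m, X, type = "probability")
  expect_equal(unname(rowSums(prob)), rep(1, n), tolerance = 1e-9)
  expect_error(train_enet_classifier(matrix(nrow = 4, ncol = 0),
                                     factor(c(1, 1, 2, 2)), lambda = 0.1),
               "empty feature set")
})

test_that("relabelling classes permutes predictions consistently", {
  set.seed(52)
  n <- 60
  y <- factor(rep(c("a", "b", "c"), each = 20))
  X <- matrix(rnorm(n * 6), n) + matrix(rnorm(18, sd = 2), 3)[as.integer(y), ]
  m1 <- train_enet_classifier(X, y, alpha = 0.5, lambda = 0.02)
  map <- c(a = "zz", b = "mm", c = "aa")
  y2 <- factor(unname(map[as.character(y)]))
  m2 <- train_enet_classifier(X, y2, alpha = 0.5, lambda = 0.02)
  expect_equal(unname(map[as.character(predict(m1, X))]),
               as.character(predict(m2, X)))
})

test_that("the SVM benchmark solves a hand-checkable margin problem", {
  # two interior points at x = +-1 fix the margin; outer points are slack
  X <- matrix(c(-1, 0, -3, 1, 1, 0, 3, -1), 4, 2, byrow = TRUE)
  y <- factor(c("neg", "neg", "pos", "pos"))
  m <- train_svm_benchmark(X, y, C = 100)
  expect_equal(as.character(predict(m, X)), as.character(y))
  sv <- sort(m$fit$index)
  expect_true(all(c(1, 3) %in% sv))
  expect_false(any(c(2, 4) %in% sv))

  # duplicating every training point leaves the decision unchanged
  m2 <- train_svm_benchmark(rbind(X, X), factor(rep(y, 2)), C = 100)
  grid <- cbind(seq(-3, 3, length.out = 11), seq(3, -3, length.out = 11))
  expect_equal(as.character(predict(m, grid)),
               as.character(predict(m2, grid)))

  # the fully regularized limit collapses to the majority class
  set.seed(53)
  Xm <- matrix(rnorm(40), 20, 2)
  ym <- factor(c(rep("big", 15), rep("small", 5)))
  m3 <- train_svm_benchmark(Xm, ym, C = 1e-4)
  expect_true(all(predict(m3, Xm) == "big"))
  expect_error(train_svm_benchmark(Xm, factor(rep("one", 20))), "2 classes")
})

test_that("repeated CV is deterministic and summarizes the diagonal", {
  cfg <- tiny_sim_config(replicates = 15, noise_sd = 0.03, seed = 6)
  ds <- generate_dataset(cfg)
  libs <- preprocess_spectra(ds$libs)
  pc <- fast_pipeline_config(keep_n = 40)
  r1 <- repeated_cv(libs, pc, k = 3, sessions = 2, seeds = c(11, 12))
  r2 <- repeated_cv(libs, pc, k = 3, sessions = 2, seeds = c(11, 12))
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$per_class_accuracy, r2$per_class_accuracy)
  # each confusion matrix accounts for every sample once
  for (cm in r1$confusion) expect_equal(sum(cm), nrow(libs$matrix))
  expect_true(all(r1$per_class_accuracy >= 0 & r1$per_class_accuracy <= 1))
  expect_equal(r1$mean_accuracy, mean(rowMeans(r1$per_class_accuracy)))

  expect_error(repeated_cv(libs, pc, k = 20, sessions = 1), "fewer than")
  one_class <- spectral_dataset(libs$matrix, libs$axis,
                                rep("only", nrow(libs$matrix)), "libs")
  expect_error(repeated_cv(one_class, pc, k = 3), "2 classes")
  expect_warning(repeated_cv(libs, pc, k = 3, sessions = 2, seeds = c(1, 1)),
                 "duplicate")
})

test_that("training accuracy dominates cross-validated accuracy", {
  cfg <- tiny_sim_config(replicates = 15, noise_sd = 0.06, seed = 8)
  ds <- generate_dataset(cfg)
  libs <- preprocess_spectra(ds$libs)
  pc <- fast_pipeline_config(keep_n = 40)
  r <- repeated_cv(libs, pc, k = 3, sessions = 2, seeds = 1:2)
  sel <- enet_select(libs$matrix[, anova_filter(libs, keep_n = 40)$indices],
                     libs$labels, alpha_grid = c(0.5, 1), nlambda = 20,
                     lambda_min_ratio = 1e-2, folds = 3, repeats = 1,
                     seed = 1, thresh = 1e-3, allow_empty = TRUE)
  train_acc <- mean(predict(sel$fit,
                            libs$matrix[, anova_filter(libs, keep_n = 40)$indices],
                            type = "class") == libs$labels)
  expect_gte(train_acc + 1e-9, r$mean_accuracy)
})

test_that("fitted masks ignore test-fold labels (no selection leakage)", {
  cfg <- tiny_sim_config(replicates = 12, noise_sd = 0.05, seed = 10)
  ds <- generate_dataset(cfg)
  libs <- preprocess_spectra(ds$libs)
  n <- nrow(libs$matrix)
  fold <- rep_len(1:3, n)
  pc <- fast_pipeline_config(keep_n = 30)
  r1 <- repeated_cv(libs, pc, k = 3, sessions = 1, seeds = 5,
                    folds = list(fold), collect_masks = TRUE)
  # permute the labels inside fold 2 only; training folds are unchanged
  scr <- libs
  i2 <- which(fold == 2)
  set.seed(99)
  scr$labels[i2] <- sample(scr$labels[i2])
  r2 <- repeated_cv(scr, pc, k = 3, sessions = 1, seeds = 5,
                    folds = list(fold), collect_masks = TRUE)
  expect_identical(r1$masks[[1]][[2]], r2$masks[[1]][[2]])
})

test_that("summaries report mean (SD) percentages of the diagonal", {
  cm1 <- matrix(c(8, 2, 2, 8), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cm2 <- matrix(c(9, 1, 1, 9), 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- cv_result(list(cm1, cm2))
  s <- summary(r)
  expect_equal(s$mean_pct[s$metric == "macro"], 85)
  expect_equal(s$sd_pct[s$metric == "macro"], sd(c(80, 90)), tolerance = 1e-9)
  expect_equal(s$display[s$metric == "macro"], "85.00 (7.07)")

  perfect <- cv_result(list(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(summary(perfect)$mean_pct[1], 100)
  expect_error(cv_result(list()), "empty")

  tab <- cv_summary_table(list(enet = list(libs = r, raman = perfect)))
  expect_equal(tab$method, "enet")
  expect_equal(tab$libs, "85.00 (7.07)")
})
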