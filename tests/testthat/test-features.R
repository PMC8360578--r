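test_that("augmentation equalizes class sizes with bounded rotations", {
  d <- small_classifier_data()[1:70, ]   # 40 compact + 30 vertical
  d$class <- droplevels(factor(d$class))
  aug <- augment_dataset(d, max_angle = 5, target_count = 50, seed = 2)
  expect_equal(as.integer(table(aug$class)), c(50L, 50L))
  expect_equal(sum(aug$augmented), 30L)
  # zero-angle augmentation copies masks verbatim
  aug0 <- augment_dataset(d, max_angle = 0, target_count = 45, seed = 2)
  copies <- aug0[aug0$augmented, ]
  orig <- d[d$class == copies$class[1], ]
  expect_identical(unclass(copies$mask[[1]]), unclass(orig$mask[[1]]))
  # determinism
  augA <- augment_dataset(d, 5, 50, seed = 9)
  augB <- augment_dataset(d, 5, 50, seed = 9)
  expect_identical(augA$mask, augB$mask)
})

test_that("the trained classifier separates synthetic classes and is deterministic", {
  fit <- small_classifier()
  g <- glance(fit)
  expect_gte(g$val_accuracy_last10, 0.9)
  expect_equal(nrow(tidy(fit)), 5L)
  # determinism: same seed, same final loss
  d <- small_classifier_data()[c(1:12, 41:52, 81:92), ]
  cfgc <- classifier_config(epochs = 2L, lr = 1e-3, batch_size = 12L, seed = 5)
  f1 <- train_shape_classifier(d, cfgc)
  f2 <- train_shape_classifier(d, cfgc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_error(train_shape_classifier(d[d$class == "compact", ], cfgc),
               "classes")
})

test_that("extracted features obey the softmax contract", {
  fit <- small_classifier()
  d <- small_classifier_data()
  ft <- extract_features(fit, d$mask[c(1, 1, 45, 90)])
  # argmax of the class probabilities is the predicted class
  probs <- as.matrix(ft[, paste0("p_", fit$classes)])
  expect_equal(fit$classes[max.col(probs)], as.character(ft$predicted))
  # probabilities normalize
  expect_equal(unname(rowSums(probs)), rep(1, 4), tolerance = 1e-9)
  # duplicate mask gives identical feature rows
  expect_equal(ft$F1[1], ft$F1[2])
  expect_equal(ft$F3[1], ft$F3[2])
  # softmax shift invariance: recompute from F with a constant added
  f <- as.matrix(ft[, c("F1", "F2", "F3")])
  soft <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  expect_equal(soft(f[3, ] + 7), soft(f[3, ]), tolerance = 1e-12)
  expect_equal(unname(soft(f[3, ])), unname(probs[3, ]), tolerance = 1e-9)
  # 256-dim intermediate layer
  fi <- extract_features(fit, d$mask[1:2], layer = "intermediate256")
  expect_true(all(paste0("X", 1:256) %in% names(fi)))
})

test_that("shape PCA has unit-sum latencies, orthonormal loadings, rank behavior", {
  set.seed(1)
  feats <- tibble::tibble(F1 = rnorm(20), F2 = rnorm(20), F3 = rnorm(20))
  pca <- fit_shape_pca(feats)
  expect_equal(sum(pca$latencies), 1, tolerance = 1e-9)
  expect_equal(crossprod(pca$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # coplanar inputs: third latency collapses
  flat <- tibble::tibble(F1 = rnorm(10), F2 = rnorm(10))
  flat$F3 <- flat$F1 + 2 * flat$F2
  expect_lt(fit_shape_pca(flat)$latencies[3], 1e-9)
  # two well-separated clusters: PC1 separation dominates within-cluster spread
  cl <- tibble::tibble(F1 = c(rnorm(10, 0, .1), rnorm(10, 8, .1)),
                       F2 = rnorm(20, 0, .1), F3 = rnorm(20, 0, .1))
  p2 <- fit_shape_pca(cl)
  sc <- project_features(p2, cl)
  gap <- abs(mean(sc$PC1[1:10]) - mean(sc$PC1[11:20]))
  spread <- sd(c(sc$PC1[1:10] - mean(sc$PC1[1:10]),
                 sc$PC1[11:20] - mean(sc$PC1[11:20])))
  expect_gt(gap, 5 * spread)
  expect_error(fit_shape_pca(feats[1:2, ]), "at least 3")
})

test_that("hand-crafted features match analytic shapes", {
  disk <- normalize_mask(disk_mask(100, 30), c(1, 0))
  h <- handcrafted_features(disk)
  expect_equal(h$h1, 1, tolerance = 0.05)
  expect_equal(h$h2, 1, tolerance = 0.05)
  expect_gt(h$h3, 0.95)
  tall <- normalize_mask(ellipse_mask(0.5, dim = 120), c(1, 0))
  ht <- handcrafted_features(tall)
  expect_gt(ht$h1, ht$h2)
  sq <- matrix(FALSE, 64, 64); sq[17:48, 17:48] <- TRUE
  hs <- handcrafted_features(sq)
  expect_equal(hs$h3, pi / 4, tolerance = 0.05)
})

test_that("feature extraction is bit-stable across calls", {
  fit <- small_classifier()
  m <- small_classifier_data()$mask[1:3]
  a <- extract_features(fit, m)
  b <- extract_features(fit, m)
  expect_identical(a, b)
})
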