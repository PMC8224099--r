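test_that("information gain matches hand-enumerated entropy arithmetic", {
  # 4-row toy table: feature {1,2,3,4}, labels {a,a,b,b} -> perfect split
  expect_equal(information_gain(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                                n_bins = 2), 1.0, tolerance = 1e-12)
  # feature {1,2,3,4} vs labels {a,b,a,b}: each bin is half a / half b
  expect_equal(information_gain(c(1, 2, 3, 4), c("a", "b", "a", "b"),
                                n_bins = 2), 0, tolerance = 1e-12)
  # hand-computed mixed case: feature {1,2,3,4}, labels {a,a,b,a}
  # H(y) = 0.8113; bin {1,2} = {a,a} (H = 0), bin {3,4} = {b,a} (H = 1)
  h_y <- -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4)
  expect_equal(information_gain(c(1, 2, 3, 4), c("a", "a", "b", "a"),
                                n_bins = 2), h_y - 0.5, tolerance = 1e-12)
  # a constant feature cannot discriminate
  expect_identical(information_gain(rep(1, 4), c("a", "a", "b", "b")), 0)
  expect_error(information_gain(1:4, rep("a", 4)), "two classes")
})

test_that("information gain of an independent feature is near zero", {
  set.seed(101)
  x <- rnorm(10000)
  y <- sample(c("a", "b"), 10000, replace = TRUE)
  expect_lt(information_gain(x, y), 0.01)
  # perfect predictor attains the label entropy
  y2 <- rep(c("a", "b"), each = 5000)
  expect_equal(information_gain(c(rnorm(5000), rnorm(5000, 10)), y2), 1,
               tolerance = 0.01)
})

test_that("svm-rfe surfaces informative features and is deterministic", {
  set.seed(102)
  n <- 200
  y <- rep(c("CAD", "non-CAD"), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("f", 1:20)
  X[, 3] <- X[, 3] + ifelse(y == "CAD", 1.5, -1.5)
  X[, 17] <- X[, 17] + ifelse(y == "CAD", -1.2, 1.2)
  X <- scale(X)
  rk <- rank_svmrfe(X, y, elimination_step = 2)
  expect_setequal(rk$features, colnames(X))
  expect_true(all(c("f3", "f17") %in% rk$features[1:4]))
  rk2 <- rank_svmrfe(X, y, elimination_step = 2)
  expect_identical(rk$features, rk2$features)
  # step >= feature count: one fit, ranking by single-fit weights
  rk3 <- rank_svmrfe(X, y, elimination_step = 20)
  yw <- table(factor(y))
  wts <- stats::setNames(as.numeric(length(y) / (2 * yw)), names(yw))
  fit <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE,
                    class.weights = wts)
  w2 <- as.numeric(t(fit$coefs) %*% fit$SV)^2
  expect_identical(rk3$features, colnames(X)[order(w2, decreasing = TRUE)])
})

test_that("subject folds are stratified partitions without leakage", {
  subjects <- data.frame(
    subject_id = sprintf("S%02d", 1:36),
    label = rep(c("CAD", "non-CAD"), c(21, 15)))
  folds <- subject_kfold(subjects, k = 5, seed = 9)
  all_ids <- unlist(folds)
  expect_setequal(all_ids, subjects$subject_id)
  expect_identical(anyDuplicated(all_ids), 0L)
  for (f in folds) {
    n_cad <- sum(subjects$label[subjects$subject_id %in% f] == "CAD")
    expect_true(n_cad %in% 4:5)
    expect_identical(sum(subjects$label[subjects$subject_id %in% f] ==
                           "non-CAD"), 3L)
  }
  expect_error(subject_kfold(subjects, k = 1), "at least 2")
  expect_error(subject_kfold(subjects[c(1:3, 22:24), ], k = 5), "at least k")
})

test_that("metrics follow the confusion-count definitions", {
  truth <- c(rep("CAD", 10), rep("non-CAD", 10))
  pred <- c(rep("CAD", 9), "non-CAD", rep("non-CAD", 8), "CAD", "CAD")
  m <- classification_metrics(truth, pred)
  expect_identical(m[["Se"]], 90)
  expect_identical(m[["Sp"]], 80)
  expect_identical(m[["Acc"]], 85)
  # accuracy is the class-size weighted mean of Se and Sp
  expect_equal(m[["Acc"]], (10 * m[["Se"]] + 10 * m[["Sp"]]) / 20)
})

test_that("the hyper-parameter grid spans 2^-5..2^5 in factor-2 steps", {
  g <- svm_grid()
  expect_identical(g$cost, 2^seq(-5, 5))
  expect_identical(g$gamma, 2^seq(-5, 5))
})

test_that("evaluation is subject-wise and free of selection leakage", {
  tab <- fixture_cohort_table()
  small_grid <- svm_grid(-2, 2, by = 2)
  folds <- subject_kfold(unique(tab[, c("subject_id", "label")]),
                         k = 5, seed = 31)
  res <- evaluate_feature_set(tab, feature_set_spec("Mul1"),
                              selector = "infogain", n_features = 30,
                              seed = 31, grid = small_grid,
                              inner_k = 3, folds = folds)
  expect_identical(nrow(res), 5L)
  expect_true(all(res$Acc >= 0 & res$Acc <= 100))
  # flipping the labels of held-out subjects must not change the
  # training-fold rankings or models (no leakage)
  tab_shuf <- tab
  idx <- tab_shuf$subject_id %in% folds[[1]]
  set.seed(99)
  tab_shuf$label[idx] <- sample(c("CAD", "non-CAD"), sum(idx),
                                replace = TRUE)
  res2 <- evaluate_feature_set(tab_shuf, feature_set_spec("Mul1"),
                               selector = "infogain", n_features = 30,
                               seed = 31, grid = small_grid,
                               inner_k = 3, folds = folds)
  expect_identical(attr(res, "rankings")[[1]], attr(res2, "rankings")[[1]])
})

test_that("a permuted-label null calibrates accuracy to the majority rate", {
  tab <- fixture_cohort_table()
  subjects <- unique(tab[, c("subject_id", "label")])
  maj <- 100 * max(table(tab$label)) / nrow(tab)
  accs <- c()
  for (rep in 1:2) {
    tabp <- tab
    set.seed(400 + rep)
    perm <- stats::setNames(sample(subjects$label), subjects$subject_id)
    tabp$label <- perm[tabp$subject_id]
    res <- evaluate_feature_set(tabp, feature_set_spec("Mul1"),
                                selector = "infogain", n_features = 20,
                                k = 5, seed = 500 + rep,
                                grid = svm_grid(-2, 2, by = 2), inner_k = 3)
    accs <- c(accs, res$Acc)
  }
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - maj), 3 * se + 1e-9)
})
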