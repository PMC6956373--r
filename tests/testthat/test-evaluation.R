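test_that("confusion-based metrics match hand arithmetic and a recount", {
  conf <- list(TP = 10, FP = 0, TN = 5, FN = 2)
  expect_equal(classwise_accuracy(conf, "stress"), 100)
  expect_equal(classwise_accuracy(list(TP = 3, FP = 1, TN = 0, FN = 0),
                                  "stress"), 75)
  expect_equal(average_accuracy(list(TP = 30, TN = 29, FP = 11, FN = 10)),
               73.75)
  expect_true(is.na(classwise_accuracy(list(TP = 0, FP = 0, TN = 5, FN = 5),
                                       "stress")))

  set.seed(1)
  truth <- sample(0:1, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.3, 1 - truth, truth)
  conf <- confusion_counts(truth, pred)
  expect_equal(conf$TP + conf$FP + conf$TN + conf$FN, 200)
  expect_equal(average_accuracy(conf), 100 * mean(truth == pred))
  expect_equal(classwise_accuracy(conf, "stress"),
               100 * sum(truth == 1 & pred == 1) / sum(pred == 1))
  expect_equal(classwise_recall(conf, "stress"),
               100 * sum(truth == 1 & pred == 1) / sum(truth == 1))
})

test_that("average accuracy is label-swap invariant, class-wise values swap", {
  conf <- list(TP = 12, FP = 3, TN = 20, FN = 5)
  swapped <- list(TP = 20, FP = 5, TN = 12, FN = 3)
  expect_equal(average_accuracy(conf), average_accuracy(swapped))
  expect_equal(classwise_accuracy(conf, "stress"),
               classwise_accuracy(swapped, "calm"))
})

test_that("full-rank PCA reconstructs and isotropic data spreads variance", {
  set.seed(2)
  x <- matrix(rnorm(100 * 4), 100, 4) %*% matrix(rnorm(16), 4, 4)
  pr <- pca_project(x, n_components = 4)
  xs <- scale(x)
  # a full orthogonal basis loses nothing: all pairwise distances survive
  expect_lt(max(abs(dist(pr$scores) - dist(xs))), 1e-8)
  expect_error(pca_project(x, n_components = 5), "exceeds rank")
  expect_error(pca_project(cbind(x, 1), 2), "constant column")

  set.seed(3)
  iso <- matrix(rnorm(2000 * 5), 2000, 5)
  ev <- pca_project(iso, 2)$explained_variance
  expect_true(all(abs(ev - 0.2) < 0.05))
})

test_that("a duplicated column raises the leading variance share", {
  set.seed(4)
  x <- matrix(rnorm(200 * 3), 200, 3)
  ev1 <- pca_project(x, 1)$explained_variance[1]
  ev2 <- pca_project(cbind(x, x[, 1] + rnorm(200, sd = 1e-6)),
                     1)$explained_variance[1]
  expect_gt(ev2, ev1)
  # eigendecomposition oracle for the variance shares
  eg <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(unname(pca_project(x, 1)$explained_variance),
               eg / sum(eg), tolerance = 1e-10)
})

test_that("one-way ANOVA matches its closed-form special cases", {
  expect_equal(one_way_anova(list(1:5, 1:5, 1:5))$F, 0)
  g1 <- rnorm(12, 1); g2 <- rnorm(15, 2)
  a <- one_way_anova(list(g1, g2))
  t2 <- stats::t.test(g1, g2, var.equal = TRUE)$statistic^2
  expect_lt(abs(a$F - t2), 1e-9)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 25)
  # perfect fit: aov warns about the unreliable summary, F is reported Inf
  expect_equal(suppressWarnings(one_way_anova(list(c(1, 1), c(2, 2)))$F), Inf)
})

test_that("published fixtures carry 25 datasets and the merged summary", {
  tab <- published_dataset_accuracies()
  expect_equal(nrow(tab), 25)
  expect_identical(names(tab), c("dataset", "participant_id", "pca_knn",
                                 "all_features_knn", "proposed"))
  merged <- published_merged_accuracies()
  expect_equal(unname(merged["proposed"]), 73.38)
})

test_that("run_method produces coherent reports for all three variants", {
  spec <- small_spec(seed = 81, n_trials = 16, n_channels = 4,
                     duration_s = 5)
  study <- generate_study(spec)
  ds <- assemble_datasets(study$trials, study$ratings)[[1]]
  fm <- extract_features(ds)
  for (v in c("proposed", "pca_knn", "all_features_knn")) {
    rp <- run_method(v, fm, seed = 9)
    expect_s3_class(rp, "method_report")
    total <- with(rp$confusion, TP + FP + TN + FN)
    expect_equal(total, rp$n_test)
    expect_true(rp$average_accuracy >= 0 && rp$average_accuracy <= 100)
    expect_true(rp$chosen_k %in% seq(1, 19, 2))
  }
  # reproducible under the same master seed
  r1 <- run_method("proposed", fm, seed = 10)
  r2 <- run_method("proposed", fm, seed = 10)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$selected_features, r2$selected_features)
})

test_that("decrement arithmetic recovers the merged-comparison columns", {
  acc <- c(pca_knn = 65.62, all_features_knn = 69.26, proposed = 73.38)
  dec <- accuracy_decrements(acc)
  expect_equal(unname(dec["all_features_knn"]), 4.12)
  expect_equal(unname(dec["pca_knn"]), 7.76)
})
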