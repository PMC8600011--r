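test_that("regression metrics match direct formula evaluation", {
  y <- c(0, 1, 2, 3); p <- c(0.1, 0.9, 2.2, 2.8)
  m <- evaluate_regression(y, p)
  expect_equal(unname(m["pearson"]), ref_pearson(y, p), tolerance = 1e-9)
  expect_equal(unname(m["spearman"]),
               ref_pearson(rank(y), rank(p)), tolerance = 1e-9)
  expect_equal(unname(m["kendall"]), ref_kendall_b(y, p), tolerance = 1e-9)
  expect_equal(unname(m["rmse"]), sqrt(mean((y - p)^2)), tolerance = 1e-12)

  expect_equal(unname(evaluate_regression(y, y)),
               c(1, 1, 1, 0), tolerance = 1e-12)
  expect_equal(unname(evaluate_regression(y, -y)["pearson"]), -1)
  expect_error(evaluate_regression(y, rep(1, 4)), "zero variance")

  set.seed(7)
  for (i in 1:25) {
    yy <- rnorm(20); pp <- yy + rnorm(20)
    m <- evaluate_regression(yy, pp)
    expect_equal(unname(m["pearson"]), ref_pearson(yy, pp), tolerance = 1e-9)
    expect_equal(unname(m["kendall"]), ref_kendall_b(yy, pp),
                 tolerance = 1e-9)
  }
})

test_that("classification-by-regression removes the neutral band and matches oracles", {
  y <- c(-2, -1.5, -0.3, 0.2, 0.5, 1.1, 2.0)
  p <- c(-1.8, 0.4, 1, -1, 2, 0.9, 1.7)
  r <- classification_by_regression(y, p)
  # the three |ddg| <= 0.5 records are excluded
  expect_equal(unname(r["n_used"]), 4)
  keep <- abs(y) > 0.5
  tp <- sum(y[keep] > 0 & p[keep] > 0); tn <- sum(y[keep] < 0 & p[keep] < 0)
  fp <- sum(y[keep] < 0 & p[keep] > 0); fn <- sum(y[keep] > 0 & p[keep] < 0)
  expect_equal(unname(r["accuracy"]), (tp + tn) / 4)
  expect_equal(unname(r["mcc"]), ref_mcc(tp, tn, fp, fn), tolerance = 1e-9)
  expect_equal(unname(r["auc"]), ref_auc(y[keep] > 0, p[keep]),
               tolerance = 1e-9)

  # perfectly separated toy
  y2 <- c(-2, -1, 1, 2); p2 <- c(-2.2, -0.8, 1.1, 1.9)
  r2 <- classification_by_regression(y2, p2)
  expect_equal(unname(r2[c("accuracy", "f1", "mcc", "auc")]), rep(1, 4))
  # closed-form MCC check: TP=8 FP=2 TN=7 FN=3 -> 50/sqrt(9900) ~ 0.50
  expect_equal(ref_mcc(8, 7, 2, 3), 50 / sqrt(9900), tolerance = 1e-12)
  expect_equal(ref_mcc(8, 7, 2, 3), 0.5, tolerance = 0.01)
  expect_equal(nabind:::.mcc(8, 7, 2, 3), ref_mcc(8, 7, 2, 3))
  expect_error(classification_by_regression(c(1, 2, 3), c(1, 2, 3)),
               "single class")
})

test_that("hot-spot metrics agree with confusion-table oracles on random draws", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(10:40, 1)
    truth <- rnorm(n, -1, 1.5)
    pred <- truth + rnorm(n, 0, 1.5)
    cutoff <- sample(c(-2, -1), 1)
    m <- evaluate_hotspot(pred, truth, cutoff)
    th <- truth <= cutoff; ph <- pred <= cutoff
    tp <- sum(th & ph); tn <- sum(!th & !ph)
    fp <- sum(!th & ph); fn <- sum(th & !ph)
    if (tp + fn > 0) expect_equal(unname(m["sen"]), tp / (tp + fn))
    if (tn + fp > 0) expect_equal(unname(m["spe"]), tn / (tn + fp))
    if (tp + fp > 0) expect_equal(unname(m["pre"]), tp / (tp + fp))
    expect_equal(unname(m["acc"]), (tp + tn) / n)
    expect_equal(unname(m["mcc"]), ref_mcc(tp, tn, fp, fn), tolerance = 1e-9)
  }
  expect_equal(unname(evaluate_hotspot(c(-3, -1, 0), c(-3, -1, 0), -2)),
               c(1, 1, 1, 1, 1, 1))
  expect_equal(unname(evaluate_hotspot(c(0, 0, 0), c(-3, -3, 0), -2)["sen"]),
               0)
})

test_that("outlier trimming drops the worst residuals deterministically", {
  set.seed(5)
  y <- rnorm(10); p <- y
  p[4] <- y[4] + 50
  t0 <- outlier_trimmed_metrics(y, p, fraction = 0)
  expect_equal(t0$metrics, evaluate_regression(y, p))
  t1 <- outlier_trimmed_metrics(y, p, fraction = 0.1)
  expect_equal(which(!t1$kept), 4L)
  expect_equal(unname(t1$metrics["pearson"]), 1, tolerance = 1e-12)
  # trimmed RMSE never exceeds untrimmed
  for (i in 1:20) {
    yy <- rnorm(30); pp <- yy + rnorm(30, 0, 2)
    tr <- outlier_trimmed_metrics(yy, pp, 0.1)
    expect_lte(unname(tr$metrics["rmse"]),
               unname(evaluate_regression(yy, pp)["rmse"]))
    expect_equal(tr$n_dropped, 3)
  }
})

test_that("group k-fold never splits a group and respects fold counts", {
  set.seed(3)
  groups <- sample(paste0("g", 1:12), 150, replace = TRUE)
  for (k in c(5, 10)) {
    folds <- group_kfold(groups, k)
    expect_equal(sort(unique(folds)), 1:k)
    tab <- table(groups, folds)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  expect_error(group_kfold(groups, 13), "configuration error")
})

test_that("cross-validation pools out-of-fold predictions with group integrity", {
  set.seed(21)
  n <- 200
  groups <- sample(paste0("c", 1:8), n, replace = TRUE)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- 1.5 * X[, 1] - 2 * X[, 2] + 0.5 * X[, 3] + rnorm(n, 0, 0.2)
  cv <- cross_validate(X, y, groups, list(kind = "group-k-fold", k = 5),
                       model_config(num_trees = 150))
  expect_equal(length(cv$predictions), n)
  expect_false(anyNA(cv$predictions))
  for (f in unique(cv$folds)) {
    expect_length(intersect(unique(groups[cv$folds == f]),
                            unique(groups[cv$folds != f])), 0)
  }
  expect_gt(unname(cv$report$regression["pearson"]), 0.9)

  # leave-one-complex-out: one fold per group, folds partition the records
  loco <- cross_validate(X, y, groups, list(kind = "leave-one-complex-out"),
                         model_config(num_trees = 100))
  expect_equal(length(unique(loco$folds)), 8)
  expect_equal(sum(table(loco$folds)), n)

  # noise monotonicity: CV quality degrades as sigma grows
  y_hi <- 1.5 * X[, 1] - 2 * X[, 2] + 0.5 * X[, 3] + rnorm(n, 0, 0.5)
  cv_hi <- cross_validate(X, y_hi, groups,
                          list(kind = "group-k-fold", k = 5),
                          model_config(num_trees = 150))
  expect_gt(unname(cv$report$regression["pearson"]),
            unname(cv_hi$report$regression["pearson"]) - 0.02)
})

test_that("forward/reverse partners stay in one fold via shared groups", {
  ds <- data.frame(complex_id = rep(paste0("c", 1:6), each = 4),
                   construct = rep("A R45G", 24),
                   ddg = rnorm(24, -1, 1),
                   group_id = rep(paste0("c", 1:6), each = 4),
                   stringsAsFactors = FALSE)
  aug <- augment_with_reverse(ds)
  folds <- group_kfold(aug$group_id, 3)
  rev <- which(aug$provenance == "reverse")
  expect_true(all(folds[rev] == folds[aug$partner[rev]]))
})

test_that("greedy selection finds the informative feature and is deterministic", {
  set.seed(31)
  n <- 120
  groups <- sample(paste0("g", 1:6), n, replace = TRUE)
  X <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(NULL, paste0("f", 1:11)))
  y <- X[, 7] + rnorm(n, 0, 0.05)
  cfg <- model_config(num_trees = 60, k = 3)
  sel <- greedy_forward_selection(X, y, groups, cfg)
  expect_equal(sel[1], "f7")
  # cap at 1
  cfg1 <- model_config(num_trees = 60, k = 3, max_selected_features = 1)
  expect_length(greedy_forward_selection(X, y, groups, cfg1), 1)
  # determinism under the same seed
  expect_identical(sel, greedy_forward_selection(X, y, groups, cfg))
  expect_error(greedy_forward_selection(X, rep(1, n), groups, cfg),
               "degenerate target")
})

test_that("training bundles enforce the schema fingerprint", {
  set.seed(41)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(100, 0, 0.1)
  m <- train_model(X, y)
  p1 <- predict_ddg(m, X)
  expect_identical(p1, predict_ddg(m, X))  # deterministic, seeded trees
  expect_true(all(is.finite(p1)))
  bad <- X; colnames(bad) <- c("a", "b", "zz")
  expect_error(predict_ddg(m, bad), "schema mismatch")
  # persistence round trip
  tf <- tempfile(fileext = ".rds")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_equal(predict_ddg(m2, X), p1)
})
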