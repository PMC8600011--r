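## Regression model and evaluation protocol: extremely-randomized-trees
## regression (via ranger), greedy bottom-up feature selection, group-aware
## k-fold and leave-one-complex-out cross-validation, regression /
## classification-by-regression / hot-spot metric suites and outlier-trimmed
## metrics.

#' Model configuration
#'
#' @param algorithm `"extratrees"` (default), `"randomforest"` or `"svr"`.
#' @param num_trees Ensemble size (300).
#' @param seed Random seed controlling tree construction and fold
#'   assignment (42).
#' @param max_selected_features Cap for greedy forward selection (13).
#' @param min_improvement Selection stops when the cross-validated Pearson
#'   gain falls below this (1e-3).
#' @param k Default fold count for selection-internal cross-validation (5).
#' @return A `ModelConfig` list.
#' @export
model_config <- function(algorithm = c("extratrees", "randomforest", "svr"),
                         num_trees = 300, seed = 42,
                         max_selected_features = 13,
                         min_improvement = 1e-3, k = 5) {
  structure(list(algorithm = match.arg(algorithm), num_trees = num_trees,
                 seed = seed, max_selected_features = max_selected_features,
                 min_improvement = min_improvement, k = k),
            class = "ModelConfig")
}

.fit_model <- function(X, y, config) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  if (config$algorithm == "svr") {
    return(e1071::svm(.y ~ ., data = df))
  }
  extratrees <- config$algorithm == "extratrees"
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = config$num_trees,
    mtry = max(1L, ncol(X)),
    splitrule = if (extratrees) "extratrees" else "variance",
    num.random.splits = 1,
    replace = !extratrees,
    sample.fraction = if (extratrees) 1 else 0.632,
    seed = config$seed, num.threads = 1
  )
}

.predict_model <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  if (inherits(fit, "svm")) return(as.numeric(stats::predict(fit, df)))
  as.numeric(stats::predict(fit, data = df, num.threads = 1)$predictions)
}

#' Group-aware fold assignment
#'
#' Whole groups are assigned to folds (largest groups first onto the
#' currently smallest fold), so no group ever spans folds.
#'
#' @param groups Group id per record.
#' @param k Number of folds; must not exceed the number of distinct groups.
#' @param seed Seed shuffling equal-sized groups deterministically.
#' @return Integer fold id (1..k) per record.
#' @export
group_kfold <- function(groups, k, seed = 42) {
  ug <- unique(groups)
  if (k > length(ug)) {
    stop(sprintf("configuration error: %d folds but only %d groups",
                 k, length(ug)))
  }
  sizes <- table(groups)[ug]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ord <- sample(seq_along(ug))
  ug <- ug[ord]; sizes <- sizes[ord]
  ug <- ug[order(-sizes)]; sizes <- sizes[order(-sizes)]
  fold_of <- integer(length(ug)); fold_load <- integer(k)
  for (i in seq_along(ug)) {
    f <- which.min(fold_load)
    fold_of[i] <- f
    fold_load[f] <- fold_load[f] + sizes[i]
  }
  fold_of[match(groups, ug)]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Group-based cross-validation of the ddG regressor
#'
#' @param X Feature matrix (records x features).
#' @param y ddG targets (kcal/mol).
#' @param groups Group id per record (complexes; forward/reverse partners
#'   must share a group id).
#' @param scheme List: `kind` = `"group-k-fold"` (uses `k`) or
#'   `"leave-one-complex-out"` (one fold per group).
#' @param config A [model_config()].
#' @return List: `report` (an `EvalReport`), `predictions` (pooled
#'   out-of-fold predictions, one per record), `folds` (fold id per record),
#'   `per_fold_pearson`.
#' @export
cross_validate <- function(X, y, groups,
                           scheme = list(kind = "group-k-fold", k = 5),
                           config = model_config()) {
  n <- nrow(X)
  stopifnot(length(y) == n, length(groups) == n)
  folds <- if (identical(scheme$kind, "leave-one-complex-out")) {
    match(groups, unique(groups))
  } else {
    group_kfold(groups, scheme$k, config$seed)
  }
  preds <- rep(NA_real_, n)
  per_fold <- numeric(0)
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- .fit_model(X[!test, , drop = FALSE], y[!test], config)
    preds[test] <- .predict_model(fit, X[test, , drop = FALSE])
    if (sum(test) >= 3 && stats::sd(y[test]) > 0 &&
        stats::sd(preds[test]) > 0) {
      per_fold <- c(per_fold, stats::cor(y[test], preds[test]))
    }
  }
  stopifnot(!anyNA(preds))
  list(report = evaluation_report(y, preds), predictions = preds,
       folds = folds, per_fold_pearson = per_fold)
}

#' Regression metrics
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 3).
#' @return Named vector: `pearson`, `spearman`, `kendall` (tau-b), `rmse`.
#' @export
evaluate_regression <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("correlation undefined: zero variance")
  }
  c(pearson = stats::cor(y_true, y_pred),
    spearman = stats::cor(y_true, y_pred, method = "spearman"),
    kendall = stats::cor(y_true, y_pred, method = "kendall"),
    rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Direction-of-change classification derived from the regressor
#'
#' Records whose true ddG lies in the neutral band (|ddg| <= band) are
#' removed; the true class is the sign of the remaining true values, the
#' predicted class the sign of the prediction, and the AUC treats the raw
#' prediction as a score for the "increasing" class.  F1 is reported for the
#' "increasing" class.
#'
#' @param y_true,y_pred ddG vectors (kcal/mol).
#' @param band Neutral half-width (0.5 kcal/mol).
#' @return Named vector: `accuracy`, `f1`, `mcc`, `auc`, `n_used`.
#' @export
classification_by_regression <- function(y_true, y_pred, band = 0.5) {
  keep <- abs(y_true) > band
  yt <- y_true[keep]; yp <- y_pred[keep]
  true_cls <- yt > 0
  if (length(unique(true_cls)) < 2L) {
    stop("single class after removing neutral records")
  }
  pred_cls <- yp > 0
  tp <- sum(true_cls & pred_cls); tn <- sum(!true_cls & !pred_cls)
  fp <- sum(!true_cls & pred_cls); fn <- sum(true_cls & !pred_cls)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = factor(true_cls, levels = c(FALSE, TRUE)),
    predictor = yp, direction = "<", quiet = TRUE)))
  c(accuracy = (tp + tn) / length(yt),
    f1 = .f1(tp, fp, fn), mcc = .mcc(tp, tn, fp, fn), auc = auc,
    n_used = length(yt))
}

.f1 <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

.mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Regression metrics after trimming the worst-predicted records
#'
#' Drops the `ceiling(fraction * n)` records with the largest absolute
#' residual (ties resolved by record order) and recomputes the regression
#' metrics.
#'
#' @param y_true,y_pred ddG vectors.
#' @param fraction Fraction to drop (default 0.10; 0 <= fraction < 1).
#' @return List: `metrics` (as [evaluate_regression()]), `kept` (logical),
#'   `n_dropped`.
#' @export
outlier_trimmed_metrics <- function(y_true, y_pred, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(y_true)
  n_drop <- ceiling(fraction * n)
  kept <- rep(TRUE, n)
  if (n_drop > 0) {
    ord <- order(-abs(y_true - y_pred), seq_len(n))
    kept[ord[seq_len(n_drop)]] <- FALSE
  }
  list(metrics = evaluate_regression(y_true[kept], y_pred[kept]),
       kept = kept, n_dropped = n_drop)
}

#' Hot-spot benchmark metrics
#'
#' Both vectors are binarized at the cutoff (hot-spot iff ddG <= cutoff) and
#' the standard confusion-table metrics are reported; intended for
#' alanine-mutation records.
#'
#' @param pred_ddg,true_ddg ddG vectors (or an already-binary prediction
#'   coded as ddG values; non-predicted residues from external tools should
#'   be ingested as non-hot-spots).
#' @param cutoff Hot-spot threshold, kcal/mol.
#' @return Named vector: `sen`, `spe`, `pre`, `acc`, `f1`, `mcc`.
#' @export
evaluate_hotspot <- function(pred_ddg, true_ddg, cutoff = -2.0) {
  stopifnot(length(pred_ddg) == length(true_ddg))
  if (length(true_ddg) == 0L) stop("empty record set after filtering")
  pred_hs <- pred_ddg <= cutoff
  true_hs <- true_ddg <= cutoff
  tp <- sum(true_hs & pred_hs); tn <- sum(!true_hs & !pred_hs)
  fp <- sum(!true_hs & pred_hs); fn <- sum(true_hs & !pred_hs)
  c(sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    pre = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    acc = (tp + tn) / length(true_ddg),
    f1 = .f1(tp, fp, fn),
    mcc = .mcc(tp, tn, fp, fn))
}

#' Full evaluation report
#'
#' @param y_true,y_pred ddG vectors.
#' @param band Neutral band half-width for the classification view.
#' @param trim_fraction Fraction for the outlier-trimmed view.
#' @return An `EvalReport` list: `regression`, `classification`,
#'   `trimmed` and `n`.
#' @export
evaluation_report <- function(y_true, y_pred, band = 0.5,
                              trim_fraction = 0.10) {
  cls <- tryCatch(classification_by_regression(y_true, y_pred, band),
                  error = function(e) NULL)
  structure(list(regression = evaluate_regression(y_true, y_pred),
                 classification = cls,
                 trimmed = outlier_trimmed_metrics(y_true, y_pred,
                                                   trim_fraction)$metrics,
                 n = length(y_true)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  r <- x$regression
  cat(sprintf("EvalReport (n = %d)\n", x$n))
  cat(sprintf("  regression: pearson %.3f  spearman %.3f  kendall %.3f  rmse %.3f\n",
              r["pearson"], r["spearman"], r["kendall"], r["rmse"]))
  t <- x$trimmed
  cat(sprintf("  10%% trimmed: pearson %.3f  rmse %.3f\n",
              t["pearson"], t["rmse"]))
  if (!is.null(x$classification)) {
    c <- x$classification
    cat(sprintf("  direction:  acc %.3f  f1 %.3f  mcc %.3f  auc %.3f (n_used %d)\n",
                c["accuracy"], c["f1"], c["mcc"], c["auc"], c["n_used"]))
  }
  invisible(x)
}

#' Greedy bottom-up feature selection
#'
#' Starting from the empty set, each round adds the feature whose addition
#' maximizes the group-cross-validated Pearson correlation of the model;
#' stops when the improvement drops below `config$min_improvement` or the
#' selection reaches `config$max_selected_features`.  Ties break toward the
#' earlier feature in schema order.
#'
#' @param X Feature matrix with column names.
#' @param y Targets; must have nonzero variance.
#' @param groups Group ids for the internal cross-validation.
#' @param config A [model_config()].
#' @return Character vector of selected feature names, in selection order.
#' @export
greedy_forward_selection <- function(X, y, groups, config = model_config()) {
  if (stats::sd(y) == 0) stop("degenerate target: zero variance")
  candidates <- colnames(X)
  stopifnot(length(candidates) >= 1L)
  selected <- character(0)
  best_score <- -Inf
  scheme <- list(kind = "group-k-fold", k = min(config$k,
                                                length(unique(groups))))
  repeat {
    scores <- vapply(setdiff(candidates, selected), function(f) {
      cols <- c(selected, f)
      cv <- cross_validate(X[, cols, drop = FALSE], y, groups, scheme, config)
      as.numeric(cv$report$regression["pearson"])
    }, numeric(1))
    if (length(scores) == 0L) break
    best_new <- names(scores)[which.max(scores)]  # first max = schema order
    if (max(scores) - best_score < config$min_improvement &&
        length(selected) > 0L) break
    if (max(scores) > best_score || length(selected) == 0L) {
      selected <- c(selected, best_new)
      best_score <- max(scores)
    } else break
    if (length(selected) >= config$max_selected_features) break
  }
  selected
}

#' Train a ddG model; predict with it
#'
#' The returned bundle stores the fitted ensemble, the feature names used
#' and a fingerprint of the full schema; [predict_ddg()] refuses feature
#' matrices whose schema fingerprint differs.
#'
#' @param X Feature matrix (columns named by [feature_schema()] or a
#'   selected subset).
#' @param y ddG targets (kcal/mol).
#' @param config A [model_config()].
#' @param features Optional character vector restricting training to these
#'   columns.
#' @return A `TrainedModel` list: `fit`, `features`, `schema_hash`,
#'   `config`.
#' @export
train_model <- function(X, y, config = model_config(), features = NULL) {
  if (is.null(features)) features <- colnames(X)
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0L) stop("features absent from matrix: ",
                                 paste(missing, collapse = ", "))
  fit <- .fit_model(X[, features, drop = FALSE], y, config)
  structure(list(fit = fit, features = features,
                 schema_hash = .schema_hash(colnames(X)),
                 config = config),
            class = "TrainedModel")
}

#' @rdname train_model
#' @param model A `TrainedModel`.
#' @param newX Feature matrix with the same schema as at training time.
#' @param check_schema Verify the schema fingerprint (default TRUE).
#' @return Numeric vector of predicted ddG values (kcal/mol).
#' @export
predict_ddg <- function(model, newX, check_schema = TRUE) {
  if (check_schema && !identical(.schema_hash(colnames(newX)),
                                 model$schema_hash)) {
    stop("version error: feature schema mismatch with the trained model")
  }
  .predict_model(model$fit, newX[, model$features, drop = FALSE])
}

#' Save / load a trained model bundle
#' @param model A `TrainedModel`; `path` an `.rds` path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "TrainedModel")) stop("not a nabind model bundle: ", path)
  m
}
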