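#' Train a random forest predicting convergence strength
#'
#' Regression forest mapping KO-set similarity features (BP/CC/MF semantic
#' similarity, brain expression correlation, set size, cell type) to a
#' convergence outcome. Rows are split 70/30 into training and held-out
#' testing sets, stratified by cell type; the forest (500 trees,
#' `mtry = ceiling(p / 3)`) is trained with bootstrap aggregation and
#' reports out-of-bag percent variance explained plus permutation
#' importances (%IncMSE and node-purity increase). Cell type is one-hot
#' encoded. Fully deterministic under the seed.
#'
#' @param data Data frame with feature columns `bp_score`, `cc_score`,
#'   `mf_score`, `brain_expr_corr`, `n_kos`, `cell_type` and the outcome
#'   column `convergence`; no missing feature values in training rows.
#' @param train_frac Training fraction (default 0.70).
#' @param n_trees Number of trees (default 500).
#' @param seed Seed for the split and the forest.
#' @return List of class `convergence_model`: `forest`, `train_idx`,
#'   `test_idx`, `metrics` (`pct_var_explained`, `importances`, and holdout
#'   `rmse` / `pearson_r` via [evaluate_model()]), `feature_levels`,
#'   `feature_medians`, `target_range`, `degenerate` flag.
#' @export
train_convergence_model <- function(data, train_frac = 0.70, n_trees = 500L,
                                    seed = 1L) {
  req <- c("bp_score", "cc_score", "mf_score", "brain_expr_corr", "n_kos",
           "cell_type", "convergence")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(data) < 30) stop("need >= 30 rows", call. = FALSE)
  feat_num <- c("bp_score", "cc_score", "mf_score", "brain_expr_corr", "n_kos")
  if (anyNA(data[, c(feat_num, "convergence")])) {
    stop("training rows must have no missing feature or outcome values",
         call. = FALSE)
  }
  levels_ct <- sort(unique(as.character(data$cell_type)))
  X <- .encode_features(data, levels_ct)
  y <- data$convergence
  degenerate <- stats::sd(y) == 0
  .with_seed(seed, {
    # Stratified split by cell type.
    train_idx <- unlist(lapply(levels_ct, function(ct) {
      rows <- which(as.character(data$cell_type) == ct)
      sample(rows, max(1L, round(train_frac * length(rows))))
    }))
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(nrow(data)), train_idx)
    mtry <- max(1L, ceiling(ncol(X) / 3))
    fit_forest <- function() randomForest::randomForest(
      x = X[train_idx, , drop = FALSE], y = y[train_idx],
      ntree = n_trees, mtry = mtry, importance = TRUE)
    # a constant target triggers a regression-sanity warning; it is already
    # flagged via `degenerate`
    forest <- if (degenerate) suppressWarnings(fit_forest()) else fit_forest()
    imp <- randomForest::importance(forest)
    metrics <- list(
      pct_var_explained = 100 * (1 - utils::tail(forest$mse, 1) /
                                   max(stats::var(y[train_idx]), 1e-300)),
      importances = data.frame(feature = rownames(imp),
                               pct_inc_mse = imp[, "%IncMSE"],
                               node_purity = imp[, "IncNodePurity"],
                               row.names = NULL, stringsAsFactors = FALSE))
    model <- structure(list(forest = forest, train_idx = train_idx,
                            test_idx = test_idx,
                            feature_levels = levels_ct,
                            feature_medians = apply(X[train_idx, , drop = FALSE],
                                                    2, stats::median),
                            target_range = range(y[train_idx]),
                            degenerate = degenerate),
                       class = "convergence_model")
    if (length(test_idx) >= 3) {
      holdout <- data[test_idx, , drop = FALSE]
      metrics <- c(metrics, evaluate_model(model, holdout))
    }
    model$metrics <- metrics
    model
  })
}

.encode_features <- function(data, levels_ct) {
  X <- data[, c("bp_score", "cc_score", "mf_score", "brain_expr_corr",
                "n_kos"), drop = FALSE]
  for (ct in levels_ct) {
    X[[paste0("cell_type_", make.names(ct))]] <-
      as.numeric(as.character(data$cell_type) == ct)
  }
  as.matrix(X)
}

#' Evaluate a convergence model on held-out rows
#'
#' Root mean squared error and Pearson correlation (with two-sided p)
#' between observed and predicted convergence.
#'
#' @param model A `convergence_model`.
#' @param holdout Data frame with the feature columns and `convergence`,
#'   disjoint from the training rows.
#' @return List with `rmse`, `pearson_r`, `pearson_p` (correlation `NA`
#'   when fewer than 3 holdout rows).
#' @export
evaluate_model <- function(model, holdout) {
  pred <- predict_convergence(model, holdout)
  obs <- holdout$convergence
  rmse <- sqrt(mean((obs - pred)^2))
  if (length(obs) < 3 || stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    return(list(rmse = rmse, pearson_r = NA_real_, pearson_p = NA_real_))
  }
  ct <- stats::cor.test(obs, pred)
  list(rmse = rmse, pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}

#' Predict convergence strength for new KO-set feature rows
#'
#' Missing numeric feature values are imputed by the training medians (with
#' a message); unseen cell-type levels are an error.
#'
#' @param model A `convergence_model`.
#' @param features Data frame with the feature columns.
#' @return Numeric vector of predictions (finite; bounded by the training
#'   target range, a property of regression forests).
#' @export
predict_convergence <- function(model, features) {
  unseen <- setdiff(unique(as.character(features$cell_type)),
                    model$feature_levels)
  if (length(unseen)) {
    stop("unknown cell_type level(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  X <- .encode_features(features, model$feature_levels)
  if (anyNA(X)) {
    message("imputing missing feature values with training medians")
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- model$feature_medians[[colnames(X)[j]]]
    }
  }
  as.numeric(stats::predict(model$forest, X))
}
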