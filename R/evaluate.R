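#' Stratified k-fold plan with train/validation/test roles
#'
#' Shuffles the dataset (stratified by label), divides it into `k` near-equal
#' folds, and derives `k` rotations: rotation j uses fold j as the test
#' fold, fold (j mod k) + 1 as the validation fold, and the remaining k - 2
#' folds for training — the 8/1/1 role split when k = 10.
#'
#' @param data A data frame with columns `id`, `seq`, `label` (only `label`
#'   and the row count matter).
#' @param k Number of folds; at least 3 (train/validation/test roles need
#'   three distinct folds).
#' @param seed Integer seed for the stratified shuffle.
#' @return An object of class `fourmc_folds`: tibble `assignment` (row
#'   `index`, `label`, `fold`) plus `k` and `seed`. Rotation r's roles are
#'   recoverable with [fold_roles()].
#' @export
make_folds <- function(data, k = 10L, seed = 1L) {
  data <- as_tibble(data)
  k <- as.integer(k)
  if (k < 3L) abort("`k` must be at least 3 (train/validation/test roles)")
  counts <- table(data$label)
  if (any(counts < k)) {
    abort(paste0("need at least k = ", k, " records per class; have ",
                 paste(counts, collapse = "/")))
  }
  local_rng(seed)
  fold <- integer(nrow(data))
  for (lab in unique(data$label)) {
    idx <- sample(which(data$label == lab))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(
    list(
      assignment = tibble(index = seq_len(nrow(data)),
                          label = data$label, fold = fold),
      k = k, seed = as.integer(seed)
    ),
    class = "fourmc_folds"
  )
}

#' Role indices for one cross-validation rotation
#'
#' @param folds A `fourmc_folds` plan.
#' @param rotation Rotation number in 1..k.
#' @return A list of integer row-index vectors `train`, `validation`, `test`
#'   (pairwise disjoint, jointly covering the dataset).
#' @export
fold_roles <- function(folds, rotation) {
  k <- folds$k
  if (rotation < 1L || rotation > k) abort("`rotation` must be in 1..k")
  test_fold <- rotation
  val_fold <- rotation %% k + 1L
  f <- folds$assignment$fold
  list(
    train = folds$assignment$index[!f %in% c(test_fold, val_fold)],
    validation = folds$assignment$index[f == val_fold],
    test = folds$assignment$index[f == test_fold]
  )
}

#' Confusion counts at a probability threshold
#'
#' @param y_true Binary label vector.
#' @param y_prob Predicted probabilities, aligned with `y_true`.
#' @param threshold Calls are positive when `y_prob >= threshold`. Default
#'   0.5.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    abort("`y_true` and `y_prob` lengths differ")
  }
  call_pos <- y_prob >= threshold
  pos <- y_true == 1
  tibble(
    tp = sum(call_pos & pos), tn = sum(!call_pos & !pos),
    fp = sum(call_pos & !pos), fn = sum(!call_pos & pos)
  )
}

#' Classification metrics from confusion counts
#'
#' Computes the Matthews correlation coefficient
#' MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' accuracy (TP+TN)/total, sensitivity TP/(TP+FN) and specificity
#' TN/(TN+FP). MCC is defined as 0 when any marginal in its denominator is
#' zero (where the formula itself is 0/0).
#'
#' @param counts A data frame with columns `tp`, `tn`, `fp`, `fn` (one row),
#'   e.g. from [confusion_counts()].
#' @return A one-row tibble with columns `mcc`, `acc`, `sn`, `sp`.
#' @export
classification_metrics <- function(counts) {
  # double precision: the product of marginals overflows 32-bit integers
  # already at benchmark-scale counts
  tp <- as.numeric(counts$tp[1]); tn <- as.numeric(counts$tn[1])
  fp <- as.numeric(counts$fp[1]); fn <- as.numeric(counts$fn[1])
  total <- tp + tn + fp + fn
  if (total == 0) abort("empty confusion counts")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  tibble(
    mcc = mcc,
    acc = (tp + tn) / total,
    sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores to trace the ROC
#' curve and integrates it with the trapezoidal rule. The resulting AUC
#' equals the normalized Mann-Whitney U statistic (fraction of
#' positive/negative pairs ranked concordantly, ties counted half).
#'
#' @param y_true Binary labels; both classes must be present.
#' @param y_prob Scores aligned with `y_true`.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) {
    abort("`y_true` and `y_prob` lengths differ")
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs both classes present")
  }
  thresholds <- c(Inf, sort(unique(y_prob), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    call_pos <- y_prob >= thresholds[i]
    tpr[i] <- sum(call_pos & y_true == 1) / n_pos
    fpr[i] <- sum(call_pos & y_true == 0) / n_neg
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(
    roc = tibble(threshold = thresholds, fpr = fpr, tpr = tpr),
    auc = auc
  )
}

#' k-fold cross-validation of the classifier
#'
#' Encodes the dataset once, builds a stratified [make_folds()] plan, and for
#' each of the k rotations trains a fresh model on the 8 training folds
#' (early-stopped against the validation fold) and evaluates it on the test
#' fold, so every record is tested exactly once and never by a model that saw
#' it. Reports per-fold MCC/ACC/Sn/Sp/AUC on both the validation and test
#' folds and their means (the aggregation convention used for these
#' benchmarks).
#'
#' @param data A data frame with columns `id`, `seq`, `label`.
#' @param scheme Encoding scheme name.
#' @param spec A [cnn_spec()].
#' @param config A [train_config()]; per-fold seeds are derived from
#'   `config$seed`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold plan.
#' @param keep_models Keep the k trained models in the result (default
#'   `FALSE`; the best-AUC fold's model is always kept as `$best_model`).
#' @return An object of class `fourmc_cv`: `per_fold` tibble (one row per
#'   rotation), `summary` (mean metrics), `folds`, `roc` (per-fold test-fold
#'   ROC points), `predictions` (record index, label, out-of-fold
#'   probability), `best_model`.
#' @export
cross_validate <- function(data, scheme, spec = cnn_spec(),
                           config = train_config(), k = 10L, seed = 1L,
                           keep_models = FALSE) {
  data <- as_tibble(data)
  tensor <- encode_dataset(data, scheme)
  folds <- make_folds(data, k = k, seed = seed)

  fold_rows <- vector("list", k)
  rocs <- vector("list", k)
  models <- vector("list", k)
  preds <- vector("list", k)
  for (r in seq_len(k)) {
    roles <- fold_roles(folds, r)
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    net <- train_cnn(
      tensor$x[roles$train, , , drop = FALSE], tensor$y[roles$train],
      tensor$x[roles$validation, , , drop = FALSE], tensor$y[roles$validation],
      spec = spec, config = cfg, scheme = scheme
    )
    p_test <- predict(net, tensor$x[roles$test, , , drop = FALSE])
    p_val <- predict(net, tensor$x[roles$validation, , , drop = FALSE])
    test_m <- classification_metrics(
      confusion_counts(tensor$y[roles$test], p_test)
    )
    val_m <- classification_metrics(
      confusion_counts(tensor$y[roles$validation], p_val)
    )
    test_roc <- roc_auc(tensor$y[roles$test], p_test)
    val_auc <- roc_auc(tensor$y[roles$validation], p_val)$auc
    fold_rows[[r]] <- dplyr::bind_cols(
      tibble(fold = r), test_m, tibble(auc = test_roc$auc),
      dplyr::rename_with(val_m, ~paste0("val_", .x)),
      tibble(val_auc = val_auc,
             n_train = length(roles$train),
             n_validation = length(roles$validation),
             n_test = length(roles$test),
             best_epoch = net$best_epoch)
    )
    rocs[[r]] <- dplyr::mutate(test_roc$roc, fold = r, .before = 1)
    preds[[r]] <- tibble(index = roles$test, label = tensor$y[roles$test],
                         prob = p_test, fold = r)
    models[[r]] <- net
  }

  per_fold <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("mcc", "acc", "sn", "sp", "auc",
                   "val_mcc", "val_acc", "val_sn", "val_sp", "val_auc")
  summary <- dplyr::summarise(
    per_fold, dplyr::across(dplyr::all_of(metric_cols), mean)
  )
  best_fold <- which.max(per_fold$auc)
  structure(
    list(
      per_fold = per_fold, summary = summary, folds = folds,
      roc = dplyr::bind_rows(rocs),
      predictions = dplyr::bind_rows(preds),
      best_model = models[[best_fold]], best_fold = best_fold,
      models = if (keep_models) models else NULL,
      scheme = scheme, spec = spec, config = config, k = k, seed = seed
    ),
    class = "fourmc_cv"
  )
}

#' @export
print.fourmc_cv <- function(x, ...) {
  cat("<fourmc_cv> ", x$k, "-fold cross-validation, scheme ", x$scheme,
      "\n  mean test metrics:\n", sep = "")
  print(x$summary[, c("mcc", "acc", "sn", "sp", "auc")])
  invisible(x)
}

#' Export a cross-validation report
#'
#' Writes the per-fold metric rows plus a final `mean` row as CSV, and the
#' pooled test-fold ROC points as a second CSV.
#'
#' @param cv A `fourmc_cv` result.
#' @param metrics_path,roc_path Output paths (`roc_path = NULL` skips the
#'   ROC file).
#' @return `metrics_path`, invisibly.
#' @export
write_cv_report <- function(cv, metrics_path, roc_path = NULL) {
  mean_row <- dplyr::mutate(
    cv$summary,
    fold = NA_integer_, n_train = NA_integer_, n_validation = NA_integer_,
    n_test = NA_integer_, best_epoch = NA_integer_, row = "mean"
  )
  per_fold <- dplyr::mutate(cv$per_fold, row = paste0("fold_", .data$fold))
  readr::write_csv(dplyr::bind_rows(per_fold, mean_row), metrics_path)
  if (!is.null(roc_path)) {
    readr::write_csv(cv$roc, roc_path)
  }
  invisible(metrics_path)
}
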