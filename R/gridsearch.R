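#' Hyperparameter grid specification
#'
#' The default candidate lists are the published tuning ranges: number of
#' conv blocks 1-5; filters 8, 12, 16, 22, 32, 42, 64, 128; kernel sizes
#' 2-8, 10, 12, 14; pool size 2 or 4; pool stride 2 or 4; dropout 0.2-0.4.
#' The full Cartesian product has 8000 combinations; restrict the lists for
#' anything run routinely.
#'
#' @param conv_layers,filters,kernel_size,pool_size,pool_stride,dropout
#'   Candidate vectors; all must be non-empty.
#' @return An object of class `fourmc_grid`.
#' @export
grid_spec <- function(conv_layers = c(1L, 2L, 3L, 4L, 5L),
                      filters = c(8L, 12L, 16L, 22L, 32L, 42L, 64L, 128L),
                      kernel_size = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L, 12L, 14L),
                      pool_size = c(2L, 4L),
                      pool_stride = c(2L, 4L),
                      dropout = c(0.2, 0.25, 0.3, 0.35, 0.4)) {
  lists <- list(conv_layers = conv_layers, filters = filters,
                kernel_size = kernel_size, pool_size = pool_size,
                pool_stride = pool_stride, dropout = dropout)
  empty <- vapply(lists, length, integer(1)) == 0L
  if (any(empty)) {
    abort(paste0("empty candidate list(s): ",
                 paste(names(lists)[empty], collapse = ", ")))
  }
  structure(lists, class = "fourmc_grid")
}

#' Enumerate all grid combinations
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per combination (Cartesian product).
#' @export
grid_combinations <- function(grid) {
  as_tibble(expand.grid(unclass(grid), KEEP.OUT.ATTRS = FALSE))
}

#' Grid search over the architecture hyperparameters
#'
#' Evaluates every combination of the grid by k-fold cross-validation and
#' picks the argmax of `selection_metric` over the mean *validation*-fold
#' metrics (ties go to the first combination in iteration order).
#' Combinations that cannot be built — a kernel wider than the surviving
#' positions, or a filter count incompatible with the group-normalization
#' groups — are skipped and recorded with their reason, not fatal.
#'
#' @param data A labelled window dataset.
#' @param scheme Encoding scheme name.
#' @param grid A [grid_spec()].
#' @param config A [train_config()].
#' @param k Folds for the inner cross-validation (default 3 to keep the
#'   search affordable; use 10 for final confirmation).
#' @param seed Fold-plan seed.
#' @param selection_metric One of `"mcc"`, `"acc"`, `"sn"`, `"sp"`, `"auc"`
#'   (validation-fold means). Default `"mcc"`.
#' @param groups Group-normalization groups used for every candidate.
#' @param verbose Log progress to stderr.
#' @return A list: `best_spec` (a [cnn_spec()]), `results` (one row per
#'   combination with status and mean validation metrics).
#' @export
grid_search <- function(data, scheme, grid = grid_spec(),
                        config = train_config(), k = 3L, seed = 1L,
                        selection_metric = c("mcc", "acc", "sn", "sp", "auc"),
                        groups = 4L, verbose = FALSE) {
  selection_metric <- match.arg(selection_metric)
  combos <- grid_combinations(grid)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    row <- dplyr::mutate(cm, combo = i, .before = 1)
    result <- tryCatch({
      spec <- cnn_spec(
        n_blocks = cm$conv_layers, filters = cm$filters,
        kernel_size = cm$kernel_size, groups = groups,
        pool_size = cm$pool_size, pool_stride = cm$pool_stride,
        dropout = cm$dropout
      )
      cv <- cross_validate(data, scheme, spec = spec, config = config,
                           k = k, seed = seed)
      dplyr::bind_cols(
        tibble(status = "ok", reason = NA_character_),
        cv$summary[, c("val_mcc", "val_acc", "val_sn", "val_sp", "val_auc")]
      )
    }, error = function(e) {
      tibble(status = "skipped", reason = conditionMessage(e),
             val_mcc = NA_real_, val_acc = NA_real_, val_sn = NA_real_,
             val_sp = NA_real_, val_auc = NA_real_)
    })
    rows[[i]] <- dplyr::bind_cols(row, result)
    if (verbose) {
      message(sprintf("[grid %d/%d] %s", i, nrow(combos), rows[[i]]$status))
    }
  }
  results <- dplyr::bind_rows(rows)
  score <- results[[paste0("val_", selection_metric)]]
  if (all(is.na(score))) {
    abort("no grid combination could be evaluated")
  }
  best <- which.max(score)  # NA-safe: which.max skips NA; ties -> first
  bc <- combos[best, ]
  best_spec <- cnn_spec(
    n_blocks = bc$conv_layers, filters = bc$filters,
    kernel_size = bc$kernel_size, groups = groups, pool_size = bc$pool_size,
    pool_stride = bc$pool_stride, dropout = bc$dropout
  )
  list(best_spec = best_spec, best_combo = best, results = results,
       selection_metric = selection_metric)
}
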