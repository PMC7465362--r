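test_that("fold plans partition the data with 8/1/1 roles and are deterministic", {
  ds <- make_dataset(100, seed = 41)
  folds <- make_folds(ds, k = 10, seed = 42)
  expect_equal(as.integer(table(folds$assignment$fold)), rep(10L, 10))
  tested <- integer(0)
  for (r in 1:10) {
    roles <- fold_roles(folds, r)
    expect_equal(length(roles$train), 80L)
    expect_equal(length(roles$validation), 10L)
    expect_equal(length(roles$test), 10L)
    expect_length(intersect(roles$train, roles$test), 0)
    expect_length(intersect(roles$train, roles$validation), 0)
    expect_length(intersect(roles$validation, roles$test), 0)
    expect_setequal(c(roles$train, roles$validation, roles$test), 1:100)
    tested <- c(tested, roles$test)
  }
  expect_setequal(tested, 1:100)
  expect_equal(length(tested), 100L)  # each record tested exactly once

  again <- make_folds(ds, k = 10, seed = 42)
  expect_identical(folds$assignment, again$assignment)

  expect_error(make_folds(ds, k = 2), "at least 3")
  expect_error(make_folds(ds[1:10, ], k = 10), "per class")
})

test_that("confusion counting follows the threshold convention", {
  expect_equal(confusion_counts(c(1, 0), c(0.9, 0.1)),
               tibble::tibble(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  expect_equal(confusion_counts(c(1, 0), c(0.1, 0.9)),
               tibble::tibble(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  # threshold 0 calls everything positive
  cc <- confusion_counts(c(1, 0, 0), c(0.2, 0.3, 0.1), threshold = 0)
  expect_equal(cc$fp, 2L)
  expect_equal(cc$fn, 0L)
  expect_error(confusion_counts(c(1, 0), 0.5), "lengths differ")
})

test_that("metric formulas match direct arithmetic and their symmetries", {
  perfect <- classification_metrics(
    tibble::tibble(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(mcc = 1, acc = 1, sn = 1, sp = 1))

  m <- classification_metrics(tibble::tibble(tp = 90, tn = 80, fp = 20, fn = 10))
  expect_equal(m$acc, 0.85)
  expect_equal(m$sn, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$mcc, 7000 / sqrt(110 * 100 * 100 * 90), tolerance = 1e-12)

  set.seed(43)
  for (i in 1:50) {
    cc <- as.list(rmultinom(1, 200, runif(4, 0.05, 1))[, 1])
    names(cc) <- c("tp", "tn", "fp", "fn")
    got <- classification_metrics(tibble::as_tibble(cc))
    want <- metrics_direct(cc$tp, cc$tn, cc$fp, cc$fn)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    expect_equal(got$acc, want$acc, tolerance = 1e-12)
    # prediction flip negates MCC and complements ACC
    flip <- classification_metrics(
      tibble::tibble(tp = cc$fn, tn = cc$fp, fp = cc$tn, fn = cc$tp))
    expect_equal(flip$mcc, -got$mcc, tolerance = 1e-12)
    expect_equal(flip$acc, 1 - got$acc, tolerance = 1e-12)
  }
  # degenerate marginal: MCC defined as 0
  expect_equal(
    classification_metrics(tibble::tibble(tp = 0, tn = 5, fp = 0, fn = 5))$mcc,
    0)
  expect_error(classification_metrics(tibble::tibble(tp = 0, tn = 0, fp = 0,
                                                     fn = 0)),
               "empty")
})

test_that("ROC/AUC equals the concordant-pair statistic and pROC agrees", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.8, 0.6, 0.4, 0.2))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")

  set.seed(44)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 1)  # coarse scores force ties
    got <- roc_auc(y, s)$auc
    expect_equal(got, auc_pairwise(y, s), tolerance = 1e-9)
    expect_equal(got,
                 as.numeric(suppressMessages(
                   pROC::auc(y, s, direction = "<", levels = c(0, 1)))),
                 tolerance = 1e-9)
  }
})

test_that("cross-validation trains k models without leakage and reports per fold", {
  d <- simulate_windows(sim_spec(n_per_class = 15, motif = "CCCC",
                                 p_positive = 1, q_negative = 0, seed = 45))
  cv <- cross_validate(
    d, "BE",
    spec = cnn_spec(n_blocks = 1, filters = 8, kernel_size = 3,
                    pool_size = 2, dropout = 0),
    config = train_config(epochs = 3L, patience = 3L, seed = 46),
    k = 3, seed = 47
  )
  expect_equal(nrow(cv$per_fold), 3L)
  expect_true(all(c("mcc", "acc", "sn", "sp", "auc") %in% names(cv$per_fold)))
  # every record scored exactly once, out of fold
  expect_setequal(cv$predictions$index, seq_len(nrow(d)))
  for (r in 1:3) {
    roles <- fold_roles(cv$folds, r)
    scored <- cv$predictions$index[cv$predictions$fold == r]
    expect_length(intersect(scored, roles$train), 0)
    expect_setequal(scored, roles$test)
  }
  expect_equal(cv$summary$acc, mean(cv$per_fold$acc))
  g <- glance(cv)
  expect_equal(g$k, 3L)
  expect_equal(nrow(tidy(cv)), 3L)

  tf <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(cv, tf)
  rep <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(nrow(rep), 4L)  # 3 folds + mean row
  expect_equal(rep$row[4], "mean")
})
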