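small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 2L, filters = 8L, kernel_size = 3L, groups = 4L,
         pool_size = 2L, pool_stride = 2L, dropout = 0),
    list(...)
  )
  do.call(cnn_spec, args)
}

test_that("architecture invariants are enforced", {
  expect_error(cnn_spec(filters = 30, groups = 4), "divisible")
  expect_error(cnn_spec(dropout = 1), "dropout")
  expect_error(cnn_spec(filters = 0), "positive")
  expect_error(train_config(patience = 200, epochs = 100), "patience")
  spec <- cnn_spec()
  expect_equal(spec$filters, 32L)
  expect_equal(spec$l2_weight, 1e-4)
})

test_that("parameter count is a pure function of spec and input shape", {
  # hand computation for the default two-block architecture on (41, 5):
  # conv1 5*5*32+32 = 832; gn1 64; conv2 5*32*32+32 = 5152; gn2 64;
  # positions 41 -> 21 -> 11, flatten 11*32 = 352; dense 352*32+32 = 11296;
  # output 32+1 = 33; total 17441
  net <- build_cnn(cnn_spec(), c(41L, 5L), seed = 1)
  expect_equal(n_params(net), 17441L)
  # MMI input builds too (smallest channel count in scope)
  expect_silent(build_cnn(cnn_spec(), c(55L, 1L), seed = 1))
  # kernel wider than the surviving positions is a shape error
  expect_error(build_cnn(cnn_spec(n_blocks = 5, kernel_size = 14), c(41L, 5L)),
               "too short")
})

test_that("analytic gradients match central finite differences", {
  set.seed(91)
  net <- build_cnn(small_spec(), c(11L, 4L), seed = 91)
  n <- 4
  X <- array(rnorm(n * 11 * 4), c(n, 11, 4))
  y <- c(1, 0, 1, 0)
  res <- fourmc:::nn_loss_grads(net, X, y, train = FALSE)
  h <- 1e-5
  loss_at <- function(net2) fourmc:::nn_loss(net2, X, y)$loss
  for (nm in names(net$params)) {
    for (pn in names(net$params[[nm]])) {
      p <- net$params[[nm]][[pn]]
      for (i in sample(length(p), min(4, length(p)))) {
        net2 <- net
        net2$params[[nm]][[pn]][i] <- p[i] + h
        fp <- loss_at(net2)
        net2$params[[nm]][[pn]][i] <- p[i] - h
        fm <- loss_at(net2)
        expect_equal(res$grads[[nm]][[pn]][i], (fp - fm) / (2 * h),
                     tolerance = 1e-3)
      }
    }
  }
  # gradient with respect to the input (the saliency ingredient)
  for (i in sample(length(X), 5)) {
    X2 <- X
    X2[i] <- X[i] + h
    fp <- fourmc:::nn_loss(net, X2, y)$loss
    X2[i] <- X[i] - h
    fm <- fourmc:::nn_loss(net, X2, y)$loss
    expect_equal(res$dX[i], (fp - fm) / (2 * h), tolerance = 1e-3)
  }
})

test_that("full-batch gradient descent monotonically decreases a smooth loss", {
  set.seed(92)
  d <- make_dataset(24, L = 15, seed = 92)
  tn <- encode_dataset(d, "BE")
  net <- train_cnn(
    tn, spec = small_spec(l2_weight = 0),
    config = train_config(learning_rate = 0.005, momentum = 0,
                          epochs = 12L, batch_size = 24L, patience = 12L,
                          seed = 5)
  )
  expect_true(all(diff(net$history$loss) <= 1e-8))
})

test_that("training separates a strongly separable synthetic benchmark", {
  d <- simulate_windows(sim_spec(n_per_class = 50, motif = "CCCC",
                                 p_positive = 1, q_negative = 0, seed = 93))
  tn <- encode_dataset(d, "DNC")
  net <- train_cnn(tn, config = train_config(epochs = 40L, patience = 40L,
                                             seed = 94))
  p <- predict(net, tn)
  expect_gte(mean((p >= 0.5) == (tn$y == 1)), 0.95)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("prediction is deterministic, bounded and shape-checked", {
  set.seed(95)
  net <- build_cnn(small_spec(dropout = 0.4), c(11L, 4L), seed = 95)
  net$trained <- TRUE
  X <- array(rnorm(6 * 11 * 4), c(6, 11, 4))
  # duplicated rows give identical outputs (dropout off at inference)
  X2 <- X[c(1, 1, 2, 2, 3, 3), , ]
  p <- predict(net, X2)
  expect_equal(length(p), 6L)
  expect_equal(p[1], p[2])
  expect_equal(p[3], p[4])
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(net, array(0, c(2, 9, 4))), "shape")
  net$trained <- FALSE
  expect_error(predict(net, X), "untrained")
})

test_that("training on a single-class target converges to the class prior", {
  d <- make_dataset(20, L = 15, seed = 96)
  d$label <- 1L
  tn <- encode_dataset(d, "NCP")
  net <- train_cnn(tn, spec = small_spec(),
                   config = train_config(epochs = 25L, patience = 25L,
                                         seed = 97))
  expect_true(all(predict(net, tn) > 0.8))
})

test_that("early stopping halts after patience epochs without improvement", {
  d <- make_dataset(16, L = 15, seed = 98)
  tn <- encode_dataset(d, "BE")
  val <- encode_dataset(make_dataset(8, L = 15, seed = 99), "BE")
  # an effectively-zero learning rate freezes the weights, so the
  # validation loss never improves after epoch 1
  net <- train_cnn(tn, x_val = val,
                   spec = small_spec(),
                   config = train_config(learning_rate = 1e-300,
                                         epochs = 50L, patience = 1L,
                                         seed = 100))
  expect_equal(nrow(net$history), 2L)
})

test_that("checkpointing restores the best-validation epoch, not the last", {
  d <- simulate_windows(sim_spec(n_per_class = 20, motif = "CC",
                                 p_positive = 0.8, q_negative = 0.2,
                                 seed = 101))
  val <- simulate_windows(sim_spec(n_per_class = 8, motif = "CC",
                                   p_positive = 0.8, q_negative = 0.2,
                                   seed = 102))
  tn <- encode_dataset(d, "BE")
  vn <- encode_dataset(val, "BE")
  cfg <- train_config(learning_rate = 0.02, epochs = 15L, patience = 15L,
                      seed = 103)
  a <- train_cnn(tn, x_val = vn, spec = small_spec(dropout = 0.1),
                 config = cfg)
  # same seed, truncated at A's best epoch: identical trajectory, so the
  # checkpointed parameters must agree exactly
  cfg_c <- train_config(learning_rate = 0.02, epochs = a$best_epoch,
                        patience = a$best_epoch, seed = 103)
  c_run <- train_cnn(tn, x_val = vn, spec = small_spec(dropout = 0.1),
                     config = cfg_c)
  expect_equal(predict(a, tn), predict(c_run, tn), tolerance = 1e-12)
  if (a$best_epoch < nrow(a$history)) {
    b <- train_cnn(tn, x_val = vn, spec = small_spec(dropout = 0.1),
                   config = utils::modifyList(cfg, list(checkpoint_best = FALSE)))
    expect_false(isTRUE(all.equal(predict(a, tn), predict(b, tn))))
  }
})

test_that("model archives round-trip through save/load", {
  d <- make_dataset(16, seed = 104)
  tn <- encode_dataset(d, "NCPNF")
  net <- train_cnn(tn, spec = small_spec(),
                   config = train_config(epochs = 3L, patience = 3L,
                                         seed = 105))
  tf <- withr::local_tempfile(fileext = ".json")
  save_cnn(net, tf)
  back <- load_cnn(tf)
  expect_equal(predict(back, tn), predict(net, tn), tolerance = 1e-12)
  expect_equal(back$scheme, "NCPNF")
})

test_that("training history tidiers expose epochs and summary", {
  d <- make_dataset(12, seed = 106)
  tn <- encode_dataset(d, "BE")
  net <- train_cnn(tn, spec = small_spec(),
                   config = train_config(epochs = 4L, patience = 4L,
                                         seed = 107))
  h <- tidy(net)
  expect_true(all(c("epoch", "loss", "acc") %in% names(h)))
  g <- glance(net)
  expect_equal(g$epochs_run, nrow(h))
  expect_equal(g$n_params, n_params(net))
})
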