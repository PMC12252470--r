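test_that("initialization is seeded and softmax rows are normalized", {
  m1 <- init_model(model_config(seed = 5L))
  m2 <- init_model(model_config(seed = 5L))
  expect_identical(m1$layers, m2$layers)
  m3 <- init_model(model_config(seed = 6L))
  expect_false(identical(m1$layers, m3$layers))
  X <- matrix(stats::rnorm(80), 10, 8)
  probs <- wearecg:::fcnn_forward(m1, X)$probs
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-6)
  # evaluation-mode forward pass is deterministic
  expect_identical(probs, wearecg:::fcnn_forward(m1, X)$probs)
})

test_that("config invariants are enforced", {
  expect_error(model_config(hidden_sizes = c(32, 16, 8)), "two hidden")
  expect_error(model_config(n_classes = 1), "2 classes")
  expect_error(model_config(dropout_rate = 1), "dropout")
  expect_error(training_config(max_epochs = 5, patience = 10), "patience")
})

test_that("early stopping halts patience epochs after the last improvement", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 30,
                                                        seed = 2L))
  # zero learning rate: the validation loss can never improve after the
  # first epoch, so training must stop at epoch 1 + patience
  fit <- train_fcnn(init_model(model_config(seed = 1L)), ds,
                    training_config(learning_rate = 0, patience = 10,
                                    seed = 1L))
  expect_equal(fit$history$stop_epoch, 11)
  expect_equal(fit$history$best_epoch, 1)
  expect_equal(fit$history$stop_epoch - fit$history$best_epoch, 10)
})

test_that("early stopping returns the best-epoch weights", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 50,
                                                        seed = 3L))
  fit <- train_fcnn(init_model(model_config(seed = 2L)), ds,
                    training_config(max_epochs = 60, seed = 2L))
  va <- ds$split == "validation"
  Xn <- sweep(sweep(ds$x, 2, fit$model$normalization$mean), 2,
              fit$model$normalization$sd, `/`)
  probs <- wearecg:::fcnn_forward(fit$model, Xn[va, , drop = FALSE])$probs
  loss <- wearecg:::cross_entropy(probs, match(ds$y[va],
                                               fit$model$class_levels))
  expect_equal(loss, min(fit$history$epochs$val_loss), tolerance = 1e-10)
})

test_that("training is fully deterministic under fixed seeds", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 30,
                                                        seed = 4L))
  cfg <- training_config(max_epochs = 15, seed = 9L)
  f1 <- train_fcnn(init_model(model_config(seed = 9L)), ds, cfg)
  f2 <- train_fcnn(init_model(model_config(seed = 9L)), ds, cfg)
  expect_identical(f1$model$layers, f2$model$layers)
  expect_identical(f1$history$epochs, f2$history$epochs)
})

test_that("linearly separable two-class blobs reach 100% held out", {
  set.seed(12)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- matrix(stats::rnorm(n * 8, sd = 0.3), n, 8)
  x[, 1] <- x[, 1] + ifelse(y == 1, 3, -3)  # wide margin on one feature
  colnames(x) <- c("rr", "pr", "st", "qrs", "qt", "sdnn", "lf", "hf")
  split <- factor(rep(c("train", "validation", "test"),
                      times = c(240, 80, 80))[sample(n)],
                  levels = c("train", "validation", "test"))
  ds <- list(x = x, y = y, split = split)
  fit <- train_fcnn(init_model(model_config(n_classes = 2, seed = 1L)), ds,
                    training_config(seed = 1L))
  te <- split == "test"
  rep_ <- evaluate_model(fit$model, x[te, , drop = FALSE], y[te])
  expect_equal(rep_$accuracy, 1.0)
  # independent oracle: a single-hidden-layer net (nnet) also separates it
  oracle <- nnet::nnet(x[split == "train", ], nnet::class.ind(y[split == "train"]),
                       size = 4, softmax = TRUE, trace = FALSE, maxit = 200)
  pred <- max.col(stats::predict(oracle, x[te, , drop = FALSE])) - 1
  expect_equal(mean(pred == y[te]), 1.0)
})

test_that("identical class distributions give chance-level accuracy", {
  set.seed(7)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- matrix(stats::rnorm(n * 8), n, 8)  # no class signal at all
  split <- factor(rep(c("train", "validation", "test"),
                      times = c(240, 80, 80))[sample(n)],
                  levels = c("train", "validation", "test"))
  ds <- list(x = x, y = y, split = split)
  fit <- train_fcnn(init_model(model_config(n_classes = 2, seed = 3L)), ds,
                    training_config(max_epochs = 40, seed = 3L))
  te <- split == "test"
  acc <- evaluate_model(fit$model, x[te, , drop = FALSE], y[te])$accuracy
  ci <- 1.96 * sqrt(0.25 / sum(te))  # binomial 95% CI around 1/2
  expect_lt(abs(acc - 0.5), ci + 1e-9)
})

test_that("confusion matrix accounting is self-consistent", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 40,
                                                        seed = 6L))
  fit <- train_fcnn(init_model(model_config(seed = 6L)), ds,
                    training_config(max_epochs = 60, seed = 6L))
  te <- ds$split == "test"
  rep_ <- evaluate_model(fit$model, ds$x[te, , drop = FALSE], ds$y[te])
  expect_equal(unname(rowSums(rep_$confusion)),
               unname(table(ds$y[te])), ignore_attr = TRUE)
  expect_equal(sum(diag(rep_$confusion)) / sum(rep_$confusion),
               rep_$accuracy)
  expect_error(evaluate_model(fit$model, ds$x[te, , drop = FALSE],
                              ds$y[te] + 100), "unseen")
})

test_that("permuting class labels destroys accuracy", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 40,
                                                        seed = 8L))
  set.seed(1)
  ds$y <- sample(ds$y)  # break every feature-label association
  fit <- train_fcnn(init_model(model_config(seed = 8L)), ds,
                    training_config(max_epochs = 40, seed = 8L))
  te <- ds$split == "test"
  acc <- evaluate_model(fit$model, ds$x[te, , drop = FALSE], ds$y[te])$accuracy
  ci <- 1.96 * sqrt(0.2 * 0.8 / sum(te))
  expect_lt(acc, 0.2 + ci + 0.05)
})

test_that("permutation importance: noise features score zero, HRV-only
           datasets rank SDNN/LF/HF on top, duplicates share credit", {
  def <- default_intensity_features()
  # only the HRV columns differ between classes
  m <- def$means
  m[, 1:5] <- rep(m[3, 1:5], each = 5)
  m[, 1] <- m[, 1] - 0.001 * (0:4)  # keep the RR-decreasing invariant, tiny
  spec <- intensity_class_spec(means = m, sds = def$sds, n_per_class = 200,
                               seed = 10L)
  ds <- generate_intensity_dataset(spec)
  fit <- train_fcnn(init_model(model_config(seed = 10L)), ds,
                    training_config(seed = 10L))
  te <- ds$split == "test"
  imp <- feature_importance(fit$model, ds$x[te, , drop = FALSE], ds$y[te],
                            n_repeats = 20, seed = 2L)
  top3 <- names(sort(imp, decreasing = TRUE))[1:3]
  expect_setequal(top3, c("sdnn", "lf", "hf"))
  # features carrying no class signal have importance ~ 0
  expect_lt(max(abs(imp[c("pr", "st", "qrs", "qt")])), 0.02)
  expect_error(feature_importance(fit$model, ds$x[te, ], ds$y[te],
                                  n_repeats = 0), "n_repeats")
})

test_that("duplicated informative features share permutation credit", {
  set.seed(20)
  n <- 600
  y <- rep(0:1, each = n / 2)
  base <- stats::rnorm(n) + ifelse(y == 1, 1.6, -1.6)
  make_ds <- function(x) {
    split <- factor(rep(c("train", "validation", "test"),
                        times = c(360, 120, 120))[sample(n)],
                    levels = c("train", "validation", "test"))
    list(x = x, y = y, split = split)
  }
  x1 <- cbind(f = base, matrix(stats::rnorm(n * 7), n, 7))
  colnames(x1) <- paste0("v", 1:8)
  x2 <- x1; x2[, 2] <- base  # identical informative copy
  colnames(x2) <- paste0("v", 1:8)
  set.seed(21); ds1 <- make_ds(x1)
  set.seed(21); ds2 <- make_ds(x2)
  f1 <- train_fcnn(init_model(model_config(n_classes = 2, seed = 2L)), ds1,
                   training_config(max_epochs = 60, seed = 2L))
  f2 <- train_fcnn(init_model(model_config(n_classes = 2, seed = 2L)), ds2,
                   training_config(max_epochs = 60, seed = 2L))
  te1 <- ds1$split == "test"; te2 <- ds2$split == "test"
  i1 <- feature_importance(f1$model, ds1$x[te1, ], y[te1], 10, seed = 3L)
  i2 <- feature_importance(f2$model, ds2$x[te2, ], y[te2], 10, seed = 3L)
  single <- i1[["v1"]]
  shared <- i2[["v1"]] + i2[["v2"]]
  expect_lt(abs(shared - single), 0.5 * max(single, shared))
})

test_that("classify returns normalized probabilities and the argmax label", {
  ds <- generate_intensity_dataset(intensity_class_spec(seed = 42L))
  fit <- train_fcnn(init_model(model_config(seed = 42L)), ds,
                    training_config(seed = 42L))
  def <- default_intensity_features()
  out <- classify(fit$model, def$means[3, ])
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
  expect_equal(out$label, names(which.max(out$probabilities)))
  # a vector at a class mean is called confidently
  expect_equal(out$label, "2")
  expect_gt(max(out$probabilities), 0.9)
  expect_error(classify(fit$model, c(NA, def$means[3, -1])), "finite")
})

test_that("model save/load round-trips weights and normalization", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 30,
                                                        seed = 5L))
  fit <- train_fcnn(init_model(model_config(seed = 5L)), ds,
                    training_config(max_epochs = 20, seed = 5L))
  p <- withr::local_tempfile(fileext = ".txt")
  save_model(fit$model, p)
  back <- load_model(p)
  expect_equal(back$layers, fit$model$layers, tolerance = 1e-15)
  expect_equal(back$normalization$mean,
               unname(fit$model$normalization$mean), ignore_attr = TRUE)
  te <- ds$split == "test"
  expect_equal(evaluate_model(back, ds$x[te, ], ds$y[te])$accuracy,
               evaluate_model(fit$model, ds$x[te, ], ds$y[te])$accuracy)
})

test_that("early-stopping savings arithmetic", {
  s <- early_stopping_savings(146, 200)
  expect_equal(s$epochs_saved, 54)
  expect_equal(s$percent_saved, 27)
})

test_that("training history export has the documented columns", {
  ds <- generate_intensity_dataset(intensity_class_spec(n_per_class = 30,
                                                        seed = 1L))
  fit <- train_fcnn(init_model(model_config(seed = 1L)), ds,
                    training_config(max_epochs = 12, seed = 1L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_history(fit$history, p)
  expect_identical(readLines(p, n = 1), "epoch,train_loss,val_loss,val_acc")
})
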