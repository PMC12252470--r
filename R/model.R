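#' FCNN model configuration
#'
#' A fully connected feed-forward classifier with exactly two hidden
#' layers: 8 -> h1 -> h2 -> K, ReLU activations, inverted dropout after
#' each hidden layer during training, softmax output.
#'
#' @param n_features Input width; 8 for the canonical ECG feature vector.
#' @param hidden_sizes Integer pair, widths of the two hidden layers.
#' @param n_classes K >= 2.
#' @param dropout_rate Dropout probability p in [0, 1).
#' @param seed Seed for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(n_features = 8, hidden_sizes = c(32, 16),
                         n_classes = 5, dropout_rate = 0.3, seed = 1L) {
  if (length(hidden_sizes) != 2 || any(hidden_sizes < 1)) {
    stop("exactly two hidden layers are required", call. = FALSE)
  }
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_features = as.integer(n_features),
                 hidden_sizes = as.integer(hidden_sizes),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize an FCNN
#'
#' He-uniform initialization, deterministic under the config seed.
#'
#' @param config A [model_config()].
#' @return An `fcnn_model` (list of weight matrices/bias vectors plus the
#'   config; normalization parameters are attached by [train_fcnn()]).
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  sizes <- c(config$n_features, config$hidden_sizes, config$n_classes)
  init_layer <- function(n_in, n_out) {
    lim <- sqrt(6 / n_in)
    list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
         b = numeric(n_out))
  }
  layers <- lapply(seq_len(3), function(i) init_layer(sizes[i], sizes[i + 1]))
  structure(list(layers = layers, config = config, normalization = NULL,
                 class_levels = NULL),
            class = "fcnn_model")
}

#' @export
print.fcnn_model <- function(x, ...) {
  s <- c(x$config$n_features, x$config$hidden_sizes, x$config$n_classes)
  cat(sprintf("<fcnn_model> %s; dropout %.2f%s\n",
              paste(s, collapse = " -> "), x$config$dropout_rate,
              if (is.null(x$normalization)) " (untrained)" else ""))
  invisible(x)
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when training, applies inverted dropout with the masks
# drawn from the current RNG stream and returns cached activations
fcnn_forward <- function(model, X, training = FALSE) {
  p <- model$config$dropout_rate
  L <- model$layers
  z1 <- sweep(X %*% L[[1]]$W, 2, L[[1]]$b, `+`)
  a1 <- relu(z1)
  m1 <- NULL
  if (training && p > 0) {
    m1 <- matrix(stats::rbinom(length(a1), 1, 1 - p), nrow(a1)) / (1 - p)
    a1 <- a1 * m1
  }
  z2 <- sweep(a1 %*% L[[2]]$W, 2, L[[2]]$b, `+`)
  a2 <- relu(z2)
  m2 <- NULL
  if (training && p > 0) {
    m2 <- matrix(stats::rbinom(length(a2), 1, 1 - p), nrow(a2)) / (1 - p)
    a2 <- a2 * m2
  }
  z3 <- sweep(a2 %*% L[[3]]$W, 2, L[[3]]$b, `+`)
  probs <- softmax_rows(z3)
  list(probs = probs, X = X, z1 = z1, a1 = a1, m1 = m1,
       z2 = z2, a2 = a2, m2 = m2)
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

#' Training configuration
#'
#' @param max_epochs Epoch cap; default 200.
#' @param patience Early-stopping patience: training halts once the
#'   validation loss has failed to improve (decrease by more than
#'   `min_delta`) for this many consecutive epochs. Default 10.
#' @param learning_rate Adam step size; default 1e-3.
#' @param batch_size Minibatch size; default 32.
#' @param min_delta Minimum absolute validation-loss decrease that counts
#'   as an improvement.
#' @param seed Seed governing shuffling and dropout masks.
#' @return A `training_config` object.
#' @export
training_config <- function(max_epochs = 200, patience = 10,
                            learning_rate = 1e-3, batch_size = 32,
                            min_delta = 1e-6, seed = 1L) {
  if (patience >= max_epochs) stop("patience must be < max_epochs",
                                   call. = FALSE)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "training_config")
}

# single Adam step over one minibatch; returns updated layers + moments
fcnn_backprop_step <- function(model, X, y_idx, opt, lr) {
  K <- model$config$n_classes
  fw <- fcnn_forward(model, X, training = TRUE)
  n <- nrow(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y_idx)] <- 1
  d3 <- (fw$probs - Y) / n
  L <- model$layers
  g <- vector("list", 3)
  g[[3]] <- list(W = t(fw$a2) %*% d3, b = colSums(d3))
  d2 <- (d3 %*% t(L[[3]]$W)) * (fw$z2 > 0)
  if (!is.null(fw$m2)) d2 <- d2 * fw$m2
  g[[2]] <- list(W = t(fw$a1) %*% d2, b = colSums(d2))
  d1 <- (d2 %*% t(L[[2]]$W)) * (fw$z1 > 0)
  if (!is.null(fw$m1)) d1 <- d1 * fw$m1
  g[[1]] <- list(W = t(fw$X) %*% d1, b = colSums(d1))

  opt$t <- opt$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in 1:3) {
    for (nm in c("W", "b")) {
      opt$m[[i]][[nm]] <- b1 * opt$m[[i]][[nm]] + (1 - b1) * g[[i]][[nm]]
      opt$v[[i]][[nm]] <- b2 * opt$v[[i]][[nm]] + (1 - b2) * g[[i]][[nm]]^2
      mhat <- opt$m[[i]][[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[i]][[nm]] / (1 - b2^opt$t)
      L[[i]][[nm]] <- L[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  model$layers <- L
  list(model = model, opt = opt)
}

#' Train the FCNN with dropout and patience-based early stopping
#'
#' Minimizes cross-entropy with Adam. After every epoch the validation
#' loss is evaluated with dropout disabled; training stops at the epoch
#' cap or as soon as the validation loss has not improved for `patience`
#' consecutive epochs, and the returned weights are those of the best
#' epoch. Feature normalization (z-score) is computed on the training
#' split only and stored with the model.
#'
#' @param model An [init_model()] result.
#' @param dataset A `labeled_dataset` (from [generate_intensity_dataset()])
#'   or any list with `x`, `y`, and a `split` factor with levels
#'   train/validation(/test).
#' @param config A [training_config()].
#' @return List `model` (trained `fcnn_model`) and `history` (a
#'   `training_history`: per-epoch data frame plus `stop_epoch`,
#'   `best_epoch`).
#' @export
train_fcnn <- function(model, dataset, config = training_config()) {
  stopifnot(inherits(model, "fcnn_model"), inherits(config, "training_config"))
  tr <- dataset$split == "train"
  va <- dataset$split == "validation"
  if (!any(tr) || !any(va)) stop("dataset must contain non-empty train and",
                                 " validation splits", call. = FALSE)
  levels_y <- sort(unique(dataset$y))
  if (length(levels_y) != model$config$n_classes) {
    stop("dataset has ", length(levels_y), " classes; model expects ",
         model$config$n_classes, call. = FALSE)
  }
  y_idx <- match(dataset$y, levels_y)
  mu <- colMeans(dataset$x[tr, , drop = FALSE])
  sg <- apply(dataset$x[tr, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  Xn <- sweep(sweep(dataset$x, 2, mu), 2, sg, `/`)
  Xtr <- Xn[tr, , drop = FALSE]; ytr <- y_idx[tr]
  Xva <- Xn[va, , drop = FALSE]; yva <- y_idx[va]
  model$normalization <- list(mean = mu, sd = sg)
  model$class_levels <- levels_y

  zero_like <- lapply(model$layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  opt <- list(m = zero_like, v = zero_like, t = 0)

  set.seed(config$seed)
  best_loss <- Inf
  best_layers <- model$layers
  best_epoch <- 0L
  wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  stop_epoch <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(ytr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in batches) {
      st <- fcnn_backprop_step(model, Xtr[bi, , drop = FALSE], ytr[bi],
                               opt, config$learning_rate)
      model <- st$model; opt <- st$opt
    }
    tr_probs <- fcnn_forward(model, Xtr)$probs
    va_probs <- fcnn_forward(model, Xva)$probs
    tr_loss <- cross_entropy(tr_probs, ytr)
    va_loss <- cross_entropy(va_probs, yva)
    va_acc <- mean(max.col(va_probs) == yva)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = va_loss, val_acc = va_acc))
    if (va_loss < best_loss - config$min_delta) {
      best_loss <- va_loss
      best_layers <- model$layers
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stop_epoch <- epoch
        break
      }
    }
  }
  model$layers <- lapply(best_layers, function(l)
    list(W = unname(l$W), b = unname(l$b)))
  history <- structure(list(epochs = hist, stop_epoch = stop_epoch,
                            best_epoch = best_epoch,
                            best_val_loss = best_loss),
                       class = "training_history")
  list(model = model, history = history)
}

#' Early-stopping savings
#'
#' How much of the epoch budget patience-based stopping saved: with a cap
#' of `max_epochs` and training halted at `stop_epoch`, the saving is
#' `max_epochs - stop_epoch` epochs, i.e. a fraction
#' `(max_epochs - stop_epoch) / max_epochs` of the budgeted training time.
#'
#' @param stop_epoch Epoch at which training halted.
#' @param max_epochs Epoch cap.
#' @return List `epochs_saved`, `fraction_saved`, `percent_saved`.
#' @export
early_stopping_savings <- function(stop_epoch, max_epochs) {
  stopifnot(stop_epoch >= 1, stop_epoch <= max_epochs)
  saved <- max_epochs - stop_epoch
  list(epochs_saved = saved, fraction_saved = saved / max_epochs,
       percent_saved = 100 * saved / max_epochs)
}

#' Evaluate a trained FCNN
#'
#' @param model A trained `fcnn_model`.
#' @param x Feature matrix (raw scale; normalization is applied using the
#'   stored training parameters).
#' @param y True labels (values drawn from the training label set).
#' @return A `classification_report`: `accuracy`, `confusion` (K x K,
#'   rows = true, columns = predicted), `precision`, `recall` per class.
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "fcnn_model"))
  if (is.null(model$normalization)) stop("model is untrained", call. = FALSE)
  if (!all(y %in% model$class_levels)) {
    stop("unseen label values in evaluation set", call. = FALSE)
  }
  Xn <- sweep(sweep(x, 2, model$normalization$mean), 2,
              model$normalization$sd, `/`)
  pred_idx <- max.col(fcnn_forward(model, Xn)$probs)
  true_idx <- match(y, model$class_levels)
  K <- model$config$n_classes
  conf <- matrix(0L, K, K,
                 dimnames = list(true = model$class_levels,
                                 predicted = model$class_levels))
  for (i in seq_along(true_idx)) {
    conf[true_idx[i], pred_idx[i]] <- conf[true_idx[i], pred_idx[i]] + 1L
  }
  acc <- sum(diag(conf)) / sum(conf)
  precision <- diag(conf) / pmax(colSums(conf), 1)
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  structure(list(accuracy = acc, confusion = conf,
                 precision = precision, recall = recall),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Permutation feature importance
#'
#' Mean accuracy drop over `n_repeats` seeded shuffles of each feature
#' column, evaluated with the trained model.
#'
#' @param model A trained `fcnn_model`.
#' @param x,y Evaluation features and labels.
#' @param n_repeats Shuffles per feature (>= 1).
#' @param seed Seed for the shuffles.
#' @return Named numeric vector of importance scores (accuracy drop).
#' @export
feature_importance <- function(model, x, y, n_repeats = 10, seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  base_acc <- evaluate_model(model, x, y)$accuracy
  set.seed(seed)
  imp <- numeric(ncol(x))
  names(imp) <- colnames(x)
  for (j in seq_len(ncol(x))) {
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      xp <- x
      xp[, j] <- xp[sample(nrow(x)), j]
      drops[r] <- base_acc - evaluate_model(model, xp, y)$accuracy
    }
    imp[j] <- mean(drops)
  }
  imp
}

#' Classify a single feature vector
#'
#' @param model A trained `fcnn_model`.
#' @param features Named or ordered numeric vector of the 8 features.
#' @return List `label` (from the training label set) and `probabilities`.
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "fcnn_model"))
  if (is.null(model$normalization)) stop("model is untrained", call. = FALSE)
  if (any(!is.finite(features))) stop("non-finite feature values",
                                      call. = FALSE)
  x <- matrix(as.numeric(features), nrow = 1)
  Xn <- sweep(sweep(x, 2, model$normalization$mean), 2,
              model$normalization$sd, `/`)
  probs <- drop(fcnn_forward(model, Xn)$probs)
  names(probs) <- as.character(model$class_levels)
  list(label = as.character(model$class_levels[which.max(probs)]),
       probabilities = probs)
}

#' Save / load a trained model as a plain-text weight file
#'
#' A JSON header line (layer sizes, dropout, normalization parameters,
#' class labels) followed by one line of whitespace-separated weights per
#' layer parameter, full double precision.
#'
#' @param model An `fcnn_model`.
#' @param path File path.
#' @return `path` (save) or the restored `fcnn_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fcnn_model"))
  header <- jsonlite::toJSON(list(
    n_features = model$config$n_features,
    hidden_sizes = model$config$hidden_sizes,
    n_classes = model$config$n_classes,
    dropout_rate = model$config$dropout_rate,
    seed = model$config$seed,
    normalization = model$normalization,
    class_levels = model$class_levels
  ), auto_unbox = TRUE, digits = NA)
  lines <- as.character(header)
  for (l in model$layers) {
    lines <- c(lines,
               paste(sprintf("%.17g", l$W), collapse = " "),
               paste(sprintf("%.17g", l$b), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  hd <- jsonlite::fromJSON(lines[1])
  cfg <- model_config(hd$n_features, hd$hidden_sizes, hd$n_classes,
                      hd$dropout_rate, hd$seed)
  model <- init_model(cfg)
  sizes <- c(cfg$n_features, cfg$hidden_sizes, cfg$n_classes)
  for (i in 1:3) {
    w <- as.numeric(strsplit(lines[2 * i], " ")[[1]])
    b <- as.numeric(strsplit(lines[2 * i + 1], " ")[[1]])
    model$layers[[i]] <- list(W = matrix(w, sizes[i], sizes[i + 1]), b = b)
  }
  if (!is.null(hd$normalization)) {
    model$normalization <- list(mean = unlist(hd$normalization$mean),
                                sd = unlist(hd$normalization$sd))
  }
  model$class_levels <- hd$class_levels
  model
}

#' Export a training history as CSV
#'
#' Columns `epoch,train_loss,val_loss,val_acc`.
#' @param history A `training_history`.
#' @param path Output path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history$epochs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
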