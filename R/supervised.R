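#' Network configuration
#'
#' Describes one of the two supported architectures. `resnet_attention`
#' is the promoter recognition / strength stack: a CNN block (convolution
#' + ReLU), `n_resblocks` residual blocks, a self-attention block, global
#' average pooling with dropout, and a one-unit head (sigmoid for binary
#' tasks, linear for regression). `simple_cnn` is the small
#' convolution-pool stack used for activity regression on small designed
#' training sets. Training minimizes mean squared error for both task
#' types (binary labels are regressed against the sigmoid output), with
#' the Adam optimizer.
#'
#' @param arch `"resnet_attention"` or `"simple_cnn"`.
#' @param task `"binary"` or `"regression"`.
#' @param n_resblocks Residual blocks between the CNN block and the
#'   attention block (default 20).
#' @param channels Convolution channel width (default 16).
#' @param attention_key_dim Attention key dimension `d_k`
#'   (default `channels`).
#' @param dropout_rate Dropout probability before the head (default 0.3).
#' @param weight_decay Decoupled L2 weight decay applied by the
#'   optimizer (default 0).
#' @param learning_rate Adam learning rate; the conventional search range
#'   is 0.0001 to 1.
#' @param batch_size Minibatch size; the conventional search range is
#'   4 to 64.
#' @param epochs Training epochs.
#' @param lr_decay `"none"` (constant learning rate) or `"cosine"`
#'   (cosine annealing from `learning_rate` to 1/100 of it over the
#'   epochs).
#' @param head Readout head: `"flatten"` (position-preserving
#'   flatten-then-dense, the default) or `"maxpool"` (global max over
#'   positions per channel — a motif-detector readout that generalizes
#'   across small placement shifts, useful for small training sets).
#' @param encoding Feature encoding: `"onehot"`, `"psednc"` or `"concat"`.
#' @param activity_transform For regression targets: `"log1p"` (tames the
#'   heavy activity tail) or `"identity"`.
#' @param seed Integer seed controlling initialization and training.
#' @return A list of class `net_config`.
#' @export
net_config <- function(arch = c("resnet_attention", "simple_cnn"),
                       task = c("binary", "regression"),
                       n_resblocks = 20L,
                       channels = 16L,
                       attention_key_dim = channels,
                       dropout_rate = 0.3,
                       weight_decay = 0,
                       learning_rate = 0.001,
                       batch_size = 32L,
                       epochs = 30L,
                       lr_decay = c("none", "cosine"),
                       head = c("flatten", "maxpool"),
                       encoding = "onehot",
                       activity_transform = c("log1p", "identity"),
                       seed = 1L) {
  arch <- match.arg(arch)
  task <- match.arg(task)
  head <- match.arg(head)
  lr_decay <- match.arg(lr_decay)
  activity_transform <- match.arg(activity_transform)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0,
            dropout_rate >= 0, dropout_rate < 1, weight_decay >= 0,
            n_resblocks >= 0,
            channels >= 1, attention_key_dim >= 1)
  structure(list(arch = arch, task = task,
                 n_resblocks = as.integer(n_resblocks),
                 channels = as.integer(channels),
                 attention_key_dim = as.integer(attention_key_dim),
                 dropout_rate = dropout_rate,
                 weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_decay = lr_decay,
                 head = head,
                 encoding = encoding,
                 activity_transform = activity_transform,
                 seed = as.integer(seed)),
            class = "net_config")
}

features_to_signal <- function(X) {
  # (n x d) feature matrix -> sample-major (n*L) x C engine layout
  X <- unclass(X)
  L <- attr(X, "sequence_length")
  enc <- attr(X, "encoding") %||% "onehot"
  if (identical(enc, "onehot") && !is.null(L) && !is.na(L) &&
      ncol(X) == 4L * L) {
    list(M = matrix(as.vector(t(X)), ncol = 4L, byrow = TRUE),
         n = nrow(X), L = L, C = 4L)
  } else {
    list(M = matrix(as.vector(t(X)), ncol = 1L),
         n = nrow(X), L = ncol(X), C = 1L)
  }
}

build_layers <- function(config, c_in, L) {
  ch <- config$channels
  Lh <- L %/% 2L
  head <- config$head %||% "flatten"
  if (config$arch == "resnet_attention") {
    trunk <- c(list(nn_conv(c_in, ch, 5L), nn_relu()),
               lapply(seq_len(config$n_resblocks),
                      function(i) nn_resblock(ch, ch, 3L)),
               list(nn_attention(ch, config$attention_key_dim)))
    layers <- if (head == "maxpool") {
      c(trunk, list(nn_gmaxpool(), nn_dropout(config$dropout_rate),
                    nn_dense(ch, 1L)))
    } else {
      c(trunk, list(nn_maxpool(), nn_flatten(),
                    nn_dropout(config$dropout_rate),
                    nn_dense(Lh * ch, 1L)))
    }
  } else {
    if (head == "maxpool") {
      layers <- list(nn_conv(c_in, ch, 7L), nn_relu(),
                     nn_conv(ch, ch, 5L), nn_relu(), nn_gmaxpool(),
                     nn_dropout(config$dropout_rate),
                     nn_dense(ch, 1L))
    } else {
      layers <- list(nn_conv(c_in, ch, 7L), nn_relu(), nn_maxpool(),
                     nn_conv(ch, ch, 5L), nn_relu(), nn_flatten(),
                     nn_dropout(config$dropout_rate),
                     nn_dense(Lh * ch, 1L))
    }
  }
  if (config$task == "binary") layers <- c(layers, list(nn_sigmoid()))
  layers
}

#' Build an (untrained) supervised network
#'
#' @param config A [net_config()].
#' @param input_shape `c(L, C)`: signal length and channel count. One-hot
#'   50-mers are `c(50, 4)`; flat encodings such as pseDNC use `C = 1`.
#' @return A `promo_model` with seeded initial parameters and empty
#'   training history.
#' @export
build_network <- function(config, input_shape) {
  stopifnot(inherits(config, "net_config"), length(input_shape) == 2L)
  set.seed(config$seed)
  layers <- build_layers(config, input_shape[2L], input_shape[1L])
  structure(list(config = config, layers = layers,
                 input_shape = as.integer(input_shape),
                 history = numeric(0)),
            class = "promo_model")
}

#' @export
print.promo_model <- function(x, ...) {
  cat("<promo_model> ", x$config$arch, " / ", x$config$task,
      ", input ", x$input_shape[1L], "x", x$input_shape[2L],
      ", ", length(x$history), " epoch(s) trained\n", sep = "")
  invisible(x)
}

#' Train a supervised network by minibatch gradient descent on MSE
#'
#' Binary labels are fit by squared error against the sigmoid output;
#' regression targets by squared error against the linear output.
#' Deterministic under the config seed (initialization, shuffling and
#' dropout all flow from it).
#'
#' @param model A [build_network()] result.
#' @param X Feature matrix (rows = samples) matching the model input.
#' @param y Numeric labels in `{0,1}` (binary) or real targets
#'   (regression).
#' @param config Optional [net_config()] override (defaults to the
#'   model's own).
#' @return The trained `promo_model` with per-epoch mean loss in
#'   `$history`.
#' @export
train_supervised <- function(model, X, y, config = model$config) {
  # force the promises now: a lazily built model would otherwise reseed
  # the RNG stream mid-training via build_network()
  force(model); force(config)
  if (anyNA(y)) stop("NA/NaN in y", call. = FALSE)
  sig <- features_to_signal(X)
  if (sig$n != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (config$task == "binary") {
    if (!all(y %in% 0:1)) stop("binary task needs y in {0,1}", call. = FALSE)
    if (length(unique(y)) < 2L) {
      warning("single-class y for binary task; proceeding")
    }
  }
  if (config$epochs == 0L) return(model)
  if (config$task == "regression") {
    # fit on standardized targets; predictions are mapped back
    ym <- mean(y)
    ys <- stats::sd(y)
    if (is.na(ys) || ys == 0) ys <- 1
    y <- (y - ym) / ys
    model$target_scale <- c(mean = ym, sd = ys)
  }
  set.seed(config$seed + 1L)
  layers <- model$layers
  params <- params_of(layers)
  opt <- adam_init(params)
  n <- sig$n
  bs <- min(config$batch_size, n)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr_ep <- if (identical(config$lr_decay, "cosine")) {
      lr_min <- config$learning_rate / 100
      lr_min + (config$learning_rate - lr_min) *
        (1 + cos(pi * (ep - 1) / max(config$epochs - 1, 1))) / 2
    } else {
      config$learning_rate
    }
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      ii <- ord[start:min(start + bs - 1L, n)]
      nb <- length(ii)
      rows <- rep((ii - 1L) * sig$L, each = sig$L) + seq_len(sig$L)
      Mb <- sig$M[rows, , drop = FALSE]
      layers <- set_params(layers, params)
      fw <- net_forward(layers, Mb, nb, sig$L, train = TRUE)
      pred <- fw$st$M[, 1L]
      err <- pred - y[ii]
      losses <- c(losses, mean(err^2))
      dY <- matrix(2 * err / nb, ncol = 1L)
      bw <- net_backward(layers, fw, dY)
      stp <- adam_step(params, bw$grads, opt, lr_ep,
                       weight_decay = config$weight_decay %||% 0)
      params <- stp$params
      opt <- stp$state
    }
    history[ep] <- mean(losses)
  }
  model$layers <- set_params(layers, params)
  model$config <- config
  model$history <- c(model$history, history)
  model
}

#' Predict scores from a trained model
#'
#' Pure function of the parameters: no state is mutated, dropout is
#' disabled, and each sample's score depends only on its own row.
#'
#' @param object A `promo_model`.
#' @param X Feature matrix with the training layout.
#' @param ... Unused.
#' @return Numeric score vector (in `(0,1)` for binary models).
#' @export
predict.promo_model <- function(object, X, ...) {
  sig <- features_to_signal(X)
  if (sig$L != object$input_shape[1L] || sig$C != object$input_shape[2L]) {
    stop("feature layout ", sig$L, "x", sig$C,
         " does not match model input ", object$input_shape[1L], "x",
         object$input_shape[2L], call. = FALSE)
  }
  fw <- net_forward(object$layers, sig$M, sig$n, sig$L, train = FALSE)
  out <- as.vector(fw$st$M[, 1L])
  if (!is.null(object$target_scale)) {
    out <- out * object$target_scale[["sd"]] + object$target_scale[["mean"]]
  }
  out
}

#' Score raw sequences with a model or scoring function
#'
#' Encodes sequences with the model's configured encoding, then predicts.
#' Plain functions (`function(sequences) scores`) are accepted anywhere a
#' scorer is needed, which makes pipeline contracts testable with stubs.
#'
#' @param model A `promo_model` or a function of a character vector.
#' @param sequences Character vector of DNA sequences.
#' @return Numeric score vector.
#' @export
score_sequences <- function(model, sequences) {
  if (is.function(model)) return(as.numeric(model(sequences)))
  stats::predict(model, encode_sequences(sequences, model$config$encoding))
}

#' Apply a residual block to a feature map
#'
#' Computes `Y = F(x; Wi) + skip`, where `F` is two convolution+ReLU
#' layers and the skip path is the identity when input and output channel
#' counts match, else a 1x1 convolution projection `Ws x`.
#'
#' @param x `L x C_in` numeric matrix (positions by channels).
#' @param weights Block parameters as produced by
#'   [residual_block_weights()].
#' @return `L x C_out` matrix.
#' @export
residual_block <- function(x, weights) {
  x <- as.matrix(x)
  cin <- ncol(x)
  cout <- ncol(weights$conv2$W)
  if (nrow(weights$conv1$W) %% cin != 0) {
    stop("irreconcilable shapes between x and weights", call. = FALSE)
  }
  layer <- list(type = "resblock", k = nrow(weights$conv1$W) %/% cin,
                cin = cin, cout = cout, params = weights)
  if (cin != cout && is.null(weights$proj)) {
    stop("channel counts differ but no projection weights given",
         call. = FALSE)
  }
  r <- layer_forward(layer, list(M = x, n = 1L, L = nrow(x)))
  r$st$M
}

#' @rdname residual_block
#' @param cin,cout Channel counts.
#' @param k Kernel width (odd).
#' @param seed Seed for the random initialization.
#' @export
residual_block_weights <- function(cin, cout, k = 3L, seed = 1L) {
  set.seed(seed)
  nn_resblock(cin, cout, k)$params
}

transform_activity <- function(a, how) {
  switch(how, log1p = log1p(a), identity = a,
         stop("unknown activity transform: ", how))
}

make_folds <- function(y, k, seed, stratify = FALSE) {
  set.seed(seed)
  n <- length(y)
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      ii <- which(y == cl)
      fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' k-fold cross-validation of a network configuration
#'
#' Folds are disjoint, cover all samples, and are stratified by class for
#' binary tasks (plain shuffled folds for regression). Each fold's model
#' is trained from scratch on the remaining folds and evaluated on the
#' held-out fold: Sn/Sp/Acc/MCC/AUROC for binary (class calls at score
#' 0.5), PCC and MSE for regression (on the configured activity
#' transform scale).
#'
#' @param config A [net_config()].
#' @param dataset A [promoter_dataset()].
#' @param k Number of folds.
#' @param seed Fold-assignment seed (recorded in the report).
#' @param target `"auto"` picks `strength_label` / `realness_label` for
#'   binary tasks (whichever is labeled) and `activity` for regression.
#' @param n_ensemble Models trained per fold with different seeds; their
#'   predictions are averaged (default 1). Seed-ensembling reduces the
#'   optimization variance that dominates small-sample regression.
#' @return An `eval_report`: list with `per_fold` (tibble), the
#'   `mean_*` metrics, `pooled_*` metrics computed on the pooled
#'   out-of-fold predictions, `fold_seed`, and `folds`.
#' @export
cross_validate <- function(config, dataset, k = 5L, seed = 1L,
                           target = c("auto", "strength", "realness",
                                      "activity"),
                           n_ensemble = 1L) {
  target <- match.arg(target)
  if (target == "auto") {
    target <- if (config$task == "regression") "activity"
    else if (length(setdiff(unique(dataset$strength_label), "unknown")) == 2L)
      "strength"
    else "realness"
  }
  y <- switch(target,
    strength = as.integer(dataset$strength_label == "strong"),
    realness = as.integer(dataset$realness_label == "real"),
    activity = transform_activity(dataset$activity,
                                  config$activity_transform))
  if (anyNA(y)) stop("target contains missing values", call. = FALSE)
  X <- encode_sequences(dataset$sequence, config$encoding)
  sig_shape <- features_to_signal(X)
  fold <- make_folds(y, k, seed, stratify = config$task == "binary")
  per <- vector("list", k)
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- keep_feat_attrs(unclass(X)[tr, , drop = FALSE], X)
    Xte <- keep_feat_attrs(unclass(X)[!tr, , drop = FALSE], X)
    preds <- vapply(seq_len(n_ensemble), function(e) {
      cfg <- config
      cfg$seed <- config$seed + k * (e - 1L) + f
      model <- build_network(cfg, c(sig_shape$L, sig_shape$C))
      model <- train_supervised(model, Xtr, y[tr], cfg)
      stats::predict(model, Xte)
    }, numeric(sum(!tr)))
    preds <- matrix(preds, ncol = n_ensemble)
    pred <- rowMeans(preds)
    oof[!tr] <- pred
    yt <- y[!tr]
    per[[f]] <- if (config$task == "binary") {
      m <- binary_metrics(confusion_counts(yt, as.integer(pred > 0.5)),
                          scores = pred, labels = yt)
      tibble::tibble(fold = f, Sn = m$Sn, Sp = m$Sp, Acc = m$Acc,
                     MCC = m$MCC, AUROC = m$AUROC)
    } else {
      tibble::tibble(fold = f,
                     PCC = if (stats::sd(pred) == 0) 0
                           else pearson_cc(pred, yt),
                     MSE = mean((pred - yt)^2))
    }
  }
  per <- do.call(rbind, per)
  out <- list(per_fold = per, task = config$task, target = target,
              fold_seed = seed, folds = fold)
  for (nm in setdiff(names(per), "fold")) {
    out[[paste0("mean_", nm)]] <- mean(per[[nm]], na.rm = TRUE)
  }
  if (config$task == "binary") {
    m <- binary_metrics(confusion_counts(y, as.integer(oof > 0.5)),
                        scores = oof, labels = y)
    out$pooled_Acc <- m$Acc
    out$pooled_AUROC <- m$AUROC
  } else {
    out$pooled_PCC <- if (stats::sd(oof) == 0) 0 else pearson_cc(oof, y)
    out$pooled_MSE <- mean((oof - y)^2)
  }
  class(out) <- "eval_report"
  out
}

keep_feat_attrs <- function(m, template) {
  attr(m, "encoding") <- attr(template, "encoding")
  attr(m, "sequence_length") <- attr(template, "sequence_length")
  m
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> task ", x$task, ", target ", x$target, ", ",
      nrow(x$per_fold), " folds\n", sep = "")
  means <- x[grep("^mean_", names(x))]
  cat(paste(sprintf("%s = %.4f", sub("mean_", "", names(means)),
                    unlist(means)), collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive grid search over learning rate and batch size
#'
#' Every grid point is scored by [cross_validate()]; the best point
#' maximizes mean accuracy (binary) or mean PCC (regression). Ties break
#' to the smaller learning rate, then the smaller batch size.
#'
#' @param config Base [net_config()].
#' @param dataset A [promoter_dataset()].
#' @param learning_rates,batch_sizes Non-empty grids; the conventional
#'   ranges are 0.0001-1 and 4-64.
#' @param k Folds per evaluation.
#' @param seed Fold seed.
#' @return List with `best_config` and a one-row-per-grid-point `report`
#'   tibble.
#' @export
hyperparameter_search <- function(config, dataset,
                                  learning_rates, batch_sizes,
                                  k = 5L, seed = 1L) {
  if (length(learning_rates) == 0L || length(batch_sizes) == 0L) {
    stop("empty grid", call. = FALSE)
  }
  grid <- expand.grid(learning_rate = sort(learning_rates),
                      batch_size = sort(batch_sizes))
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$learning_rate <- grid$learning_rate[g]
    cfg$batch_size <- as.integer(grid$batch_size[g])
    rep_g <- cross_validate(cfg, dataset, k = k, seed = seed)
    score[g] <- if (config$task == "binary") rep_g$mean_Acc else rep_g$mean_PCC
  }
  report <- tibble::tibble(learning_rate = grid$learning_rate,
                           batch_size = grid$batch_size, score = score)
  ord <- order(-score, grid$learning_rate, grid$batch_size)
  best <- ord[1L]
  best_config <- config
  best_config$learning_rate <- grid$learning_rate[best]
  best_config$batch_size <- as.integer(grid$batch_size[best])
  list(best_config = best_config, report = report)
}

#' Classical regression baselines (elastic net, gradient boosted trees)
#'
#' k-fold mean PCC of an elastic-net (glmnet, alpha grid with internal
#' lambda cross-validation) or gradient-boosted-tree (xgboost, small
#' depth/rounds grid chosen on an internal 80/20 split) regressor. A fold
#' whose prediction is constant contributes PCC 0.
#'
#' @param X Feature matrix.
#' @param y Numeric activities.
#' @param model_type `"elastic_net"` or `"gradient_boosted_trees"`.
#' @param k Folds.
#' @param seed Fold and fit seed.
#' @return List with `mean_PCC` and `per_fold`.
#' @export
baseline_ml <- function(X, y,
                        model_type = c("elastic_net",
                                       "gradient_boosted_trees"),
                        k = 5L, seed = 1L) {
  model_type <- match.arg(model_type)
  X <- unclass(X)
  fold <- make_folds(y, k, seed)
  pcc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    set.seed(seed + f)
    pred <- if (model_type == "elastic_net") {
      fits <- lapply(c(0.1, 0.5, 0.9), function(a)
        glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = a,
                          nfolds = 5L))
      best <- which.min(vapply(fits, function(f0) min(f0$cvm), numeric(1)))
      as.vector(stats::predict(fits[[best]], X[!tr, , drop = FALSE],
                               s = "lambda.min"))
    } else {
      ntr <- sum(tr)
      hold <- sample.int(ntr, max(1L, round(0.2 * ntr)))
      itr <- which(tr)
      grid <- expand.grid(depth = c(2L, 4L), nrounds = c(50L, 200L))
      val_err <- apply(grid, 1L, function(gp) {
        m <- xgboost::xgboost(
          X[itr[-hold], , drop = FALSE], y[itr[-hold]],
          max_depth = gp[["depth"]], nrounds = gp[["nrounds"]],
          learning_rate = 0.1, objective = "reg:squarederror",
          verbosity = 0L, nthreads = 1L)
        p <- stats::predict(m, X[itr[hold], , drop = FALSE])
        mean((p - y[itr[hold]])^2)
      })
      gp <- grid[which.min(val_err), ]
      m <- xgboost::xgboost(
        X[tr, , drop = FALSE], y[tr],
        max_depth = gp$depth, nrounds = gp$nrounds, learning_rate = 0.1,
        objective = "reg:squarederror", verbosity = 0L, nthreads = 1L)
      stats::predict(m, X[!tr, , drop = FALSE])
    }
    pcc[f] <- if (stats::sd(pred) == 0) 0 else pearson_cc(pred, y[!tr])
  }
  list(mean_PCC = mean(pcc), per_fold = pcc)
}

#' Save / load a model checkpoint
#'
#' Single-file container (RDS) holding a format version, the config, the
#' fitted parameters, the input shape and the training history; diffusion
#' models additionally carry their noise schedule and per-epoch
#' checkpoints.
#'
#' @param model A `promo_model` or `promodiff_model`.
#' @param path File path.
#' @return `path` invisibly; `load_model()` returns the reconstructed
#'   model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "promo_model")) {
    obj <- list(format_version = 1L, kind = "supervised",
                config = model$config, input_shape = model$input_shape,
                params = params_of(model$layers), history = model$history)
  } else if (inherits(model, "promodiff_model")) {
    obj <- list(format_version = 1L, kind = "diffusion",
                unet_config = model$unet_config, schedule = model$schedule,
                params = params_of(model$layers),
                checkpoints = model$checkpoints, history = model$history,
                seq_length = model$seq_length,
                objective = model$objective)
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported checkpoint format version", call. = FALSE)
  }
  if (obj$kind == "supervised") {
    model <- build_network(obj$config, obj$input_shape)
    model$layers <- set_params(model$layers, obj$params)
    model$history <- obj$history
    model
  } else {
    model <- promodiff_skeleton(obj$unet_config, obj$schedule)
    model$layers <- set_params(model$layers, obj$params)
    model$checkpoints <- obj$checkpoints
    model$history <- obj$history
    model$seq_length <- obj$seq_length
    model$objective <- obj$objective
    model
  }
}
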