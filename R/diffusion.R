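#' Linear-beta diffusion noise schedule
#'
#' Builds the step-wise variance schedule of the forward (noising)
#' process: `beta_t` linearly spaced in `[beta_min, beta_max]`,
#' `alpha_t = 1 - beta_t`, and `alpha_bar_t = prod(alpha_1..alpha_t)`
#' (strictly decreasing).
#'
#' @param T Number of diffusion steps (>= 1).
#' @param beta_min,beta_max Schedule bounds, `0 < beta_min <= beta_max
#'   < 1`. Defaults 1e-4 and 0.02.
#' @return A list of class `diffusion_schedule` with `T`, `beta`,
#'   `alpha`, `alpha_bar`.
#' @export
make_schedule <- function(T = 1000L, beta_min = 1e-4, beta_max = 0.02) {
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  if (!(beta_min > 0 && beta_min <= beta_max && beta_max < 1)) {
    stop("need 0 < beta_min <= beta_max < 1", call. = FALSE)
  }
  beta <- if (T == 1L) beta_min else seq(beta_min, beta_max, length.out = T)
  alpha <- 1 - beta
  structure(list(T = as.integer(T), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "diffusion_schedule")
}

#' Encode sequences for diffusion
#'
#' One-hot encodes and rescales to `[-1, 1]` (the continuous relaxation
#' the diffusion process operates on).
#'
#' @param sequences Character vector of equal-length sequences.
#' @return An `n x 4L` matrix with values in `{-1, 1}`.
#' @export
encode_for_diffusion <- function(sequences) {
  X <- one_hot_encode(sequences)
  keep_feat_attrs(2 * unclass(X) - 1, X)
}

#' Closed-form forward diffusion
#'
#' Draws `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`
#' with `eps ~ N(0, I)` — the marginal `q(x_t | x_0)` of the noising
#' chain, applied in one jump.
#'
#' @param x0 Numeric matrix of encoded samples (values in `[-1, 1]`).
#' @param t Step index in `1..T`.
#' @param schedule A [make_schedule()] result.
#' @param seed Integer RNG seed.
#' @return Matrix of the same shape as `x0`.
#' @export
forward_diffuse <- function(x0, t, schedule, seed = 1L) {
  if (t < 1L || t > schedule$T) {
    stop("t out of range 1..", schedule$T, call. = FALSE)
  }
  x0 <- unclass(x0)
  set.seed(seed)
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) *
    matrix(stats::rnorm(length(x0)), nrow(x0), ncol(x0))
}

#' UNet denoiser configuration
#'
#' The denoiser takes the noised `50 x 4` signal plus a sinusoidal
#' embedding of the step index and predicts the added noise. Encoder:
#' convolution, residual block (skip-connected to the decoder),
#' max-pool downsampling, residual block and self-attention at the
#' bottleneck; decoder: residual block, nearest-neighbor upsampling back
#' to the input length, skip concatenation and two convolutions. The
#' downsampling and upsampling factors compose to the identity on the
#' input shape.
#'
#' @param channels Channel width (default 16).
#' @param time_dim Sinusoidal time-embedding dimension (default 16).
#' @param pos_dim Sinusoidal positional-encoding channels appended to
#'   the input (default 4). Convolutions and un-positioned attention are
#'   translation-equivariant, so without these channels the denoiser
#'   could not place motifs at absolute positions.
#' @param seed Initialization seed.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(channels = 16L, time_dim = 16L, pos_dim = 4L,
                        seed = 1L) {
  stopifnot(pos_dim %% 2L == 0L)
  structure(list(channels = as.integer(channels),
                 time_dim = as.integer(time_dim),
                 pos_dim = as.integer(pos_dim),
                 seed = as.integer(seed)),
            class = "unet_config")
}

position_encoding <- function(L, pos_dim) {
  half <- pos_dim %/% 2L
  p <- seq_len(L)
  do.call(cbind, c(
    lapply(seq_len(half), function(j) sin(2^j * pi * p / L)),
    lapply(seq_len(half), function(j) cos(2^j * pi * p / L))))
}

promodiff_skeleton <- function(cfg, schedule) {
  set.seed(cfg$seed)
  ch <- cfg$channels
  layers <- list(
    conv_in = nn_conv(4L + cfg$pos_dim, ch, 5L),
    temb1 = nn_dense(cfg$time_dim, ch),
    temb2 = nn_dense(cfg$time_dim, ch),
    res1 = nn_resblock(ch, ch, 3L),
    res2 = nn_resblock(ch, ch, 3L),
    attn = nn_attention(ch, ch),
    res3 = nn_resblock(ch, ch, 3L),
    dec1 = nn_conv(2L * ch, ch, 3L),
    conv_out = nn_conv(ch, 4L, 3L)
  )
  # zero-init the output conv so the untrained net predicts zero (the
  # residual branches already start at identity)
  layers$conv_out$params$W[] <- 0
  structure(list(unet_config = cfg, schedule = schedule, layers = layers,
                 checkpoints = list(), history = numeric(0)),
            class = "promodiff_model")
}

#' @export
print.promodiff_model <- function(x, ...) {
  cat("<promodiff_model> ", x$unet_config$channels, " channels, T = ",
      x$schedule$T, ", ", length(x$history), " epoch(s) trained, ",
      length(x$checkpoints), " checkpoint(s)\n", sep = "")
  invisible(x)
}

time_embedding <- function(t, T, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(t / T * 1000, freqs)
  cbind(sin(ang), cos(ang))
}

unet_forward <- function(layers, M, n, temb, train = FALSE) {
  L <- nrow(M) %/% n
  Lh <- L %/% 2L
  cc <- list()
  pos_dim <- layers$conv_in$cin - 4L
  if (pos_dim > 0L) {
    pe <- position_encoding(L, pos_dim)
    M <- cbind(M, pe[rep(seq_len(L), n), , drop = FALSE])
  }
  t1 <- sweep(temb %*% layers$temb1$params$W, 2L,
              layers$temb1$params$b[1L, ], "+")
  t2 <- sweep(temb %*% layers$temb2$params$W, 2L,
              layers$temb2$params$b[1L, ], "+")
  r_in <- conv_forward(layers$conv_in, M, n, L)
  cc$conv_in <- r_in$cache
  h0 <- r_in$out + t1[rep(seq_len(n), each = L), , drop = FALSE]
  cc$mask0 <- h0 > 0
  h0 <- h0 * cc$mask0
  f1 <- layer_forward(layers$res1, list(M = h0, n = n, L = L))
  cc$res1 <- f1$cache
  skip <- f1$st$M
  fp <- layer_forward(nn_maxpool(), list(M = skip, n = n, L = L))
  cc$pool <- fp$cache
  p <- fp$st$M + t2[rep(seq_len(n), each = Lh), , drop = FALSE]
  f2 <- layer_forward(layers$res2, list(M = p, n = n, L = Lh))
  cc$res2 <- f2$cache
  fa <- attention_forward(layers$attn, f2$st$M, n, Lh)
  cc$attn <- fa$cache
  f3 <- layer_forward(layers$res3, list(M = fa$out, n = n, L = Lh))
  cc$res3 <- f3$cache
  up <- f3$st$M[rep(seq_len(n * Lh), each = 2L), , drop = FALSE]
  catM <- cbind(up, skip)
  rd <- conv_forward(layers$dec1, catM, n, L)
  cc$dec1 <- rd$cache
  cc$maskd <- rd$out > 0
  hd <- rd$out * cc$maskd
  ro <- conv_forward(layers$conv_out, hd, n, L)
  cc$conv_out <- ro$cache
  list(out = ro$out, cache = cc, temb = temb, n = n, L = L)
}

unet_backward <- function(layers, fw, dY) {
  n <- fw$n; L <- fw$L; Lh <- L %/% 2L
  ch <- ncol(layers$temb1$params$W)
  g <- list()
  bo <- conv_backward(layers$conv_out, dY, fw$cache$conv_out)
  g$conv_out <- bo$grads
  d_hd <- bo$dx * fw$cache$maskd
  bd <- conv_backward(layers$dec1, d_hd, fw$cache$dec1)
  g$dec1 <- bd$grads
  d_up <- bd$dx[, seq_len(ch), drop = FALSE]
  d_skip <- bd$dx[, ch + seq_len(ch), drop = FALSE]
  grp <- rep(seq_len(n * Lh), each = 2L)
  d_r3 <- rowsum(d_up, grp)
  b3 <- layer_backward(layers$res3, d_r3, fw$cache$res3,
                       list(n = n, L = Lh))
  g$res3 <- b3$grads
  ba <- attention_backward(layers$attn, b3$dx, fw$cache$attn)
  g$attn <- ba$grads
  b2 <- layer_backward(layers$res2, ba$dx, fw$cache$res2,
                       list(n = n, L = Lh))
  g$res2 <- b2$grads
  # time-embedding branch at the bottleneck
  grp2 <- rep(seq_len(n), each = Lh)
  d_t2 <- rowsum(b2$dx, grp2)
  g$temb2 <- list(W = crossprod(fw$temb, d_t2),
                  b = matrix(colSums(d_t2), 1L))
  bp <- layer_backward(nn_maxpool(), b2$dx, fw$cache$pool,
                       list(n = n, L = L))
  d_skip_total <- d_skip + bp$dx
  b1 <- layer_backward(layers$res1, d_skip_total, fw$cache$res1,
                       list(n = n, L = L))
  g$res1 <- b1$grads
  d_h0 <- b1$dx * fw$cache$mask0
  grp1 <- rep(seq_len(n), each = L)
  d_t1 <- rowsum(d_h0, grp1)
  g$temb1 <- list(W = crossprod(fw$temb, d_t1),
                  b = matrix(colSums(d_t1), 1L))
  bi <- conv_backward(layers$conv_in, d_h0, fw$cache$conv_in)
  g$conv_in <- bi$grads
  list(grads = g, dx = bi$dx)
}

#' Train the diffusion generator
#'
#' Epsilon-prediction training: for random `(sample, t)` pairs the UNet
#' is trained by squared error to recover the Gaussian noise injected by
#' the closed-form forward process. One parameter checkpoint is stored
#' per `checkpoint_every` epochs (default: every epoch). Deterministic
#' under `seed`.
#'
#' @param dataset A fixed-length-50 [promoter_dataset()] (any fixed even
#'   length works).
#' @param cfg A [unet_config()].
#' @param schedule A [make_schedule()] result.
#' @param epochs Training epochs.
#' @param seed Integer RNG seed.
#' @param batch_size Minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param checkpoint_every Checkpoint cadence in epochs.
#' @param ema_decay Exponential-moving-average decay for the sampling
#'   weights (default 0.999 with warmup; checkpoints and the final model
#'   store the EMA parameters, the standard practice for diffusion
#'   sampling).
#' @param objective `"x0"` (default) trains the UNet to reconstruct the
#'   clean signal; `"epsilon"` trains it to predict the injected noise.
#'   The two are affinely equivalent parameterizations of the same
#'   posterior mean; signal reconstruction trains markedly faster on
#'   near-deterministic one-hot data because at high noise the target is
#'   the (simple) clean pattern rather than a precise affine function of
#'   the noisy input.
#' @param verbose Print per-epoch loss.
#' @return A `promodiff_model` with per-epoch mean loss in `$history`
#'   and epoch-indexed `$checkpoints`.
#' @export
train_promodiff <- function(dataset, cfg = unet_config(),
                            schedule = make_schedule(), epochs = 100L,
                            seed = 1L, batch_size = 128L,
                            learning_rate = 1e-3, checkpoint_every = 1L,
                            ema_decay = 0.999,
                            objective = c("x0", "epsilon"),
                            verbose = FALSE) {
  objective <- match.arg(objective)
  if (is.null(fixed_length(dataset))) {
    stop("dataset must be fixed-length", call. = FALSE)
  }
  L <- fixed_length(dataset)
  X <- encode_for_diffusion(dataset$sequence)
  n <- nrow(X)
  M0 <- matrix(as.vector(t(unclass(X))), ncol = 4L, byrow = TRUE)
  model <- promodiff_skeleton(cfg, schedule)
  set.seed(seed)
  params <- params_of(model$layers)
  ema <- params
  step <- 0L
  opt <- adam_init(params)
  layers <- model$layers
  bs <- min(batch_size, n)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      ii <- ord[start:min(start + bs - 1L, n)]
      nb <- length(ii)
      rows <- rep((ii - 1L) * L, each = L) + seq_len(L)
      x0 <- M0[rows, , drop = FALSE]
      t <- sample.int(schedule$T, nb, replace = TRUE)
      ab <- schedule$alpha_bar[t]
      sab <- sqrt(ab)[rep(seq_len(nb), each = L)]
      somab <- sqrt(1 - ab)[rep(seq_len(nb), each = L)]
      eps <- matrix(stats::rnorm(nb * L * 4L), nb * L, 4L)
      xt <- sab * x0 + somab * eps
      temb <- time_embedding(t, schedule$T, cfg$time_dim)
      layers <- set_params(layers, params)
      fw <- unet_forward(layers, xt, nb, temb, train = TRUE)
      err <- fw$out - (if (objective == "x0") x0 else eps)
      losses <- c(losses, mean(err^2))
      bw <- unet_backward(layers, fw, 2 * err / length(err))
      stp <- adam_step(params, bw$grads, opt, learning_rate)
      params <- stp$params
      opt <- stp$state
      step <- step + 1L
      d <- min(ema_decay, (1 + step) / (10 + step))
      ema <- tree_map2(function(e, p) d * e + (1 - d) * p, ema, params)
    }
    history[ep] <- mean(losses)
    if (verbose) message("epoch ", ep, " loss ", signif(history[ep], 4))
    if (ep %% checkpoint_every == 0L) {
      model$checkpoints[[as.character(ep)]] <- ema
    }
  }
  model$layers <- set_params(layers, ema)
  model$history <- history
  model$seq_length <- L
  model$objective <- objective
  model
}

#' Sample promoters by ancestral reverse diffusion
#'
#' Starts from pure Gaussian noise and runs the learned reverse process
#' through all `T` steps, then decodes each `50 x 4` sample to a DNA
#' string by per-position argmax.
#'
#' @param model A trained `promodiff_model`.
#' @param n Number of sequences to generate.
#' @param seed Integer RNG seed.
#' @param epoch Checkpoint epoch to sample from (default: final
#'   parameters).
#' @return A `generation_batch`: list with `sequences`, `epoch`, `rpp`
#'   (unset).
#' @export
sample_promoters <- function(model, n, seed = 1L, epoch = NULL) {
  sch <- model$schedule
  cfg <- model$unet_config
  L <- model$seq_length %||% 50L
  layers <- model$layers
  if (!is.null(epoch)) {
    key <- as.character(epoch)
    if (!key %in% names(model$checkpoints)) {
      stop("no checkpoint for epoch ", epoch, call. = FALSE)
    }
    layers <- set_params(layers, model$checkpoints[[key]])
  }
  set.seed(seed)
  x <- matrix(stats::rnorm(n * L * 4L), n * L, 4L)
  ab_prev <- c(1, sch$alpha_bar)
  objective <- model$objective %||% "epsilon"
  for (t in rev(seq_len(sch$T))) {
    temb <- time_embedding(rep(t, n), sch$T, cfg$time_dim)
    net_out <- unet_forward(layers, x, n, temb)$out
    # posterior mean through the clipped x0 estimate (stabilizes the
    # late reverse steps on the bounded one-hot relaxation)
    ab_t <- sch$alpha_bar[t]
    x0_hat <- if (objective == "x0") net_out
              else (x - sqrt(1 - ab_t) * net_out) / sqrt(ab_t)
    x0_hat[x0_hat > 1] <- 1
    x0_hat[x0_hat < -1] <- -1
    mean_t <- (sqrt(ab_prev[t]) * sch$beta[t] * x0_hat +
                 sqrt(sch$alpha[t]) * (1 - ab_prev[t]) * x) / (1 - ab_t)
    if (t > 1L) {
      var_t <- (1 - ab_prev[t]) / (1 - ab_t) * sch$beta[t]
      x <- mean_t + sqrt(var_t) * matrix(stats::rnorm(n * L * 4L), n * L, 4L)
    } else {
      x <- mean_t
    }
  }
  seqs <- vapply(seq_len(n), function(i) {
    one_hot_decode(x[((i - 1L) * L + 1L):(i * L), , drop = FALSE])
  }, character(1))
  structure(list(sequences = seqs,
                 epoch = epoch %||% length(model$history), rpp = NULL),
            class = "generation_batch")
}

#' @export
print.generation_batch <- function(x, ...) {
  cat("<generation_batch> ", length(x$sequences), " sequence(s), epoch ",
      x$epoch, if (!is.null(x$rpp)) paste0(", RPP ", signif(x$rpp, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Redundancy of generated sequences
#'
#' Counts exact duplicates within a generated batch (each repeat beyond
#' the first occurrence counts once) and against a training set.
#'
#' @param batch A `generation_batch` or character vector.
#' @param training A [promoter_dataset()] or character vector.
#' @return List with `n`, `within_duplicates`, `cross_duplicates`,
#'   `unique_fraction`.
#' @export
novelty_report <- function(batch, training) {
  seqs <- if (inherits(batch, "generation_batch")) batch$sequences
          else as.character(batch)
  tr <- if (is.data.frame(training)) training$sequence
        else as.character(training)
  list(n = length(seqs),
       within_duplicates = sum(duplicated(seqs)),
       cross_duplicates = sum(seqs %in% tr),
       unique_fraction = length(unique(setdiff(seqs, tr))) /
         max(length(seqs), 1L))
}

#' Real promoter portion (RPP) of a generated batch
#'
#' Fraction of sequences that a real-vs-fake classifier scores above the
#' threshold.
#'
#' @param batch A `generation_batch` or character vector.
#' @param promor A trained real/fake `promo_model`, or a scoring
#'   function of a character vector.
#' @param threshold Score cut (default 0.5).
#' @return RPP in `[0, 1]`.
#' @export
rpp <- function(batch, promor, threshold = 0.5) {
  seqs <- if (inherits(batch, "generation_batch")) batch$sequences
          else as.character(batch)
  if (length(seqs) == 0L) stop("empty batch", call. = FALSE)
  mean(score_sequences(promor, seqs) > threshold)
}

#' RPP across training checkpoints
#'
#' Samples `n_per_epoch` sequences from every stored checkpoint and
#' scores their RPP — the curve used to pick the generation epoch.
#'
#' @param model A trained `promodiff_model` with checkpoints.
#' @param promor Real/fake scorer (model or function).
#' @param n_per_epoch Sequences sampled per checkpoint (default 100).
#' @param seed Integer RNG seed.
#' @param threshold RPP score cut.
#' @return Tibble with `epoch`, `rpp`; attribute `best_epoch` holds the
#'   argmax (first on ties).
#' @export
checkpoint_rpp_curve <- function(model, promor, n_per_epoch = 100L,
                                 seed = 1L, threshold = 0.5) {
  eps <- as.integer(names(model$checkpoints))
  if (length(eps) == 0L) stop("model has no checkpoints", call. = FALSE)
  vals <- vapply(seq_along(eps), function(j) {
    b <- sample_promoters(model, n_per_epoch, seed = seed + j,
                          epoch = eps[j])
    rpp(b, promor, threshold)
  }, numeric(1))
  out <- tibble::tibble(epoch = eps, rpp = vals)
  attr(out, "best_epoch") <- eps[which.max(vals)]
  out
}
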