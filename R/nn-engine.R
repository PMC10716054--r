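# Minimal vectorized neural-network engine.
#
# Batches of length-L, C-channel signals are carried as (n*L) x C matrices
# with rows sample-major (sample 1 positions 1..L, then sample 2, ...).
# Convolutions are im2col + one BLAS matmul; gradients are exact analytic
# backprop. Everything is deterministic given R's RNG state.

nn_rnorm <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# ---- layer constructors ------------------------------------------------

nn_conv <- function(cin, cout, k = 3L) {
  sd <- sqrt(2 / (k * cin))
  list(type = "conv", k = k, cin = cin, cout = cout,
       params = list(W = nn_rnorm(k * cin, cout, sd),
                     b = matrix(0, 1L, cout)))
}

nn_dense <- function(din, dout, act = "linear") {
  sd <- sqrt(2 / din)
  list(type = "dense", din = din, dout = dout, act = act,
       params = list(W = nn_rnorm(din, dout, sd),
                     b = matrix(0, 1L, dout)))
}

nn_relu <- function() list(type = "relu", params = list())

nn_resblock <- function(cin, cout, k = 3L) {
  # Y = F(x; Wi) + skip, F = conv-relu-conv-relu; skip is a 1x1 projection
  # when channel counts differ, identity otherwise. The second conv starts
  # at zero so a freshly built block is the identity (up to projection):
  # deep unnormalized stacks would otherwise double their activation
  # variance at every block.
  bl <- list(type = "resblock", k = k, cin = cin, cout = cout,
             params = list(conv1 = nn_conv(cin, cout, k)$params,
                           conv2 = nn_conv(cout, cout, k)$params))
  bl$params$conv2$W[] <- 0
  if (cin != cout) bl$params$proj <- nn_conv(cin, cout, 1L)$params
  bl
}

nn_attention <- function(c_in, d_k = c_in) {
  sd <- sqrt(1 / c_in)
  list(type = "attention", c_in = c_in, d_k = d_k,
       params = list(Wq = nn_rnorm(c_in, d_k, sd),
                     Wk = nn_rnorm(c_in, d_k, sd),
                     Wv = nn_rnorm(c_in, c_in, sd)))
}

nn_maxpool <- function() list(type = "maxpool", params = list())
nn_flatten <- function() list(type = "flatten", params = list())
nn_gmaxpool <- function() list(type = "gmaxpool", params = list())
nn_upsample <- function() list(type = "upsample", params = list())
nn_gap <- function() list(type = "gap", params = list())
nn_dropout <- function(rate) list(type = "dropout", rate = rate, params = list())
nn_sigmoid <- function() list(type = "sigmoid", params = list())

# ---- conv plumbing -----------------------------------------------------

conv_indices <- function(n, L, k) {
  pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  base <- rep((seq_len(n) - 1L) * Lp, each = L)
  pos <- rep(seq_len(L), times = n)
  lapply(0:(k - 1L), function(o) base + pos + o)
}

pad_rows <- function(M, n, L, pad) {
  if (pad == 0L) return(M)
  Lp <- L + 2L * pad
  Mp <- matrix(0, n * Lp, ncol(M))
  keep <- rep((seq_len(n) - 1L) * Lp, each = L) + rep(seq_len(L), n) + pad
  Mp[keep, ] <- M
  Mp
}

unpad_rows <- function(Mp, n, L, pad) {
  if (pad == 0L) return(Mp)
  Lp <- L + 2L * pad
  keep <- rep((seq_len(n) - 1L) * Lp, each = L) + rep(seq_len(L), n) + pad
  Mp[keep, , drop = FALSE]
}

conv_forward <- function(layer, M, n, L) {
  k <- layer$k
  pad <- (k - 1L) %/% 2L
  Mp <- pad_rows(M, n, L, pad)
  idx <- conv_indices(n, L, k)
  Xcol <- do.call(cbind, lapply(idx, function(ii) Mp[ii, , drop = FALSE]))
  Y <- Xcol %*% layer$params$W
  Y <- sweep(Y, 2L, layer$params$b[1L, ], "+")
  list(out = Y, cache = list(Xcol = Xcol, n = n, L = L))
}

conv_backward <- function(layer, dY, cache) {
  k <- layer$k; cin <- layer$cin
  n <- cache$n; L <- cache$L
  pad <- (k - 1L) %/% 2L
  dW <- crossprod(cache$Xcol, dY)
  db <- matrix(colSums(dY), 1L)
  dXcol <- dY %*% t(layer$params$W)
  Lp <- L + 2L * pad
  dMp <- matrix(0, n * Lp, cin)
  idx <- conv_indices(n, L, k)
  for (o in seq_len(k)) {
    cols <- ((o - 1L) * cin + 1L):(o * cin)
    ii <- idx[[o]]
    dMp[ii, ] <- dMp[ii, , drop = FALSE] + dXcol[, cols, drop = FALSE]
  }
  list(dx = unpad_rows(dMp, n, L, pad),
       grads = list(W = dW, b = db))
}

# ---- attention ---------------------------------------------------------

#' Scaled dot-product self-attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`, the single-head
#' self-attention map. Each row of the attention-weight matrix is a
#' probability distribution over the key positions.
#'
#' @param Q,K,V Numeric matrices: `Q` is `Lq x d_k`, `K` is `Lk x d_k`,
#'   `V` is `Lk x d_v`.
#' @param d_k Key dimension used in the scaling (default `ncol(K)`).
#' @param return_weights Also return the attention-weight matrix.
#' @return The `Lq x d_v` output matrix, or a list with `out` and
#'   `weights` when `return_weights = TRUE`.
#' @export
self_attention <- function(Q, K, V, d_k = ncol(K), return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (d_k <= 0) stop("d_k must be positive", call. = FALSE)
  if (ncol(Q) != ncol(K)) stop("Q and K must share dimension", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must share position count",
                               call. = FALSE)
  S <- Q %*% t(K) / sqrt(d_k)
  A <- exp(S - apply(S, 1L, max))
  A <- A / rowSums(A)
  out <- A %*% V
  if (return_weights) list(out = out, weights = A) else out
}

attention_forward <- function(layer, M, n, L) {
  p <- layer$params
  dk <- layer$d_k
  out <- matrix(0, n * L, layer$c_in)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    X <- M[rows, , drop = FALSE]
    Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
    S <- Q %*% t(K) / sqrt(dk)
    A <- exp(S - apply(S, 1L, max))
    A <- A / rowSums(A)
    out[rows, ] <- X + A %*% V   # residual connection around the head
    caches[[i]] <- list(X = X, Q = Q, K = K, V = V, A = A)
  }
  list(out = out, cache = list(per = caches, n = n, L = L))
}

attention_backward <- function(layer, dY, cache) {
  p <- layer$params
  dk <- layer$d_k
  n <- cache$n; L <- cache$L
  dWq <- 0 * p$Wq; dWk <- 0 * p$Wk; dWv <- 0 * p$Wv
  dM <- matrix(0, n * L, layer$c_in)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    cc <- cache$per[[i]]
    dO <- dY[rows, , drop = FALSE]
    dV <- crossprod(cc$A, dO)
    dA <- dO %*% t(cc$V)
    dS <- (dA - rowSums(dA * cc$A)) * cc$A / sqrt(dk)
    dQ <- dS %*% cc$K
    dK <- crossprod(dS, cc$Q)
    dWq <- dWq + crossprod(cc$X, dQ)
    dWk <- dWk + crossprod(cc$X, dK)
    dWv <- dWv + crossprod(cc$X, dV)
    dM[rows, ] <- dO + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(dx = dM, grads = list(Wq = dWq, Wk = dWk, Wv = dWv))
}

# ---- generic sequential forward/backward -------------------------------

pool_pair_idx <- function(n, L) {
  base <- rep((seq_len(n) - 1L) * L, each = L %/% 2L)
  first <- base + rep(seq(1L, L - 1L, by = 2L), n)
  list(a = first, b = first + 1L)
}

layer_forward <- function(layer, st, train = FALSE) {
  M <- st$M; n <- st$n; L <- st$L
  switch(layer$type,
    conv = {
      r <- conv_forward(layer, M, n, L)
      list(st = list(M = r$out, n = n, L = L), cache = r$cache)
    },
    relu = {
      mask <- M > 0
      list(st = list(M = M * mask, n = n, L = L), cache = mask)
    },
    sigmoid = {
      s <- 1 / (1 + exp(-M))
      list(st = list(M = s, n = n, L = L), cache = s)
    },
    resblock = {
      c1 <- list(type = "conv", k = layer$k, cin = layer$cin,
                 cout = layer$cout, params = layer$params$conv1)
      c2 <- list(type = "conv", k = layer$k, cin = layer$cout,
                 cout = layer$cout, params = layer$params$conv2)
      r1 <- conv_forward(c1, M, n, L)
      m1 <- r1$out > 0
      h1 <- r1$out * m1
      r2 <- conv_forward(c2, h1, n, L)
      m2 <- r2$out > 0
      f <- r2$out * m2
      if (!is.null(layer$params$proj)) {
        cp <- list(type = "conv", k = 1L, cin = layer$cin,
                   cout = layer$cout, params = layer$params$proj)
        rp <- conv_forward(cp, M, n, L)
        skip <- rp$out
        cache_p <- rp$cache
      } else {
        skip <- M
        cache_p <- NULL
      }
      list(st = list(M = f + skip, n = n, L = L),
           cache = list(c1 = r1$cache, m1 = m1, c2 = r2$cache, m2 = m2,
                        proj = cache_p))
    },
    attention = {
      r <- attention_forward(layer, M, n, L)
      list(st = list(M = r$out, n = n, L = L), cache = r$cache)
    },
    maxpool = {
      ii <- pool_pair_idx(n, L)
      A <- M[ii$a, , drop = FALSE]; B <- M[ii$b, , drop = FALSE]
      mask <- A >= B
      list(st = list(M = pmax(A, B), n = n, L = L %/% 2L),
           cache = list(mask = mask, idx = ii, L_in = L))
    },
    upsample = {
      rows <- rep(seq_len(n * L), each = 2L)
      list(st = list(M = M[rows, , drop = FALSE], n = n, L = 2L * L),
           cache = NULL)
    },
    gap = {
      grp <- rep(seq_len(n), each = L)
      list(st = list(M = rowsum(M, grp) / L, n = n, L = 1L),
           cache = list(L_in = L))
    },
    flatten = {
      # (n*L) x C -> n x (L*C), position-major within each row
      list(st = list(M = matrix(as.vector(t(M)), nrow = n, byrow = TRUE),
                     n = n, L = 1L),
           cache = list(L_in = L, C_in = ncol(M)))
    },
    gmaxpool = {
      # global max over positions, per sample and channel
      C <- ncol(M)
      out <- matrix(-Inf, n, C)
      amax <- matrix(0L, n, C)
      for (i in seq_len(n)) {
        block <- M[((i - 1L) * L + 1L):(i * L), , drop = FALSE]
        amax[i, ] <- max.col(t(block), ties.method = "first")
        out[i, ] <- block[cbind(amax[i, ], seq_len(C))]
      }
      list(st = list(M = out, n = n, L = 1L),
           cache = list(L_in = L, amax = amax))
    },
    dropout = {
      if (train && layer$rate > 0) {
        mask <- (matrix(stats::runif(length(M)), nrow(M)) >= layer$rate) /
          (1 - layer$rate)
        list(st = list(M = M * mask, n = n, L = L), cache = mask)
      } else {
        list(st = list(M = M, n = n, L = L), cache = NULL)
      }
    },
    dense = {
      Y <- sweep(M %*% layer$params$W, 2L, layer$params$b[1L, ], "+")
      list(st = list(M = Y, n = n, L = L), cache = M)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dY, cache, st_in) {
  switch(layer$type,
    conv = conv_backward(layer, dY, cache),
    relu = list(dx = dY * cache, grads = list()),
    sigmoid = list(dx = dY * cache * (1 - cache), grads = list()),
    resblock = {
      c1 <- list(type = "conv", k = layer$k, cin = layer$cin,
                 cout = layer$cout, params = layer$params$conv1)
      c2 <- list(type = "conv", k = layer$k, cin = layer$cout,
                 cout = layer$cout, params = layer$params$conv2)
      d_f <- dY * cache$m2
      b2 <- conv_backward(c2, d_f, cache$c2)
      d_h1 <- b2$dx * cache$m1
      b1 <- conv_backward(c1, d_h1, cache$c1)
      grads <- list(conv1 = b1$grads, conv2 = b2$grads)
      dx <- b1$dx
      if (!is.null(layer$params$proj)) {
        cp <- list(type = "conv", k = 1L, cin = layer$cin,
                   cout = layer$cout, params = layer$params$proj)
        bp <- conv_backward(cp, dY, cache$proj)
        grads$proj <- bp$grads
        dx <- dx + bp$dx
      } else {
        dx <- dx + dY
      }
      list(dx = dx, grads = grads)
    },
    attention = attention_backward(layer, dY, cache),
    maxpool = {
      n <- st_in$n; L <- cache$L_in
      dM <- matrix(0, n * L, ncol(dY))
      dM[cache$idx$a, ] <- dY * cache$mask
      dM[cache$idx$b, ] <- dM[cache$idx$b, , drop = FALSE] + dY * (!cache$mask)
      list(dx = dM, grads = list())
    },
    upsample = {
      grp <- rep(seq_len(nrow(dY) %/% 2L), each = 2L)
      list(dx = rowsum(dY, grp), grads = list())
    },
    gap = {
      L <- cache$L_in
      rows <- rep(seq_len(nrow(dY)), each = L)
      list(dx = dY[rows, , drop = FALSE] / L, grads = list())
    },
    flatten = {
      list(dx = matrix(as.vector(t(dY)), ncol = cache$C_in, byrow = TRUE),
           grads = list())
    },
    gmaxpool = {
      n <- nrow(dY); C <- ncol(dY); L <- cache$L_in
      dM <- matrix(0, n * L, C)
      rows <- (rep(seq_len(n), times = C) - 1L) * L + as.vector(cache$amax)
      dM[cbind(rows, rep(seq_len(C), each = n))] <- as.vector(dY)
      list(dx = dM, grads = list())
    },
    dropout = {
      if (is.null(cache)) list(dx = dY, grads = list())
      else list(dx = dY * cache, grads = list())
    },
    dense = {
      list(dx = dY %*% t(layer$params$W),
           grads = list(W = crossprod(cache, dY),
                        b = matrix(colSums(dY), 1L)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

net_forward <- function(layers, M, n, L, train = FALSE) {
  st <- list(M = M, n = n, L = L)
  caches <- vector("list", length(layers))
  states <- vector("list", length(layers))
  for (j in seq_along(layers)) {
    states[[j]] <- st
    r <- layer_forward(layers[[j]], st, train = train)
    caches[[j]] <- r$cache
    st <- r$st
  }
  list(st = st, caches = caches, states = states)
}

net_backward <- function(layers, fw, dY) {
  grads <- vector("list", length(layers))
  for (j in rev(seq_along(layers))) {
    b <- layer_backward(layers[[j]], dY, fw$caches[[j]], fw$states[[j]])
    grads[[j]] <- b$grads
    dY <- b$dx
  }
  list(dx = dY, grads = grads)
}

# ---- parameter tree utilities and Adam ---------------------------------

params_of <- function(layers) lapply(layers, function(l) l$params)

set_params <- function(layers, params) {
  for (j in seq_along(layers)) layers[[j]]$params <- params[[j]]
  layers
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && !is.null(names(b))) names(a)
            else seq_along(a)
    for (nm in keys) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_init <- function(params) list(m = tree_zero(params),
                                   v = tree_zero(params), t = 0L)

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) {
    # decoupled (AdamW-style) decay
    params <- tree_map2(function(p, g) p * (1 - lr * weight_decay),
                        params, params)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
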