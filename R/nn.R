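# Compact CNN engine for fixed-length one-hot DNA windows.
#
# Convolutions are im2col gathers (base-R row indexing against a
# zero-padded activation matrix) followed by dense GEMM, so the heavy
# arithmetic rides on BLAS; the col2im scatter-add in the backward pass
# is rowsum(). Layers: residual blocks of conv -> batchnorm -> leaky
# ReLU -> conv -> batchnorm added to a (projected) skip path, leaky
# ReLU, average pooling; then global average pooling, dropout on the
# feature vector, a dense layer and softmax. Training is Adam on softmax
# cross-entropy with L2 weight decay. For inference the batch-norm
# affine transforms are folded into the convolution weights.

# im2col index plan: gather/scatter vectors for a conv with 'same' zero
# padding, channel-fastest ordering on both sides. `idx` points into the
# rows of the activation matrix with one extra zero sentinel row
# (C*L + 1); `tgt` maps each patch row back to its source row for the
# scatter-add (out-of-range taps also map to the sentinel, which is
# dropped).
make_conv_plan <- function(C, L, K) {
  pad <- (K - 1L) %/% 2L
  cs <- rep_len(seq_len(C), C * K * L)
  ks <- rep(rep(seq_len(K), each = C), L)
  ls <- rep(seq_len(L), each = C * K)
  p <- ls + ks - 1L - pad
  src <- ifelse(p >= 1L & p <= L, cs + C * (p - 1L), C * L + 1L)
  list(idx = src, tgt = src, C = C, K = K, L = L)
}

# Average-pooling plan: `group[r]` is the pooled output row fed by input
# row r; `w[r]` its averaging weight (1/count, trailing window may be
# short). L1 = ceiling(L / s).
make_pool_plan <- function(C, L, s) {
  L1 <- as.integer(ceiling(L / s))
  l <- rep(seq_len(L), each = C)
  c_ <- rep_len(seq_len(C), C * L)
  q <- (l - 1L) %/% s + 1L
  cnt <- pmin(q * s, L) - (q - 1L) * s
  list(group = c_ + C * (q - 1L), w = 1 / cnt, L1 = L1)
}

# Network geometry + index plans for a model_config.
nn_build <- function(config) {
  nb <- config$n_res_blocks
  channels <- rep_len(config$channels, nb)
  pool <- rep_len(config$pool, nb)
  K <- config$kernel
  if (K %% 2L == 0L) stop("kernel width must be odd")
  lens <- integer(nb + 1L)
  lens[1] <- config$window_len
  cins <- c(4L, channels[-nb])
  ops <- vector("list", nb)
  for (b in seq_len(nb)) {
    if (K > lens[b]) {
      stop("kernel (", K, " bp) wider than pooled length (", lens[b],
           ") at block ", b)
    }
    pp <- make_pool_plan(channels[b], lens[b], pool[b])
    ops[[b]] <- list(
      conv1 = make_conv_plan(cins[b], lens[b], K),
      conv2 = make_conv_plan(channels[b], lens[b], K),
      pool = pp,
      proj = cins[b] != channels[b]
    )
    lens[b + 1L] <- pp$L1
  }
  Cl <- channels[nb]
  list(nb = nb, channels = channels, cins = cins, K = K, lens = lens,
       pool = pool, ops = ops, n_features = Cl * lens[nb + 1L])
}

nn_init_params <- function(config, geom) {
  set.seed(config$seed)
  K <- geom$K
  params <- list()
  for (b in seq_len(geom$nb)) {
    cin <- geom$cins[b]; cb <- geom$channels[b]
    sd1 <- sqrt(2 / (cin * K)); sd2 <- sqrt(2 / (cb * K))
    params[[paste0("W1.", b)]] <- matrix(stats::rnorm(cb * cin * K, 0, sd1),
                                         cb, cin * K)
    params[[paste0("b1.", b)]] <- numeric(cb)
    params[[paste0("g1.", b)]] <- rep(1, cb)
    params[[paste0("be1.", b)]] <- numeric(cb)
    params[[paste0("rm1.", b)]] <- numeric(cb)
    params[[paste0("rv1.", b)]] <- rep(1, cb)
    params[[paste0("W2.", b)]] <- matrix(stats::rnorm(cb * cb * K, 0, sd2),
                                         cb, cb * K)
    params[[paste0("b2.", b)]] <- numeric(cb)
    params[[paste0("g2.", b)]] <- rep(1, cb)
    params[[paste0("be2.", b)]] <- numeric(cb)
    params[[paste0("rm2.", b)]] <- numeric(cb)
    params[[paste0("rv2.", b)]] <- rep(1, cb)
    if (geom$ops[[b]]$proj) {
      params[[paste0("Wp.", b)]] <- matrix(stats::rnorm(cb * cin, 0,
                                                        sqrt(2 / cin)),
                                           cb, cin)
    }
  }
  nf <- geom$n_features
  params$Wd <- matrix(stats::rnorm(config$n_outputs * nf, 0, sqrt(2 / nf)),
                      config$n_outputs, nf)
  params$bd <- numeric(config$n_outputs)
  params
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Gather patches: H is (C*L) x B, returns (C*K) x (L*B) plus the padded
# activation (reused by the weight-gradient GEMM).
im2col <- function(plan, H, B) {
  Hp <- rbind(H, 0)
  P <- Hp[plan$idx, , drop = FALSE]
  dim(P) <- c(plan$C * plan$K, plan$L * B)
  P
}

conv_forward <- function(plan, W, b, H, B) {
  P <- im2col(plan, H, B)
  Y <- W %*% P + b
  dim(Y) <- c(nrow(W) * plan$L, B)
  list(Y = Y, P = P)
}

conv_backward <- function(plan, W, P, dY, B) {
  Cout <- nrow(W)
  L <- plan$L
  dYr <- dY
  dim(dYr) <- c(Cout, L * B)
  db <- rowSums(dYr)
  dW <- tcrossprod(dYr, P)
  dP <- crossprod(W, dYr)
  dim(dP) <- c(plan$C * plan$K * L, B)
  dHp <- rowsum(dP, plan$tgt)               # sorted by target row
  CL <- plan$C * L
  dH <- dHp[seq_len(min(CL, nrow(dHp))), , drop = FALSE]
  if (nrow(dH) < CL) {  # degenerate: some rows never sourced (K=1 only)
    full <- matrix(0, CL, B)
    full[as.integer(rownames(dHp))[seq_len(nrow(dH))], ] <- dH
    dH <- full
  }
  list(dW = dW, db = db, dH = dH)
}

pool_forward <- function(plan, R) {
  rowsum(R * plan$w, plan$group)
}

pool_backward <- function(plan, dH1) {
  dH1[plan$group, , drop = FALSE] * plan$w
}

bn_forward <- function(X, C, g, be, rm, rv, train) {
  N <- length(X) / C
  Xr <- X
  dim(Xr) <- c(C, N)
  if (train) {
    m <- rowMeans(Xr)
    v <- pmax(rowMeans(Xr * Xr) - m * m, 0)
    new_rm <- BN_MOMENTUM * rm + (1 - BN_MOMENTUM) * m
    new_rv <- BN_MOMENTUM * rv + (1 - BN_MOMENTUM) * v
  } else {
    m <- rm; v <- rv; new_rm <- rm; new_rv <- rv
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (Xr - m) * invstd
  out <- g * xhat + be
  dim(out) <- dim(X)
  list(out = out, xhat = xhat, invstd = invstd,
       new_rm = new_rm, new_rv = new_rv, C = C, dims = dim(X))
}

bn_backward <- function(dout, cache, g) {
  C <- cache$C
  dr <- dout
  dim(dr) <- c(C, length(dout) / C)
  N <- ncol(dr)
  xhat <- cache$xhat
  dg <- rowSums(dr * xhat)
  dbe <- rowSums(dr)
  dxhat <- dr * g
  dx <- (cache$invstd / N) *
    (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dx) <- cache$dims
  list(dx = dx, dg = dg, dbe = dbe)
}

lrelu_forward <- function(X, slope) {
  fac <- (X > 0) + 0  # numeric 0/1
  fac[fac == 0] <- slope
  list(out = X * fac, fac = fac)
}

proj_forward <- function(Wp, H, Cin, L, B) {
  Hr <- H
  dim(Hr) <- c(Cin, L * B)
  S <- Wp %*% Hr
  dim(S) <- c(nrow(Wp) * L, B)
  list(S = S, Hr = Hr)
}

# Forward pass. Returns probs and, when train = TRUE, the caches needed
# for the backward pass plus updated batch-norm running statistics.
nn_forward <- function(geom, params, config, X, train = FALSE) {
  B <- ncol(X)
  slope <- config$leaky_slope
  H <- X
  caches <- if (train) vector("list", geom$nb) else NULL
  for (b in seq_len(geom$nb)) {
    op <- geom$ops[[b]]
    c1 <- conv_forward(op$conv1, params[[paste0("W1.", b)]],
                       params[[paste0("b1.", b)]], H, B)
    bn1 <- bn_forward(c1$Y, geom$channels[b],
                      params[[paste0("g1.", b)]], params[[paste0("be1.", b)]],
                      params[[paste0("rm1.", b)]], params[[paste0("rv1.", b)]],
                      train)
    lr1 <- lrelu_forward(bn1$out, slope)
    c2 <- conv_forward(op$conv2, params[[paste0("W2.", b)]],
                       params[[paste0("b2.", b)]], lr1$out, B)
    bn2 <- bn_forward(c2$Y, geom$channels[b],
                      params[[paste0("g2.", b)]], params[[paste0("be2.", b)]],
                      params[[paste0("rm2.", b)]], params[[paste0("rv2.", b)]],
                      train)
    if (op$proj) {
      pj <- proj_forward(params[[paste0("Wp.", b)]], H, geom$cins[b],
                         geom$lens[b], B)
      S <- pj$S
      Hr <- pj$Hr
    } else {
      S <- H
      Hr <- NULL
    }
    lr2 <- lrelu_forward(bn2$out + S, slope)
    Hnew <- pool_forward(op$pool, lr2$out)
    if (train) {
      caches[[b]] <- list(H = H, Hr = Hr, c1 = c1, bn1 = bn1, lr1 = lr1,
                          c2 = c2, bn2 = bn2, lr2 = lr2)
      params[[paste0("rm1.", b)]] <- bn1$new_rm
      params[[paste0("rv1.", b)]] <- bn1$new_rv
      params[[paste0("rm2.", b)]] <- bn2$new_rm
      params[[paste0("rv2.", b)]] <- bn2$new_rv
    }
    H <- Hnew
  }
  # the flattened final feature map is the feature vector: position is
  # preserved, which is what makes the prediction model position-specific
  F_ <- H
  if (train) {
    keep <- config$dropout_keep
    mask <- matrix((stats::runif(length(F_)) < keep) / keep,
                   nrow(F_), ncol(F_))
    Fd <- F_ * mask
  } else {
    mask <- NULL
    Fd <- F_
  }
  logits <- params$Wd %*% Fd + params$bd
  lmax <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lmax))
  probs <- sweep(el, 2, colSums(el), "/")
  list(probs = probs, logits = logits, F_ = F_, Fd = Fd, mask = mask,
       caches = caches, params = params)
}

# Backward pass from softmax cross-entropy; returns gradients named like
# the parameters.
nn_backward <- function(geom, params, config, fwd, X, y) {
  B <- ncol(X)
  nout <- config$n_outputs
  Y1 <- matrix(0, nout, B)
  Y1[cbind(y, seq_len(B))] <- 1
  grads <- list()
  dlogits <- (fwd$probs - Y1) / B
  grads$Wd <- tcrossprod(dlogits, fwd$Fd)
  grads$bd <- rowSums(dlogits)
  dFd <- crossprod(params$Wd, dlogits)
  dF <- dFd * fwd$mask
  dH <- dF
  for (b in rev(seq_len(geom$nb))) {
    op <- geom$ops[[b]]
    L <- geom$lens[b]
    cache <- fwd$caches[[b]]
    dZ <- pool_backward(op$pool, dH) * cache$lr2$fac
    # conv2 branch
    bb2 <- bn_backward(dZ, cache$bn2, params[[paste0("g2.", b)]])
    grads[[paste0("g2.", b)]] <- bb2$dg
    grads[[paste0("be2.", b)]] <- bb2$dbe
    cb2 <- conv_backward(op$conv2, params[[paste0("W2.", b)]], cache$c2$P,
                         bb2$dx, B)
    grads[[paste0("W2.", b)]] <- cb2$dW
    grads[[paste0("b2.", b)]] <- cb2$db
    dZ1 <- cb2$dH * cache$lr1$fac
    bb1 <- bn_backward(dZ1, cache$bn1, params[[paste0("g1.", b)]])
    grads[[paste0("g1.", b)]] <- bb1$dg
    grads[[paste0("be1.", b)]] <- bb1$dbe
    cb1 <- conv_backward(op$conv1, params[[paste0("W1.", b)]], cache$c1$P,
                         bb1$dx, B)
    grads[[paste0("W1.", b)]] <- cb1$dW
    grads[[paste0("b1.", b)]] <- cb1$db
    # skip branch
    if (op$proj) {
      dSr <- dZ
      dim(dSr) <- c(geom$channels[b], L * B)
      grads[[paste0("Wp.", b)]] <- tcrossprod(dSr, cache$Hr)
      dHskip <- crossprod(params[[paste0("Wp.", b)]], dSr)
      dim(dHskip) <- dim(cb1$dH)
    } else {
      dHskip <- dZ
    }
    dH <- cb1$dH + dHskip
  }
  grads
}

nn_loss <- function(probs, y, w = NULL) {
  p <- probs[cbind(y, seq_len(ncol(probs)))]
  ll <- log(pmax(p, 1e-12))
  if (is.null(w)) return(-mean(ll))
  -sum(w * ll) / sum(w)
}

# Per-sample weights equalizing the total weight of each class; keeps a
# class-imbalanced validation set from rewarding majority-class collapse.
class_balanced_weights <- function(y) {
  tab <- table(y)
  w <- 1 / (length(tab) * as.numeric(tab[as.character(y)]))
  unname(w)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Weight decay applies to convolution/dense weight matrices only.
is_weight_name <- function(nm) grepl("^(W1|W2|Wp|Wd)", nm)

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && is_weight_name(nm)) {
      g <- g + weight_decay * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Fold evaluation-mode batch norm (a per-channel affine transform) into
# the convolution weights, so inference runs conv -> leaky ReLU only.
nn_fold_eval <- function(geom, params) {
  fp <- list()
  for (b in seq_len(geom$nb)) {
    for (half in c(1L, 2L)) {
      W <- params[[paste0("W", half, ".", b)]]
      bias <- params[[paste0("b", half, ".", b)]]
      g <- params[[paste0("g", half, ".", b)]]
      be <- params[[paste0("be", half, ".", b)]]
      rm <- params[[paste0("rm", half, ".", b)]]
      rv <- params[[paste0("rv", half, ".", b)]]
      a <- g / sqrt(rv + BN_EPS)
      fp[[paste0("W", half, ".", b)]] <- W * a
      fp[[paste0("b", half, ".", b)]] <- a * (bias - rm) + be
    }
    if (geom$ops[[b]]$proj) fp[[paste0("Wp.", b)]] <- params[[paste0("Wp.", b)]]
  }
  fp$Wd <- params$Wd
  fp$bd <- params$bd
  fp
}

# Inference-only forward with folded batch norm; returns the class
# probability matrix.
# One residual block in eval mode (folded batch norm), without the
# trailing pooling; `plans` supplies conv index plans for the (possibly
# non-default) input length.
block_eval <- function(geom, fparams, config, b, X, plans, B) {
  slope <- config$leaky_slope
  Y1 <- conv_forward(plans$c1, fparams[[paste0("W1.", b)]],
                     fparams[[paste0("b1.", b)]], X, B)$Y
  neg <- Y1 < 0
  Y1[neg] <- slope * Y1[neg]
  Y2 <- conv_forward(plans$c2, fparams[[paste0("W2.", b)]],
                     fparams[[paste0("b2.", b)]], Y1, B)$Y
  if (geom$ops[[b]]$proj) {
    Y2 <- Y2 + proj_forward(fparams[[paste0("Wp.", b)]], X, geom$cins[b],
                            plans$c1$L, B)$S
  } else {
    Y2 <- Y2 + X
  }
  neg <- Y2 < 0
  Y2[neg] <- slope * Y2[neg]
  Y2
}

# Blocks from `from_block` on, plus the head, in eval mode. `H` is the
# pre-pooling activation of block `from_block - 1` when pool_first
# names that block, otherwise the input of block `from_block`.
nn_eval_tail <- function(geom, fparams, config, H, from_block,
                         pool_first = NULL) {
  B <- ncol(H)
  if (!is.null(pool_first)) {
    H <- pool_forward(geom$ops[[pool_first]]$pool, H)
  }
  bs <- seq_len(geom$nb)
  bs <- bs[bs >= from_block]
  for (b in bs) {
    op <- geom$ops[[b]]
    H <- pool_forward(op$pool,
                      block_eval(geom, fparams, config, b, H,
                                 list(c1 = op$conv1, c2 = op$conv2), B))
  }
  logits <- fparams$Wd %*% H + fparams$bd
  lmax <- do.call(pmax, lapply(seq_len(nrow(logits)),
                               function(r) logits[r, ]))
  el <- exp(sweep(logits, 2, lmax))
  sweep(el, 2, colSums(el), "/")
}

nn_forward_eval <- function(geom, fparams, config, X) {
  op <- geom$ops[[1]]
  R <- block_eval(geom, fparams, config, 1L, X,
                  list(c1 = op$conv1, c2 = op$conv2), ncol(X))
  nn_eval_tail(geom, fparams, config, R, from_block = 2L, pool_first = 1L)
}

# One-hot encode `w` consecutive bases starting at 0-based genome
# position `starts[b]` for each window; out-of-range positions are N.
encode_span <- function(codes, starts, w) {
  B <- length(starts)
  idx <- outer(seq_len(w), as.integer(starts), "+")  # 1-based genome index
  inb <- idx >= 1L & idx <= length(codes)
  cval <- matrix(5L, w, B)
  cval[inb] <- codes[idx[inb]]
  X <- matrix(0, 4L * w, B)
  keep <- which(cval <= 4L)
  if (length(keep)) {
    lpos <- (keep - 1L) %% w + 1L
    bpos <- (keep - 1L) %/% w + 1L
    X[cbind(cval[keep] + 4L * (lpos - 1L), bpos)] <- 1
  }
  X
}

# Genome-scan fast path. Block 1 of the network is position-local in
# eval mode (folded batch norm), so its pre-pooling output over a whole
# chromosome is computed once and per-window activations are slices of
# that map. The only discrepancy is at the outermost 2*pad window
# columns, where the per-window zero padding differs from chromosome
# context; those columns are recomputed exactly per window. Scores are
# identical to nn_predict.
nn_scan_prepare <- function(geom, fparams, config, codes,
                            chunk = 32768L) {
  L <- config$window_len
  half <- (L - 1L) %/% 2L
  C1 <- geom$channels[1]
  pad <- (geom$K - 1L) %/% 2L
  halo <- 2L * pad
  plen <- length(codes) + 2L * half
  pos_of_col <- function(col) col - half - 1L  # Rmap col -> 0-based genome pos
  Rmap <- matrix(0, C1, plen)
  Lc <- min(chunk, plen)
  plans <- list(c1 = make_conv_plan(4L, Lc + 2L * halo, geom$K),
                c2 = make_conv_plan(C1, Lc + 2L * halo, geom$K))
  s <- 1L
  while (s <= plen) {
    e <- min(s + Lc - 1L, plen)
    X <- encode_span(codes, pos_of_col(s - halo), Lc + 2L * halo)
    R <- block_eval(geom, fparams, config, 1L, X, plans, 1L)
    dim(R) <- c(C1, Lc + 2L * halo)
    Rmap[, s:e] <- R[, (halo + 1L):(halo + (e - s + 1L)), drop = FALSE]
    s <- e + 1L
  }
  ein <- 2L * halo
  list(Rmap = Rmap, half = half, ew = halo, ein = ein,
       edge_plans = list(c1 = make_conv_plan(4L, ein, geom$K),
                         c2 = make_conv_plan(C1, ein, geom$K)))
}

nn_scan_score <- function(geom, fparams, config, prep, codes, centers) {
  L <- config$window_len
  half <- prep$half
  C1 <- geom$channels[1]
  B <- length(centers)
  ew <- prep$ew
  ein <- prep$ein
  # interior: window column j lives at Rmap column center + j
  colidx <- outer(seq_len(L), as.integer(centers), "+")
  Rwin <- prep$Rmap[, as.vector(colidx), drop = FALSE]
  dim(Rwin) <- c(C1 * L, B)
  # exact per-window edges (window zero padding)
  Xl <- encode_span(codes, centers - half, ein)
  Rl <- block_eval(geom, fparams, config, 1L, Xl, prep$edge_plans, B)
  Rwin[seq_len(C1 * ew), ] <- Rl[seq_len(C1 * ew), ]
  Xr <- encode_span(codes, centers + half - ein + 1L, ein)
  Rr <- block_eval(geom, fparams, config, 1L, Xr, prep$edge_plans, B)
  Rwin[(C1 * (L - ew) + 1L):(C1 * L), ] <-
    Rr[(C1 * (ein - ew) + 1L):(C1 * ein), ]
  nn_eval_tail(geom, fparams, config, Rwin, from_block = 2L,
               pool_first = 1L)
}

# Evaluation-mode class probabilities, chunked to bound memory.
nn_predict <- function(geom, params, config, X, chunk = 64L,
                       fparams = NULL) {
  B <- ncol(X)
  if (B == 0L) return(matrix(numeric(), config$n_outputs, 0L))
  fparams <- fparams %||% nn_fold_eval(geom, params)
  out <- matrix(0, config$n_outputs, B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    out[, s:e] <- nn_forward_eval(geom, fparams, config,
                                  X[, s:e, drop = FALSE])
  }
  out
}

# Train with minibatch Adam and early stopping on validation loss.
# data_fn(epoch) must return list(X, y) (fresh augmentation every epoch);
# val is list(X, y) encoded once. Returns best-validation parameters.
nn_fit <- function(geom, params, config, data_fn, val,
                   max_epochs = 40L, patience = 5L, batch_size = 32L,
                   lr = NULL, seed = 1L, verbose = FALSE) {
  lr <- lr %||% config$lr
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  since_best <- 0L
  for (epoch in seq_len(max_epochs)) {
    set.seed(derive_seed(seed, 100000L + epoch))
    dat <- data_fn(epoch)
    n <- length(dat$y)
    perm <- sample.int(n)
    tl <- 0; nb <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      e <- min(s + batch_size - 1L, n)
      sel <- perm[s:e]
      Xb <- dat$X[, sel, drop = FALSE]
      yb <- dat$y[sel]
      fwd <- nn_forward(geom, params, config, Xb, train = TRUE)
      params <- fwd$params  # batch-norm running statistics
      grads <- nn_backward(geom, params, config, fwd, Xb, yb)
      upd <- adam_step(params, grads, state, lr, config$weight_decay)
      params <- upd$params
      state <- upd$state
      tl <- tl + nn_loss(fwd$probs, yb)
      nb <- nb + 1L
    }
    vp <- nn_predict(geom, params, config, val$X)
    vloss <- nn_loss(vp, val$y, val$w)
    vacc <- if (is.null(val$w)) {
      mean(apply(vp, 2, which.max) == val$y)
    } else {
      hit <- apply(vp, 2, which.max) == val$y
      sum(val$w * hit) / sum(val$w)      # class-balanced accuracy
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl / nb,
                                         val_loss = vloss, val_acc = vacc))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                      epoch, tl / nb, vloss, vacc))
    }
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       best_val_loss = best$loss)
}
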