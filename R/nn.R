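# Minimal 1D convolutional network engine for multichannel time series.
#
# A batch of B inputs, each T time steps x C channels, is represented as a
# single (B*T) x C matrix with samples stacked along the rows; convolutions
# are evaluated with im2col gathers and one BLAS matmul per layer, so the
# whole batch costs one dgemm. 'same' padding throughout. All weights are
# plain R matrices; Adam is implemented over flat parameter lists. No
# general autograd: each architecture wires its forward/backward pass
# explicitly (and is validated against finite differences in the tests).

.idx_cache <- new.env(parent = emptyenv())

pad_rows_idx <- function(B, T, k) {
  key <- sprintf("p%d_%d_%d", B, T, k)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  p1 <- (k - 1L) %/% 2L
  Tp <- T + k - 1L
  res <- list(p1 = p1, Tp = Tp,
              fill = rep((0:(B - 1)) * Tp, each = T) + p1 + seq_len(T))
  .idx_cache[[key]] <- res
  res
}

tap_idx <- function(B, T, k, j) {
  key <- sprintf("t%d_%d_%d_%d", B, T, k, j)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Tp <- T + k - 1L
  res <- rep((0:(B - 1)) * Tp, each = T) + (j - 1L) + seq_len(T)
  .idx_cache[[key]] <- res
  res
}

im2col <- function(X, B, T, k, pad_value = 0) {
  Cin <- ncol(X)
  pr <- pad_rows_idx(B, T, k)
  Xp <- matrix(pad_value, nrow = B * pr$Tp, ncol = Cin)
  Xp[pr$fill, ] <- X
  Xc <- matrix(0, nrow = B * T, ncol = k * Cin)
  for (j in seq_len(k)) {
    Xc[, ((j - 1) * Cin + 1):(j * Cin)] <- Xp[tap_idx(B, T, k, j), ,
                                              drop = FALSE]
  }
  Xc
}

col2im <- function(dXc, B, T, k, Cin) {
  pr <- pad_rows_idx(B, T, k)
  dXp <- matrix(0, nrow = B * pr$Tp, ncol = Cin)
  for (j in seq_len(k)) {
    idx <- tap_idx(B, T, k, j)
    dXp[idx, ] <- dXp[idx, ] + dXc[, ((j - 1) * Cin + 1):(j * Cin),
                                   drop = FALSE]
  }
  dXp[pr$fill, , drop = FALSE]
}

conv_init <- function(k, cin, cout) {
  list(W = matrix(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                  nrow = k * cin, ncol = cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

conv_fw <- function(p, X, B, T) {
  if (p$k == 1L) {
    # pointwise convolution is a plain channel mix
    Y <- X %*% p$W
    Y <- sweep(Y, 2, p$b, "+")
    return(list(Y = Y, cache = X))
  }
  Xc <- im2col(X, B, T, p$k)
  Y <- Xc %*% p$W
  Y <- sweep(Y, 2, p$b, "+")
  list(Y = Y, cache = Xc)
}

conv_bw <- function(p, cache, dY, B, T) {
  if (p$k == 1L) {
    return(list(dW = crossprod(cache, dY), db = colSums(dY),
                dX = dY %*% t(p$W)))
  }
  list(dW = crossprod(cache, dY), db = colSums(dY),
       dX = col2im(dY %*% t(p$W), B, T, p$k, p$cin))
}

relu_fw <- function(X) pmax(X, 0)
relu_bw <- function(X, dY) dY * (X > 0)

# Width-3 same-padded max pooling via clamped shift indices: position t
# pools {t-1, t, t+1} within its own sample, edges pooling what exists.
mp3_idx <- function(B, T) {
  key <- sprintf("m%d_%d", B, T)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  t <- seq_len(T)
  prev <- pmax(t - 1L, 1L); nxt <- pmin(t + 1L, T)
  off <- rep((0:(B - 1)) * T, each = T)
  res <- list(prev = off + prev, nxt = off + nxt,
              starts = (0:(B - 1)) * T + 1L, ends = (1:B) * T)
  .idx_cache[[key]] <- res
  res
}

maxpool3_fw <- function(X, B, T) {
  ix <- mp3_idx(B, T)
  a <- X[ix$prev, , drop = FALSE]
  c <- X[ix$nxt, , drop = FALSE]
  Y <- pmax(a, X, c)
  list(Y = Y, cache = list(a = a, b = X, c = c, Y = Y))
}

maxpool3_bw <- function(cache, dY, B, T) {
  ix <- mp3_idx(B, T)
  m1 <- cache$a == cache$Y
  m2 <- (cache$b == cache$Y) & !m1
  m3 <- (cache$c == cache$Y) & !m1 & !m2
  dX <- dY * m2
  ga <- dY * m1                     # flows to row prev[t]
  gc <- dY * m3                     # flows to row nxt[t]
  n <- nrow(dX)
  # shift-down scatter for the prev taps (cross-sample rows masked out)
  sh <- rbind(ga[-1, , drop = FALSE], 0)
  sh[ix$ends, ] <- 0
  dX <- dX + sh
  dX[ix$starts, ] <- dX[ix$starts, ] + ga[ix$starts, ]
  # shift-up scatter for the next taps
  sh <- rbind(0, gc[-n, , drop = FALSE])
  sh[ix$starts, ] <- 0
  dX <- dX + sh
  dX[ix$ends, ] <- dX[ix$ends, ] + gc[ix$ends, ]
  dX
}

# Non-overlapping average pooling along time with stride s (truncates the
# remainder); returns T2 = floor(T / s) steps per sample.
avgpool_fw <- function(X, B, T, s) {
  T2 <- T %/% s
  keep <- as.vector(vapply(0:(B - 1), function(b) b * T + seq_len(T2 * s),
                           numeric(T2 * s)))
  Xk <- X[keep, , drop = FALSE]
  grp <- rep(seq_len(B * T2), each = s)
  Y <- rowsum(Xk, grp, reorder = FALSE) / s
  list(Y = Y, T2 = T2)
}

avgpool_bw <- function(dY, B, T, s) {
  T2 <- T %/% s
  dXk <- dY[rep(seq_len(B * T2), each = s), , drop = FALSE] / s
  dX <- matrix(0, nrow = B * T, ncol = ncol(dY))
  keep <- as.vector(vapply(0:(B - 1), function(b) b * T + seq_len(T2 * s),
                           numeric(T2 * s)))
  dX[keep, ] <- dXk
  dX
}

gap_fw <- function(X, B, T) {
  rowsum(X, rep(seq_len(B), each = T), reorder = FALSE) / T
}

gap_bw <- function(dY, B, T) {
  dY[rep(seq_len(B), each = T), , drop = FALSE] / T
}

dense_init <- function(fin, fout) {
  list(W = matrix(rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout),
       b = numeric(fout))
}

dense_fw <- function(p, X) sweep(X %*% p$W, 2, p$b, "+")

dense_bw <- function(p, X, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = dY %*% t(p$W))
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Cross-entropy loss and gradient wrt logits; y in {0, 1} -> columns 1, 2.
softmax_ce <- function(Z, y) {
  P <- softmax(Z)
  B <- nrow(Z)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dZ = dZ / B, P = P)
}

# ---- Adam over arbitrarily nested parameter lists -------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p) %||% as.character(seq_along(p))
  nms[nms == ""] <- as.character(which(nms == ""))
  for (i in seq_along(p)) {
    v <- p[[i]]
    key <- paste0(prefix, nms[i])
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(key, ".")))
    else if (is.numeric(v) && nms[i] %in% c("W", "b")) out[[key]] <- v
  }
  out
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(x) x * 0), v = lapply(fl, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  fl_p <- flatten_params(params)
  for (key in names(fl_p)) {
    g <- grads[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    fl_p[[key]] <- fl_p[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = unflatten_params(params, fl_p), state = state)
}

unflatten_params <- function(p, fl, prefix = "") {
  nms <- names(p) %||% as.character(seq_along(p))
  nms[nms == ""] <- as.character(which(nms == ""))
  for (i in seq_along(p)) {
    v <- p[[i]]
    key <- paste0(prefix, nms[i])
    if (is.list(v)) p[[i]] <- unflatten_params(v, fl, paste0(key, "."))
    else if (is.numeric(v) && nms[i] %in% c("W", "b") && !is.null(fl[[key]])) {
      p[[i]] <- fl[[key]]
    }
  }
  p
}

# ---- Architectures --------------------------------------------------------

# FCN: three conv blocks (kernels 8, 5, 3) + ReLU, global average pooling,
# dense softmax head. Filter counts follow the reference design scaled by
# `nf` (reference uses 128/256/128).
fcn_init <- function(cin, nf) {
  list(c1 = conv_init(8L, cin, nf), c2 = conv_init(5L, nf, 2L * nf),
       c3 = conv_init(3L, 2L * nf, nf), head = dense_init(nf, 2L))
}

fcn_fwbw <- function(params, X, B, T, y = NULL) {
  f1 <- conv_fw(params$c1, X, B, T); a1 <- relu_fw(f1$Y)
  f2 <- conv_fw(params$c2, a1, B, T); a2 <- relu_fw(f2$Y)
  f3 <- conv_fw(params$c3, a2, B, T); a3 <- relu_fw(f3$Y)
  g <- gap_fw(a3, B, T)
  Z <- dense_fw(params$head, g)
  if (is.null(y)) return(list(probs = softmax(Z)))
  ce <- softmax_ce(Z, y)
  dh <- dense_bw(params$head, g, ce$dZ)
  d3 <- conv_bw(params$c3, f3$cache, relu_bw(f3$Y, gap_bw(dh$dX, B, T)), B, T)
  d2 <- conv_bw(params$c2, f2$cache, relu_bw(f2$Y, d3$dX), B, T)
  d1 <- conv_bw(params$c1, f1$cache, relu_bw(f1$Y, d2$dX), B, T)
  list(loss = ce$loss, probs = ce$P, grads = list(
    c1.W = d1$dW, c1.b = d1$db, c2.W = d2$dW, c2.b = d2$db,
    c3.W = d3$dW, c3.b = d3$db, head.W = dh$dW, head.b = dh$db))
}

# Simple CNN: two conv + ReLU + average-pool (stride 3) stages, then global
# average pooling and a dense softmax head.
cnn_init <- function(cin, nf) {
  list(c1 = conv_init(7L, cin, nf), c2 = conv_init(7L, nf, 2L * nf),
       head = dense_init(2L * nf, 2L))
}

cnn_fwbw <- function(params, X, B, T, y = NULL) {
  f1 <- conv_fw(params$c1, X, B, T); a1 <- relu_fw(f1$Y)
  p1 <- avgpool_fw(a1, B, T, 3L); T1 <- p1$T2
  f2 <- conv_fw(params$c2, p1$Y, B, T1); a2 <- relu_fw(f2$Y)
  p2 <- avgpool_fw(a2, B, T1, 3L); T2 <- p2$T2
  g <- gap_fw(p2$Y, B, T2)
  Z <- dense_fw(params$head, g)
  if (is.null(y)) return(list(probs = softmax(Z)))
  ce <- softmax_ce(Z, y)
  dh <- dense_bw(params$head, g, ce$dZ)
  dp2 <- avgpool_bw(gap_bw(dh$dX, B, T2), B, T1, 3L)
  d2 <- conv_bw(params$c2, f2$cache, relu_bw(f2$Y, dp2), B, T1)
  dp1 <- avgpool_bw(d2$dX, B, T, 3L)
  d1 <- conv_bw(params$c1, f1$cache, relu_bw(f1$Y, dp1), B, T)
  list(loss = ce$loss, probs = ce$P, grads = list(
    c1.W = d1$dW, c1.b = d1$db, c2.W = d2$dW, c2.b = d2$db,
    head.W = dh$dW, head.b = dh$db))
}

# InceptionTime-style network: `depth` inception modules (bottleneck, three
# parallel convs with kernels 40/20/10, and a maxpool->1x1-conv branch,
# concatenated and ReLU-activated), a residual shortcut every third module,
# global average pooling and a dense softmax head.
ict_init <- function(cin, nf, depth = 3L, kernels = c(40L, 20L, 10L),
                     bottleneck = NULL) {
  bottleneck <- bottleneck %||% nf
  modules <- vector("list", depth)
  cur <- cin
  res_in <- cin
  for (i in seq_len(depth)) {
    m <- list(bn = conv_init(1L, cur, bottleneck),
              k1 = conv_init(kernels[1], bottleneck, nf),
              k2 = conv_init(kernels[2], bottleneck, nf),
              k3 = conv_init(kernels[3], bottleneck, nf),
              mp = conv_init(1L, cur, nf))
    if (i %% 3L == 0L) {
      m$sc <- conv_init(1L, res_in, 4L * nf)
      res_in <- 4L * nf
    }
    modules[[i]] <- m
    cur <- 4L * nf
  }
  list(modules = modules, head = dense_init(4L * nf, 2L),
       depth = depth, kernels = kernels)
}

ict_fwbw <- function(params, X, B, T, y = NULL) {
  depth <- params$depth
  caches <- vector("list", depth)
  Z <- X
  res <- X
  for (i in seq_len(depth)) {
    m <- params$modules[[i]]
    bn <- conv_fw(m$bn, Z, B, T)
    b1 <- conv_fw(m$k1, bn$Y, B, T)
    b2 <- conv_fw(m$k2, bn$Y, B, T)
    b3 <- conv_fw(m$k3, bn$Y, B, T)
    mp <- maxpool3_fw(Z, B, T)
    bm <- conv_fw(m$mp, mp$Y, B, T)
    cat <- cbind(b1$Y, b2$Y, b3$Y, bm$Y)
    if (!is.null(m$sc)) {
      sc <- conv_fw(m$sc, res, B, T)
      pre <- cat + sc$Y
    } else {
      sc <- NULL
      pre <- cat
    }
    out <- relu_fw(pre)
    caches[[i]] <- list(Z = Z, bn = bn, b1 = b1, b2 = b2, b3 = b3, mp = mp,
                        bm = bm, sc = sc, pre = pre, res = res)
    Z <- out
    if (!is.null(m$sc)) res <- out
  }
  g <- gap_fw(Z, B, T)
  logits <- dense_fw(params$head, g)
  if (is.null(y)) return(list(probs = softmax(logits)))
  ce <- softmax_ce(logits, y)
  dh <- dense_bw(params$head, g, ce$dZ)
  dZ <- gap_bw(dh$dX, B, T)
  grads <- list(head.W = dh$dW, head.b = dh$db)
  # shortcut gradients rejoin at the module whose output fed the residual
  pending <- vector("list", depth)
  dX0_extra <- NULL
  for (i in rev(seq_len(depth))) {
    m <- params$modules[[i]]
    cc <- caches[[i]]
    if (!is.null(pending[[i]])) { dZ <- dZ + pending[[i]] }
    dpre <- relu_bw(cc$pre, dZ)
    nf <- m$k1$cout
    d1 <- conv_bw(m$k1, cc$b1$cache, dpre[, 1:nf, drop = FALSE], B, T)
    d2 <- conv_bw(m$k2, cc$b2$cache, dpre[, nf + 1:nf, drop = FALSE], B, T)
    d3 <- conv_bw(m$k3, cc$b3$cache, dpre[, 2 * nf + 1:nf, drop = FALSE],
                  B, T)
    dm <- conv_bw(m$mp, cc$bm$cache, dpre[, 3 * nf + 1:nf, drop = FALSE],
                  B, T)
    dbn_out <- d1$dX + d2$dX + d3$dX
    dbn <- conv_bw(m$bn, cc$bn$cache, dbn_out, B, T)
    dZ_in <- dbn$dX + maxpool3_bw(cc$mp$cache, dm$dX, B, T)
    pre_key <- sprintf("modules.%d.", i)
    grads[[paste0(pre_key, "bn.W")]] <- dbn$dW
    grads[[paste0(pre_key, "bn.b")]] <- dbn$db
    grads[[paste0(pre_key, "k1.W")]] <- d1$dW
    grads[[paste0(pre_key, "k1.b")]] <- d1$db
    grads[[paste0(pre_key, "k2.W")]] <- d2$dW
    grads[[paste0(pre_key, "k2.b")]] <- d2$db
    grads[[paste0(pre_key, "k3.W")]] <- d3$dW
    grads[[paste0(pre_key, "k3.b")]] <- d3$db
    grads[[paste0(pre_key, "mp.W")]] <- dm$dW
    grads[[paste0(pre_key, "mp.b")]] <- dm$db
    if (!is.null(m$sc)) {
      dsc <- conv_bw(m$sc, cc$sc$cache, dpre, B, T)
      grads[[paste0(pre_key, "sc.W")]] <- dsc$dW
      grads[[paste0(pre_key, "sc.b")]] <- dsc$db
      target <- i - 3L
      if (target >= 1L) {
        pending[[target]] <- if (is.null(pending[[target]])) dsc$dX else
          pending[[target]] + dsc$dX
      } else {
        dX0_extra <- if (is.null(dX0_extra)) dsc$dX else dX0_extra + dsc$dX
      }
    }
    dZ <- dZ_in
  }
  list(loss = ce$loss, probs = ce$P, grads = grads,
       dX = dZ + if (!is.null(dX0_extra)) dX0_extra else 0)
}

net_init <- function(arch, cin, nf, depth = 3L, kernels = c(40L, 20L, 10L)) {
  switch(arch,
         fcn = fcn_init(cin, nf),
         cnn = cnn_init(cin, nf),
         ict = ict_init(cin, nf, depth, kernels),
         stop(sprintf("unknown architecture '%s'", arch)))
}

net_fwbw <- function(arch, params, X, B, T, y = NULL) {
  switch(arch,
         fcn = fcn_fwbw(params, X, B, T, y),
         cnn = cnn_fwbw(params, X, B, T, y),
         ict = ict_fwbw(params, X, B, T, y))
}
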