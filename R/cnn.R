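# Small CNN engine: 3x3 same-padded convolutions realised as nine
# shift-and-GEMM accumulations (BLAS does the heavy lifting), 2x2 max
# pooling, fully connected layers, softmax cross-entropy, Adam. Double
# precision throughout; deterministic given the R RNG seed and BLAS.

conv_init <- function(out_c, in_c, k = 3L) {
  # He-normal fan-in initialisation
  w <- array(stats::rnorm(out_c * in_c * k * k, 0,
                          sqrt(2 / (in_c * k * k))),
             c(out_c, in_c, k, k))
  list(W = w, b = numeric(out_c))
}

fc_init <- function(out_f, in_f) {
  list(W = matrix(stats::rnorm(out_f * in_f, 0, sqrt(2 / in_f)), out_f, in_f),
       b = numeric(out_f))
}

# im2col index cache, keyed by the (C, H, W) layer shape. For a padded
# sample of shape (C, H+2, W+2) it stores the flat gather index mapping
# each (kernel element, output pixel) pair to its padded input element.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(C, H, W_) {
  key <- paste(C, H, W_, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  # row order (c, dy, dx) fastest matches matrix(par$W, outC, C*9) columns;
  # column order (y, x) matches the output raster
  g <- expand.grid(c = seq_len(C), dy = 0:2, dx = 0:2,
                   y = seq_len(H), x = seq_len(W_))
  base <- g$c + C * (g$y + g$dy - 1L) + C * (H + 2L) * (g$x + g$dx - 1L)
  res <- list(base = base, C = C, H = H, W = W_)
  .conv_idx_cache[[key]] <- res
  res
}

pad_batch <- function(X, C, H, W_, n) {
  P <- array(0, c(C, H + 2L, W_ + 2L, n))
  P[, 2:(H + 1L), 2:(W_ + 1L), ] <- X
  dim(P) <- c(C * (H + 2L) * (W_ + 2L), n)
  P
}

im2col <- function(X) {
  d <- dim(X); C <- d[1]; H <- d[2]; W_ <- d[3]; n <- d[4]
  ci <- conv_indices(C, H, W_)
  Pm <- pad_batch(X, C, H, W_, n)
  Xg <- Pm[ci$base, , drop = FALSE]          # (C*9*H*W) x n
  dim(Xg) <- c(C * 9L, H * W_ * n)
  Xg
}

# X: (C, H, W, n) -> (outC, H, W, n), 3x3 kernel, same padding
conv_fwd <- function(X, par, Xcol = NULL) {
  d <- dim(X); H <- d[2]; W_ <- d[3]; n <- d[4]
  outC <- dim(par$W)[1]
  if (is.null(Xcol)) Xcol <- im2col(X)
  Wm <- matrix(par$W, outC)
  array(Wm %*% Xcol + par$b, c(outC, H, W_, n))
}

conv_bwd <- function(X, par, dY, Xcol = NULL) {
  d <- dim(X); C <- d[1]; H <- d[2]; W_ <- d[3]; n <- d[4]
  outC <- dim(par$W)[1]
  if (is.null(Xcol)) Xcol <- im2col(X)
  dYm <- matrix(dY, outC, H * W_ * n)
  dW <- array(tcrossprod(dYm, Xcol), dim(par$W))
  dXcol <- crossprod(matrix(par$W, outC), dYm)     # (C*9) x (H*W*n)
  # col2im: scatter-add kernel-element gradients back onto the padded grid
  ci <- conv_indices(C, H, W_)
  dim(dXcol) <- c(C * 9L * H * W_, n)
  acc <- rowsum(dXcol, group = ci$base)
  dP <- matrix(0, C * (H + 2L) * (W_ + 2L), n)
  dP[as.integer(rownames(acc)), ] <- acc
  dim(dP) <- c(C, H + 2L, W_ + 2L, n)
  list(dX = dP[, 2:(H + 1L), 2:(W_ + 1L), , drop = FALSE],
       dW = dW, db = rowSums(dYm))
}

pool_fwd <- function(X) {
  d <- dim(X); H <- d[2]; W_ <- d[3]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W_, 2L); c2 <- seq(2L, W_, 2L)
  A1 <- X[, o1, c1, , drop = FALSE]; A2 <- X[, o2, c1, , drop = FALSE]
  A3 <- X[, o1, c2, , drop = FALSE]; A4 <- X[, o2, c2, , drop = FALSE]
  Y <- pmax(A1, A2, A3, A4)
  # first-match argmax masks (ties resolved by window order)
  m1 <- A1 == Y
  m2 <- (A2 == Y) & !m1
  m3 <- (A3 == Y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(Y = Y, masks = list(m1, m2, m3, m4), in_dim = d)
}

pool_bwd <- function(cache, dY) {
  d <- cache$in_dim
  H <- d[2]; W_ <- d[3]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W_, 2L); c2 <- seq(2L, W_, 2L)
  dX <- array(0, d)
  dX[, o1, c1, ] <- dY * cache$masks[[1]]
  dX[, o2, c1, ] <- dY * cache$masks[[2]]
  dX[, o1, c2, ] <- dY * cache$masks[[3]]
  dX[, o2, c2, ] <- dY * cache$masks[[4]]
  dX
}

cnn_init_weights <- function() {
  list(conv1 = conv_init(32L, 1L),
       conv2 = conv_init(64L, 32L),
       conv3 = conv_init(128L, 64L),
       fc1 = fc_init(512L, 128L * 4L * 4L),
       fc2 = fc_init(256L, 512L),
       fc3 = fc_init(2L, 256L))
}

cnn_n_parameters <- function(w) {
  sum(vapply(unlist(w, recursive = FALSE), length, 1))
}

# pixels: n x 1024 matrix (already normalised); returns list with class
# probabilities (n x 2) and, when keep_cache, the activations for backprop.
cnn_fwd <- function(w, pixels, keep_cache = FALSE) {
  n <- nrow(pixels)
  X0 <- array(t(pixels), c(1L, 32L, 32L, n))
  Z1 <- conv_fwd(X0, w$conv1); A1 <- pmax(Z1, 0)
  P1 <- pool_fwd(A1)
  Z2 <- conv_fwd(P1$Y, w$conv2); A2 <- pmax(Z2, 0)
  P2 <- pool_fwd(A2)
  Z3 <- conv_fwd(P2$Y, w$conv3); A3 <- pmax(Z3, 0)
  P3 <- pool_fwd(A3)
  F0 <- matrix(P3$Y, 128L * 4L * 4L, n)
  Z4 <- w$fc1$W %*% F0 + w$fc1$b; A4 <- pmax(Z4, 0)
  Z5 <- w$fc2$W %*% A4 + w$fc2$b; A5 <- pmax(Z5, 0)
  Z6 <- w$fc3$W %*% A5 + w$fc3$b
  mx <- apply(Z6, 2, max)
  e <- exp(sweep(Z6, 2, mx))
  probs <- t(sweep(e, 2, colSums(e), "/"))   # n x 2
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(X0 = X0, Z1 = Z1, P1 = P1, A1pre = Z1,
                      Z2 = Z2, P2 = P2, Z3 = Z3, P3 = P3,
                      F0 = F0, Z4 = Z4, A4 = A4, Z5 = Z5, A5 = A5,
                      A1 = A1, A2 = A2, A3 = A3)
  }
  out
}

# labels01: 0 = out-of-vessel, 1 = in-vessel (class column label+1)
cnn_bwd <- function(w, fwd, labels01) {
  ca <- fwd$cache
  n <- length(labels01)
  dZ6 <- t(fwd$probs)
  dZ6[cbind(labels01 + 1L, seq_len(n))] <-
    dZ6[cbind(labels01 + 1L, seq_len(n))] - 1
  dZ6 <- dZ6 / n
  g <- list()
  g$fc3 <- list(W = dZ6 %*% t(ca$A5), b = rowSums(dZ6))
  dA5 <- t(w$fc3$W) %*% dZ6
  dZ5 <- dA5 * (ca$Z5 > 0)
  g$fc2 <- list(W = dZ5 %*% t(ca$A4), b = rowSums(dZ5))
  dA4 <- t(w$fc2$W) %*% dZ5
  dZ4 <- dA4 * (ca$Z4 > 0)
  g$fc1 <- list(W = dZ4 %*% t(ca$F0), b = rowSums(dZ4))
  dF0 <- t(w$fc1$W) %*% dZ4
  dP3 <- array(dF0, c(128L, 4L, 4L, n))
  dA3 <- pool_bwd(ca$P3, dP3)
  dZ3 <- dA3 * (ca$Z3 > 0)
  b3 <- conv_bwd(ca$P2$Y, w$conv3, dZ3)
  g$conv3 <- list(W = b3$dW, b = b3$db)
  dA2 <- pool_bwd(ca$P2, b3$dX)
  dZ2 <- dA2 * (ca$Z2 > 0)
  b2 <- conv_bwd(ca$P1$Y, w$conv2, dZ2)
  g$conv2 <- list(W = b2$dW, b = b2$db)
  dA1 <- pool_bwd(ca$P1, b2$dX)
  dZ1 <- dA1 * (ca$Z1 > 0)
  b1 <- conv_bwd(ca$X0, w$conv1, dZ1)
  g$conv1 <- list(W = b1$dW, b = b1$db)
  g
}

adam_init <- function(w) {
  zero_like <- function(x) rapply(x, function(a) a * 0, how = "replace")
  list(m = zero_like(w), v = zero_like(w), t = 0L)
}

adam_step <- function(w, g, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (ly in names(w)) for (p in names(w[[ly]])) {
    st$m[[ly]][[p]] <- beta1 * st$m[[ly]][[p]] + (1 - beta1) * g[[ly]][[p]]
    st$v[[ly]][[p]] <- beta2 * st$v[[ly]][[p]] + (1 - beta2) * g[[ly]][[p]]^2
    w[[ly]][[p]] <- w[[ly]][[p]] -
      lr * (st$m[[ly]][[p]] / bc1) / (sqrt(st$v[[ly]][[p]] / bc2) + eps)
  }
  list(w = w, st = st)
}

# per-patch standardisation to zero mean / unit variance; constant patches
# become all-zero
normalise_pixels <- function(pixels) {
  mu <- rowMeans(pixels)
  ctr <- pixels - mu
  sd <- sqrt(rowMeans(ctr^2))
  sd[sd == 0] <- 1
  ctr / sd
}
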