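# Minimal convolutional-network engine used by the shape classifier.
# Activations are kept as flat matrices with (spatial position, sample)
# rows and channel columns; convolutions become a single gather plus a
# BLAS matrix product, and max-pooling a pmax over 9 gathered row subsets.
# This layout avoids large array permutations, which dominate the runtime
# of a naive im2col implementation in R.

# position indices (pos = r + (c-1)*H, 1-based) of the 9 neighbors of every
# valid 3x3 convolution window on an H x W grid; one column per offset
conv_pos <- function(H, W, k = 3L) {
  outH <- H - k + 1L; outW <- W - k + 1L
  i <- rep(seq_len(outH), outW)
  j <- rep(seq_len(outW), each = outH)
  m <- matrix(0L, outH * outW, k * k)
  o <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    o <- o + 1L
    m[, o] <- (i + dr) + (j + dc - 1L) * H
  }
  m
}

# position indices of the 9 members of every 3x3 (stride 3) pooling window
pool_pos <- function(H, W, k = 3L) {
  outH <- H %/% k; outW <- W %/% k
  ri <- rep((seq_len(outH) - 1L) * k + 1L, outW)
  cj <- rep((seq_len(outW) - 1L) * k + 1L, each = outH)
  m <- matrix(0L, outH * outW, k * k)
  o <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    o <- o + 1L
    m[, o] <- (ri + dr) + (cj + dc - 1L) * H
  }
  m
}

# replicate per-sample position indices across a batch of N samples whose
# rows are stacked sample-major (row = pos + (n-1)*npos_in)
batch_rows <- function(pos_mat, npos_in, N) {
  off <- rep((0:(N - 1L)) * npos_in, each = nrow(pos_mat))
  do.call(cbind, lapply(seq_len(ncol(pos_mat)), function(o) {
    rep(pos_mat[, o], N) + off
  }))
}

# all gather/scatter indices for one batch size
cnn_layout <- function(N, config) {
  k <- config$kernel; d0 <- config$input_dim
  c1 <- d0 - k + 1L                    # 62
  p1 <- c1 %/% config$pool             # 20
  c2 <- p1 - k + 1L                    # 18
  p2 <- c2 %/% config$pool             # 6
  list(
    N = N, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
    conv1 = batch_rows(conv_pos(d0, d0, k), d0 * d0, N),
    pool1 = batch_rows(pool_pos(c1, c1, config$pool), c1 * c1, N),
    conv2 = batch_rows(conv_pos(p1, p1, k), p1 * p1, N),
    pool2 = batch_rows(pool_pos(c2, c2, config$pool), c2 * c2, N)
  )
}

gather_cols <- function(Xm, rows_mat) {
  # column blocks ordered offset-major: block o holds all channels
  do.call(cbind, lapply(seq_len(ncol(rows_mat)), function(o) {
    Xm[rows_mat[, o], , drop = FALSE]
  }))
}


# max pool: returns the pooled values and the argmax offset (first maximum
# wins on ties; backpropagation routes the gradient to that element)
pool_max <- function(Xm, rows_mat) {
  out <- Xm[rows_mat[, 1], , drop = FALSE]
  wh <- matrix(1L, nrow(out), ncol(out))
  for (o in 2:ncol(rows_mat)) {
    cand <- Xm[rows_mat[, o], , drop = FALSE]
    m <- cand > out
    if (any(m)) {
      out[m] <- cand[m]
      wh[m] <- o
    }
  }
  list(out = out, wh = wh)
}

pool_grad <- function(dOut, pool, nrow_in, rows_mat) {
  # linear scatter indices: rows_mat windows are disjoint, so no collisions
  src_row <- matrix(rows_mat[cbind(rep(seq_len(nrow(pool$wh)),
                                       ncol(pool$wh)),
                                   as.vector(pool$wh))],
                    nrow(pool$wh), ncol(pool$wh))
  idx <- src_row + (col(src_row) - 1L) * nrow_in
  dX <- matrix(0, nrow_in, ncol(pool$wh))
  dX[idx] <- dOut
  dX
}

relu_mask <- function(x) x > 0

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adam_update <- function(par, grads, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (nm in names(par)) {
    g <- grads[[nm]]
    st[[nm]]$m <- beta1 * st[[nm]]$m + (1 - beta1) * g
    st[[nm]]$v <- beta2 * st[[nm]]$v + (1 - beta2) * g^2
    mh <- st[[nm]]$m / (1 - beta1^t)
    vh <- st[[nm]]$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, st = st)
}

cnn_init_params <- function(config) {
  f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
  k2 <- config$kernel^2
  p2 <- ((config$input_dim - config$kernel + 1L) %/% config$pool -
           config$kernel + 1L) %/% config$pool
  flat <- p2 * p2 * f2
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  xav <- function(fan_in, fan_out, n) {
    stats::runif(n, -1, 1) * sqrt(6 / (fan_in + fan_out))
  }
  list(
    W1 = matrix(he(k2, k2 * f1), k2, f1),
    b1 = numeric(f1),
    W2 = matrix(he(k2 * f1, k2 * f1 * f2), k2 * f1, f2),
    b2 = numeric(f2),
    W3 = matrix(he(flat, flat * config$dense[1]), flat, config$dense[1]),
    b3 = numeric(config$dense[1]),
    W4 = matrix(xav(config$dense[1], config$dense[2],
                    config$dense[1] * config$dense[2]),
                config$dense[1], config$dense[2]),
    b4 = numeric(config$dense[2]),
    W5 = matrix(xav(config$dense[2], config$n_classes,
                    config$dense[2] * config$n_classes),
                config$dense[2], config$n_classes),
    b5 = numeric(config$n_classes)
  )
}

# X: (H, W, 1, N) array (or flat (H*W, N) matrix). Returns feature layers
# (3-node pre-softmax F, 256-dim intermediate) and, optionally, the cache
# for the backward pass.
cnn_forward <- function(par, X, config, ly, keep_cache = TRUE) {
  N <- ly$N
  Xflat <- matrix(as.vector(X), ncol = 1)         # stacked sample-major
  ones1 <- rep(1, nrow(ly$conv1))
  Xc1 <- cbind(gather_cols(Xflat, ly$conv1), ones1)  # (c1^2*N, 9+1)
  Z1 <- Xc1 %*% rbind(par$W1, par$b1)
  M1 <- relu_mask(Z1)
  A1 <- Z1 * M1
  P1 <- pool_max(A1, ly$pool1)                    # (p1^2*N, f1)
  Xc2 <- cbind(gather_cols(P1$out, ly$conv2), rep(1, nrow(ly$conv2)))
  Z2 <- Xc2 %*% rbind(par$W2, par$b2)
  M2 <- relu_mask(Z2)
  A2 <- Z2 * M2
  P2 <- pool_max(A2, ly$pool2)                    # (p2^2*N, f2)
  np2 <- ly$p2^2
  flat <- matrix(aperm(array(P2$out, c(np2, N, ncol(P2$out))), c(2, 1, 3)),
                 N, np2 * ncol(P2$out))
  z3 <- cbind(flat, 1) %*% rbind(par$W3, par$b3)
  a3 <- z3 * (z3 > 0)                             # 256-dim intermediate
  z4 <- cbind(a3, 1) %*% rbind(par$W4, par$b4)
  a4 <- tanh(z4)
  z5 <- cbind(a4, 1) %*% rbind(par$W5, par$b5)    # pre-softmax F
  zs <- z5 - apply(z5, 1, max)
  ez <- exp(zs)
  probs <- ez / rowSums(ez)
  out <- list(F = z5, probs = probs, intermediate = a3)
  if (keep_cache) {
    out$cache <- list(Xc1 = Xc1, M1 = M1, A1 = A1, P1 = P1, Xc2 = Xc2,
                      M2 = M2, A2 = A2, P2 = P2, flat = flat, z3 = z3,
                      a3 = a3, a4 = a4)
  }
  out
}

cnn_backward <- function(par, fwd, y_onehot, config, ly) {
  ca <- fwd$cache
  N <- ly$N
  dz5 <- (fwd$probs - y_onehot) / N
  g <- list()
  g$W5 <- crossprod(ca$a4, dz5); g$b5 <- colSums(dz5)
  dz4 <- tcrossprod(dz5, par$W5) * (1 - ca$a4^2)
  g$W4 <- crossprod(ca$a3, dz4); g$b4 <- colSums(dz4)
  dz3 <- tcrossprod(dz4, par$W4) * (ca$z3 > 0)
  g$W3 <- crossprod(ca$flat, dz3); g$b3 <- colSums(dz3)
  dflat <- tcrossprod(dz3, par$W3)
  np2 <- ly$p2^2
  dP2 <- matrix(aperm(array(dflat, c(N, np2, ncol(ca$P2$out))), c(2, 1, 3)),
                np2 * N, ncol(ca$P2$out))
  dZ2 <- pool_grad(dP2, ca$P2, nrow(ca$A2), ly$pool2) * ca$M2
  gW2 <- crossprod(ca$Xc2, dZ2)
  g$W2 <- gW2[seq_len(nrow(gW2) - 1L), , drop = FALSE]
  g$b2 <- gW2[nrow(gW2), ]
  dXc2 <- tcrossprod(dZ2, par$W2)
  f1 <- config$conv_filters[1]
  dP1 <- matrix(0, nrow(ca$P1$out), f1)
  for (o in seq_len(ncol(ly$conv2))) {
    r <- ly$conv2[, o]
    dP1[r, ] <- dP1[r, ] + dXc2[, (o - 1L) * f1 + seq_len(f1), drop = FALSE]
  }
  dZ1 <- pool_grad(dP1, ca$P1, nrow(ca$A1), ly$pool1) * ca$M1
  gW1 <- crossprod(ca$Xc1, dZ1)
  g$W1 <- gW1[seq_len(nrow(gW1) - 1L), , drop = FALSE]
  g$b1 <- gW1[nrow(gW1), ]
  # no input gradient needed: conv1 is the first layer
  g
}
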