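# Minimal 1-D neural-network engine: tensors are arrays of dim (L, N, C) =
# (time, batch, channels). Convolutions use im2col so all heavy lifting is
# BLAS matrix multiplication; every layer has an explicit backward pass.

nn_im2col <- function(X, K) {
  d <- dim(X); L <- d[1]; N <- d[2]; C <- d[3]
  P <- (K - 1L) %/% 2L
  if (P == 0L) return(matrix(X, L * N, C))
  Xp <- array(0, c(L + 2L * P, N, C))
  Xp[(P + 1L):(P + L), , ] <- X
  A <- array(0, c(L, N, K * C))
  for (k in seq_len(K)) {
    A[, , ((k - 1L) * C + 1L):(k * C)] <- Xp[k:(k + L - 1L), , , drop = FALSE]
  }
  matrix(A, L * N, K * C)
}

nn_col2im <- function(dM, K, L, N, C) {
  P <- (K - 1L) %/% 2L
  if (P == 0L) return(array(dM, c(L, N, C)))
  dA <- array(dM, c(L, N, K * C))
  dXp <- array(0, c(L + 2L * P, N, C))
  for (k in seq_len(K)) {
    dXp[k:(k + L - 1L), , ] <- dXp[k:(k + L - 1L), , , drop = FALSE] +
      dA[, , ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  dXp[(P + 1L):(P + L), , , drop = FALSE]
}

nn_addbias <- function(Z, b) Z + rep(b, each = nrow(Z))

# conv (same padding, odd K) ------------------------------------------------
nn_conv_fwd <- function(X, W, b, K) {
  d <- dim(X)
  M <- nn_im2col(X, K)
  Z <- nn_addbias(M %*% W, b)
  list(Y = array(Z, c(d[1], d[2], ncol(W))), M = M, dims = d)
}

nn_conv_bwd <- function(cache, W, K, dY) {
  d <- cache$dims
  dZ <- matrix(dY, d[1] * d[2], dim(dY)[3])
  list(dW = crossprod(cache$M, dZ),
       db = colSums(dZ),
       dX = nn_col2im(dZ %*% t(W), K, d[1], d[2], d[3]))
}

# relu ----------------------------------------------------------------------
nn_relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}
nn_relu_bwd <- function(cache, dY) dY * cache$mask

# max pool, factor 2 (tie -> first sample) ----------------------------------
nn_pool_fwd <- function(X) {
  L <- dim(X)[1]
  o <- seq(1L, L, 2L); e <- seq(2L, L, 2L)
  X1 <- X[o, , , drop = FALSE]; X2 <- X[e, , , drop = FALSE]
  mask <- X1 >= X2
  list(Y = pmax(X1, X2), mask = mask, L = L)
}
nn_pool_bwd <- function(cache, dY) {
  d <- dim(dY)
  dX <- array(0, c(cache$L, d[2], d[3]))
  dX[seq(1L, cache$L, 2L), , ] <- dY * cache$mask
  dX[seq(2L, cache$L, 2L), , ] <- dY * !cache$mask
  dX
}

# transpose conv, kernel 2 stride 2 (stride = kernel: no overlap) -----------
nn_up_fwd <- function(X, W, b) {
  d <- dim(X); L <- d[1]; N <- d[2]; Cin <- d[3]; Cout <- ncol(W)
  Xm <- matrix(X, L * N, Cin)
  W1 <- W[seq_len(Cin), , drop = FALSE]
  W2 <- W[Cin + seq_len(Cin), , drop = FALSE]
  Y <- array(0, c(2L * L, N, Cout))
  Y[seq(1L, 2L * L, 2L), , ] <- array(nn_addbias(Xm %*% W1, b), c(L, N, Cout))
  Y[seq(2L, 2L * L, 2L), , ] <- array(nn_addbias(Xm %*% W2, b), c(L, N, Cout))
  list(Y = Y, Xm = Xm, dims = d)
}
nn_up_bwd <- function(cache, W, dY) {
  d <- cache$dims; L <- d[1]; N <- d[2]; Cin <- d[3]
  Cout <- ncol(W)
  dY1 <- matrix(dY[seq(1L, 2L * L, 2L), , , drop = FALSE], L * N, Cout)
  dY2 <- matrix(dY[seq(2L, 2L * L, 2L), , , drop = FALSE], L * N, Cout)
  W1 <- W[seq_len(Cin), , drop = FALSE]
  W2 <- W[Cin + seq_len(Cin), , drop = FALSE]
  dW <- rbind(crossprod(cache$Xm, dY1), crossprod(cache$Xm, dY2))
  db <- colSums(dY1) + colSums(dY2)
  dX <- array(dY1 %*% t(W1) + dY2 %*% t(W2), c(L, N, Cin))
  list(dW = dW, db = db, dX = dX)
}

# nearest-neighbour upsample followed by a kernel-2 conv (same param count
# as the transpose-conv path)
nn_upnn_fwd <- function(X, W, b) {
  d <- dim(X); L <- d[1]; N <- d[2]; Cin <- d[3]
  idx <- rep(seq_len(L), each = 2L)
  Xup <- X[idx, , , drop = FALSE] # (2L, N, Cin)
  # causal kernel-2 conv: y[t] = W1 x[t-1] + W2 x[t] (left pad repeats edge)
  Xprev <- Xup[c(1L, seq_len(2L * L - 1L)), , , drop = FALSE]
  Cout <- ncol(W)
  W1 <- W[seq_len(Cin), , drop = FALSE]
  W2 <- W[Cin + seq_len(Cin), , drop = FALSE]
  Xm2 <- matrix(Xup, 2L * L * N, Cin)
  Xm1 <- matrix(Xprev, 2L * L * N, Cin)
  Y <- array(nn_addbias(Xm1 %*% W1 + Xm2 %*% W2, b), c(2L * L, N, Cout))
  list(Y = Y, Xm1 = Xm1, Xm2 = Xm2, dims = d)
}
nn_upnn_bwd <- function(cache, W, dY) {
  d <- cache$dims; L <- d[1]; N <- d[2]; Cin <- d[3]
  Cout <- ncol(W)
  dZ <- matrix(dY, 2L * L * N, Cout)
  W1 <- W[seq_len(Cin), , drop = FALSE]
  W2 <- W[Cin + seq_len(Cin), , drop = FALSE]
  dW <- rbind(crossprod(cache$Xm1, dZ), crossprod(cache$Xm2, dZ))
  db <- colSums(dZ)
  dX1 <- array(dZ %*% t(W1), c(2L * L, N, Cin))
  dX2 <- array(dZ %*% t(W2), c(2L * L, N, Cin))
  # undo the causal shift of the W1 path
  dXup <- dX2
  dXup[seq_len(2L * L - 1L), , ] <- dXup[seq_len(2L * L - 1L), , , drop = FALSE] +
    dX1[1L + seq_len(2L * L - 1L), , , drop = FALSE]
  dXup[1L, , ] <- dXup[1L, , , drop = FALSE] + dX1[1L, , , drop = FALSE]
  # undo nearest-neighbour repetition
  dX <- dXup[seq(1L, 2L * L, 2L), , , drop = FALSE] +
    dXup[seq(2L, 2L * L, 2L), , , drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

# dense ----------------------------------------------------------------------
nn_dense_fwd <- function(Xm, W, b) list(Y = nn_addbias(Xm %*% W, b), Xm = Xm)
nn_dense_bwd <- function(cache, W, dY) {
  list(dW = crossprod(cache$Xm, dY), db = colSums(dY), dX = dY %*% t(W))
}

# (L, N, C) <-> per-sample flat matrix (N, L*C)
nn_flatten <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2L, 1L, 3L)), d[2], d[1] * d[3])
}
nn_unflatten <- function(Xm, L, C) {
  aperm(array(Xm, c(nrow(Xm), L, C)), c(2L, 1L, 3L))
}

# Adam ------------------------------------------------------------------------
nn_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

nn_he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}
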