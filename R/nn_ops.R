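# Differentiable layer primitives (forward + hand-written backward) used by
# the generator and discriminator.  Feature maps are column-major arrays
# with channels last: (H, W, C) in 2D, (X, Y, Z, C) in 3D.  Convolutions
# are im2col (C++) followed by a BLAS matrix multiply; weight arrays are
# (k, k, Cin, Cout) / (k, k, k, Cin, Cout) so their column-major flattening
# matches the im2col column order.

conv2d_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  kd <- dim(W)
  cols <- cpp_im2col2d(x, kd[1], stride, pad)
  Wm <- matrix(W, ncol = kd[4])
  ym <- cols %*% Wm
  ym <- ym + rep(b, each = nrow(ym))
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- (H + 2 * pad - kd[1]) %/% stride + 1
  Wo <- (Wd + 2 * pad - kd[1]) %/% stride + 1
  out <- array(ym, dim = c(Ho, Wo, kd[4]))
  list(out = out, cache = list(cols = cols, xdim = dim(x), W = W,
                               stride = stride, pad = pad))
}

conv2d_bwd <- function(cache, dout) {
  kd <- dim(cache$W)
  dm <- matrix(dout, ncol = kd[4])
  dW <- array(crossprod(cache$cols, dm), dim = kd)
  db <- colSums(dm)
  dcols <- tcrossprod(dm, matrix(cache$W, ncol = kd[4]))
  dx <- cpp_col2im2d(dcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                     kd[1], cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

# 3D convolutions run fully in C++ (im2col into a reused workspace + BLAS
# dgemm); only the layer input is cached and the patch matrix is rebuilt in
# the backward pass, keeping the per-sample memory footprint small.
conv3d_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  out <- cpp_conv3d_fwd(x, W, b, stride, pad)
  list(out = out, cache = list(x = x, W = W, stride = stride, pad = pad))
}

conv3d_bwd <- function(cache, dout) {
  cpp_conv3d_bwd(cache$x, cache$W, dout, cache$stride, cache$pad)
}

# Normalisation over all spatial positions per channel (the batch-1 case of
# batch normalisation; deterministic and batch-size independent).  During
# training the running statistics are updated with `momentum`; evaluation
# uses the running statistics.
bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  dm <- dim(x)
  C <- dm[length(dm)]
  xm <- matrix(x, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  N <- nrow(xm)
  xhat <- (xm - rep(mu, each = N)) * rep(invstd, each = N)
  out <- array(xhat * rep(gamma, each = N) + rep(beta, each = N), dim = dm)
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    dm = dm, training = training),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(cache, dout) {
  dm <- cache$dm
  C <- dm[length(dm)]
  dom <- matrix(dout, ncol = C)
  dgamma <- colSums(dom * cache$xhat)
  dbeta <- colSums(dom)
  N <- nrow(dom)
  dxhat <- dom * rep(cache$gamma, each = N)
  if (cache$training) {
    t1 <- dxhat - rep(colMeans(dxhat), each = N)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = N)
    dx <- (t1 - t2) * rep(cache$invstd, each = N)
  } else {
    dx <- dxhat * rep(cache$invstd, each = N)
  }
  list(dx = array(dx, dim = dm), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  out <- pmax(x, 0)
  list(out = out, cache = x > 0)
}
relu_bwd <- function(cache, dout) dout * cache

lrelu_fwd <- function(x, slope = 0.2) {
  pos <- x > 0
  out <- x
  out[!pos] <- out[!pos] * slope
  list(out = out, cache = list(pos = pos, slope = slope))
}
lrelu_bwd <- function(cache, dout) {
  dout[!cache$pos] <- dout[!cache$pos] * cache$slope
  dout
}

sigmoid_fwd <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, cache = out)
}
sigmoid_bwd <- function(cache, dout) dout * cache * (1 - cache)

# Non-local self-attention on a 2D feature map x (H, W, C):
#   y = x + Proj(softmax(theta(x) phi(x)^T) sigma(x))
# with 1x1-convolution embeddings realised as channel matrix multiplies.
nonlocal_fwd <- function(x, Wt, Wp, Ws, Wo) {
  dm <- dim(x)
  Xm <- matrix(x, ncol = dm[3])
  Th <- Xm %*% Wt
  Ph <- Xm %*% Wp
  Sg <- Xm %*% Ws
  S <- tcrossprod(Th, Ph)              # N x N similarity
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, "first"))]
  A <- exp(S)
  A <- A / rowSums(A)
  O <- A %*% Sg
  Y <- Xm + O %*% Wo
  list(out = array(Y, dim = dm),
       cache = list(Xm = Xm, Th = Th, Ph = Ph, Sg = Sg, A = A, O = O,
                    Wt = Wt, Wp = Wp, Ws = Ws, Wo = Wo, dm = dm))
}

nonlocal_bwd <- function(cache, dout) {
  dm <- cache$dm
  dY <- matrix(dout, ncol = dm[3])
  dWo <- crossprod(cache$O, dY)
  dO <- tcrossprod(dY, cache$Wo)
  dA <- tcrossprod(dO, cache$Sg)
  dSg <- crossprod(cache$A, dO)
  # softmax rows backward
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dTh <- dS %*% cache$Ph
  dPh <- crossprod(dS, cache$Th)
  dXm <- dY +
    tcrossprod(dTh, cache$Wt) +
    tcrossprod(dPh, cache$Wp) +
    tcrossprod(dSg, cache$Ws)
  list(dx = array(dXm, dim = dm),
       dWt = crossprod(cache$Xm, dTh),
       dWp = crossprod(cache$Xm, dPh),
       dWs = crossprod(cache$Xm, dSg),
       dWo = dWo)
}

# Nearest-neighbour x2 upsampling of a (X, Y, Z, C) volume; the backward
# pass is its exact adjoint, 2x2x2 sum pooling.
upsample2_fwd <- function(x) {
  dm <- dim(x)
  i <- rep(seq_len(dm[1]), each = 2)
  j <- rep(seq_len(dm[2]), each = 2)
  k <- rep(seq_len(dm[3]), each = 2)
  list(out = x[i, j, k, , drop = FALSE], cache = dm)
}

upsample2_bwd <- function(cache, dout) {
  dm <- cache
  dx <- array(0, dim = dm)
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    dx <- dx + dout[seq(a, 2 * dm[1], 2), seq(b, 2 * dm[2], 2),
                    seq(cc, 2 * dm[3], 2), , drop = FALSE]
  }
  dx
}

# Adam optimiser step over a named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
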