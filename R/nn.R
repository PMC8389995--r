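# Feed-forward network internals: Glorot-normal initialization, leaky-ReLU
# forward/backward passes with inverted dropout, and Adam with the AMSGrad
# correction. Weight matrices are stored input-dim x output-dim so a batch
# forward pass is X %*% W + b.

.glorotInit <- function(layerSizes, leakySlope, biasInit = 0.005) {
  gain <- sqrt(2 / (1 + leakySlope^2))
  nl <- length(layerSizes) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    fanIn <- layerSizes[l]
    fanOut <- layerSizes[l + 1L]
    sd <- gain * sqrt(2 / (fanIn + fanOut))
    W[[l]] <- matrix(stats::rnorm(fanIn * fanOut, sd = sd), fanIn, fanOut)
    b[[l]] <- rep(biasInit, fanOut)
  }
  list(W = W, b = b)
}

.lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
.lreluGrad <- function(z, slope) ifelse(z > 0, 1, slope)

# Forward pass. Hidden layers: leaky ReLU then (in training) inverted dropout.
# Returns the output plus the per-layer pre-activations and post-dropout
# activations needed by the backward pass.
.mlpForward <- function(W, b, X, slope, dropout = 0, training = FALSE) {
  nl <- length(W)
  Z <- vector("list", nl)
  A <- vector("list", nl + 1L)
  masks <- vector("list", nl)
  A[[1L]] <- X
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], `+`)
    if (l < nl) {
      act <- .lrelu(Z[[l]], slope)
      if (training && dropout > 0) {
        masks[[l]] <- matrix(stats::runif(length(act)) >= dropout,
                             nrow(act), ncol(act)) / (1 - dropout)
        act <- act * masks[[l]]
      }
      A[[l + 1L]] <- act
    } else {
      A[[l + 1L]] <- Z[[l]]   # linear output
    }
  }
  list(out = A[[nl + 1L]], Z = Z, A = A, masks = masks)
}

# Backward pass from dL/d(output); returns gradients for W and b.
.mlpBackward <- function(W, fwd, dOut, slope) {
  nl <- length(W)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- dOut
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(fwd$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(W[[l]])
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
      delta <- delta * .lreluGrad(fwd$Z[[l - 1L]], slope)
    }
  }
  list(W = gW, b = gb)
}

.adamInit <- function(W, b) {
  zeroLike <- function(x) lapply(x, function(p) p * 0)
  list(mW = zeroLike(W), vW = zeroLike(W), vhatW = zeroLike(W),
       mb = zeroLike(b), vb = zeroLike(b), vhatb = zeroLike(b), t = 0L)
}

# One Adam/AMSGrad step with L2 weight decay folded into the gradient.
.adamStep <- function(params, grads, state, lr, beta1, beta2,
                      weightDecay, epsilon = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v, vhat) {
    g <- g + weightDecay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    vhat <- pmax(vhat, v)
    p <- p - lr * (m / bc1) / (sqrt(vhat / bc2) + epsilon)
    list(p = p, m = m, v = v, vhat = vhat)
  }
  for (l in seq_along(params$W)) {
    u <- upd(params$W[[l]], grads$W[[l]], state$mW[[l]], state$vW[[l]],
             state$vhatW[[l]])
    params$W[[l]] <- u$p; state$mW[[l]] <- u$m
    state$vW[[l]] <- u$v; state$vhatW[[l]] <- u$vhat
    u <- upd(params$b[[l]], grads$b[[l]], state$mb[[l]], state$vb[[l]],
             state$vhatb[[l]])
    params$b[[l]] <- u$p; state$mb[[l]] <- u$m
    state$vb[[l]] <- u$v; state$vhatb[[l]] <- u$vhat
  }
  list(params = params, state = state)
}
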