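#' Latent-space pairwise probabilities
#'
#' Heavy-tailed (one degree of freedom t-distribution) pairwise probabilities
#' over latent points:
#' \deqn{q_{ij} = \frac{(1 + \|s_i - s_j\|^2)^{-1}}
#'   {\sum_{k \ne l} (1 + \|s_k - s_l\|^2)^{-1}}, \qquad q_{ii} = 0.}
#' The heavy tail counteracts the crowding problem: moderately distant feature
#' pairs can sit far apart in the latent space without loss penalty.
#'
#' @param s latent points (m x d matrix, m >= 2).
#' @return symmetric m x m matrix with zero diagonal summing to 1 over all
#'   ordered pairs.
#' @examples
#' latentQ(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))  # both entries 1/2
#' @export
latentQ <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 2) stop("need at least two latent points")
  E <- 1 / (1 + unname(as.matrix(stats::dist(s)))^2)
  diag(E) <- 0
  E / sum(E)
}

#' Kullback-Leibler embedding loss
#'
#' \eqn{D_{KL}(M \| Q) = \sum_{ij} p_{ij} \log(p_{ij}/q_{ij})} over a batch.
#' The row-stochastic multiscale matrix is divided by the batch size before
#' the comparison so that both arguments are joint distributions over ordered
#' pairs.
#'
#' @param M batch feature probabilities: a \code{\linkS4class{MultiscaleP}}
#'   (its mixture divided by the batch size) or a matrix already normalized to
#'   total mass 1.
#' @param Q latent pairwise probabilities from \code{\link{latentQ}}.
#' @return non-negative scalar; 0 iff M = Q elementwise.
#' @export
klLoss <- function(M, Q) {
  P <- if (is(M, "MultiscaleP")) mixtureMatrix(M) / nrow(mixtureMatrix(M)) else M
  if (!all(dim(P) == dim(Q))) stop("M and Q must have identical dimensions")
  pos <- P > 0
  if (any(Q[pos] == 0))
    stop("q_ij = 0 where p_ij > 0: KL divergence undefined")
  sum(P[pos] * log(P[pos] / Q[pos]))
}

# Gradient of the KL loss with respect to the latent points, for asymmetric P
# normalized over all pairs:
#   dL/ds_i = 2 sum_j (s_i - s_j) E_ij [ (p_ij + p_ji) - 2 q_ij ],
# E_ij = (1 + ||s_i - s_j||^2)^{-1}. Reduces to the familiar t-SNE gradient
# for symmetric P.
.klGradLatent <- function(P, s) {
  E <- 1 / (1 + unname(as.matrix(stats::dist(s)))^2)
  diag(E) <- 0
  Q <- E / sum(E)
  C <- (P + t(P) - 2 * Q) * E
  2 * (diag(rowSums(C)) %*% s - C %*% s)
}

#' Network architecture specification
#'
#' @param k input (feature) dimension.
#' @param d output (CV) dimension.
#' @param hidden sizes of the three hidden layers.
#' @param leakySlope negative-side slope of the leaky-ReLU activations.
#' @param dropout training-time dropout probability after each hidden layer.
#'   Default 0: because the latent coordinates are a sum over the last hidden
#'   layer, dropout injects positional noise proportional to the embedding's
#'   own scale, which empirically stalls the Kullback-Leibler objective well
#'   short of the distance-preserving solution (see the package vignette).
#'   Set a positive value to regularize anyway.
#' @return a list consumed by \code{\link{trainEmbedding}}.
#' @export
networkSpec <- function(k, d = 2L, hidden = c(500L, 500L, 2000L),
                        leakySlope = 0.2, dropout = 0) {
  list(layerSizes = as.integer(c(k, hidden, d)),
       leakySlope = leakySlope, dropout = dropout)
}

#' Training configuration
#'
#' Defaults: Adam with the AMSGrad correction, learning rate \eqn{10^{-3}},
#' momenta 0.9/0.999, weight decay \eqn{10^{-4}}, batch size 500, 100 epochs,
#' seed 111, Glorot-normal weight initialization (leaky-ReLU gain) with biases
#' 0.005.
#'
#' @param learningRate,beta1,beta2,weightDecay Adam/AMSGrad hyperparameters.
#' @param batchSize batch size \eqn{N_b}.
#' @param epochs training epochs.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @return a list consumed by \code{\link{trainEmbedding}}.
#' @export
trainConfig <- function(learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        weightDecay = 1e-4, batchSize = 500L, epochs = 100L,
                        seed = 111) {
  list(learningRate = learningRate, beta1 = beta1, beta2 = beta2,
       weightDecay = weightDecay, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), seed = seed)
}

#' Train a parametric embedding
#'
#' Trains the feed-forward embedding \eqn{f_\theta} by minimizing the batched
#' Kullback-Leibler divergence between the multiscale reweighted feature
#' probabilities and the heavy-tailed latent probabilities. Each epoch the
#' landmarks are reshuffled and split into batches of \code{batchSize}; the
#' feature probability matrix and its perplexity ladder are rebuilt within
#' each batch (the loss is defined per batch, and slicing a global matrix
#' would break row normalization). With \code{reweight = FALSE} all weights
#' are forced to 1 in the feature probabilities, the non-reweighted ablation.
#'
#' @param landmarks a \code{\linkS4class{LandmarkSet}} or a feature matrix.
#' @param spec architecture from \code{\link{networkSpec}}; defaults to the
#'   standard [k, 500, 500, 2000, d] layout.
#' @param cfg optimization settings from \code{\link{trainConfig}}.
#' @param reweight incorporate the landmark weights into the feature
#'   probabilities.
#' @param weights explicit weights when \code{landmarks} is a plain matrix.
#' @param standardize standardize features before training (constants are
#'   stored in the model and re-applied at projection time).
#' @param verbose print the loss every 10 epochs.
#' @return an \code{\linkS4class{EmbeddingModel}}.
#' @export
trainEmbedding <- function(landmarks, spec = NULL, cfg = trainConfig(),
                           reweight = TRUE, weights = NULL,
                           standardize = FALSE, verbose = FALSE) {
  if (is(landmarks, "LandmarkSet")) {
    X <- features(landmarks)
    w <- sampleWeights(landmarks)
  } else {
    X <- as.matrix(landmarks)
    w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  }
  if (!reweight) w <- rep(1, nrow(X))
  N <- nrow(X)
  k <- ncol(X)
  if (is.null(spec)) spec <- networkSpec(k)
  if (spec$layerSizes[1] != k)
    stop(sprintf("spec expects %d features, data has %d",
                 spec$layerSizes[1], k))
  if (standardize) {
    st <- standardizeFeatures(X)
    X <- st$x
    center <- st$center
    scale <- st$scale
  } else {
    center <- rep(0, k)
    scale <- rep(1, k)
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  params <- .glorotInit(spec$layerSizes, spec$leakySlope)
  state <- .adamInit(params$W, params$b)
  lossHist <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(N)
    nBatch <- max(1L, floor(N / cfg$batchSize))
    splits <- split(perm, rep(seq_len(nBatch), length.out = N))
    epochLoss <- 0
    for (batch in splits) {
      Xb <- X[batch, , drop = FALSE]
      wb <- w[batch]
      M <- multiscaleMatrix(Xb, wb,
                            ladder = perplexityLadder(length(batch)))
      P <- mixtureMatrix(M) / length(batch)
      fwd <- .mlpForward(params$W, params$b, Xb, spec$leakySlope,
                         spec$dropout, training = TRUE)
      S <- fwd$out
      Q <- latentQ(S)
      epochLoss <- epochLoss + klLoss(P, Q)
      dS <- .klGradLatent(P, S)
      grads <- .mlpBackward(params$W, fwd, dS, spec$leakySlope)
      res <- .adamStep(params, grads, state, cfg$learningRate,
                       cfg$beta1, cfg$beta2, cfg$weightDecay)
      params <- res$params
      state <- res$state
    }
    lossHist[epoch] <- epochLoss / length(splits)
    if (verbose && epoch %% 10 == 0)
      message(sprintf("epoch %d: loss %.5f", epoch, lossHist[epoch]))
  }

  new("EmbeddingModel",
      layerSizes = spec$layerSizes, leakySlope = spec$leakySlope,
      dropout = spec$dropout, weights = params$W, biases = params$b,
      center = center, scale = scale, lossHistory = lossHist,
      seed = cfg$seed)
}

#' Project feature samples to the latent space
#'
#' Deterministic evaluation of the trained embedding (dropout disabled). The
#' model's standardization constants are applied to the input first.
#'
#' @param model an \code{\linkS4class{EmbeddingModel}}.
#' @param x feature vector or matrix (columns must match the model's input).
#' @return matrix of latent coordinates (n x d).
#' @export
projectEmbedding <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != model@layerSizes[1])
    stop(sprintf("model expects %d features, got %d",
                 model@layerSizes[1], ncol(x)))
  xs <- sweep(sweep(x, 2L, model@center, `-`), 2L, model@scale, `/`)
  .mlpForward(model@weights, model@biases, xs, model@leakySlope,
              dropout = 0, training = FALSE)$out
}

#' Save / load an embedding checkpoint
#'
#' Single-file checkpoint holding the architecture, parameters,
#' standardization constants and training metadata under a versioned schema.
#'
#' @param model an \code{\linkS4class{EmbeddingModel}}.
#' @param path checkpoint file path.
#' @return \code{saveEmbedding}: the path, invisibly. \code{loadEmbedding}:
#'   the restored \code{EmbeddingModel}.
#' @export
saveEmbedding <- function(model, path) {
  obj <- list(schema = 1L,
              layerSizes = model@layerSizes, leakySlope = model@leakySlope,
              dropout = model@dropout, weights = model@weights,
              biases = model@biases, center = model@center,
              scale = model@scale, lossHistory = model@lossHistory,
              seed = model@seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveEmbedding
#' @export
loadEmbedding <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L)
    stop("unsupported checkpoint schema")
  new("EmbeddingModel",
      layerSizes = obj$layerSizes, leakySlope = obj$leakySlope,
      dropout = obj$dropout, weights = obj$weights, biases = obj$biases,
      center = obj$center, scale = obj$scale,
      lossHistory = obj$lossHistory, seed = obj$seed)
}

#' Jacobian of the embedding at a point
#'
#' \eqn{\partial s / \partial x} (d x k) by reverse accumulation through the
#' network in deterministic mode — the derivative needed to turn the learned
#' CVs into biasing forces via the chain rule.
#'
#' @param model an \code{\linkS4class{EmbeddingModel}}.
#' @param x feature vector of length k.
#' @return d x k Jacobian matrix (standardization included).
#' @export
embeddingJacobian <- function(model, x) {
  if (length(x) != model@layerSizes[1])
    stop(sprintf("model expects %d features, got %d",
                 model@layerSizes[1], length(x)))
  xs <- (x - model@center) / model@scale
  fwd <- .mlpForward(model@weights, model@biases, matrix(xs, nrow = 1),
                     model@leakySlope, dropout = 0, training = FALSE)
  nl <- length(model@weights)
  # J accumulates dS/dA_l going backwards
  J <- t(model@weights[[nl]])
  for (l in rev(seq_len(nl - 1L))) {
    g <- .lreluGrad(as.numeric(fwd$Z[[l]]), model@leakySlope)
    J <- (J * rep(g, each = nrow(J))) %*% t(model@weights[[l]])
  }
  sweep(J, 2L, model@scale, `/`)
}
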