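#' Perplexity ladder for the multiscale mixture
#'
#' The mixture averages neighbor-probability matrices fitted at perplexities
#' \eqn{PP_l = 2^{L_{PP} - l + 1}} for \eqn{l = 0, \ldots, L_{PP}} with
#' \eqn{L_{PP} = \lfloor \log N \rfloor - 2}, spanning scales from
#' \eqn{2^{L_{PP}+1}} effective neighbors down to 2. The logarithm base is
#' configurable; the natural log (default) gives a conventional maximum
#' perplexity of 64 at \eqn{N = 2000}.
#'
#' @param N training-set size.
#' @param logBase base of the logarithm in \eqn{L_{PP}} ("natural" or "2").
#' @return numeric vector of perplexities, strictly decreasing, all \eqn{\ge 2},
#'   with attributes \code{LPP} and \code{logBase}.
#' @examples
#' perplexityLadder(2000)        # 64 32 16 8 4 2
#' @export
perplexityLadder <- function(N, logBase = c("natural", "2")) {
  logBase <- match.arg(logBase)
  lpp <- floor(if (logBase == "natural") log(N) else log2(N)) - 2
  if (lpp < 0) stop("N too small for a perplexity ladder (need floor(log N) >= 2)")
  pp <- 2^(lpp - (0:lpp) + 1)
  if (max(pp) > N - 1) pp <- pp[pp <= N - 1]
  structure(pp, LPP = lpp, logBase = logBase)
}

#' Reweighted Gaussian kernel
#'
#' \eqn{\tilde K_{\epsilon_i}(x_i, x_j) = r(x_i, x_j)\,
#' e^{-\epsilon_i \|x_i - x_j\|_2^2}} with the symmetric reweighting factor
#' \eqn{r(x_i, x_j) = \sqrt{w_i w_j}} (geometric mean). For unit weights this
#' is the plain Gaussian kernel with scale \eqn{\epsilon_i = 1/(2\sigma_i^2)};
#' for exponential weights \eqn{w = e^{\beta V}} it equals
#' \eqn{e^{\beta(V_i + V_j)/2}} times the Gaussian.
#'
#' @param xi,xj feature vectors.
#' @param eps scale parameter \eqn{\epsilon_i > 0}.
#' @param wi,wj statistical weights (> 0).
#' @param r pairwise reweighting function of the two weights; the geometric
#'   mean by default, pluggable.
#' @return positive scalar.
#' @export
reweightedKernel <- function(xi, xj, eps, wi = 1, wj = 1,
                             r = function(wi, wj) sqrt(wi * wj)) {
  if (!(eps > 0)) stop("eps must be > 0")
  if (wi <= 0 || wj <= 0) stop("weights must be > 0")
  r(wi, wj) * exp(-eps * sum((xi - xj)^2))
}

# row-stochastic reweighted probability matrix for a per-row eps vector;
# D2 is the full squared-distance matrix, sw = sqrt(weights). Computed as a
# row-wise softmax in log space so extreme scales cannot underflow.
.rowProbMatrix <- function(D2, sw, eps) {
  N <- length(sw)
  # (D2 * eps) recycles eps down columns => multiplies row i by eps[i]
  L <- -(D2 * eps) + rep(log(sw), each = N)   # column j gets + log sqrt(w_j)
  diag(L) <- -Inf
  m <- apply(L, 1L, max)
  if (any(!is.finite(m))) stop("numerically zero kernel row: all neighbors too far")
  K <- exp(L - m)
  K / rowSums(K)
}

#' Reweighted neighbor probabilities for one row
#'
#' Row \eqn{i} of the reweighted pairwise probability matrix:
#' \eqn{p_{ij}^{\epsilon_i} = \tilde K_{\epsilon_i}(x_i, x_j) /
#' \sum_{j' \ne i} \tilde K_{\epsilon_i}(x_i, x_{j'})} with
#' \eqn{p_{ii} = 0}. The row's own weight cancels in the normalization, so
#' only the neighbors' weights matter: downweighting a sample drives its
#' probability of being anyone's neighbor to zero.
#'
#' @param x feature matrix (N x k).
#' @param weights statistical weights (default all 1).
#' @param eps scale parameter for this row.
#' @param i row index.
#' @return numeric(N) probability row summing to 1 with entry i equal to 0.
#' @export
rowProbabilities <- function(x, weights = rep(1, nrow(x)), eps, i) {
  x <- as.matrix(x)
  N <- nrow(x)
  if (N < 2) stop("need at least two samples")
  if (!(eps > 0)) stop("eps must be > 0")
  d2 <- colSums((t(x) - x[i, ])^2)
  K <- sqrt(weights) * exp(-eps * d2)
  K[i] <- 0
  s <- sum(K)
  if (s == 0) stop("numerically zero kernel row: all neighbors too far")
  K / s
}

#' Shannon entropy of a probability row
#'
#' \eqn{H = -\sum_j p_{ij} \log_2 p_{ij}} in bits, with
#' \eqn{0 \log 0 := 0}. The perplexity of the row is \eqn{2^H}.
#'
#' @param p probability row (non-negative, sums to 1).
#' @return entropy in bits, in \eqn{[0, \log_2(N-1)]}.
#' @export
rowEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# vectorized entropies of all rows of a row-stochastic matrix
.rowEntropies <- function(P) {
  L <- P * log2(P)
  L[P == 0] <- 0
  -rowSums(L)
}

# entropies (bits) of the reweighted probability rows `rows` of D2 at scales
# eps[rows], computed from the logits without forming the full matrix:
# H = log Z - sum_j p_j l_j (natural units), l = logit - rowmax.
.rowEntropiesAt <- function(D2, logsw, rows, eps) {
  L <- -(D2[rows, , drop = FALSE] * eps) +
    rep(logsw, each = length(rows))
  L[cbind(seq_along(rows), rows)] <- -Inf
  # ties.method = "first" is exact and consumes no RNG (the default "random"
  # does fuzzy comparisons and draws random numbers)
  m <- L[cbind(seq_along(rows), max.col(L, ties.method = "first"))]
  K <- exp(L - m)
  K[cbind(seq_along(rows), rows)] <- 0
  Z <- rowSums(K)
  KL <- K * (L - m)
  KL[cbind(seq_along(rows), rows)] <- 0
  (log(Z) - rowSums(KL) / Z) / log(2)
}

#' Fit scale parameters to a target perplexity
#'
#' Binary search, separately for each row, for the scale parameter
#' \eqn{\epsilon_i} whose reweighted probability row has perplexity
#' \eqn{2^{H(\epsilon_i)}} equal to the target. The entropy is strictly
#' decreasing in \eqn{\epsilon}, so bisection converges. The initial bracket
#' is \eqn{[2^{-20}, 2^{20}]} over the median pairwise squared distance,
#' widened if necessary.
#'
#' @param x feature matrix (N x k).
#' @param weights statistical weights (default all 1).
#' @param perplexity target perplexity, in \eqn{[2, N - 1]}.
#' @param tol convergence tolerance on the achieved perplexity.
#' @param maxIter maximum bisection iterations per row.
#' @param D2 optional precomputed squared-distance matrix.
#' @return numeric(N) fitted scales, with attribute \code{achieved} (the
#'   achieved perplexities). A warning is raised for rows that exhaust
#'   \code{maxIter}.
#' @export
fitScale <- function(x, weights = rep(1, nrow(x)), perplexity,
                     tol = 1e-5, maxIter = 64L, D2 = NULL) {
  x <- as.matrix(x)
  N <- nrow(x)
  if (perplexity < 2 || perplexity > N - 1)
    stop("perplexity must lie in [2, N - 1]")
  if (is.null(D2)) D2 <- unname(as.matrix(stats::dist(x)))^2
  logsw <- log(sqrt(weights))
  targetH <- log2(perplexity)
  med <- stats::median(D2[upper.tri(D2)])
  if (!(med > 0)) med <- 1
  lo <- rep(2^-20 / med, N)
  hi <- rep(2^20 / med, N)
  # widen brackets until H(lo) >= target >= H(hi) row-wise
  act <- seq_len(N)
  for (k in 1:40) {
    bad <- act[.rowEntropiesAt(D2, logsw, act, lo[act]) < targetH]
    if (!length(bad)) break
    lo[bad] <- lo[bad] / 16
    act <- bad
  }
  act <- seq_len(N)
  for (k in 1:40) {
    bad <- act[.rowEntropiesAt(D2, logsw, act, hi[act]) > targetH]
    if (!length(bad)) break
    hi[bad] <- hi[bad] * 16
    act <- bad
  }
  eps <- (lo + hi) / 2
  achieved <- rep(NA_real_, N)
  act <- seq_len(N)   # rows still outside tolerance
  for (iter in seq_len(maxIter)) {
    H <- .rowEntropiesAt(D2, logsw, act, eps[act])
    achieved[act] <- 2^H
    conv <- abs(achieved[act] - perplexity) <= tol
    highH <- H > targetH     # entropy too high -> eps too small
    lo[act][highH & !conv] <- eps[act][highH & !conv]
    hi[act][!highH & !conv] <- eps[act][!highH & !conv]
    act <- act[!conv]
    if (!length(act)) break
    eps[act] <- (lo[act] + hi[act]) / 2
  }
  if (length(act))
    warning(sprintf("%d row(s) did not reach perplexity %g within tol %g",
                    length(act), perplexity, tol))
  structure(eps, achieved = achieved)
}

#' Multiscale reweighted probability matrix
#'
#' Fits per-row scale parameters at every perplexity of the ladder and
#' averages the resulting row-stochastic reweighted probability matrices:
#' \eqn{p_{ij} = N_{PP}^{-1} \sum_l p_{ij}^{\epsilon^{PP_l}}}. With all
#' weights equal to one this reduces bit-for-bit to the non-reweighted
#' multiscale SNE matrix.
#'
#' @param x feature matrix (N x k).
#' @param weights statistical weights (default all 1).
#' @param ladder perplexity ladder (default \code{perplexityLadder(nrow(x))}).
#' @param tol,maxIter passed to \code{\link{fitScale}}.
#' @return a \code{\linkS4class{MultiscaleP}}.
#' @examples
#' x <- matrix(rnorm(60), ncol = 2)
#' M <- multiscaleMatrix(x)
#' range(rowSums(mixtureMatrix(M)))
#' @export
multiscaleMatrix <- function(x, weights = rep(1, nrow(x)),
                             ladder = perplexityLadder(nrow(x)),
                             tol = 1e-5, maxIter = 64L) {
  x <- as.matrix(x)
  if (length(ladder) == 0) stop("perplexity ladder is empty")
  D2 <- unname(as.matrix(stats::dist(x)))^2
  sw <- sqrt(weights)
  mats <- vector("list", length(ladder))
  epss <- vector("list", length(ladder))
  for (l in seq_along(ladder)) {
    eps <- fitScale(x, weights, ladder[l], tol = tol, maxIter = maxIter,
                    D2 = D2)
    mats[[l]] <- .rowProbMatrix(D2, sw, eps)
    epss[[l]] <- eps
  }
  mix <- Reduce(`+`, mats) / length(mats)
  new("MultiscaleP", mixture = mix, perPerplexity = mats,
      perplexities = as.numeric(ladder), epsilons = epss,
      weights = weights, reweighted = any(weights != 1))
}
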