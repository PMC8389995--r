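#' Weight-tempered random sampling of landmarks
#'
#' Selects \code{n} unique landmarks from a weighted sample pool with
#' selection probability proportional to the tempered weights
#' \eqn{w^{1/\alpha}}. \eqn{\alpha = 1} recovers weighted random sampling (an
#' equilibrium representation); \eqn{\alpha = \infty} ignores the weights and
#' returns a uniform subsample of the biased data. Intermediate values trade
#' equilibrium representation against coverage of higher-lying metastable
#' states. Sampling is without replacement via the exponential-sort
#' (Efraimidis-Spirakis) scheme: draw keys \eqn{u_i^{1/\tilde w_i}} and keep
#' the \code{n} largest.
#'
#' @param pool a \code{\linkS4class{BiasedTrajectory}} with weights attached,
#'   a \code{\linkS4class{LandmarkSet}}, or a numeric matrix of samples.
#' @param weights statistical weights (ignored when \code{pool} carries its
#'   own); recycled to 1 when missing.
#' @param alpha tempering parameter \eqn{\alpha \ge 1}; \code{Inf} ignores the
#'   weights.
#' @param n number of landmarks to select (\eqn{\le} pool size).
#' @param seed RNG seed; the draw is reproducible given the seed.
#' @return a \code{\linkS4class{LandmarkSet}}.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' w <- runif(100, 0.1, 1)
#' lm <- weightTemperedSample(x, weights = w, alpha = 2, n = 20, seed = 111)
#' nSamples(lm)
#' @export
weightTemperedSample <- function(pool, weights = NULL, alpha = 2, n, seed = 111) {
  if (is(pool, "BiasedTrajectory")) {
    x <- coords(pool)
    if (is.null(weights)) weights <- sampleWeights(pool)
  } else if (is(pool, "LandmarkSet")) {
    x <- features(pool)
    if (is.null(weights)) weights <- sampleWeights(pool)
  } else {
    x <- as.matrix(pool)
  }
  N <- nrow(x)
  if (is.null(weights)) weights <- rep(1, N)
  if (length(weights) != N) stop("weights must match the pool size")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("all weights are zero")
  if (!(alpha >= 1)) stop("alpha must be >= 1 (Inf allowed)")
  if (n > N) stop("cannot select more landmarks than pool samples")
  wt <- if (is.infinite(alpha)) rep(1, N) else weights^(1 / alpha)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # keys u^(1/w) are monotone in log(u)/w; zero-weight samples get -Inf keys
  keys <- rep(-Inf, N)
  pos <- wt > 0
  keys[pos] <- log(stats::runif(sum(pos))) / wt[pos]
  idx <- order(keys, decreasing = TRUE)[seq_len(n)]
  new("LandmarkSet",
      features = x[idx, , drop = FALSE],
      weights = weights[idx],
      indices = as.integer(idx),
      alpha = alpha, seed = seed)
}

#' Effective tempering parameter
#'
#' For landmarks drawn with tempering parameter \eqn{\alpha} from a
#' well-tempered run with bias factor \eqn{\gamma}, the landmark density in
#' the biased-CV space follows \eqn{[P(s)]^{1/\tilde\alpha}} with
#' \deqn{\tilde\alpha = \frac{\alpha\gamma}{\alpha + \gamma - 1}.}
#' It is unity at \eqn{\alpha = 1} (equilibrium representation) and tends to
#' \eqn{\gamma} as \eqn{\alpha \to \infty} (biased representation).
#'
#' @param alpha tempering parameter \eqn{\alpha \ge 1} (Inf allowed).
#' @param gamma bias factor \eqn{\gamma > 1}.
#' @return scalar \eqn{\tilde\alpha \in [1, \gamma)}.
#' @examples
#' effectiveTempering(2, 5)  # 10/6
#' @export
effectiveTempering <- function(alpha, gamma) {
  if (!(alpha >= 1)) stop("alpha must be >= 1")
  if (!(gamma > 1)) stop("gamma must be > 1")
  if (is.infinite(alpha)) return(gamma)
  alpha * gamma / (alpha + gamma - 1)
}
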