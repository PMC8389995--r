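#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Mueller-Brown potential parameters
#'
#' Coefficients of the two-dimensional Mueller-Brown potential
#' \deqn{U(x,y) = \sum_{j=1}^4 A_j \exp[a_j(x-x_{0,j})^2 +
#'   b_j(x-x_{0,j})(y-y_{0,j}) + c_j(y-y_{0,j})^2]}{
#'   U(x,y) = sum_j A_j exp(p_j(x,y))}
#' in energy units with \eqn{k_B = 1}. The default amplitudes are the classic
#' Mueller-Brown values scaled down by a factor of 5, so that at \eqn{T = 1}
#' the barrier between the two principal states is about 20 \eqn{k_B T} and
#' barrier crossings are rare events.
#'
#' @slot A numeric(4) Gaussian amplitudes (energy units).
#' @slot a,b,c numeric(4) quadratic-form coefficients of each term.
#' @slot x0,y0 numeric(4) term centers.
#' @export
setClass("MBParams",
  representation(A = "numeric", a = "numeric", b = "numeric",
                 c = "numeric", x0 = "numeric", y0 = "numeric"),
  prototype(A = c(-40, -20, -34, 3),
            a = c(-1, -1, -6.5, 0.7),
            b = c(0, 0, 11, 0.6),
            c = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1)))

setValidity("MBParams", function(object) {
  lens <- c(length(object@A), length(object@a), length(object@b),
            length(object@c), length(object@x0), length(object@y0))
  if (any(lens != 4L)) return("all parameter vectors must have length 4")
  if (!all(is.finite(c(object@A, object@a, object@b, object@c,
                       object@x0, object@y0))))
    return("parameters must be finite")
  TRUE
})

#' Langevin dynamics configuration
#'
#' Settings for the Bussi-Parrinello Langevin integrator (mass = 1,
#' \eqn{k_B = 1}). Defaults follow the reference Mueller-Brown setup:
#' temperature 1, friction 10 (inverse time), time step 0.005.
#'
#' @slot temperature numeric(1), \eqn{T > 0} in energy units.
#' @slot friction numeric(1), friction coefficient (inverse time), \eqn{\ge 0}.
#' @slot timestep numeric(1), integration time step.
#' @slot nSteps numeric(1), number of integration steps.
#' @slot seed numeric(1), RNG seed for the thermostat noise.
#' @slot saveStride integer(1), steps between saved frames (default 1600).
#' @export
setClass("LangevinConfig",
  representation(temperature = "numeric", friction = "numeric",
                 timestep = "numeric", nSteps = "numeric",
                 seed = "numeric", saveStride = "integer"),
  prototype(temperature = 1, friction = 10, timestep = 0.005,
            nSteps = 1e5, seed = 111, saveStride = 1600L))

setValidity("LangevinConfig", function(object) {
  if (object@temperature < 0) return("temperature must be >= 0")
  if (object@friction < 0) return("friction must be >= 0")
  if (object@timestep <= 0) return("timestep must be > 0")
  if (object@nSteps < 1) return("nSteps must be >= 1")
  if (object@saveStride < 1) return("saveStride must be >= 1")
  TRUE
})

#' Well-tempered metadynamics configuration
#'
#' Gaussian hill deposition settings. A hill of height
#' \eqn{h_0 \exp[-V(s,t)/((\gamma-1)k_B T)]} is added every \code{pace} steps
#' at the current position; \code{biasFactor = Inf} is the sentinel for
#' non-tempered metadynamics (constant hill height). The grid is used only for
#' the c(t) quadrature; forces always come from the exact hill sum.
#'
#' @slot biasFactor numeric(1), bias factor \eqn{\gamma > 1} (Inf allowed).
#' @slot initialHeight numeric(1), initial hill height \eqn{h_0 > 0}.
#' @slot widths numeric(2), Gaussian hill widths per CV.
#' @slot pace integer(1), steps between depositions.
#' @slot gridBounds numeric(4), c(xlo, xhi, ylo, yhi) for the c(t) grid.
#' @slot gridShape integer(2), grid points per axis.
#' @slot ctStride integer(1), depositions between c(t) updates (default 1:
#'   recompute at every deposition).
#' @export
setClass("MetaDConfig",
  representation(biasFactor = "numeric", initialHeight = "numeric",
                 widths = "numeric", pace = "integer",
                 gridBounds = "numeric", gridShape = "integer",
                 ctStride = "integer"),
  prototype(biasFactor = 5, initialHeight = 1.2, widths = c(0.1, 0.1),
            pace = 200L, gridBounds = c(-5, 5, -5, 5),
            gridShape = c(500L, 500L), ctStride = 1L))

setValidity("MetaDConfig", function(object) {
  if (!(object@biasFactor > 1)) return("biasFactor must be > 1 (Inf allowed)")
  if (object@initialHeight <= 0) return("initialHeight must be > 0")
  if (length(object@widths) != 2L || any(object@widths <= 0))
    return("widths must be two positive numbers")
  if (object@pace < 1) return("pace must be >= 1")
  if (length(object@gridBounds) != 4L ||
      object@gridBounds[2] <= object@gridBounds[1] ||
      object@gridBounds[4] <= object@gridBounds[3])
    return("gridBounds must be c(xlo, xhi, ylo, yhi) with hi > lo")
  if (length(object@gridShape) != 2L || any(object@gridShape < 2))
    return("gridShape must be two integers >= 2")
  if (object@ctStride < 1) return("ctStride must be >= 1")
  TRUE
})

#' Metadynamics bias state
#'
#' The accumulated bias: the list of deposited hills, the running bias grid
#' used for the c(t) quadrature, and the current c(t) value. The exact hill
#' sum (\code{\link{biasValue}}) is authoritative for energies and forces;
#' the grid is authoritative only for \code{\link{computeCt}}.
#'
#' @slot hills matrix with columns time, x, y, height (one row per hill).
#' @slot widths numeric(2), hill widths (shared by all hills).
#' @slot grid matrix of accumulated bias values on the quadrature grid.
#' @slot gridX,gridY numeric, grid axes.
#' @slot ct numeric(1), current value of the reweighting offset c(t).
#' @export
setClass("BiasState",
  representation(hills = "matrix", widths = "numeric", grid = "matrix",
                 gridX = "numeric", gridY = "numeric", ct = "numeric"))

setValidity("BiasState", function(object) {
  if (ncol(object@hills) != 4L)
    return("hills must have columns time, x, y, height")
  if (nrow(object@hills) > 0 && any(object@hills[, 4] <= 0))
    return("hill heights must be strictly positive")
  if (nrow(object@hills) == 0 && object@ct != 0)
    return("c(t) must be 0 when no hills have been deposited")
  TRUE
})

#' Biased trajectory with statistical weights
#'
#' A time series of feature samples from a (possibly biased) simulation,
#' carrying per-frame bias values \eqn{V}, the reweighting offset \eqn{c(t)}
#' and, once attached by \code{\link{trajectoryWeights}}, statistical weights
#' \eqn{w = e^{\beta(V - c(t))}}.
#'
#' @slot time numeric, frame times.
#' @slot coords matrix (frames x features), feature samples.
#' @slot bias numeric, bias potential at each frame.
#' @slot ct numeric, c(t) at each frame.
#' @slot weight numeric or NULL, statistical weights (NULL until attached).
#' @slot metadata list: temperature, bias factor, seed, burn-in fraction, ...
#' @export
setClass("BiasedTrajectory",
  representation(time = "numeric", coords = "matrix", bias = "numeric",
                 ct = "numeric", weight = "numericOrNULL",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("BiasedTrajectory", function(object) {
  n <- length(object@time)
  if (nrow(object@coords) != n || length(object@bias) != n ||
      length(object@ct) != n)
    return("time, coords, bias and ct must have one entry per frame")
  if (!is.null(object@weight)) {
    if (length(object@weight) != n) return("weight must have one entry per frame")
    if (any(object@weight <= 0)) return("weights must be strictly positive")
  }
  TRUE
})

#' Weight-tempered landmark set
#'
#' Landmarks selected from a weighted sample pool with probability
#' proportional to \eqn{w^{1/\alpha}} (sampling without replacement).
#'
#' @slot features matrix (n x k), the selected feature samples.
#' @slot weights numeric, their original statistical weights.
#' @slot indices integer, unique source indices into the pool.
#' @slot alpha numeric(1), tempering parameter used (Inf = ignore weights).
#' @slot seed numeric(1), RNG seed used for the draw.
#' @export
setClass("LandmarkSet",
  representation(features = "matrix", weights = "numeric",
                 indices = "integer", alpha = "numeric", seed = "numeric"))

setValidity("LandmarkSet", function(object) {
  n <- nrow(object@features)
  if (length(object@weights) != n || length(object@indices) != n)
    return("features, weights and indices must agree in length")
  if (anyDuplicated(object@indices)) return("indices must be unique")
  if (any(object@weights <= 0)) return("weights must be strictly positive")
  if (!(object@alpha >= 1)) return("alpha must be >= 1")
  TRUE
})

#' Multiscale feature pairwise probability matrix
#'
#' Row-stochastic reweighted neighbor probabilities averaged over a ladder of
#' perplexities: \eqn{p_{ij} = N_{PP}^{-1} \sum_l p_{ij}^{\epsilon^{PP_l}}}.
#'
#' @slot mixture matrix (N x N), the perplexity-averaged probabilities.
#' @slot perPerplexity list of per-perplexity row-stochastic matrices.
#' @slot perplexities numeric, the ladder that was used.
#' @slot epsilons list of fitted scale-parameter vectors (one per perplexity).
#' @slot weights numeric, the statistical weights used.
#' @slot reweighted logical(1), FALSE when all weights were forced to 1.
#' @export
setClass("MultiscaleP",
  representation(mixture = "matrix", perPerplexity = "list",
                 perplexities = "numeric", epsilons = "list",
                 weights = "numeric", reweighted = "logical"))

setValidity("MultiscaleP", function(object) {
  m <- object@mixture
  if (nrow(m) != ncol(m)) return("mixture must be square")
  if (any(abs(diag(m)) > 0)) return("diagonal of mixture must be zero")
  if (any(abs(rowSums(m) - 1) > 1e-8)) return("mixture rows must sum to 1")
  for (p in object@perPerplexity) {
    if (any(abs(rowSums(p) - 1) > 1e-8))
      return("per-perplexity rows must sum to 1")
  }
  TRUE
})

#' Parametric neural-network embedding
#'
#' A trained feed-forward map from feature space to latent (CV) space:
#' linear layers with leaky-ReLU hidden activations, linear output. Dropout is
#' used only during training; evaluation is deterministic. Feature
#' standardization constants are baked in and applied by
#' \code{\link{projectEmbedding}}.
#'
#' @slot layerSizes integer, c(k, h1, h2, h3, d).
#' @slot leakySlope numeric(1), negative-side slope of the hidden activations.
#' @slot dropout numeric(1), training-time dropout probability.
#' @slot weights list of weight matrices (input-dim x output-dim).
#' @slot biases list of bias vectors.
#' @slot center,scale numeric(k), feature standardization constants.
#' @slot lossHistory numeric, mean batch loss per epoch.
#' @slot seed numeric(1), training seed.
#' @export
setClass("EmbeddingModel",
  representation(layerSizes = "integer", leakySlope = "numeric",
                 dropout = "numeric", weights = "list", biases = "list",
                 center = "numeric", scale = "numeric",
                 lossHistory = "numeric", seed = "numeric"))

setValidity("EmbeddingModel", function(object) {
  nl <- length(object@layerSizes) - 1L
  if (length(object@weights) != nl || length(object@biases) != nl)
    return("one weight matrix and bias vector per layer required")
  for (l in seq_len(nl)) {
    if (!all(dim(object@weights[[l]]) ==
             object@layerSizes[c(l, l + 1L)]))
      return(sprintf("weight matrix %d has wrong shape", l))
  }
  TRUE
})

#' Gridded free-energy surface
#'
#' \eqn{F(s) = -\beta^{-1} \log \hat P(s)} on a regular grid, aligned so that
#' \eqn{\min F = 0}. Cells whose density falls below a floor (1e-12 of the
#' maximum) carry \code{Inf}.
#'
#' @slot axes list of grid axis vectors (length 1 or 2).
#' @slot values array of free energies (length or matrix matching axes).
#' @slot bandwidths numeric, KDE bandwidths used.
#' @slot weighted logical(1), whether statistical weights entered the KDE.
#' @slot beta numeric(1), inverse temperature used.
#' @export
setClass("FreeEnergySurface",
  representation(axes = "list", values = "array", bandwidths = "numeric",
                 weighted = "logical", beta = "numeric"))

setValidity("FreeEnergySurface", function(object) {
  dims <- vapply(object@axes, length, integer(1))
  if (!identical(unname(dim(object@values)), unname(dims)) &&
      !(length(dims) == 1L && length(object@values) == dims))
    return("values shape must match axes")
  fin <- object@values[is.finite(object@values)]
  if (length(fin) && abs(min(fin)) > 1e-8)
    return("minimum of finite F must be 0")
  TRUE
})
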