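#' Silverman's rule-of-thumb KDE bandwidths
#'
#' Per-dimension Gaussian-kernel bandwidths
#' \eqn{h_j = \sigma_j \left[4 / ((d + 2) n)\right]^{1/(d+4)}}, which in one
#' dimension reduces to the familiar \eqn{1.06\, \sigma\, n^{-1/5}}.
#'
#' @param samples numeric matrix (n x d) or vector.
#' @return numeric(d) bandwidths.
#' @export
bandwidthSilverman <- function(samples) {
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2) stop("need at least two samples")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance dimension: cannot set a bandwidth")
  sds * (4 / ((d + 2) * n))^(1 / (d + 4))
}

# weighted Gaussian product-kernel density on a grid (1-D or 2-D), evaluated
# by one kernel matrix per axis and a single matrix product
.kdeDensity <- function(x, weights, bandwidths, axes) {
  d <- ncol(x)
  kmat <- function(g, xi, h)
    exp(-outer(g, xi, `-`)^2 / (2 * h^2)) / (h * sqrt(2 * pi))
  if (d == 1L) {
    K <- kmat(axes[[1]], x[, 1], bandwidths[1])
    as.numeric(K %*% weights) / sum(weights)
  } else {
    Kx <- kmat(axes[[1]], x[, 1], bandwidths[1])
    Ky <- kmat(axes[[2]], x[, 2], bandwidths[2])
    (Kx %*% (weights * t(Ky))) / sum(weights)
  }
}

#' Reweighted kernel-density free-energy surface
#'
#' Estimates \eqn{F(s) = -\beta^{-1} \log \hat P(s)} from (possibly biased)
#' samples, weighing each Gaussian KDE kernel by the sample's statistical
#' weight so that the unbiased density is recovered from well-tempered
#' metadynamics data. The surface is aligned so its minimum is 0; grid cells
#' whose density falls below \code{floorFraction} of the maximum are set to
#' \code{Inf}.
#'
#' @param samples numeric matrix (n x 1 or n x 2) or vector of CV samples.
#' @param weights statistical weights (default all 1).
#' @param bandwidths per-dimension KDE bandwidths; Silverman's rule when NULL.
#' @param gridBounds c(lo, hi) per dimension (flattened); data range when NULL.
#' @param gridSize grid points per axis (default 200).
#' @param beta inverse temperature.
#' @param floorFraction density floor relative to the maximum density.
#' @return a \code{\linkS4class{FreeEnergySurface}}.
#' @examples
#' s <- matrix(rnorm(2000), ncol = 2)
#' fes <- kdeFes(s, gridSize = 50)
#' fes
#' @export
kdeFes <- function(samples, weights = NULL, bandwidths = NULL,
                   gridBounds = NULL, gridSize = 200L, beta = 1,
                   floorFraction = 1e-12) {
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  if (nrow(x) == 0) stop("no samples")
  d <- ncol(x)
  if (d > 2) stop("kdeFes supports 1- or 2-dimensional CV spaces")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (length(weights) != nrow(x)) stop("weights must match samples")
  weighted <- any(weights != weights[1])
  if (is.null(bandwidths)) {
    bandwidths <- if (nrow(x) >= 2) bandwidthSilverman(x) else rep(0.1, d)
  }
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  if (is.null(gridBounds)) {
    gridBounds <- as.numeric(apply(x, 2L, range) +
                             outer(c(-3, 3), bandwidths))
  }
  axes <- lapply(seq_len(d), function(j)
    seq(gridBounds[2 * j - 1], gridBounds[2 * j], length.out = gridSize))
  dens <- .kdeDensity(x, weights, bandwidths, axes)
  floorVal <- floorFraction * max(dens)
  f <- -log(pmax(dens, floorVal)) / beta
  f <- f - min(f)
  f[dens < floorVal] <- Inf
  vals <- if (d == 1L) array(f, dim = gridSize) else
    array(f, dim = c(gridSize, gridSize))
  new("FreeEnergySurface", axes = axes, values = vals,
      bandwidths = bandwidths, weighted = weighted, beta = beta)
}

# region -> logical mask helper; region is c(xlo, xhi[, ylo, yhi]) or a
# predicate function of the coordinates
.regionMask <- function(region, pts) {
  if (is.function(region)) {
    apply(pts, 1L, region)
  } else if (ncol(pts) == 1L) {
    pts[, 1] >= region[1] & pts[, 1] <= region[2]
  } else {
    pts[, 1] >= region[1] & pts[, 1] <= region[2] &
      pts[, 2] >= region[3] & pts[, 2] <= region[4]
  }
}

#' KDE versus histogram FES mismatch
#'
#' Root-mean-square difference between the KDE free-energy surface at given
#' bandwidths and a discrete weighted-histogram FES on the same grid, over
#' cells where both are finite and the histogram F lies below \code{fMax}.
#' Intended as the report guiding manual bandwidth adjustment: too-large
#' bandwidths oversmooth the basins, too-small ones chase histogram noise.
#'
#' @param samples,weights,gridBounds,gridSize,beta as in \code{\link{kdeFes}}.
#' @param bandwidths KDE bandwidths to assess.
#' @param fMax restrict the comparison to cells this far (in \eqn{k_B T})
#'   above the minimum.
#' @return RMS mismatch in energy units.
#' @export
fesMismatch <- function(samples, weights = NULL, bandwidths,
                        gridBounds = NULL, gridSize = 100L, beta = 1,
                        fMax = 5) {
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  fes <- kdeFes(x, weights, bandwidths, gridBounds, gridSize, beta)
  axes <- fesAxes(fes)
  d <- length(axes)
  brk <- function(ax) c(ax[1] - diff(ax[1:2]) / 2,
                        ax + diff(ax[1:2]) / 2)
  if (d == 1L) {
    bin <- cut(x[, 1], brk(axes[[1]]), labels = FALSE)
    hw <- tapply(weights, factor(bin, levels = seq_along(axes[[1]])),
                 sum, default = 0)
    hist <- as.numeric(hw)
  } else {
    b1 <- cut(x[, 1], brk(axes[[1]]), labels = FALSE)
    b2 <- cut(x[, 2], brk(axes[[2]]), labels = FALSE)
    hist <- matrix(0, length(axes[[1]]), length(axes[[2]]))
    ok <- !is.na(b1) & !is.na(b2)
    for (i in which(ok)) hist[b1[i], b2[i]] <- hist[b1[i], b2[i]] + weights[i]
  }
  fh <- -log(hist / sum(hist)) / beta
  fh <- fh - min(fh[is.finite(fh)])
  fk <- fesValues(fes)
  use <- is.finite(fh) & is.finite(fk) & fh < fMax
  sqrt(mean((fk[use] - fh[use])^2))
}

#' Free-energy difference between two CV-space regions
#'
#' \deqn{\Delta F_{AB} = -\beta^{-1} \log \frac{\int_B P(s)\, ds}
#'   {\int_A P(s)\, ds}.}
#' The probabilities are taken either from a
#' \code{\linkS4class{FreeEnergySurface}} (grid quadrature of
#' \eqn{e^{-\beta F}}; invariant to any constant shift of F) or directly from
#' weighted samples (sums of statistical weights). Antisymmetric under
#' swapping A and B.
#'
#' @param object a \code{FreeEnergySurface}, or a samples matrix.
#' @param regionA,regionB rectangular regions c(xlo, xhi[, ylo, yhi]) or
#'   predicate functions of a coordinate row.
#' @param weights sample weights when \code{object} is a matrix.
#' @param beta inverse temperature (taken from the FES when available).
#' @return scalar \eqn{\Delta F_{AB}} in energy units.
#' @export
freeEnergyDifference <- function(object, regionA, regionB, weights = NULL,
                                 beta = 1) {
  if (is(object, "FreeEnergySurface")) {
    beta <- object@beta
    axes <- fesAxes(object)
    f <- fesValues(object)
    if (length(axes) == 1L) {
      pts <- matrix(axes[[1]], ncol = 1)
      p <- exp(-beta * f)
      p[!is.finite(f)] <- 0
      mA <- .regionMask(regionA, pts)
      mB <- .regionMask(regionB, pts)
      intA <- sum(p[mA])
      intB <- sum(p[mB])
    } else {
      p <- exp(-beta * f)
      p[!is.finite(f)] <- 0
      gx <- axes[[1]]; gy <- axes[[2]]
      pts <- cbind(rep(gx, times = length(gy)),
                   rep(gy, each = length(gx)))
      mA <- matrix(.regionMask(regionA, pts), length(gx), length(gy))
      mB <- matrix(.regionMask(regionB, pts), length(gx), length(gy))
      intA <- sum(p[mA])
      intB <- sum(p[mB])
    }
  } else {
    x <- if (is.matrix(object)) object else matrix(object, ncol = 1)
    if (is.null(weights)) weights <- rep(1, nrow(x))
    mA <- .regionMask(regionA, x)
    mB <- .regionMask(regionB, x)
    intA <- sum(weights[mA])
    intB <- sum(weights[mB])
  }
  if (intA <= 0 || intB <= 0)
    stop("a region carries zero probability mass")
  -log(intB / intA) / beta
}

#' Conditional free-energy surface
#'
#' Two-dimensional FES over two CV axes conditioned on a third axis lying in
#' an interval \eqn{S}: the restricted, reweighted density of the samples with
#' \eqn{s_{cond} \in S}, re-aligned so its minimum is zero.
#'
#' @param samples numeric matrix with (at least) 3 columns.
#' @param conditionAxis column index of the conditioning CV.
#' @param interval c(lo, hi) conditioning window.
#' @param weights statistical weights.
#' @param ... passed to \code{\link{kdeFes}} (bandwidths, grid, beta, ...).
#' @return a \code{\linkS4class{FreeEnergySurface}} over the two free axes.
#' @export
conditionalFes <- function(samples, conditionAxis = 3L, interval,
                           weights = NULL, ...) {
  x <- as.matrix(samples)
  if (ncol(x) < 3) stop("need at least three CV columns")
  keep <- x[, conditionAxis] >= interval[1] & x[, conditionAxis] <= interval[2]
  if (!any(keep)) stop("no samples inside the conditioning interval")
  free <- setdiff(seq_len(ncol(x)), conditionAxis)[1:2]
  w <- if (is.null(weights)) NULL else weights[keep]
  kdeFes(x[keep, free, drop = FALSE], weights = w, ...)
}

#' Procrustes rotation onto a reference
#'
#' Finds the orthogonal map R minimizing
#' \eqn{\|X_c R - Y_c\|_F} over rotations (optionally allowing reflections),
#' where both point sets are centered internally. Used to align an embedding
#' — whose overall rotation is arbitrary, set by the training seed — with
#' reference coordinates.
#'
#' @param x points to rotate (n x d).
#' @param reference target points (n x d).
#' @param allowReflection permit determinant -1 maps.
#' @return list with \code{rotation} (d x d, orthogonal), \code{aligned}
#'   (centered, rotated x), \code{referenceCentered}, and \code{residual}
#'   (Frobenius norm of the remaining difference).
#' @export
procrustesAlign <- function(x, reference, allowReflection = FALSE) {
  x <- as.matrix(x)
  reference <- as.matrix(reference)
  if (!all(dim(x) == dim(reference)))
    stop("x and reference must have identical dimensions")
  xc <- scale(x, scale = FALSE)
  yc <- scale(reference, scale = FALSE)
  M <- crossprod(xc, yc)
  sv <- svd(M)
  if (min(sv$d) < 1e-12 * max(sv$d))
    warning("rank-deficient cross-covariance: rotation not unique")
  R <- sv$u %*% t(sv$v)
  if (!allowReflection && det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  aligned <- xc %*% R
  list(rotation = R, aligned = aligned, referenceCentered = yc,
       residual = sqrt(sum((aligned - yc)^2)))
}

#' Distance-preservation histogram
#'
#' Joint density of pairwise distances in feature space versus latent space,
#' both rescaled to [0, 1] by their maxima. An embedding that preserves
#' distances concentrates all mass on the identity line; reweighted
#' embeddings may deviate at intermediate distances because low-weight
#' landmarks are pushed away from their geometric neighbors.
#'
#' @param x feature samples (n x k).
#' @param latent latent samples (n x d), same n.
#' @param bins number of histogram bins per axis.
#' @return list with \code{density} (bins x bins, sums to 1),
#'   \code{breaks} (shared bin edges in [0, 1]) and \code{diagonalMass} (the
#'   mass within one bin of the identity line).
#' @export
distancePreservation <- function(x, latent, bins = 50L) {
  x <- as.matrix(x)
  latent <- as.matrix(latent)
  if (nrow(x) != nrow(latent)) stop("sample counts must agree")
  if (nrow(x) < 2) stop("need at least two samples")
  df <- as.numeric(stats::dist(x))
  dl <- as.numeric(stats::dist(latent))
  df <- if (max(df) > 0) df / max(df) else df
  dl <- if (max(dl) > 0) dl / max(dl) else dl
  breaks <- seq(0, 1, length.out = bins + 1L)
  bf <- pmin(findInterval(df, breaks, rightmost.closed = TRUE), bins)
  bl <- pmin(findInterval(dl, breaks, rightmost.closed = TRUE), bins)
  h <- matrix(0, bins, bins)
  for (i in seq_along(bf)) h[bf[i], bl[i]] <- h[bf[i], bl[i]] + 1
  h <- h / sum(h)
  list(density = h, breaks = breaks,
       diagonalMass = sum(h[abs(row(h) - col(h)) <= 1]))
}

#' Drop low-variance feature columns
#'
#' Removes columns whose variance falls below a threshold — the impartial
#' feature pre-selection used before training (e.g. dropping near-constant
#' pairwise distances).
#'
#' @param x feature matrix.
#' @param threshold variance threshold; columns with variance strictly below
#'   it are dropped. 0 keeps everything.
#' @return integer vector of kept column indices, with attribute
#'   \code{dropped} naming the removed columns.
#' @export
varianceFilter <- function(x, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  x <- as.matrix(x)
  v <- apply(x, 2L, function(col) mean((col - mean(col))^2))
  keep <- which(v >= threshold)
  if (length(keep) == 0) stop("variance filter removed every column")
  nm <- colnames(x)
  dropped <- if (is.null(nm)) setdiff(seq_len(ncol(x)), keep)
             else nm[setdiff(seq_len(ncol(x)), keep)]
  structure(keep, dropped = dropped)
}

#' Standardize feature columns
#'
#' Centers each column to mean zero and rescales to unit standard deviation
#' (population convention, denominator n; set \code{population = FALSE} for
#' the n-1 convention). The constants are returned for re-use when projecting
#' new data and can be inverted exactly.
#'
#' @param x feature matrix.
#' @param population use the 1/n variance convention (default TRUE).
#' @return list with \code{x} (standardized matrix), \code{center} and
#'   \code{scale}.
#' @export
standardizeFeatures <- function(x, population = TRUE) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- sqrt(apply(x, 2L, function(col) mean((col - mean(col))^2)))
  if (!population)
    scale <- apply(x, 2L, stats::sd)
  if (any(scale == 0))
    stop("zero-variance column: run varianceFilter first")
  xs <- sweep(sweep(x, 2L, center, `-`), 2L, scale, `/`)
  list(x = xs, center = center, scale = scale)
}
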