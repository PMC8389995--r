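#' Construct Mueller-Brown potential parameters
#'
#' Returns the scaled Mueller-Brown parameters used throughout the package.
#' The amplitudes \code{A} are the classic values divided by 5 so that the
#' barrier between the two principal metastable states is about 20
#' \eqn{k_B T} at \eqn{T = 1} (rescaled units, \eqn{k_B = 1}).
#'
#' @param A,a,b,c,x0,y0 numeric(4) coefficient vectors; see
#'   \code{\linkS4class{MBParams}}.
#' @return an \code{MBParams} object.
#' @examples
#' p <- mbParams()
#' mbEnergy(c(-0.558, 1.442), p)
#' @export
mbParams <- function(A = base::c(-40, -20, -34, 3),
                     a = base::c(-1, -1, -6.5, 0.7),
                     b = base::c(0, 0, 11, 0.6),
                     c = base::c(-10, -10, -6.5, 0.7),
                     x0 = base::c(1, 0, -0.5, -1),
                     y0 = base::c(0, 0.5, 1.5, 1)) {
  # base::c in the defaults: the argument named `c` (the potential's own
  # notation) would otherwise shadow the combine function
  new("MBParams", A = A, a = a, b = b, c = c, x0 = x0, y0 = y0)
}

#' Mueller-Brown potential energy
#'
#' Evaluates \eqn{U(x,y) = \sum_j A_j e^{p_j(x,y)}} with
#' \eqn{p_j = a_j(x-x_{0,j})^2 + b_j(x-x_{0,j})(y-y_{0,j}) +
#' c_j(y-y_{0,j})^2}.
#'
#' @param point numeric(2) or an n x 2 matrix of coordinates.
#' @param params an \code{\linkS4class{MBParams}} object.
#' @return scalar energy, or a vector for matrix input.
#' @export
mbEnergy <- function(point, params = mbParams()) {
  if (is.matrix(point)) {
    if (!all(is.finite(point))) stop("coordinates must be finite")
    return(apply(point, 1L, mbEnergy, params = params))
  }
  if (length(point) != 2L || !all(is.finite(point)))
    stop("point must be two finite coordinates")
  dx <- point[1] - params@x0
  dy <- point[2] - params@y0
  sum(params@A * exp(params@a * dx^2 + params@b * dx * dy + params@c * dy^2))
}

#' Mueller-Brown potential gradient
#'
#' Analytic gradient \eqn{\nabla U(x, y)} of \code{\link{mbEnergy}}.
#'
#' @inheritParams mbEnergy
#' @return numeric(2), c(dU/dx, dU/dy).
#' @export
mbGradient <- function(point, params = mbParams()) {
  if (length(point) != 2L || !all(is.finite(point)))
    stop("point must be two finite coordinates")
  dx <- point[1] - params@x0
  dy <- point[2] - params@y0
  e <- params@A * exp(params@a * dx^2 + params@b * dx * dy + params@c * dy^2)
  c(sum(e * (2 * params@a * dx + params@b * dy)),
    sum(e * (params@b * dx + 2 * params@c * dy)))
}

mbHessian <- function(point, params = mbParams(), h = 1e-6) {
  gx1 <- mbGradient(point + c(h, 0), params)
  gx0 <- mbGradient(point - c(h, 0), params)
  gy1 <- mbGradient(point + c(0, h), params)
  gy0 <- mbGradient(point - c(0, h), params)
  H <- cbind((gx1 - gx0) / (2 * h), (gy1 - gy0) / (2 * h))
  (H + t(H)) / 2
}

#' Stationary points of the Mueller-Brown potential
#'
#' Finds minima and saddle points by a dense grid scan over the canonical
#' window followed by Newton refinement of \eqn{\nabla U = 0}, classifying
#' each converged point by the Hessian eigenvalues. The potential diverges
#' outside the canonical window (the third Gaussian term has a hyperbolic
#' quadratic form), so the search is restricted to it.
#'
#' @param params an \code{\linkS4class{MBParams}} object.
#' @param window numeric(4), c(xlo, xhi, ylo, yhi) search window.
#' @param nGrid integer, grid points per axis for the scan.
#' @return data.frame with columns x, y, energy, kind ("minimum"/"saddle").
#' @export
mbStationaryPoints <- function(params = mbParams(),
                               window = c(-1.5, 1.1, -0.2, 2.0),
                               nGrid = 40L) {
  newton <- function(p) {
    for (k in 1:100) {
      g <- mbGradient(p, params)
      if (sqrt(sum(g^2)) < 1e-11) return(p)
      step <- tryCatch(solve(mbHessian(p, params), g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      nrm <- sqrt(sum(step^2))
      if (nrm > 0.5) step <- step * (0.5 / nrm)
      p <- p - step
      if (p[1] < window[1] - 0.5 || p[1] > window[2] + 0.5 ||
          p[2] < window[3] - 0.5 || p[2] > window[4] + 0.5) return(NULL)
    }
    NULL
  }
  xs <- seq(window[1], window[2], length.out = nGrid)
  ys <- seq(window[3], window[4], length.out = nGrid)
  found <- matrix(numeric(0), ncol = 2)
  for (x in xs) for (y in ys) {
    p <- newton(c(x, y))
    if (!is.null(p)) found <- rbind(found, p)
  }
  if (nrow(found) == 0) stop("no stationary points found")
  found <- found[!duplicated(round(found, 4)), , drop = FALSE]
  kind <- character(nrow(found))
  energy <- numeric(nrow(found))
  for (i in seq_len(nrow(found))) {
    ev <- eigen(mbHessian(found[i, ], params), symmetric = TRUE,
                only.values = TRUE)$values
    kind[i] <- if (all(ev > 0)) "minimum"
               else if (all(ev < 0)) "maximum" else "saddle"
    energy[i] <- mbEnergy(found[i, ], params)
  }
  out <- data.frame(x = found[, 1], y = found[, 2], energy = energy,
                    kind = kind)
  out <- out[out$kind != "maximum", ]
  out[order(out$energy), ]
}

#' Barrier between the two principal Mueller-Brown states
#'
#' Energy difference between the saddle separating the upper-left basin from
#' the rest of the landscape (the highest-energy saddle) and the deepest
#' minimum, in units of \eqn{k_B T}.
#'
#' @inheritParams mbStationaryPoints
#' @param temperature numeric(1), \eqn{T} (\eqn{k_B = 1}).
#' @return scalar barrier height in \eqn{k_B T}.
#' @export
mbBarrier <- function(params = mbParams(), temperature = 1) {
  sp <- mbStationaryPoints(params)
  mins <- sp[sp$kind == "minimum", ]
  sads <- sp[sp$kind == "saddle", ]
  if (nrow(mins) < 2 || nrow(sads) < 1)
    stop("could not identify two minima and a saddle")
  (max(sads$energy) - min(mins$energy)) / temperature
}

#' Basin labels for Mueller-Brown samples
#'
#' Assigns each sample to the nearest of the two principal minima when within
#' \code{radius} of it, with hysteresis: samples outside both basins inherit
#' the previous label (NA before the first basin visit). Used for counting
#' barrier crossings and for ground-truth state labels in embedding tests.
#'
#' @param xy n x 2 matrix of coordinates.
#' @param params an \code{\linkS4class{MBParams}} object.
#' @param radius basin capture radius around each minimum.
#' @return integer vector: 1 (upper-left basin), 2 (lower-right basin), or NA.
#' @export
mbBasinLabels <- function(xy, params = mbParams(), radius = 0.4) {
  sp <- mbStationaryPoints(params)
  mins <- sp[sp$kind == "minimum", ]
  mins <- mins[order(mins$energy), ]
  # the two principal states: the deepest minimum and the farthest-away one
  m1 <- c(mins$x[1], mins$y[1])
  d <- (mins$x - m1[1])^2 + (mins$y - m1[2])^2
  m2 <- c(mins$x[which.max(d)], mins$y[which.max(d)])
  d1 <- sqrt((xy[, 1] - m1[1])^2 + (xy[, 2] - m1[2])^2)
  d2 <- sqrt((xy[, 1] - m2[1])^2 + (xy[, 2] - m2[2])^2)
  lab <- rep(NA_integer_, nrow(xy))
  lab[d1 < radius] <- 1L
  lab[d2 < radius] <- 2L
  last <- NA_integer_
  for (i in seq_along(lab)) {
    if (is.na(lab[i])) lab[i] <- last else last <- lab[i]
  }
  lab
}

#' Count basin crossings
#'
#' Number of transitions between the two principal basins along a labelled
#' trajectory (NA labels before the first basin visit are skipped).
#'
#' @param labels integer labels from \code{\link{mbBasinLabels}}.
#' @return integer crossing count.
#' @export
countCrossings <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) < 2) return(0L)
  sum(diff(labels) != 0)
}
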