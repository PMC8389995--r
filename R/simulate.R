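#' @useDynLib mrse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Langevin configuration constructor
#'
#' @param temperature temperature \eqn{T} in energy units (\eqn{k_B = 1}).
#' @param friction friction coefficient (inverse time).
#' @param timestep integration time step.
#' @param nSteps number of steps.
#' @param seed RNG seed for the thermostat noise.
#' @param saveStride steps between saved frames.
#' @return a \code{\linkS4class{LangevinConfig}}.
#' @export
langevinConfig <- function(temperature = 1, friction = 10, timestep = 0.005,
                           nSteps = 1e5, seed = 111, saveStride = 1600L) {
  new("LangevinConfig", temperature = temperature, friction = friction,
      timestep = timestep, nSteps = nSteps, seed = seed,
      saveStride = as.integer(saveStride))
}

#' Well-tempered metadynamics configuration constructor
#'
#' @param biasFactor bias factor \eqn{\gamma > 1}; \code{Inf} selects
#'   non-tempered metadynamics (constant hill height).
#' @param initialHeight initial Gaussian hill height \eqn{h_0}.
#' @param widths Gaussian hill widths, one per CV.
#' @param pace steps between hill depositions.
#' @param gridBounds c(xlo, xhi, ylo, yhi) for the c(t) quadrature grid.
#' @param gridShape grid points per axis.
#' @param ctStride depositions between c(t) recomputations.
#' @return a \code{\linkS4class{MetaDConfig}}.
#' @export
metadConfig <- function(biasFactor = 5, initialHeight = 1.2,
                        widths = c(0.1, 0.1), pace = 200L,
                        gridBounds = c(-5, 5, -5, 5),
                        gridShape = c(500L, 500L), ctStride = 1L) {
  new("MetaDConfig", biasFactor = biasFactor, initialHeight = initialHeight,
      widths = widths, pace = as.integer(pace), gridBounds = gridBounds,
      gridShape = as.integer(gridShape), ctStride = as.integer(ctStride))
}

#' Run Langevin dynamics, optionally with well-tempered metadynamics
#'
#' Integrates a single particle (mass 1) with the Bussi-Parrinello Langevin
#' scheme: exact Ornstein-Uhlenbeck velocity half-steps around a velocity-
#' Verlet step. With a \code{MetaDConfig}, Gaussian hills are deposited every
#' \code{pace} steps with well-tempered height damping
#' \eqn{h = h_0 e^{-V(s,t)/((\gamma - 1) k_B T)}}, the reweighting offset
#' \eqn{c(t)} is recomputed by grid quadrature at every deposition, and each
#' saved frame records the instantaneous bias \eqn{V} and \eqn{c(t)}.
#'
#' @param start numeric(2), initial position.
#' @param params \code{\linkS4class{MBParams}} (ignored for
#'   \code{potential = "harmonic"}).
#' @param cfg a \code{\linkS4class{LangevinConfig}}.
#' @param bias a \code{\linkS4class{MetaDConfig}} or NULL for an unbiased run.
#' @param potential "muellerBrown" or "harmonic" (a validation potential
#'   \eqn{U = \kappa(x^2 + y^2)/2}).
#' @param kappa spring constant for the harmonic potential.
#' @return a \code{\linkS4class{BiasedTrajectory}}; velocities and deposited
#'   hills are kept in \code{metadata}.
#' @examples
#' cfg <- langevinConfig(nSteps = 2000, saveStride = 100, seed = 7)
#' traj <- runLangevin(c(-0.55, 1.44), cfg = cfg)
#' traj
#' @export
runLangevin <- function(start, params = mbParams(), cfg = langevinConfig(),
                        bias = NULL, potential = c("muellerBrown", "harmonic"),
                        kappa = 1) {
  potential <- match.arg(potential)
  if (length(start) != 2L || !all(is.finite(start)))
    stop("start must be two finite coordinates")
  validObject(cfg)
  useBias <- !is.null(bias)
  if (useBias) validObject(bias)
  b <- if (useBias) bias else metadConfig()
  gammaInf <- useBias && is.infinite(b@biasFactor)
  res <- .cpp_run_langevin(
    start, params@A, params@a, params@b, params@c, params@x0, params@y0,
    if (potential == "muellerBrown") 0L else 1L, kappa,
    cfg@temperature, cfg@friction, cfg@timestep, cfg@nSteps,
    cfg@saveStride, cfg@seed,
    useBias, gammaInf, if (gammaInf) 2 else b@biasFactor,
    b@initialHeight, b@widths[1], b@widths[2], b@pace,
    b@gridBounds, b@gridShape, b@ctStride)
  hills <- cbind(time = res$hill_time, x = res$hill_x, y = res$hill_y,
                 height = res$hill_height)
  new("BiasedTrajectory",
      time = res$time,
      coords = cbind(x = res$x, y = res$y),
      bias = res$bias, ct = res$ct, weight = NULL,
      metadata = list(temperature = cfg@temperature,
                      friction = cfg@friction, timestep = cfg@timestep,
                      seed = cfg@seed, potential = potential,
                      biasFactor = if (useBias) b@biasFactor else NA_real_,
                      burnInFraction = 0,
                      velocities = cbind(vx = res$vx, vy = res$vy),
                      hills = hills))
}

#' Create an empty metadynamics bias state
#'
#' @param cfg a \code{\linkS4class{MetaDConfig}} supplying the hill widths and
#'   the c(t) quadrature grid.
#' @return a \code{\linkS4class{BiasState}} with no hills and c(t) = 0.
#' @export
newBiasState <- function(cfg = metadConfig()) {
  gx <- seq(cfg@gridBounds[1], cfg@gridBounds[2], length.out = cfg@gridShape[1])
  gy <- seq(cfg@gridBounds[3], cfg@gridBounds[4], length.out = cfg@gridShape[2])
  new("BiasState",
      hills = matrix(numeric(0), ncol = 4,
                     dimnames = list(NULL, c("time", "x", "y", "height"))),
      widths = cfg@widths,
      grid = matrix(0, length(gx), length(gy)),
      gridX = gx, gridY = gy, ct = 0)
}

#' Exact bias value from the hill sum
#'
#' @param state a \code{\linkS4class{BiasState}}.
#' @param s numeric(2), evaluation point.
#' @return scalar bias potential \eqn{V(s)}.
#' @export
biasValue <- function(state, s) {
  if (nrow(state@hills) == 0) return(0)
  dx <- s[1] - state@hills[, "x"]
  dy <- s[2] - state@hills[, "y"]
  sum(state@hills[, "height"] *
      exp(-(dx^2 / (2 * state@widths[1]^2) + dy^2 / (2 * state@widths[2]^2))))
}

#' Deposit a well-tempered hill
#'
#' Appends one Gaussian hill at \code{s} with height
#' \eqn{h_0 e^{-V(s,t)/((\gamma-1) k_B T)}} (or constant \eqn{h_0} for
#' \code{biasFactor = Inf}) and updates the bias grid. The grid is used only
#' by \code{\link{computeCt}}.
#'
#' @param state a \code{\linkS4class{BiasState}}.
#' @param s numeric(2), deposition point.
#' @param cfg a \code{\linkS4class{MetaDConfig}}.
#' @param beta inverse temperature.
#' @param time deposit time recorded with the hill.
#' @return the updated \code{BiasState} (c(t) is not recomputed here).
#' @export
depositHill <- function(state, s, cfg = metadConfig(), beta = 1, time = 0) {
  v <- biasValue(state, s)
  h <- if (is.infinite(cfg@biasFactor)) cfg@initialHeight
       else cfg@initialHeight * exp(-v * beta / (cfg@biasFactor - 1))
  state@hills <- rbind(state@hills, c(time, s[1], s[2], h))
  colnames(state@hills) <- c("time", "x", "y", "height")
  dx2 <- outer(state@gridX - s[1], rep(1, length(state@gridY)))^2
  dy2 <- outer(rep(1, length(state@gridX)), state@gridY - s[2])^2
  state@grid <- state@grid +
    h * exp(-(dx2 / (2 * state@widths[1]^2) + dy2 / (2 * state@widths[2]^2)))
  state
}

#' Reweighting offset c(t) from the bias grid
#'
#' Evaluates
#' \deqn{c(t) = \beta^{-1} \log \frac{\int ds\, e^{\gamma \beta V(s,t)/(\gamma-1)}}
#'   {\int ds\, e^{\beta V(s,t)/(\gamma-1)}}}
#' by trapezoidal quadrature on the state's grid (the common cell area cancels
#' in the ratio). Returns 0 when no bias has been deposited; grows as hills
#' accumulate, up to tiny transient dips when a hill lands in a low-bias
#' region.
#'
#' @param state a \code{\linkS4class{BiasState}}.
#' @param biasFactor bias factor \eqn{\gamma}; \code{Inf} gives the
#'   non-tempered limit \eqn{\beta^{-1}\log \langle e^{\beta V}\rangle_{grid}}.
#' @param beta inverse temperature.
#' @return scalar c(t).
#' @export
computeCt <- function(state, biasFactor = 5, beta = 1) {
  if (length(state@grid) == 0) stop("empty bias grid")
  v <- state@grid
  if (is.infinite(biasFactor)) {
    facNum <- beta; facDen <- 0
  } else {
    facNum <- biasFactor * beta / (biasFactor - 1)
    facDen <- beta / (biasFactor - 1)
  }
  wx <- rep(1, nrow(v)); wx[c(1, nrow(v))] <- 0.5
  wy <- rep(1, ncol(v)); wy[c(1, ncol(v))] <- 0.5
  wgt <- outer(wx, wy)
  vmax <- max(v)
  ((facNum - facDen) * vmax +
    log(sum(wgt * exp(facNum * (v - vmax)))) -
    log(sum(wgt * exp(facDen * (v - vmax))))) / beta
}

#' Attach statistical weights to a biased trajectory
#'
#' Drops the burn-in segment, then attaches per-frame weights
#' \eqn{w = e^{\beta(V - c(t))}}. With \code{normalize = TRUE} weights are
#' divided by their maximum, mapping them to \eqn{(0, 1]} while preserving
#' ratios.
#'
#' @param traj a \code{\linkS4class{BiasedTrajectory}} carrying bias and c(t).
#' @param burnInFraction fraction of initial frames to discard (default 0.2:
#'   the early period where the bias changes rapidly and weights are
#'   unreliable).
#' @param normalize divide weights by their maximum.
#' @param beta inverse temperature; defaults to 1/temperature from metadata.
#' @return the trajectory with weights attached and burn-in removed.
#' @export
trajectoryWeights <- function(traj, burnInFraction = 0.2, normalize = TRUE,
                              beta = NULL) {
  if (length(traj@bias) == 0 || length(traj@ct) == 0)
    stop("trajectory must carry bias and c(t) values")
  if (burnInFraction < 0 || burnInFraction >= 1)
    stop("burnInFraction must be in [0, 1)")
  if (is.null(beta)) {
    temp <- traj@metadata$temperature
    beta <- if (is.null(temp)) 1 else 1 / temp
  }
  n <- nSamples(traj)
  keep <- seq.int(floor(burnInFraction * n) + 1L, n)
  w <- exp(beta * (traj@bias[keep] - traj@ct[keep]))
  if (normalize) w <- w / max(w)
  md <- traj@metadata
  md$burnInFraction <- burnInFraction
  new("BiasedTrajectory",
      time = traj@time[keep],
      coords = traj@coords[keep, , drop = FALSE],
      bias = traj@bias[keep], ct = traj@ct[keep],
      weight = w, metadata = md)
}
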