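#' Read a COLVAR-style whitespace table
#'
#' Parses the PLUMED COLVAR dialect: a header line
#' \code{#! FIELDS <name> <name> ...} followed by whitespace-delimited numeric
#' rows. Additional comment lines (starting with \code{#}) are skipped.
#'
#' @param path file path.
#' @return data.frame with the named columns; attribute \code{hasWeights}
#'   records whether a \code{weight} column is present (downstream code
#'   defaults missing weights to 1).
#' @export
readColvar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("malformed header: expected '#! FIELDS ...' on line 1")
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  dataIdx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  vals <- matrix(NA_real_, length(dataIdx), length(fields))
  for (r in seq_along(dataIdx)) {
    tok <- strsplit(trimws(lines[dataIdx[r]]), "\\s+")[[1]]
    if (length(tok) != length(fields))
      stop(sprintf("line %d: expected %d columns, found %d",
                   dataIdx[r], length(fields), length(tok)))
    vals[r, ] <- as.numeric(tok)
  }
  if (anyNA(vals)) stop("non-numeric value in data rows")
  df <- as.data.frame(vals)
  names(df) <- fields
  if ("time" %in% fields && is.unsorted(df$time))
    stop("time column must be monotone non-decreasing")
  attr(df, "hasWeights") <- "weight" %in% fields
  df
}

#' Write a COLVAR-style whitespace table
#'
#' Writes \code{#! FIELDS ...} plus one row per frame. The default format
#' (\code{\%.17e}) round-trips doubles losslessly through
#' \code{\link{readColvar}}.
#'
#' @param x data.frame or matrix with named columns.
#' @param path output path.
#' @param format sprintf format per value.
#' @return invisibly, the path.
#' @export
writeColvar <- function(x, path, format = "%.17e") {
  x <- as.data.frame(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all columns must be named")
  header <- paste("#! FIELDS", paste(names(x), collapse = " "))
  body <- apply(as.matrix(x), 1L, function(row)
    paste(sprintf(format, row), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert a trajectory to a COLVAR table
#'
#' @param traj a \code{\linkS4class{BiasedTrajectory}}.
#' @return data.frame with columns time, the coordinates, metad.bias,
#'   metad.ct and (when attached) weight.
#' @export
trajectoryToColvar <- function(traj) {
  cn <- colnames(coords(traj))
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(coords(traj))))
  df <- data.frame(time = frameTimes(traj))
  for (j in seq_along(cn)) df[[cn[j]]] <- coords(traj)[, j]
  df$metad.bias <- biasValues(traj)
  df$metad.ct <- ctValues(traj)
  if (!is.null(sampleWeights(traj))) df$weight <- sampleWeights(traj)
  df
}

#' Build a trajectory from a COLVAR table
#'
#' Inverse of \code{\link{trajectoryToColvar}}: coordinate columns are
#' everything except time, metad.bias, metad.ct and weight. A missing weight
#' column leaves weights unattached (downstream defaults to 1).
#'
#' @param df data.frame as returned by \code{\link{readColvar}}.
#' @param metadata optional metadata list.
#' @return a \code{\linkS4class{BiasedTrajectory}}.
#' @export
colvarToTrajectory <- function(df, metadata = list()) {
  special <- c("time", "metad.bias", "metad.ct", "weight")
  coordCols <- setdiff(names(df), special)
  n <- nrow(df)
  new("BiasedTrajectory",
      time = if ("time" %in% names(df)) df$time else as.numeric(seq_len(n)),
      coords = as.matrix(df[, coordCols, drop = FALSE]),
      bias = if ("metad.bias" %in% names(df)) df$metad.bias else rep(0, n),
      ct = if ("metad.ct" %in% names(df)) df$metad.ct else rep(0, n),
      weight = if ("weight" %in% names(df)) df$weight else NULL,
      metadata = metadata)
}

#' Generate synthetic weighted feature clouds
#'
#' Reproducible fixtures for testing the learning stack without running any
#' simulation:
#' \describe{
#'   \item{two-cluster}{two well-separated 2-D Gaussians, unit weights, with a
#'     \code{label} column.}
#'   \item{gauss-mixture}{a k-dimensional Gaussian mixture; each sample gets a
#'     bias value (0 by default via \code{biasSd = 0}) and weight
#'     \eqn{w = e^{\beta V}}.}
#'   \item{biased-double-well}{1-D samples drawn from the well-tempered
#'     distribution \eqn{\propto [P(s)]^{1/\gamma}} of a quartic double well
#'     \eqn{F(s) = h (s^2 - 1)^2}, with the static converged bias
#'     \eqn{V = -(1 - 1/\gamma) F} recorded and weights \eqn{e^{\beta V}}.}
#' }
#'
#' @param kind one of "two-cluster", "gauss-mixture", "biased-double-well".
#' @param n number of samples.
#' @param seed RNG seed (the output is a deterministic function of it).
#' @param k feature dimension (gauss-mixture).
#' @param nComponents mixture components (gauss-mixture).
#' @param biasSd standard deviation of the random per-sample bias
#'   (gauss-mixture; 0 gives unit weights).
#' @param gamma bias factor of the emulated well-tempered run
#'   (biased-double-well).
#' @param barrier barrier height h of the double well, in \eqn{k_B T}.
#' @param beta inverse temperature.
#' @return data.frame in COLVAR column layout (time, features, metad.bias,
#'   metad.ct, weight, plus ground-truth \code{label} where applicable).
#' @export
makeFixture <- function(kind = c("two-cluster", "gauss-mixture",
                                 "biased-double-well"),
                        n = 200L, seed = 111, k = 2L, nComponents = 3L,
                        biasSd = 0, gamma = 5, barrier = 5, beta = 1) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (kind == "two-cluster") {
    lab <- rep(1:2, length.out = n)
    centers <- rbind(c(-2, 0), c(2, 0))
    xy <- centers[lab, ] + matrix(stats::rnorm(2 * n, sd = 0.4), n, 2)
    df <- data.frame(time = seq_len(n) - 1, x = xy[, 1], y = xy[, 2],
                     metad.bias = 0, metad.ct = 0, weight = 1, label = lab)
  } else if (kind == "gauss-mixture") {
    lab <- sample.int(nComponents, n, replace = TRUE)
    centers <- matrix(stats::rnorm(nComponents * k, sd = 3), nComponents, k)
    x <- centers[lab, , drop = FALSE] +
      matrix(stats::rnorm(n * k, sd = 0.5), n, k)
    v <- if (biasSd > 0) abs(stats::rnorm(n, sd = biasSd)) else rep(0, n)
    w <- exp(beta * v)
    w <- w / max(w)
    df <- data.frame(time = seq_len(n) - 1)
    for (j in seq_len(k)) df[[paste0("x", j)]] <- x[, j]
    df$metad.bias <- v
    df$metad.ct <- 0
    df$weight <- w
    df$label <- lab
  } else {
    fes <- function(s) barrier * (s^2 - 1)^2
    grid <- seq(-2.5, 2.5, length.out = 4001)
    pv <- exp(-beta * fes(grid) / gamma)      # well-tempered density P^{1/gamma}
    cdf <- cumsum(pv) / sum(pv)
    u <- stats::runif(n)
    s <- stats::approx(cdf, grid, xout = u, rule = 2)$y
    v <- -(1 - 1 / gamma) * fes(s)            # converged static bias
    w <- exp(beta * v)
    w <- w / max(w)
    df <- data.frame(time = seq_len(n) - 1, s = s,
                     metad.bias = v, metad.ct = 0, weight = w,
                     label = ifelse(s < 0, 1L, 2L))
  }
  attr(df, "hasWeights") <- TRUE
  df
}

#' Derive a module-specific child seed
#'
#' Deterministically maps a global seed and a module name to a child seed
#' below \eqn{2^{31}}, so one run seed reproducibly feeds the simulator, the
#' landmark draw and the training shuffle.
#'
#' @param seed global integer seed.
#' @param name module name.
#' @return integer child seed.
#' @export
deriveSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Read a run configuration
#'
#' YAML with optional sections \code{simulate}, \code{landmarks},
#' \code{train} and \code{analysis} plus a global \code{seed}; unknown
#' sections or keys are rejected. Missing values fall back to the package
#' defaults (bias factor 5, hill height 1.2, widths 0.1, pace 200, alpha 2,
#' learning rate 1e-3, batch 500, 100 epochs, seed 111).
#'
#' @param path YAML file path, or NULL for all defaults.
#' @return nested list of settings with defaults filled in.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    seed = 111,
    simulate = list(temperature = 1, friction = 10, timestep = 0.005,
                    nSteps = 1e6, saveStride = 100, start = c(-0.558, 1.442),
                    biasFactor = 5, initialHeight = 1.2, widths = c(0.1, 0.1),
                    pace = 200, gridBounds = c(-5, 5, -5, 5),
                    gridShape = c(500, 500), burnInFraction = 0.2),
    landmarks = list(alpha = 2, n = 2000),
    train = list(hidden = c(500, 500, 2000), d = 2, leakySlope = 0.2,
                 dropout = 0.1, learningRate = 1e-3, beta1 = 0.9,
                 beta2 = 0.999, weightDecay = 1e-4, batchSize = 500,
                 epochs = 100, reweight = TRUE),
    analysis = list(gridSize = 200, beta = 1))
  badSec <- setdiff(names(cfg), names(defaults))
  if (length(badSec)) stop("unknown config section(s): ",
                           paste(badSec, collapse = ", "))
  for (sec in names(cfg)) {
    if (sec == "seed") { defaults$seed <- cfg$seed; next }
    badKey <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(badKey)) stop(sprintf("unknown key(s) in '%s': %s", sec,
                                     paste(badKey, collapse = ", ")))
    defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  defaults
}
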