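# Lazily computed simulation runs shared by the acceptance tests (the same
# biased run feeds the crossing-count and end-to-end embedding checks).

.acceptCache <- new.env(parent = emptyenv())

# scaled-down WT-MetaD run: 1e6 steps, gamma = 5, frames every 100 steps
acceptanceRun <- function() {
  if (is.null(.acceptCache$run)) {
    lc <- langevinConfig(nSteps = 1e6, saveStride = 100, seed = 111)
    tb <- runLangevin(c(-0.558, 1.442), cfg = lc,
                      bias = metadConfig(biasFactor = 5))
    .acceptCache$run <- list(raw = tb, weighted = trajectoryWeights(tb))
  }
  .acceptCache$run
}

# longer run for free-energy reconstruction: 4e6 steps, frames every 25 steps
acceptanceFesRun <- function() {
  if (is.null(.acceptCache$fesRun)) {
    lc <- langevinConfig(nSteps = 4e6, saveStride = 25, seed = 111)
    tb <- runLangevin(c(-0.558, 1.442), cfg = lc,
                      bias = metadConfig(biasFactor = 5))
    .acceptCache$fesRun <- trajectoryWeights(tb)
  }
  .acceptCache$fesRun
}

# analytic Boltzmann reference of the scaled Mueller-Brown system on the
# canonical window, via dense quadrature
mbReference <- function(nGrid = 200L) {
  if (is.null(.acceptCache$ref) || nrow(.acceptCache$ref$U) != nGrid) {
    p <- mbParams()
    win <- c(-1.7, 1.3, -0.5, 2.3)
    gx <- seq(win[1], win[2], length.out = nGrid)
    gy <- seq(win[3], win[4], length.out = nGrid)
    U <- outer(gx, gy, Vectorize(function(x, y) mbEnergy(c(x, y), p)))
    .acceptCache$ref <- list(win = win, gx = gx, gy = gy, U = U,
                             Fref = U - min(U))
  }
  .acceptCache$ref
}
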