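# Mueller-Brown potential, Langevin integrator, hill deposition, c(t) and
# statistical weights.

test_that("potential energy and gradient are consistent and match fixtures", {
  p <- mbParams()
  expect_equal(mbEnergy(c(0.3, 0.8), mbParams(A = rep(0, 4))), 0)
  # frozen stationary-point fixtures from an independent Newton search
  expect_equal(mbEnergy(c(-0.558223635, 1.441725842), p), -29.339903442,
               tolerance = 1e-8)
  expect_equal(mbEnergy(c(0.623499405, 0.028037759), p), -21.633344823,
               tolerance = 1e-8)
  # gradient vanishes at the minimum and matches central differences elsewhere
  expect_lt(max(abs(mbGradient(c(-0.558223635, 1.441725842), p))), 1e-4)
  for (pt in list(c(0, 0.5), c(-1, 1.2), c(0.5, 0.2))) {
    expect_equal(mbGradient(pt, p),
                 numGrad(function(z) mbEnergy(z, p), pt),
                 tolerance = 1e-6)
  }
  expect_error(mbEnergy(c(NA, 0)), "finite")
})

test_that("stationary-point search finds the classic landscape and barrier", {
  sp <- mbStationaryPoints()
  expect_equal(sum(sp$kind == "minimum"), 3)
  expect_gte(sum(sp$kind == "saddle"), 2)
  expect_equal(mbBarrier(), 21.206935, tolerance = 1e-4)
})

test_that("frozen particle on a flat potential stays put", {
  cfg <- langevinConfig(temperature = 0, friction = 0, nSteps = 1000,
                        saveStride = 100, seed = 1)
  traj <- runLangevin(c(0.3, -0.2), cfg = cfg, potential = "harmonic",
                      kappa = 0)
  expect_true(all(coords(traj)[, 1] == 0.3))
  expect_true(all(coords(traj)[, 2] == -0.2))
})

test_that("harmonic well equipartition: positional variance is kT/kappa", {
  kappa <- 4
  cfg <- langevinConfig(temperature = 1, friction = 2, timestep = 0.01,
                        nSteps = 1e6, saveStride = 20, seed = 2)
  traj <- runLangevin(c(0, 0), cfg = cfg, potential = "harmonic",
                      kappa = kappa)
  v <- apply(coords(traj), 2, var)
  expect_equal(unname(v), rep(1 / kappa, 2), tolerance = 0.05)
})

test_that("energy is conserved without thermostat coupling", {
  cfg <- langevinConfig(temperature = 0, friction = 0, timestep = 0.001,
                        nSteps = 1e4, saveStride = 10, seed = 3)
  traj <- runLangevin(c(-0.4, 1.0), cfg = cfg)
  vel <- traj@metadata$velocities
  etot <- mbEnergy(coords(traj)) + 0.5 * rowSums(vel^2)
  # drift per step should be O(dt^2)
  expect_lt(max(abs(etot - etot[1])), 1e4 * 0.001^2)
})

test_that("unbiased run at T=1 is trapped in its starting basin", {
  cfg <- langevinConfig(nSteps = 1e5, saveStride = 100, seed = 4)
  traj <- runLangevin(c(-0.558, 1.442), cfg = cfg)
  lab <- mbBasinLabels(coords(traj))
  expect_true(all(lab == 1L, na.rm = TRUE))
  expect_equal(countCrossings(lab), 0L)
})

test_that("hill heights follow the well-tempered damping law", {
  cfg <- metadConfig(biasFactor = 5, initialHeight = 1.2)
  st <- newBiasState(cfg)
  s <- c(0.1, 0.4)
  st1 <- depositHill(st, s, cfg, beta = 1)
  expect_equal(unname(st1@hills[1, "height"]), 1.2)  # first hill: V = 0
  st2 <- depositHill(st1, s, cfg, beta = 1)
  expect_equal(unname(st2@hills[2, "height"]),
               1.2 * exp(-1.2 / (5 - 1)))          # closed form after one hill
  # non-tempered sentinel: heights stay h0
  cfgInf <- metadConfig(biasFactor = Inf)
  sI <- depositHill(depositHill(newBiasState(cfgInf), s, cfgInf), s, cfgInf)
  expect_equal(unname(sI@hills[, "height"]), c(1.2, 1.2))
})

test_that("hill heights decay while the walker fills its basin", {
  mc <- metadConfig(biasFactor = 5)
  lc <- langevinConfig(nSteps = 4e4, saveStride = 200, seed = 5)
  traj <- runLangevin(c(-0.558, 1.442), cfg = lc, bias = mc)
  h <- traj@metadata$hills[, "height"]
  expect_true(all(h > 0))
  # heights decay in trend as the basin fills (individual hills can tick up
  # when the walker moves to a less-filled spot within the basin)
  n <- length(h)
  expect_lt(mean(h[(n - 19):n]), 0.5 * mean(h[1:20]))
  expect_lt(max(h[(n %/% 2):n]), max(h[1:(n %/% 2)]))
  # at a fixed revisited point the damping law is exact: second hill at the
  # same spot is strictly lower
  st <- depositHill(newBiasState(mc), c(0, 1), mc)
  st2 <- depositHill(st, c(0, 1), mc)
  expect_lt(st2@hills[2, "height"], st2@hills[1, "height"])
})

test_that("c(t) quadrature matches trivial and independent oracles", {
  cfg <- metadConfig(gridShape = c(200L, 200L))
  st <- newBiasState(cfg)
  expect_equal(computeCt(st, biasFactor = 5, beta = 1), 0)
  # constant bias V0 on the grid: c = V0 for any gamma
  stC <- st
  stC@grid <- matrix(3.7, 200, 200)
  expect_equal(computeCt(stC, biasFactor = 5), 3.7, tolerance = 1e-12)
  expect_equal(computeCt(stC, biasFactor = 2.5), 3.7, tolerance = 1e-12)
  # single hill: compare against an independent high-resolution trapezoidal
  # quadrature oracle (the integrand is smooth on the hill width, so the
  # 200^2 estimate must agree with a 1601^2 one to high relative accuracy)
  s0 <- c(0.2, -0.3)
  st1 <- depositHill(st, s0, cfg, beta = 1)
  ct <- computeCt(st1, biasFactor = 5)
  n <- 1601L
  gx <- seq(-5, 5, length.out = n)
  vv <- cfg@initialHeight *
    exp(-(outer(gx - s0[1], rep(1, n))^2 / (2 * 0.1^2) +
          outer(rep(1, n), gx - s0[2])^2 / (2 * 0.1^2)))
  wt <- rep(1, n); wt[c(1, n)] <- 0.5
  wgt <- outer(wt, wt)
  oracle <- log(sum(wgt * exp(5 / 4 * vv)) / sum(wgt * exp(vv / 4)))
  expect_equal(ct, oracle, tolerance = 1e-6)
  expect_gt(ct, 0)
})

test_that("c(t) increases as hills accumulate and weights are positive", {
  mc <- metadConfig(biasFactor = 5, gridShape = c(250L, 250L))
  lc <- langevinConfig(nSteps = 5e4, saveStride = 100, seed = 6)
  traj <- runLangevin(c(-0.558, 1.442), cfg = lc, bias = mc)
  ct <- ctValues(traj)
  expect_gt(ct[length(ct)], ct[2] + 0.5)     # strong net growth
  expect_true(all(diff(ct) > -1e-3))         # transient dips are tiny
  tw <- trajectoryWeights(traj)
  expect_true(all(sampleWeights(tw) > 0))
})

test_that("weights are exp(beta * (V - c)) with burn-in and normalization", {
  mkTraj <- function(v, ct, n = length(v)) {
    new("BiasedTrajectory", time = as.numeric(seq_len(n)),
        coords = matrix(0, n, 2), bias = v, ct = ct,
        weight = NULL, metadata = list(temperature = 1))
  }
  # Vtilde = 0 everywhere -> all weights 1
  t0 <- trajectoryWeights(mkTraj(rep(2, 10), rep(2, 10)), burnInFraction = 0)
  expect_equal(sampleWeights(t0), rep(1, 10))
  # Vtilde = 0, 1, 2 at beta = 1 -> (1, e, e^2) unnormalized
  t1 <- trajectoryWeights(mkTraj(c(0, 1, 2), rep(0, 3)), burnInFraction = 0,
                          normalize = FALSE)
  expect_equal(sampleWeights(t1), c(1, exp(1), exp(2)))
  # 20% burn-in on 100 frames leaves 80
  t2 <- trajectoryWeights(mkTraj(rep(0, 100), rep(0, 100)),
                          burnInFraction = 0.2)
  expect_equal(nSamples(t2), 80L)
  # normalization maps to (0, 1] with max exactly 1
  t3 <- trajectoryWeights(mkTraj(c(0, 3, 1), rep(0, 3)), burnInFraction = 0)
  expect_equal(max(sampleWeights(t3)), 1)
  expect_equal(sampleWeights(t3), exp(c(0, 3, 1) - 3))
  # missing bias errors
  bad <- new("BiasedTrajectory", time = numeric(0),
             coords = matrix(0, 0, 2), bias = numeric(0), ct = numeric(0),
             weight = NULL, metadata = list())
  expect_error(trajectoryWeights(bad), "bias")
})

test_that("simulator-recorded bias and c(t) match an R-side reconstruction", {
  mc <- metadConfig(biasFactor = 5, gridShape = c(300L, 300L))
  lc <- langevinConfig(nSteps = 6000, saveStride = 600, seed = 8)
  traj <- runLangevin(c(-0.558, 1.442), cfg = lc, bias = mc)
  hills <- traj@metadata$hills
  # rebuild the bias state hill by hill and compare the final frame
  st <- newBiasState(mc)
  for (i in seq_len(nrow(hills))) {
    st@hills <- rbind(st@hills, hills[i, , drop = FALSE])
    dx2 <- outer(st@gridX - hills[i, "x"], rep(1, length(st@gridY)))^2
    dy2 <- outer(rep(1, length(st@gridX)), st@gridY - hills[i, "y"])^2
    st@grid <- st@grid + hills[i, "height"] *
      exp(-(dx2 / (2 * 0.1^2) + dy2 / (2 * 0.1^2)))
  }
  lastPos <- coords(traj)[nSamples(traj), ]
  expect_equal(biasValues(traj)[nSamples(traj)], biasValue(st, lastPos),
               tolerance = 1e-10)
  expect_equal(ctValues(traj)[nSamples(traj)],
               computeCt(st, biasFactor = 5, beta = 1), tolerance = 1e-6)
  # recorded hill heights obey the damping law against the rebuilt state
  st2 <- newBiasState(mc)
  for (i in seq_len(nrow(hills))) {
    v <- biasValue(st2, hills[i, c("x", "y")])
    expect_equal(unname(hills[i, "height"]), 1.2 * exp(-v / 4),
                 tolerance = 1e-8)
    st2 <- depositHill(st2, hills[i, c("x", "y")], mc,
                       time = hills[i, "time"])
  }
})

test_that("trajectories are reproducible and blow-ups are reported", {
  cfg <- langevinConfig(nSteps = 5000, saveStride = 100, seed = 42)
  t1 <- runLangevin(c(0, 0.5), cfg = cfg)
  t2 <- runLangevin(c(0, 0.5), cfg = cfg)
  expect_identical(coords(t1), coords(t2))
  # enormous timestep on the steep MB walls must blow up with a step report
  bad <- langevinConfig(timestep = 1, nSteps = 1000, saveStride = 100,
                        seed = 1)
  expect_error(runLangevin(c(-0.558, 1.442), cfg = bad), "step")
})
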