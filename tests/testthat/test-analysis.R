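# FES estimation, free-energy differences, Procrustes, diagnostics,
# feature filtering and standardization.

test_that("Silverman bandwidths follow the closed form and scale with data", {
  set.seed(2)
  x <- rnorm(1000)
  h <- bandwidthSilverman(x)
  expect_equal(h, sd(x) * (4 / 3)^(1 / 5) * 1000^(-1 / 5), tolerance = 1e-12)
  expect_equal((4 / 3)^(1 / 5), 1.059, tolerance = 1e-3)  # the 1.06 rule
  expect_equal(bandwidthSilverman(3 * x), 3 * h, tolerance = 1e-12)
  # duplicating the data changes only the n-dependence
  xx <- c(x, x)
  expect_equal(bandwidthSilverman(xx) / bandwidthSilverman(x),
               (2000 / 1000)^(-1 / 5) * sd(xx) / sd(x), tolerance = 1e-12)
  expect_error(bandwidthSilverman(cbind(x, 0 * x)), "variance")
})

test_that("kdeFes: single sample, Gaussian recovery, reweighted double well", {
  # single sample: minimum exactly at the sample, radially increasing
  f1 <- kdeFes(matrix(c(0.5, -0.2), 1, 2), bandwidths = c(0.3, 0.3),
               gridBounds = c(-1, 2, -2, 1), gridSize = 61)
  ax <- fesAxes(f1)
  v <- fesValues(f1)
  ij <- which(v == 0, arr.ind = TRUE)
  expect_equal(ax[[1]][ij[1]], 0.5, tolerance = 0.03)
  expect_equal(ax[[2]][ij[2]], -0.2, tolerance = 0.03)
  # 1e4 standard-normal draws recover F = s^2/2 within 0.15 over the 2-sigma disk
  set.seed(3)
  s <- matrix(rnorm(2e4), ncol = 2)
  fes <- kdeFes(s, bandwidths = c(0.15, 0.15), gridBounds = c(-3, 3, -3, 3),
                gridSize = 100)
  gx <- fesAxes(fes)[[1]]; gy <- fesAxes(fes)[[2]]
  r2 <- outer(gx^2, gy^2, `+`)
  ftheory <- r2 / 2
  mask <- r2 < 4
  dev <- fesValues(fes)[mask] - ftheory[mask]
  expect_lt(sqrt(mean(dev^2)), 0.15)
  # reweighted biased double-well samples recover the unbiased F; the
  # unweighted estimate recovers the flattened F/gamma instead
  gamma <- 4; barrier <- 4
  fix <- makeFixture("biased-double-well", n = 5e4, seed = 5,
                     gamma = gamma, barrier = barrier)
  fw <- kdeFes(fix$s, weights = fix$weight, bandwidths = 0.05,
               gridBounds = c(-1.8, 1.8), gridSize = 200)
  fu <- kdeFes(fix$s, bandwidths = 0.05, gridBounds = c(-1.8, 1.8),
               gridSize = 200)
  sg <- fesAxes(fw)[[1]]
  ftrue <- barrier * (sg^2 - 1)^2
  ftrue <- ftrue - min(ftrue)
  mask <- ftrue < 3
  expect_lt(mean(abs(fesValues(fw)[mask] - ftrue[mask])), 0.15)
  expect_lt(mean(abs(fesValues(fu)[mask] - ftrue[mask] / gamma)), 0.15)
  expect_error(kdeFes(matrix(0, 0, 2)), "samples")
})

test_that("free-energy differences match closed forms and are antisymmetric", {
  # discrete two-state toy: populations 0.8/0.2 -> dF = log 4
  s <- matrix(c(rep(-1, 8), rep(1, 2)), ncol = 1)
  expect_equal(freeEnergyDifference(s, c(-2, 0), c(0, 2)), log(4))
  expect_equal(freeEnergyDifference(s, c(0, 2), c(-2, 0)), -log(4))
  # symmetric double well with symmetric regions: 0
  sg <- seq(-2, 2, length.out = 2001)
  w <- exp(-3 * (sg^2 - 1)^2)
  expect_equal(freeEnergyDifference(matrix(sg, ncol = 1), c(-2, 0), c(0, 2),
                                    weights = w), 0, tolerance = 1e-10)
  # FES-grid route agrees with the sample route and ignores constant shifts
  set.seed(7)
  x <- matrix(c(rnorm(3000, -1, 0.3), rnorm(1000, 1, 0.3)), ncol = 1)
  dSamp <- freeEnergyDifference(x, c(-2, 0), c(0, 2))
  fes <- kdeFes(x, bandwidths = 0.1, gridBounds = c(-2.5, 2.5),
                gridSize = 500)
  dFes <- freeEnergyDifference(fes, c(-2, 0), c(0, 2))
  expect_equal(dFes, dSamp, tolerance = 0.02)
  expect_equal(dSamp, log(3), tolerance = 0.1)
  expect_error(freeEnergyDifference(x, c(-2, 0), c(10, 12)), "mass")
})

test_that("conditional FES reduces to the marginal and obeys independence", {
  set.seed(11)
  x <- cbind(rnorm(5000), rnorm(5000, 1, 0.5), rnorm(5000, -1, 0.7))
  full <- conditionalFes(x, 3, interval = c(-10, 10), bandwidths = c(0.2, 0.2),
                         gridBounds = c(-3, 3, -1, 3), gridSize = 50)
  marg <- kdeFes(x[, 1:2], bandwidths = c(0.2, 0.2),
                 gridBounds = c(-3, 3, -1, 3), gridSize = 50)
  expect_equal(fesValues(full), fesValues(marg))
  # product density: conditioning on any interval leaves the marginal shape
  cond <- conditionalFes(x, 3, interval = c(-1.5, -0.5),
                         bandwidths = c(0.2, 0.2),
                         gridBounds = c(-3, 3, -1, 3), gridSize = 50)
  m <- is.finite(fesValues(cond)) & is.finite(fesValues(marg)) &
       fesValues(marg) < 3
  expect_lt(mean(abs(fesValues(cond)[m] - fesValues(marg)[m])), 0.2)
  # 3-D Gaussian with known covariance: conditional equals the closed form
  sig3 <- 0.6
  y <- cbind(rnorm(8000), rnorm(8000), 0)
  y[, 3] <- 0.8 * y[, 1] + sig3 * rnorm(8000)
  condY <- conditionalFes(y, 3, interval = c(0.75, 0.85),
                          bandwidths = c(0.15, 0.15),
                          gridBounds = c(-2, 2, -2, 2), gridSize = 40)
  gx <- fesAxes(condY)[[1]]
  # P(x1 | x3 = 0.8) is normal with mean 0.8*0.8/(0.8^2+sig3^2), reduced var
  vpost <- sig3^2 / (0.8^2 + sig3^2)
  mpost <- 0.8 * 0.8 / (0.8^2 + sig3^2)
  fx <- apply(exp(-fesValues(condY)), 1, sum)
  fx <- -log(fx / max(fx))
  ftheory <- (gx - mpost)^2 / (2 * vpost)
  ftheory <- ftheory - min(ftheory)
  m2 <- ftheory < 2 & is.finite(fx)
  expect_lt(mean(abs(fx[m2] - ftheory[m2])), 0.25)
  expect_error(conditionalFes(y, 3, interval = c(50, 60)), "interval")
})

test_that("Procrustes recovers rotations, handles reflections, is orthogonal", {
  set.seed(13)
  ref <- matrix(rnorm(60), 30, 2)
  # identity case
  a0 <- procrustesAlign(ref, ref)
  expect_equal(a0$rotation, diag(2), tolerance = 1e-12)
  expect_lt(a0$residual, 1e-10)
  # known 37-degree rotation is inverted
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  aR <- procrustesAlign(ref %*% R, ref)
  expect_lt(aR$residual, 1e-10)
  expect_equal(aR$rotation %*% R, diag(2), tolerance = 1e-10)
  expect_equal(t(aR$rotation) %*% aR$rotation, diag(2), tolerance = 1e-12)
  # mirrored embedding: recovered only when reflections are allowed
  mir <- ref %*% diag(c(-1, 1))
  aNo <- procrustesAlign(mir, ref, allowReflection = FALSE)
  aYes <- procrustesAlign(mir, ref, allowReflection = TRUE)
  expect_gt(aNo$residual, 1)
  expect_lt(aYes$residual, 1e-10)
  expect_equal(det(aNo$rotation), 1, tolerance = 1e-12)
  expect_equal(det(aYes$rotation), -1, tolerance = 1e-12)
})

test_that("Procrustes agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  ref <- matrix(rnorm(80), 40, 2)
  emb <- ref %*% matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2) +
    matrix(rnorm(80, sd = 0.1), 40, 2)
  ours <- procrustesAlign(emb, ref)
  veg <- vegan::procrustes(ref, emb, scale = FALSE, symmetric = FALSE)
  expect_equal(abs(det(ours$rotation)), 1, tolerance = 1e-12)
  expect_equal(ours$rotation, veg$rotation, tolerance = 1e-8)
})

test_that("distance preservation histograms capture isometries", {
  set.seed(19)
  x <- matrix(rnorm(100), 50, 2)
  # isometric copy: all mass on the diagonal
  iso <- distancePreservation(x, x + 5, bins = 20)
  expect_equal(iso$diagonalMass, 1)
  expect_equal(sum(iso$density), 1)
  exact <- distancePreservation(x, x, bins = 25)
  expect_equal(exact$diagonalMass, 1)
  # constant latent point: all mass in the zero-latent-distance column
  cst <- distancePreservation(x, matrix(1, 50, 2), bins = 20)
  expect_equal(sum(cst$density[, 1]), 1)
  expect_error(distancePreservation(x[1, , drop = FALSE],
                                    x[1, , drop = FALSE]), "two")
})

test_that("variance filter drops exactly the low-variance columns", {
  set.seed(23)
  n <- 400
  # mirror of the 45-feature case: 24 near-constant, 21 informative columns
  lowSd <- sqrt(1e-5)
  hiSd <- sqrt(1e-2)
  x <- cbind(matrix(rnorm(n * 24, sd = lowSd), n, 24),
             matrix(rnorm(n * 21, sd = hiSd), n, 21))
  colnames(x) <- paste0("d", 1:45)
  kept <- varianceFilter(x, 2e-4)
  expect_equal(length(kept), 21L)
  expect_true(all(kept > 24))
  expect_equal(length(attr(kept, "dropped")), 24L)
  # constant column always dropped; threshold 0 drops nothing
  xc <- cbind(x, const = 1)
  expect_false(46L %in% varianceFilter(xc, 1e-12))
  expect_equal(length(varianceFilter(x, 0)), 45L)
  expect_error(varianceFilter(matrix(1, 5, 2), 1), "every column")
})

test_that("standardization is exact, reusable, and invertible", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  st <- standardizeFeatures(x)
  expect_equal(colMeans(st$x), c(a = 0, b = 0))
  expect_equal(apply(st$x, 2, function(v) mean(v^2)), c(a = 1, b = 1))
  # population sd convention: column (1,2,3) maps to (-1,0,1)*sqrt(3/2)
  expect_equal(st$x[, "a"], c(-1, 0, 1) * sqrt(3 / 2), ignore_attr = TRUE)
  # already standardized input: constants are 0/1
  st2 <- standardizeFeatures(st$x)
  expect_equal(unname(st2$center), c(0, 0))
  expect_equal(unname(st2$scale), c(1, 1))
  # round trip on new data
  new <- cbind(a = c(4, 5), b = c(-3, 8))
  fwd <- sweep(sweep(new, 2, st$center, `-`), 2, st$scale, `/`)
  back <- sweep(sweep(fwd, 2, st$scale, `*`), 2, st$center, `+`)
  expect_equal(back, new)
  expect_error(standardizeFeatures(cbind(c(1, 1, 1), c(1, 2, 3))), "variance")
})

test_that("fesMismatch reports oversmoothing", {
  set.seed(29)
  x <- matrix(c(rnorm(4000, -1, 0.2), rnorm(4000, 1, 0.2)), ncol = 1)
  mSmall <- fesMismatch(x, bandwidths = 0.05, gridBounds = c(-2, 2),
                        gridSize = 80)
  mHuge <- fesMismatch(x, bandwidths = 1, gridBounds = c(-2, 2),
                       gridSize = 80)
  expect_lt(mSmall, mHuge)
})
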