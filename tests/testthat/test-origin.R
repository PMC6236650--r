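test_that("site correlation: perfect gradient, zero variance, composition
           oracle", {
  # kernels on a meridian with diversity strictly decreasing in distance
  kd <- data.frame(lat = seq(36, 44, by = 2), lon = 100,
                   n_members = 5, multiplicity = 1,
                   h_mean = c(0.9, 0.7, 0.5, 0.3, 0.1))
  expect_equal(siteCorrelation(34, 100, kd), -1, tolerance = 1e-9)

  kdFlat <- transform(kd, h_mean = 0.5)
  expect_warning(r <- siteCorrelation(34, 100, kdFlat), "zero-variance")
  expect_true(is.na(r))
  expect_warning(siteCorrelation(34, 100, kd[1, ]), "fewer than two")

  # equals haversine + product-moment composed independently
  set.seed(4)
  kd30 <- data.frame(lat = runif(30, 30, 40), lon = runif(30, 95, 115),
                     n_members = 5, multiplicity = 1,
                     h_mean = runif(30))
  d <- mapply(function(la, lo) haversineKm(33, 102, la, lo),
              kd30$lat, kd30$lon)
  expect_equal(siteCorrelation(33, 102, kd30),
               directPearson(d, kd30$h_mean), tolerance = 1e-12)
})

test_that("correlation surface recovers a simulated origin and fails
           cleanly on degenerate input", {
  sim <- simulateExpansion(expansionConfig(seed = 42))
  grid <- buildGrid(c(30, 40), c(95, 115), 1)
  surf <- correlationSurface(sim$table, grid)
  b <- bestOrigin(surf)
  dKm <- min(haversineKm(b$lat, b$lon, sim$truth@origin[1],
                         sim$truth@origin[2]))
  expect_lt(dKm, 500)
  r <- surfaceValues(surf)
  expect_true(all(r >= -1 & r <= 1, na.rm = TRUE))

  # single accepted kernel: error path
  tab1 <- SampleTable(
    data.frame(sample_id = paste0("s", 1:5), latitude = rep(35, 5),
               longitude = rep(100, 5)),
    matrix("10", 5, 1, dimnames = list(NULL, "locus_01")))
  expect_error(
    correlationSurface(tab1, buildGrid(c(35, 35), c(100, 100), 1)),
    "at least two")
})

test_that("spatially shuffled genotypes lose the origin signal", {
  sim <- simulateExpansion(expansionConfig(seed = 5))
  grid <- buildGrid(c(30, 40), c(95, 115), 1)
  kdTrue <- kernelDiversity(acceptKernels(sim$table, grid), sim$table)
  rTrue <- siteCorrelation(sim$truth@origin[1], sim$truth@origin[2],
                           kdTrue)
  argmins <- matrix(NA_real_, 3, 2)
  for (s in 1:3) {
    shuf <- nullShuffle(sim$table, seed = s)
    surfS <- correlationSurface(shuf, grid)
    kdS <- kernelDiversity(surfS@kernels, shuf)
    rS <- siteCorrelation(sim$truth@origin[1], sim$truth@origin[2], kdS)
    expect_lt(abs(rS), abs(rTrue))
    b <- bestOrigin(surfS)
    argmins[s, ] <- c(b$lat[1], b$lon[1])
  }
  # argmin is unstable across shuffle seeds
  expect_gt(nrow(unique(argmins)), 1)
})

test_that("site comparison: coincident sites give delta r = 0 and p = 1", {
  tab <- makeTable(30, 4, seed = 6)
  grid <- buildGrid(c(30, 40), c(95, 115), 2)
  cmp <- compareOrigins(tab, c(35, 100), c(35, 100), grid, nPerm = 49,
                        seed = 2)
  expect_equal(observedDeltaR(cmp), 0)
  expect_equal(pValue(cmp), 1)
})

test_that("swapping the sites negates delta r and preserves p", {
  tab <- makeTable(40, 6, seed = 12, missing = 0.05)
  grid <- buildGrid(c(30, 40), c(95, 115), 2)
  ab <- compareOrigins(tab, c(32, 98), c(38, 112), grid, nPerm = 99,
                       seed = 7)
  ba <- compareOrigins(tab, c(38, 112), c(32, 98), grid, nPerm = 99,
                       seed = 7)
  expect_equal(observedDeltaR(ab), -observedDeltaR(ba), tolerance = 1e-12)
  expect_equal(nullDeltaR(ab), -nullDeltaR(ba), tolerance = 1e-12)
  expect_equal(pValue(ab), pValue(ba))
})

test_that("a strong simulated gradient separates the true origin from a
           distant site", {
  cfg <- expansionConfig(origin = c(35, 70), latRange = c(25, 45),
                         lonRange = c(60, 140), demeStep = 2,
                         nSamples = 400, seed = 31)
  sim <- simulateExpansion(cfg)
  grid <- buildGrid(c(25, 45), c(60, 140), 2)
  cmp <- compareOrigins(sim$table, sim$truth@origin, c(35, 135), grid,
                        nPerm = 999, seed = 31)
  expect_lt(observedDeltaR(cmp), 0)
  expect_lte(pValue(cmp), 0.01)
})

test_that("kernel memberships are fixed across permutations", {
  # recomputing kernels from the shuffled table changes nothing, because
  # coordinates are never permuted
  tab <- makeTable(25, 3, seed = 14)
  grid <- buildGrid(c(30, 40), c(95, 115), 2)
  k1 <- acceptKernels(tab, grid)
  k2 <- acceptKernels(nullShuffle(tab, seed = 3), grid)
  expect_equal(kernelCenters(k1), kernelCenters(k2))
  expect_equal(kernelMembers(k1), kernelMembers(k2))
})

test_that("bilinear interpolation is display-only and node-exact", {
  tab <- makeTable(30, 4, seed = 20)
  grid <- buildGrid(c(30, 40), c(95, 115), 2.5)
  surf <- correlationSurface(tab, grid)
  expect_identical(interpolateSurface(surf, 1), surf)
  expect_error(interpolateSurface(surf, 0.5), "factor")

  up <- interpolateSurface(surf, 4)
  lats <- gridLats(surf@grid); lons <- gridLons(surf@grid)
  upLats <- gridLats(up@grid); upLons <- gridLons(up@grid)
  # exact agreement at the original nodes
  ri <- match(round(lats, 9), round(upLats, 9))
  ci <- match(round(lons, 9), round(upLons, 9))
  expect_equal(surfaceValues(up)[ri, ci], surfaceValues(surf),
               tolerance = 1e-9, ignore_attr = TRUE)
  # midpoint of four nodes equals their arithmetic mean
  up2 <- interpolateSurface(surf, 2)
  mid <- surfaceValues(up2)[2, 2]
  expect_equal(mid, mean(surfaceValues(surf)[1:2, 1:2]),
               tolerance = 1e-9)
})
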