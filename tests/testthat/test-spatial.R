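test_that("haversine distance: identity, antipode, closed-form oracles", {
  expect_equal(haversineKm(35, 105, 35, 105), 0)
  # half the great circle
  expect_equal(haversineKm(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-9)
  # independent spherical-law-of-cosines computation
  expect_lt(abs(haversineKm(35, 105, 42, 120) - slocKm(35, 105, 42, 120)),
            0.1)
  # third-party spherical implementation agrees
  expect_equal(
    haversineKm(35, 105, 42, 120),
    geosphere::distHaversine(c(105, 35), c(120, 42), r = 6371008.8) / 1000,
    tolerance = 1e-9)
  # symmetry and non-negativity on random pairs
  set.seed(1)
  a <- cbind(runif(20, -90, 90), runif(20, -180, 180))
  b <- cbind(runif(20, -90, 90), runif(20, -180, 180))
  d1 <- haversineKm(a[, 1], a[, 2], b[, 1], b[, 2])
  d2 <- haversineKm(b[, 1], b[, 2], a[, 1], a[, 2])
  expect_equal(d1, d2)
  expect_true(all(d1 >= 0))
})

test_that("grid construction counts nodes correctly", {
  expect_equal(nrow(gridNodes(buildGrid(c(0, 1), c(0, 1), 0.5))), 9)
  # continental bounds at 1 degree: 59 latitudes x 161 longitudes
  g <- buildGrid(c(9, 67), c(-7, 153), 1)
  expect_equal(length(gridLats(g)), 59)
  expect_equal(length(gridLons(g)), 161)
  expect_equal(nrow(gridNodes(g)), 161 * 59)
  # degenerate bounds give a single node
  expect_equal(nrow(gridNodes(buildGrid(c(35, 35), c(100, 100), 0.1))), 1)
  # node registration: lattice starts at the lower bound, never exceeds
  g2 <- buildGrid(c(30, 30.95), c(100, 100.95), 0.3)
  expect_equal(gridLats(g2), c(30, 30.3, 30.6, 30.9))
  expect_error(buildGrid(c(0, 1), c(0, 1), 0), "resolution")
  expect_error(buildGrid(c(0, 1), c(0, 1), -0.5), "resolution")
})

test_that("kernel acceptance: threshold, emptiness, boundary inclusion", {
  # five co-located samples at a grid node: accepted with n_members = 5
  tab <- SampleTable(
    data.frame(sample_id = paste0("s", 1:5), latitude = rep(35, 5),
               longitude = rep(100, 5)),
    matrix("10", 5, 1, dimnames = list(NULL, "locus_01")))
  grid <- buildGrid(c(34, 36), c(99, 101), 1)
  ks <- acceptKernels(tab, grid)
  expect_true(any(kernelCenters(ks)$lat == 35 &
                    kernelCenters(ks)$lon == 100))
  expect_true(all(kernelCenters(ks)$n_members == 5))

  # four samples everywhere: below the five-sample rule, empty set
  tab4 <- SampleTable(sampleData(tab)[1:4, ], genotypes(tab)[1:4, ,
                                                             drop = FALSE])
  expect_warning(ks4 <- acceptKernels(tab4, grid), "no grid node")
  expect_equal(nKernels(ks4), 0)

  # boundary-inclusive membership: a sample exactly at the radius counts
  lonAt <- 100 + 500 / (6371.0088 * cos(35 * pi / 180) * pi / 180)
  tabB <- SampleTable(
    data.frame(sample_id = paste0("s", 1:5), latitude = rep(35, 5),
               longitude = c(rep(100, 4), lonAt)),
    matrix("10", 5, 1, dimnames = list(NULL, "locus_01")))
  gridB <- buildGrid(c(35, 35), c(100, 100), 1)
  dEdge <- haversineKm(35, 100, 35, lonAt)
  ksB <- acceptKernels(tabB, gridB, radiusKm = dEdge, minSamples = 5)
  expect_equal(nKernels(ksB), 1)

  # empty geolocated table warns and returns an empty set
  sNA <- sampleData(tab); sNA$latitude <- NA
  expect_warning(
    ksNA <- acceptKernels(SampleTable(sNA, genotypes(tab)), grid),
    "no geolocated")
  expect_equal(nKernels(ksNA), 0)
})

test_that("kernel acceptance equals a brute-force distance scan", {
  tab <- makeTable(50, 2, seed = 11)
  grid <- buildGrid(c(30, 40), c(95, 115), 2.5)
  ks <- acceptKernels(tab, grid, dedupe = FALSE)
  ref <- bruteKernels(tab, grid)
  expect_equal(nKernels(ks), length(ref))
  got <- lapply(seq_len(nKernels(ks)), function(i)
    list(lat = kernelCenters(ks)$lat[i], lon = kernelCenters(ks)$lon[i],
         members = sort(kernelMembers(ks)[[i]])))
  ord <- order(vapply(got, `[[`, numeric(1), "lat"),
               vapply(got, `[[`, numeric(1), "lon"))
  ordRef <- order(vapply(ref, `[[`, numeric(1), "lat"),
                  vapply(ref, `[[`, numeric(1), "lon"))
  expect_equal(got[ord], ref[ordRef])
})

test_that("kernel acceptance is sample-order invariant and radius-monotone", {
  tab <- makeTable(40, 2, seed = 3)
  grid <- buildGrid(c(30, 40), c(95, 115), 2.5)
  set.seed(7)
  perm <- sample.int(40)
  tabP <- SampleTable(sampleData(tab)[perm, ],
                      genotypes(tab)[perm, , drop = FALSE])
  ks <- acceptKernels(tab, grid)
  ksP <- acceptKernels(tabP, grid)
  expect_equal(kernelCenters(ks)[c("lat", "lon", "n_members")],
               kernelCenters(ksP)[c("lat", "lon", "n_members")])
  expect_equal(lapply(kernelMembers(ks), sort),
               lapply(kernelMembers(ksP), sort))

  counts <- vapply(c(200, 400, 600, 800), function(r) {
    k <- suppressWarnings(acceptKernels(tab, grid, radiusKm = r,
                                        dedupe = FALSE))
    nKernels(k)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("deduplicated kernels leave downstream correlations unchanged", {
  tab <- makeTable(30, 4, seed = 5, missing = 0.1)
  grid <- buildGrid(c(30, 40), c(95, 115), 1)
  sDed <- correlationSurface(tab, grid, dedupe = TRUE)
  sAll <- correlationSurface(tab, grid, dedupe = FALSE)
  expect_equal(surfaceValues(sDed), surfaceValues(sAll), tolerance = 1e-12)
  # every node is retained either way; only the stored member sets shrink
  expect_equal(nKernels(sDed@kernels), nKernels(sAll@kernels))
  expect_lt(length(sDed@kernels@members), length(sAll@kernels@members))
  expect_equal(kernelMembers(sDed@kernels), kernelMembers(sAll@kernels))
})
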