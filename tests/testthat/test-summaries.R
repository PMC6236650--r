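test_that("genotype matrix encoding: indicators, imputation, row sums", {
  g <- matrix(c("A", "B", "X", "X"), nrow = 2,
              dimnames = list(NULL, c("locus_01", "locus_02")))
  tab <- SampleTable(data.frame(sample_id = c("a", "b"),
                                latitude = c(35, 36),
                                longitude = c(100, 101)), g)
  M <- genotypeMatrix(tab, dropZeroVar = FALSE)
  expect_equal(unname(M[, "locus_01.A"]), c(1, 0))
  expect_equal(unname(M[, "locus_01.B"]), c(0, 1))
  expect_equal(unname(M[, "locus_02.X"]), c(1, 1))

  # sample missing a locus receives the column means for that locus
  g2 <- matrix(c("A", "B", NA, "X", "X", "Y"), nrow = 3,
               dimnames = list(NULL, c("locus_01", "locus_02")))
  tab2 <- SampleTable(data.frame(sample_id = c("a", "b", "c"),
                                 latitude = 35:37,
                                 longitude = 100:102), g2)
  M2 <- genotypeMatrix(tab2, dropZeroVar = FALSE)
  expect_equal(unname(M2[3, c("locus_01.A", "locus_01.B")]), c(0.5, 0.5))

  # complete rows sum to 1 per locus
  tab3 <- makeTable(15, 6, seed = 13)
  M3 <- genotypeMatrix(tab3, dropZeroVar = FALSE)
  al <- attr(M3, "alleles")
  for (l in unique(al$locus))
    expect_equal(unname(rowSums(M3[, al$locus == l, drop = FALSE])),
                 rep(1, 15))

  gMono <- matrix("A", 3, 1, dimnames = list(NULL, "locus_01"))
  tabM <- SampleTable(sampleData(tab2), gMono)
  expect_warning(genotypeMatrix(tabM), "constant|monomorphic")
})

test_that("PCA variance fractions match a dense eigendecomposition", {
  # one informative direction duplicated: PC1 carries all the variance
  M <- cbind(c(0, 1, 0, 1), c(0, 1, 0, 1))
  p <- pcaGenotypes(M, nComponents = 1)
  expect_equal(unname(p$varianceFraction), 1)

  tab <- makeTable(25, 8, seed = 16, missing = 0.05)
  M2 <- genotypeMatrix(tab)
  p2 <- pcaGenotypes(M2, nComponents = 5)
  ev <- eigen(stats::cov(scale(M2, center = TRUE, scale = FALSE)),
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(p2$varianceFraction), (ev / sum(ev))[1:5],
               tolerance = 1e-8)
  expect_true(all(diff(p2$varianceFraction) <= 1e-12))
  expect_lte(sum(p2$varianceFraction), 1 + 1e-12)

  # permutation invariance of row order
  set.seed(1)
  p3 <- pcaGenotypes(M2[sample.int(nrow(M2)), ], nComponents = 5)
  expect_equal(p3$varianceFraction, p2$varianceFraction,
               tolerance = 1e-10)

  expect_warning(pcaGenotypes(M, nComponents = 4), "rank")
})

test_that("delta-K: flat second difference, constructed elbow, degenerate
           replicates", {
  # lnP linear in K: interior delta-K is near zero relative to the elbow
  set.seed(5)
  lin <- expand.grid(run = 1:10, K = 1:8)
  lin$lnP <- -5000 + 100 * lin$K + rnorm(nrow(lin), sd = 10)
  dkLin <- deltaK(lin)
  expect_true(all(is.na(dkLin$deltaK[c(1, nrow(dkLin))])))
  expect_lt(max(dkLin$deltaK, na.rm = TRUE), 3)

  # sharp elbow at K = 3
  runs <- simulateClusterLogs(kRange = 1:10, nRuns = 10, elbowAt = 3,
                              seed = 8)
  dk <- deltaK(runs)
  expect_equal(dk$K[which.max(dk$deltaK)], 3)

  # identical replicates: sd = 0 path flagged undefined, not infinite
  ident <- expand.grid(run = 1:3, K = 1:4)
  ident$lnP <- c(-100, -50, -40, -35)[ident$K]
  dkI <- deltaK(ident)
  expect_true(all(is.na(dkI$deltaK)))

  expect_error(deltaK(lin[lin$K <= 2, ]), "consecutive")
  expect_error(deltaK(lin[lin$run == 1, ]), "replicates")
})

test_that("delta-K is shift-invariant and scales linearly", {
  runs <- simulateClusterLogs(kRange = 1:8, nRuns = 6, elbowAt = 4,
                              seed = 11)
  base <- deltaK(runs)$deltaK
  shifted <- runs; shifted$lnP <- shifted$lnP + 12345
  expect_equal(deltaK(shifted)$deltaK, base, tolerance = 1e-9)
  scaled <- runs; scaled$lnP <- scaled$lnP * 3.7
  expect_equal(deltaK(scaled)$deltaK, base, tolerance = 1e-9)
})

test_that("cluster-run logs round-trip through the delimited schema", {
  runs <- simulateClusterLogs(kRange = 1:6, nRuns = 4, elbowAt = 3,
                              seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- readClusterRuns(path)
  expect_equal(back, runs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GBSSI summary: dominance rule, waxy classes, counting oracle", {
  s <- data.frame(
    sample_id = paste0("s", 1:6),
    latitude = rep(35, 6), longitude = rep(100, 6),
    gbssi_s = c("S0/S0", "S0/S-15", "S-15/S-15", "S-15/S-15",
                "S-15/S-15", NA),
    gbssi_l = c("LC/LC", "LY/Lf", "LC/LY", "LY/LY", NA, "Lf/Lf"),
    region = c("w", "w", "w", "e", "e", "e"))
  tab <- SampleTable(s, matrix("10", 6, 1,
                               dimnames = list(NULL, "locus_01")))
  sm <- gbssiSummary(tab)
  ph <- sm$phenotypes$phenotype
  expect_equal(ph[1], "wild_type")
  expect_equal(ph[2], "wild_type")   # S0 is dominant over S-15
  expect_equal(ph[3], "waxy")        # LC still present at the L locus
  expect_equal(ph[4], "fully_waxy")  # no wild-type LC allele left
  expect_equal(ph[5], "waxy")        # L genotype unknown
  expect_true(is.na(ph[6]))

  # frequencies equal hand-tallied counts, missing excluded
  fs <- sm$alleleFreqS
  expect_equal(fs$count[fs$allele == "S0"], 3)     # 2 + 1 copies
  expect_equal(fs$count[fs$allele == "S-15"], 7)
  expect_equal(sum(fs$freq), 1)
  fl <- sm$alleleFreqL
  expect_equal(fl$count[fl$allele == "LC"], 3)
  expect_equal(sum(fl$freq), 1)

  # per-group tallies and reorder invariance
  smG <- gbssiSummary(tab, grouping = "region")
  fsW <- smG$alleleFreqS[smG$alleleFreqS$group == "w", ]
  expect_equal(sum(fsW$count), 6)
  set.seed(3)
  perm <- sample.int(6)
  tabP <- SampleTable(s[perm, ], genotypes(tab)[perm, , drop = FALSE])
  smP <- gbssiSummary(tabP)
  expect_equal(smP$alleleFreqS[order(smP$alleleFreqS$allele), ],
               sm$alleleFreqS[order(sm$alleleFreqS$allele), ],
               ignore_attr = TRUE)

  # the L-locus refinement is switchable
  smNoL <- gbssiSummary(tab, useL = FALSE)
  expect_equal(smNoL$phenotypes$phenotype[4], "waxy")
})

test_that("map builders return renderable plots and skip unplaced
           samples", {
  tab <- makeTable(12, 3, seed = 23)
  s <- sampleData(tab)
  s$gbssi_s <- rep_len(c("S0/S0", "S-15/S-15"), 12)
  s$latitude[3] <- NA
  tab <- SampleTable(s, genotypes(tab))
  grid <- buildGrid(c(30, 40), c(95, 115), 2.5)
  surf <- correlationSurface(tab, grid)
  expect_message(
    p <- plotOriginSurface(surf, samples = tab,
                           sites = data.frame(lat = 35, lon = 100,
                                              label = "A")),
    "skipped")
  expect_s3_class(p, "ggplot")
  expect_message(p2 <- plotGBSSIMap(tab, "S"), "skipped")
  expect_s3_class(p2, "ggplot")
  q <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.8, 0.1), 2, byrow = TRUE)
  p3 <- plotAncestryPies(data.frame(lat = c(35, 36), lon = c(100, 101)), q)
  expect_s3_class(p3, "ggplot")
})
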