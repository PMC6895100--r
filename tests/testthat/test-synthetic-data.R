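# Seeded synthetic-data generators: reproducibility, planted structure,
# sampling-model calibration.

test_that("generators are byte-reproducible under a fixed seed", {
  a <- genProfileDataset(nDecoys = 50, seed = 5)
  b <- genProfileDataset(nDecoys = 50, seed = 5)
  expect_identical(presenceMatrix(a$dataset), presenceMatrix(b$dataset))
  expect_identical(geneAnnotations(a$dataset), geneAnnotations(b$dataset))
  c_ <- genProfileDataset(nDecoys = 50, seed = 6)
  expect_false(identical(presenceMatrix(a$dataset), presenceMatrix(c_$dataset)))

  t1 <- genTRNASet(n = 4, seed = 3)
  t2 <- genTRNASet(n = 4, seed = 3)
  expect_identical(lapply(t1$seqs, serializeModifiedSequence),
                   lapply(t2$seqs, serializeModifiedSequence))

  p1 <- genPileups(t1, seed = 4)
  p2 <- genPileups(t2, seed = 4)
  expect_identical(p1, p2)
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(genProfileDataset(nDecoys = 10, seed = 99))
  invisible(genTRNASet(n = 2, seed = 98))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("planted profile group passes the strict screen by construction", {
  for (seed in c(1, 17, 123)) {
    g <- genProfileDataset(nDecoys = 100, seed = seed)
    expect_true(g$truth$plantedGroup %in% candidates(screenCandidates(g$dataset)))
  }
  # zero decoys: the planted group is the only one
  g0 <- genProfileDataset(nDecoys = 0, seed = 1)
  expect_identical(rownames(presenceMatrix(g0$dataset)), "OG_planted")
})

test_that("decoy passer counts match the combinatorial expectation", {
  # a random non-empty profile over 8 labeled taxa matches the phenotype
  # with probability (1/2)^8 / (1 - (1/2)^8)
  g <- genProfileDataset(nDecoys = 1000, seed = 42)
  res <- screenCandidates(g$dataset)
  nDecoyPass <- length(setdiff(candidates(res), "OG_planted"))
  p <- (1 / 2)^8 / (1 - (1 / 2)^8)
  bounds <- qbinom(c(0.005, 0.995), 1000, p)
  expect_gte(nDecoyPass, bounds[1])
  expect_lte(nDecoyPass, bounds[2])
})

test_that("modification planting follows the requested probabilities", {
  # probability 1 -> every sequence modified; probability 0 -> none
  all1 <- genTRNASet(n = 10, plant = data.frame(label = "47", code = "acp3U",
                                                prob = 1), seed = 1)
  expect_true(all(vapply(all1$seqs, function(s) {
    identical(residueAt(s, "47")$mod, "acp3U")
  }, logical(1))))
  none <- genTRNASet(n = 10, plant = data.frame(label = "47", code = "acp3U",
                                                prob = 0), seed = 1)
  expect_true(all(vapply(none$seqs, function(s) {
    is.na(residueAt(s, "47")$mod)
  }, logical(1))))
  # mixture 0.5, n = 200: planted count within the binomial 99% interval
  mix <- genTRNASet(n = 200, plant = data.frame(label = "47", code = "acp3U",
                                                prob = 0.5), seed = 77)
  k <- sum(mix$truth$planted)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("synthetic tRNAs are structurally valid", {
  ts <- genTRNASet(n = 5, plant = data.frame(label = "20a", code = "acp3D",
                                             prob = 1), seed = 13)
  for (s in ts$seqs) {
    expect_true(validObject(s, test = TRUE))
    expect_true(hasSprinzlPosition(s, "20a"))
    expect_identical(residueAt(s, "20a")$mod, "acp3D")
  }
})

test_that("peak lists honor jitter and decoy settings", {
  theo <- data.frame(mz = c(650.1, 800.2, 1200.3))
  clean <- genPeakList(theo, jitterPpm = 0, decoyFraction = 0, seed = 1)
  expect_equal(clean$mz, sort(theo$mz), tolerance = 1e-12)
  expect_true(all(clean$is_true))
  jit <- genPeakList(theo, jitterPpm = 5, decoyFraction = 1, seed = 2)
  expect_identical(nrow(jit), 6L)
  expect_identical(sum(jit$is_true), 3L)
  # decoy-only list yields no assignments at tight tolerance (away from theory)
  decoys <- jit[!jit$is_true, c("mz", "intensity")]
  far <- vapply(decoys$mz, function(m) all(abs(m - theo$mz) / theo$mz * 1e6 > 5),
                logical(1))
  res <- matchPeaks(theo, decoys[far, , drop = FALSE], tolPpm = 5)
  expect_true(all(!res$assigned))
})

test_that("pileup generator matches its sampling model", {
  ts <- genTRNASet(n = 3, plant = data.frame(label = "47", code = "acp3U",
                                             prob = 1), seed = 5)
  # p_mod = 0, p_err = 0 -> all columns have rate 0
  p0 <- genPileups(ts, pMod = 0, pErr = 0, coverage = 100, seed = 6)
  expect_true(all(misincorporationRate(p0) == 0))
  # p_mod = 0.3, coverage 500: observed rates at modified sites within the
  # binomial 99% interval
  p1 <- genPileups(ts, pMod = 0.3, pErr = 0, coverage = 500, seed = 7)
  at47 <- p1[p1$sprinzl_label == "47", ]
  rates <- misincorporationRate(at47)
  cov <- rowSums(at47[, c("nA", "nC", "nG", "nU", "nDel")])
  for (i in seq_along(rates)) {
    bounds <- qbinom(c(0.005, 0.995), cov[i], 0.3) / cov[i]
    expect_gte(rates[i], bounds[1])
    expect_lte(rates[i], bounds[2])
  }
})

test_that("melting-curve generator recovers its own truth", {
  pair <- genMeltingCurves(noiseSd = 0, seed = 1)
  expect_equal(estimateTmInflection(pair$modified), pair$truth$tmModified,
               tolerance = 0.1)
  expect_equal(estimateTmInflection(pair$unmodified), pair$truth$tmUnmodified,
               tolerance = 0.1)
  expect_identical(round(deltaTm(pair$modified, pair$unmodified)), 3)
  # seeded reproducibility with noise
  n1 <- genMeltingCurves(noiseSd = 0.002, seed = 9)
  n2 <- genMeltingCurves(noiseSd = 0.002, seed = 9)
  expect_identical(curveAbsorbance(n1$modified), curveAbsorbance(n2$modified))
})
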