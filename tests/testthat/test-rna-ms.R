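# Mass tables, digestion, CID series, peak matching, quantification rules.

test_that("shipped mass constants match the elemental oracle", {
  mt <- massTables()
  expect_equal(unname(mt$nmp["A"]), oracleCountsMass(ORACLE_NMP$A), tolerance = 1e-7)
  expect_equal(unname(mt$nmp["C"]), oracleCountsMass(ORACLE_NMP$C), tolerance = 1e-7)
  expect_equal(unname(mt$nmp["G"]), oracleCountsMass(ORACLE_NMP$G), tolerance = 1e-7)
  expect_equal(unname(mt$nmp["U"]), oracleCountsMass(ORACLE_NMP$U), tolerance = 1e-7)
  expect_equal(mt$water, oracleCountsMass(ORACLE_WATER), tolerance = 1e-7)
  expect_equal(mt$hpo3, oracleCountsMass(ORACLE_HPO3), tolerance = 1e-7)
  for (b in c("A", "C", "G", "U")) {
    expect_equal(unname(mt$base[b]), oracleCountsMass(ORACLE_BASE[[b]]),
                 tolerance = 1e-7, info = b)
  }
  # frozen reference values (Da)
  expect_equal(unname(mt$nmp), c(347.06308, 323.05185, 363.05799, 324.03587),
               tolerance = 1e-5)
  expect_equal(mt$water, 18.010565, tolerance = 1e-6)
  expect_equal(mt$proton, 1.007276, tolerance = 1e-6)
  expect_equal(mt$hpo3, 79.96633, tolerance = 1e-5)
  expect_equal(unname(mt$base), c(135.0545, 111.0433, 151.0494, 112.0273),
               tolerance = 1e-4)
})

test_that("neutral masses: UMP, the acp3U hexamer, delta additivity", {
  expect_equal(neutralMass("U"), 324.0359, tolerance = 1e-4)
  # the V-loop RNase T1 hexamer {A2 C2 G1 acp3U1}, 5'-OH / 3'-phosphate
  expect_equal(neutralMass("AC[acp3U]CAG"), 2038.3186, tolerance = 1e-4)
  expect_equal(neutralMass("AC[acp3U]CAG") - neutralMass("ACUCAG"),
               101.0477, tolerance = 1e-4)
  # termini adjustments against the oracle
  set.seed(7)
  for (i in 1:20) {
    s <- randomModifiedSeq(sample(2:15, 1))
    for (tp in c("phosphate", "cyclicPhosphate", "OH")) {
      for (fp in c("OH", "phosphate")) {
        expect_equal(neutralMass(s, fp, tp),
                     oracleOligoMass(residueBases(s), residueMods(s), fp, tp),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("charge-state m/z arithmetic", {
  M <- neutralMass("AC[acp3U]CAG")
  expect_equal(round(mzForMass(M, 3), 2), 678.43)
  expect_equal(round(mzForMass(neutralMass("ACUCAG"), 3), 2), 644.75)
  expect_equal(mzForMass(1000, 1), 1000 - 1.00727646, tolerance = 1e-6)
  expect_equal(mzForMass(1000, 2, "positive"), (1000 + 2 * 1.00727646) / 2,
               tolerance = 1e-6)
  expect_error(mzForMass(1000, 0), "charge")
})

test_that("RNase T1 digestion enumerates fragments correctly", {
  # no G: single fragment with 5'-OH / 3'-OH
  fr <- digestRNA(parseModifiedSequence("AUCA"))
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$seq, "AUCA")
  expect_identical(fr$three_prime, "OH")
  # hand-enumerated cleavage
  fr <- digestRNA(parseModifiedSequence("AUGCAUG"))
  expect_identical(fr$seq, c("AUG", "CAUG"))
  expect_identical(fr$three_prime, c("phosphate", "OH"))
  # RNase A cleaves after pyrimidines
  fra <- digestRNA(parseModifiedSequence("GACUGG"), enzyme = "RNaseA")
  expect_identical(fra$seq, c("GAC", "U", "GG"))
  # missed cleavages add merged fragments
  frm <- digestRNA(parseModifiedSequence("AGCGAA"), missedCleavages = 1L)
  expect_true(all(c("AG", "AGCG", "CG", "CGAA", "AA") %in% frm$seq))
})

test_that("cleavage-blocking modifications suppress T1 cuts", {
  s <- parseModifiedSequence("AU[Gm]CAG")   # Gm blocks T1
  fr <- digestRNA(s)
  expect_identical(fr$seq, "AU[Gm]CAG")
  s2 <- parseModifiedSequence("AU[m7G]CAG") # m7G does not (default)
  fr2 <- digestRNA(s2)
  expect_identical(fr2$seq, c("AU[m7G]", "CAG"))
})

test_that("digest fragments tile the parent and reconstruct its mass", {
  set.seed(11)
  for (i in 1:25) {
    s <- randomModifiedSeq(sample(10:40, 1))
    fr <- digestRNA(s)
    # spans tile [0, n)
    expect_identical(fr$start, c(0L, fr$end[-nrow(fr)]))
    expect_identical(fr$end[nrow(fr)], length(s))
    # concatenated fragment text reproduces the parent
    expect_identical(paste(fr$seq, collapse = ""), serializeModifiedSequence(s))
    # sum of fragment masses minus water per cut reconstructs the parent
    cuts <- nrow(fr) - 1L
    parent <- neutralMass(s, "OH", "OH")
    expect_equal(sum(fr$mass) - cuts * massTables()$water, parent,
                 tolerance = 1e-6)
  }
})

test_that("planted acp3U47 ends up in exactly one T1 fragment", {
  ts <- genTRNASet(n = 5, seed = 3)   # default: acp3U at 47, prob 1
  for (s in ts$seqs) {
    i47 <- match("47", sprinzlMap(s)) - 1L   # 0-based
    fr <- digestRNA(s)
    hits <- fr$start <= i47 & fr$end > i47
    expect_identical(sum(hits), 1L)
    expect_true(grepl("acp3U", fr$seq[hits], fixed = TRUE))
  }
})

test_that("CID series: closed forms, complementarity, acp delta", {
  mt <- massTables()
  ions <- cidSeries("UG", charges = 1)
  c1 <- ions$neutral_mass[ions$series == "c" & ions$index == 1]
  expect_equal(c1, 324.0359, tolerance = 1e-4)
  M <- neutralMass("UG")
  y1 <- ions$neutral_mass[ions$series == "y" & ions$index == 1]
  expect_equal(y1, M + mt$water - c1, tolerance = 1e-6)
  w1 <- ions$neutral_mass[ions$series == "w" & ions$index == 1]
  expect_equal(w1, y1 + mt$hpo3, tolerance = 1e-6)

  expect_error(cidSeries("UG", series = "q"), "unsupported")
  expect_error(cidSeries("U"), "at least 2")

  set.seed(23)
  for (i in 1:25) {
    s <- randomModifiedSeq(sample(3:12, 1))
    M <- neutralMass(s)
    ions <- cidSeries(s, charges = 1)
    n <- length(s)
    for (k in seq_len(n - 1)) {
      ck <- ions$neutral_mass[ions$series == "c" & ions$index == k]
      ynk <- ions$neutral_mass[ions$series == "y" & ions$index == n - k]
      ak <- ions$neutral_mass[ions$series == "a" & ions$index == k]
      wnk <- ions$neutral_mass[ions$series == "w" & ions$index == n - k]
      expect_equal(ck + ynk, M + massTables()$water, tolerance = 1e-4)
      expect_equal(ak + wnk, M + massTables()$water, tolerance = 1e-4)
    }
  }

  # every series ion containing the acp3U residue is +101.0477 vs unmodified
  mod <- cidSeries("AC[acp3U]CAG", charges = 1)
  unmod <- cidSeries("ACUCAG", charges = 1)
  delta <- modMassDelta(defaultRegistry(), "acp3U")
  for (s_ in c("c", "a", "y", "w")) {
    for (k in 1:5) {
      m1 <- mod$neutral_mass[mod$series == s_ & mod$index == k]
      m0 <- unmod$neutral_mass[unmod$series == s_ & unmod$index == k]
      contains <- if (s_ %in% c("c", "a")) k >= 3 else k >= 4  # residue 3 of 6
      expect_equal(m1 - m0, if (contains) delta else 0, tolerance = 1e-4,
                   info = paste(s_, k))
    }
  }
})

test_that("peak matching is tolerance-bounded and deterministic", {
  theo <- data.frame(ion = c("c1", "c2"), mz = c(500, 800))
  obs <- data.frame(mz = c(500, 800 * (1 + 21e-6)), intensity = c(1, 1))
  res <- matchPeaks(theo, obs, tolPpm = 20)
  expect_true(res$assigned[1])
  expect_equal(res$ppm_error[1], 0)
  expect_false(res$assigned[2])   # 21 ppm away at 20 ppm tolerance
  expect_error(matchPeaks(theo[0, ], obs), "empty")
  # exact tie in ppm error: the lower theoretical entry wins
  theo2 <- data.frame(mz = c(1000, 1000))
  obs2 <- data.frame(mz = 1000.05, intensity = 1)
  res2 <- matchPeaks(theo2, obs2, tolPpm = 200)
  expect_identical(res2$theory_index, 1L)
})

test_that("matcher recovers jittered true ions and rejects decoys", {
  s <- parseModifiedSequence("AC[acp3U]CAGGAUCCG")
  theo <- cidSeries(s, charges = 1:3)
  theo <- theo[theo$mz >= 600 & theo$mz <= 2000, , drop = FALSE]
  peaks <- genPeakList(theo, jitterPpm = 5, decoyFraction = 0.2, seed = 99)
  res <- matchPeaks(theo, peaks, tolPpm = 15)   # 3 sigma
  trueRecovered <- mean(res$assigned[peaks$is_true])
  expect_gte(trueRecovered, 0.95)
  # a decoy within 15 ppm of theory is indistinguishable by construction;
  # decoys far from every theoretical ion must stay unassigned
  decoyIdx <- which(!peaks$is_true)
  nearTheory <- vapply(peaks$mz[decoyIdx], function(m) {
    any(abs(m - theo$mz) / theo$mz * 1e6 <= 15)
  }, logical(1))
  expect_true(all(!res$assigned[decoyIdx[!nearTheory]]))
  expect_equal(sum(nearTheory), 0)   # with this seed no decoy lands on theory
})

test_that("stoichiometry normalization rules", {
  expect_equal(fragmentModFraction(0, 5), 0)
  expect_equal(fragmentModFraction(2, 2), 0.5)
  expect_equal(fragmentModFraction(3, 1), 0.75)
  expect_error(fragmentModFraction(0, 0), class = "tRNAcp_undefined_signal")

  expect_equal(nucleosideModLevel(0, 10), 0)
  expect_equal(nucleosideModLevel(5, 5), 1)
  expect_error(nucleosideModLevel(1, 0), "reference")
})

test_that("XIC integration matches closed forms", {
  # rectangle
  xic <- data.frame(rt = seq(0, 10, by = 0.1), intensity = 2)
  expect_equal(integrateXIC(xic), 20, tolerance = 1e-9)
  # triangle, base 10 height 3
  rt <- seq(0, 10, length.out = 201)
  tri <- data.frame(rt = rt, intensity = 3 * (1 - abs(rt - 5) / 5))
  expect_equal(integrateXIC(tri), 15, tolerance = 0.01 * 15)
  # zero trace
  expect_equal(integrateXIC(data.frame(rt = 0:5, intensity = 0)), 0)
  # window errors
  expect_error(integrateXIC(xic, window = c(20, 30)), "fewer than 2")
})

test_that("knockout-emulating XIC pair gives zero modified level", {
  rt <- seq(0, 10, by = 0.05)
  shape <- exp(-(rt - 5)^2 / 0.5)
  wtMod <- data.frame(rt = rt, intensity = 1000 * shape)
  koMod <- data.frame(rt = rt, intensity = 0 * shape)   # knockout: no signal
  ref <- data.frame(rt = rt, intensity = 5000 * shape)
  wtLevel <- nucleosideModLevel(integrateXIC(wtMod), integrateXIC(ref))
  koLevel <- nucleosideModLevel(integrateXIC(koMod), integrateXIC(ref))
  expect_gt(wtLevel, 0)
  expect_equal(koLevel, 0)
})
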