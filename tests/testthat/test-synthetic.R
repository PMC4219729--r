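test_that("Born fixtures carry correct analytic truths", {
  b <- makeBornFixture(2, 2)
  expect_equal(b$analytic, -166.0318 * 4 / 2 * (1 - 1 / 80), tolerance = 1e-3)
  expect_equal(makeBornFixture(2, 0)$analytic, 0)
  expect_equal(makeBornFixture(4, 2)$analytic, b$analytic / 2,
               tolerance = 1e-12)
  expect_error(makeBornFixture(-1, 1), "positive")
})

test_that("the mini-receptor satisfies its documented construction", {
  for (seed in c(1, 9)) {
    r <- makeAcidicPocketReceptor(seed)
    s <- assignParameters(r$structure)
    pocketIdx <- selectIndices(s, chain = "B", resSeq = c(26, 55, 68, 69))
    expect_equal(sum(s@charge[pocketIdx]), -4, tolerance = 1e-6)
    decoyIdx <- selectIndices(s, chain = "C")
    expect_equal(sum(s@charge[decoyIdx]), 2, tolerance = 1e-6)
    expect_gt(sqrt(sum((r$truth$pocketCentroid - r$truth$decoyCentroid)^2)), 15)
    # carboxylate groups clustered: inter-group O-O within the stated band
    og <- function(res) coords(selectAtoms(s, chain = "B", resSeq = res,
                                           atomName = c("OE1", "OE2")))
    for (pr in list(c(26, 68), c(26, 69), c(68, 69))) {
      d <- ionpocket:::pairDist(og(pr[1]), og(pr[2]))
      expect_gt(min(d), 2.5)
      expect_lt(min(d), 8.5)
    }
  }
  # bitwise reproducible per seed
  expect_identical(coords(makeAcidicPocketReceptor(5)$structure),
                   coords(makeAcidicPocketReceptor(5)$structure))
})

test_that("peptide composition follows the class rules", {
  acidic <- c("ASP", "GLU")
  for (seed in 1:10) {
    res <- function(p, k) atomData(p$structure)$resName[
      atomData(p$structure)$resSeq == k][1]
    st <- makePeptide("strong", seed = seed)
    expect_true(res(st, 4) %in% acidic)
    expect_true(res(st, 7) %in% acidic)
    wk <- makePeptide("weak", seed = seed)
    expect_equal(sum(c(res(wk, 4), res(wk, 7)) %in% acidic), 1L)
    nt <- makePeptide("natural", seed = seed)
    expect_false(any(c(res(nt, 4), res(nt, 7)) %in% acidic))
    expect_true(res(nt, 1) %in% c("PHE", "LEU", "ILE", "VAL"))
    expect_true(res(nt, 6) %in% c("PHE", "LEU", "ILE", "VAL"))
    expect_true(res(nt, 10) %in% c("SER", "THR", "TYR"))
    dr <- makePeptide("DR", seed = seed)
    expect_false(any(c(res(dr, 4), res(dr, 7)) %in% acidic))
    # exactly 10 residues everywhere
    for (p in list(st, wk, nt, dr))
      expect_equal(length(unique(atomData(p$structure)$resSeq)), 10L)
  }
  expect_error(makePeptide("mystery"), "arg")
})

test_that("template reproduction modes print the reference sequences", {
  nat <- makePeptide("natural", template = TRUE)
  expect_equal(nat$truth$sequence,
               "PHE-HIS-TYR-LEU-PRO-PHE-LEU-PRO-SER-THR")
  dr <- makePeptide("DR", template = TRUE)
  expect_equal(dr$truth$sequence,
               "TYR-VAL-LYS-GLN-ASN-THR-LEU-LYS-LEU-ALA")
  expect_error(makePeptide("strong", template = TRUE), "template")
})

test_that("trajectory generator modes encode their ground truth", {
  rec <- makeAcidicPocketReceptor(1)$structure
  st <- makeTrajectory(rec, "static", noiseSd = 0, nFrames = 20, seed = 1)
  d <- caDistanceSeries(st$trajectory)
  expect_equal(max(apply(d, 2, sd)), 0)
  expect_true(all(st$truth$pairTrend == "flat"))
  cl <- makeTrajectory(rec, "closing_D3toD5", noiseSd = 0, nFrames = 30,
                       seed = 1)
  dc <- caDistanceSeries(cl$trajectory)
  for (lb in c("D3", "D4", "D5"))
    expect_lt(mean(dc[19:30, lb]), mean(dc[1:12, lb]))
  for (lb in c("D1", "D2"))
    expect_equal(sd(dc[, lb]), 0, tolerance = 1e-12)
  expect_error(makeTrajectory(rec, "static", nFrames = 5), "10")
  # plateau recovered within noise by window statistics
  op <- makeTrajectory(rec, "opening", noiseSd = 0.2, nFrames = 100, seed = 7)
  do <- caDistanceSeries(op$trajectory)
  d0 <- caDistanceSeries(makeTrajectory(rec, "static", noiseSd = 0,
                                        nFrames = 10, seed = 1)$trajectory)
  for (lb in c("D4", "D5")) {
    ws <- windowStats(do[, lb], 0.4)
    expect_lt(abs(ws$mean - (d0[1, lb] + op$truth$plateau)), 2 * ws$sd + 0.1)
  }
  # seeded determinism
  t1 <- makeTrajectory(rec, "opening", noiseSd = 0.1, nFrames = 20, seed = 3)
  t2 <- makeTrajectory(rec, "opening", noiseSd = 0.1, nFrames = 20, seed = 3)
  expect_identical(t1$trajectory@xyz, t2$trajectory@xyz)
})
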