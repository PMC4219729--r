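test_that("a structure at its minimum does not move", {
  rmin <- 1.7 + 1.9
  atoms <- ionpocket:::emptyAtomTable(2)
  atoms$serial <- 1:2; atoms$name <- c("A1", "A2"); atoms$element <- "C"
  atoms$resName <- "XXX"; atoms$resSeq <- 1:2; atoms$insert <- ""
  atoms$chainId <- "Z"
  pair <- ionpocket:::newStructure(atoms, rbind(c(0, 0, 0), c(rmin, 0, 0)),
                                   charge = c(0, 0), radius = c(1.6, 1.6),
                                   ljEpsilon = c(0.2, 0.45),
                                   ljRminHalf = c(1.7, 1.9))
  out <- minimizeStructure(pair, new("MinimizerConfig", forceTol = 1e-3))
  expect_lte(length(out$trace), 2)
  expect_equal(coords(out$structure), coords(pair), tolerance = 1e-8)
})

test_that("a compressed LJ pair relaxes to its analytic minimum", {
  rmin <- 1.7 + 1.9
  atoms <- ionpocket:::emptyAtomTable(2)
  atoms$serial <- 1:2; atoms$name <- c("A1", "A2"); atoms$element <- "C"
  atoms$resName <- "XXX"; atoms$resSeq <- 1:2; atoms$insert <- ""
  atoms$chainId <- "Z"
  pair <- ionpocket:::newStructure(atoms, rbind(c(0, 0, 0), c(0.8 * rmin, 0, 0)),
                                   charge = c(0, 0), radius = c(1.6, 1.6),
                                   ljEpsilon = c(0.2, 0.45),
                                   ljRminHalf = c(1.7, 1.9))
  out <- minimizeStructure(pair, new("MinimizerConfig", maxSteps = 2000L,
                                     forceTol = 1e-4))
  d <- sqrt(sum(diff(coords(out$structure))^2))
  expect_equal(d, rmin, tolerance = 0.01)
  expect_true(all(diff(out$trace) <= 1e-12))
})

test_that("minimizing a clashing complex removes hard contacts", {
  rec <- makeAcidicPocketReceptor(1)$structure
  pep <- makePeptide("strong", seed = 3)$structure
  cx <- assignParameters(buildComplex(rec, pep))
  out <- minimizeStructure(cx, new("MinimizerConfig", maxSteps = 300L))
  d <- ionpocket:::pairDist(coords(out$structure))
  excl <- ionpocket:::exclusionMask(out$structure)
  vdw <- outer(out$structure@radius, out$structure@radius, "+")
  ok <- d[!excl] >= 0.8 * vdw[!excl]
  expect_gt(mean(ok), 0.999)
  expect_true(all(diff(out$trace) <= 1e-12))
})

test_that("Langevin sampling is frozen at zero temperature", {
  rec <- makeAcidicPocketReceptor(1)$structure
  cfg <- new("DynamicsConfig", temperature = 0, nSteps = 500L,
             snapshotEvery = 100L, seed = 2L)
  tr <- enmLangevinSample(rec, cfg)
  expect_gte(nFrames(tr), 2)
  disp <- max(abs(sweep(matrix(tr@xyz, nFrames(tr)), 2,
                        as.numeric(tr@xyz[1, , ]))))
  expect_lt(disp, 1e-6)
})

test_that("Langevin sampling is bitwise reproducible per seed", {
  rec <- makeAcidicPocketReceptor(2)$structure
  cfg <- new("DynamicsConfig", nSteps = 400L, snapshotEvery = 50L, seed = 9L)
  t1 <- enmLangevinSample(rec, cfg)
  t2 <- enmLangevinSample(rec, cfg)
  expect_identical(t1@xyz, t2@xyz)
  cfg2 <- cfg; cfg2@seed <- 10L
  t3 <- enmLangevinSample(rec, cfg2)
  expect_false(identical(t1@xyz, t3@xyz))
})

test_that("a two-bead spring equilibrates to kT/k fluctuations", {
  atoms <- ionpocket:::emptyAtomTable(2)
  atoms$serial <- 1:2; atoms$name <- "CA"; atoms$element <- "C"
  atoms$resName <- "GLY"; atoms$resSeq <- 1:2; atoms$insert <- ""
  atoms$chainId <- "Z"
  s <- ionpocket:::newStructure(atoms, rbind(c(0, 0, 0), c(5, 0, 0)))
  cfg <- new("DynamicsConfig", temperature = 298, nSteps = 100000L,
             dt = 0.05, friction = 1, snapshotEvery = 10L, seed = 4L,
             enmCutoff = 10, enmK = 1)
  tr <- enmLangevinSample(s, cfg)
  d <- apply(tr@xyz, 1, function(m) sqrt(sum((m[1, ] - m[2, ])^2)))
  d <- d[-(1:1000)]  # discard equilibration
  kT <- 0.0019872041 * 298
  expect_equal(var(d), kT / 1, tolerance = 0.1 * kT)
})

test_that("sampler trajectories round-trip through multi-model PDB", {
  rec <- makeAcidicPocketReceptor(3)$structure
  cfg <- new("DynamicsConfig", nSteps = 300L, snapshotEvery = 100L, seed = 1L)
  tr <- enmLangevinSample(rec, cfg)
  f <- tempfile(fileext = ".pdb")
  writePDB(tr, f)
  back <- readTrajectory(f)
  expect_equal(nFrames(back), nFrames(tr))
  expect_lt(max(abs(back@xyz - tr@xyz)), 1e-3)
  expect_equal(back@source, "file")
})

test_that("trajectory import enforces frame counts and roster consistency", {
  rec <- makeAcidicPocketReceptor(1)$structure
  f <- tempfile(fileext = ".pdb")
  writePDB(rec, f)
  expect_error(readTrajectory(f, minFrames = 2), "at least 2")
  # mismatched rosters across models
  lines <- c("MODEL        1",
             "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL", "MODEL        2",
             "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  expect_error(readTrajectory(f2), "model 2")
})
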