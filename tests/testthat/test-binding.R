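makePair <- function(r, e1 = 0.2, e2 = 0.45, q = c(0, 0)) {
  atoms <- ionpocket:::emptyAtomTable(2)
  atoms$serial <- 1:2; atoms$name <- c("A1", "A2"); atoms$element <- "C"
  atoms$resName <- "XXX"; atoms$resSeq <- 1:2; atoms$insert <- ""
  atoms$chainId <- c("Y", "Z")
  ionpocket:::newStructure(atoms, rbind(c(0, 0, 0), c(r, 0, 0)),
                           charge = q, radius = c(1.6, 1.6),
                           ljEpsilon = c(e1, e2), ljRminHalf = c(1.7, 1.9))
}

test_that("Lennard-Jones energy has the analytic minimum and decays", {
  rmin <- 1.7 + 1.9
  pair <- makePair(rmin)
  expect_equal(ljEnergy(pair), -sqrt(0.2 * 0.45), tolerance = 1e-9)
  farPair <- makePair(1e4)
  expect_lt(abs(ljEnergy(farPair)), 1e-12)
  expect_error(ljEnergy(makePair(0.05)), "0.1")
})

test_that("whole-structure and cross-partition LJ match brute force", {
  s <- randomStructure(30, seed = 21, spread = 12)
  excl <- ionpocket:::exclusionMask(s)
  expect_equal(ljEnergy(s),
               bruteLJ(coords(s), s@ljEpsilon, s@ljRminHalf, exclude = excl),
               tolerance = 1e-9)
  expect_equal(ljEnergy(s, partitionA = 1:10, partitionB = 11:30),
               bruteLJ(coords(s), s@ljEpsilon, s@ljRminHalf, 1:10, 11:30),
               tolerance = 1e-9)
})

test_that("total free energy decomposes and recombines exactly", {
  single <- ionpocket:::subsetStructure(makePair(3, q = c(0, 0)), 1L)
  g <- totalG(single)
  expect_equal(c(g@eCoul, g@eSolvPolar, g@eVdw, g@gTotal), c(0, 0, 0, 0))
  born <- makeBornFixture(2, 2)$structure
  gb <- totalG(born, new("SolverConfig", scale = 0.5))
  expect_equal(gb@eCoul, 0)
  expect_equal(gb@eVdw, 0)
  expect_equal(gb@gTotal, gb@eSolvPolar)
  pair <- makePair(3, q = c(0.5, -0.5))
  gp <- totalG(pair, new("SolverConfig", scale = 0.5))
  expect_equal(gp@gTotal, gp@eCoul + gp@eSolvPolar + gp@eVdw)
})

test_that("binding bookkeeping identities hold exactly as stored", {
  pair <- makePair(3, q = c(1, -1))
  res <- bindingEnergy(pair, 1L, 2L, new("SolverConfig", scale = 0.5),
                       minimize = "none")
  expect_identical(res@dG,
                   res@gAB@gTotal - res@gA@gTotal - res@gB@gTotal)
  expect_length(intersect(res@partitionA, res@partitionB), 0)
  expect_match(res@note, "ranking")
  expect_error(bindingEnergy(pair, 1L, 1L, minimize = "none"), "partition")
})

test_that("rigid-split dG vanishes for well-separated partners", {
  pair <- makePair(100, q = c(1, -1))
  res <- bindingEnergy(pair, 1L, 2L, new("SolverConfig", scale = 1),
                       minimize = "none")
  expect_lt(abs(res@dG), 0.5)
})

test_that("vacuum Coulomb part of a +1/-1 split is the analytic pair energy", {
  pair <- makePair(3, q = c(1, -1))
  res <- bindingEnergy(pair, 1L, 2L, minimize = "none")
  dCoul <- res@gAB@eCoul - res@gA@eCoul - res@gB@eCoul
  expect_equal(dCoul, -332.0636 / 3, tolerance = 1e-9)
})

test_that("dG is invariant under a global rigid transform of the complex", {
  pair <- makePair(3.5, q = c(0.8, -0.6))
  cfg <- new("SolverConfig", scale = 0.25)
  r1 <- bindingEnergy(pair, 1L, 2L, cfg, minimize = "none")
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- pair
  moved@coords <- pair@coords %*% rot +
    matrix(c(1.3, -0.4, 2.2), 2, 3, byrow = TRUE)
  r2 <- bindingEnergy(moved, 1L, 2L, cfg, minimize = "none")
  expect_lt(abs(r1@dG - r2@dG), 0.5)
})

test_that("scenario comparison is deterministic and labels censored cases", {
  rec <- makeAcidicPocketReceptor(1)$structure
  pep <- makePeptide("strong", seed = 4)$structure
  a <- compareScenarios(rec, pep, minimize = "none", seed = 3)
  b <- compareScenarios(rec, pep, minimize = "none", seed = 3)
  expect_identical(vapply(a, function(r) r@dG, numeric(1)),
                   vapply(b, function(r) r@dG, numeric(1)))
  expect_named(a, c("no_ion", "pep_to_Be_protein", "Bepep_to_protein"))
})

test_that("class summaries reproduce hand-computed medians", {
  mk <- function(v) new("BindingResult", scenario = "x",
                        gAB = new("EnergyBreakdown", eCoul = v, eSolvPolar = 0,
                                  eVdw = 0, gTotal = v),
                        gA = ionpocket:::emptyBreakdown(),
                        gB = ionpocket:::emptyBreakdown(), dG = v,
                        partitionA = integer(0), partitionB = integer(0),
                        note = "ranking-only")
  res <- lapply(c(-10, -8, -5, -4), mk)
  cs <- classSummary(res, c("a", "a", "b", "b"))
  expect_equal(cs$median[cs$class == "a"], -9)
  expect_equal(cs$median[cs$class == "b"], -4.5)
  one <- classSummary(list(mk(-3)), "solo")
  expect_equal(one$median, -3)
  cens <- mk(0); cens@note <- "no stable Be-peptide complex"
  cs2 <- classSummary(list(mk(-2), cens), c("a", "a"))
  expect_equal(cs2$n, 1L)
})
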