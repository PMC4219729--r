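test_that("grid geometry follows the perfil rule", {
  b <- makeBornFixture(2, 1)$structure
  g <- buildGrid(b, new("SolverConfig", scale = 1, perfil = 70))
  # extent 4 A at perfil 70 -> edge 5.71 A -> 6.71 nodes -> next odd = 7
  expect_equal(g$dims, c(7L, 7L, 7L))
  g2 <- buildGrid(b, new("SolverConfig", scale = 0.5, perfil = 70))
  expect_true(all(g2$dims >= 2 * g$dims - 3 & g2$dims <= 2 * g$dims + 3))
  g3 <- buildGrid(b, new("SolverConfig", scale = 1, perfil = 100))
  expect_true(all(g3$dims < g$dims))
  expect_error(buildGrid(ionpocket:::newStructure(
    ionpocket:::emptyAtomTable(0), matrix(numeric(0), 0, 3))), "empty")
})

test_that("charge spreading is trilinear and conservative", {
  b <- makeBornFixture(1.5, 1)$structure
  geom <- buildGrid(b, new("SolverConfig"))
  arr <- mapCharges(b, geom)
  ctr <- (geom$dims + 1) / 2
  expect_equal(arr[ctr[1], ctr[2], ctr[3]], 1)  # charge on the centre node
  expect_equal(sum(arr), 1, tolerance = 1e-12)
  # charge at a cell centre spreads 1/8 to each corner
  b2 <- b
  b2@coords <- b2@coords + geom$spacing / 2
  arr2 <- mapCharges(b2, geom)
  expect_equal(sort(unique(round(arr2[arr2 > 0], 12))), 0.125)
  expect_equal(sum(arr2), 1, tolerance = 1e-12)
  # arbitrary multi-atom set conserves total charge to 1e-9
  s <- randomStructure(5, seed = 11, spread = 3)
  geom3 <- buildGrid(s, new("SolverConfig"))
  expect_equal(sum(mapCharges(s, geom3)), sum(s@charge), tolerance = 1e-9)
  out <- b
  out@coords <- out@coords + 100
  expect_error(mapCharges(out, geom), "outside")
})

test_that("uniform-dielectric point charge recovers Coulomb's law", {
  s <- makeBornFixture(2, 1)$structure
  cfg <- new("SolverConfig", scale = 0.5, epsIn = 80, epsOut = 80, perfil = 25)
  g <- solvePoisson(s, cfg)
  for (r in c(3, 5, 6)) {
    expect_equal(potentialAt(g, matrix(c(r, 0, 0), 1)),
                 332.0636 / (80 * r),
                 tolerance = 0.05)
  }
})

test_that("zero charge gives an identically zero field", {
  s <- randomStructure(4, seed = 3, charged = FALSE)
  g <- solvePoisson(s, new("SolverConfig"))
  expect_equal(max(abs(g@values)), 0)
  expect_equal(reactionFieldEnergy(s), 0)
})

test_that("Born solvation matches the analytic value and scales quadratically", {
  born <- makeBornFixture(2, 2)
  cfg <- new("SolverConfig", scale = 0.5)
  e <- reactionFieldEnergy(born$structure, cfg)
  expect_lt(abs(e - born$analytic) / abs(born$analytic), 0.05)
  expect_lt(e, 0)
  # linear response: doubling the charge quadruples the energy
  born1 <- makeBornFixture(2, 1)
  e1 <- reactionFieldEnergy(born1$structure, cfg)
  expect_equal(e / e1, 4, tolerance = 0.01)
})

test_that("reaction-field energy is invariant under whole-cell translation", {
  born <- makeBornFixture(2, 2)
  cfg <- new("SolverConfig", scale = 0.5)
  e0 <- reactionFieldEnergy(born$structure, cfg)
  moved <- born$structure
  moved@coords <- moved@coords + cfg@scale  # one grid cell in each axis
  e1 <- reactionFieldEnergy(moved, cfg)
  expect_equal(e0, e1, tolerance = 1e-6)
})

test_that("Coulomb energies match the analytic pair and a brute-force loop", {
  atoms <- ionpocket:::emptyAtomTable(2)
  atoms$serial <- 1:2; atoms$name <- c("A1", "A2"); atoms$element <- "C"
  atoms$resName <- "XXX"; atoms$resSeq <- 1:2; atoms$insert <- ""
  atoms$chainId <- "Z"
  pair <- ionpocket:::newStructure(atoms, rbind(c(0, 0, 0), c(3, 0, 0)),
                                   charge = c(1, -1), radius = c(1.5, 1.5),
                                   ljEpsilon = c(0.1, 0.1),
                                   ljRminHalf = c(1.5, 1.5))
  expect_equal(coulombEnergy(pair, eps = 1), -332.0636 / 3, tolerance = 1e-9)
  single <- ionpocket:::subsetStructure(pair, 1L)
  expect_equal(coulombEnergy(single), 0)
  s <- randomStructure(50, seed = 7)
  expect_equal(coulombEnergy(s, eps = 2),
               bruteCoulomb(coords(s), s@charge, eps = 2),
               tolerance = 1e-9)
  idxA <- 1:20; idxB <- 21:50
  expect_equal(coulombEnergy(s, eps = 1, partitionA = idxA, partitionB = idxB),
               bruteCoulomb(coords(s), s@charge, 1, idxA, idxB),
               tolerance = 1e-9)
  clash <- pair
  clash@coords[2, ] <- clash@coords[1, ]
  expect_error(coulombEnergy(clash), "coincident")
})
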