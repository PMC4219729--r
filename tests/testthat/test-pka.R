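gluCompound <- function() {
  # carboxylate side chain alone (the model-compound fixture)
  pep <- makePeptide("strong", seed = 105)$structure
  glu <- selectAtoms(pep, resSeq = 4,
                     atomName = c("CB", "CG", "CD", "OE1", "OE2"))
  assignParameters(glu)
}

withFixedCharge <- function(glu, d) {
  ionAtoms <- data.frame(serial = 1L, name = "BE", element = "BE",
                         resName = "BE", resSeq = 1L, insert = "",
                         chainId = "I", het = TRUE, stringsAsFactors = FALSE)
  oe <- colMeans(coords(selectAtoms(glu, atomName = c("OE1", "OE2"))))
  ion <- ionpocket:::newStructure(ionAtoms, matrix(oe + c(0, 0, d), 1, 3))
  assignParameters(ionpocket:::concatStructures(list(glu, ion)))
}

test_that("titratable sites are identified by residue type", {
  rec <- makeAcidicPocketReceptor(1)$structure
  sites <- identifySites(rec)
  expect_setequal(sites$type[sites$chainId == "B"], c("GLU", "ASP"))
  expect_true(all(c(26, 68, 69) %in% sites$resSeq[sites$type == "GLU"]))
  expect_true(all(sites$acid[sites$type %in% c("GLU", "ASP")]))
  expect_false(any(sites$acid[sites$type %in% c("LYS", "ARG")]))
  polyG <- selectAtoms(rec, chain = "A")
  expect_equal(nrow(identifySites(polyG)), 0L)
  glu <- gluCompound()
  s1 <- identifySites(glu)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$modelPka, 4.25)
})

test_that("an isolated model compound recovers its model pKa", {
  glu <- gluCompound()
  expect_equal(intrinsicPka(glu, "P", 4), 4.25, tolerance = 0.05)
})

test_that("a nearby +2 fixed charge monotonically lowers an acid pKa", {
  glu <- gluCompound()
  pkas <- vapply(c(12, 8, 6, 4), function(d)
    intrinsicPka(withFixedCharge(glu, d), "P", 4), numeric(1))
  expect_true(all(diff(pkas) < 0))
  expect_true(all(pkas < 4.25))
})

test_that("burial in a low-dielectric environment raises an acid pKa", {
  glu <- gluCompound()
  # surround the carboxylate with neutral bulk spheres (a desolvation cage)
  n <- 12
  set.seed(8)
  ctr <- colMeans(coords(glu))
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  atoms <- ionpocket:::emptyAtomTable(n)
  atoms$serial <- 1:n; atoms$name <- paste0("X", 1:n); atoms$element <- "C"
  atoms$resName <- "XXX"; atoms$resSeq <- 100 + 1:n; atoms$insert <- ""
  atoms$chainId <- "W"
  cage <- ionpocket:::newStructure(
    atoms, sweep(dirs * 5.5, 2, -ctr), charge = rep(0, n),
    radius = rep(2.4, n), ljEpsilon = rep(0.1, n), ljRminHalf = rep(2, n))
  buried <- ionpocket:::concatStructures(list(glu, cage))
  expect_gt(intrinsicPka(buried, "P", 4), 4.25)
})

test_that("the interaction matrix is symmetric, screened and decays", {
  rec <- assignParameters(makeAcidicPocketReceptor(1)$structure)
  sites <- identifySites(rec)
  pocket <- sites[sites$resSeq %in% c(26, 68, 69) & sites$type == "GLU", ]
  W <- interactionMatrix(rec, pocket)
  expect_equal(W, t(W), tolerance = 1e-6)
  expect_equal(diag(W), rep(0, 3))
  expect_true(all(W[upper.tri(W)] > 0))  # like-charged acids repel
  # two acid charges ~5 A apart in water: roughly the screened Coulomb value
  glu <- gluCompound()
  g2 <- glu
  g2@coords <- g2@coords + matrix(c(0, 0, 9), nAtoms(g2), 3, byrow = TRUE)
  g2@atoms$resSeq <- g2@atoms$resSeq + 10L
  both <- ionpocket:::concatStructures(list(glu, g2))
  s2 <- identifySites(both)
  W2 <- interactionMatrix(both, s2)
  dOO <- 9  # proton-atom separation by construction
  screened <- 332.0636 / (80 * dOO)
  expect_equal(W2[1, 2], screened, tolerance = 0.5 * screened)
  expect_gt(W2[1, 2], 0)
})

test_that("single-site titration reproduces Henderson-Hasselbalch", {
  sites <- data.frame(chainId = "A", resSeq = 1L, type = "GLU", acid = TRUE,
                      modelPka = 4.25, pkaInt = 5.3)
  tt <- titrate(sites)
  expect_equal(tt@pka50, 5.3, tolerance = 0.01)
  expect_true(all(diff(tt@curves[1, ]) <= 1e-12))
  ph <- tt@pH
  expect_equal(tt@curves[1, ], 1 / (1 + 10^(ph - 5.3)), tolerance = 1e-6)
  # base titration rises toward low pH
  bs <- data.frame(chainId = "A", resSeq = 1L, type = "LYS", acid = FALSE,
                   modelPka = 10.53, pkaInt = 10)
  tb <- titrate(bs)
  expect_equal(tb@pka50, 10, tolerance = 0.01)
})

test_that("Metropolis titration converges to exact enumeration", {
  set.seed(31)
  n <- 5
  sites <- data.frame(chainId = "A", resSeq = 1:n,
                      type = sample(c("GLU", "ASP", "LYS", "HIS"), n, TRUE),
                      acid = NA, modelPka = 0, pkaInt = runif(n, 3, 9))
  sites$acid <- sites$type %in% c("GLU", "ASP")
  sgn <- ifelse(sites$acid, -1, 1)
  W <- matrix(runif(n * n, 0, 1.5), n)
  W <- (W + t(W)) / 2 * outer(sgn, sgn)
  diag(W) <- 0
  te <- titrate(sites, W, method = "enumerate")
  for (seed in c(1, 2, 3)) {
    tm <- titrate(sites, W, method = "monte_carlo", mcSweeps = 1e5,
                  seed = seed)
    expect_lt(max(abs(te@pka50 - tm@pka50)), 0.1)
  }
})

test_that("strongly coupled acids split but stay monotone", {
  s2 <- data.frame(chainId = "A", resSeq = 1:2, type = "GLU", acid = TRUE,
                   modelPka = 4.25, pkaInt = c(4.5, 4.5))
  W2 <- matrix(c(0, 3, 3, 0), 2)
  t2 <- titrate(s2, W2)
  expect_true(all(diff(t2@curves[1, ]) <= 1e-9))
  # coupling delays full deprotonation relative to the uncoupled site
  t0 <- titrate(s2, matrix(0, 2, 2))
  expect_gt(t2@pka50[1], t0@pka50[1])
})

test_that("pKa shift reports subtract states and propagate censoring", {
  sites <- data.frame(chainId = "B", resSeq = c(26L, 69L), type = "GLU",
                      acid = TRUE, modelPka = 4.25, pkaInt = c(6.0, 6.5))
  free <- titrate(sites)
  expect_equal(pkaShiftReport(free, free)$shift, c(0, 0), tolerance = 1e-12)
  boundSites <- sites
  boundSites$pkaInt <- c(2.0, -1.5)  # strong acidification
  bound <- titrate(boundSites)
  rep <- pkaShiftReport(bound, free)
  expect_true(all(rep$shift < 0 | nzchar(rep$note)))
  other <- sites
  other$resSeq <- c(1L, 2L)
  expect_error(pkaShiftReport(bound, titrate(other)), "rosters differ")
})

test_that("cation placement in the pocket acidifies the pocket carboxylates", {
  r <- makeAcidicPocketReceptor(1)
  rec <- assignParameters(r$structure)
  sites <- identifySites(rec)
  focus <- sites[sites$resSeq %in% c(26, 68, 69) & sites$type == "GLU", ]
  free <- computeTitration(rec, sites = focus)
  site <- predictIonSite(rec)
  ionAtoms <- data.frame(serial = 1L, name = "BE", element = "BE",
                         resName = "BE", resSeq = 1L, insert = "",
                         chainId = "I", het = TRUE, stringsAsFactors = FALSE)
  ion <- ionpocket:::newStructure(ionAtoms, matrix(site$position, 1, 3))
  bound <- assignParameters(ionpocket:::concatStructures(list(r$structure, ion)))
  boundT <- computeTitration(bound, sites = focus)
  rep <- pkaShiftReport(boundT, free)
  shiftsDown <- rep$shift < 0 | grepl("<min", rep$note)
  expect_true(all(shiftsDown))
})
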