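test_that("PDB files round-trip atoms, names, chains and coordinates", {
  rec <- makeAcidicPocketReceptor(4)$structure
  f <- tempfile(fileext = ".pdb")
  writePDB(rec, f)
  back <- readPDB(f)
  expect_equal(nAtoms(back), nAtoms(rec))
  expect_equal(atomData(back)$name, atomData(rec)$name)
  expect_equal(atomData(back)$chainId, atomData(rec)$chainId)
  expect_equal(atomData(back)$resSeq, atomData(rec)$resSeq)
  expect_lt(max(abs(coords(back) - coords(rec))), 1e-3)
  # second round trip is exact
  f2 <- tempfile(fileext = ".pdb")
  writePDB(back, f2)
  again <- readPDB(f2)
  expect_identical(coords(again), coords(back))
})

test_that("a minimal hand-written ATOM file parses", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.400   1.100   0.000  1.00  0.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_equal(nAtoms(s), 3L)
  expect_equal(chains(s), "A")
  expect_equal(unname(coords(s)[2, 1]), 1.45)
})

test_that("malformed coordinate fields fail with the line number", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       xx.xxx   0.000   0.000  1.00  0.00           C"), f)
  expect_error(readPDB(f), "line 2")
  expect_error(readPDB(tempfile()), "cannot read")
})

test_that("writing refuses an empty structure and writes multi-model files", {
  empty <- ionpocket:::newStructure(ionpocket:::emptyAtomTable(0),
                                    matrix(numeric(0), 0, 3))
  expect_error(writePDB(empty, tempfile()), "empty")
  tr <- makeTrajectory(makeAcidicPocketReceptor(1)$structure,
                       "static", noiseSd = 0, nFrames = 10, seed = 1)$trajectory
  tr@xyz <- tr@xyz[1:3, , , drop = FALSE]
  f <- tempfile(fileext = ".pdb")
  writePDB(tr, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3L)
})

test_that("parameter assignment reproduces formal charges and never moves atoms", {
  params <- defaultParameterSet()
  sums <- tapply(params@table$charge, params@table$resName, sum)
  expect_true(all(abs(sums - params@formalCharge[names(sums)]) < 1e-6))
  pep <- makePeptide("strong", seed = 5)$structure
  pp <- assignParameters(pep)
  expect_identical(coords(pp), coords(pep))
  # a deprotonated GLU/ASP side chain carries exactly -1 e
  at <- atomData(pp)
  acid <- which(at$resName %in% c("GLU", "ASP"))[1]
  res <- at$resSeq[acid]
  side <- selectIndices(pp, resSeq = res)
  side <- setdiff(side, selectIndices(pp, resSeq = res,
                                      atomName = c("N", "CA", "C", "O")))
  expect_equal(sum(pp@charge[side]), -1, tolerance = 1e-6)
})

test_that("ion atoms take the ion specification and unknown residues error", {
  rec <- makeAcidicPocketReceptor(1)$structure
  ionAtoms <- data.frame(serial = 1L, name = "BE", element = "BE",
                         resName = "BE", resSeq = 1L, insert = "",
                         chainId = "I", het = TRUE, stringsAsFactors = FALSE)
  ion <- ionpocket:::newStructure(ionAtoms, matrix(c(0, 0, 10), 1, 3))
  s <- assignParameters(ionpocket:::concatStructures(list(rec, ion)))
  i <- selectIndices(s, chain = "I")
  expect_equal(s@charge[i], 2.0)
  expect_equal(s@radius[i], 1.53)
  bad <- rec
  bad@atoms$resName[1] <- "UNK"
  expect_error(assignParameters(bad), "UNK")
  expect_warning(assignParameters(bad, strict = FALSE), "UNK")
})

test_that("selections subset by chain, residue range and atom name", {
  rec <- makeAcidicPocketReceptor(2)$structure
  helix <- selectAtoms(rec, chain = "B", resSeq = 50:86)
  expect_true(all(atomData(helix)$chainId == "B"))
  expect_true(all(atomData(helix)$resSeq >= 50 & atomData(helix)$resSeq <= 86))
  ca <- selectAtoms(rec, atomName = "CA")
  expect_equal(nAtoms(ca), length(unique(ionpocket:::residueKeys(atomData(rec)))))
  pocket <- selectAtoms(rec, chain = "B", resSeq = c(26, 68, 69),
                        resName = "GLU", atomName = c("OE1", "OE2"))
  expect_equal(nAtoms(pocket), 6L)
  expect_equal(nAtoms(selectAtoms(rec, chain = "Q")), 0L)
  expect_error(selectIndices(rec, resSeq = "fifty"), "numeric")
})

test_that("side-chain mutation preserves the backbone exactly", {
  pep <- makePeptide("natural", template = TRUE)$structure
  expect_identical(mutateSideChain(pep, "P", 4, "LEU"), pep)  # LEU -> LEU
  toGly <- mutateSideChain(pep, "P", 5, "GLY")
  expect_equal(atomData(toGly)$resName[atomData(toGly)$resSeq == 5][1], "GLY")
  bb <- function(s, res) coords(selectAtoms(s, resSeq = res,
                                            atomName = c("N", "CA", "C", "O")))
  for (res in 1:10) expect_identical(bb(toGly, res), bb(pep, res))
  toGlu <- mutateSideChain(pep, "P", 4, "GLU", seed = 9)
  expect_equal(unique(atomData(selectAtoms(toGlu, resSeq = 4))$resName), "GLU")
  for (res in 1:10) expect_identical(bb(toGlu, res), bb(pep, res))
  expect_true(all(c("OE1", "OE2") %in% atomData(toGlu)$name))
  expect_error(mutateSideChain(pep, "P", 99, "GLU"), "no residue")
})

test_that("complex building keeps clash-free poses and resolves overlaps", {
  rec <- makeAcidicPocketReceptor(1)$structure
  pep <- makePeptide("natural", seed = 2)$structure
  far <- pep
  far@coords <- far@coords + matrix(c(0, 0, 60), nAtoms(far), 3, byrow = TRUE)
  cx <- buildComplex(rec, far)
  i <- selectIndices(cx, chain = "P")
  expect_identical(unname(coords(cx)[i, ]), unname(coords(far)))
  # a forced overlap is pushed out beyond the clash cutoff
  onTop <- pep
  onTop@coords <- sweep(onTop@coords, 2,
                        colMeans(onTop@coords) - colMeans(rec@coords))
  cx2 <- buildComplex(rec, onTop)
  i2 <- selectIndices(cx2, chain = "P")
  d <- ionpocket:::pairDist(coords(cx2)[-i2, , drop = FALSE],
                            coords(cx2)[i2, , drop = FALSE])
  rr <- ionpocket:::clashRadii(cx2)
  cut <- outer(rr[-i2], rr[i2], "+") * 0.7
  expect_true(all(d >= cut))
  # composition: receptor chains + peptide chain + HETATM ion
  cx3 <- buildComplex(rec, pep, ion = ionSpec(), ionPosition = c(11.7, 2, -10.5))
  expect_setequal(chains(cx3), c("A", "B", "C", "D", "P", "I"))
  expect_equal(sum(atomData(cx3)$het), 1L)
})

test_that("chain renumbering shifts one chain only", {
  rec <- makeAcidicPocketReceptor(1)$structure
  shifted <- renumberChain(rec, "A", 100L)
  expect_equal(sort(unique(atomData(shifted)$resSeq[atomData(shifted)$chainId == "A"])),
               sort(unique(atomData(rec)$resSeq[atomData(rec)$chainId == "A"])) + 100L)
  expect_equal(atomData(shifted)$resSeq[atomData(shifted)$chainId == "B"],
               atomData(rec)$resSeq[atomData(rec)$chainId == "B"])
})
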