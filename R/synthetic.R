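# Seeded generators for every fixture the pipeline and its tests need.
# The mini-receptor is a pseudo-protein (backbone scaffolds plus charged
# functional groups), not a folded domain: sufficient for electrostatics
# and geometry work while staying small enough for dense grid solves.

#' Born-ion solver validation fixture
#'
#' A single charged sphere with the analytic Born solvation energy
#' attached: `dG = -166.0318 q^2 / a (1 - 1/epsOut)` kcal/mol.
#'
#' @param radius sphere radius, Angstrom.
#' @param charge charge, e.
#' @param epsOut solvent dielectric (default 80).
#' @return list with `structure` (parameterized, single atom at the
#'   origin) and `analytic` (kcal/mol).
#' @export
makeBornFixture <- function(radius, charge, epsOut = 80) {
  if (radius <= 0) stop("radius must be positive")
  atoms <- data.frame(serial = 1L, name = "ION", element = "X",
                      resName = "ION", resSeq = 1L, insert = "",
                      chainId = "X", het = TRUE, stringsAsFactors = FALSE)
  s <- newStructure(atoms, matrix(0, 1, 3), charge = charge, radius = radius,
                    ljEpsilon = 0, ljRminHalf = radius,
                    title = "Born fixture")
  list(structure = s,
       analytic = -KE / 2 * charge^2 / radius * (1 - 1 / epsOut))
}

# Carboxylate head group grown from CA along dir; perp sets the O-O split.
carboxylate <- function(ca, dir, perp, nSpine) {
  dir <- dir / sqrt(sum(dir^2))
  perp <- perp - sum(perp * dir) * dir
  perp <- perp / sqrt(sum(perp^2))
  sp <- t(vapply(seq_len(nSpine), function(k) ca + (1.53 + 1.35 * (k - 1)) * dir,
                 numeric(3)))
  cd <- sp[nSpine, ]
  o1 <- cd + 1.25 * (0.5 * dir + 0.866 * perp)
  o2 <- cd + 1.25 * (0.5 * dir - 0.866 * perp)
  rbind(sp, o1, o2)
}

glyBackbone <- function(ca) {
  rbind(N = ca + c(-0.95, 0.95, 0), CA = ca, C = ca + c(0.95, 0.95, 0),
        O = ca + c(0.95, 1.55, 1.05))
}

appendResidue <- function(state, chain, resSeq, resName, names, coords) {
  n <- length(names)
  state$atoms[[length(state$atoms) + 1L]] <- data.frame(
    serial = 0L, name = names,
    element = ifelse(substr(names, 1, 1) %in% c("N", "O", "S"),
                     substr(names, 1, 1), "C"),
    resName = resName, resSeq = as.integer(resSeq), insert = "",
    chainId = chain, het = FALSE, stringsAsFactors = FALSE)
  state$coords[[length(state$coords) + 1L]] <- coords
  state
}

#' Synthetic acidic-pocket mini-receptor
#'
#' A two-walled binding groove (chains A and B, about 12 Angstrom apart)
#' carrying, on one wall, a cluster of three glutamate carboxylates
#' (residues B:26, B:68, B:69; inter-group O-O spacing roughly 2.5-8 Angstrom)
#' mimicking the acidic pocket of an MHC class II groove, an aspartate
#' (B:55) at the groove end, and a two-residue basic decoy patch (chain
#' C) more than 15 Angstrom from the pocket. Residue numbers on the
#' walls are chosen so the five standard pocket-width pairs
#' ([defaultPocketPairs()]) resolve on the fixture.
#'
#' @param seed integer; coordinates receive a seeded 0.15 Angstrom
#'   Gaussian jitter so repeated fixtures differ realistically.
#' @return list with `structure` (bare; run [assignParameters()]) and
#'   `truth`: `pocketCentroid` (carboxylate-oxygen centroid of the three
#'   glutamates), `decoyCentroid` (centroid of the decoy's basic nitrogens),
#'   `grooveAxis`, and `seed`.
#' @export
makeAcidicPocketReceptor <- function(seed = 1L) {
  st <- list(atoms = list(), coords = list())
  # wall A (y = -6): GLY scaffold, numbering covers the pocket-pair residues
  resA <- c(52L, 56L, 60L, 65L, 70L, 76L, 80L)
  xA <- seq(0, by = 3.0, length.out = length(resA))
  for (i in seq_along(resA)) {
    bb <- glyBackbone(c(xA[i], -7.5, 0))
    bb[, 2] <- -15 - bb[, 2]  # mirror so carbonyls face away from the groove
    st <- appendResidue(st, "A", resA[i], "GLY", rownames(bb), bb)
  }
  # wall B (y = +6): GLY scaffold with GLU 68/69 and ASP 55
  resB <- c(50L, 55L, 58L, 64L, 68L, 69L, 76L, 83L)
  xB <- seq(0, by = 2.6, length.out = length(resB))
  for (i in seq_along(resB)) {
    ca <- c(xB[i], 6, 0)
    bb <- glyBackbone(ca)
    nm <- "GLY"
    extra <- NULL
    if (resB[i] == 68L) {
      nm <- "GLU"
      extra <- carboxylate(ca, c(9.45, 2.3, -1.75) - ca, c(-0.5, 0, -0.866), 3)
      rownames(extra) <- c("CB", "CG", "CD", "OE1", "OE2")
    } else if (resB[i] == 69L) {
      nm <- "GLU"
      extra <- carboxylate(ca, c(13.95, 2.3, -1.75) - ca, c(-0.5, 0, 0.866), 3)
      rownames(extra) <- c("CB", "CG", "CD", "OE1", "OE2")
    } else if (resB[i] == 55L) {
      nm <- "ASP"
      extra <- carboxylate(ca, c(0, -0.90, -0.45), c(1, 0, 0), 2)
      rownames(extra) <- c("CB", "CG", "OD1", "OD2")
    }
    st <- appendResidue(st, "B", resB[i], nm, c(rownames(bb), rownames(extra)),
                        rbind(bb, extra))
  }
  # neutral bulk enclosing the cage flanks, floor and back, so the seat
  # keeps the strong negative potential of a buried acidic pocket while
  # the mouth stays open toward the groove centre line
  for (spec in list(list(34L, c(6.6, 2.3, -3.0)),
                    list(40L, c(16.8, 2.3, -3.0)),
                    list(30L, c(11.7, 1.2, -7.8)),
                    list(32L, c(11.7, 5.0, -3.2)))) {
    bb <- glyBackbone(spec[[2]])
    st <- appendResidue(st, "B", spec[[1]], "GLY", rownames(bb), bb)
  }
  # groove-floor strand carrying GLU 26; its carboxylate completes the
  # upward-facing tripod around the cation seat with GLU 68/69
  for (spec in list(list(24L, "GLY", NULL),
                    list(26L, "GLU", TRUE),
                    list(28L, "GLY", NULL))) {
    x0 <- c(9.1, 11.7, 14.3)[match(spec[[1]], c(24L, 26L, 28L))]
    ca <- c(x0, 3.6, -10.1)
    bb <- glyBackbone(ca)
    bb[, 3] <- 2 * ca[3] - bb[, 3]  # keep the floor carbonyls below the groove
    bb["CA", ] <- ca
    extra <- NULL
    nm <- spec[[2]]
    if (!is.null(spec[[3]])) {
      extra <- carboxylate(ca, c(11.7, 2.3, -5.65) - ca, c(1, 0, 0), 3)
      rownames(extra) <- c("CB", "CG", "CD", "OE1", "OE2")
    }
    st <- appendResidue(st, "B", spec[[1]], nm, c(rownames(bb), rownames(extra)),
                        rbind(bb, extra))
  }
  # basic decoy patch far from the pocket, plus a compensating surface
  # patch behind the acidic wall so the scaffold is net neutral (class
  # contrasts then reflect the local pocket field, not a global monopole)
  for (spec in list(list("C", 1L, "LYS", c(-5, -9.5, 0), c("CB", "CG", "CD", "CE", "NZ")),
                    list("C", 2L, "ARG", c(24, -9.5, 0), c("CB", "CG", "CD", "NE", "CZ")),
                    list("D", 1L, "LYS", c(-4, 10.5, 3), c("CB", "CG", "CD", "CE", "NZ")),
                    list("D", 2L, "LYS", c(26, 10.5, 3), c("CB", "CG", "CD", "CE", "NZ")))) {
    ca <- spec[[4]]
    bb <- glyBackbone(ca)
    dir <- if (ca[2] > 0) c(0, 1, 0) else c(0, -1, 0)
    sp <- t(vapply(seq_along(spec[[5]]),
                   function(k) ca + (1.53 + 1.3 * (k - 1)) * dir, numeric(3)))
    rownames(sp) <- spec[[5]]
    nmres <- spec[[3]]
    if (nmres == "ARG") {
      nh <- rbind(NH1 = sp["CZ", ] + c(-1.0, -0.6, 0),
                  NH2 = sp["CZ", ] + c(1.0, -0.6, 0))
      sp <- rbind(sp, nh)
    }
    st <- appendResidue(st, spec[[1]], spec[[2]], nmres,
                        c(rownames(glyBackbone(ca)), rownames(sp)),
                        rbind(glyBackbone(ca), sp))
  }
  atoms <- do.call(rbind, st$atoms)
  co <- do.call(rbind, st$coords)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  co <- co + withSeed(seed, matrix(stats::rnorm(length(co), 0, 0.15),
                                   nrow(co), 3))
  s <- newStructure(atoms, co, title = sprintf("acidic-pocket receptor (seed %d)", seed))
  oIdx <- selectIndices(s, chain = "B", resSeq = c(26, 68, 69),
                        atomName = c("OE1", "OE2"))
  decoyIdx <- selectIndices(s, chain = "C",
                            atomName = c("NZ", "NH1", "NH2"))
  list(structure = s,
       truth = list(pocketCentroid = colMeans(co[oIdx, , drop = FALSE]),
                    decoyCentroid = colMeans(co[decoyIdx, , drop = FALSE]),
                    grooveAxis = c(1, 0, 0), seed = seed))
}

peptideClassSets <- list(
  acidic = c("ASP", "GLU"),
  basic = c("LYS", "ARG"),
  hydrophobic = c("PHE", "LEU", "ILE", "VAL"),
  polarTail = c("SER", "THR", "TYR"),
  neutral = c("ALA", "VAL", "LEU", "SER", "THR", "GLY", "ASN", "GLN"),
  basicOrNeutral = c("LYS", "ARG", "GLN", "LEU")
)

templateSequences <- c(natural = "FHYLPFLPST", DR = "YVKQNTLKLA")

#' Synthetic class-structured 10-mer peptide
#'
#' Builds an extended-backbone 10-residue peptide posed in the
#' mini-receptor groove frame (backbone along the groove axis, key side
#' chains pointing at the acidic wall). Sequence composition follows the
#' class rules: `strong` peptides carry acidic residues at both p4 and
#' p7; `weak` at exactly one of them; `natural` peptides have
#' hydrophobic p1/p6, a polar p10 and neutral p4/p7; `DR` peptides have
#' basic-or-neutral p4/p7. With `template = TRUE` the class template
#' sequence is reproduced verbatim (`natural` = FHYLPFLPST, `DR` =
#' YVKQNTLKLA).
#'
#' @param class `"natural"`, `"strong"`, `"weak"` or `"DR"`.
#' @param seed integer seed for the composition draw.
#' @param template reproduce the printed template sequence (only for
#'   `natural` and `DR`).
#' @return list with `structure` (bare 10-residue chain P) and `truth`
#'   (`class`, `sequence`, `seed`).
#' @export
makePeptide <- function(class = c("natural", "strong", "weak", "DR"),
                        seed = 1L, template = FALSE) {
  class <- match.arg(class)
  if (template) {
    if (!class %in% names(templateSequences))
      stop("no printed template for class ", class)
    seq3 <- unname(aaThree[strsplit(templateSequences[class], "")[[1]]])
  } else {
    seq3 <- withSeed(seed, {
      pick <- function(set, n = 1) sample(peptideClassSets[[set]], n,
                                          replace = TRUE)
      s <- pick("neutral", 10)
      s[c(1, 6)] <- pick("hydrophobic", 2)
      s[10] <- pick("polarTail")
      s[c(4, 7)] <- switch(class,
        strong = pick("acidic", 2),
        weak = {
          which47 <- sample(c(4, 7), 1)
          out <- pick("neutral", 2)
          out[if (which47 == 4) 1 else 2] <- pick("acidic")
          out
        },
        natural = pick("neutral", 2),
        DR = pick("basicOrNeutral", 2))
      s
    })
  }
  st <- list(atoms = list(), coords = list())
  for (k in 1:10) {
    ca <- c(17.7 - 2.0 * (k - 1), 0.8, 2.6)
    bb <- glyBackbone(ca)
    bb[, 2] <- -bb[, 2] * 0.4  # keep the backbone tight to the axis
    bb["CA", ] <- ca
    tpl <- sideChainTemplate(seq3[k])
    if (!is.null(tpl)) {
      # p4/p7 descend to the pocket mouth; the hydrophobic anchors p1/p6
      # slot against the opposite wall, p10 reaches the Asp-bearing wall,
      # and the remaining side chains point out of the groove
      dir <- if (k %in% c(4, 7)) c(0, -0.15, -0.99)
             else if (k %in% c(1, 6)) c(0, -0.75, -0.66)
             else if (k == 10) c(0, 0.80, -0.60)
             else c(0, 0.55 * (-1)^k, 0.84)
      dir <- dir / sqrt(sum(dir^2))
      perp <- c(1, 0, 0)
      zax <- dir
      xax <- perp - sum(perp * zax) * zax
      xax <- xax / sqrt(sum(xax^2))
      yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
               zax[3] * xax[1] - zax[1] * xax[3],
               zax[1] * xax[2] - zax[2] * xax[1])
      pos <- t(cbind(xax, yax, zax) %*% t(tpl)) +
        matrix(ca, nrow(tpl), 3, byrow = TRUE)
      bb <- rbind(bb, pos)
    }
    st <- appendResidue(st, "P", k, seq3[k], rownames(bb), bb)
  }
  atoms <- do.call(rbind, st$atoms)
  co <- do.call(rbind, st$coords)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  co <- co + withSeed(seed + 7L, matrix(stats::rnorm(length(co), 0, 0.10),
                                        nrow(co), 3))
  s <- newStructure(atoms, co,
                    title = sprintf("synthetic %s peptide (seed %d)", class, seed))
  list(structure = s,
       truth = list(class = class, sequence = paste(seq3, collapse = "-"),
                    seed = seed))
}

#' Synthetic trajectory with known pocket-width ground truth
#'
#' Generates a multi-frame trajectory over the input structure in which
#' the groove either stays static, opens, or closes at the D3-D5 pairs:
#' the chain-B residues of those pairs are displaced across the groove
#' with a saturating ramp to `plateau`, while D1/D2 residues stay put.
#' Gaussian jitter of `noiseSd` is added to every atom in every frame.
#'
#' @param structure a [Structure-class] on which the five default pocket
#'   pairs resolve (e.g. a mini-receptor or receptor-peptide complex).
#' @param mode `"static"`, `"opening"` or `"closing_D3toD5"`.
#' @param noiseSd Gaussian jitter per coordinate, Angstrom.
#' @param nFrames number of frames (>= 10).
#' @param seed RNG seed.
#' @param plateau asymptotic displacement of the moving wall, Angstrom
#'   (default 2).
#' @return list with `trajectory` ([Trajectory-class],
#'   `source = "generator"`) and `truth` (per-pair intended trend and
#'   plateau).
#' @export
makeTrajectory <- function(structure, mode = c("static", "opening",
                                               "closing_D3toD5"),
                           noiseSd = 0.1, nFrames = 50L, seed = 1L,
                           plateau = 2) {
  mode <- match.arg(mode)
  if (nFrames < 10) stop("need at least 10 frames")
  pairs <- defaultPocketPairs()
  moving <- selectIndices(structure, chain = "B",
                          resSeq = pairs$res2[3:5])
  if (!length(moving) && mode != "static")
    stop("no D3-D5 chain-B residues on this structure")
  dirSign <- switch(mode, static = 0, opening = 1, closing_D3toD5 = -1)
  co0 <- structure@coords
  xyz <- array(NA_real_, c(nFrames, nrow(co0), 3))
  noise <- withSeed(seed, array(stats::rnorm(nFrames * length(co0), 0,
                                             noiseSd),
                                c(nFrames, nrow(co0), 3)))
  for (f in seq_len(nFrames)) {
    disp <- dirSign * plateau * (1 - exp(-3 * (f - 1) / (nFrames - 1)))
    co <- co0
    if (length(moving)) co[moving, 2] <- co[moving, 2] + disp
    xyz[f, , ] <- co + noise[f, , ]
  }
  trend <- c("flat", "flat",
             rep(switch(mode, static = "flat", opening = "up",
                        closing_D3toD5 = "down"), 3))
  list(trajectory = new("Trajectory", topology = structure, xyz = xyz,
                        source = "generator"),
       truth = list(mode = mode, pairTrend = stats::setNames(trend, pairs$label),
                    plateau = dirSign * plateau, noiseSd = noiseSd,
                    seed = seed))
}
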