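# Template-based side-chain construction. Templates are idealized heavy-atom
# geometries in a local frame with CA at the origin and the CB direction
# along +z; realism is limited to bond lengths and branch splay, which is
# sufficient for electrostatics- and geometry-level modelling.

backboneNames <- c("N", "CA", "C", "O", "OXT")

sideChainTemplate <- function(resName) {
  spine <- function(names) {
    k <- seq_along(names)
    cbind(x = 0.45 * (k %% 2), y = 0, z = 1.53 + 1.30 * (k - 1),
          deparse.level = 0) -> m
    rownames(m) <- names
    m
  }
  branch <- function(parent, names, dx = c(-1.1, 1.1), dz = 1.15) {
    m <- cbind(x = parent[1] + dx, y = 0, z = parent[3] + dz)
    rownames(m) <- names
    m
  }
  ring6 <- function(cg, names) {
    # planar six-ring grown from CG along +z
    m <- rbind(c(-1.20, 0, 0.70), c(1.20, 0, 0.70), c(-1.20, 0, 2.09),
               c(1.20, 0, 2.09), c(0, 0, 2.79))
    m <- sweep(m, 2, -cg)
    rownames(m) <- names
    m
  }
  tpl <- switch(resName,
    GLY = NULL,
    ALA = spine("CB"),
    SER = spine(c("CB", "OG")),
    CYS = spine(c("CB", "SG")),
    THR = { s <- spine("CB"); rbind(s, branch(s["CB", ], c("OG1", "CG2"))) },
    VAL = { s <- spine("CB"); rbind(s, branch(s["CB", ], c("CG1", "CG2"))) },
    LEU = { s <- spine(c("CB", "CG"))
            rbind(s, branch(s["CG", ], c("CD1", "CD2"))) },
    ILE = { s <- spine(c("CB", "CG1", "CD1"))
            rbind(s, branch(s["CB", ], c("CG2"), dx = -1.2)) },
    PRO = spine(c("CB", "CG", "CD")),
    MET = spine(c("CB", "CG", "SD", "CE")),
    ASP = { s <- spine(c("CB", "CG"))
            rbind(s, branch(s["CG", ], c("OD1", "OD2"))) },
    ASN = { s <- spine(c("CB", "CG"))
            rbind(s, branch(s["CG", ], c("OD1", "ND2"))) },
    GLU = { s <- spine(c("CB", "CG", "CD"))
            rbind(s, branch(s["CD", ], c("OE1", "OE2"))) },
    GLN = { s <- spine(c("CB", "CG", "CD"))
            rbind(s, branch(s["CD", ], c("OE1", "NE2"))) },
    LYS = spine(c("CB", "CG", "CD", "CE", "NZ")),
    ARG = { s <- spine(c("CB", "CG", "CD", "NE", "CZ"))
            rbind(s, branch(s["CZ", ], c("NH1", "NH2"))) },
    HIS = { s <- spine(c("CB", "CG"))
            rbind(s, branch(s["CG", ], c("ND1", "CD2")),
                  branch(s["CG", ], c("CE1", "NE2"), dx = c(-0.75, 0.75),
                         dz = 2.15)) },
    PHE = { s <- spine(c("CB", "CG"))
            rbind(s, ring6(s["CG", ], c("CD1", "CD2", "CE1", "CE2", "CZ"))) },
    TYR = { s <- spine(c("CB", "CG"))
            r <- ring6(s["CG", ], c("CD1", "CD2", "CE1", "CE2", "CZ"))
            rbind(s, r, matrix(r["CZ", ] + c(0, 0, 1.40), nrow = 1,
                               dimnames = list("OH"))) },
    TRP = { s <- spine(c("CB", "CG"))
            ring <- rbind(CD1 = c(-1.10, 0, 0.70), NE1 = c(-0.75, 0, 2.05),
                          CD2 = c(1.15, 0, 0.65), CE2 = c(0.55, 0, 1.95),
                          CE3 = c(2.50, 0, 0.85), CZ2 = c(1.20, 0, 3.05),
                          CZ3 = c(3.15, 0, 1.95), CH2 = c(2.45, 0, 3.05))
            rbind(s, sweep(ring, 2, -s["CG", ])) },
    stop("unknown residue type: ", resName)
  )
  tpl
}

# Orthonormal frame at a residue: z along the idealized CB direction
# (tetrahedral, away from N and C), x perpendicular in the N-CA-C plane.
residueFrame <- function(nPos, caPos, cPos) {
  u1 <- nPos - caPos
  u2 <- cPos - caPos
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2
  bis <- bis / sqrt(sum(bis^2))
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / sqrt(sum(perp^2))
  zax <- -bis * cos(0.9626) + perp * sin(0.9626)  # ~55 deg out of plane
  zax <- zax / sqrt(sum(zax^2))
  xax <- u1 - sum(u1 * zax) * zax
  xax <- xax / sqrt(sum(xax^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  cbind(xax, yax, zax)
}

rotZ <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3)
}

#' Replace the side chain of one residue
#'
#' Removes the residue's side-chain atoms and grafts an idealized
#' template side chain of the requested type onto the unchanged backbone.
#' Backbone atoms (N, CA, C, O, OXT) of all residues are never moved. The
#' seed perturbs the side-chain dihedral about the CA-CB axis so repeated
#' builds explore slightly different rotamers deterministically.
#'
#' After mutation the structure must be re-parameterized
#' (parameters are cleared because the atom roster changed).
#'
#' @param structure a [Structure-class].
#' @param chain,resSeq identify the residue to mutate.
#' @param newRes target 3-letter residue code.
#' @param seed integer controlling the deterministic dihedral placement.
#' @return the mutated [Structure-class].
#' @export
mutateSideChain <- function(structure, chain, resSeq, newRes, seed = 1L) {
  at <- structure@atoms
  resIdx <- which(at$chainId == chain & at$resSeq == resSeq)
  if (!length(resIdx)) stop("no residue ", resSeq, " in chain ", chain)
  if (at$resName[resIdx[1]] == newRes) return(structure)
  bbIdx <- resIdx[at$name[resIdx] %in% backboneNames]
  need <- c("N", "CA", "C")
  have <- at$name[bbIdx]
  if (!all(need %in% have))
    stop("residue ", chain, ":", resSeq, " lacks backbone atoms: ",
         paste(setdiff(need, have), collapse = ", "))
  tpl <- sideChainTemplate(newRes)
  co <- structure@coords
  gp <- function(nm) co[resIdx[at$name[resIdx] == nm][1], ]
  keep <- setdiff(seq_len(nrow(at)), setdiff(resIdx, bbIdx))
  atoms2 <- at[keep, , drop = FALSE]
  co2 <- co[keep, , drop = FALSE]
  atoms2$resName[atoms2$chainId == chain & atoms2$resSeq == resSeq] <- newRes
  if (!is.null(tpl)) {
    fr <- residueFrame(gp("N"), gp("CA"), gp("C"))
    theta <- withSeed(seed, stats::runif(1, -pi / 6, pi / 6))
    pos <- t(fr %*% rotZ(theta) %*% t(tpl)) +
      matrix(gp("CA"), nrow(tpl), 3, byrow = TRUE)
    lastBB <- max(which(atoms2$chainId == chain & atoms2$resSeq == resSeq))
    ins <- data.frame(serial = 0L, name = rownames(tpl),
                      element = substr(gsub("[0-9]", "", rownames(tpl)), 1, 1),
                      resName = newRes, resSeq = as.integer(resSeq),
                      insert = "", chainId = chain, het = FALSE,
                      stringsAsFactors = FALSE)
    atoms2 <- rbind(atoms2[seq_len(lastBB), , drop = FALSE], ins,
                    atoms2[-seq_len(lastBB), , drop = FALSE])
    co2 <- rbind(co2[seq_len(lastBB), , drop = FALSE], pos,
                 co2[-seq_len(lastBB), , drop = FALSE])
  }
  atoms2$serial <- seq_len(nrow(atoms2))
  rownames(atoms2) <- NULL
  newStructure(atoms2, co2, title = structure@title)
}
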