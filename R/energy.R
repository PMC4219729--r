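# Covalent bond detection by interatomic distance; used for 1-2/1-3
# exclusions in whole-structure nonbonded sums and for minimizer restraints.
bondPairs <- function(structure) {
  co <- structure@coords
  n <- nrow(co)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- pairDist(co)
  elem <- structure@atoms$element
  cut <- outer(ifelse(elem == "S", 1.15, 0.95),
               ifelse(elem == "S", 1.15, 0.95), "+")
  sameMol <- outer(structure@atoms$chainId, structure@atoms$chainId, "==")
  hit <- which(d < cut & upper.tri(d) & sameMol, arr.ind = TRUE)
  hit
}

# 1-2 and 1-3 exclusion mask (logical n x n, TRUE = excluded).
exclusionMask <- function(structure, bonds = bondPairs(structure)) {
  n <- nAtoms(structure)
  adj <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    adj[bonds] <- TRUE
    adj[bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  one3 <- (adj %*% adj) > 0
  excl <- adj | one3
  diag(excl) <- TRUE
  excl
}

#' Lennard-Jones (van der Waals) energy
#'
#' 12-6 potential with Lorentz-Berthelot combining:
#' `rmin_ij = rminHalf_i + rminHalf_j`, `eps_ij = sqrt(eps_i eps_j)`,
#' `E = eps_ij ((rmin/r)^12 - 2 (rmin/r)^6)`. In whole-structure mode,
#' covalently bonded (1-2) and angle (1-3) pairs are excluded; in
#' cross-partition mode all A-B pairs count.
#'
#' @param structure a parameterized [Structure-class].
#' @param partitionA,partitionB optional disjoint atom index sets for
#'   cross-partition mode.
#' @param cutoff optional distance cutoff, Angstrom (default none).
#' @return energy, kcal/mol.
#' @export
ljEnergy <- function(structure, partitionA = NULL, partitionB = NULL,
                     cutoff = NULL) {
  eps <- structure@ljEpsilon
  rmh <- structure@ljRminHalf
  if (anyNA(eps)) stop("structure is not parameterized")
  co <- structure@coords
  if (!is.null(partitionA)) {
    if (is.null(partitionB)) stop("both partitions are required")
    d <- pairDist(co[partitionA, , drop = FALSE],
                  co[partitionB, , drop = FALSE])
    if (any(d < 0.1)) stop("atoms closer than 0.1 Angstrom")
    e <- sqrt(outer(eps[partitionA], eps[partitionB]))
    rm <- outer(rmh[partitionA], rmh[partitionB], "+")
    keep <- if (is.null(cutoff)) TRUE else d <= cutoff
    sr6 <- (rm / d)^6
    return(sum((e * (sr6^2 - 2 * sr6))[keep]))
  }
  n <- nrow(co)
  if (n < 2) return(0)
  d <- pairDist(co)
  excl <- exclusionMask(structure)
  off <- upper.tri(d) & !excl
  if (any(d[off] < 0.1)) stop("atoms closer than 0.1 Angstrom")
  e <- sqrt(outer(eps, eps))
  rm <- outer(rmh, rmh, "+")
  keep <- off & (if (is.null(cutoff)) TRUE else d <= cutoff)
  sr6 <- (rm / pmax(d, 1e-12))^6
  sum((e * (sr6^2 - 2 * sr6))[keep])
}

#' Total free-energy breakdown of a structure
#'
#' The model free energy `G = E_Coul + E_solv(polar) + E_vdW`: Coulomb
#' energy at the interior dielectric, polar solvation via
#' [reactionFieldEnergy()], and Lennard-Jones energy. Nonpolar solvation
#' and entropic terms are excluded from the model by construction.
#'
#' @param structure a parameterized [Structure-class].
#' @param config a [SolverConfig-class].
#' @param geom optional grid geometry (from [buildGrid()]); pass a
#'   common geometry when differencing energies across partitions so
#'   per-atom grid self-energy artifacts cancel.
#' @return an [EnergyBreakdown-class].
#' @export
totalG <- function(structure, config = new("SolverConfig"), geom = NULL) {
  eCoul <- coulombEnergy(structure, eps = config@epsIn)
  eSolv <- reactionFieldEnergy(structure, config, geom = geom)
  eVdw <- ljEnergy(structure)
  new("EnergyBreakdown", eCoul = eCoul, eSolvPolar = eSolv, eVdw = eVdw,
      gTotal = eCoul + eSolv + eVdw)
}
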