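#' Solve the Poisson equation for a structure on a finite-difference grid
#'
#' Successive over-relaxation solution of
#' `div(eps grad phi) = -4 pi k rho` in a two-dielectric model: `epsIn`
#' inside the atom-sphere union, `epsOut` outside, with screened-Coulomb
#' boundary values on the grid faces. Potentials are reported in
#' kcal/(mol e).
#'
#' @param structure a parameterized [Structure-class].
#' @param config a [SolverConfig-class].
#' @param geom optional grid geometry (from [buildGrid()]); computed from
#'   the structure when omitted.
#' @param uniform if `TRUE`, solve with `epsIn` everywhere (the reference
#'   state used for reaction-field energies).
#' @param charges optional replacement charge vector (one per atom).
#' @return a [PotentialGrid-class]; attributes `iterations` and
#'   `residual` carry convergence diagnostics.
#' @export
solvePoisson <- function(structure, config = new("SolverConfig"),
                         geom = NULL, uniform = FALSE, charges = NULL) {
  if (!is.null(charges)) structure@charge <- charges
  if (is.null(geom)) geom <- buildGrid(structure, config)
  eps <- faceEps(structure, geom, config, uniform = uniform)
  solvePoissonRaw(structure, config, geom, eps, uniform = uniform)
}

# Core driver reusable with precomputed dielectric maps (the pKa module
# solves many charge sets on one geometry).
solvePoissonRaw <- function(structure, config, geom, eps, uniform = FALSE) {
  d <- geom$dims
  h <- geom$spacing
  qArr <- mapCharges(structure, geom)
  bEps <- if (uniform) config@epsIn else config@epsOut
  phi0 <- coulombField(structure, geom, bEps)
  src <- 4 * pi * KE * qArr / h
  omega <- 2 / (1 + sin(pi / max(d)))
  res <- cpp_sor(as.numeric(phi0), as.numeric(src), d,
                 eps$ex, eps$ey, eps$ez, omega, config@tol, config@maxIter)
  if (!res$converged)
    stop(sprintf("Poisson solver did not converge in %d iterations (residual %.3g)",
                 config@maxIter, res$residual))
  grid <- new("PotentialGrid", origin = geom$origin, spacing = h,
              dims = d, values = array(res$phi, d))
  attr(grid, "iterations") <- res$iterations
  attr(grid, "residual") <- res$residual
  grid
}

#' Interpolate grid potential at arbitrary points
#'
#' Trilinear interpolation of a [PotentialGrid-class].
#'
#' @param grid a [PotentialGrid-class].
#' @param points n x 3 matrix of coordinates, Angstrom.
#' @return numeric vector of potentials, kcal/(mol e).
#' @export
potentialAt <- function(grid, points) {
  points <- matrix(points, ncol = 3)
  d <- grid@dims
  rel <- sweep(points, 2, grid@origin) / grid@spacing
  i0 <- floor(rel)
  if (any(i0 < 0) || any(i0 > matrix(d - 2, nrow(rel), 3, byrow = TRUE)))
    stop("point outside grid")
  fr <- rel - i0
  out <- numeric(nrow(points))
  v <- grid@values
  for (p in seq_len(nrow(points))) {
    ii <- i0[p, 1] + 1L; jj <- i0[p, 2] + 1L; kk <- i0[p, 3] + 1L
    fx <- fr[p, 1]; fy <- fr[p, 2]; fz <- fr[p, 3]
    c00 <- v[ii, jj, kk] * (1 - fx) + v[ii + 1, jj, kk] * fx
    c10 <- v[ii, jj + 1, kk] * (1 - fx) + v[ii + 1, jj + 1, kk] * fx
    c01 <- v[ii, jj, kk + 1] * (1 - fx) + v[ii + 1, jj, kk + 1] * fx
    c11 <- v[ii, jj + 1, kk + 1] * (1 - fx) + v[ii + 1, jj + 1, kk + 1] * fx
    out[p] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
      (c01 * (1 - fy) + c11 * fy) * fz
  }
  out
}

#' Polar (reaction-field) solvation energy
#'
#' Two Poisson runs on an identical grid - solvent dielectric `epsOut`
#' versus a uniform `epsIn` reference - whose difference cancels the grid
#' self-energy:
#' `dG = 1/2 sum_i q_i (phi_i(solvated) - phi_i(uniform))`.
#' Negative for any net-charged solute when `epsOut > epsIn`.
#'
#' @inheritParams solvePoisson
#' @return polar solvation energy, kcal/mol.
#' @export
reactionFieldEnergy <- function(structure, config = new("SolverConfig"),
                                geom = NULL) {
  q <- structure@charge
  if (anyNA(q)) stop("structure is not parameterized")
  if (all(q == 0)) return(0)
  if (is.null(geom)) geom <- buildGrid(structure, config)
  gS <- solvePoisson(structure, config, geom = geom, uniform = FALSE)
  gU <- solvePoisson(structure, config, geom = geom, uniform = TRUE)
  phiS <- potentialAt(gS, structure@coords)
  phiU <- potentialAt(gU, structure@coords)
  0.5 * sum(q * (phiS - phiU))
}

#' Pairwise Coulomb energy
#'
#' `sum_{i<j} k q_i q_j / (eps r_ij)` with `k = 332.0636`
#' kcal Angstrom/(mol e^2). With a partition, only cross pairs
#' (i in A, j in B) are summed.
#'
#' @param structure a parameterized [Structure-class].
#' @param eps uniform dielectric constant.
#' @param partitionA,partitionB optional disjoint atom index sets; when
#'   given, only A-B cross pairs contribute.
#' @return energy, kcal/mol.
#' @export
coulombEnergy <- function(structure, eps = 1, partitionA = NULL,
                          partitionB = NULL) {
  q <- structure@charge
  if (anyNA(q)) stop("structure is not parameterized")
  co <- structure@coords
  if (nrow(co) < 2 && is.null(partitionA)) return(0)
  if (!is.null(partitionA)) {
    if (is.null(partitionB)) stop("both partitions are required")
    d <- pairDist(co[partitionA, , drop = FALSE], co[partitionB, , drop = FALSE])
    if (any(d < 1e-6 & outer(q[partitionA] != 0, q[partitionB] != 0)))
      stop("coincident charged atoms")
    return(KE / eps * sum(outer(q[partitionA], q[partitionB]) / pmax(d, 1e-12)))
  }
  d <- pairDist(co)
  qq <- outer(q, q)
  off <- upper.tri(d)
  if (any(d[off] < 1e-6 & qq[off] != 0)) stop("coincident charged atoms")
  KE / eps * sum(qq[off] / pmax(d[off], 1e-12))
}
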