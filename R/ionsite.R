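#' Surface-shell grid points around a solute
#'
#' Grid nodes whose distance to the nearest atom surface (centre distance
#' minus vdW radius) lies within a shell, the candidate positions for a
#' surface-bound ion. The default shell spans from one ion radius to one
#' ion radius + 2 Angstrom off the surface.
#'
#' @param structure a [Structure-class] (radii used; fallback radii for
#'   bare structures).
#' @param grid a [PotentialGrid-class] for the bare solute.
#' @param shell numeric(2), `[dMin, dMax]` off the atom surface, Angstrom.
#' @return data.frame with node coordinates (`x`, `y`, `z`), `potential`
#'   (kcal/(mol e)) and `minDist` (Angstrom off the surface).
#' @export
surfaceShellPoints <- function(structure, grid, shell) {
  if (shell[1] > shell[2]) stop("shell must satisfy dMin <= dMax")
  d <- grid@dims
  ax <- lapply(1:3, function(k) grid@origin[k] + grid@spacing * (seq_len(d[k]) - 1))
  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  rad <- clashRadii(structure)
  # distance to nearest atom surface, chunked to bound memory
  n <- nrow(nodes)
  minDist <- numeric(n)
  step <- 20000L
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(n, s + step - 1L)
    dm <- pairDist(nodes[idx, , drop = FALSE], structure@coords)
    minDist[idx] <- apply(sweep(dm, 2, rad), 1, min)
  }
  keep <- minDist >= shell[1] & minDist <= shell[2]
  if (!any(keep))
    stop("no grid nodes fall in the surface shell; use a finer scale")
  data.frame(x = nodes[keep, 1], y = nodes[keep, 2], z = nodes[keep, 3],
             potential = as.numeric(grid@values)[keep],
             minDist = minDist[keep])
}

#' Rank and cluster candidate ion positions by potential
#'
#' Keeps only sign-compatible points (negative potential for cations,
#' positive for anions), sorts by absolute potential in descending order
#' and clusters greedily: the strongest remaining point seeds a cluster
#' and absorbs every point within `clusterRadius`; the seed (the
#' cluster's extremum) represents the cluster and the order of cluster
#' creation is the Rank. Ties are broken by node order (x fastest), which
#' is deterministic.
#'
#' @param candidates data.frame from [surfaceShellPoints()].
#' @param ion an [IonSpec-class] (the charge sign selects compatible
#'   points).
#' @param clusterRadius Angstrom (default 3).
#' @return data.frame of cluster representatives with columns `rank`,
#'   `x`, `y`, `z`, `potential`, `clusterSize`, `minDist`; zero rows
#'   (with a warning) when no sign-compatible point exists.
#' @export
rankAndCluster <- function(candidates, ion = ionSpec(), clusterRadius = 3) {
  if (!nrow(candidates)) stop("no candidate points supplied")
  ok <- if (ion@charge > 0) candidates$potential < 0 else candidates$potential > 0
  cand <- candidates[ok, , drop = FALSE]
  out <- data.frame(rank = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), potential = numeric(0),
                    clusterSize = integer(0), minDist = numeric(0))
  if (!nrow(cand)) {
    warning("no sign-compatible surface points for this ion")
    return(out)
  }
  ord <- order(-abs(cand$potential), seq_len(nrow(cand)))
  cand <- cand[ord, , drop = FALSE]
  pos <- as.matrix(cand[, c("x", "y", "z")])
  alive <- rep(TRUE, nrow(cand))
  rk <- 0L
  rows <- list()
  while (any(alive)) {
    seed <- which(alive)[1]
    dd <- sqrt(colSums((t(pos) - pos[seed, ])^2))
    members <- alive & dd <= clusterRadius
    rk <- rk + 1L
    rows[[rk]] <- data.frame(rank = rk, x = pos[seed, 1], y = pos[seed, 2],
                             z = pos[seed, 3],
                             potential = cand$potential[seed],
                             clusterSize = sum(members),
                             minDist = cand$minDist[seed])
    alive <- alive & !members
  }
  do.call(rbind, rows)
}

#' Relax a placed ion to the nearest local energy minimum
#'
#' Gradient descent of the ion position alone (all other atoms fixed) on
#' the Lennard-Jones + distance-dependent-dielectric Coulomb field of the
#' host. Grid-ranked candidate sites are only resolved to one grid cell;
#' this settles the cation into its coordination geometry (e.g. between
#' carboxylate oxygens) before complex assembly.
#'
#' @param structure parameterized host [Structure-class].
#' @param ion an [IonSpec-class].
#' @param position starting 3-vector, Angstrom; a matrix of candidate
#'   rows triggers multi-start refinement returning the lowest-energy
#'   minimum.
#' @param maxSteps iteration cap.
#' @return the relaxed position (3-vector, with the final energy in
#'   attribute `"energy"`).
#' @export
refineIonPosition <- function(structure, ion, position, maxSteps = 200L) {
  # multi-start: a matrix of candidate positions is refined row-wise and
  # the lowest-energy minimum wins, so the ion is not trapped in a
  # shallow edge basin of the pocket
  if (is.matrix(position) && nrow(position) > 1) {
    outs <- lapply(seq_len(nrow(position)), function(k)
      refineIonPosition(structure, ion, as.numeric(position[k, ]), maxSteps))
    es <- vapply(outs, function(p) attr(p, "energy"), numeric(1))
    return(outs[[which.min(es)]])
  }
  position <- as.numeric(position)
  q <- structure@charge
  eps <- structure@ljEpsilon
  rmh <- structure@ljRminHalf
  if (anyNA(q)) stop("structure is not parameterized")
  e12 <- sqrt(0.01 * eps)
  rmin <- ion@radius / 2 + rmh
  energy <- function(p) {
    dv <- sweep(structure@coords, 2, p)
    r <- pmax(sqrt(rowSums(dv^2)), 1e-6)
    sr6 <- (rmin / r)^6
    list(E = sum(e12 * (sr6^2 - 2 * sr6) + KE * ion@charge * q / (4 * r^2)),
         grad = colSums(dv * (e12 * (-12 * sr6^2 + 12 * sr6) / r -
                                2 * KE * ion@charge * q / (4 * r^3)) / r) * -1)
  }
  p <- position
  eg <- energy(p)
  step <- 1e-3
  for (it in seq_len(maxSteps)) {
    if (max(abs(eg$grad)) < 1e-3) break
    ok <- FALSE
    for (try in 1:20) {
      pNew <- p - step * eg$grad
      egNew <- energy(pNew)
      if (is.finite(egNew$E) && egNew$E <= eg$E) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    p <- pNew
    eg <- egNew
    step <- step * 1.2
  }
  attr(p, "energy") <- eg$E
  p
}

#' Predict the top-ranked surface binding site for an ion
#'
#' Solves the Poisson equation for the bare solute, collects
#' surface-shell nodes, ranks and clusters them, and returns the first
#' ranked plausible position - plausible meaning the ion does not
#' overlap any atom (centre distance at least ion radius + atom radius
#' - 0.4 Angstrom).
#'
#' @param structure a parameterized [Structure-class] (assigned
#'   automatically if bare).
#' @param ion an [IonSpec-class].
#' @param config a [SolverConfig-class].
#' @param shell surface shell off the vdW surface, Angstrom; default
#'   `c(ion radius, ion radius + 2)`.
#' @param clusterRadius Angstrom (default 3).
#' @return list with `position` (3-vector), `potential`, `rank`,
#'   `clusterSize`, and `sites` (the full ranked table).
#' @export
predictIonSite <- function(structure, ion = ionSpec(),
                           config = new("SolverConfig"), shell = NULL,
                           clusterRadius = 3) {
  if (!isParameterized(structure))
    structure <- assignParameters(structure, ion = ion)
  if (is.null(shell)) shell <- c(ion@radius, ion@radius + 2)
  grid <- solvePoisson(structure, config)
  cand <- surfaceShellPoints(structure, grid, shell)
  sites <- suppressWarnings(rankAndCluster(cand, ion, clusterRadius))
  if (!nrow(sites)) stop("no plausible ion site: no sign-compatible points")
  rad <- clashRadii(structure)
  plausible <- function(p) {
    dd <- sqrt(colSums((t(structure@coords) - p)^2))
    all(dd >= ion@radius + rad - 0.4)
  }
  for (i in seq_len(nrow(sites))) {
    p <- as.numeric(sites[i, c("x", "y", "z")])
    if (plausible(p))
      return(list(position = p, potential = sites$potential[i],
                  rank = sites$rank[i], clusterSize = sites$clusterSize[i],
                  sites = sites))
  }
  stop("no plausible ion site: all ranked positions overlap the solute")
}
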