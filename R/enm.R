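#' Sample conformations with elastic-network Langevin dynamics
#'
#' Coarse-grains the structure to one bead per residue (the CA atom, or
#' the first atom of residues without one), connects beads closer than
#' `enmCutoff` with harmonic springs (`E = 1/2 k (d - d0)^2`, native
#' distances as rest lengths), and integrates Langevin dynamics with the
#' BAOAB splitting at the configured temperature. Snapshots are stored
#' every `snapshotEvery` steps (plus the initial frame) and runs are
#' bitwise reproducible for a given seed.
#'
#' This sampler stands in for production molecular dynamics at desk
#' scale; the downstream trajectory analytics consume imported
#' multi-model PDB trajectories just as well.
#'
#' @param structure a [Structure-class].
#' @param config a [DynamicsConfig-class].
#' @param restrainedSelection optional bead indices harmonically tethered
#'   to their starting positions (spring constant `enmK`).
#' @return a [Trajectory-class] over the bead topology,
#'   `source = "sampler"`.
#' @export
enmLangevinSample <- function(structure, config = new("DynamicsConfig"),
                              restrainedSelection = NULL) {
  caIdx <- selectIndices(structure, atomName = "CA")
  beads <- if (length(caIdx)) caIdx else
    vapply(residueIndexList(structure), `[`, integer(1), 1)
  topo <- subsetStructure(structure, beads)
  x <- topo@coords
  n <- nrow(x)
  d <- pairDist(x)
  sel <- which(d < config@enmCutoff & upper.tri(d), arr.ind = TRUE)
  if (!nrow(sel) && n > 1) warning("no springs within cutoff; beads are free")
  # connectivity check (flood fill over springs)
  if (n > 1) {
    comp <- seq_len(n)
    for (r in seq_len(nrow(sel))) {
      a <- comp[sel[r, 1]]; b <- comp[sel[r, 2]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) > 1)
      warning("elastic network is disconnected (",
              length(unique(comp)), " components); simulating as-is")
  }
  d0 <- d[sel]
  kT <- KB * config@temperature
  dt <- config@dt
  c1 <- exp(-config@friction * dt)
  c2 <- sqrt(max(0, (1 - c1^2) * kT))
  force <- function(pos) {
    f <- matrix(0, n, 3)
    if (nrow(sel)) {
      dv <- pos[sel[, 1], , drop = FALSE] - pos[sel[, 2], , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      fac <- -config@enmK * (r - d0) / pmax(r, 1e-8)
      fv <- dv * fac
      acc <- rowsum(rbind(fv, -fv), group = c(sel[, 1], sel[, 2]))
      tgt <- as.integer(rownames(acc))
      f[tgt, ] <- f[tgt, ] + acc
    }
    if (length(restrainedSelection))
      f[restrainedSelection, ] <- f[restrainedSelection, ] -
        config@enmK * (pos[restrainedSelection, , drop = FALSE] -
                         x[restrainedSelection, , drop = FALSE])
    f
  }
  nSnap <- floor(config@nSteps / config@snapshotEvery)
  xyz <- array(NA_real_, c(nSnap + 1L, n, 3))
  xyz[1, , ] <- x
  withSeed(config@seed, {
    pos <- x
    vel <- matrix(0, n, 3)
    f <- force(pos)
    snap <- 1L
    for (s in seq_len(config@nSteps)) {
      vel <- vel + 0.5 * dt * f
      pos <- pos + 0.5 * dt * vel
      vel <- c1 * vel + c2 * matrix(stats::rnorm(3 * n), n, 3)
      pos <- pos + 0.5 * dt * vel
      f <- force(pos)
      vel <- vel + 0.5 * dt * f
      if (s %% config@snapshotEvery == 0L) {
        snap <- snap + 1L
        xyz[snap, , ] <- pos
      }
    }
  })
  new("Trajectory", topology = topo, xyz = xyz, source = "sampler")
}
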