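#' Derive the finite-difference grid geometry for a structure
#'
#' Builds a cubic grid centred on the geometric centre of the molecule.
#' The molecule's largest dimension (atom extents including vdW radii)
#' occupies `perfil` percent of the grid edge, and the node count is the
#' next odd integer so a centre node exists.
#'
#' @param structure a parameterized [Structure-class] (radii required).
#' @param config a [SolverConfig-class].
#' @return list with `origin` (3-vector, Angstrom), `spacing` and `dims`.
#' @export
buildGrid <- function(structure, config = new("SolverConfig")) {
  if (nAtoms(structure) == 0) stop("cannot grid an empty structure")
  r <- clashRadii(structure)
  co <- structure@coords
  ext <- max(apply(co + r, 2, max) - apply(co - r, 2, min))
  edge <- ext / (config@perfil / 100)
  n <- ceiling(edge / config@scale + 1)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, 5)
  center <- (apply(co, 2, max) + apply(co, 2, min)) / 2
  origin <- center - (n - 1) / 2 * config@scale
  list(origin = as.numeric(origin), spacing = config@scale,
       dims = as.integer(c(n, n, n)))
}

#' Spread atomic charges onto grid nodes
#'
#' Trilinear distribution of each atomic charge to its eight surrounding
#' nodes; total gridded charge equals total atomic charge to machine
#' precision.
#'
#' @param structure a parameterized [Structure-class].
#' @param geom grid geometry from [buildGrid()].
#' @return 3-d array of node charges, e.
#' @export
mapCharges <- function(structure, geom) {
  q <- structure@charge
  if (anyNA(q)) stop("structure is not parameterized")
  h <- geom$spacing
  d <- geom$dims
  rel <- sweep(structure@coords, 2, geom$origin) / h
  i0 <- floor(rel)
  if (any(i0 < 0) || any(i0 > matrix(d - 2, nrow(rel), 3, byrow = TRUE)))
    stop("atom outside grid interior; enlarge the grid or reduce perfil")
  fr <- rel - i0
  arr <- array(0, d)
  for (a in seq_len(nrow(rel))) {
    if (q[a] == 0) next
    ii <- i0[a, 1] + 1L; jj <- i0[a, 2] + 1L; kk <- i0[a, 3] + 1L
    fx <- fr[a, 1]; fy <- fr[a, 2]; fz <- fr[a, 3]
    wx <- c(1 - fx, fx); wy <- c(1 - fy, fy); wz <- c(1 - fz, fz)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
      arr[ii + dx, jj + dy, kk + dz] <- arr[ii + dx, jj + dy, kk + dz] +
        q[a] * wx[dx + 1] * wy[dy + 1] * wz[dz + 1]
  }
  arr
}

# Face-centred dielectric maps (harmonic average weighted by the fraction
# of each grid link inside the probe-inflated atom-sphere union).
faceEps <- function(structure, geom, config, uniform = FALSE) {
  d <- geom$dims
  if (uniform) {
    return(list(ex = rep(config@epsIn, (d[1] - 1) * d[2] * d[3]),
                ey = rep(config@epsIn, d[1] * (d[2] - 1) * d[3]),
                ez = rep(config@epsIn, d[1] * d[2] * (d[3] - 1))))
  }
  cpp_face_eps(geom$origin, geom$spacing, d, structure@coords,
               clashRadii(structure) + config@probeRadius,
               config@epsIn, config@epsOut)
}

# Screened-Coulomb field of all charges at every grid node: the boundary
# condition on the six faces and the solver's initial guess everywhere.
coulombField <- function(structure, geom, eps) {
  array(cpp_coulomb_phi(geom$origin, geom$spacing, geom$dims,
                        structure@coords, structure@charge, eps, KE),
        geom$dims)
}

# Screened-Coulomb boundary condition on the six faces only (interior 0);
# retained for boundary-specific diagnostics.
boundaryPhi <- function(structure, geom, eps) {
  d <- geom$dims
  phi <- array(0, d)
  q <- structure@charge
  pos <- structure@coords
  ax <- lapply(1:3, function(k) geom$origin[k] + geom$spacing * (seq_len(d[k]) - 1))
  face <- function(fixDim, fixVal) {
    oth <- setdiff(1:3, fixDim)
    g <- expand.grid(ax[[oth[1]]], ax[[oth[2]]])
    pts <- matrix(0, nrow(g), 3)
    pts[, fixDim] <- fixVal
    pts[, oth[1]] <- g[, 1]
    pts[, oth[2]] <- g[, 2]
    dmat <- pairDist(pts, pos)
    dmat[dmat < 1e-6] <- 1e-6
    vals <- as.numeric((dmat^-1) %*% q) * KE / eps
    list(pts = pts, vals = vals, oth = oth)
  }
  for (fixDim in 1:3) for (side in c(1L, d[fixDim])) {
    f <- face(fixDim, ax[[fixDim]][side])
    idx <- array(FALSE, d)
    if (fixDim == 1) idx[side, , ] <- TRUE
    if (fixDim == 2) idx[, side, ] <- TRUE
    if (fixDim == 3) idx[, , side] <- TRUE
    phi[idx] <- f$vals
  }
  phi
}
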