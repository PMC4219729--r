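# Nonbonded + restraint potential used for desk-scale minimization:
# 12-6 Lennard-Jones, Coulomb with distance-dependent dielectric
# eps(r) = 4r (a standard implicit-screening shortcut), and harmonic
# bond/1-3 restraints taken from the input geometry.
minimizerModel <- function(structure, kBond = 100, kAngle = 50) {
  n <- nAtoms(structure)
  bonds <- bondPairs(structure)
  excl <- exclusionMask(structure, bonds)
  nb <- which(upper.tri(excl) & !excl, arr.ind = TRUE)
  adj <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    adj[bonds] <- TRUE
    adj[bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  one3 <- which(((adj %*% adj) > 0) & !adj & upper.tri(adj), arr.ind = TRUE)
  one3 <- one3[one3[, 1] != one3[, 2], , drop = FALSE]
  co <- structure@coords
  rlen <- function(p) sqrt(rowSums((co[p[, 1], , drop = FALSE] -
                                      co[p[, 2], , drop = FALSE])^2))
  eps <- structure@ljEpsilon
  rmh <- structure@ljRminHalf
  q <- structure@charge
  # placed ions keep their predicted site: minimization relaxes contacts
  # around them rather than re-docking the ion
  tether <- which(structure@atoms$het &
                    !(structure@atoms$name %in% c("HOH", "WAT")))
  list(
    tether = tether, x0 = co[tether, , drop = FALSE], kTether = 10,
    n = n, nb = nb, bonds = bonds, one3 = one3,
    b0 = if (nrow(bonds)) rlen(bonds) else numeric(0),
    a0 = if (nrow(one3)) rlen(one3) else numeric(0),
    kBond = kBond, kAngle = kAngle,
    q = q, eps = eps, rmh = rmh,
    e12 = sqrt(eps[nb[, 1]] * eps[nb[, 2]]),
    rmin = rmh[nb[, 1]] + rmh[nb[, 2]],
    qq = KE * q[nb[, 1]] * q[nb[, 2]]
  )
}

# Soft-core variant of the nonbonded pair energy: repulsion is damped by
# an r^2 shift so steepest descent can cross packing barriers early on.
softPair <- function(model, delta2) {
  function(r, p) {
    r2 <- r^2 + delta2
    sr6 <- (model$rmin^2 / r2)^3
    list(e = model$e12 * (sr6^2 - 2 * sr6) + model$qq / (4 * r2),
         de = (model$e12 * (-12 * sr6^2 + 12 * sr6) / r2 -
                 2 * model$qq / (4 * r2^2)) * r)
  }
}

energyGradient <- function(x, model) {
  co <- matrix(x, ncol = 3)
  g <- matrix(0, model$n, 3)
  E <- 0
  pairTerm <- function(pairs, fun) {
    if (!nrow(pairs)) return(invisible())
    dvec <- co[pairs[, 1], , drop = FALSE] - co[pairs[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    r <- pmax(r, 1e-8)
    ed <- fun(r, pairs)  # list(E per pair, dE/dr per pair)
    E <<- E + sum(ed$e)
    f <- ed$de / r
    gx <- dvec * f
    acc <- rowsum(rbind(gx, -gx), group = c(pairs[, 1], pairs[, 2]))
    tgt <- as.integer(rownames(acc))
    g[tgt, ] <<- g[tgt, ] + acc
    invisible()
  }
  if (nrow(model$nb)) {
    fun <- if (is.null(model$soft2)) function(r, p) {
      sr6 <- (model$rmin / r)^6
      list(e = model$e12 * (sr6^2 - 2 * sr6) + model$qq / (4 * r^2),
           de = model$e12 * (-12 * sr6^2 + 12 * sr6) / r -
             2 * model$qq / (4 * r^3))
    } else softPair(model, model$soft2)
    pairTerm(model$nb, fun)
  }
  if (nrow(model$bonds))
    pairTerm(model$bonds, function(r, p)
      list(e = model$kBond * (r - model$b0)^2,
           de = 2 * model$kBond * (r - model$b0)))
  if (nrow(model$one3))
    pairTerm(model$one3, function(r, p)
      list(e = model$kAngle * (r - model$a0)^2,
           de = 2 * model$kAngle * (r - model$a0)))
  if (length(model$tether)) {
    dv <- co[model$tether, , drop = FALSE] - model$x0
    E <- E + model$kTether * sum(dv^2)
    g[model$tether, ] <- g[model$tether, ] + 2 * model$kTether * dv
  }
  list(E = E, grad = as.numeric(g))
}

# Energy without the gradient; used by the line search.
energyOnly <- function(x, model) {
  co <- matrix(x, ncol = 3)
  E <- 0
  term <- function(pairs, fun) {
    if (!nrow(pairs)) return(0)
    dvec <- co[pairs[, 1], , drop = FALSE] - co[pairs[, 2], , drop = FALSE]
    r <- pmax(sqrt(rowSums(dvec^2)), 1e-8)
    sum(fun(r, pairs))
  }
  E <- E + term(model$nb, if (is.null(model$soft2)) function(r, p) {
    sr6 <- (model$rmin / r)^6
    model$e12 * (sr6^2 - 2 * sr6) + model$qq / (4 * r^2)
  } else function(r, p) {
    r2 <- r^2 + model$soft2
    sr6 <- (model$rmin^2 / r2)^3
    model$e12 * (sr6^2 - 2 * sr6) + model$qq / (4 * r2)
  })
  E <- E + term(model$bonds, function(r, p) model$kBond * (r - model$b0)^2)
  E <- E + term(model$one3, function(r, p) model$kAngle * (r - model$a0)^2)
  if (length(model$tether))
    E <- E + model$kTether *
      sum((co[model$tether, , drop = FALSE] - model$x0)^2)
  E
}

#' Energy-minimize a structure
#'
#' Steepest descent with backtracking line search on a heavy-atom
#' potential (Lennard-Jones + screened Coulomb with distance-dependent
#' dielectric + harmonic bond/1-3 restraints derived from the input
#' geometry). The energy trace is non-increasing by construction; the
#' run stops at `maxSteps` or when the largest force component falls
#' below `forceTol`.
#'
#' @param structure a parameterized [Structure-class].
#' @param config a [MinimizerConfig-class].
#' @param seed seed for the one-shot jitter applied when overlapping
#'   charges make the initial energy non-finite.
#' @return list with `structure` (minimized) and `trace` (energy per
#'   accepted step, kcal/mol).
#' @export
minimizeStructure <- function(structure, config = new("MinimizerConfig"),
                              seed = 1L, softStart = TRUE) {
  if (!isParameterized(structure)) stop("structure is not parameterized")
  model <- minimizerModel(structure)
  x <- as.numeric(structure@coords)
  eg <- energyGradient(x, model)
  if (!is.finite(eg$E)) {
    x <- x + withSeed(seed, stats::rnorm(length(x), 0, 0.05))
    eg <- energyGradient(x, model)
    if (!is.finite(eg$E)) stop("non-finite energy even after jitter")
  }
  if (max(abs(eg$grad)) < config@forceTol)
    return(list(structure = structure, trace = eg$E, softTrace = NULL))
  descend <- function(x, model, maxSteps) {
    eg <- energyGradient(x, model)
    trace <- eg$E
    step <- config@stepInit
    for (it in seq_len(maxSteps)) {
      if (max(abs(eg$grad)) < config@forceTol) break
      accepted <- FALSE
      for (try in 1:25) {
        xNew <- x - step * eg$grad
        eNew <- energyOnly(xNew, model)
        if (is.finite(eNew) && eNew <= eg$E) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      x <- xNew
      eg <- energyGradient(xNew, model)
      eg$E <- eNew
      trace <- c(trace, eg$E)
      step <- step * 1.2
    }
    list(x = x, trace = trace)
  }
  trace <- numeric(0)
  if (softStart && config@maxSteps >= 20L) {
    soft <- model
    soft$soft2 <- 1.0
    ph1 <- descend(x, soft, as.integer(config@maxSteps / 2))
    x <- ph1$x
    trace <- ph1$trace
  }
  ph2 <- descend(x, model, config@maxSteps)
  structure@coords <- matrix(ph2$x, ncol = 3,
                             dimnames = dimnames(structure@coords))
  list(structure = structure, trace = ph2$trace,
       softTrace = if (length(trace)) trace else NULL)
}
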