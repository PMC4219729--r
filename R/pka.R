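# Single-conformer continuum-electrostatics pKa machinery.
#
# Conventions. For every titratable site the bundled parameter table holds
# the residue's standard-state charges (charged for ASP/GLU/LYS/ARG,
# neutral for HIS/TYR); protonation adds +1 e on the proton-bearing atom.
# "Ionizing" a site means neutral -> charged. The intrinsic pKa is
#   acid:  pKa_int = pKa_model + ddG / (2.303 RT)
#   base:  pKa_int = pKa_model - ddG / (2.303 RT)
# with ddG the extra free energy of ionizing in the protein relative to
# the isolated model compound (desolvation + fixed-background terms), and
# 2.303 RT = 1.364 kcal/mol at 298 K. A positive fixed charge near an
# acid makes ddG negative and lowers its pKa.

acidTypes <- c("ASP", "GLU", "TYR")
baseTypes <- c("HIS", "LYS", "ARG")

#' Identify titratable sites in a structure
#'
#' Lists the side-chain titratable residues (ASP, GLU, HIS, LYS, ARG,
#' TYR) with their acid/base class and model pKa. Ions and HETATM
#' records never titrate.
#'
#' @param structure a [Structure-class].
#' @param types residue types to include.
#' @param modelPka named model-pKa table (defaults to the bundled one).
#' @return data.frame with columns `chainId`, `resSeq`, `type`, `acid`,
#'   `modelPka`; zero rows when nothing titrates.
#' @export
identifySites <- function(structure, types = c(acidTypes, baseTypes),
                          modelPka = defaultModelPkaTable) {
  at <- structure@atoms
  keys <- !duplicated(residueKeys(at))
  res <- at[keys & !at$het & at$resName %in% types, , drop = FALSE]
  data.frame(chainId = res$chainId, resSeq = res$resSeq,
             type = res$resName, acid = res$resName %in% acidTypes,
             modelPka = unname(modelPka[res$resName]),
             stringsAsFactors = FALSE)
}

# Per-site atom indices and charged/neutral charge vectors over those
# atoms. Side-chain atoms only; the proton-bearing atom takes the +-1.
sitePrep <- function(structure, sites) {
  at <- structure@atoms
  lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    idx <- which(at$chainId == s$chainId & at$resSeq == s$resSeq &
                   !(at$name %in% backboneNames))
    if (!length(idx)) stop("site ", s$type, " ", s$chainId, ":", s$resSeq,
                           " has no side-chain atoms")
    q <- structure@charge[idx]
    protAtom <- protonAtomTable[s$type]
    pj <- which(at$name[idx] == protAtom)
    if (!length(pj)) stop("site ", s$type, " lacks proton atom ", protAtom)
    qCharged <- q
    qNeutral <- q
    if (s$type %in% c("ASP", "GLU")) qNeutral[pj] <- qNeutral[pj] + 1
    else if (s$type %in% c("LYS", "ARG")) qNeutral[pj] <- qNeutral[pj] - 1
    else if (s$type == "HIS") qCharged[pj] <- qCharged[pj] + 1
    else if (s$type == "TYR") qCharged[pj] <- qCharged[pj] - 1
    list(idx = idx, qCharged = qCharged, qNeutral = qNeutral,
         delta = qCharged - qNeutral)
  })
}

# Reaction-field energy of an arbitrary charge vector on a fixed
# geometry/dielectric pair; phi evaluated at the charged atoms only.
rfEnergyOn <- function(structure, config, geom, epsS, epsU, charges) {
  s2 <- structure
  s2@charge <- charges
  gS <- solvePoissonRaw(s2, config, geom, epsS, uniform = FALSE)
  gU <- solvePoissonRaw(s2, config, geom, epsU, uniform = TRUE)
  act <- which(charges != 0)
  phiS <- potentialAt(gS, structure@coords[act, , drop = FALSE])
  phiU <- potentialAt(gU, structure@coords[act, , drop = FALSE])
  list(energy = 0.5 * sum(charges[act] * (phiS - phiU)), gridS = gS,
       gridU = gU)
}

# Core engine: intrinsic pKa of every site plus the site-site interaction
# matrix, sharing Poisson solutions (4 protein + 4 model runs per site).
pkaMachinery <- function(structure, sites, config = solverConfigPka(),
                         params = defaultParameterSet()) {
  if (!isParameterized(structure))
    structure <- assignParameters(structure, params)
  prep <- sitePrep(structure, sites)
  n <- nrow(sites)
  geom <- buildGrid(structure, config)
  epsS <- faceEps(structure, geom, config, uniform = FALSE)
  epsU <- faceEps(structure, geom, config, uniform = TRUE)
  nAt <- nAtoms(structure)
  # background = all charges with every site in its neutral form
  qBack <- structure@charge
  for (p in prep) qBack[p$idx] <- p$qNeutral
  pkaInt <- numeric(n)
  deltaGrids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prep[[i]]
    qN <- numeric(nAt); qN[p$idx] <- p$qNeutral
    qD <- numeric(nAt); qD[p$idx] <- p$delta
    rfN <- rfEnergyOn(structure, config, geom, epsS, epsU, qN)
    rfD <- rfEnergyOn(structure, config, geom, epsS, epsU, qD)
    deltaGrids[[i]] <- rfD$gridS
    # G_rf(charged) - G_rf(neutral) in the protein, via linearity:
    # phi_c = phi_n + phi_d at every point
    act <- p$idx
    phiNS <- potentialAt(rfN$gridS, structure@coords[act, , drop = FALSE])
    phiNU <- potentialAt(rfN$gridU, structure@coords[act, , drop = FALSE])
    phiDS <- potentialAt(rfD$gridS, structure@coords[act, , drop = FALSE])
    phiDU <- potentialAt(rfD$gridU, structure@coords[act, , drop = FALSE])
    gProtC <- 0.5 * sum(p$qCharged * ((phiNS + phiDS) - (phiNU + phiDU)))
    gProtN <- 0.5 * sum(p$qNeutral * (phiNS - phiNU))
    # fixed-background interaction difference (solvated protein dielectric)
    bgIdx <- setdiff(which(qBack != 0), p$idx)
    gBack <- if (length(bgIdx))
      sum(qBack[bgIdx] *
            potentialAt(rfD$gridS, structure@coords[bgIdx, , drop = FALSE]))
      else 0
    # isolated model compound: site atoms alone in water
    ms <- subsetStructure(structure, p$idx)
    mgeom <- buildGrid(ms, config)
    mEpsS <- faceEps(ms, mgeom, config, uniform = FALSE)
    mEpsU <- faceEps(ms, mgeom, config, uniform = TRUE)
    mN <- rfEnergyOn(ms, config, mgeom, mEpsS, mEpsU, p$qNeutral)
    mD <- rfEnergyOn(ms, config, mgeom, mEpsS, mEpsU, p$delta)
    mphiNS <- potentialAt(mN$gridS, ms@coords)
    mphiNU <- potentialAt(mN$gridU, ms@coords)
    mphiDS <- potentialAt(mD$gridS, ms@coords)
    mphiDU <- potentialAt(mD$gridU, ms@coords)
    gModC <- 0.5 * sum(p$qCharged * ((mphiNS + mphiDS) - (mphiNU + mphiDU)))
    gModN <- 0.5 * sum(p$qNeutral * (mphiNS - mphiNU))
    ddG <- (gProtC - gProtN) - (gModC - gModN) + gBack
    pkaInt[i] <- sites$modelPka[i] +
      ifelse(sites$acid[i], 1, -1) * ddG / RT_LN10
  }
  W <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pj <- prep[[j]]
      wij <- sum(pj$delta *
                   potentialAt(deltaGrids[[i]],
                               structure@coords[pj$idx, , drop = FALSE]))
      W[i, j] <- W[j, i] <- wij
    }
    W <- (W + t(W)) / 2
  }
  list(sites = cbind(sites, pkaInt = pkaInt), W = W, prep = prep)
}

#' Solver configuration for pKa runs
#'
#' The pKa stage uses an internal dielectric of 4 (rather than 1 as in
#' the binding-energy stage); everything else follows the defaults.
#'
#' @param ... overrides for [SolverConfig-class] slots.
#' @return a [SolverConfig-class] with `epsIn = 4`.
#' @export
solverConfigPka <- function(...) new("SolverConfig", epsIn = 4, ...)

#' Intrinsic pKa of one titratable site
#'
#' The site's pKa including desolvation and fixed-background effects but
#' excluding interactions with other titrating sites (which enter through
#' the interaction matrix during titration).
#'
#' @param structure a parameterized [Structure-class].
#' @param chain,resSeq identify the site.
#' @param config a [SolverConfig-class]; pKa runs use `epsIn = 4`.
#' @param params a [ParameterSet-class].
#' @return the intrinsic pKa (numeric).
#' @export
intrinsicPka <- function(structure, chain, resSeq,
                         config = solverConfigPka(),
                         params = defaultParameterSet()) {
  sites <- identifySites(structure)
  sel <- sites$chainId == chain & sites$resSeq == resSeq
  if (!any(sel)) stop("no titratable site at ", chain, ":", resSeq)
  m <- pkaMachinery(structure, sites[sel, , drop = FALSE], config, params)
  m$sites$pkaInt[1]
}

#' Site-site electrostatic interaction matrix
#'
#' `W[i, j]` is the interaction energy (kcal/mol) between the charged
#' forms of sites i and j, computed from the Poisson solution of each
#' site's ionization charge difference in the solvated protein
#' dielectric. Symmetrized; zero diagonal.
#'
#' @inheritParams intrinsicPka
#' @param sites data.frame from [identifySites()] (default: all sites).
#' @return symmetric numeric matrix, kcal/mol.
#' @export
interactionMatrix <- function(structure, sites = identifySites(structure),
                              config = solverConfigPka(),
                              params = defaultParameterSet()) {
  if (nrow(sites) < 2) stop("need at least 2 sites")
  pkaMachinery(structure, sites, config, params)$W
}

#' Titrate a set of interacting sites
#'
#' Computes mean protonation per site across a pH grid, either by exact
#' enumeration of all `2^N` ionization microstates (N <= 20) or by
#' Metropolis Monte Carlo single-flip sweeps. `pka50` is the linearly
#' interpolated pH of half-protonation, censored as `"<min"`/`">max"`
#' when the curve does not cross one half on the grid. The MC path runs
#' two independent chains; a split-half pka50 discrepancy above 0.2
#' units is recorded as a convergence warning in the result.
#'
#' @param sites data.frame with columns `chainId`, `resSeq`, `type`,
#'   `acid`, `modelPka` and `pkaInt` (from [pkaMachinery] via
#'   [computeTitration()], or constructed directly for model studies).
#' @param W site-site interaction matrix, kcal/mol.
#' @param pH numeric pH grid (default 0 to 14 by 0.25).
#' @param method `"enumerate"`, `"monte_carlo"` or `"auto"` (enumerate
#'   up to 20 sites).
#' @param mcSweeps Monte Carlo sweeps per pH point (default 1e5).
#' @param seed RNG seed for the MC path.
#' @return a [TitrationResult-class].
#' @export
titrate <- function(sites, W = matrix(0, nrow(sites), nrow(sites)),
                    pH = seq(0, 14, by = 0.25),
                    method = c("auto", "enumerate", "monte_carlo"),
                    mcSweeps = 1e5, seed = 1L) {
  method <- match.arg(method)
  n <- nrow(sites)
  if (method == "auto") method <- if (n <= 20) "enumerate" else "monte_carlo"
  if (method == "enumerate" && n > 20)
    stop("enumeration allowed only for <= 20 sites")
  gamma <- ifelse(sites$acid, 1, -1)
  curves <- matrix(NA_real_, n, length(pH))
  mcWarning <- ""
  if (method == "enumerate") {
    states <- as.matrix(expand.grid(rep(list(0:1), n)))
    pairE <- rowSums((states %*% W) * states) / 2
    for (k in seq_along(pH)) {
      nu <- RT_LN10 * ifelse(sites$acid, sites$pkaInt - pH[k],
                             pH[k] - sites$pkaInt)
      E <- as.numeric(states %*% nu) + pairE
      wgt <- exp(-(E - min(E)) / (RT_LN10 / log(10)))
      xMean <- colSums(states * wgt) / sum(wgt)
      curves[, k] <- ifelse(sites$acid, 1 - xMean, xMean)
    }
  } else {
    half <- matrix(NA_real_, 2, n)
    curvesA <- curves
    curvesB <- curves
    for (k in seq_along(pH)) {
      nu <- RT_LN10 * ifelse(sites$acid, sites$pkaInt - pH[k],
                             pH[k] - sites$pkaInt)
      xa <- cpp_mc_titrate(nu, W, as.integer(mcSweeps), 0.2,
                           deriveSeed(seed, paste0("mcA", k)),
                           RT_LN10 / log(10))
      xb <- cpp_mc_titrate(nu, W, as.integer(mcSweeps), 0.2,
                           deriveSeed(seed, paste0("mcB", k)),
                           RT_LN10 / log(10))
      curvesA[, k] <- ifelse(sites$acid, 1 - xa, xa)
      curvesB[, k] <- ifelse(sites$acid, 1 - xb, xb)
    }
    curves <- (curvesA + curvesB) / 2
    pa <- apply(curvesA, 1, pka50FromCurve, pH = pH)
    pb <- apply(curvesB, 1, pka50FromCurve, pH = pH)
    disc <- suppressWarnings(max(abs(as.numeric(pa) - as.numeric(pb)),
                                 na.rm = TRUE))
    if (is.finite(disc) && disc > 0.2)
      mcWarning <- sprintf(
        "MC split-half pka50 discrepancy %.2f exceeds 0.2; increase sweeps",
        disc)
  }
  pka50 <- numeric(n)
  censored <- character(n)
  for (i in seq_len(n)) {
    v <- pka50FromCurve(curves[i, ], pH)
    if (is.na(v)) {
      censored[i] <- if (mean(curves[i, ]) < 0.5) "<min" else ">max"
      pka50[i] <- NA_real_
    } else {
      censored[i] <- ""
      pka50[i] <- v
    }
  }
  new("TitrationResult", sites = sites, W = W, pH = pH, curves = curves,
      pka50 = pka50, censored = censored, method = method,
      mcWarning = mcWarning)
}

pka50FromCurve <- function(curve, pH) {
  above <- curve - 0.5
  sgn <- sign(above)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                   (sgn[-1] != sgn[-length(sgn)] | sgn[-1] == 0))
  if (!length(cross)) {
    if (any(above == 0)) return(pH[which(above == 0)[1]])
    return(NA_real_)
  }
  k <- cross[1]
  if (above[k] == 0) return(pH[k])
  pH[k] + (0.5 - curve[k]) * (pH[k + 1] - pH[k]) / (curve[k + 1] - curve[k])
}

#' Full titration of a structure
#'
#' Convenience wrapper: identifies sites, computes intrinsic pKas and the
#' interaction matrix from the Poisson solver, and titrates.
#'
#' @inheritParams intrinsicPka
#' @inheritParams titrate
#' @param sites optional site subset (default all).
#' @return a [TitrationResult-class].
#' @export
computeTitration <- function(structure, sites = NULL,
                             config = solverConfigPka(),
                             params = defaultParameterSet(),
                             pH = seq(0, 14, by = 0.25),
                             method = "auto", mcSweeps = 1e5, seed = 1L) {
  if (is.null(sites)) sites <- identifySites(structure)
  if (!nrow(sites))
    return(new("TitrationResult", sites = sites,
               W = matrix(0, 0, 0), pH = pH,
               curves = matrix(0, 0, length(pH)), pka50 = numeric(0),
               censored = character(0)))
  m <- pkaMachinery(structure, sites, config, params)
  titrate(m$sites, m$W, pH = pH, method = method, mcSweeps = mcSweeps,
          seed = seed)
}

#' pKa shifts between two states
#'
#' Per-site `pka50(bound) - pka50(free)`, with censored values propagated
#' as inequalities. The conventional focus is the pocket carboxylates.
#'
#' @param bound,free [TitrationResult-class] objects over matching site
#'   rosters.
#' @param focus optional data.frame with `chainId`, `resSeq` restricting
#'   the report.
#' @return data.frame with `chainId`, `resSeq`, `type`, `pkaFree`,
#'   `pkaBound`, `shift` and `note` (inequality strings for censored
#'   sites).
#' @export
pkaShiftReport <- function(bound, free, focus = NULL) {
  kb <- paste(bound@sites$chainId, bound@sites$resSeq, bound@sites$type)
  kf <- paste(free@sites$chainId, free@sites$resSeq, free@sites$type)
  if (!setequal(kb, kf))
    stop("site rosters differ: ",
         paste(c(setdiff(kb, kf), setdiff(kf, kb)), collapse = ", "))
  m <- match(kb, kf)
  out <- data.frame(chainId = bound@sites$chainId,
                    resSeq = bound@sites$resSeq,
                    type = bound@sites$type,
                    pkaFree = free@pka50[m],
                    pkaBound = bound@pka50,
                    shift = bound@pka50 - free@pka50[m],
                    note = "", stringsAsFactors = FALSE)
  cb <- bound@censored
  cf <- free@censored[m]
  for (i in seq_len(nrow(out))) {
    if (nzchar(cb[i]) || nzchar(cf[i])) {
      lo <- if (nzchar(cb[i])) cb[i] else sprintf("%.2f", bound@pka50[i])
      hi <- if (nzchar(cf[i])) cf[i] else sprintf("%.2f", free@pka50[m][i])
      out$note[i] <- paste0("censored: bound ", lo, ", free ", hi)
      if (identical(cb[i], "<min") && !nzchar(cf[i]))
        out$note[i] <- paste0(out$note[i], " (shift < ",
                              sprintf("%.2f", min(bound@pH) - free@pka50[m][i]),
                              ")")
    }
  }
  if (!is.null(focus))
    out <- out[paste(out$chainId, out$resSeq) %in%
                 paste(focus$chainId, focus$resSeq), , drop = FALSE]
  rownames(out) <- NULL
  out
}
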