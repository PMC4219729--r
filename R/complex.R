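# Element-based fallback radii for clash checks on bare structures.
fallbackRadius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, BE = 1.53, H = 1.10)
  out <- r[element]
  out[is.na(out)] <- 1.7
  unname(out)
}

clashRadii <- function(structure) {
  r <- structure@radius
  miss <- is.na(r)
  r[miss] <- fallbackRadius(structure@atoms$element[miss])
  r
}

#' Assemble a receptor-peptide(-ion) complex
#'
#' Concatenates the receptor and peptide into one structure with distinct
#' chain identifiers, optionally adding a placed cation as a HETATM chain.
#' Steric overlap between receptor and peptide (interatomic distance below
#' `clashFactor` times the sum of vdW radii) is resolved by rigidly
#' lifting the whole peptide out of the pocket in `liftStep` increments
#' along the receptor-to-peptide axis, with small deterministic tilts when
#' lifting alone is insufficient; peptide-internal geometry is never
#' altered.
#'
#' @param receptor,peptide [Structure-class] objects.
#' @param ion optional [IonSpec-class]; requires `ionPosition`.
#' @param ionPosition 3-vector, Angstrom; where to put the ion.
#' @param ionAttachedTo `"receptor"` or `"peptide"`: which partner the
#'   placed ion belongs to. An ion attached to the peptide moves rigidly
#'   with it during clash resolution; either way the ion participates in
#'   the clash check.
#' @param scenario label stored in the title (e.g. `"no_ion"`,
#'   `"pep_to_Be_protein"`, `"Bepep_to_protein"`).
#' @param clashFactor clash cutoff as a fraction of the vdW-radius sum
#'   (default 0.7).
#' @param liftStep rigid lift increment, Angstrom (default 0.2).
#' @param liftDirection unit 3-vector for the rigid lift; default: the
#'   axis from the nearby receptor atoms toward the peptide.
#' @param maxIter maximum lift/tilt iterations (default 50).
#' @param approach if `TRUE`, dock the peptide: slide it along the lift
#'   axis until just-contact even when the input pose is clash-free
#'   (the scenario pipeline uses this); with the default `FALSE` a
#'   clash-free input is returned unchanged.
#' @param seed seed for the deterministic tilt sequence.
#' @return the combined [Structure-class]; peptide atoms carry chain
#'   `"P"` (or the next free letter), an ion chain `"I"`.
#' @export
buildComplex <- function(receptor, peptide, ion = NULL, ionPosition = NULL,
                         ionAttachedTo = c("receptor", "peptide"),
                         scenario = "no_ion", clashFactor = 0.7,
                         liftStep = 0.2, liftDirection = NULL,
                         maxIter = 50L, approach = FALSE, seed = 1L) {
  ionAttachedTo <- match.arg(ionAttachedTo)
  if (!is.null(ion) && is.null(ionPosition))
    stop("an ion requires an ionPosition")
  pepChain <- setdiff(c("P", "Q", "S", "T", "U"), chains(receptor))[1]
  rc <- receptor@coords
  rr <- clashRadii(receptor)
  pr <- clashRadii(peptide)
  pc <- peptide@coords
  nPep <- nrow(pc)
  if (!is.null(ion)) {
    if (ionAttachedTo == "receptor") {
      rc <- rbind(rc, ionPosition)
      rr <- c(rr, ion@radius)
    } else {
      pc <- rbind(pc, ionPosition)
      pr <- c(pr, ion@radius)
    }
  }
  if (is.null(liftDirection)) {
    # exit axis of the binding site: from the nearby receptor atoms (the
    # pocket environment) toward the peptide, not the global centroid
    dmat <- pairDist(rc, pc)
    near <- which(apply(dmat, 1, min) < 8)
    if (!length(near)) near <- seq_len(nrow(rc))
    liftDirection <- colMeans(pc) - colMeans(rc[near, , drop = FALSE])
  }
  lift <- liftDirection
  nl <- sqrt(sum(lift^2))
  lift <- if (nl > 1e-8) lift / nl else c(0, 0, 1)
  cutoffs <- outer(rr, pr, "+") * clashFactor
  worst <- function(pcNow) {
    d <- pairDist(rc, pcNow)
    excess <- cutoffs - d
    i <- which(excess == max(excess), arr.ind = TRUE)[1, ]
    list(clash = max(excess) > 0, d = d[i[1], i[2]],
         cut = cutoffs[i[1], i[2]], pair = i)
  }
  tilts <- withSeed(seed, stats::runif(maxIter, -5, 5) * pi / 180)
  it <- 0L
  w <- worst(pc)
  while (w$clash && it < maxIter) {
    it <- it + 1L
    pc <- pc + matrix(lift * liftStep, nrow(pc), 3, byrow = TRUE)
    if (it %% 20L == 0L) {
      ctr <- colMeans(pc)
      ax <- rotZ(tilts[it])
      pc <- sweep(sweep(pc, 2, ctr) %*% ax, 2, -ctr)
    }
    w <- worst(pc)
  }
  if (w$clash)
    stop(sprintf(
      "unresolvable clash after %d iterations: receptor atom %d / peptide atom %d at %.2f A (cutoff %.2f A)",
      it, w$pair[1], w$pair[2], w$d, w$cut))
  # settle back toward the receptor to just-contact, so clash resolution
  # never strands the peptide above the pocket; in approach mode this
  # also docks clash-free input poses into contact
  if (approach || it > 0L) for (back in seq_len(200L)) {
    pcTest <- pc - matrix(lift * liftStep / 4, nrow(pc), 3, byrow = TRUE)
    if (worst(pcTest)$clash) break
    pc <- pcTest
  }
  finalIonPos <- if (is.null(ion)) NULL
    else if (ionAttachedTo == "receptor") ionPosition else pc[nPep + 1L, ]
  pep <- peptide
  pep@coords <- pc[seq_len(nPep), , drop = FALSE]
  pep@atoms$chainId <- pepChain
  parts <- list(receptor, pep)
  if (!is.null(ion)) {
    ionAtoms <- data.frame(serial = 0L, name = ion@element,
                           element = ion@element, resName = ion@element,
                           resSeq = 1L, insert = "", chainId = "I",
                           het = TRUE, stringsAsFactors = FALSE)
    ionStruct <- newStructure(ionAtoms, matrix(finalIonPos, 1, 3),
                              charge = ion@charge, radius = ion@radius,
                              ljEpsilon = 0.01, ljRminHalf = ion@radius)
    parts <- c(parts, list(ionStruct))
  }
  out <- concatStructures(parts, title = scenario)
  out
}

# Stack structures; parameters survive only if every part carries them.
concatStructures <- function(parts, title = "") {
  atoms <- do.call(rbind, lapply(parts, function(p) p@atoms))
  co <- do.call(rbind, lapply(parts, function(p) p@coords))
  param <- all(vapply(parts, isParameterized, logical(1)))
  g <- function(sl) if (param) unlist(lapply(parts, slot, sl)) else NULL
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  newStructure(atoms, co, charge = g("charge"), radius = g("radius"),
               ljEpsilon = g("ljEpsilon"), ljRminHalf = g("ljRminHalf"),
               title = title)
}
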