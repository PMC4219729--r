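#' Binding free energy of a partitioned complex
#'
#' Computes `dG = G_AB - G_A - G_B` with each `G` a Coulomb +
#' polar-solvation + van der Waals breakdown ([totalG()]). The
#' `minimize` argument selects how coordinates are prepared:
#' \describe{
#'   \item{`"complex"` (default)}{the complex is energy-minimized and
#'     the partner energies are evaluated on a rigid split of the
#'     minimized coordinates - the partners are taken from one step of
#'     the complex minimization, so conformational strain differences
#'     do not contaminate the ranking.}
#'   \item{`"parts"`}{the complex and each partner are independently
#'     energy-minimized before evaluation.}
#'   \item{`"none"`}{rigid split of the input coordinates (the oracle
#'     mode used by the bookkeeping and limit tests).}
#' }
#' With `commonGrid = TRUE` (default) the polar-solvation terms of the
#' complex and both partners are evaluated on one shared grid derived
#' from the complex, so per-atom grid self-energy artifacts cancel in
#' the difference; with `FALSE` each part gets its own perfil-derived
#' grid. Values are flagged ranking-only: the decomposition carries no
#' entropic or nonpolar terms, so absolute affinities are not implied.
#'
#' @param complex a parameterized [Structure-class].
#' @param partitionA,partitionB disjoint atom index sets covering every
#'   atom of the complex.
#' @param config a [SolverConfig-class].
#' @param minimize `"complex"`, `"parts"` or `"none"` (see above).
#' @param minimizerConfig a [MinimizerConfig-class] used when minimizing.
#' @param commonGrid evaluate all three polar-solvation terms on one
#'   grid derived from the complex (default `TRUE`).
#' @param scenario label stored in the result.
#' @return a [BindingResult-class].
#' @export
bindingEnergy <- function(complex, partitionA, partitionB,
                          config = new("SolverConfig"),
                          minimize = c("complex", "parts", "none"),
                          minimizerConfig = new("MinimizerConfig"),
                          commonGrid = TRUE,
                          scenario = "no_ion") {
  minimize <- match.arg(minimize)
  n <- nAtoms(complex)
  partitionA <- as.integer(partitionA)
  partitionB <- as.integer(partitionB)
  if (length(intersect(partitionA, partitionB)) ||
      !setequal(union(partitionA, partitionB), seq_len(n)))
    stop("partition must split the complex atoms into two disjoint sets")
  if (minimize == "complex")
    complex <- minimizeStructure(complex, minimizerConfig)$structure
  a <- subsetStructure(complex, partitionA)
  b <- subsetStructure(complex, partitionB)
  if (minimize == "parts") {
    complex <- minimizeStructure(complex, minimizerConfig)$structure
    a <- minimizeStructure(a, minimizerConfig)$structure
    b <- minimizeStructure(b, minimizerConfig)$structure
  }
  geom <- if (commonGrid) buildGrid(complex, config) else NULL
  gAB <- totalG(complex, config, geom = geom)
  gA <- totalG(a, config, geom = geom)
  gB <- totalG(b, config, geom = geom)
  new("BindingResult", scenario = scenario, gAB = gAB, gA = gA, gB = gB,
      dG = gAB@gTotal - gA@gTotal - gB@gTotal,
      partitionA = partitionA, partitionB = partitionB,
      note = "ranking-only")
}

emptyBreakdown <- function() {
  new("EnergyBreakdown", eCoul = 0, eSolvPolar = 0, eVdw = 0, gTotal = 0)
}

#' Compare the three ion/peptide binding-order scenarios
#'
#' Builds and scores the three cases used to ask in which order the
#' cation and the peptide bind:
#' \describe{
#'   \item{`no_ion`}{receptor + peptide, no cation.}
#'   \item{`pep_to_Be_protein`}{the cation is first placed at its
#'     predicted site on the free receptor; the peptide then binds the
#'     loaded receptor (partition: receptor+ion vs peptide).}
#'   \item{`Bepep_to_protein`}{the cation is first placed at its
#'     predicted site on the free peptide; the loaded peptide then binds
#'     the receptor (partition: receptor vs peptide+ion).}
#' }
#' The same complex-building path is used for all three. When no
#' plausible cation site exists on a free peptide, the third scenario is
#' returned as a zero-energy result annotated
#' `"no stable Be-peptide complex"`.
#'
#' @param receptor,peptide parameterized [Structure-class] objects, posed
#'   in a common frame (the peptide where it binds the groove).
#' @param ion an [IonSpec-class].
#' @param config a [SolverConfig-class].
#' @param params a [ParameterSet-class] for re-parameterizing built
#'   complexes.
#' @param minimize,minimizerConfig,commonGrid passed to
#'   [bindingEnergy()].
#' @param receptorSite optional precomputed result of
#'   [predictIonSite()] on the receptor (avoids re-solving when the
#'   same receptor is scored against many peptides).
#' @param seed deterministic seed for complex building.
#' @return named list of three [BindingResult-class] objects.
#' @export
compareScenarios <- function(receptor, peptide, ion = ionSpec(),
                             config = new("SolverConfig"),
                             params = defaultParameterSet(),
                             minimize = "complex",
                             minimizerConfig = new("MinimizerConfig"),
                             commonGrid = TRUE, receptorSite = NULL,
                             seed = 1L) {
  nR <- nAtoms(receptor)
  nP <- nAtoms(peptide)
  scoreCase <- function(cx, idxA, idxB, label) {
    cx <- assignParameters(cx, params, ion = ion)
    bindingEnergy(cx, idxA, idxB, config, minimize = minimize,
                  minimizerConfig = minimizerConfig, commonGrid = commonGrid,
                  scenario = label)
  }
  # (i) no ion: A = receptor, B = peptide
  cx1 <- buildComplex(receptor, peptide, scenario = "no_ion",
                      approach = TRUE, seed = seed)
  res1 <- scoreCase(cx1, seq_len(nR), nR + seq_len(nP), "no_ion")
  # (ii) ion on the receptor, peptide binds the loaded receptor
  siteR <- receptorSite %||% predictIonSite(receptor, ion, config)
  posR <- refineIonPosition(assignParameters(receptor, params, ion = ion),
                            ion, siteR$position)
  cx2 <- buildComplex(receptor, peptide, ion = ion,
                      ionPosition = posR,
                      ionAttachedTo = "receptor",
                      scenario = "pep_to_Be_protein", approach = TRUE,
                      seed = seed)
  res2 <- scoreCase(cx2, c(seq_len(nR), nR + nP + 1L), nR + seq_len(nP),
                    "pep_to_Be_protein")
  # (iii) ion on the free peptide, loaded peptide binds the receptor
  siteP <- tryCatch(predictIonSite(peptide, ion, config),
                    error = function(e) NULL)
  if (is.null(siteP)) {
    res3 <- new("BindingResult", scenario = "Bepep_to_protein",
                gAB = emptyBreakdown(), gA = emptyBreakdown(),
                gB = emptyBreakdown(), dG = 0,
                partitionA = integer(0), partitionB = integer(0),
                note = "no stable Be-peptide complex")
  } else {
    posP <- refineIonPosition(assignParameters(peptide, params, ion = ion),
                              ion, siteP$position)
    cx3 <- buildComplex(receptor, peptide, ion = ion,
                        ionPosition = posP,
                        ionAttachedTo = "peptide",
                        scenario = "Bepep_to_protein", approach = TRUE,
                        seed = seed)
    res3 <- scoreCase(cx3, seq_len(nR), nR + seq_len(nP + 1L),
                      "Bepep_to_protein")
  }
  list(no_ion = res1, pep_to_Be_protein = res2, Bepep_to_protein = res3)
}

#' Summarize binding results by peptide class
#'
#' Median and quartiles of `dG` per class, with classes ordered by median
#' affinity (most negative first). Empty classes are dropped with a
#' warning; censored results (e.g. no stable ion-peptide complex) are
#' excluded from the statistics.
#'
#' @param results list of [BindingResult-class] objects.
#' @param classes character vector of class labels, parallel to
#'   `results`.
#' @return data.frame with columns `class`, `n`, `median`, `q1`, `q3`,
#'   plus attribute `"dG"`: the per-class dG lists.
#' @export
classSummary <- function(results, classes) {
  stopifnot(length(results) == length(classes))
  keep <- vapply(results, function(r) !grepl("no stable", r@note), logical(1))
  if (!all(keep)) classes <- classes[keep]
  dG <- vapply(results[keep], function(r) r@dG, numeric(1))
  lst <- split(dG, classes)
  empty <- setdiff(unique(classes), names(lst))
  if (length(empty)) warning("empty class(es) excluded: ",
                             paste(empty, collapse = ", "))
  out <- data.frame(
    class = names(lst),
    n = vapply(lst, length, integer(1)),
    median = vapply(lst, stats::median, numeric(1)),
    q1 = vapply(lst, function(x) unname(stats::quantile(x, 0.25)), numeric(1)),
    q3 = vapply(lst, function(x) unname(stats::quantile(x, 0.75)), numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$median), ]
  rownames(out) <- NULL
  attr(out, "dG") <- lst
  out
}
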