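#' Construct a pipeline run configuration
#'
#' @param seed global seed; all stage seeds derive from it
#'   deterministically.
#' @param nPerClass synthetic peptides per class.
#' @param classes peptide classes.
#' @param scenarios scenario subset to report.
#' @param minimizeSteps minimization step cap before binding energies.
#' @param pkaCases `"representative"` (first case of each class per ion
#'   scenario), `"all"`, or `"none"`.
#' @param outDir output directory for JSON/TSV reports ("" = in-memory
#'   only).
#' @param dynamicsConfig a [DynamicsConfig-class] for the per-case
#'   sampler.
#' @param windowFraction trailing window for trajectory statistics.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(seed = 1L, nPerClass = 10L,
                      classes = c("natural", "strong", "weak", "DR"),
                      scenarios = c("no_ion", "pep_to_Be_protein",
                                    "Bepep_to_protein"),
                      minimizeSteps = 200L, pkaCases = "representative",
                      outDir = "", dynamicsConfig = new("DynamicsConfig"),
                      windowFraction = 0.4) {
  new("RunConfig", seed = as.integer(seed), nPerClass = as.integer(nPerClass),
      classes = classes, scenarios = scenarios,
      bindingConfig = new("SolverConfig"),
      pkaConfig = solverConfigPka(),
      dynamicsConfig = dynamicsConfig,
      minimizeSteps = as.integer(minimizeSteps),
      windowFraction = windowFraction, pkaCases = pkaCases, outDir = outDir)
}

#' Run the full analysis pipeline
#'
#' End-to-end, per peptide and scenario: synthetic receptor and peptide
#' generation, cation-site prediction, complex building, minimization,
#' binding free energies for the three binding-order scenarios,
#' elastic-network sampling with groove geometry statistics, and (per
#' the `pkaCases` setting) pocket pKa shifts relative to the free
#' receptor. Fully reproducible from the configuration's global seed.
#'
#' @param config a [RunConfig-class].
#' @return list with `cases` (per-case records), `classSummary`
#'   (per-scenario class dG tables), `geometry` (per-class window
#'   statistics), `pkaShifts`, `receptorTruth` and `config` echo. When
#'   `outDir` is set, `report.json` and TSV tables are written there.
#' @export
runAll <- function(config = runConfig()) {
  seed <- config@seed
  ion <- ionSpec()
  params <- defaultParameterSet()
  minCfg <- new("MinimizerConfig", maxSteps = config@minimizeSteps)
  rec <- makeAcidicPocketReceptor(deriveSeed(seed, "receptor"))
  receptor <- rec$structure
  receptorSite <- predictIonSite(assignParameters(receptor, params, ion = ion),
                                 ion, config@bindingConfig)
  cases <- list()
  for (cls in config@classes) {
    for (i in seq_len(config@nPerClass)) {
      pepSeed <- deriveSeed(seed, paste0("peptide-", cls, "-", i))
      pep <- makePeptide(cls, seed = pepSeed)
      res <- tryCatch(
        compareScenarios(receptor, pep$structure, ion = ion,
                         config = config@bindingConfig, params = params,
                         minimize = if (config@minimizeSteps > 0L)
                           "complex" else "none",
                         minimizerConfig = minCfg,
                         receptorSite = receptorSite,
                         seed = deriveSeed(seed, paste0("cx-", cls, "-", i))),
        error = function(e) e)
      if (inherits(res, "error")) {
        cases[[length(cases) + 1L]] <- list(class = cls, index = i,
                                            sequence = pep$truth$sequence,
                                            error = conditionMessage(res))
        next
      }
      # conformational sampling + groove geometry on the no-ion complex
      cx <- buildComplex(receptor, pep$structure, approach = TRUE,
                         seed = deriveSeed(seed, paste0("cx-", cls, "-", i)))
      dyn <- config@dynamicsConfig
      dyn@seed <- deriveSeed(seed, paste0("dyn-", cls, "-", i))
      traj <- enmLangevinSample(cx, dyn)
      helix <- selectIndices(traj@topology, chain = "B", resSeq = 50:86,
                             atomName = "CA")
      rms <- rmsdSeries(traj, helix)
      dists <- caDistanceSeries(traj)
      geom <- list(
        rmsd = windowStats(rms, config@windowFraction),
        distances = lapply(as.data.frame(dists), windowStats,
                           windowFraction = config@windowFraction))
      cases[[length(cases) + 1L]] <- list(
        class = cls, index = i, sequence = pep$truth$sequence,
        dG = lapply(res[config@scenarios], function(r)
          list(scenario = r@scenario, dG = r@dG,
               eCoul = r@gAB@eCoul - r@gA@eCoul - r@gB@eCoul,
               eSolvPolar = r@gAB@eSolvPolar - r@gA@eSolvPolar -
                 r@gB@eSolvPolar,
               eVdw = r@gAB@eVdw - r@gA@eVdw - r@gB@eVdw,
               note = r@note)),
        geometry = geom)
    }
  }
  ok <- !vapply(cases, function(x) !is.null(x$error), logical(1))
  classSummaries <- lapply(config@scenarios, function(sc) {
    usable <- Filter(function(x) !is.null(x$dG[[sc]]), cases[ok])
    if (!length(usable)) return(NULL)
    # lightweight result shells carrying the stored dG values
    results <- lapply(usable, function(x) {
      g <- new("EnergyBreakdown", eCoul = x$dG[[sc]]$dG, eSolvPolar = 0,
               eVdw = 0, gTotal = x$dG[[sc]]$dG)
      new("BindingResult", scenario = sc, gAB = g, gA = emptyBreakdown(),
          gB = emptyBreakdown(), dG = x$dG[[sc]]$dG,
          partitionA = integer(0), partitionB = integer(0),
          note = x$dG[[sc]]$note)
    })
    classSummary(results, vapply(usable, `[[`, character(1), "class"))
  })
  names(classSummaries) <- config@scenarios
  pkaShifts <- NULL
  if (config@pkaCases != "none") {
    focus <- identifySites(receptor)
    focus <- focus[focus$chainId == "B" &
                     focus$resSeq %in% c(26L, 68L, 69L), , drop = FALSE]
    recP <- assignParameters(receptor, params, ion = ion)
    free <- computeTitration(recP, sites = focus, config = config@pkaConfig,
                             seed = deriveSeed(seed, "pka-free"))
    site <- receptorSite
    ionAtoms <- data.frame(serial = 1L, name = ion@element,
                           element = ion@element, resName = ion@element,
                           resSeq = 1L, insert = "", chainId = "I",
                           het = TRUE, stringsAsFactors = FALSE)
    ionStruct <- newStructure(ionAtoms, matrix(site$position, 1, 3))
    bound <- concatStructures(list(receptor, ionStruct))
    boundP <- assignParameters(bound, params, ion = ion)
    boundT <- computeTitration(boundP, sites = focus,
                               config = config@pkaConfig,
                               seed = deriveSeed(seed, "pka-bound"))
    pkaShifts <- pkaShiftReport(boundT, free)
  }
  out <- list(cases = cases, classSummary = classSummaries,
              pkaShifts = pkaShifts, receptorTruth = rec$truth,
              config = list(seed = seed, nPerClass = config@nPerClass,
                            classes = config@classes,
                            scenarios = config@scenarios,
                            minimizeSteps = config@minimizeSteps,
                            windowFraction = config@windowFraction,
                            pkaCases = config@pkaCases))
  if (nzchar(config@outDir)) {
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(config@outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    tabs <- reportTables(out)
    for (nm in names(tabs))
      utils::write.table(tabs[[nm]],
                         file.path(config@outDir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Summary tables from a pipeline run
#'
#' Builds the standard report tables: per-scenario class dG box
#' statistics, pocket-distance means with 2 sd error bars (class
#' aggregation: median for RMSD, mean for distances), and the pocket pKa
#' shift table.
#'
#' @param run output of [runAll()].
#' @return named list of data.frames (`binding`, `distances`, `rmsd`,
#'   and `pka` when available).
#' @export
reportTables <- function(run) {
  if (!length(run$cases)) stop("no case records to tabulate")
  binding <- do.call(rbind, lapply(names(run$classSummary), function(sc) {
    cs <- run$classSummary[[sc]]
    if (is.null(cs)) return(NULL)
    cbind(scenario = sc, cs[, c("class", "n", "median", "q1", "q3")])
  }))
  okCases <- Filter(function(x) is.null(x$error), run$cases)
  classes <- vapply(okCases, `[[`, character(1), "class")
  pairLabels <- names(okCases[[1]]$geometry$distances)
  distances <- do.call(rbind, lapply(unique(classes), function(cl) {
    sub <- okCases[classes == cl]
    do.call(rbind, lapply(pairLabels, function(lb) {
      means <- vapply(sub, function(x) x$geometry$distances[[lb]]$mean,
                      numeric(1))
      sds <- vapply(sub, function(x) x$geometry$distances[[lb]]$twoSd,
                    numeric(1))
      data.frame(class = cl, pair = lb,
                 mean = groupAggregate(means, "mean"),
                 twoSd = groupAggregate(sds, "mean"))
    }))
  }))
  rmsd <- do.call(rbind, lapply(unique(classes), function(cl) {
    sub <- okCases[classes == cl]
    vals <- vapply(sub, function(x) x$geometry$rmsd$mean, numeric(1))
    data.frame(class = cl, medianRmsd = groupAggregate(vals, "median"),
               n = length(vals))
  }))
  out <- list(binding = binding, distances = distances, rmsd = rmsd)
  if (!is.null(run$pkaShifts)) out$pka <- run$pkaShifts
  out
}
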