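#' @useDynLib ionpocket, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Molecular structure with optional physical parameters
#'
#' An ordered collection of atoms with identity (serial, name, element,
#' residue, chain), coordinates in Angstrom, and - once
#' [assignParameters()] has run - partial charges (e), vdW radii (Angstrom)
#' and Lennard-Jones parameters (kcal/mol, Angstrom). HETATM records are
#' retained and flagged.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resName`, `resSeq`, `insert`, `chainId`, `het`.
#' @slot coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @slot charge,radius,ljEpsilon,ljRminHalf per-atom physical parameters;
#'   `NA` until assigned.
#' @slot title free-text description.
#' @export
setClass("Structure",
  representation(
    atoms = "data.frame",
    coords = "matrix",
    charge = "numeric",
    radius = "numeric",
    ljEpsilon = "numeric",
    ljRminHalf = "numeric",
    title = "character"
  ),
  prototype(title = "")
)

setValidity("Structure", function(object) {
  n <- nrow(object@atoms)
  msgs <- character()
  need <- c("serial", "name", "element", "resName", "resSeq", "insert",
            "chainId", "het")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@coords) != n || ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must be an n x 3 matrix matching atoms")
  if (n > 0 && !all(is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  for (s in c("charge", "radius", "ljEpsilon", "ljRminHalf"))
    if (length(slot(object, s)) != n)
      msgs <- c(msgs, paste(s, "must have one entry per atom"))
  if (n > 0) {
    key <- paste(object@atoms$chainId, object@atoms$resSeq,
                 object@atoms$insert, object@atoms$name)
    if (anyDuplicated(key))
      msgs <- c(msgs, "(chainId, resSeq, insert, name) must be unique")
    if (any(!is.na(object@radius) & object@radius < 0))
      msgs <- c(msgs, "radii must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Physical parameter table for atoms and residues
#'
#' Per (residue, atom) partial charges, vdW radii and Lennard-Jones
#' parameters, plus per-residue formal charges and model (solution) pKa
#' values for titratable residue types. The bundled default is an
#' Amber-flavoured heavy-atom (united-atom style) table in which each
#' residue's partial charges sum exactly to its formal charge.
#'
#' @slot table data.frame with columns `resName`, `atomName`, `charge`,
#'   `radius`, `ljEpsilon`, `ljRminHalf`.
#' @slot formalCharge named numeric, formal charge per residue type.
#' @slot modelPka named numeric, solution pKa per titratable residue type.
#' @export
setClass("ParameterSet",
  representation(table = "data.frame", formalCharge = "numeric",
                 modelPka = "numeric")
)

setValidity("ParameterSet", function(object) {
  msgs <- character()
  need <- c("resName", "atomName", "charge", "radius", "ljEpsilon", "ljRminHalf")
  if (!all(need %in% names(object@table)))
    msgs <- c(msgs, paste("table needs columns:", paste(need, collapse = ", ")))
  else {
    sums <- tapply(object@table$charge, object@table$resName, sum)
    fc <- object@formalCharge[names(sums)]
    bad <- names(sums)[is.na(fc) | abs(sums - fc) > 1e-6]
    if (length(bad))
      msgs <- c(msgs, paste("residues whose charges do not sum to the formal",
                            "charge within 1e-6:", paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Ion specification
#'
#' Element, charge, radius, and a stored continuum-titration reference
#' energy. The default describes Be2+ (radius 1.53 Angstrom, charge +2.0 e,
#' reference energy -18.430 kcal/mol); the reference energy is carried as
#' metadata only - single-conformer titration here does not consume it.
#'
#' @slot element element symbol, e.g. "BE".
#' @slot charge ionic charge, e.
#' @slot radius ionic radius, Angstrom.
#' @slot referenceEnergy kcal/mol (metadata).
#' @export
setClass("IonSpec",
  representation(element = "character", charge = "numeric", radius = "numeric",
                 referenceEnergy = "numeric")
)

setValidity("IonSpec", function(object) {
  msgs <- character()
  if (object@charge == 0) msgs <- c(msgs, "ion charge must be nonzero")
  if (object@radius <= 0) msgs <- c(msgs, "ion radius must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Finite-difference solver configuration
#'
#' Grid and dielectric settings for the Poisson solver. `scale` is the grid
#' spacing in Angstrom per grid unit; `perfil` the percentage of the grid
#' edge occupied by the molecule's largest dimension; `epsIn`/`epsOut` the
#' interior and solvent dielectric constants (1/80 for binding-energy runs,
#' 4/80 for pKa runs).
#'
#' @slot scale grid spacing, Angstrom (default 1).
#' @slot perfil grid fill percentage (default 70).
#' @slot epsIn,epsOut dielectric constants.
#' @slot tol convergence tolerance, max node update per sweep,
#'   kcal/(mol e).
#' @slot maxIter iteration cap.
#' @slot probeRadius probe inflation of atom radii for the dielectric
#'   boundary, Angstrom (0 = bare vdW union).
#' @export
setClass("SolverConfig",
  representation(scale = "numeric", perfil = "numeric", epsIn = "numeric",
                 epsOut = "numeric", tol = "numeric", maxIter = "integer",
                 probeRadius = "numeric"),
  prototype(scale = 1, perfil = 70, epsIn = 1, epsOut = 80, tol = 1e-6,
            maxIter = 20000L, probeRadius = 0)
)

setValidity("SolverConfig", function(object) {
  msgs <- character()
  if (object@scale <= 0) msgs <- c(msgs, "scale must be positive")
  if (object@perfil <= 0 || object@perfil > 100)
    msgs <- c(msgs, "perfil must lie in (0, 100]")
  if (object@epsIn < 1 || object@epsOut < object@epsIn)
    msgs <- c(msgs, "need epsOut >= epsIn >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Electrostatic potential on a cubic grid
#'
#' @slot origin coordinates of grid node (1,1,1), Angstrom.
#' @slot spacing grid spacing, Angstrom.
#' @slot dims grid dimensions (three odd integers).
#' @slot values 3-d array of potential, kcal/(mol e).
#' @export
setClass("PotentialGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 values = "array")
)

setValidity("PotentialGrid", function(object) {
  msgs <- character()
  if (any(object@dims < 3L)) msgs <- c(msgs, "all dims must be >= 3")
  if (!identical(dim(object@values), as.integer(object@dims)))
    msgs <- c(msgs, "values array must match dims")
  if (length(msgs)) msgs else TRUE
})

#' Free-energy decomposition of a structure
#'
#' Coulomb, polar-solvation (reaction field) and van der Waals terms, with
#' `gTotal` their exact sum. Nonpolar solvation and entropic terms are
#' deliberately excluded from the model.
#'
#' @slot eCoul,eSolvPolar,eVdw,gTotal kcal/mol.
#' @export
setClass("EnergyBreakdown",
  representation(eCoul = "numeric", eSolvPolar = "numeric", eVdw = "numeric",
                 gTotal = "numeric")
)

setValidity("EnergyBreakdown", function(object) {
  if (!isTRUE(all.equal(object@gTotal,
                        object@eCoul + object@eSolvPolar + object@eVdw,
                        tolerance = 0)) &&
      object@gTotal != object@eCoul + object@eSolvPolar + object@eVdw)
    "gTotal must equal eCoul + eSolvPolar + eVdw exactly" else TRUE
})

#' Binding free energy result for one complex partition
#'
#' Stores the free-energy breakdowns of the complex (`gAB`) and its two
#' partners (`gA`, `gB`) and the binding free energy
#' `dG = gAB - gA - gB`. Values are intended for ranking across peptides
#' and scenarios, not as absolute affinities.
#'
#' @slot scenario one of `"no_ion"`, `"pep_to_Be_protein"`,
#'   `"Bepep_to_protein"` (or a user label).
#' @slot gAB,gA,gB [EnergyBreakdown-class] objects.
#' @slot dG kcal/mol.
#' @slot partitionA,partitionB integer atom indices into the complex.
#' @slot note free text (e.g. "ranking-only", censoring notes).
#' @export
setClass("BindingResult",
  representation(scenario = "character", gAB = "EnergyBreakdown",
                 gA = "EnergyBreakdown", gB = "EnergyBreakdown",
                 dG = "numeric", partitionA = "integer",
                 partitionB = "integer", note = "character"),
  prototype(note = "ranking-only")
)

setValidity("BindingResult", function(object) {
  msgs <- character()
  if (object@dG != object@gAB@gTotal - object@gA@gTotal - object@gB@gTotal)
    msgs <- c(msgs, "dG must equal gAB - gA - gB exactly")
  if (length(intersect(object@partitionA, object@partitionB)))
    msgs <- c(msgs, "partitions must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Coordinate trajectory over a fixed atom roster
#'
#' @slot topology [Structure-class] defining the atom roster.
#' @slot xyz numeric array, frames x atoms x 3, Angstrom.
#' @slot source `"sampler"`, `"generator"` or `"file"`.
#' @export
setClass("Trajectory",
  representation(topology = "Structure", xyz = "array", source = "character"),
  prototype(source = "sampler")
)

setValidity("Trajectory", function(object) {
  d <- dim(object@xyz)
  msgs <- character()
  if (length(d) != 3L || d[3] != 3L)
    msgs <- c(msgs, "xyz must be a frames x atoms x 3 array")
  else if (d[2] != nrow(object@topology@atoms))
    msgs <- c(msgs, "xyz atom dimension must match topology")
  if (length(msgs)) msgs else TRUE
})

#' Minimizer configuration
#'
#' Steepest descent with backtracking on a heavy-atom potential
#' (Lennard-Jones + Coulomb with distance-dependent dielectric
#' eps(r) = 4r + harmonic bond/1-3 restraints derived from the input
#' geometry).
#'
#' @slot maxSteps step cap (default 5000, mirroring a typical
#'   minimization length for these systems).
#' @slot forceTol max force component for convergence, kcal/(mol Angstrom).
#' @slot stepInit initial step size, Angstrom^2 mol/kcal.
#' @export
setClass("MinimizerConfig",
  representation(maxSteps = "integer", forceTol = "numeric",
                 stepInit = "numeric"),
  prototype(maxSteps = 5000L, forceTol = 0.1, stepInit = 1e-3)
)

#' Langevin dynamics configuration for elastic-network sampling
#'
#' @slot temperature Kelvin (default 298).
#' @slot nSteps integration steps.
#' @slot dt time step, reduced units.
#' @slot friction 1/time, reduced units.
#' @slot snapshotEvery frames are stored every this many steps (default 100).
#' @slot seed RNG seed; trajectories are bitwise reproducible per seed.
#' @slot enmCutoff spring cutoff, Angstrom (default 10).
#' @slot enmK spring constant, kcal/(mol Angstrom^2).
#' @export
setClass("DynamicsConfig",
  representation(temperature = "numeric", nSteps = "integer", dt = "numeric",
                 friction = "numeric", snapshotEvery = "integer",
                 seed = "integer", enmCutoff = "numeric", enmK = "numeric"),
  prototype(temperature = 298, nSteps = 2000L, dt = 0.05, friction = 1,
            snapshotEvery = 100L, seed = 1L, enmCutoff = 10, enmK = 1)
)

setValidity("DynamicsConfig", function(object) {
  msgs <- character()
  if (object@temperature < 0) msgs <- c(msgs, "temperature must be >= 0")
  if (object@snapshotEvery < 1L) msgs <- c(msgs, "snapshotEvery must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Continuum-electrostatics titration result
#'
#' @slot sites data.frame with one row per titratable site (`chainId`,
#'   `resSeq`, `type`, `acid`, `modelPka`, `pkaInt`).
#' @slot W symmetric site-site interaction matrix, kcal/mol, zero diagonal.
#' @slot pH pH grid of the titration curves.
#' @slot curves matrix sites x pH of mean protonation fractions.
#' @slot pka50 per-site pH of half-protonation (NA when censored).
#' @slot censored per-site `""`, `"<min"` or `">max"`.
#' @slot method `"enumerate"` or `"monte_carlo"`.
#' @slot mcWarning diagnostic text when MC split-half agreement is poor.
#' @export
setClass("TitrationResult",
  representation(sites = "data.frame", W = "matrix", pH = "numeric",
                 curves = "matrix", pka50 = "numeric", censored = "character",
                 method = "character", mcWarning = "character"),
  prototype(method = "enumerate", mcWarning = "")
)

setValidity("TitrationResult", function(object) {
  n <- nrow(object@sites)
  msgs <- character()
  if (n > 0) {
    if (!identical(dim(object@W), c(n, n)) ||
        max(abs(object@W - t(object@W))) > 1e-6)
      msgs <- c(msgs, "W must be an n x n symmetric matrix (1e-6)")
    if (nrow(object@curves) != n || ncol(object@curves) != length(object@pH))
      msgs <- c(msgs, "curves must be sites x pH")
  }
  if (length(msgs)) msgs else TRUE
})

#' Pipeline run configuration
#'
#' Everything needed to reproduce a full analysis run: generator settings,
#' scenario set, solver configurations for binding (epsIn = 1) and pKa
#' (epsIn = 4) stages, dynamics settings, trailing-window fraction and a
#' single global seed from which all stage seeds derive.
#'
#' @slot nPerClass synthetic peptides generated per class.
#' @slot classes peptide classes to run.
#' @slot scenarios scenario labels to run.
#' @slot bindingConfig,pkaConfig [SolverConfig-class] objects.
#' @slot dynamicsConfig [DynamicsConfig-class].
#' @slot minimizeSteps minimization steps applied before binding energies.
#' @slot windowFraction trailing window for trajectory statistics.
#' @slot pkaCases `"representative"`, `"all"` or `"none"`.
#' @slot outDir output directory ("" = no files written).
#' @slot seed global seed.
#' @export
setClass("RunConfig",
  representation(nPerClass = "integer", classes = "character",
                 scenarios = "character", bindingConfig = "SolverConfig",
                 pkaConfig = "SolverConfig", dynamicsConfig = "DynamicsConfig",
                 minimizeSteps = "integer", windowFraction = "numeric",
                 pkaCases = "character", outDir = "character",
                 seed = "integer"),
  prototype(nPerClass = 10L, classes = c("natural", "strong", "weak", "DR"),
            scenarios = c("no_ion", "pep_to_Be_protein", "Bepep_to_protein"),
            minimizeSteps = 200L, windowFraction = 0.4,
            pkaCases = "representative", outDir = "", seed = 1L)
)
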