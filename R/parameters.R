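# Residue-level reference data used across modules.

# Model (solution) pKa values per titratable residue type. NTR/CTR are the
# peptide termini. One documented table; override via identifySites().
defaultModelPkaTable <- c(ASP = 3.65, GLU = 4.25, HIS = 6.45, LYS = 10.53,
                          ARG = 12.0, TYR = 9.84, NTR = 8.0, CTR = 3.2)

# Proton-bearing atom per titratable type: protonation adds +1 e there.
protonAtomTable <- c(ASP = "OD2", GLU = "OE2", HIS = "ND1", LYS = "NZ",
                     ARG = "NH2", TYR = "OH")

aaThree <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Load a physical parameter set
#'
#' `defaultParameterSet()` loads the parameter table bundled with the
#' package: an Amber-flavoured heavy-atom table (partial charges summing
#' exactly to each residue's formal charge, Bondi-like radii, standard
#' 12-6 Lennard-Jones parameters). `readParameterSet()` loads a
#' user-supplied TSV with columns `res_name`, `atom_name`, `charge_e`,
#' `radius_A`, `lj_eps_kcal`, `lj_rmin_half_A`.
#'
#' @param path TSV file path.
#' @return a [ParameterSet-class].
#' @export
defaultParameterSet <- function() {
  readParameterSet(system.file("extdata", "heavy_atom_params.tsv",
                               package = "ionpocket", mustWork = TRUE))
}

#' @rdname defaultParameterSet
#' @export
readParameterSet <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- c("resName", "atomName", "charge", "radius", "ljEpsilon",
                  "ljRminHalf")
  fc <- round(tapply(tab$charge, tab$resName, sum))
  new("ParameterSet", table = tab,
      formalCharge = stats::setNames(as.numeric(fc), names(fc)),
      modelPka = defaultModelPkaTable)
}

#' Beryllium (or other cation) specification
#'
#' Defaults describe Be2+: radius 1.53 Angstrom, charge +2.0 e and a
#' continuum-titration reference energy of -18.430 kcal/mol carried as
#' metadata.
#'
#' @param element element symbol.
#' @param charge ionic charge, e.
#' @param radius ionic radius, Angstrom.
#' @param referenceEnergy kcal/mol, stored but not consumed by the
#'   single-conformer titration implemented here.
#' @return an [IonSpec-class].
#' @export
ionSpec <- function(element = "BE", charge = 2.0, radius = 1.53,
                    referenceEnergy = -18.430) {
  new("IonSpec", element = element, charge = charge, radius = radius,
      referenceEnergy = referenceEnergy)
}

#' Assign charges, radii and Lennard-Jones parameters to a structure
#'
#' Looks up every atom in the parameter table by (residue, atom) name.
#' Ion HETATMs matching `ion@element` are parameterized from the ion
#' specification. Coordinates are never modified.
#'
#' @param structure a [Structure-class].
#' @param params a [ParameterSet-class] (default the bundled table).
#' @param strict if `TRUE` (default), unknown residues or atoms are an
#'   error listing the offenders; if `FALSE`, they are skipped with a
#'   warning and left with zero charge and a generic radius.
#' @param ion an [IonSpec-class] used for matching monoatomic ions.
#' @return the structure with all parameter slots populated.
#' @export
assignParameters <- function(structure, params = defaultParameterSet(),
                             strict = TRUE, ion = ionSpec()) {
  n <- nAtoms(structure)
  if (n == 0) stop("cannot parameterize an empty structure")
  at <- structure@atoms
  key <- paste(at$resName, at$name)
  tab <- params@table
  hit <- match(key, paste(tab$resName, tab$atomName))
  charge <- tab$charge[hit]
  radius <- tab$radius[hit]
  eps <- tab$ljEpsilon[hit]
  rmh <- tab$ljRminHalf[hit]
  # monoatomic ions absent from the table fall back to the ion spec
  isIon <- at$het & (at$element == ion@element | at$resName == ion@element) &
    is.na(charge)
  charge[isIon] <- ion@charge
  radius[isIon] <- ion@radius
  eps[isIon] <- 0.01
  rmh[isIon] <- ion@radius / 2
  miss <- is.na(charge)
  if (any(miss)) {
    offenders <- unique(paste0(at$resName[miss], ":", at$name[miss]))
    if (strict)
      stop("no parameters for: ", paste(offenders, collapse = ", "))
    warning("skipping atoms without parameters: ",
            paste(offenders, collapse = ", "))
    charge[miss] <- 0
    radius[miss] <- 1.7
    eps[miss] <- 0.1
    rmh[miss] <- 2.0
  }
  structure@charge <- as.numeric(charge)
  structure@radius <- as.numeric(radius)
  structure@ljEpsilon <- as.numeric(eps)
  structure@ljRminHalf <- as.numeric(rmh)
  validObject(structure)
  structure
}
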