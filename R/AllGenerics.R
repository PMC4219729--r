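#' @rdname Structure-class
#' @param x,object a [Structure-class] (or other ionpocket object).
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Structure-class
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname Structure-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Structure-class
#' @param value replacement value.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname Structure-class
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname Structure-class
#' @export
setGeneric("isParameterized", function(x) standardGeneric("isParameterized"))

#' @rdname Structure-class
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))

#' @rdname Trajectory-class
#' @param x a [Trajectory-class].
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @param i frame index.
#' @export
setGeneric("frameStructure", function(x, i) standardGeneric("frameStructure"))

setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
setMethod("atomData", "Structure", function(x) x@atoms)
setMethod("coords", "Structure", function(x) x@coords)
setMethod("coords<-", "Structure", function(x, value) {
  stopifnot(identical(dim(value), dim(x@coords)))
  x@coords <- value
  validObject(x)
  x
})
setMethod("chains", "Structure", function(x) unique(x@atoms$chainId))
setMethod("isParameterized", "Structure", function(x) {
  nAtoms(x) > 0 && !anyNA(x@charge) && !anyNA(x@radius)
})
setMethod("netCharge", "Structure", function(x) {
  if (!isParameterized(x)) stop("structure is not parameterized")
  sum(x@charge)
})

setMethod("nFrames", "Trajectory", function(x) dim(x@xyz)[1])
setMethod("nAtoms", "Trajectory", function(x) dim(x@xyz)[2])
setMethod("frameStructure", "Trajectory", function(x, i) {
  s <- x@topology
  s@coords <- matrix(x@xyz[i, , ], ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  s
})

setMethod("show", "Structure", function(object) {
  cat("Structure:", nAtoms(object), "atoms,",
      length(chains(object)), "chain(s)",
      if (isParameterized(object)) sprintf("[parameterized, net charge %+.3f e]",
                                           sum(object@charge)) else "[bare]",
      "\n")
  if (nzchar(object@title)) cat(" ", object@title, "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nAtoms(object),
      "atoms (source:", paste0(object@source, ")"), "\n")
})

setMethod("show", "PotentialGrid", function(object) {
  cat(sprintf("PotentialGrid: %d x %d x %d, spacing %.3f A, range [%.3g, %.3g] kcal/(mol e)\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              min(object@values), max(object@values)))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown: G = %.3f (Coul %.3f, solv %.3f, vdW %.3f) kcal/mol\n",
              object@gTotal, object@eCoul, object@eSolvPolar, object@eVdw))
})

setMethod("show", "BindingResult", function(object) {
  cat(sprintf("BindingResult [%s]: dG = %.3f kcal/mol (%s)\n",
              object@scenario, object@dG, object@note))
})

setMethod("show", "TitrationResult", function(object) {
  cat("TitrationResult:", nrow(object@sites), "site(s), method",
      object@method, "\n")
  if (nrow(object@sites)) {
    df <- object@sites
    df$pka50 <- ifelse(nzchar(object@censored), object@censored,
                       sprintf("%.2f", object@pka50))
    print(df, row.names = FALSE)
  }
})

setMethod("show", "IonSpec", function(object) {
  cat(sprintf("IonSpec %s: charge %+.1f e, radius %.2f A, reference energy %.3f kcal/mol\n",
              object@element, object@charge, object@radius,
              object@referenceEnergy))
})
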