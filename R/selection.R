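#' Select atoms from a structure
#'
#' `selectIndices()` resolves a selection to integer atom indices (in file
#' order); `selectAtoms()` returns the corresponding sub-structure. All
#' criteria are combined with AND; `NULL` criteria are ignored. An empty
#' selection is allowed and returns a zero-atom result.
#'
#' @param structure a [Structure-class].
#' @param chain chain identifier(s).
#' @param resSeq residue number(s); pass a range as e.g. `50:86`.
#' @param resName residue name(s), e.g. `"GLU"`.
#' @param atomName atom name(s), e.g. `"CA"`.
#' @param element element symbol(s).
#' @param het `TRUE`/`FALSE` to keep only HETATM / only ATOM records.
#' @return `selectIndices()`: integer vector; `selectAtoms()`: a
#'   [Structure-class] preserving atom order.
#' @examples
#' r <- makeAcidicPocketReceptor(1)$structure
#' selectAtoms(r, chain = "B", resName = "GLU")
#' @export
selectIndices <- function(structure, chain = NULL, resSeq = NULL,
                          resName = NULL, atomName = NULL, element = NULL,
                          het = NULL) {
  at <- structure@atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chainId %in% chain
  if (!is.null(resSeq)) {
    if (!is.numeric(resSeq)) stop("resSeq selection must be numeric")
    keep <- keep & at$resSeq %in% resSeq
  }
  if (!is.null(resName)) keep <- keep & at$resName %in% resName
  if (!is.null(atomName)) keep <- keep & at$name %in% atomName
  if (!is.null(element)) keep <- keep & at$element %in% element
  if (!is.null(het)) keep <- keep & at$het == het
  which(keep)
}

#' @rdname selectIndices
#' @export
selectAtoms <- function(structure, chain = NULL, resSeq = NULL,
                        resName = NULL, atomName = NULL, element = NULL,
                        het = NULL) {
  idx <- selectIndices(structure, chain = chain, resSeq = resSeq,
                       resName = resName, atomName = atomName,
                       element = element, het = het)
  subsetStructure(structure, idx)
}

subsetStructure <- function(structure, idx) {
  newStructure(structure@atoms[idx, , drop = FALSE],
               structure@coords[idx, , drop = FALSE],
               charge = structure@charge[idx],
               radius = structure@radius[idx],
               ljEpsilon = structure@ljEpsilon[idx],
               ljRminHalf = structure@ljRminHalf[idx],
               title = structure@title)
}

#' Remap residue numbering of a chain
#'
#' Applies a constant offset to the residue numbers of one chain, for
#' reconciling author numbering between structures.
#'
#' @param structure a [Structure-class].
#' @param chain chain to renumber.
#' @param offset integer added to `resSeq`.
#' @return the renumbered structure.
#' @export
renumberChain <- function(structure, chain, offset) {
  sel <- structure@atoms$chainId %in% chain
  structure@atoms$resSeq[sel] <- structure@atoms$resSeq[sel] + as.integer(offset)
  validObject(structure)
  structure
}
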