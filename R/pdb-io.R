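#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM/MODEL/TER records (via bio3d) into a
#' [Structure-class]. Atom order, insertion codes and HETATM records are
#' preserved; HETATM atoms are flagged in the atom table.
#'
#' @param path path to a PDB file.
#' @param modelIndex optional model number for multi-model files (default
#'   the first model).
#' @return a [Structure-class].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writePDB(makeBornFixture(2, 2)$structure, f)
#' readPDB(f)
#' @export
readPDB <- function(path, modelIndex = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  checkCoordinateFields(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    if (modelIndex > nrow(xyz)) stop("modelIndex beyond number of models")
    xyz <- xyz[modelIndex, ]
  }
  bio3dToStructure(pdb, as.numeric(xyz), title = basename(path))
}

# Fail early, naming the offending line, when coordinate columns are not
# numeric; bio3d's own message does not locate the record.
checkCoordinateFields <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) return(invisible(TRUE))
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    val <- suppressWarnings(as.numeric(substr(lines[rec], fld[1], fld[2])))
    if (anyNA(val)) {
      bad <- which(rec)[which(is.na(val))[1]]
      stop("malformed coordinate field at line ", bad, " of ", path)
    }
  }
  invisible(TRUE)
}

bio3dToStructure <- function(pdb, xyz, title = "") {
  at <- pdb$atom
  n <- nrow(at)
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | !nzchar(elem)
  if (any(blank)) elem[blank] <- elementFromName(at$elety[blank])
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = toupper(elem),
    resName = trimws(at$resid),
    resSeq = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", trimws(at$insert)),
    chainId = ifelse(is.na(at$chain), " ", at$chain),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  co <- matrix(xyz[seq_len(3 * n)], ncol = 3, byrow = TRUE)
  newStructure(atoms, co, title = title)
}

elementFromName <- function(name) {
  nm <- toupper(gsub("[0-9'\" ]", "", name))
  two <- c("BE", "FE", "ZN", "MG", "CA", "NA", "CL", "MN", "CU", "BR")
  ifelse(nm %in% two & nchar(nm) == 2, nm, substr(nm, 1, 1))
}

structureToBio3dArgs <- function(structure) {
  at <- structure@atoms
  list(
    xyz = as.numeric(t(structure@coords)),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resSeq,
    resid = at$resName,
    eleno = at$serial,
    elety = at$name,
    chain = at$chainId,
    insert = ifelse(nzchar(at$insert), at$insert, NA),
    elesy = at$element
  )
}

#' Write a structure (or trajectory) to a PDB file
#'
#' Fixed-column PDB output via bio3d. A [Trajectory-class] is written as a
#' multi-model file with one MODEL/ENDMDL block per frame.
#'
#' @param x a [Structure-class] or [Trajectory-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePDB <- function(x, path) {
  if (is(x, "Trajectory")) {
    a <- structureToBio3dArgs(x@topology)
    nf <- nFrames(x)
    a$xyz <- t(vapply(seq_len(nf),
                      function(i) as.numeric(t(x@xyz[i, , ])),
                      numeric(3 * nAtoms(x))))
  } else {
    if (nAtoms(x) == 0) stop("refusing to write an empty structure")
    a <- structureToBio3dArgs(x)
  }
  do.call(bio3d::write.pdb,
          c(list(pdb = NULL, file = path), a))
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path multi-model PDB file.
#' @param minFrames minimum number of frames the caller requires
#'   (default 2; trajectory statistics need at least two frames).
#' @return a [Trajectory-class] with `source = "file"`, frames in model
#'   order.
#' @export
readTrajectory <- function(path, minFrames = 2L) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  checkModelRosters(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < minFrames)
    stop("trajectory has ", nrow(xyz), " frame(s); at least ", minFrames,
         " required")
  topo <- bio3dToStructure(pdb, as.numeric(xyz[1, ]), title = basename(path))
  arr <- array(NA_real_, c(nrow(xyz), nAtoms(topo), 3))
  for (i in seq_len(nrow(xyz)))
    arr[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  new("Trajectory", topology = topo, xyz = arr, source = "file")
}

# Verify that every MODEL block names the same atoms in the same order.
checkModelRosters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  roster <- function(b, e) {
    rec <- lines[b:e]
    rec <- rec[grepl("^(ATOM  |HETATM)", rec)]
    substr(rec, 7, 27)
  }
  ref <- roster(starts[1], ends[1])
  for (m in seq_along(starts)[-1]) {
    if (!identical(roster(starts[m], ends[m]), ref))
      stop("atom roster of model ", m, " differs from model 1 in ", path)
  }
  invisible(TRUE)
}

#' Export a potential grid in OpenDX format
#'
#' Writes the scalar field in the OpenDX regular-grid dialect understood by
#' PyMOL, VMD and Chimera.
#'
#' @param grid a [PotentialGrid-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeOpenDX <- function(grid, path) {
  d <- grid@dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %g 0 0", grid@spacing),
    sprintf("delta 0 %g 0", grid@spacing),
    sprintf("delta 0 0 %g", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX stores z fastest; our array is x fastest
  vals <- aperm(grid@values, c(3, 2, 1))
  writeLines(apply(matrix(c(as.numeric(vals),
                            rep(NA, (3 - prod(d) %% 3) %% 3)),
                          nrow = 3),
                   2, function(r) paste(stats::na.omit(r), collapse = " ")),
             con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
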