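# Internal helpers shared across modules.

# Coulomb constant, kcal A / (mol e^2)
KE <- 332.0636
# Boltzmann constant, kcal/(mol K)
KB <- 0.0019872041
# 2.303 R T at 298 K, kcal/mol per pKa unit
RT_LN10 <- 1.364

`%||%` <- function(a, b) if (is.null(a)) b else a

newStructure <- function(atoms, coords, charge = NULL, radius = NULL,
                         ljEpsilon = NULL, ljRminHalf = NULL, title = "") {
  n <- nrow(atoms)
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("Structure", atoms = atoms, coords = coords,
      charge = charge %||% rep(NA_real_, n),
      radius = radius %||% rep(NA_real_, n),
      ljEpsilon = ljEpsilon %||% rep(NA_real_, n),
      ljRminHalf = ljRminHalf %||% rep(NA_real_, n),
      title = title)
}

emptyAtomTable <- function(n = 0) {
  data.frame(serial = integer(n), name = character(n), element = character(n),
              resName = character(n), resSeq = integer(n),
              insert = character(n), chainId = character(n),
              het = logical(n), stringsAsFactors = FALSE)
}

# Pairwise distance matrix between row-coordinate matrices (Angstrom).
pairDist <- function(a, b = a) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Deterministic derivation of stage seeds from a global seed (kept < 2^31).
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103 + h * 7919 + 12345) %% 2147483647)
}

# Evaluate with a local RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Unique residue identifiers in atom order.
residueKeys <- function(atoms) {
  paste(atoms$chainId, atoms$resSeq, atoms$insert, sep = "|")
}

residueIndexList <- function(structure) {
  keys <- residueKeys(structure@atoms)
  split(seq_along(keys), factor(keys, levels = unique(keys)))
}
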