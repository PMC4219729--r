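#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mov` onto `ref` in
#' the least-squares sense, with optional weights. Reflections are
#' corrected so the returned rotation always has determinant +1.
#'
#' @param ref,mov n x 3 coordinate matrices, n >= 3 and non-collinear.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3;
#'   `mov %*% rotation + translation` approximates `ref`) and `rmsd`.
#' @export
kabschSuperpose <- function(ref, mov, weights = NULL) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  n <- nrow(ref)
  if (n < 3 || nrow(mov) != n) stop("need matching point sets of size >= 3")
  w <- if (is.null(weights)) rep(1, n) else weights
  w <- w / sum(w)
  cr <- colSums(ref * w)
  cm <- colSums(mov * w)
  a <- sweep(ref, 2, cr)
  b <- sweep(mov, 2, cm)
  h <- t(b * w) %*% a
  sv <- svd(h)
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12)
    stop("degenerate (collinear) point set")
  sgn <- sign(det(sv$v %*% t(sv$u)))
  dmat <- diag(c(1, 1, sgn))
  rot <- sv$u %*% dmat %*% t(sv$v)
  fit <- b %*% rot
  rmsd <- sqrt(sum(w * rowSums((fit - a)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot),
       rmsd = rmsd)
}

#' Default pocket residue pairs
#'
#' The five CA-CA distances across the binding-groove helices used to
#' monitor pocket width, labelled D1-D5: (Arg76.A, Glu50.B),
#' (Leu70.A, Tyr58.B), (Ile65.A, Asp64.B), (Leu60.A, Met76.B),
#' (Ala56.A, Leu83.B).
#'
#' @return data.frame with columns `label`, `chain1`, `res1`, `chain2`,
#'   `res2`.
#' @export
defaultPocketPairs <- function() {
  data.frame(
    label = paste0("D", 1:5),
    chain1 = "A", res1 = c(76L, 70L, 65L, 60L, 56L),
    chain2 = "B", res2 = c(50L, 58L, 64L, 76L, 83L),
    stringsAsFactors = FALSE
  )
}

#' RMSD time series over a trajectory
#'
#' Per frame, superposes the fit selection onto the reference and reports
#' the (unweighted) RMSD over the measurement selection. Selections are
#' integer atom indices into the trajectory topology (see
#' [selectIndices()]); the default measurement in groove analyses is the
#' CA atoms of helix residues 50-86 of chain B.
#'
#' @param traj a [Trajectory-class].
#' @param fitSelection atom indices used for superposition (default: all
#'   atoms outside the measurement selection, falling back to the
#'   measurement selection itself).
#' @param measureSelection atom indices whose RMSD is reported.
#' @param reference `"frame1"` (default) or a [Structure-class] with the
#'   same roster (e.g. the crystallographic structure).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdSeries <- function(traj, measureSelection,
                       fitSelection = NULL, reference = "frame1") {
  nA <- nAtoms(traj)
  if (!length(measureSelection)) stop("empty measurement selection")
  if (any(measureSelection > nA)) stop("selection outside atom roster")
  if (is.null(fitSelection)) {
    fitSelection <- setdiff(seq_len(nA), measureSelection)
    if (length(fitSelection) < 3) fitSelection <- measureSelection
  }
  refCo <- if (is(reference, "Structure")) reference@coords
           else matrix(traj@xyz[1, , ], ncol = 3)
  out <- numeric(nFrames(traj))
  for (f in seq_len(nFrames(traj))) {
    co <- matrix(traj@xyz[f, , ], ncol = 3)
    kb <- kabschSuperpose(refCo[fitSelection, , drop = FALSE],
                          co[fitSelection, , drop = FALSE])
    fitted <- co %*% kb$rotation +
      matrix(kb$translation, nA, 3, byrow = TRUE)
    dif <- fitted[measureSelection, , drop = FALSE] -
      refCo[measureSelection, , drop = FALSE]
    out[f] <- sqrt(mean(rowSums(dif^2)))
  }
  out
}

#' CA-CA distance time series for residue pairs
#'
#' Euclidean distance between the CA atoms of each residue pair in each
#' frame.
#'
#' @param traj a [Trajectory-class].
#' @param pairs data.frame as from [defaultPocketPairs()].
#' @return matrix frames x pairs (columns named by `label`), Angstrom.
#' @export
caDistanceSeries <- function(traj, pairs = defaultPocketPairs()) {
  topo <- traj@topology
  idx <- function(chain, res) {
    i <- selectIndices(topo, chain = chain, resSeq = res, atomName = "CA")
    if (!length(i))
      stop("no CA atom for residue ", res, " in chain ", chain)
    i[1]
  }
  i1 <- mapply(idx, pairs$chain1, pairs$res1)
  i2 <- mapply(idx, pairs$chain2, pairs$res2)
  out <- matrix(NA_real_, nFrames(traj), nrow(pairs),
                dimnames = list(NULL, pairs$label))
  for (f in seq_len(nFrames(traj))) {
    co <- matrix(traj@xyz[f, , ], ncol = 3)
    out[f, ] <- sqrt(rowSums((co[i1, , drop = FALSE] -
                                co[i2, , drop = FALSE])^2))
  }
  out
}

#' Trailing-window statistics of a series
#'
#' Mean, standard deviation and 2 x sd over the trailing fraction of a
#' series - the saturation window of an equilibrating trajectory
#' observable (default: the last 40 percent of frames).
#'
#' @param series numeric vector (one observable over frames).
#' @param windowFraction trailing fraction in (0, 1], default 0.4.
#' @return list with `windowFraction`, `n`, `mean`, `sd`, `twoSd`,
#'   `median`.
#' @export
windowStats <- function(series, windowFraction = 0.4) {
  nWin <- floor(length(series) * windowFraction)
  if (nWin < 2) stop("window must contain at least 2 frames")
  w <- series[(length(series) - nWin + 1):length(series)]
  s <- stats::sd(w)
  list(windowFraction = windowFraction, n = nWin, mean = mean(w), sd = s,
       twoSd = 2 * s, median = stats::median(w))
}

#' Aggregate window statistics across the cases of a group
#'
#' Group-level representative value across cases (e.g. the 10 peptides
#' of a class): the median of per-case values for RMSD observables and
#' the mean for distance observables, following the aggregation
#' convention used in groove analyses.
#'
#' @param values numeric vector of per-case window statistics.
#' @param aggregate `"median"` or `"mean"`.
#' @return the aggregated value.
#' @export
groupAggregate <- function(values, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "median") stats::median(values) else mean(values)
}
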