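# Ensemble superposition and statistics: Kabsch least-squares fitting,
# iterative superposition onto the mean structure, per-residue RMSF,
# alignment-guided cross-structure superposition with outlier pruning,
# and sequence-separation classification of NOE distance restraints.

BACKBONE_ATOMS <- c("N", "CA", "C")

# Row indices of the ensemble's atom table matching a residue range and atom
# class. "backbone" = N, CA, C (carbonyl oxygen excluded); "heavy" = all
# non-hydrogen atoms; "CA" = alpha carbons only.
selectAtoms <- function(ensemble, residueRange = NULL,
                        atomClass = c("backbone", "heavy", "CA")) {
  atomClass <- match.arg(atomClass)
  at <- atomTable(ensemble)
  keep <- !grepl("^H|^[0-9]H", at$atomName) # hydrogens never selected
  if (atomClass == "backbone") keep <- keep & at$atomName %in% BACKBONE_ATOMS
  if (atomClass == "CA") keep <- keep & at$atomName == "CA"
  if (!is.null(residueRange))
    keep <- keep & at$residueId >= residueRange[1] &
      at$residueId <= residueRange[2]
  idx <- which(keep)
  if (!length(idx)) stop("empty atom selection", call. = FALSE)
  idx
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' of \code{moving} onto \code{fixed} via the SVD of the covariance matrix;
#' a reflection in the SVD solution is corrected by flipping the sign of the
#' smallest singular vector, so the result is always a pure rotation.
#'
#' @param moving,fixed n x 3 coordinate matrices with matched rows (n >= 3)
#' @param weights optional non-negative per-atom weights
#' @return a \linkS4class{SuperpositionResult}; apply the transform as
#'   \code{moving \%*\% t(rotation) + translation} (rows)
#' @export
kabsch <- function(moving, fixed, weights = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopIfNot(nrow(moving) == nrow(fixed) && ncol(moving) == 3 &&
              ncol(fixed) == 3, "need matched n x 3 coordinate sets")
  n <- nrow(moving)
  stopIfNot(n >= 3, "need >= 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)

  cm <- colSums(moving * w)
  cf <- colSums(fixed * w)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- crossprod(A * w, B) # 3x3 covariance
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate geometry: points are (nearly) collinear", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - B)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cf - cm %*% t(R)),
      rmsd = rmsd, nPairs = as.integer(n))
}

applySuperposition <- function(coords, sup) {
  sweep(coords %*% t(sup@rotation), 2, sup@translation, "+")
}

# Superpose all models of a coordinate stack (n x 3 x m) onto the mean
# structure, iterating until the mean moves by < tol Angstrom.
superposeToMean <- function(stack, tol = 1e-6, maxIter = 100) {
  m <- dim(stack)[3]
  mean0 <- apply(stack, c(1, 2), mean)
  for (iter in seq_len(maxIter)) {
    for (k in seq_len(m)) {
      sup <- kabsch(stack[, , k], mean0)
      stack[, , k] <- applySuperposition(stack[, , k], sup)
    }
    mean1 <- apply(stack, c(1, 2), mean)
    if (max(abs(mean1 - mean0)) < tol) break
    mean0 <- mean1
  }
  list(stack = stack, mean = mean1)
}

#' Ensemble precision statistics (RMSD to the mean structure)
#'
#' Superposes every model onto the evolving mean structure over the selected
#' atoms until the mean converges, then reports the distribution of
#' per-model RMSDs to the mean — the convention behind "mean (+/- SD)
#' (min..max)" precision tables for NMR bundles. A pairwise alternative
#' (mean RMSD over all model pairs, each pair optimally superposed) is
#' available via \code{method = "pairwise"}.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}
#' @param residueRange \code{c(from, to)} or NULL for all residues
#' @param atomClass "backbone" (N, CA, C), "heavy" or "CA"
#' @param method "to-mean" (default) or "pairwise"
#' @return list with \code{mean}, \code{sd}, \code{min}, \code{max} and
#'   \code{perModel} (numeric vector of per-model RMSDs; per-pair RMSDs for
#'   the pairwise method)
#' @export
ensembleStats <- function(ensemble, residueRange = NULL,
                          atomClass = c("backbone", "heavy", "CA"),
                          method = c("to-mean", "pairwise")) {
  atomClass <- match.arg(atomClass)
  method <- match.arg(method)
  stopIfNot(nModels(ensemble) >= 2, "need >= 2 models")
  idx <- selectAtoms(ensemble, residueRange, atomClass)
  stack <- ensemble@coords[idx, , , drop = FALSE]
  if (method == "to-mean") {
    sp <- superposeToMean(stack)
    per <- vapply(seq_len(dim(stack)[3]), function(k)
      sqrt(mean(rowSums((sp$stack[, , k] - sp$mean)^2))), 0)
  } else {
    m <- dim(stack)[3]
    pairs <- utils::combn(m, 2)
    per <- apply(pairs, 2, function(p)
      kabsch(stack[, , p[1]], stack[, , p[2]])@rmsd)
  }
  list(mean = mean(per), sd = stats::sd(per), min = min(per),
       max = max(per), perModel = per)
}

#' Per-residue root-mean-square fluctuation
#'
#' After iterative superposition onto the mean structure,
#' \deqn{RMSF_r = \sqrt{\mathrm{mean}_{models,\,atoms\,of\,r}
#'   \; \|x - \bar{x}\|^2}}
#' over the residue's selected atoms.
#'
#' @inheritParams ensembleStats
#' @return data frame with columns \code{residue} and \code{rmsf} (Angstrom)
#' @export
perResidueRmsf <- function(ensemble, atomClass = c("backbone", "heavy", "CA")) {
  atomClass <- match.arg(atomClass)
  idx <- selectAtoms(ensemble, NULL, atomClass)
  stack <- ensemble@coords[idx, , , drop = FALSE]
  sp <- superposeToMean(stack)
  dev2 <- sapply(seq_len(dim(stack)[3]), function(k)
    rowSums((sp$stack[, , k] - sp$mean)^2))
  perAtom <- rowMeans(dev2)
  res <- atomTable(ensemble)$residueId[idx]
  agg <- tapply(perAtom, res, mean)
  data.frame(residue = as.integer(names(agg)), rmsf = sqrt(unname(agg)))
}

# One-letter sequence of an ensemble's first model, with the residue ids it
# corresponds to.
ensembleSequence <- function(ensemble) {
  at <- atomTable(ensemble)
  ca <- at$atomName == "CA"
  list(residues = at$residueId[ca], seq = paste(aa321(at$residueName[ca]),
                                                collapse = ""))
}

#' Alignment-guided superposition of two structures
#'
#' Derives each chain's sequence from its residue records, pairs C-alpha
#' atoms through a global sequence alignment, superposes them with
#' [kabsch()], then iteratively prunes pairs deviating more than
#' \code{pruneCutoff} Angstrom beyond the current RMSD and re-superposes
#' until the pair set is stable. Pruning concentrates the fit on the
#' conserved core, the standard practice when comparing homologous folds
#' with divergent loops and tails.
#'
#' @param a,b \linkS4class{StructureEnsemble}s; the first model of each is
#'   used
#' @param pruneCutoff pruning margin in Angstrom; \code{Inf} disables
#'   pruning
#' @param maxIter maximal pruning iterations
#' @return a \linkS4class{SuperpositionResult} for \code{a} onto \code{b}
#'   (nPairs = pairs surviving pruning)
#' @export
alignSuperpose <- function(a, b, pruneCutoff = 2, maxIter = 20) {
  sa <- ensembleSequence(a)
  sb <- ensembleSequence(b)
  al <- globalAlign(sa$seq, sb$seq)
  pa <- strsplit(al$alignedA, "")[[1]]
  pb <- strsplit(al$alignedB, "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  paired <- pa != "-" & pb != "-"
  idxA <- ia[paired]
  idxB <- ib[paired]

  caA <- selectAtoms(a, NULL, "CA")
  caB <- selectAtoms(b, NULL, "CA")
  xa <- modelCoords(a)[caA, , 1, drop = FALSE][, , 1][idxA, , drop = FALSE]
  xb <- modelCoords(b)[caB, , 1, drop = FALSE][, , 1][idxB, , drop = FALSE]

  keep <- rep(TRUE, nrow(xa))
  sup <- NULL
  for (it in seq_len(maxIter)) {
    if (sum(keep) < 3)
      stop("fewer than 3 aligned pairs after pruning (", sum(keep),
           " left)", call. = FALSE)
    sup <- kabsch(xa[keep, ], xb[keep, ])
    if (!is.finite(pruneCutoff)) break
    dev <- sqrt(rowSums((applySuperposition(xa, sup) - xb)^2))
    newKeep <- keep & dev <= sup@rmsd + pruneCutoff
    if (identical(newKeep, keep)) break
    keep <- newKeep
  }
  sup
}

#' Classify NOE distance restraints by sequence separation
#'
#' Classes are defined solely by \eqn{|i-j|}: short when \eqn{|i-j| \le 1}
#' (intra-residue and sequential), medium when \eqn{1 < |i-j| < 5}
#' (helix-defining), long when \eqn{|i-j| \ge 5} (tertiary contacts). Every
#' restraint falls in exactly one class, so the counts always sum to the
#' total.
#'
#' @param restraints data frame with integer columns \code{residue_i},
#'   \code{residue_j} (other columns are ignored)
#' @return list with \code{short}, \code{medium}, \code{long}, \code{total}
#'   and a \code{class} factor aligned with the input rows
#' @export
classifyRestraints <- function(restraints) {
  i <- restraints$residue_i
  j <- restraints$residue_j
  if (any(i < 1 | j < 1) || anyNA(i) || anyNA(j))
    stop("residue ids must be positive integers", call. = FALSE)
  sep <- abs(i - j)
  cls <- cut(sep, c(-1, 1, 4, Inf), labels = c("short", "medium", "long"))
  cnt <- table(cls)
  list(short = unname(cnt[["short"]]), medium = unname(cnt[["medium"]]),
       long = unname(cnt[["long"]]), total = length(sep), class = cls)
}
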