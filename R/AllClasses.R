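#' @import methods
NULL

# ---------------------------------------------------------------------------
# Design objects for the synthetic-data generators
# ---------------------------------------------------------------------------

#' Design of a synthetic fast-exchange titration
#'
#' Describes a two-dimensional \eqn{^1H}-\eqn{^{15}N} HSQC titration in the
#' fast-exchange regime: peaks of residues at the binding interface move from
#' their free position towards the bound position by the fraction of protein
#' bound, which follows the quadratic 1:1 binding isotherm with a single
#' dissociation constant shared by all residues.
#'
#' @slot proteinTotal total protein concentration \eqn{[P]_t} in micromolar,
#'   held constant across titration points.
#' @slot ligandRatios strictly increasing molar ratios \eqn{[L]_t/[P]_t};
#'   the first ratio must be 0 (the free reference spectrum).
#' @slot trueKd dissociation constant in micromolar, shared by all residues.
#' @slot interface data frame with columns \code{residue}, \code{dHmax},
#'   \code{dNmax}: per-residue maximal shift changes (ppm) at saturation.
#'   Residues absent from this table do not move.
#' @slot broadened integer residue ids whose peaks vanish (exchange
#'   broadening) once the bound fraction exceeds \code{broadenCutoff}.
#' @slot broadenCutoff bound fraction above which broadened peaks are dropped.
#' @slot nResidues number of assigned residues in the spectrum.
#' @slot noiseSd standard deviation (ppm) of independent Gaussian noise added
#'   to each peak coordinate on each axis.
#' @slot seed integer seed making generation reproducible.
#' @export
setClass("TitrationDesign", representation(
  proteinTotal  = "numeric",
  ligandRatios  = "numeric",
  trueKd        = "numeric",
  interface     = "data.frame",
  broadened     = "integer",
  broadenCutoff = "numeric",
  nResidues     = "integer",
  noiseSd       = "numeric",
  seed          = "integer"
))

setValidity("TitrationDesign", function(object) {
  msg <- character()
  r <- object@ligandRatios
  if (length(r) < 2 || any(diff(r) <= 0))
    msg <- c(msg, "ligandRatios must be strictly increasing with >= 2 points")
  if (length(r) && r[1] != 0)
    msg <- c(msg, "first ligand ratio must be 0 (free reference point)")
  if (object@trueKd <= 0) msg <- c(msg, "trueKd must be > 0")
  if (object@proteinTotal <= 0) msg <- c(msg, "proteinTotal must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  need <- c("residue", "dHmax", "dNmax")
  if (!all(need %in% names(object@interface)))
    msg <- c(msg, "interface must have columns residue, dHmax, dNmax")
  else if (any(!object@interface$residue %in% seq_len(object@nResidues)))
    msg <- c(msg, "interface residues must lie in 1..nResidues")
  if (any(!object@broadened %in% seq_len(object@nResidues)))
    msg <- c(msg, "broadened residues must lie in 1..nResidues")
  if (object@broadenCutoff <= 0 || object@broadenCutoff > 1)
    msg <- c(msg, "broadenCutoff must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Design of a synthetic relaxation-decay experiment
#'
#' Intensities decay as \eqn{I(t) = I_0 \exp(-t/T)} on a fixed delay grid,
#' with optional additive Gaussian noise.
#'
#' @slot kind "T1" or "T2" (labels the delay grid; the decay model is shared).
#' @slot delays strictly increasing relaxation delays in seconds (>= 0).
#' @slot trueT named numeric: true time constant (s) per residue.
#' @slot I0 named numeric: true intensity at zero delay per residue.
#' @slot noiseSd standard deviation of additive intensity noise.
#' @slot seed integer seed.
#' @export
setClass("RelaxationDesign", representation(
  kind    = "character",
  delays  = "numeric",
  trueT   = "numeric",
  I0      = "numeric",
  noiseSd = "numeric",
  seed    = "integer"
))

setValidity("RelaxationDesign", function(object) {
  msg <- character()
  d <- object@delays
  if (length(d) < 3 || any(d < 0) || any(diff(d) <= 0))
    msg <- c(msg, "delays must be >= 0, strictly increasing, length >= 3")
  if (any(object@trueT <= 0)) msg <- c(msg, "all trueT must be > 0")
  if (length(object@trueT) != length(object@I0))
    msg <- c(msg, "trueT and I0 must have the same length")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@kind %in% c("T1", "T2")) msg <- c(msg, "kind must be T1 or T2")
  if (length(msg)) msg else TRUE
})

#' Design of a synthetic coordinate ensemble
#'
#' Emulates an NMR-style structure bundle: a rigid folded core plus flexible
#' segments (typically the termini) whose positional scatter across models is
#' larger. Models are noisy copies of a common self-avoiding backbone trace.
#'
#' @slot nModels number of models (>= 2).
#' @slot nResidues chain length.
#' @slot flexibleRanges list of integer vectors \code{c(from, to)} (1-based,
#'   inclusive) marking residue intervals with inflated noise.
#' @slot coreNoiseSd per-coordinate Gaussian noise (Angstrom) in the core.
#' @slot tailNoiseSd per-coordinate noise inside \code{flexibleRanges};
#'   must be >= \code{coreNoiseSd}.
#' @slot seed integer seed.
#' @export
setClass("EnsembleDesign", representation(
  nModels        = "integer",
  nResidues      = "integer",
  flexibleRanges = "list",
  coreNoiseSd    = "numeric",
  tailNoiseSd    = "numeric",
  seed           = "integer"
))

setValidity("EnsembleDesign", function(object) {
  msg <- character()
  if (object@nModels < 2L) msg <- c(msg, "nModels must be >= 2")
  if (object@nResidues < 2L) msg <- c(msg, "nResidues must be >= 2")
  if (object@coreNoiseSd < 0) msg <- c(msg, "coreNoiseSd must be >= 0")
  if (object@tailNoiseSd < object@coreNoiseSd)
    msg <- c(msg, "tailNoiseSd must be >= coreNoiseSd")
  for (rg in object@flexibleRanges) {
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 1 ||
        rg[2] > object@nResidues)
      msg <- c(msg, "each flexible range must be c(from, to) within the chain")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' Titration series: one peak list per titration point
#'
#' @slot peaks list of data frames, one per titration point, each with
#'   columns \code{residue}, \code{deltaH} (ppm), \code{deltaN} (ppm) and
#'   optionally \code{height}.
#' @slot proteinTotal numeric vector of \eqn{[P]_t} (micromolar) per point.
#' @slot ligandTotal numeric vector of \eqn{[L]_t} (micromolar) per point.
#' @export
setClass("TitrationSeries", representation(
  peaks        = "list",
  proteinTotal = "numeric",
  ligandTotal  = "numeric"
))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  n <- length(object@peaks)
  if (length(object@proteinTotal) != n || length(object@ligandTotal) != n)
    msg <- c(msg, "concentration vectors must match the number of peak lists")
  if (any(object@proteinTotal < 0) || any(object@ligandTotal < 0))
    msg <- c(msg, "concentrations must be >= 0")
  for (p in object@peaks) {
    if (!all(c("residue", "deltaH", "deltaN") %in% names(p)))
      msg <- c(msg, "each peak list needs columns residue, deltaH, deltaN")
    else if (anyDuplicated(p$residue))
      msg <- c(msg, "at most one peak per residue per titration point")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Per-residue relaxation data
#'
#' For kinds "T1" and "T2", \code{intensities} is a residues-by-delays matrix
#' (rownames are residue ids). For kind "hetNOE" it has exactly two columns,
#' \code{sat} and \code{unsat}.
#'
#' @slot kind "T1", "T2" or "hetNOE".
#' @slot delays delay grid in seconds (empty for hetNOE).
#' @slot intensities numeric matrix, see Details.
#' @slot noiseEstimate spectral noise level in intensity units.
#' @export
setClass("RelaxationSeries", representation(
  kind          = "character",
  delays        = "numeric",
  intensities   = "matrix",
  noiseEstimate = "numeric"
))

setValidity("RelaxationSeries", function(object) {
  msg <- character()
  if (!object@kind %in% c("T1", "T2", "hetNOE"))
    msg <- c(msg, "kind must be T1, T2 or hetNOE")
  if (object@kind %in% c("T1", "T2")) {
    if (ncol(object@intensities) != length(object@delays))
      msg <- c(msg, "one intensity column per delay is required")
    if (length(object@delays) && any(diff(object@delays) <= 0))
      msg <- c(msg, "delays must be strictly increasing")
  } else if (!identical(colnames(object@intensities), c("sat", "unsat"))) {
    msg <- c(msg, "hetNOE intensities need columns sat, unsat")
  }
  if (is.null(rownames(object@intensities)))
    msg <- c(msg, "intensity rows must be named by residue id")
  if (length(msg)) msg else TRUE
})

#' Multi-model coordinate ensemble
#'
#' All models share one atom inventory; coordinates are stored as an
#' \code{nAtoms x 3 x nModels} array in Angstrom.
#'
#' @slot atoms data frame with columns \code{residueId}, \code{residueName},
#'   \code{atomName}, one row per atom of the shared inventory.
#' @slot coords numeric array \code{c(nAtoms, 3, nModels)}.
#' @export
setClass("StructureEnsemble", representation(
  atoms  = "data.frame",
  coords = "array"
))

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be an nAtoms x 3 x nModels array")
  else if (d[1] != nrow(object@atoms))
    msg <- c(msg, "coords rows must match the atom table")
  if (!all(c("residueId", "residueName", "atomName") %in% names(object@atoms)))
    msg <- c(msg, "atoms needs columns residueId, residueName, atomName")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Result objects
# ---------------------------------------------------------------------------

#' Result of a dissociation-constant fit
#'
#' @slot kd fitted dissociation constant (micromolar). In per-residue mode a
#'   named vector with one entry per residue.
#' @slot kdStderr bootstrap standard error(s) of \code{kd}.
#' @slot kdCI 95 percent bootstrap percentile interval(s); a matrix with
#'   columns \code{lower}, \code{upper}.
#' @slot cspMax named numeric, fitted maximal CSP (ppm) per residue.
#' @slot cspMaxStderr bootstrap standard errors of \code{cspMax}.
#' @slot residuals fit residuals (ppm), one per residue and non-zero point.
#' @slot fitMode "shared" or "per-residue".
#' @slot nBoot number of bootstrap resamples used.
#' @export
setClass("BindingFit", representation(
  kd           = "numeric",
  kdStderr     = "numeric",
  kdCI         = "matrix",
  cspMax       = "numeric",
  cspMaxStderr = "numeric",
  residuals    = "numeric",
  fitMode      = "character",
  nBoot        = "integer"
))

#' Interface call from a CSP profile
#'
#' @slot threshold the mean + k*SD cutoff in ppm.
#' @slot mean mean CSP over non-broadened residues.
#' @slot sd standard deviation used for the cutoff.
#' @slot interfaceResidues residues with CSP strictly above the threshold.
#' @slot excludedBroadened residues excluded from the statistics because
#'   their peaks exchange out; reported separately as qualitative interface
#'   evidence, never with a numeric CSP.
#' @export
setClass("InterfaceCall", representation(
  threshold         = "numeric",
  mean              = "numeric",
  sd                = "numeric",
  interfaceResidues = "integer",
  excludedBroadened = "integer"
))

#' Result of a least-squares rigid-body superposition
#'
#' @slot rotation proper 3x3 rotation matrix (determinant +1).
#' @slot translation translation vector applied after rotation.
#' @slot rmsd root-mean-square deviation (Angstrom) after superposition.
#' @slot nPairs number of atom pairs used.
#' @export
setClass("SuperpositionResult", representation(
  rotation    = "matrix",
  translation = "numeric",
  rmsd        = "numeric",
  nPairs      = "integer"
))

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries with", length(object@peaks), "points\n")
  cat("  [P]t (uM):", paste(signif(object@proteinTotal, 4), collapse = ", "), "\n")
  cat("  [L]t (uM):", paste(signif(object@ligandTotal, 4), collapse = ", "), "\n")
  cat("  peaks per point:",
      paste(vapply(object@peaks, nrow, 0L), collapse = ", "), "\n")
})

setMethod("show", "RelaxationSeries", function(object) {
  cat("RelaxationSeries (", object@kind, "), ",
      nrow(object@intensities), " residues", sep = "")
  if (object@kind != "hetNOE")
    cat(", delays ", paste(object@delays, collapse = " "), " s", sep = "")
  cat("\n")
})

setMethod("show", "StructureEnsemble", function(object) {
  d <- dim(object@coords)
  cat("StructureEnsemble:", d[3], "models,", d[1], "atoms,",
      length(unique(object@atoms$residueId)), "residues\n")
})

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit (", object@fitMode, " mode)\n", sep = "")
  if (object@fitMode == "shared") {
    cat(sprintf("  Kd = %.4g uM (boot se %.3g, 95%% CI %.4g..%.4g, %d resamples)\n",
                object@kd, object@kdStderr,
                object@kdCI[1, "lower"], object@kdCI[1, "upper"], object@nBoot))
  } else {
    cat("  per-residue Kd (uM):\n")
    print(signif(object@kd, 4))
  }
  cat("  residues fit:", length(object@cspMax),
      " RMS residual:", signif(sqrt(mean(object@residuals^2)), 3), "ppm\n")
})

setMethod("show", "InterfaceCall", function(object) {
  cat(sprintf("InterfaceCall: threshold %.4g ppm (mean %.4g + 2 x SD %.4g)\n",
              object@threshold, object@mean, object@sd))
  cat("  interface residues:",
      if (length(object@interfaceResidues))
        paste(object@interfaceResidues, collapse = ", ") else "none", "\n")
  cat("  broadened (excluded from stats):",
      if (length(object@excludedBroadened))
        paste(object@excludedBroadened, collapse = ", ") else "none", "\n")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4g A over %d pairs\n",
              object@rmsd, object@nPairs))
})
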