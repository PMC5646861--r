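# Seeded generators for titrations, relaxation decays, coordinate ensembles,
# restraint tables and motif-bearing sequences. Each generator inverts the
# model the corresponding analysis stage fits, so noiseless round trips are
# exact and parameter recovery can be quantified under controlled noise.

#' Construct a titration design
#'
#' @param proteinTotal total protein concentration in micromolar (default 50).
#' @param ligandRatios molar ratios \eqn{[L]_t/[P]_t}; must start at 0 and
#'   increase strictly. Default \code{c(0, 0.25, 0.5, 1, 2, 5)}: a titration
#'   up to five-fold ligand excess.
#' @param trueKd dissociation constant in micromolar.
#' @param interface data frame (\code{residue}, \code{dHmax}, \code{dNmax})
#'   of per-residue maximal shifts in ppm. Default: five contiguous interface
#'   residues with shifts typical of a peptide-binding groove.
#' @param broadened residue ids that exchange out above \code{broadenCutoff}.
#' @param broadenCutoff bound fraction above which broadened peaks vanish.
#' @param nResidues number of assigned residues (default 90, a small
#'   SUMO-like protein).
#' @param noiseSd Gaussian peak-position noise per axis, ppm.
#' @param seed integer seed.
#' @return a validated \linkS4class{TitrationDesign}
#' @export
titrationDesign <- function(proteinTotal = 50,
                            ligandRatios = c(0, 0.25, 0.5, 1, 2, 5),
                            trueKd = 31,
                            interface = data.frame(
                              residue = 40:44,
                              dHmax = c(0.12, 0.20, 0.25, 0.18, 0.10),
                              dNmax = c(0.60, 1.00, 1.30, 0.80, 0.50)),
                            broadened = integer(),
                            broadenCutoff = 0.5,
                            nResidues = 90,
                            noiseSd = 0,
                            seed = 1L) {
  new("TitrationDesign",
      proteinTotal = proteinTotal,
      ligandRatios = as.numeric(ligandRatios),
      trueKd = trueKd,
      interface = interface,
      broadened = as.integer(broadened),
      broadenCutoff = broadenCutoff,
      nResidues = as.integer(nResidues),
      noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Simulate a fast-exchange HSQC titration
#'
#' Peaks start at random but reproducible free positions (amide-like ranges:
#' \eqn{\delta^H \sim} 7.5--9.1 ppm, \eqn{\delta^N \sim} 105--130 ppm). At
#' each titration point an interface residue's peak is displaced by the bound
#' fraction times its maximal shift on each axis — the fast-exchange
#' population average — with independent Gaussian noise added per axis.
#' Broadened residues are removed from peak lists once the bound fraction
#' exceeds the design cutoff.
#'
#' @param design a \linkS4class{TitrationDesign}
#' @return a \linkS4class{TitrationSeries}
#' @seealso [boundFraction()] for the quadratic isotherm the displacement
#'   follows, [fitKd()] for the inverse problem.
#' @export
simulateTitration <- function(design) {
  validObject(design)
  withSeed(design@seed, {
    n <- design@nResidues
    freeH <- stats::runif(n, 7.5, 9.1)
    freeN <- stats::runif(n, 105, 130)
    dHmax <- dNmax <- rep(0, n)
    dHmax[design@interface$residue] <- design@interface$dHmax
    dNmax[design@interface$residue] <- design@interface$dNmax

    pt <- design@proteinTotal
    lt <- design@ligandRatios * pt
    pts <- lapply(seq_along(lt), function(i) {
      fb <- boundFraction(pt, lt[i], design@trueKd)
      keep <- seq_len(n)
      if (fb > design@broadenCutoff && length(design@broadened))
        keep <- setdiff(keep, design@broadened)
      data.frame(
        residue = keep,
        deltaH = freeH[keep] + fb * dHmax[keep] +
          stats::rnorm(length(keep), 0, design@noiseSd),
        deltaN = freeN[keep] + fb * dNmax[keep] +
          stats::rnorm(length(keep), 0, design@noiseSd),
        height = rep(1, length(keep)))
    })
    new("TitrationSeries",
        peaks = pts,
        proteinTotal = rep(pt, length(lt)),
        ligandTotal = lt)
  })
}

#' Construct a relaxation-decay design
#'
#' Default delay grids are the standard 15N T1 grid
#' 0.002, 0.005, 0.01, 0.03, 0.05, 0.1, 0.2, 0.4 s and T2 grid
#' 0.002, 0.008, 0.016, 0.024, 0.032, 0.064, 0.096, 0.2 s.
#'
#' @param kind "T1" or "T2"; selects the default delay grid.
#' @param delays delay grid in seconds (overrides the default).
#' @param trueT named numeric of true time constants (s) per residue.
#' @param I0 intensities at zero delay (recycled to match \code{trueT}).
#' @param noiseSd additive intensity noise.
#' @param seed integer seed.
#' @return a validated \linkS4class{RelaxationDesign}
#' @export
relaxationDesign <- function(kind = c("T1", "T2"),
                             delays = NULL,
                             trueT = c(`1` = 0.45),
                             I0 = 100,
                             noiseSd = 0,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(delays))
    delays <- if (kind == "T1") c(0.002, 0.005, 0.01, 0.03, 0.05, 0.1, 0.2, 0.4)
              else c(0.002, 0.008, 0.016, 0.024, 0.032, 0.064, 0.096, 0.2)
  I0 <- rep_len(I0, length(trueT))
  names(I0) <- names(trueT)
  new("RelaxationDesign", kind = kind, delays = as.numeric(delays),
      trueT = trueT, I0 = I0, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Simulate mono-exponential relaxation decays
#'
#' Generates \eqn{I(t) = I_0 e^{-t/T} + \epsilon} per residue on the design's
#' delay grid, \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d.
#'
#' @param design a \linkS4class{RelaxationDesign}
#' @return a \linkS4class{RelaxationSeries}
#' @export
simulateRelaxation <- function(design) {
  validObject(design)
  withSeed(design@seed, {
    m <- outer(design@I0, rep(1, length(design@delays))) *
      exp(-outer(1 / design@trueT, design@delays))
    m <- m + stats::rnorm(length(m), 0, design@noiseSd)
    rownames(m) <- if (is.null(names(design@trueT)))
      as.character(seq_along(design@trueT)) else names(design@trueT)
    colnames(m) <- paste0("d", seq_along(design@delays))
    new("RelaxationSeries", kind = design@kind, delays = design@delays,
        intensities = m, noiseEstimate = design@noiseSd)
  })
}

#' Simulate saturated/unsaturated intensity pairs for hetNOE
#'
#' @param trueNoe named numeric of true NOE ratios per residue.
#' @param unsat unsaturated reference intensity (recycled).
#' @param noiseSd additive intensity noise on both spectra.
#' @param seed integer seed.
#' @return a \linkS4class{RelaxationSeries} of kind "hetNOE"
#' @export
simulateHetNoe <- function(trueNoe, unsat = 100, noiseSd = 0, seed = 1L) {
  withSeed(seed, {
    unsat <- rep_len(unsat, length(trueNoe))
    m <- cbind(sat = trueNoe * unsat + stats::rnorm(length(trueNoe), 0, noiseSd),
               unsat = unsat + stats::rnorm(length(trueNoe), 0, noiseSd))
    rownames(m) <- if (is.null(names(trueNoe)))
      as.character(seq_along(trueNoe)) else names(trueNoe)
    new("RelaxationSeries", kind = "hetNOE", delays = numeric(),
        intensities = m, noiseEstimate = noiseSd)
  })
}

#' Construct an ensemble design
#'
#' @param nModels number of models (default 20, a typical NMR bundle size).
#' @param nResidues chain length (default 90).
#' @param flexibleRanges list of \code{c(from, to)} residue intervals with
#'   inflated noise; default both termini (residues 1--14 and 86--90,
#'   emulating a long disordered N-terminal tail and a short C-terminal tail
#'   around a rigid folded core).
#' @param coreNoiseSd per-coordinate model-to-model scatter in the core (A).
#' @param tailNoiseSd scatter inside the flexible ranges (A).
#' @param seed integer seed.
#' @return a validated \linkS4class{EnsembleDesign}
#' @export
ensembleDesign <- function(nModels = 20, nResidues = 90,
                           flexibleRanges = list(
                             c(1, min(14, nResidues)),
                             c(max(nResidues - 4, 1), nResidues)),
                           coreNoiseSd = 0.3, tailNoiseSd = 3,
                           seed = 1L) {
  new("EnsembleDesign", nModels = as.integer(nModels),
      nResidues = as.integer(nResidues), flexibleRanges = flexibleRanges,
      coreNoiseSd = coreNoiseSd, tailNoiseSd = tailNoiseSd,
      seed = as.integer(seed))
}

# Self-avoiding smoothed random walk of C-alpha positions, 3.8 A spacing.
# Direction changes are damped to keep the trace locally straight; steps that
# come closer than 3 A to any previous C-alpha are re-drawn.
generateCaTrace <- function(nResidues, minSeparation = 3) {
  ca <- matrix(0, nResidues, 3)
  dir <- c(1, 0, 0)
  for (i in 2:nResidues) {
    for (attempt in 1:200) {
      prop <- dir + stats::rnorm(3, 0, 0.6)
      prop <- prop / sqrt(sum(prop^2))
      cand <- ca[i - 1, ] + 3.8 * prop
      prev <- ca[seq_len(i - 2), , drop = FALSE]
      d2 <- if (nrow(prev))
        rowSums(sweep(prev, 2, cand)^2) else numeric()
      if (!length(d2) || min(d2) > minSeparation^2) {
        ca[i, ] <- cand
        dir <- prop
        break
      }
      if (attempt == 200) stop("self-avoiding walk failed; try another seed")
    }
  }
  ca
}

#' Simulate a coordinate ensemble with a rigid core and flexible segments
#'
#' Builds one backbone trace (a self-avoiding smoothed random walk with fixed
#' 3.8 A C-alpha spacing, plus N, C and O atoms at fixed local offsets) and
#' emits \code{nModels} noisy copies. Noise is independent Gaussian per
#' coordinate: \code{tailNoiseSd} inside the flexible ranges,
#' \code{coreNoiseSd} elsewhere. Residues are alanine throughout; side chains
#' are not modelled because superposition and RMSF statistics only require a
#' consistent backbone inventory.
#'
#' @param design an \linkS4class{EnsembleDesign}
#' @return a \linkS4class{StructureEnsemble}
#' @export
simulateEnsemble <- function(design) {
  validObject(design)
  withSeed(design@seed, {
    nr <- design@nResidues
    ca <- generateCaTrace(nr)
    # fixed intra-residue offsets (idealised, sufficient for RMSD/RMSF work)
    offsets <- rbind(N = c(-1.46, 0.0, 0.0),
                     CA = c(0, 0, 0),
                     C = c(1.52, 0.0, 0.0),
                     O = c(2.15, 1.05, 0.0))
    atoms <- data.frame(
      residueId = rep(seq_len(nr), each = 4),
      residueName = "ALA",
      atomName = rep(rownames(offsets), nr))
    base <- ca[atoms$residueId, ] + offsets[atoms$atomName, ]

    flex <- rep(FALSE, nr)
    for (rg in design@flexibleRanges) flex[rg[1]:rg[2]] <- TRUE
    sdAtom <- ifelse(flex[atoms$residueId], design@tailNoiseSd,
                     design@coreNoiseSd)

    coords <- array(0, c(nrow(base), 3, design@nModels))
    for (m in seq_len(design@nModels))
      coords[, , m] <- base + stats::rnorm(length(base), 0, sdAtom)
    new("StructureEnsemble", atoms = atoms, coords = coords)
  })
}

#' Simulate a table of NOE distance restraints
#'
#' Draws residue pairs uniformly from a chain and assigns upper bounds in the
#' 2.5--6 A range typical of NOE-derived limits. Useful for exercising the
#' short/medium/long classification on inputs with a known composition.
#'
#' @param n number of restraints.
#' @param nResidues chain length to draw residue ids from.
#' @param seed integer seed.
#' @return data frame with columns residue_i, name_i, atom_i, residue_j,
#'   name_j, atom_j, upper (Angstrom)
#' @export
simulateRestraints <- function(n = 100, nResidues = 90, seed = 1L) {
  withSeed(seed, {
    i <- sample.int(nResidues, n, replace = TRUE)
    j <- sample.int(nResidues, n, replace = TRUE)
    data.frame(
      residue_i = i, name_i = "ALA", atom_i = "HA",
      residue_j = j, name_j = "ALA", atom_j = "HN",
      upper = round(stats::runif(n, 2.5, 6), 2))
  })
}

# motif templates used by the sequence generator
plantMotifText <- function(kind) {
  switch(kind,
    sumo_consensus = paste0(sample(c("L", "I", "V"), 1), "K",
                            sample(AMINO_ACIDS, 1), "E"),
    sim = {
      core <- paste(sample(c("V", "I", "L"), 4, replace = TRUE), collapse = "")
      flank <- function() paste(sample(c("D", "E", "S"), 2, replace = TRUE),
                                collapse = "")
      paste0(flank(), core, flank())
    },
    stop("unknown motif kind: ", kind))
}

#' Generate a random protein sequence with planted motifs
#'
#' Background residues are drawn uniformly from the 20 standard amino acids,
#' so accidental motif hits adjacent to (or away from) the plants are
#' possible by construction. The returned ground truth is therefore a full
#' rescan of the final sequence, not the plant list: scanners must be
#' validated against an independent exhaustive rescan.
#'
#' @param length sequence length.
#' @param planted list of \code{list(position =, kind =)} entries with kind
#'   "sumo_consensus" or "sim"; planted stretches must fit and not overlap.
#' @param seed integer seed.
#' @return list with elements \code{sequence} (character scalar) and
#'   \code{planted} (data frame of plant positions, kinds and texts)
#' @export
simulateMotifSequence <- function(length, planted = list(), seed = 1L) {
  withSeed(seed, {
    texts <- lapply(planted, function(p) plantMotifText(p$kind))
    spans <- lapply(seq_along(planted), function(k) {
      pos <- planted[[k]]$position
      seq(pos, pos + nchar(texts[[k]]) - 1L)
    })
    all <- unlist(spans)
    if (length(all)) {
      if (max(all) > length || min(all) < 1)
        stop("planted motif does not fit within the sequence", call. = FALSE)
      if (anyDuplicated(all))
        stop("planted motifs overlap", call. = FALSE)
    }
    chars <- sample(AMINO_ACIDS, length, replace = TRUE)
    for (k in seq_along(planted))
      chars[spans[[k]]] <- strsplit(texts[[k]], "")[[1]]
    list(
      sequence = paste(chars, collapse = ""),
      planted = if (length(planted))
        data.frame(
          position = vapply(planted, `[[`, 0, "position"),
          kind = vapply(planted, `[[`, "", "kind"),
          text = unlist(texts))
      else data.frame(position = integer(), kind = character(),
                      text = character()))
  })
}
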