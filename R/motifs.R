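# Sequence-level analysis: global alignment and percent identity,
# SUMOylation-consensus (psi-K-x-E) scanning, SUMO-interacting-motif (SIM)
# scanning, and lysine-to-arginine construct generation.

checkSequence <- function(seq) {
  stopIfNot(is.character(seq) && length(seq) == 1 && nchar(seq) > 0,
            "sequence must be a non-empty character scalar")
  if (grepl(sprintf("[^%sX]", paste(AMINO_ACIDS, collapse = "")),
            toupper(seq)))
    stop("invalid characters in sequence (20 standard letters plus X only)",
         call. = FALSE)
  toupper(seq)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment through
#' [Biostrings::pairwiseAlignment()], scored with BLOSUM62 and affine gaps
#' (default opening 10, extension 0.5 — the familiar protein defaults).
#'
#' @param a,b amino-acid sequences (character scalars)
#' @param gapOpening,gapExtension affine gap penalties (positive costs)
#' @param substitutionMatrix name of a substitution matrix shipped with
#'   Biostrings, or a matrix
#' @return list with \code{score}, \code{alignedA}, \code{alignedB}
#'   (gapped strings of equal length)
#' @export
globalAlign <- function(a, b, gapOpening = 10, gapExtension = 0.5,
                        substitutionMatrix = "BLOSUM62") {
  a <- checkSequence(a); b <- checkSequence(b)
  if (is.character(substitutionMatrix)) {
    e <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
    substitutionMatrix <- get(substitutionMatrix, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  list(score = Biostrings::score(pa),
       alignedA = as.character(Biostrings::alignedPattern(pa)),
       alignedB = as.character(Biostrings::alignedSubject(pa)))
}

#' Percent identity of a pairwise alignment
#'
#' Identical aligned positions divided by the chosen denominator, times
#' 100. With \code{denominator = "alignment"} (default) every column of the
#' alignment counts, including gap columns; "shorter" divides by the length
#' of the shorter ungapped sequence. The convention matters: the two can
#' differ by several points on divergent pairs, so it is always reported.
#'
#' @param alignment list from [globalAlign()]
#' @param denominator "alignment" or "shorter"
#' @return list with \code{raw} (exact percentage) and \code{reported}
#'   (rounded to the nearest integer)
#' @export
percentIdentity <- function(alignment,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(alignment$alignedA, "")[[1]]
  cb <- strsplit(alignment$alignedB, "")[[1]]
  stopIfNot(length(ca) == length(cb) && length(ca) > 0,
            "empty or ragged alignment")
  ident <- sum(ca == cb & ca != "-")
  den <- if (denominator == "alignment") length(ca)
         else min(sum(ca != "-"), sum(cb != "-"))
  raw <- 100 * ident / den
  list(raw = raw, reported = round(raw))
}

#' Scan for SUMOylation consensus sites (psi-K-x-E)
#'
#' Reports every 4-residue window psi-K-x-E where psi is a bulky
#' branched-chain hydrophobic residue (default L, I, V; an extended set
#' including M and F is common in the literature and available via
#' \code{psiSet}). x is any residue. Overlapping hits are all reported. The
#' acceptor lysine is the second position of the motif.
#'
#' @param seq amino-acid sequence (character scalar, length >= 4)
#' @param psiSet allowed psi residues
#' @return data frame with columns \code{kind}, \code{start}, \code{end}
#'   (1-based inclusive), \code{matchedText}, \code{anchorLysine}
#' @export
scanSumoConsensus <- function(seq, psiSet = c("L", "I", "V")) {
  seq <- checkSequence(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- integer()
  if (n >= 4)
    for (s in seq_len(n - 3))
      if (ch[s] %in% psiSet && ch[s + 1] == "K" && ch[s + 3] == "E")
        hits <- c(hits, s)
  data.frame(kind = rep("sumo_consensus", length(hits)),
             start = hits, end = hits + 3L,
             matchedText = if (length(hits))
               substring(seq, hits, hits + 3L) else character(),
             anchorLysine = hits + 1L)
}

#' Scan for SUMO-interacting motifs (SIM)
#'
#' A SIM is a short beta-strand-forming stretch of branched hydrophobic
#' residues flanked by serines and/or acidic residues, docking into the
#' groove between SUMO's beta-2 strand and alpha-1 helix. The scanner's
#' operational rule (version "sim-1"): a 4-residue core window containing
#' at least \code{minCore} residues from \{V, I, L\} whose two flanking
#' 4-residue windows (clipped at the termini) together contain at least
#' \code{minFlank} residues from \{D, E, S\}. Overlapping qualifying cores
#' are merged into one hit spanning their union.
#'
#' @param seq amino-acid sequence (character scalar, length >= 4)
#' @param minCore minimal hydrophobic count in the 4-residue core
#' @param minFlank minimal acidic/serine count over both flanks combined
#' @param flankWidth width of each flanking window
#' @return data frame with columns \code{kind}, \code{start}, \code{end},
#'   \code{matchedText}, \code{rule}
#' @export
scanSim <- function(seq, minCore = 3, minFlank = 2, flankWidth = 4) {
  seq <- checkSequence(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hydro <- ch %in% c("V", "I", "L")
  acidic <- ch %in% c("D", "E", "S")
  cores <- integer()
  if (n >= 4)
    for (s in seq_len(n - 3)) {
      if (sum(hydro[s:(s + 3)]) < minCore) next
      left <- if (s > 1) seq(max(1, s - flankWidth), s - 1) else integer()
      right <- if (s + 4 <= n) seq(s + 4, min(n, s + 3 + flankWidth))
               else integer()
      if (sum(acidic[c(left, right)]) >= minFlank) cores <- c(cores, s)
    }
  if (!length(cores))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), matchedText = character(),
                      rule = character()))
  # merge cores whose 4-residue spans overlap
  starts <- ends <- integer()
  curS <- cores[1]; curE <- cores[1] + 3L
  for (s in cores[-1]) {
    if (s <= curE) curE <- s + 3L
    else { starts <- c(starts, curS); ends <- c(ends, curE)
           curS <- s; curE <- s + 3L }
  }
  starts <- c(starts, curS); ends <- c(ends, curE)
  data.frame(kind = "sim", start = starts, end = ends,
             matchedText = substring(seq, starts, ends),
             rule = "sim-1")
}

#' Replace every lysine by arginine
#'
#' Produces the K-to-R construct used to abolish all SUMO acceptor sites
#' while preserving charge: the output contains no lysines, so a consensus
#' rescan of it is always empty. Idempotent.
#'
#' @param seq amino-acid sequence (character scalar)
#' @return sequence of the same length with K replaced by R
#' @export
kToR <- function(seq) {
  gsub("K", "R", checkSequence(seq), fixed = TRUE)
}
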