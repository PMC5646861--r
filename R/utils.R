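# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Weighted 1H/15N distance used both for CSPs and for peak matching; the 1/5
# factor down-scales the wider 15N dispersion onto the 1H ppm scale.
weightedShiftDistance <- function(dH, dN, nitrogenWeight = 5) {
  sqrt(dH^2 + (dN / nitrogenWeight)^2)
}

# Three-letter -> one-letter amino-acid codes (X for anything unknown).
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa321 <- function(three) {
  out <- AA_321[toupper(three)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa123 <- function(one) {
  inv <- names(AA_321)
  names(inv) <- AA_321
  out <- inv[toupper(one)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

AMINO_ACIDS <- unname(AA_321)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
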