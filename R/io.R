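# Readers and writers: Sparky-style peak lists, titration manifests, CSV
# intensity tables, multi-model PDB ensembles (via bio3d), CYANA-style
# upper-limit restraint tables, FASTA (via Biostrings).

#' Read a Sparky-style peak list
#'
#' One peak per line in the assignment-first dialect
#' \preformatted{<Res><Num>N-H  <w1 ppm (15N)>  <w2 ppm (1H)>  [height]}
#' e.g. \code{K37N-H 121.500 8.210}. Lines starting with \code{#} (and the
#' conventional \code{Assignment w1 w2} header) are ignored.
#'
#' @param path file path
#' @return data frame with columns \code{residue}, \code{deltaH},
#'   \code{deltaN}, \code{height} (NA when absent)
#' @export
readPeakList <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !grepl("^Assignment\\b", lines)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty peak list: ", path)
    return(data.frame(residue = integer(), deltaH = numeric(),
                      deltaN = numeric(), height = numeric()))
  }
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "\\s+")[[1]]
    m <- regmatches(f[1], regexec("^([A-Za-z]+)([0-9]+)N-H$", f[1]))[[1]]
    if (length(m) != 3 || length(f) < 3 ||
        anyNA(suppressWarnings(as.numeric(f[2:3]))))
      stop("malformed peak list line ", k, ": '", lines[k], "'",
           call. = FALSE)
    data.frame(residue = as.integer(m[3]),
               deltaN = as.numeric(f[2]),
               deltaH = as.numeric(f[3]),
               height = if (length(f) >= 4) as.numeric(f[4]) else NA_real_)
  })
  out <- do.call(rbind, rows)[, c("residue", "deltaH", "deltaN", "height")]
  if (anyDuplicated(out$residue))
    stop("duplicate residue(s) in peak list: ",
         paste(unique(out$residue[duplicated(out$residue)]), collapse = ", "),
         call. = FALSE)
  out
}

#' Write a Sparky-style peak list
#'
#' Inverse of [readPeakList()]; ppm values are printed to 3 decimals, the
#' precision at which round trips are exact. Residue type is written as the
#' generic "R" unless a \code{residueName} column provides one-letter codes.
#'
#' @param peaks data frame with residue, deltaH, deltaN, optional height
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writePeakList <- function(peaks, path) {
  type <- if ("residueName" %in% names(peaks)) peaks$residueName else "R"
  lines <- sprintf("%s%dN-H %10.3f %10.3f%s",
                   type, peaks$residue, peaks$deltaN, peaks$deltaH,
                   ifelse(is.na(peaks$height) | is.null(peaks$height), "",
                          sprintf(" %12.3f", peaks$height)))
  writeLines(c("# Assignment w1(15N) w2(1H) height", lines), path)
  invisible(path)
}

#' Read a titration manifest
#'
#' Comma-separated table with columns \code{path}, \code{protein_total},
#' \code{ligand_total} (micromolar), one row per titration point, ordered;
#' the first row must be the ligand-free reference. Relative peak-list
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest file path
#' @return a \linkS4class{TitrationSeries}
#' @export
readTitrationManifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("path", "protein_total", "ligand_total") %in% names(man)),
            "manifest needs columns path, protein_total, ligand_total")
  stopIfNot(man$ligand_total[1] == 0,
            "first manifest entry must have ligand_total 0")
  base <- dirname(path)
  files <- ifelse(file.exists(man$path), man$path, file.path(base, man$path))
  peaks <- lapply(files, readPeakList)
  new("TitrationSeries", peaks = peaks,
      proteinTotal = as.numeric(man$protein_total),
      ligandTotal = as.numeric(man$ligand_total))
}

#' Write a titration series as peak lists plus a manifest
#'
#' @param series a \linkS4class{TitrationSeries}
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix for the per-point peak lists
#' @return the manifest path, invisibly
#' @export
writeTitrationSeries <- function(series, dir, prefix = "point") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s%02d.list", prefix, seq_len(nPoints(series)))
  for (i in seq_len(nPoints(series)))
    writePeakList(peakList(series, i), file.path(dir, files[i]))
  man <- data.frame(path = files,
                    protein_total = proteinTotal(series),
                    ligand_total = ligandTotal(series))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Read / write per-residue intensity tables
#'
#' CSV with a \code{residue} column followed by one column per delay named
#' \code{d<seconds>} (T1/T2) or the two columns \code{sat}, \code{unsat}
#' (hetNOE).
#'
#' @param path file path
#' @param kind "T1", "T2" or "hetNOE"
#' @param noiseEstimate spectral noise level recorded with the table
#' @return a \linkS4class{RelaxationSeries}
#' @export
readIntensityTable <- function(path, kind = c("T1", "T2", "hetNOE"),
                               noiseEstimate = 0) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE)
  stopIfNot("residue" %in% names(df), "intensity table needs a residue column")
  m <- as.matrix(df[, setdiff(names(df), "residue"), drop = FALSE])
  rownames(m) <- df$residue
  if (kind == "hetNOE") {
    stopIfNot(all(c("sat", "unsat") %in% colnames(m)),
              "hetNOE table needs columns sat, unsat")
    new("RelaxationSeries", kind = kind, delays = numeric(),
        intensities = m[, c("sat", "unsat")], noiseEstimate = noiseEstimate)
  } else {
    delays <- as.numeric(sub("^d", "", colnames(m)))
    stopIfNot(!anyNA(delays), "delay columns must be named d<seconds>")
    new("RelaxationSeries", kind = kind, delays = delays,
        intensities = m, noiseEstimate = noiseEstimate)
  }
}

#' @rdname readIntensityTable
#' @param series a \linkS4class{RelaxationSeries} to write
#' @export
writeIntensityTable <- function(series, path) {
  m <- intensities(series)
  df <- data.frame(residue = rownames(m))
  cols <- as.data.frame(m)
  if (series@kind != "hetNOE") names(cols) <- paste0("d", delays(series))
  utils::write.csv(cbind(df, cols), path, row.names = FALSE)
  invisible(path)
}

bio3dToEnsemble <- function(pdb) {
  at <- pdb$atom
  keep <- which(at$type == "ATOM" &
                  !grepl("^H|^[0-9]+H", at$elety) &
                  (is.na(at$alt) | at$alt %in% c("", "A")))
  nm <- max(1, nrow(pdb$xyz))
  coords <- array(0, c(length(keep), 3, nm))
  for (m in seq_len(nm)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    coords[, , m] <- xyz[keep, ]
  }
  new("StructureEnsemble",
      atoms = data.frame(residueId = at$resno[keep],
                         residueName = at$resid[keep],
                         atomName = at$elety[keep]),
      coords = coords)
}

#' Read a multi-model PDB file as a structure ensemble
#'
#' Parses MODEL/ENDMDL-delimited coordinate sets (a single unnumbered model
#' also works), dropping hydrogens, HETATM records and alternate locations
#' other than blank/A. If the models disagree on their atom inventory the
#' file is re-read model by model and the inventories are reconciled by
#' intersection, with a warning.
#'
#' @param path PDB file path
#' @return a \linkS4class{StructureEnsemble}
#' @export
readEnsemblePdb <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ragged <- FALSE
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    stopIfNot(length(starts) == length(ends),
              "unbalanced MODEL/ENDMDL records")
    counts <- vapply(seq_along(starts), function(k)
      sum(grepl("^ATOM", lines[starts[k]:ends[k]])), 0L)
    ragged <- length(unique(counts)) > 1
  }
  if (!ragged) {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(pdb) && nrow(pdb$atom)) return(bio3dToEnsemble(pdb))
  }

  # ragged models: split the file at MODEL records and intersect inventories
  if (!length(starts)) stop("no ATOM records in ", path, call. = FALSE)
  ends <- grep("^ENDMDL", lines)
  parts <- lapply(seq_along(starts), function(k) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(c(lines[(starts[k] + 1):(ends[k] - 1)], "END"), tmp)
    on.exit(unlink(tmp))
    bio3dToEnsemble(suppressWarnings(
      bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)))
  })
  keyOf <- function(e) paste(e@atoms$residueId, e@atoms$atomName)
  shared <- Reduce(intersect, lapply(parts, keyOf))
  if (!length(shared)) stop("no ATOM records shared across models",
                            call. = FALSE)
  warning("models disagree on atom inventory; using the intersection (",
          length(shared), " atoms)")
  idx1 <- match(shared, keyOf(parts[[1]]))
  coords <- array(0, c(length(shared), 3, length(parts)))
  for (m in seq_along(parts))
    coords[, , m] <- parts[[m]]@coords[match(shared, keyOf(parts[[m]])), , 1]
  new("StructureEnsemble", atoms = parts[[1]]@atoms[idx1, ],
      coords = coords)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' @param ensemble a \linkS4class{StructureEnsemble}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeEnsemblePdb <- function(ensemble, path) {
  at <- atomTable(ensemble)
  xyz <- t(apply(ensemble@coords, 3, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$residueId, resid = at$residueName,
                   elety = at$atomName, chain = "A")
  invisible(path)
}

#' Read / write CYANA-style upper-limit restraint tables
#'
#' Whitespace-separated columns
#' \code{resid1 resname1 atom1 resid2 resname2 atom2 upper_A}; comment
#' lines start with \code{#}.
#'
#' @param path file path
#' @return data frame with columns residue_i, name_i, atom_i, residue_j,
#'   name_j, atom_j, upper
#' @export
readRestraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  rows <- lapply(keep, function(k) {
    f <- strsplit(lines[k], "\\s+")[[1]]
    if (length(f) < 7 ||
        anyNA(suppressWarnings(as.numeric(f[c(1, 4, 7)]))))
      stop("malformed restraint at line ", k, ": '", lines[k], "'",
           call. = FALSE)
    data.frame(residue_i = as.integer(f[1]), name_i = f[2], atom_i = f[3],
               residue_j = as.integer(f[4]), name_j = f[5], atom_j = f[6],
               upper = as.numeric(f[7]))
  })
  if (!length(rows))
    return(data.frame(residue_i = integer(), name_i = character(),
                      atom_i = character(), residue_j = integer(),
                      name_j = character(), atom_j = character(),
                      upper = numeric()))
  do.call(rbind, rows)
}

#' @rdname readRestraints
#' @param restraints data frame in the [readRestraints()] layout
#' @export
writeRestraints <- function(restraints, path) {
  lines <- sprintf("%4d %-4s %-4s %4d %-4s %-4s %6.2f",
                   restraints$residue_i, restraints$name_i,
                   restraints$atom_i, restraints$residue_j,
                   restraints$name_j, restraints$atom_j, restraints$upper)
  writeLines(c("# resid1 resname1 atom1 resid2 resname2 atom2 upper_A",
               lines), path)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA file path
#' @return named character vector of sequences
#' @export
readFastaSequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname readFastaSequences
#' @param seqs named character vector of sequences
#' @export
writeFastaSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
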