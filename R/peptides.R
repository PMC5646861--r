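#' Reference peptide sequences
#'
#' The peptide sequences used throughout the examples and validation suite:
#' the PML and IE2 SUMO-interacting motif peptides and the synthetic
#' SUMOylation substrate peptide carrying two psi-K-x-E consensus sites.
#' Shipped as a FASTA file under \code{inst/extdata}.
#'
#' @return named character vector with entries \code{PML_SIM},
#'   \code{IE2_SIM}, \code{substrate}
#' @examples
#' scanSumoConsensus(referencePeptides()[["substrate"]])
#' @export
referencePeptides <- function() {
  readFastaSequences(system.file("extdata", "peptides.fasta",
                                 package = "SumoNMR", mustWork = TRUE))
}
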