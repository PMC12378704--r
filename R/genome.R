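#' Construct a genome object
#'
#' A genome is a named character vector of uppercase chromosome sequences over
#' the alphabet A/C/G/T/N. Any other character is an input error (ambiguity
#' codes beyond N are not expanded).
#'
#' @param sequences Named character vector of DNA sequences.
#' @return A named character vector of class `im_genome`.
#' @examples
#' g <- genome_seq(c(chr1 = "CCCACCCACCCACCCTTT"))
#' @export
genome_seq <- function(sequences) {
  if (length(sequences) == 0) stop_input("genome must contain at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop_input("every chromosome must be named")
  }
  if (anyDuplicated(nm)) stop_input("chromosome names must be unique")
  sequences <- toupper(sequences)
  check_dna(sequences, allow_n = TRUE, what = "genome")
  structure(sequences, class = "im_genome")
}

#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and returns an
#' `im_genome`. Record names are truncated at the first whitespace, as is
#' conventional for assembly FASTA headers.
#'
#' @param path Path to a FASTA file.
#' @param chroms Optional character vector restricting to these chromosomes.
#' @return An `im_genome`.
#' @export
read_genome <- function(path, chroms = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (!is.null(chroms)) {
    missing <- setdiff(chroms, names(seqs))
    if (length(missing) > 0) {
      stop_input("chromosomes not present in FASTA: ", paste(missing, collapse = ", "))
    }
    seqs <- seqs[chroms]
  }
  genome_seq(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome An `im_genome` (or named character vector).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
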