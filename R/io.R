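## Readers, writers and small sequence utilities.

#' Read a FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet`; sequences are upper-cased on
#' ingest. Wrapped or unwrapped lines and multi-record files are handled;
#' an empty file yields an empty set.
#'
#' @param path FASTA file path.
#' @return a `DNAStringSet`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  info <- file.info(path)
  if (info$size == 0) return(Biostrings::DNAStringSet())
  x <- Biostrings::readDNAStringSet(path)
  ## DNAStringSet is already upper-case by alphabet; normalize names
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences as FASTA
#'
#' @param x a `DNAStringSet` or named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a validated TSV lane/series table
#'
#' Reads a tab-separated table with a header and checks that every
#' required column is present, naming any missing column in the error.
#'
#' @param path TSV file path.
#' @param requiredCols character vector of column names that must exist.
#' @return data.frame.
#' @export
readLaneTable <- function(path, requiredCols = character()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(requiredCols, names(tab))
  if (length(miss))
    stop(sprintf("table %s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  tab
}

#' Reverse complement of a DNA string
#'
#' @param seq ACGTN character string (case-insensitive); `""` allowed.
#' @return the reverse complement, upper case.
#' @examples
#' revcomp("CCATATTAGG")  # "CCTAATATGG"
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(seq))))
}

#' Protein length encoded by an open reading frame
#'
#' An ORF of `n` nucleotides including the stop codon encodes
#' `n/3 - 1` amino acids (the stop codon is untranslated). The 732 bp
#' MADS-box ORF handled by this package encodes 243 residues.
#'
#' @param orfNt ORF length in nucleotides, including the stop codon;
#'   must be >= 6 and divisible by 3.
#' @return amino-acid count.
#' @examples
#' orfProteinLength(732)  # 243
#' @export
orfProteinLength <- function(orfNt) {
  if (any(orfNt %% 3 != 0))
    stop("frame error: ORF length must be divisible by 3")
  if (any(orfNt < 6))
    stop("ORF too short: need at least start and stop codons (6 nt)")
  orfNt / 3 - 1
}
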