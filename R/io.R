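# Thin wrappers over Biostrings for the standard sequence formats.

#' Read sequences from FASTA or FASTQ
#'
#' @param path Input file; format inferred from the extension
#'   (`.fa/.fasta` vs `.fq/.fastq`, optionally `.gz`) unless given.
#' @param format `"fasta"`, `"fastq"` or `NULL` to infer.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
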