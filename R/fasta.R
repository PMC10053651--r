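#' Read the first record of a FASTA file
#'
#' Reads a DNA FASTA file and returns its first record as an upper-case
#' character string. A warning is issued when the file holds more than one
#' record, matching the single-array-per-run contract of the annotator.
#'
#' @param path Path to a FASTA file.
#' @return Named character scalar (name = record id, value = sequence).
#' @export
read_fasta_first <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file holds no records: ", path, call. = FALSE)
  if (length(set) > 1L) {
    warning("FASTA file holds ", length(set), " records; using the first",
            call. = FALSE)
  }
  stats::setNames(toupper(as.character(set[[1]])), names(set)[1])
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
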