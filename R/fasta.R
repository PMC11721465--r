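#' Read / write protein sequences in FASTA
#'
#' Thin wrappers around Biostrings for the screen's sequence inputs.
#' Sequences are returned as plain named character strings, the form
#' the hydropathy functions consume.
#'
#' @param path FASTA file.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings required for FASTA I/O", call. = FALSE)
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings required for FASTA I/O", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
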