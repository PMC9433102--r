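#' Write reads to a FASTQ file
#'
#' @param reads A tibble with `read_id`, `sequence`, `quality` (Phred+33).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(
    seqs, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file path.
#' @return A tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}
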