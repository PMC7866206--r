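# Reference sequence and region IO. FASTA goes through Biostrings; BED goes
# through rtracklayer, which converts 0-based half-open BED to 1-based closed
# GRanges exactly once at this boundary.

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return `DNAStringSet`, names truncated to the first whitespace token.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a reference FASTA
#'
#' @param sequences `DNAStringSet` or [synthetic_reference].
#' @param path output FASTA file.
#' @export
write_reference <- function(sequences, path) {
  Biostrings::writeXStringSet(reference_sequences(sequences), path)
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED file (0-based half-open intervals).
#' @return `GRanges` with 1-based closed coordinates; a BED name column is
#'   kept as metadata column `name`.
#' @export
read_bed_regions <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write regions to BED
#'
#' @param regions `GRanges` (1-based closed); converted back to BED 0-based
#'   half-open on write.
#' @param path output BED file.
#' @export
write_bed_regions <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' Total width of a region set in megabases
#'
#' Overlapping intervals are merged before summing, so the value is the size
#' of the interrogated territory (the tumor-mutational-burden denominator).
#'
#' @param regions `GRanges`.
#' @return numeric scalar, megabases.
#' @export
region_megabases <- function(regions) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(regions)))) / 1e6
}
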