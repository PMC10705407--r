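#' Construct a genome object
#'
#' A genome is a named collection of contig sequences over {A,C,G,T,N}
#' (case preserved). All coordinates used by the package are 0-based,
#' half-open.
#'
#' @param genome_id Single string identifying the genome (used as the
#'   `genome.` prefix in MAF `src` fields).
#' @param contigs Named character vector or list, one nucleotide string per
#'   contig.
#' @return An object of class `genome` with fields `genome_id`, `contigs`
#'   (named character vector) and `lengths` (named integer vector).
#' @examples
#' g <- genome("toy", c(chr1 = "ACGTACGT"))
#' g$lengths
#' @export
genome <- function(genome_id, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  contigs <- vapply(contigs, as.character, character(1))
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be named")
  if (anyDuplicated(names(contigs))) stop("duplicate contig names")
  structure(
    list(genome_id = genome_id,
         contigs = contigs,
         lengths = vapply(contigs, nchar, integer(1))),
    class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, ": ", length(x$contigs), " contig(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return A [genome()] object.
#' @export
read_genome <- function(path, genome_id = sub("\\.(fa|fasta)(\\.gz)?$", "", basename(path))) {
  ss <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(ss)
  # FASTA headers may carry descriptions after whitespace
  names(contigs) <- sub("\\s.*$", "", names(ss))
  genome(genome_id, contigs)
}

#' Write a genome to FASTA
#'
#' @param g A [genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## Fetch single bases at 0-based positions (vectorised). Out-of-range -> NA.
genome_bases <- function(g, contig, pos) {
  seqs <- g$contigs[[contig]]
  if (is.null(seqs)) stop("unknown contig: ", contig)
  ok <- !is.na(pos) & pos >= 0L & pos < nchar(seqs)
  out <- rep(NA_character_, length(pos))
  if (any(ok)) out[ok] <- substring(seqs, pos[ok] + 1L, pos[ok] + 1L)
  out
}

## Extract [start, end) as a string (0-based half-open).
genome_segment <- function(g, contig, start, end) {
  seqs <- g$contigs[[contig]]
  if (is.null(seqs)) stop("unknown contig: ", contig)
  if (start < 0L || end > nchar(seqs) || start > end)
    stop("segment out of range: ", contig, ":", start, "-", end)
  substr(seqs, start + 1L, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
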