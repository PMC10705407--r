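#' A two-genome toy world for the conservation function
#'
#' Builds a minimal worked example: a human-like reference with one
#' two-exon gene (intron flanked by GT..AG) and one mouse-like target genome
#' in which both canonical donor bases are intact while the first canonical
#' acceptor base is substituted. The MAF is written to disk and read back
#' through [load_maf()], so the example exercises the real ingestion path.
#'
#' The expected conservation values are C(d1, 0, t2) = C(d1, 1, t2) = 1 and
#' C(a1, 0, t2) = 0, C(a1, 1, t2) = 1.
#'
#' @param dir Directory for the FASTA/MAF files (a tempdir by default).
#' @return `list(ref, targets, aln, donors, acceptors, dir)` ready for
#'   [conservation()].
#' @examples
#' w <- toy_splice_world()
#' conservation(w$aln, w$ref, w$targets, w$donors$contig, w$donors$strand,
#'              w$donors$origin, shift = 0L, target = "mouse")
#' @export
toy_splice_world <- function(dir = tempfile("toyworld")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  #             exon1 [0,20)       intron [20,40): GT ........ AG   exon2 [40,60)
  ref_seq <- paste0("ATGGCCATTGCTGACCTGAA",  # exon 1
                    "GTAAGTCCATTGCTGACAAG",  # intron: donor GT .. acceptor AG
                    "GCTGACCTGAAATGGCCATT")  # exon 2
  # target: identical except the first canonical acceptor base (pos 38, A->G)
  # and two neutral intron substitutions (pos 27, 31)
  tgt <- strsplit(ref_seq, "")[[1L]]
  tgt[c(28L, 32L)] <- c("G", "T")
  tgt[39L] <- "G"
  tgt_seq <- paste(tgt, collapse = "")

  ref <- genome("human", c(chr1 = ref_seq))
  mouse <- genome("mouse", c(chr7 = tgt_seq))
  write_genome(ref, file.path(dir, "human.fa"))
  write_genome(mouse, file.path(dir, "mouse.fa"))
  maf <- file.path(dir, "toy.maf")
  writeLines(c("##maf version=1",
               "a score=0",
               sprintf("s human.chr1 0 60 + 60 %s", ref_seq),
               sprintf("s mouse.chr7 0 60 + 60 %s", tgt_seq),
               ""), maf)
  aln <- load_maf(maf, "human")
  donors <- data.frame(contig = "chr1", strand = "+", kind = "donor",
                       origin = 20L, key = site_key("chr1", "+", "donor", 20L),
                       stringsAsFactors = FALSE)
  acceptors <- data.frame(contig = "chr1", strand = "+", kind = "acceptor",
                          origin = 38L,
                          key = site_key("chr1", "+", "acceptor", 38L),
                          stringsAsFactors = FALSE)
  list(ref = ref, targets = list(mouse = mouse), aln = aln,
       donors = donors, acceptors = acceptors, dir = dir)
}
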