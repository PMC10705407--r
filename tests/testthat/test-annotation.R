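toy_ref <- function() {
  # 300 bp contig: gene A (+) exons [10,50) [100,140) [200,240),
  # gene B (-) exons [250,270) [280,295)
  set.seed(123)
  chars <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  # plant canonical motifs for gene A introns [50,100) and [140,200)
  chars[50 + 1:2] <- c("G", "T"); chars[c(99, 100)] <- c("A", "G")
  chars[140 + 1:2] <- c("G", "T"); chars[c(199, 200)] <- c("A", "G")
  # gene B (- strand) intron [270,280): donor at high end, acceptor at low end
  chars[270 + 1:2] <- c("C", "T"); chars[c(279, 280)] <- c("A", "C")
  genome("toy", c(chrT = paste(chars, collapse = "")))
}

gtf_line <- function(contig, start0, end0, strand, gid, tid, extra) {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
          contig, start0 + 1L, end0, strand, gid, tid, extra)
}

write_toy_gtf <- function(extra_a, extra_b, path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    gtf_line("chrT", 10L, 50L, "+", "gA", "gA.t1", extra_a),
    gtf_line("chrT", 100L, 140L, "+", "gA", "gA.t1", extra_a),
    gtf_line("chrT", 200L, 240L, "+", "gA", "gA.t1", extra_a),
    gtf_line("chrT", 250L, 270L, "-", "gB", "gB.t1", extra_b),
    gtf_line("chrT", 280L, 295L, "-", "gB", "gB.t1", extra_b)), path)
  path
}

test_that("catalog dialects type transcripts from their own attributes", {
  p <- write_toy_gtf(' transcript_type "protein_coding";',
                     ' transcript_type "lncRNA";')
  cat_g <- parse_catalog(p, "gencode")
  expect_equal(cat_g$transcripts$gene_type[cat_g$transcripts$transcript_id == "gA.t1"],
               "coding")
  expect_equal(cat_g$transcripts$gene_type[cat_g$transcripts$transcript_id == "gB.t1"],
               "lncRNA")
  # GTF 1-based closed converted to 0-based half-open
  expect_equal(cat_g$exons$start[1], 10L)
  expect_equal(cat_g$exons$end[1], 50L)

  p2 <- write_toy_gtf(' gene_type "protein_coding";', ' gene_type "lncRNA";')
  cat_c <- parse_catalog(p2, "chess")
  expect_equal(sort(unique(cat_c$transcripts$gene_type)), c("coding", "lncRNA"))

  # RefSeq needs the gene- and transcript-level attributes to agree
  p3 <- write_toy_gtf(' gene_biotype "protein_coding"; transcript_biotype "mRNA";',
                      ' gene_biotype "protein_coding"; transcript_biotype "misc_RNA";')
  cat_r <- parse_catalog(p3, "refseq")
  expect_equal(cat_r$transcripts$gene_type[cat_r$transcripts$transcript_id == "gA.t1"],
               "coding")
  expect_equal(cat_r$transcripts$gene_type[cat_r$transcripts$transcript_id == "gB.t1"],
               "other")
  # missing dialect attribute -> typed other with a warning
  p4 <- write_toy_gtf("", "")
  expect_warning(cat_m <- parse_catalog(p4, "gencode"), "missing")
  expect_true(all(cat_m$transcripts$gene_type == "other"))
})

test_that("site extraction follows the origin and dinucleotide definitions", {
  ref <- toy_ref()
  p <- write_toy_gtf(' transcript_type "protein_coding";',
                     ' transcript_type "lncRNA";')
  sites <- extract_sites(parse_catalog(p, "gencode"), ref)
  dA <- sites$donors[sites$donors$strand == "+", ]
  aA <- sites$acceptors[sites$acceptors$strand == "+", ]
  # plus strand: intron [50,100) -> donor origin 50 (GT), acceptor origin 98 (AG)
  expect_setequal(dA$origin, c(50L, 140L))
  expect_setequal(aA$origin, c(98L, 198L))
  expect_true(all(dA$dinuc == "GT"))
  expect_true(all(aA$dinuc == "AG"))
  expect_true(all(dA$canonical_class == "GT-AG"))
  # minus strand: intron [270,280) -> donor origin 279, acceptor origin 271
  dB <- sites$donors[sites$donors$strand == "-", ]
  aB <- sites$acceptors[sites$acceptors$strand == "-", ]
  expect_equal(dB$origin, 279L)
  expect_equal(dB$dinuc, "GT")
  expect_equal(aB$origin, 271L)
  expect_equal(aB$dinuc, "AG")
  # intron bookkeeping
  expect_equal(nrow(sites$introns), 3L)
  expect_equal(sum(sites$introns$strand == "+"), 2L)
})

test_that("extraction matches a brute-force per-intron oracle on the small world", {
  sw <- small_world()
  cat_ <- sw$catalog
  sites <- extract_sites(cat_, sw$ref)
  # oracle: iterate transcripts and introns directly
  keys <- character(0)
  for (tid in cat_$transcripts$transcript_id[cat_$transcripts$n_exons >= 2]) {
    ex <- cat_$exons[cat_$exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    for (i in seq_len(nrow(ex) - 1L)) {
      s <- ex$end[i]; e <- ex$start[i + 1L]
      if (ex$strand[1] == "+") {
        keys <- c(keys, site_key(ex$contig[1], "+", "donor", s),
                  site_key(ex$contig[1], "+", "acceptor", e - 2L))
      } else {
        keys <- c(keys, site_key(ex$contig[1], "-", "donor", e - 1L),
                  site_key(ex$contig[1], "-", "acceptor", s + 1L))
      }
    }
  }
  expect_setequal(c(sites$donors$key, sites$acceptors$key), unique(keys))
  # extraction is idempotent / order-independent
  cat_shuf <- cat_
  set.seed(8)
  cat_shuf$exons <- cat_shuf$exons[sample(nrow(cat_shuf$exons)), ]
  sites2 <- extract_sites(cat_shuf, sw$ref)
  expect_setequal(sites2$donors$key, sites$donors$key)
  # counts: introns per transcript = exons - 1
  n_int <- table(sites$introns$transcript_id)
  n_ex <- setNames(cat_$transcripts$n_exons, cat_$transcripts$transcript_id)
  expect_true(all(n_int == n_ex[names(n_int)] - 1L))
})

test_that("MANE subtraction removes shared coding sites only", {
  sw <- small_world()
  mane_sites <- extract_sites(sw$mane, sw$ref)
  cat_sites <- extract_sites(sw$catalog, sw$ref)
  mkeys <- c(mane_sites$donors$key, mane_sites$acceptors$key)
  red <- subtract_mane(cat_sites$donors, rbind(mane_sites$donors,
                                               mane_sites$acceptors))
  # oracle: set difference restricted to coding
  want <- cat_sites$donors[!(cat_sites$donors$gene_type == "coding" &
                               cat_sites$donors$key %in% mkeys), ]
  expect_identical(red$key, want$key)
  expect_true(all(!red$key[red$gene_type == "coding"] %in% mkeys))
  # lncRNA sites unchanged
  expect_setequal(red$key[red$gene_type == "lncRNA"],
                  cat_sites$donors$key[cat_sites$donors$gene_type == "lncRNA"])
  # reconstruction: subtracted + (coding /\ MANE) = original coding set
  inter <- cat_sites$donors$key[cat_sites$donors$gene_type == "coding" &
                                  cat_sites$donors$key %in% mkeys]
  expect_setequal(c(red$key[red$gene_type == "coding"], inter),
                  cat_sites$donors$key[cat_sites$donors$gene_type == "coding"])
  # disjoint catalogs unchanged
  expect_identical(subtract_mane(cat_sites$donors, data.frame(key = "none")),
                   cat_sites$donors)
})

test_that("exclusions drop chrY, unaligned contigs and single-exon transcripts", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", 0L, 50L, "+", "g1", "t1", ' transcript_type "protein_coding";'),
    gtf_line("chr1", 100L, 150L, "+", "g1", "t1", ' transcript_type "protein_coding";'),
    gtf_line("chrY", 0L, 50L, "+", "g2", "t2", ' transcript_type "protein_coding";'),
    gtf_line("chrY", 100L, 150L, "+", "g2", "t2", ' transcript_type "protein_coding";'),
    gtf_line("chr1", 300L, 400L, "+", "g3", "t3", ' transcript_type "protein_coding";'),
    gtf_line("chr1_patch", 0L, 50L, "+", "g4", "t4", ' transcript_type "protein_coding";'),
    gtf_line("chr1_patch", 100L, 150L, "+", "g4", "t4", ' transcript_type "protein_coding";')),
    p)
  cat_ <- parse_catalog(p, "gencode")
  out <- apply_exclusions(cat_, exclude_contigs = "chrY",
                          aligned_contigs = c("chr1", "chrY"))
  expect_identical(out$transcripts$transcript_id, "t1")
})

test_that("GTF writing round-trips through parse_catalog", {
  sw <- small_world()
  p <- tempfile(fileext = ".gtf")
  write_gtf(sw$catalog, p)
  back <- parse_catalog(p, "gencode", catalog = sw$catalog$catalog)
  expect_setequal(back$transcripts$transcript_id,
                  sw$catalog$transcripts$transcript_id)
  o1 <- back$exons[order(back$exons$transcript_id, back$exons$start),
                   c("transcript_id", "start", "end", "gene_type")]
  o2 <- sw$catalog$exons[order(sw$catalog$exons$transcript_id,
                               sw$catalog$exons$start),
                         c("transcript_id", "start", "end", "gene_type")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})
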