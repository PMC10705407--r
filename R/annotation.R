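type_from_dialect <- function(df, dialect) {
  get_attr <- function(name) {
    if (name %in% names(df)) as.character(df[[name]]) else rep(NA_character_, nrow(df))
  }
  if (dialect %in% c("gencode", "mane")) {
    tt <- get_attr("transcript_type")
    out <- ifelse(tt == "protein_coding", "coding",
                  ifelse(tt == "lncRNA", "lncRNA", "other"))
    missing <- is.na(tt)
  } else if (dialect == "chess") {
    gt <- get_attr("gene_type")
    out <- ifelse(gt == "protein_coding", "coding",
                  ifelse(gt == "lncRNA", "lncRNA", "other"))
    missing <- is.na(gt)
  } else if (dialect == "refseq") {
    gb <- get_attr("gene_biotype"); tb <- get_attr("transcript_biotype")
    out <- ifelse(gb == "protein_coding" & tb == "mRNA", "coding",
                  ifelse(gb == "lncRNA" & tb == "lnc_RNA", "lncRNA", "other"))
    missing <- is.na(gb) | is.na(tb)
    out[is.na(out)] <- "other"
  } else stop("unknown dialect: ", dialect)
  out[is.na(out)] <- "other"
  if (any(missing))
    warning(sum(missing), " transcript record(s) missing the ", dialect,
            " gene-type attribute; typed 'other'")
  out
}

#' Parse a gene catalog (GTF/GFF3) with its gene-type dialect
#'
#' Catalogs spell their gene/transcript types differently: GENCODE and MANE
#' use the `transcript_type` attribute, CHESS uses `gene_type`, and RefSeq
#' requires `gene_biotype == "protein_coding"` together with
#' `transcript_biotype == "mRNA"` for coding (and `lncRNA`/`lnc_RNA` for
#' lncRNA). GTF 1-based closed coordinates are converted to the package's
#' 0-based half-open convention on ingestion.
#'
#' @param path GTF/GFF3 file; exon features must carry `transcript_id`.
#' @param dialect One of `"gencode"`, `"mane"`, `"refseq"`, `"chess"`.
#' @param catalog Catalog label stored with every transcript; defaults to the
#'   dialect (upper-cased).
#' @return An object of class `splice_catalog`: a list with `transcripts` and
#'   `exons` data frames, `catalog`, and `dialect`. Transcripts typed
#'   `"other"` are retained but flagged by their `gene_type`.
#' @export
parse_catalog <- function(path, dialect = c("gencode", "mane", "refseq", "chess"),
                          catalog = toupper(dialect)) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon features in ", path)
  if (is.null(df$transcript_id) || anyNA(df$transcript_id))
    stop("exon features lacking transcript_id in ", path)
  exons <- data.frame(
    transcript_id = as.character(df$transcript_id),
    gene_id = if (!is.null(df$gene_id)) as.character(df$gene_id) else
      as.character(df$transcript_id),
    contig = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = as.integer(df$start) - 1L,   # -> 0-based half-open
    end = as.integer(df$end),
    gene_type = type_from_dialect(df, dialect),
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  tx <- exons[!duplicated(exons$transcript_id),
              c("transcript_id", "gene_id", "contig", "strand", "gene_type")]
  tx$n_exons <- as.integer(table(exons$transcript_id)[tx$transcript_id])
  tx$catalog <- catalog
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = exons,
                 catalog = catalog, dialect = dialect),
            class = "splice_catalog")
}

#' @export
print.splice_catalog <- function(x, ...) {
  cat("<splice_catalog> ", x$catalog, " (", x$dialect, " dialect): ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exon records; ",
      "types: ", paste(names(table(x$transcripts$gene_type)),
                       table(x$transcripts$gene_type),
                       sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Splice-site identity key
#'
#' Sites are keyed by (contig, strand, kind, origin); two sites are "the
#' same" (e.g. shared with MANE) iff their keys are equal.
#' @param contig,strand,kind,origin Site fields (vectors).
#' @return Character vector of keys.
#' @export
site_key <- function(contig, strand, kind, origin) {
  paste(contig, strand, kind, origin, sep = ":")
}

canonical_class_of <- function(donor_dinuc, acceptor_dinuc) {
  pair <- paste0(toupper(donor_dinuc), "-", toupper(acceptor_dinuc))
  ifelse(pair == "GT-AG", "GT-AG",
         ifelse(pair == "GC-AG", "GC-AG",
                ifelse(pair == "AT-AC", "AT-AC", "other")))
}

#' Extract donor/acceptor splice sites and introns from a catalog
#'
#' One donor site at each intron 5' end and one acceptor at each 3' end, in
#' transcript orientation. The origin o(s) is the reference position of the
#' first canonical-dinucleotide base read along the transcript: for a
#' plus-strand intron `[s, e)` the donor origin is `s` and the acceptor
#' origin `e - 2`; on the minus strand the donor origin is `e - 1` and the
#' acceptor origin `s + 1`. Dinucleotides are read from the reference
#' sequence (reverse-complemented on the minus strand) and the canonical
#' class (GT-AG / GC-AG / AT-AC / other) is assigned from the intron's
#' donor/acceptor pair. Sites are deduplicated across transcripts on
#' (contig, strand, kind, origin) with transcript membership lists.
#'
#' @param catalog A `splice_catalog` (single-exon transcripts are ignored).
#' @param ref Reference [genome()] for dinucleotide lookup.
#' @return `list(donors, acceptors, introns)`. Donor/acceptor data frames
#'   carry `contig`, `strand`, `kind`, `origin`, `dinuc`, `canonical_class`,
#'   `gene_type`, `catalogs`, `n_transcripts`, `key` and a list-column
#'   `transcripts`. The intron data frame has one row per
#'   (transcript, intron) with both site keys. Transcripts containing an
#'   intron shorter than 4 bp are skipped and listed in
#'   `attr(, "flagged_transcripts")`.
#' @export
extract_sites <- function(catalog, ref) {
  ex <- catalog$exons
  tx <- catalog$transcripts
  multi <- tx$transcript_id[tx$n_exons >= 2L]
  ex <- ex[ex$transcript_id %in% multi, , drop = FALSE]
  if (nrow(ex) == 0L)
    stop("no multi-exon transcripts in catalog ", catalog$catalog)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  # introns: gaps between consecutive exons of the same transcript
  same <- ex$transcript_id[-1L] == ex$transcript_id[-nrow(ex)]
  i1 <- which(same)          # upstream exon row of each junction
  introns <- data.frame(
    transcript_id = ex$transcript_id[i1],
    gene_id = ex$gene_id[i1],
    contig = ex$contig[i1],
    strand = ex$strand[i1],
    start = ex$end[i1],
    end = ex$start[i1 + 1L],
    gene_type = ex$gene_type[i1],
    stringsAsFactors = FALSE)
  if (any(introns$end < introns$start))
    stop("overlapping exons within a transcript")
  short <- introns$end - introns$start < 4L
  flagged <- unique(introns$transcript_id[short])
  introns <- introns[!introns$transcript_id %in% flagged, , drop = FALSE]
  plus <- introns$strand == "+"
  introns$donor_origin <- ifelse(plus, introns$start, introns$end - 1L)
  introns$acceptor_origin <- ifelse(plus, introns$end - 2L, introns$start + 1L)

  dinuc_at <- function(contig, start2) {  # 2-mer at plus-strand [start2, start2+2)
    out <- character(length(start2))
    for (ctg in unique(contig)) {
      sel <- contig == ctg
      out[sel] <- paste0(genome_bases(ref, ctg, start2[sel]),
                         genome_bases(ref, ctg, start2[sel] + 1L))
    }
    out
  }
  d_plus2 <- ifelse(plus, introns$start, introns$end - 2L)
  a_plus2 <- ifelse(plus, introns$end - 2L, introns$start)
  dd <- dinuc_at(introns$contig, d_plus2)
  ad <- dinuc_at(introns$contig, a_plus2)
  dd[!plus] <- revcomp(dd[!plus])
  ad[!plus] <- revcomp(ad[!plus])
  introns$donor_dinuc <- toupper(dd)
  introns$acceptor_dinuc <- toupper(ad)
  introns$canonical_class <- canonical_class_of(dd, ad)
  introns$donor_key <- site_key(introns$contig, introns$strand, "donor",
                                introns$donor_origin)
  introns$acceptor_key <- site_key(introns$contig, introns$strand, "acceptor",
                                   introns$acceptor_origin)
  rownames(introns) <- NULL

  dedup <- function(kind) {
    org <- if (kind == "donor") introns$donor_origin else introns$acceptor_origin
    din <- if (kind == "donor") introns$donor_dinuc else introns$acceptor_dinuc
    key <- if (kind == "donor") introns$donor_key else introns$acceptor_key
    first <- !duplicated(key)
    s <- data.frame(contig = introns$contig[first], strand = introns$strand[first],
                    kind = kind, origin = org[first], dinuc = din[first],
                    stringsAsFactors = FALSE)
    s$key <- key[first]
    # site class/type: most frequent among member introns (coding preferred on tie)
    byk <- split(seq_len(nrow(introns)), key)[s$key]
    s$canonical_class <- vapply(byk, function(ii) {
      tt <- sort(table(introns$canonical_class[ii]), decreasing = TRUE)
      names(tt)[1L]
    }, character(1))
    s$gene_type <- vapply(byk, function(ii) {
      ty <- introns$gene_type[ii]
      if (any(ty == "coding")) "coding"
      else if (any(ty == "lncRNA")) "lncRNA" else "other"
    }, character(1))
    s$transcripts <- lapply(byk, function(ii) unique(introns$transcript_id[ii]))
    s$n_transcripts <- lengths(s$transcripts)
    s$catalogs <- catalog$catalog
    rownames(s) <- NULL
    s
  }
  out <- list(donors = dedup("donor"), acceptors = dedup("acceptor"),
              introns = introns)
  attr(out, "flagged_transcripts") <- flagged
  out
}

#' Remove MANE splice sites from a catalog's site set
#'
#' Protein-coding sites whose key appears in the MANE site set are dropped;
#' lncRNA and other sites pass through unchanged (MANE contains only
#' protein-coding transcripts).
#'
#' @param catalog_sites Data frame of sites (as from [extract_sites()]).
#' @param mane_sites Data frame of MANE sites (or anything with a `key`
#'   column).
#' @return The reduced site data frame.
#' @export
subtract_mane <- function(catalog_sites, mane_sites) {
  drop <- catalog_sites$gene_type == "coding" &
    catalog_sites$key %in% mane_sites$key
  out <- catalog_sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the standard transcript exclusions
#'
#' Removes transcripts on excluded contigs (chromosome Y by default), on
#' contigs absent from the alignment (when `aligned_contigs` is given, e.g.
#' unaligned patch sequences), and single-exon transcripts.
#'
#' @param catalog A `splice_catalog`.
#' @param exclude_contigs Contig names to drop (default `"chrY"`).
#' @param aligned_contigs If non-`NULL`, transcripts on contigs outside this
#'   set are dropped too.
#' @return The filtered `splice_catalog`.
#' @export
apply_exclusions <- function(catalog, exclude_contigs = "chrY",
                             aligned_contigs = NULL) {
  tx <- catalog$transcripts
  keep <- !tx$contig %in% exclude_contigs & tx$n_exons >= 2L
  if (!is.null(aligned_contigs)) keep <- keep & tx$contig %in% aligned_contigs
  catalog$transcripts <- tx[keep, , drop = FALSE]
  catalog$exons <- catalog$exons[
    catalog$exons$transcript_id %in% tx$transcript_id[keep], , drop = FALSE]
  rownames(catalog$transcripts) <- rownames(catalog$exons) <- NULL
  catalog
}

#' Write a catalog's exons as GTF
#'
#' Coordinates are converted back from the internal 0-based half-open
#' convention to GTF 1-based closed. Gene types are spelled per dialect (see
#' [parse_catalog()]).
#'
#' @param catalog A `splice_catalog`.
#' @param path Output file.
#' @param header Optional comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path, header = NULL) {
  ex <- catalog$exons
  d <- catalog$dialect
  attr_of <- function(ty) {
    val <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "misc_RNA")[ty]
    if (d %in% c("gencode", "mane")) sprintf(' transcript_type "%s";', val)
    else if (d == "chess") sprintf(' gene_type "%s";', val)
    else if (d == "refseq") {
      tb <- c(coding = "mRNA", lncRNA = "lnc_RNA", other = "misc_RNA")[ty]
      gb <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "misc_RNA")[ty]
      sprintf(' gene_biotype "%s"; transcript_biotype "%s";', gb, tb)
    } else stop("unknown dialect: ", d)
  }
  lines <- sprintf(
    '%s\tsplicecons\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
    ex$contig, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    attr_of(ex$gene_type))
  if (!is.null(header)) lines <- c(paste0("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}
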