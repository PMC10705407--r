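#' Configuration for the Random (neutral baseline) annotation
#'
#' The Random annotation places two-exon transcripts inside MANE introns,
#' away from annotated splicing motifs, as a stand-in for neutrally evolving
#' sequence. Defaults: 180,000 transcripts (the full-scale dataset size;
#' desk-scale runs use fewer), 100 bp exons, a 150 bp internal intron, and a
#' 35 bp exclusion radius around every annotated splice-site origin (which
#' covers the [-30, 31] conservation feature window).
#'
#' @param n_transcripts Number of transcripts to generate.
#' @param exon_length,intron_length Exon and internal-intron lengths (bp).
#' @param radius Exclusion radius (bp) around annotated site origins.
#' @param require_gt_ag If `TRUE`, only placements whose reference
#'   dinucleotides read GT/AG in transcript orientation are kept (off by
#'   default: random loci stand in for neutral sequence regardless of motif).
#' @param seed RNG seed used by [generate_random_annotation()].
#' @return A list of class `random_config`.
#' @export
random_config <- function(n_transcripts = 180000L, exon_length = 100L,
                          intron_length = 150L, radius = 35L,
                          require_gt_ag = FALSE, seed = 1L) {
  stopifnot(n_transcripts > 0L, exon_length > 0L, intron_length > 0L, radius >= 0L)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 radius = as.integer(radius),
                 require_gt_ag = require_gt_ag,
                 seed = as.integer(seed)),
            class = "random_config")
}

#' Eligible regions for random-site placement
#'
#' MANE intron intervals minus half-open exclusion zones
#' `[o - radius, o + radius)` around every annotated splice-site origin (from
#' all loaded catalogs), with fragments too short to host one transcript
#' footprint (2 exons + internal intron) dropped.
#'
#' @param mane_introns Data frame of introns (`contig`, `start`, `end`;
#'   0-based half-open), e.g. from [extract_sites()] on MANE.
#' @param site_origins Data frame with `contig` and `origin` columns covering
#'   every annotated splice site of every catalog.
#' @param config A [random_config()].
#' @return Data frame `contig`, `start`, `end` (0-based half-open).
#' @export
eligible_regions <- function(mane_introns, site_origins, config = random_config()) {
  footprint <- 2L * config$exon_length + config$intron_length
  out <- list()
  for (ctg in unique(mane_introns$contig)) {
    ir <- mane_introns[mane_introns$contig == ctg, , drop = FALSE]
    rng <- IRanges::reduce(IRanges::IRanges(ir$start + 1L, ir$end))
    so <- site_origins$origin[site_origins$contig == ctg]
    if (length(so) > 0L && config$radius > 0L) {
      zones <- IRanges::reduce(IRanges::IRanges(so - config$radius + 1L,
                                                so + config$radius))
      rng <- IRanges::setdiff(rng, zones)
    }
    rng <- rng[IRanges::width(rng) >= footprint]
    if (length(rng) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(rng) - 1L, end = IRanges::end(rng),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    stop("no eligible regions: all MANE introns excluded or too short")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate the Random neutral-baseline annotation
#'
#' Draws two-exon transcripts uniformly over eligible placements (region
#' chosen proportionally to its number of admissible start positions, start
#' uniform within region, strand uniform). Each transcript yields exactly one
#' donor and one acceptor site; all site origins are kept distinct by
#' rejection sampling. Deterministic given `config$seed`.
#'
#' @param regions Data frame from [eligible_regions()].
#' @param ref Reference [genome()] (dinucleotide lookup, GT/AG restriction).
#' @param config A [random_config()].
#' @return `list(catalog, donors, acceptors, introns)`; the catalog is a
#'   `splice_catalog` named `"Random"` and the site tables flow through the
#'   same representation as real catalogs.
#' @export
generate_random_annotation <- function(regions, ref, config = random_config()) {
  set.seed(config$seed)
  n <- config$n_transcripts
  exl <- config$exon_length; inl <- config$intron_length
  footprint <- 2L * exl + inl
  cap <- pmax(0L, (regions$end - regions$start) - footprint + 1L)
  if (sum(cap) == 0L) stop("no admissible start positions")
  used <- new.env(hash = TRUE)
  rows <- vector("list", n)
  # the GT/AG restriction accepts ~1/256 of uniform placements, so the try
  # budget scales accordingly
  got <- 0L; tries <- 0L
  max_tries <- if (config$require_gt_ag) 2000 * n else 50 * n
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    ri <- sample.int(nrow(regions), 1L, prob = cap)
    p <- regions$start[ri] + sample.int(cap[ri], 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    istart <- p + exl; iend <- istart + inl
    if (strand == "+") {
      dor <- istart; aor <- iend - 2L
      dpl <- istart; apl <- iend - 2L
    } else {
      dor <- iend - 1L; aor <- istart + 1L
      dpl <- iend - 2L; apl <- istart
    }
    kd <- paste0(regions$contig[ri], ":", dor)
    ka <- paste0(regions$contig[ri], ":", aor)
    if (!is.null(used[[kd]]) || !is.null(used[[ka]]) || kd == ka) next
    if (config$require_gt_ag) {
      dd <- paste0(genome_bases(ref, regions$contig[ri], c(dpl, dpl + 1L)),
                   collapse = "")
      ad <- paste0(genome_bases(ref, regions$contig[ri], c(apl, apl + 1L)),
                   collapse = "")
      if (strand == "-") { dd <- revcomp(dd); ad <- revcomp(ad) }
      if (toupper(dd) != "GT" || toupper(ad) != "AG") next
    }
    used[[kd]] <- TRUE; used[[ka]] <- TRUE
    got <- got + 1L
    id <- sprintf("RAND_%06d", got)
    rows[[got]] <- data.frame(
      transcript_id = id, gene_id = id, contig = regions$contig[ri],
      strand = strand,
      start = c(p, iend), end = c(istart, iend + exl),
      gene_type = "other", stringsAsFactors = FALSE)
  }
  if (got < n)
    stop("placement capacity exhausted: generated ", got, " of ", n,
         " requested transcripts")
  exons <- do.call(rbind, rows)
  tx <- exons[!duplicated(exons$transcript_id),
              c("transcript_id", "gene_id", "contig", "strand", "gene_type")]
  tx$n_exons <- 2L
  tx$catalog <- "Random"
  rownames(tx) <- rownames(exons) <- NULL
  catalog <- structure(list(transcripts = tx, exons = exons,
                            catalog = "Random", dialect = "gencode"),
                       class = "splice_catalog")
  sites <- extract_sites(catalog, ref)
  list(catalog = catalog, donors = sites$donors, acceptors = sites$acceptors,
       introns = sites$introns)
}
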