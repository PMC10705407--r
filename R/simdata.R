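#' Configuration for the synthetic test world
#'
#' The generator emulates the statistical structure of a reference-anchored
#' mammalian alignment at desk scale: a ~2 Mb reference with multi-exon
#' genes (plus a small chrY contig to exercise exclusions), a star phylogeny
#' of target species whose per-position substitution rate depends on the
#' position class (conserved splicing motif < coding exon < neutral), MAF
#' blocks with some exon/species rows withheld (their sequence intact in the
#' target FASTA so realignment can recover them) and ragged exon-block edges
#' (so that the aligned-exon score baseline has positive spread), VCFs whose
#' homozygous-SNP rates differ by position class, and junction coverage whose
#' depth differs by intron category.
#'
#' @param seed RNG seed; the whole world is deterministic given the seed.
#' @param genome_length,chry_length Lengths of the main contig (`chr1`) and
#'   of the small `chrY` contig (bp).
#' @param n_genes,n_chry_genes Gene counts on chr1 and chrY.
#' @param exons_per_gene,exon_length,intron_length,intergenic Ranges
#'   (length-2 integer vectors) for gene structure sampling.
#' @param p_coding Probability that a chr1 gene is protein-coding (the rest
#'   are lncRNA); chrY genes are coding.
#' @param n_targets,n_close Number of target species, and how many of them
#'   form the low-divergence (primate-like) clade.
#' @param d_close,d_far Per-species neutral mismatch probability ranges for
#'   the close and far species (evenly spaced ladders).
#' @param conserved_multiplier,coding_multiplier Mismatch probability at
#'   conserved-motif / coding positions as a fraction of the species'
#'   neutral rate.
#' @param motif_radius Half-width (bp) of the conserved window planted
#'   around conserved-intent site origins.
#' @param lnc_well_prob Probability that a lncRNA primary-transcript site is
#'   conserved-intent.
#' @param alt_isoform_fraction Fraction of multi-intron genes receiving one
#'   alternative isoform with a novel splice site (novel sites alternate
#'   conserved/neutral intent).
#' @param withheld_fraction Fraction of (internal exon, species) pairs whose
#'   MAF rows are withheld.
#' @param trim_prob,trim_max Probability and maximum length (bp) of the
#'   random per-(exon, species) alignment-edge trims.
#' @param indel_rate Per-position target deletion probability (0 by default;
#'   deletions appear as gap columns in MAF rows and are absent from the
#'   target FASTA).
#' @param snp_canonical_cons,snp_motif,snp_neutral,snp_nohom Homozygous-SNV
#'   planting probabilities per position class (canonical dinucleotide of a
#'   conserved site; other motif/coding positions; neutral genic positions)
#'   and the rate of extra zero-homozygote variants.
#' @param af_cons,af_neutral Allele-frequency ranges for variants at
#'   conserved vs other positions.
#' @param clin_cons,clin_neutral,clin_benign Clinical-variant planting
#'   probabilities at canonical dinucleotides (pathogenic at conserved /
#'   neutral sites; benign anywhere).
#' @param coverage_means Negative-binomial mean junction coverage per intron
#'   category 1..4.
#' @param n_tissues,nb_size Number of tissue columns and NB size parameter.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2000000L, chry_length = 80000L,
                       n_genes = 50L, n_chry_genes = 2L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(90L, 180L),
                       intron_length = c(400L, 1500L),
                       intergenic = c(5000L, 15000L),
                       p_coding = 0.7,
                       n_targets = 25L, n_close = 5L,
                       d_close = c(0.01, 0.05), d_far = c(0.2, 0.8),
                       conserved_multiplier = 0.04, coding_multiplier = 0.5,
                       motif_radius = 8L, lnc_well_prob = 0.3,
                       alt_isoform_fraction = 0.4,
                       withheld_fraction = 0.05,
                       trim_prob = 0.4, trim_max = 8L,
                       indel_rate = 0,
                       snp_canonical_cons = 0.008, snp_motif = 0.02,
                       snp_neutral = 0.05, snp_nohom = 0.01,
                       af_cons = c(0.001, 0.02), af_neutral = c(0.005, 0.05),
                       clin_cons = 0.03, clin_neutral = 0.01, clin_benign = 0.02,
                       coverage_means = c(50, 75, 75, 200),
                       n_tissues = 5L, nb_size = 2) {
  cfg <- as.list(environment())
  probs <- c(p_coding, d_close, d_far, conserved_multiplier, coding_multiplier,
             lnc_well_prob, alt_isoform_fraction, withheld_fraction, trim_prob,
             indel_rate, snp_canonical_cons, snp_motif, snp_neutral, snp_nohom,
             clin_cons, clin_neutral, clin_benign)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (conserved_multiplier >= 1) stop("conserved_multiplier must be < 1")
  if (exon_length[1L] <= 2L * trim_max + 10L)
    stop("exons too short for edge trims")
  if (intron_length[1L] < 200L) stop("introns must be at least 200 bp")
  if (n_close >= n_targets) stop("n_close must be < n_targets")
  if (length(coverage_means) != 4L) stop("coverage_means must have 4 entries")
  # feasibility of the layout (checked before any generation)
  max_gene <- exons_per_gene[2L] * exon_length[2L] +
    (exons_per_gene[2L] - 1L) * intron_length[2L]
  if (n_genes * (max_gene + intergenic[2L]) + intergenic[2L] > genome_length)
    stop("genome_length cannot host n_genes at the configured sizes")
  if (n_chry_genes * (max_gene + intergenic[2L]) + intergenic[2L] > chry_length)
    stop("chry_length cannot host n_chry_genes at the configured sizes")
  structure(cfg, class = "sim_config")
}

runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

BASES <- c("A", "C", "G", "T")

mutate_chars <- function(chars, rate_by_pos) {
  hit <- which(stats::runif(length(chars)) < rate_by_pos)
  if (length(hit)) {
    cur <- match(chars[hit], BASES)
    chars[hit] <- BASES[(cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  }
  chars
}

## plant canonical dinucleotides for one intron (plus-strand base edits)
plant_dinucs <- function(chars, istart, iend, strand) {
  if (strand == "+") {
    chars[istart + 1:2] <- c("G", "T"); chars[iend - 1:0] <- c("G", "A")[2:1]
  } else {
    # minus strand: plus-strand text reads CT...AC (revcomp of GT...AG)
    chars[istart + 1:2] <- c("C", "T"); chars[iend - 1:0] <- c("C", "A")[2:1]
  }
  chars
}

#' Generate the synthetic test world
#'
#' Writes a complete, deterministic test world to `out_dir`: reference FASTA,
#' one FASTA per target species, a reference-anchored MAF, a MANE-like GTF
#' and a superset catalog GTF, a population VCF (AF/nhomalt), a ClinVar-style
#' VCF (CLNSIG), a junction coverage table, and a machine-readable truth
#' file. See [sim_config()] for what is emulated.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return An object of class `sim_world`: `list(config, dir, paths, truth,
#'   species)`. `truth` carries per-site intents, withheld exon/species pairs
#'   with realized divergence, planted variants, intended intron categories,
#'   and the exon universe.
#' @export
simulate_world <- function(config = sim_config(), out_dir = tempfile("simworld")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "targets"), showWarnings = FALSE)

  ## ---- gene layout -------------------------------------------------------
  lay_contig <- function(contig, clen, n_genes, coding_p) {
    genes <- vector("list", n_genes)
    pos <- runif_int(1L, config$intergenic)
    for (i in seq_len(n_genes)) {
      n_ex <- runif_int(1L, config$exons_per_gene)
      exl <- runif_int(n_ex, config$exon_length)
      inl <- runif_int(n_ex - 1L, config$intron_length)
      starts <- pos + cumsum(c(0L, exl[-n_ex] + inl))
      gid <- sprintf("%s_G%03d", contig, i)
      genes[[i]] <- list(gene_id = gid, contig = contig,
                         strand = sample(c("+", "-"), 1L),
                         gene_type = if (stats::runif(1) < coding_p) "coding" else "lncRNA",
                         starts = starts, ends = starts + exl)
      pos <- starts[n_ex] + exl[n_ex] + runif_int(1L, config$intergenic)
    }
    if (pos > clen) stop("layout overflow on ", contig)  # guarded by sim_config
    genes
  }
  genes <- c(lay_contig("chr1", config$genome_length, config$n_genes, config$p_coding),
             lay_contig("chrY", config$chry_length, config$n_chry_genes, 1))

  ## ---- transcripts: primary + alternative isoforms -----------------------
  tx_rows <- list()     # exon data frames per transcript
  add_tx <- function(g, suffix, starts, ends) {
    data.frame(transcript_id = paste0(g$gene_id, ".", suffix),
               gene_id = g$gene_id, contig = g$contig, strand = g$strand,
               start = starts, end = ends, gene_type = g$gene_type,
               stringsAsFactors = FALSE)
  }
  alt_info <- list()    # novel site bookkeeping
  n_alt_ok <- 0L
  for (g in genes) tx_rows[[length(tx_rows) + 1L]] <- add_tx(g, "T1", g$starts, g$ends)
  multi_intron <- which(vapply(genes, function(g) length(g$starts) >= 3L, TRUE) &
                          vapply(genes, function(g) g$contig == "chr1", TRUE))
  alt_genes <- sort(sample(multi_intron,
                           round(config$alt_isoform_fraction * length(multi_intron))))
  alt_modified_exons <- character(0)
  for (ai in seq_along(alt_genes)) {
    g <- genes[[alt_genes[ai]]]
    n_ex <- length(g$starts)
    j <- sample(seq_len(n_ex - 1L), 1L)            # intron j is modified
    intron_len <- g$starts[j + 1L] - g$ends[j]
    delta <- runif_int(1L, c(60L, min(200L, intron_len - 100L)))
    starts <- g$starts; ends <- g$ends
    side <- sample(c("right", "left"), 1L)
    if (side == "right") {        # extend exon j rightward: novel intron start
      ends[j] <- ends[j] + delta
      novel_kind <- if (g$strand == "+") "donor" else "acceptor"
      istart <- ends[j]; iend <- starts[j + 1L]
      alt_modified_exons <- c(alt_modified_exons,
                              paste(g$contig, g$starts[j], g$ends[j]))
    } else {                      # extend exon j+1 leftward: novel intron end
      starts[j + 1L] <- starts[j + 1L] - delta
      novel_kind <- if (g$strand == "+") "acceptor" else "donor"
      istart <- ends[j]; iend <- starts[j + 1L]
      alt_modified_exons <- c(alt_modified_exons,
                              paste(g$contig, g$starts[j + 1L], g$ends[j + 1L]))
    }
    novel_origin <- if (novel_kind == "donor") {
      if (g$strand == "+") istart else iend - 1L
    } else {
      if (g$strand == "+") iend - 2L else istart + 1L
    }
    tx_rows[[length(tx_rows) + 1L]] <- add_tx(g, "T2", starts, ends)
    n_alt_ok <- n_alt_ok + 1L
    alt_info[[n_alt_ok]] <- data.frame(
      gene_id = g$gene_id, contig = g$contig, strand = g$strand,
      kind = novel_kind, origin = novel_origin,
      intent = if (n_alt_ok %% 2L == 1L) "well" else "less",
      stringsAsFactors = FALSE)
  }
  exons_all <- do.call(rbind, tx_rows)
  alt_sites <- if (length(alt_info)) do.call(rbind, alt_info) else
    data.frame(gene_id = character(0), contig = character(0), strand = character(0),
               kind = character(0), origin = integer(0), intent = character(0))

  ## ---- reference sequence with planted splice motifs ---------------------
  contig_len <- c(chr1 = config$genome_length, chrY = config$chry_length)
  ref_chars <- lapply(contig_len, function(L)
    sample(BASES, L, replace = TRUE))
  # plant GT..AG (transcript orientation) at every intron of every transcript
  for (df in tx_rows) {
    n <- nrow(df)
    if (n < 2L) next
    for (i in seq_len(n - 1L))
      ref_chars[[df$contig[1L]]] <- plant_dinucs(ref_chars[[df$contig[1L]]],
                                                 df$end[i], df$start[i + 1L],
                                                 df$strand[1L])
  }
  ref <- genome("ref", vapply(ref_chars, paste, character(1), collapse = ""))

  ## ---- catalogs ----------------------------------------------------------
  mane_exons <- exons_all[exons_all$gene_type == "coding" &
                            endsWith(exons_all$transcript_id, ".T1"), , drop = FALSE]
  mane <- structure(list(
    transcripts = local({
      tx <- mane_exons[!duplicated(mane_exons$transcript_id),
                       c("transcript_id", "gene_id", "contig", "strand", "gene_type")]
      tx$n_exons <- as.integer(table(mane_exons$transcript_id)[tx$transcript_id])
      tx$catalog <- "MANE"; rownames(tx) <- NULL; tx
    }),
    exons = mane_exons, catalog = "MANE", dialect = "mane"),
    class = "splice_catalog")
  superset <- structure(list(
    transcripts = local({
      tx <- exons_all[!duplicated(exons_all$transcript_id),
                      c("transcript_id", "gene_id", "contig", "strand", "gene_type")]
      tx$n_exons <- as.integer(table(exons_all$transcript_id)[tx$transcript_id])
      tx$catalog <- "SUPERSET"; rownames(tx) <- NULL; tx
    }),
    exons = exons_all, catalog = "SUPERSET", dialect = "gencode"),
    class = "splice_catalog")

  sites <- extract_sites(superset, ref)
  all_sites <- rbind(sites$donors[, c("contig", "strand", "kind", "origin", "key", "gene_type")],
                     sites$acceptors[, c("contig", "strand", "kind", "origin", "key", "gene_type")])
  mane_site <- extract_sites(mane, ref)
  mane_keys <- c(mane_site$donors$key, mane_site$acceptors$key)

  ## ---- per-site intent ----------------------------------------------------
  alt_keys <- site_key(alt_sites$contig, alt_sites$strand, alt_sites$kind,
                       alt_sites$origin)
  intent <- rep(NA_character_, nrow(all_sites))
  intent[all_sites$key %in% mane_keys] <- "MANE"
  m <- match(all_sites$key, alt_keys)
  intent[!is.na(m)] <- alt_sites$intent[m[!is.na(m)]]
  lnc <- is.na(intent) & all_sites$gene_type == "lncRNA"
  intent[lnc] <- ifelse(stats::runif(sum(lnc)) < config$lnc_well_prob, "well", "less")
  # any remaining (coding non-MANE shared boundaries) follow MANE conservation
  intent[is.na(intent)] <- "well"
  all_sites$intent <- intent

  ## ---- position class map: 0 neutral, 1 coding, 2 conserved motif --------
  classes <- lapply(contig_len, function(L) integer(L))
  for (i in seq_len(nrow(exons_all))) {
    e <- exons_all[i, ]
    classes[[e$contig]][(e$start + 1L):e$end] <- 1L
  }
  conserved <- all_sites[all_sites$intent %in% c("MANE", "well"), , drop = FALSE]
  r <- config$motif_radius
  for (i in seq_len(nrow(conserved))) {
    s <- conserved[i, ]
    lo <- max(0L, s$origin - r); hi <- min(contig_len[[s$contig]] - 1L, s$origin + r)
    classes[[s$contig]][(lo + 1L):(hi + 1L)] <- 2L
  }
  canon_cons <- unique(data.frame(
    contig = rep(conserved$contig, 2L),
    pos = c(conserved$origin,
            ifelse(conserved$strand == "+", conserved$origin + 1L,
                   conserved$origin - 1L))))
  canon_neutral_sites <- all_sites[all_sites$intent == "less", , drop = FALSE]
  canon_neut <- unique(data.frame(
    contig = rep(canon_neutral_sites$contig, 2L),
    pos = c(canon_neutral_sites$origin,
            ifelse(canon_neutral_sites$strand == "+",
                   canon_neutral_sites$origin + 1L,
                   canon_neutral_sites$origin - 1L))))

  ## ---- exon universe, withheld pairs, trims ------------------------------
  exon_univ <- unique(exons_all[, c("contig", "start", "end", "gene_id", "gene_type")])
  exon_univ <- exon_univ[order(exon_univ$contig, exon_univ$start), , drop = FALSE]
  rownames(exon_univ) <- NULL
  exon_univ$exon_id <- paste(exon_univ$contig, exon_univ$start, exon_univ$end)
  exon_univ$chromosome <- exon_univ$contig

  species <- sprintf("t%02d", seq_len(config$n_targets))
  d_t <- c(seq(config$d_close[1L], config$d_close[2L], length.out = config$n_close),
           seq(config$d_far[1L], config$d_far[2L],
               length.out = config$n_targets - config$n_close))
  names(d_t) <- species

  # internal exons of primary transcripts, untouched by alt isoforms
  internal <- unlist(lapply(genes, function(g) {
    n <- length(g$starts)
    if (n < 3L) return(character(0))
    paste(g$contig, g$starts[2:(n - 1L)], g$ends[2:(n - 1L)])
  }))
  internal <- setdiff(internal, alt_modified_exons)
  pool <- expand.grid(exon_id = internal, species = species,
                      stringsAsFactors = FALSE)
  n_wh <- round(config$withheld_fraction * nrow(pool))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  gene_of_exon <- stats::setNames(exon_univ$gene_id, exon_univ$exon_id)
  exon_index_in_gene <- function(eid) {
    g <- genes[[match(gene_of_exon[[eid]], vapply(genes, `[[`, "", "gene_id"))]]
    match(eid, paste(g$contig, g$starts, g$ends))
  }
  taken <- new.env(hash = TRUE)  # gene|species -> withheld exon indices
  withheld <- list()
  for (i in seq_len(nrow(pool))) {
    if (length(withheld) >= n_wh) break
    eid <- pool$exon_id[i]; sp <- pool$species[i]
    gid <- gene_of_exon[[eid]]
    kk <- paste0(gid, "|", sp)
    idx <- exon_index_in_gene(eid)
    prev <- taken[[kk]]
    if (!is.null(prev) && any(abs(prev - idx) <= 1L)) next
    taken[[kk]] <- c(prev, idx)
    withheld[[length(withheld) + 1L]] <- data.frame(
      exon_id = eid, species = sp, stringsAsFactors = FALSE)
  }
  withheld <- if (length(withheld)) do.call(rbind, withheld) else
    data.frame(exon_id = character(0), species = character(0))
  eu <- exon_univ[match(withheld$exon_id, exon_univ$exon_id), , drop = FALSE]
  withheld$contig <- eu$contig; withheld$start <- eu$start; withheld$end <- eu$end

  trims <- expand.grid(exon_id = exon_univ$exon_id, species = species,
                       stringsAsFactors = FALSE)
  trims$lead <- ifelse(stats::runif(nrow(trims)) < config$trim_prob,
                       runif_int(nrow(trims), c(1L, config$trim_max)), 0L)
  trims$tail <- ifelse(stats::runif(nrow(trims)) < config$trim_prob,
                       runif_int(nrow(trims), c(1L, config$trim_max)), 0L)
  eu <- exon_univ[match(trims$exon_id, exon_univ$exon_id), ]
  trims$contig <- eu$contig; trims$start <- eu$start; trims$end <- eu$end

  ## ---- MAF block layout --------------------------------------------------
  pad <- 50L
  blocks <- list()
  for (g in genes) {
    bp <- sort(unique(c(g$starts, g$ends,
                        unlist(lapply(tx_rows, function(df)
                          if (df$gene_id[1L] == g$gene_id) c(df$start, df$end))))))
    bp <- c(max(0L, bp[1L] - pad), bp, min(contig_len[[g$contig]], bp[length(bp)] + pad))
    blocks[[length(blocks) + 1L]] <- data.frame(
      contig = g$contig, start = bp[-length(bp)], end = bp[-1L])
  }
  blocks <- do.call(rbind, blocks)
  blocks <- blocks[blocks$end > blocks$start, , drop = FALSE]

  ## ---- mutate targets, write FASTAs, assemble MAF rows -------------------
  mult <- c(1, config$coding_multiplier, config$conserved_multiplier)
  row_text <- vector("list", length(species))   # per species: per-block rows
  names(row_text) <- species
  tgt_lengths <- list()
  withheld$divergence <- rep(NA_real_, nrow(withheld))
  neutral_div <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    per_block <- vector("list", nrow(blocks))
    lens <- integer(0)
    sp_contigs <- character(0)
    for (ctg in names(contig_len)) {
      rate <- d_t[[sp]] * mult[classes[[ctg]] + 1L]
      chars <- mutate_chars(ref_chars[[ctg]], rate)
      del <- if (config$indel_rate > 0)
        stats::runif(length(chars)) < config$indel_rate else
        rep(FALSE, length(chars))
      cumnd <- cumsum(!del)
      lens[[ctg]] <- cumnd[length(cumnd)]
      if (ctg == "chr1") {   # empirical neutral divergence (diagnostic)
        neu <- which(classes[[ctg]] == 0L)
        neu <- neu[seq_len(min(length(neu), 50000L))]
        neutral_div[[sp]] <- mean(chars[neu] != ref_chars[[ctg]][neu])
      }
      wsel <- which(withheld$species == sp & withheld$contig == ctg)
      for (wi in wsel)
        withheld$divergence[wi] <- mean(
          chars[(withheld$start[wi] + 1L):withheld$end[wi]] !=
            ref_chars[[ctg]][(withheld$start[wi] + 1L):withheld$end[wi]])
      # species-specific unaligned ranges: withheld exons + exon-edge trims
      una <- rep(FALSE, length(chars))
      for (wi in wsel) una[(withheld$start[wi] + 1L):withheld$end[wi]] <- TRUE
      tsel <- which(trims$species == sp & trims$contig == ctg &
                      (trims$lead > 0L | trims$tail > 0L))
      for (ti in tsel) {
        if (trims$lead[ti] > 0L)
          una[(trims$start[ti] + 1L):(trims$start[ti] + trims$lead[ti])] <- TRUE
        if (trims$tail[ti] > 0L)
          una[(trims$end[ti] - trims$tail[ti] + 1L):trims$end[ti]] <- TRUE
      }
      bsel <- which(blocks$contig == ctg)
      for (bi in bsel) {
        s <- blocks$start[bi]; e <- blocks$end[bi]
        idx <- (s + 1L):e
        if (all(una[idx] | del[idx])) next   # row dropped (withheld exon)
        una_blk <- una[idx]
        if (any(una_blk)) {
          covered <- which(!una_blk)
          if (any(una_blk[covered[1L]:covered[length(covered)]]))
            stop("internal coverage hole in block")  # impossible by construction
        }
        txt <- chars[idx]
        txt[una[idx] | del[idx]] <- "-"
        nongap <- which(txt != "-")
        if (length(nongap) == 0L) next
        tstart <- cumnd[idx[nongap[1L]]] - 1L
        per_block[[bi]] <- sprintf("s %s.%s %d %d + %d %s", sp, ctg,
                                   tstart, length(nongap), lens[[ctg]],
                                   paste(txt, collapse = ""))
      }
      sp_contigs[[ctg]] <- paste(chars[!del], collapse = "")
    }
    tg <- genome(sp, sp_contigs)
    write_genome(tg, file.path(out_dir, "targets", paste0(sp, ".fa")))
    tgt_lengths[[sp]] <- lens
    row_text[[sp]] <- per_block
  }

  maf_path <- file.path(out_dir, "alignment.maf")
  con <- file(maf_path, "w")
  writeLines("##maf version=1 scoring=none", con)
  for (bi in seq_len(nrow(blocks))) {
    s <- blocks$start[bi]; e <- blocks$end[bi]; ctg <- blocks$contig[bi]
    refrow <- sprintf("s ref.%s %d %d + %d %s", ctg, s, e - s,
                      contig_len[[ctg]],
                      paste(ref_chars[[ctg]][(s + 1L):e], collapse = ""))
    rows <- unlist(lapply(species, function(sp) row_text[[sp]][[bi]]))
    writeLines(c("a score=0", refrow, rows, ""), con)
  }
  close(con)

  ## ---- reference FASTA + GTFs --------------------------------------------
  ref_path <- file.path(out_dir, "ref.fa")
  write_genome(ref, ref_path)
  mane_path <- file.path(out_dir, "mane.gtf")
  catalog_path <- file.path(out_dir, "catalog.gtf")
  write_gtf(mane, mane_path, header = paste0(" seed=", config$seed))
  write_gtf(superset, catalog_path, header = paste0(" seed=", config$seed))

  ## ---- population VCF ----------------------------------------------------
  genic <- lapply(contig_len, function(L) rep(FALSE, L))
  for (g in genes) {
    lo <- max(0L, g$starts[1L] - pad)
    hi <- min(contig_len[[g$contig]], g$ends[length(g$ends)] + pad)
    genic[[g$contig]][(lo + 1L):hi] <- TRUE
  }
  plant <- list(); extra <- list()
  for (ctg in names(contig_len)) {
    cls <- classes[[ctg]]
    p <- rep(0, length(cls))
    gsel <- genic[[ctg]]
    p[gsel & cls == 0L] <- config$snp_neutral
    p[gsel & cls >= 1L] <- config$snp_motif
    cc <- canon_cons$pos[canon_cons$contig == ctg]
    p[cc + 1L] <- config$snp_canonical_cons
    cn <- canon_neut$pos[canon_neut$contig == ctg]
    p[cn + 1L] <- config$snp_neutral
    hit <- which(stats::runif(length(p)) < p) - 1L     # 0-based positions
    if (length(hit)) {
      is_cons <- cls[hit + 1L] == 2L
      afr <- ifelse(is_cons,
                    stats::runif(length(hit), config$af_cons[1L], config$af_cons[2L]),
                    stats::runif(length(hit), config$af_neutral[1L], config$af_neutral[2L]))
      plant[[ctg]] <- data.frame(contig = ctg, pos = hit,
                                 n_hom = sample.int(5L, length(hit), replace = TRUE),
                                 af = round(afr, 6), stringsAsFactors = FALSE)
    }
    nh <- which(stats::runif(length(p)) < ifelse(gsel, config$snp_nohom, 0)) - 1L
    nh <- setdiff(nh, hit)
    if (length(nh))
      extra[[ctg]] <- data.frame(contig = ctg, pos = nh, n_hom = 0L,
                                 af = round(stats::runif(length(nh),
                                                         config$af_neutral[1L],
                                                         config$af_neutral[2L]), 6),
                                 stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, c(plant, extra))
  planted <- planted[order(planted$contig, planted$pos), , drop = FALSE]
  rownames(planted) <- NULL
  refb <- character(nrow(planted)); altb <- character(nrow(planted))
  for (ctg in unique(planted$contig)) {
    sel <- planted$contig == ctg
    refb[sel] <- ref_chars[[ctg]][planted$pos[sel] + 1L]
  }
  altb <- BASES[(match(refb, BASES) - 1L +
                   sample.int(3L, nrow(planted), replace = TRUE)) %% 4L + 1L]
  planted$ref <- refb; planted$alt <- altb
  vcf_path <- file.path(out_dir, "variants.vcf")
  write_sim_vcf(planted, vcf_path, contig_len,
                info = sprintf("AF=%s;nhomalt=%d", planted$af, planted$n_hom),
                info_header = c(
                  '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
                  '##INFO=<ID=nhomalt,Number=A,Type=Integer,Description="Homozygous sample count">'))

  ## ---- clinical VCF ------------------------------------------------------
  canon_all <- rbind(cbind(canon_cons, cons = TRUE), cbind(canon_neut, cons = FALSE))
  pclin <- ifelse(canon_all$cons, config$clin_cons, config$clin_neutral)
  path_hit <- stats::runif(nrow(canon_all)) < pclin
  ben_hit <- !path_hit & stats::runif(nrow(canon_all)) < config$clin_benign
  conf_hit <- !path_hit & !ben_hit & stats::runif(nrow(canon_all)) < 0.005
  canon_all$clnsig <- NA_character_
  canon_all$clnsig[path_hit] <- sample(c("Pathogenic", "Likely_pathogenic"),
                                       sum(path_hit), replace = TRUE)
  canon_all$clnsig[ben_hit] <- "Benign"
  canon_all$clnsig[conf_hit] <- "Conflicting_classifications_of_pathogenicity"
  clin_df <- canon_all[!is.na(canon_all$clnsig),
                       c("contig", "pos", "clnsig"), drop = FALSE]
  clin_df <- clin_df[order(clin_df$contig, clin_df$pos), , drop = FALSE]
  rownames(clin_df) <- NULL
  refb <- character(nrow(clin_df))
  for (ctg in unique(clin_df$contig)) {
    sel <- clin_df$contig == ctg
    refb[sel] <- ref_chars[[ctg]][clin_df$pos[sel] + 1L]
  }
  clin_df$ref <- refb
  clin_df$alt <- BASES[(match(refb, BASES) - 1L +
                          sample.int(3L, nrow(clin_df), replace = TRUE)) %% 4L + 1L]
  clin_path <- file.path(out_dir, "clinical.vcf")
  write_sim_vcf(clin_df, clin_path, contig_len,
                info = sprintf("CLNSIG=%s", clin_df$clnsig),
                info_header = '##INFO=<ID=CLNSIG,Number=.,Type=String,Description="Clinical significance">')

  ## ---- junction coverage table -------------------------------------------
  intr <- sites$introns
  intr_u <- intr[!duplicated(paste(intr$contig, intr$strand, intr$start, intr$end)), ,
                 drop = FALSE]
  dintent <- all_sites$intent[match(intr_u$donor_key, all_sites$key)]
  aintent <- all_sites$intent[match(intr_u$acceptor_key, all_sites$key)]
  dok <- dintent %in% c("MANE", "well"); aok <- aintent %in% c("MANE", "well")
  cat_int <- 1L + dok + 2L * aok
  tissue_factor <- stats::runif(config$n_tissues, 0.5, 1.5)
  cov <- sapply(seq_len(config$n_tissues), function(t)
    stats::rnbinom(nrow(intr_u), size = config$nb_size,
                   mu = config$coverage_means[cat_int] * tissue_factor[t]))
  cov <- matrix(cov, nrow = nrow(intr_u))
  colnames(cov) <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  junc <- data.frame(contig = intr_u$contig, strand = intr_u$strand,
                     intron_start = intr_u$start, intron_end = intr_u$end,
                     stringsAsFactors = FALSE)
  junc <- cbind(junc, as.data.frame(cov))
  attr(junc, "tissues") <- colnames(cov)
  junc_path <- file.path(out_dir, "junctions.tsv")
  write_junction_table(junc, junc_path, tissues = colnames(cov))

  ## ---- truth --------------------------------------------------------------
  truth <- list(
    sites = all_sites[, c("key", "contig", "strand", "kind", "origin",
                          "gene_type", "intent")],
    withheld = withheld[, c("exon_id", "species", "contig", "start", "end",
                            "divergence")],
    variants = planted[, c("contig", "pos", "ref", "alt", "af", "n_hom")],
    intron_intent = data.frame(contig = intr_u$contig, strand = intr_u$strand,
                               start = intr_u$start, end = intr_u$end,
                               gene_type = intr_u$gene_type,
                               category = cat_int, stringsAsFactors = FALSE),
    exon_universe = exon_univ,
    species = data.frame(species = species, divergence = unname(d_t),
                         neutral_mismatch = unname(neutral_div),
                         stringsAsFactors = FALSE),
    mane_keys = mane_keys,
    seed = config$seed)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, dataframe = "columns", digits = NA)

  structure(list(
    config = config, dir = out_dir,
    paths = list(ref_fasta = ref_path,
                 target_fastas = stats::setNames(
                   file.path(out_dir, "targets", paste0(species, ".fa")), species),
                 maf = maf_path, mane_gtf = mane_path, catalog_gtf = catalog_path,
                 variants_vcf = vcf_path, clinical_vcf = clin_path,
                 junctions = junc_path, truth = truth_path),
    truth = truth,
    species = truth$species),
    class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world> seed ", x$config$seed, " in ", x$dir, "\n",
      "  ", nrow(x$truth$exon_universe), " exons, ",
      nrow(x$truth$sites), " splice sites (",
      sum(x$truth$sites$intent == "MANE"), " MANE, ",
      sum(x$truth$sites$intent == "well"), " well, ",
      sum(x$truth$sites$intent == "less"), " less), ",
      nrow(x$species), " target species, ",
      nrow(x$truth$withheld), " withheld exon/species pairs\n", sep = "")
  invisible(x)
}

write_sim_vcf <- function(df, path, contig_len, info, info_header) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contig_len),
                     unname(contig_len)),
             info_header,
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                     df$contig, df$pos + 1L, df$ref, df$alt, info))
  writeLines(lines, path)
  invisible(path)
}

#' Load the pieces of a simulated world
#'
#' Convenience loader: reads the reference and target genomes, the MAF and
#' both catalogs of a [simulate_world()] output back into package objects.
#'
#' @param world A `sim_world`.
#' @return `list(ref, targets, aln, mane, catalog)`.
#' @export
load_world <- function(world) {
  ref <- read_genome(world$paths$ref_fasta, "ref")
  targets <- lapply(world$paths$target_fastas, read_genome)
  names(targets) <- names(world$paths$target_fastas)
  for (i in seq_along(targets)) targets[[i]]$genome_id <- names(targets)[i]
  aln <- suppressWarnings(load_maf(world$paths$maf, "ref"))
  mane <- parse_catalog(world$paths$mane_gtf, "mane", catalog = "MANE")
  catalog <- parse_catalog(world$paths$catalog_gtf, "gencode", catalog = "SUPERSET")
  list(ref = ref, targets = targets, aln = aln, mane = mane, catalog = catalog)
}

#' Verify a simulated world against its ground truth
#'
#' Re-reads the emitted files and checks the generator's contracts: withheld
#' exon/species pairs are absent from the MAF but their sequence is present
#' in the target FASTA; every annotated splice site of the superset catalog
#' has a truth intent; every planted variant appears in the VCF.
#'
#' @param world A `sim_world`.
#' @return `list(report, ok, failures)`; `report` has one row per check with
#'   counts, `failures` names the offending objects (if any).
#' @export
truth_check <- function(world) {
  w <- load_world(world)
  truth <- world$truth
  failures <- list()

  wh <- truth$withheld
  wh_bad <- character(0)
  for (i in seq_len(nrow(wh))) {
    st <- exon_alignment_status(w$aln, wh$contig[i], wh$start[i], wh$end[i],
                                wh$species[i])
    glen <- w$targets[[wh$species[i]]]$lengths[[wh$contig[i]]]
    if (st != "unaligned" || is.null(glen) || glen < wh$end[i] * (1 - 0.01))
      wh_bad <- c(wh_bad, paste0(wh$exon_id[i], "/", wh$species[i]))
  }

  st <- extract_sites(w$catalog, w$ref)
  keys <- c(st$donors$key, st$acceptors$key)
  missing_sites <- setdiff(keys, truth$sites$key)

  v <- read_variants(world$paths$variants_vcf)
  vk <- paste0(v$contig, ":", v$pos)
  tk <- paste0(truth$variants$contig, ":", truth$variants$pos)
  missing_var <- setdiff(tk, vk)

  report <- data.frame(
    check = c("withheld_absent_from_maf_present_in_fasta",
              "every_site_has_truth_intent",
              "planted_variants_in_vcf"),
    n = c(nrow(wh), length(keys), length(tk)),
    n_failed = c(length(wh_bad), length(missing_sites), length(missing_var)),
    stringsAsFactors = FALSE)
  report$ok <- report$n_failed == 0L
  failures <- list(withheld = wh_bad, sites = missing_sites,
                   variants = missing_var)
  list(report = report, ok = all(report$ok), failures = failures)
}
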