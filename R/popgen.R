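#' Read population or clinical variants from VCF
#'
#' Parses a VCF into a flat per-allele SNV table. Multi-allelic records are
#' split into alleles before filtering; only single-nucleotide ref/alt pairs
#' are retained. INFO key names for the allele frequency, homozygous-sample
#' count and clinical significance are configurable (gnomAD/ClinVar-style
#' defaults). Coordinates are converted from VCF 1-based to the package's
#' 0-based convention.
#'
#' @param path VCF file (plain or bgzipped).
#' @param af_key,hom_key,clnsig_key INFO field names for allele frequency,
#'   homozygous-alternate sample count and clinical significance. Missing
#'   fields default to `AF = NA`, `n_hom = 0`, `clnsig = ""`.
#' @return Data frame `contig`, `pos` (0-based), `ref`, `alt`, `af`, `n_hom`,
#'   `clnsig`.
#' @export
read_variants <- function(path, af_key = "AF", hom_key = "nhomalt",
                          clnsig_key = "CLNSIG") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L)
    return(data.frame(contig = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0), n_hom = integer(0),
                      clnsig = character(0), stringsAsFactors = FALSE))
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, n) else as.character(val)
  }
  af_raw <- info_field(af_key)
  hom_raw <- info_field(hom_key)
  cln_raw <- info_field(clnsig_key)
  alt_list <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  nalt <- lengths(alt_list)
  per_allele <- function(raw) {
    parts <- strsplit(ifelse(is.na(raw), "", raw), ",", fixed = TRUE)
    lapply(seq_len(n), function(i) {
      p <- parts[[i]]
      if (length(p) == nalt[i]) p else rep(if (length(p)) p[1L] else NA_character_,
                                           nalt[i])
    })
  }
  af_pa <- per_allele(af_raw)
  hom_pa <- per_allele(hom_raw)
  idx <- rep(seq_len(n), nalt)
  out <- data.frame(
    contig = as.character(fix[idx, "CHROM"]),
    pos = as.integer(fix[idx, "POS"]) - 1L,
    ref = as.character(fix[idx, "REF"]),
    alt = unlist(alt_list),
    af = suppressWarnings(as.numeric(unlist(af_pa))),
    n_hom = suppressWarnings(as.integer(unlist(hom_pa))),
    clnsig = ifelse(is.na(cln_raw[idx]), "", cln_raw[idx]),
    stringsAsFactors = FALSE)
  out$n_hom[is.na(out$n_hom)] <- 0L
  out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L &
               out$alt %in% c("A", "C", "G", "T"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## positions (contig:pos keys) of variants passing the homozygous filter
qualifying_keys <- function(variants, require_hom) {
  v <- variants[variants$n_hom >= require_hom, , drop = FALSE]
  unique(paste0(v$contig, ":", v$pos))
}

#' SNP-rate profile around splice sites
#'
#' For each shift in the window (transcript orientation, as in
#' [conservation()]), the fraction of sites having at least one SNV with at
#' least `require_hom` homozygous-alternate samples at the corresponding
#' reference position.
#'
#' @param sites Site data frame (`contig`, `strand`, `origin`).
#' @param variants Variant table from [read_variants()].
#' @param window Integer vector of shifts, default `-4:7` (covers the plotted
#'   region around the canonical dinucleotides).
#' @param require_hom Minimum homozygous-sample count (default 1; 0 disables
#'   the homozygous filter).
#' @return Data frame `shift`, `n_sites`, `n_with_snp`, `rate`.
#' @export
snp_rate_profile <- function(sites, variants, window = -4:7, require_hom = 1L) {
  keys <- qualifying_keys(variants, require_hom)
  n <- nrow(sites)
  out <- lapply(window, function(s) {
    p <- shift_position(sites$origin, sites$strand, s)
    hit <- paste0(sites$contig, ":", p) %in% keys
    data.frame(shift = s, n_sites = n, n_with_snp = sum(hit),
               rate = if (n > 0L) sum(hit) / n else NA_real_)
  })
  do.call(rbind, out)
}

is_pathogenic <- function(clnsig) {
  cl <- tolower(clnsig)
  (grepl("pathogenic", cl, fixed = TRUE)) & !grepl("conflicting", cl, fixed = TRUE)
}

#' Pathogenic-variant overlap with canonical dinucleotides
#'
#' Counts sites having at least one ClinVar-style variant classified as
#' pathogenic or likely pathogenic (case-insensitive substring match,
#' "conflicting" records excluded) at either canonical dinucleotide position
#' (shifts 0 and 1). Each site counts at most once. Percentages are relative
#' to the number of sites in each (site kind x label) category.
#'
#' @param sites Site data frame (`contig`, `strand`, `origin`, `kind`, `key`).
#' @param clinical_variants Variant table from [read_variants()] with a
#'   populated `clnsig` column.
#' @param labels Site labels from [label_sites()] (sites without a label are
#'   grouped as `"unlabelled"`).
#' @return Data frame `kind`, `label`, `n_sites`, `n_overlapping`, `percent`.
#' @export
pathogenic_overlap <- function(sites, clinical_variants, labels) {
  pv <- clinical_variants[is_pathogenic(clinical_variants$clnsig), , drop = FALSE]
  keys <- unique(paste0(pv$contig, ":", pv$pos))
  p0 <- shift_position(sites$origin, sites$strand, 0L)
  p1 <- shift_position(sites$origin, sites$strand, 1L)
  hit <- paste0(sites$contig, ":", p0) %in% keys |
         paste0(sites$contig, ":", p1) %in% keys
  lab <- labels$label[match(sites$key, labels$key)]
  lab[is.na(lab)] <- "unlabelled"
  grp <- interaction(sites$kind, lab, drop = TRUE, sep = "\r")
  out <- lapply(levels(grp), function(g) {
    sel <- grp == g
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    data.frame(kind = parts[1L], label = parts[2L],
               n_sites = sum(sel), n_overlapping = sum(hit[sel]),
               percent = 100 * sum(hit[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Allele-frequency distribution of homozygous SNPs at canonical dinucleotides
#'
#' Collects the allele frequencies of SNVs passing the homozygous filter that
#' overlap a site's canonical dinucleotide positions (shifts 0 and 1), grouped
#' by label class, and summarises each class by median and interquartile
#' range.
#'
#' @inheritParams pathogenic_overlap
#' @param variants Variant table from [read_variants()].
#' @param require_hom Minimum homozygous-sample count (default 1).
#' @return `list(values, summary)`: per-(site, variant) AF values with label,
#'   and per-label `n`, `median_af`, `iqr_af` (`NA` for empty classes).
#' @export
hom_af_distribution <- function(sites, variants, labels, require_hom = 1L) {
  v <- variants[variants$n_hom >= require_hom & !is.na(variants$af), , drop = FALSE]
  vkey <- paste0(v$contig, ":", v$pos)
  p0 <- shift_position(sites$origin, sites$strand, 0L)
  p1 <- shift_position(sites$origin, sites$strand, 1L)
  lab <- labels$label[match(sites$key, labels$key)]
  lab[is.na(lab)] <- "unlabelled"
  vtab <- data.frame(key = vkey, af = v$af, stringsAsFactors = FALSE)
  stab <- data.frame(key = c(paste0(sites$contig, ":", p0),
                             paste0(sites$contig, ":", p1)),
                     label = rep(lab, 2L), stringsAsFactors = FALSE)
  values <- merge(vtab, stab, by = "key")[, c("af", "label")]
  classes <- sort(unique(lab))
  summary <- do.call(rbind, lapply(classes, function(cl) {
    af <- values$af[values$label == cl]
    data.frame(label = cl, n = length(af),
               median_af = if (length(af)) stats::median(af) else NA_real_,
               iqr_af = if (length(af)) stats::IQR(af) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(values = values, summary = summary)
}
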