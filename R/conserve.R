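## Reference position of shift l from a site origin, along transcript
## orientation: origin + l on the plus strand, origin - l on the minus strand.
shift_position <- function(origin, strand, shift) {
  ifelse(strand == "+", origin + shift, origin - shift)
}

## Vectorised conservation indicator for one (shift, target) over many sites.
## Returns integer 0/1; unaligned, out-of-range, mismatching, or N -> 0.
cons_indicator <- function(aln, ref, target_genomes, contig, strand, origin,
                           shift, target) {
  out <- integer(length(origin))
  p <- shift_position(origin, strand, shift)
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    if (!ctg %in% names(aln$maps)) next
    lk <- map_lookup(aln, ctg, p[sel], target)
    ok <- !is.na(lk$pos)
    if (!any(ok)) next
    rb <- toupper(genome_bases(ref, ctg, p[sel][ok]))
    tg <- target_genomes[[target]]
    tb <- rep(NA_character_, sum(ok))
    for (tctg in unique(lk$contig[ok])) {
      tsel <- lk$contig[ok] == tctg
      tb[tsel] <- toupper(genome_bases(tg, tctg, lk$pos[ok][tsel]))
    }
    tb[lk$minus[ok]] <- chartr("ACGT", "TGCA", tb[lk$minus[ok]])
    match_ok <- !is.na(rb) & !is.na(tb) & rb == tb & rb != "N"
    out[sel][ok] <- as.integer(match_ok)
  }
  out
}

#' The conservation function C(s, l, t)
#'
#' Indicator that the reference nucleotide at shift `l` from a splice site's
#' origin (counted along transcript orientation) matches its aligned
#' homologous nucleotide in a target genome. Unaligned positions, positions
#' outside the contig, mismatches, and N bases all give 0. Comparison is
#' case-insensitive; minus-strand alignment rows are compared via the
#' complemented target base (equivalently, the MAF column character).
#'
#' @param aln A `ref_alignment`.
#' @param ref Reference [genome()].
#' @param target_genomes Named list of target [genome()] objects.
#' @param contig,strand,origin Site fields (vectors, recycled).
#' @param shift Single integer shift `l` (0 and 1 are the canonical
#'   dinucleotide).
#' @param target Target genome id.
#' @return Integer vector of 0/1, one per site.
#' @export
conservation <- function(aln, ref, target_genomes, contig, strand, origin,
                         shift, target) {
  n <- max(length(contig), length(strand), length(origin))
  cons_indicator(aln, ref, target_genomes,
                 rep_len(contig, n), rep_len(strand, n), rep_len(origin, n),
                 shift, target)
}

#' Per-site conservation feature vectors
#'
#' For every site: the number of target species in which both canonical
#' dinucleotide positions (shifts 0 and 1) are conserved jointly, and the
#' per-shift species counts for every other shift in the window. This is the
#' feature representation consumed by the classifier (61 features for the
#' default window [-30, 31]).
#'
#' @inheritParams conservation
#' @param sites Data frame with `contig`, `strand`, `origin` (and usually
#'   `key`) columns.
#' @param window Length-2 integer vector `c(lo, hi)`, default `c(-30, 31)`.
#' @return Integer matrix, one row per site (rownames = site keys when
#'   available), columns `joint` then `p_<shift>` for shifts in the window
#'   excluding 0 and 1. Attributes: `m_used` (number of target genomes),
#'   `window`.
#' @export
feature_vectors <- function(sites, aln, ref, target_genomes,
                            window = c(-30L, 31L)) {
  shifts <- seq.int(window[1L], window[2L])
  pos_shifts <- setdiff(shifts, c(0L, 1L))
  targets <- names(target_genomes)
  n <- nrow(sites)
  joint <- integer(n)
  pc <- matrix(0L, n, length(pos_shifts),
               dimnames = list(NULL, paste0("p_", pos_shifts)))
  for (tg in targets) {
    c0 <- cons_indicator(aln, ref, target_genomes, sites$contig, sites$strand,
                         sites$origin, 0L, tg)
    c1 <- cons_indicator(aln, ref, target_genomes, sites$contig, sites$strand,
                         sites$origin, 1L, tg)
    joint <- joint + (c0 & c1)
    for (j in seq_along(pos_shifts)) {
      pc[, j] <- pc[, j] + cons_indicator(aln, ref, target_genomes,
                                          sites$contig, sites$strand,
                                          sites$origin, pos_shifts[j], tg)
    }
  }
  out <- cbind(joint = joint, pc)
  if (!is.null(sites$key)) rownames(out) <- sites$key
  attr(out, "m_used") <- length(targets)
  attr(out, "window") <- window
  out
}

#' Joint-dinucleotide conservation histogram
#'
#' Distribution of the number of species jointly conserving the canonical
#' dinucleotides, over a set of sites, normalised to total mass 1.
#'
#' @param joint_counts Integer vector (the `joint` column of
#'   [feature_vectors()]).
#' @param m Number of target species (histogram support is 0..m).
#' @return Data frame `n_species`, `count`, `fraction`.
#' @export
dinuc_conservation_histogram <- function(joint_counts, m) {
  if (length(joint_counts) == 0L)
    return(data.frame(n_species = integer(0), count = integer(0),
                      fraction = numeric(0)))
  counts <- tabulate(joint_counts + 1L, nbins = m + 1L)
  data.frame(n_species = 0:m, count = counts,
             fraction = counts / sum(counts))
}

#' Positional conservation profile
#'
#' Mean conservation fraction per shift over a set of sites: for each shift
#' in the window (including the canonical shifts 0 and 1), the mean over
#' sites of (number of conserving species / m).
#'
#' @inheritParams feature_vectors
#' @return Data frame `shift`, `mean_conservation`.
#' @export
positional_profile <- function(sites, aln, ref, target_genomes,
                               window = c(-30L, 31L)) {
  stopifnot(nrow(sites) >= 1L)
  shifts <- seq.int(window[1L], window[2L])
  m <- length(target_genomes)
  vals <- vapply(shifts, function(s) {
    tot <- integer(nrow(sites))
    for (tg in names(target_genomes))
      tot <- tot + cons_indicator(aln, ref, target_genomes, sites$contig,
                                  sites$strand, sites$origin, s, tg)
    mean(tot / m)
  }, numeric(1))
  data.frame(shift = shifts, mean_conservation = vals)
}

#' Ranking of species by joint dinucleotide conservation
#'
#' For each target genome, the number of sites whose canonical dinucleotides
#' are jointly conserved in it, sorted in decreasing order.
#'
#' @inheritParams feature_vectors
#' @return Data frame `target`, `n_sites`, sorted descending.
#' @export
conserved_species_ranking <- function(sites, aln, ref, target_genomes) {
  counts <- vapply(names(target_genomes), function(tg) {
    c0 <- cons_indicator(aln, ref, target_genomes, sites$contig, sites$strand,
                         sites$origin, 0L, tg)
    c1 <- cons_indicator(aln, ref, target_genomes, sites$contig, sites$strand,
                         sites$origin, 1L, tg)
    sum(c0 & c1)
  }, integer(1))
  out <- data.frame(target = names(counts), n_sites = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sites, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
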