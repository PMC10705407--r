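#' Find unaligned-but-syntenic exons
#'
#' An exon is syntenic in a target genome if it is unaligned there while an
#' aligned exon exists strictly upstream and another strictly downstream on
#' the same reference contig. The nearest qualifying aligned flank is chosen
#' on each side; both flanks must have all their aligned positions on one
#' common target contig, otherwise the exon is omitted.
#'
#' @param aln A `ref_alignment`.
#' @param exons Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open), deduplicated and non-overlapping per contig.
#' @param target Target genome id.
#' @return Data frame of candidates: the unaligned exon (`contig`, `start`,
#'   `end`) and its flanks (`flank_a_start`, `flank_a_end`, `flank_b_start`,
#'   `flank_b_end`).
#' @export
find_syntenic_unaligned <- function(aln, exons, target) {
  out <- list()
  for (ctg in unique(exons$contig)) {
    ex <- exons[exons$contig == ctg, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (!ctg %in% names(aln$maps)) next
    st <- exon_alignment_status(aln, ctg, ex$start, ex$end, target)
    aligned <- st == "aligned"
    single_contig <- function(i) {
      mm <- get_map(aln, ctg, target)
      ci <- mm$cidx[(ex$start[i] + 1L):ex$end[i]]
      ci <- ci[!is.na(ci)]
      if (length(ci) == 0L) NA_character_
      else if (length(unique(ci)) == 1L) mm$tcontigs[ci[1L]]
      else NA_character_
    }
    for (i in which(!aligned)) {
      up <- which(aligned & ex$end <= ex$start[i] & seq_len(nrow(ex)) < i)
      dn <- which(aligned & ex$start >= ex$end[i] & seq_len(nrow(ex)) > i)
      ia <- NA_integer_; ib <- NA_integer_
      ca <- NA_character_; cb <- NA_character_
      for (j in rev(up)) {                 # nearest first
        cj <- single_contig(j)
        if (!is.na(cj)) { ia <- j; ca <- cj; break }
      }
      for (j in dn) {
        cj <- single_contig(j)
        if (!is.na(cj)) { ib <- j; cb <- cj; break }
      }
      if (is.na(ia) || is.na(ib) || ca != cb) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = ex$start[i], end = ex$end[i],
        flank_a_start = ex$start[ia], flank_a_end = ex$end[ia],
        flank_b_start = ex$start[ib], flank_b_end = ex$end[ib],
        target_contig = ca, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), start = integer(0), end = integer(0),
                      flank_a_start = integer(0), flank_a_end = integer(0),
                      flank_b_start = integer(0), flank_b_end = integer(0),
                      target_contig = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Target segment between two aligned flanking exons
#'
#' u = [max A(e_a) + 1, min A(e_b) - 1] (0-based, inclusive bounds) on the
#' target contig shared by the two anchors; `NULL` (INVALID) if the anchors'
#' aligned positions lie on different target contigs or the interval is
#' inverted.
#'
#' @inheritParams find_syntenic_unaligned
#' @param flank_a,flank_b Length-3 lists/vectors `(contig, start, end)` of the
#'   upstream and downstream anchor exons (reference coordinates).
#' @return `list(contig, start, end)` with inclusive bounds, or `NULL`.
#' @export
target_segment <- function(aln, flank_a, flank_b, target) {
  seg_of <- function(f) {
    mm <- get_map(aln, f$contig, target)
    idx <- (f$start + 1L):f$end
    ok <- !is.na(mm$pos[idx])
    if (!any(ok)) return(NULL)
    ci <- unique(mm$cidx[idx][ok])
    if (length(ci) != 1L) return(NULL)
    list(contig = mm$tcontigs[ci], lo = min(mm$pos[idx][ok]),
         hi = max(mm$pos[idx][ok]))
  }
  a <- seg_of(flank_a); b <- seg_of(flank_b)
  if (is.null(a) || is.null(b) || a$contig != b$contig) return(NULL)
  s <- a$hi + 1L; e <- b$lo - 1L
  if (s > e) return(NULL)
  list(contig = a$contig, start = s, end = e)
}

#' Realign an exon inside a target segment
#'
#' Computes a minimum-edit-distance infix alignment (exon fully consumed,
#' segment flanks free, unit costs) of the exon sequence against the segment
#' sequence. Each exon position landing in a match or mismatch column maps to
#' its target column; gap columns map nothing. Ties between optimal placements
#' are broken by the leftmost segment start.
#'
#' @param exon_sequence,segment_sequence Nucleotide strings.
#' @param cap Maximum segment length considered (candidates over longer
#'   segments are skipped upstream); default 100,000.
#' @return `list(map, score, distance, start, end)` where `map` is an integer
#'   vector (one entry per exon position, 0-based segment-relative column or
#'   `NA`), `score` = mapped fraction r'(e), and `start`/`end` delimit the
#'   placement in segment columns.
#' @export
realign_exon <- function(exon_sequence, segment_sequence, cap = 100000L) {
  stopifnot(nchar(exon_sequence) > 0L, nchar(segment_sequence) > 0L)
  if (nchar(segment_sequence) >= cap)
    stop("segment-too-long (", nchar(segment_sequence), " >= cap ", cap, ")")
  r <- .infix_align_cpp(exon_sequence, segment_sequence)
  list(map = r$map,
       score = sum(!is.na(r$map)) / nchar(exon_sequence),
       distance = r$distance, start = r$start, end = r$end)
}

#' Baseline score distribution of originally aligned exons
#'
#' R_t = { r(e) : e aligned in target }, with arithmetic mean and standard
#' deviation. Realignments are accepted only when their score exceeds
#' mean - sd (see [accept_candidate()]).
#'
#' @inheritParams find_syntenic_unaligned
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return An object of class `score_baseline`: `list(target, scores, mean, sd)`.
#' @export
score_baseline <- function(aln, exons, target, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  scores <- numeric(0)
  for (ctg in unique(exons$contig)) {
    if (!ctg %in% names(aln$maps)) next
    ex <- exons[exons$contig == ctg, , drop = FALSE]
    mm <- get_map(aln, ctg, target)
    notna <- !is.na(mm$pos)
    cs <- c(0, cumsum(notna))
    cnt <- cs[ex$end + 1L] - cs[ex$start + 1L]
    r <- cnt / (ex$end - ex$start)
    scores <- c(scores, r[cnt > 0L])
  }
  if (length(scores) < 2L)
    stop("baseline undefined: fewer than 2 aligned exons in target ", target)
  mu <- mean(scores)
  sdv <- if (sd_type == "population")
    sqrt(mean((scores - mu)^2)) else stats::sd(scores)
  structure(list(target = target, scores = scores, mean = mu, sd = sdv,
                 sd_type = sd_type),
            class = "score_baseline")
}

#' @export
print.score_baseline <- function(x, ...) {
  cat("<score_baseline> target ", x$target, ": n=", length(x$scores),
      ", mean=", round(x$mean, 4), ", sd=", round(x$sd, 4),
      " (", x$sd_type, "), threshold mean-sd=", round(x$mean - x$sd, 4), "\n",
      sep = "")
  invisible(x)
}

#' Accept or reject a realignment candidate
#'
#' Accepted iff r'(e) > mean(R_t) - sd(R_t), strictly.
#'
#' @param score_rprime Realignment score r'(e).
#' @param baseline A [score_baseline()].
#' @return Logical.
#' @export
accept_candidate <- function(score_rprime, baseline) {
  score_rprime > baseline$mean - baseline$sd
}

#' Realign all syntenic unaligned exons for one target genome
#'
#' Drives the full recovery procedure: candidate discovery, target-segment
#' derivation, infix realignment, and the mean-minus-sd score filter.
#'
#' @inheritParams find_syntenic_unaligned
#' @param ref Reference [genome()].
#' @param target_genome Target [genome()] (for segment sequence extraction).
#' @param cap Maximum target-segment length (default 100,000).
#' @param baseline Optional precomputed [score_baseline()]; computed from the
#'   original alignment if `NULL`.
#' @return Data frame of candidates with columns `contig`, `start`, `end`,
#'   `target`, `segment_contig`, `segment_start`, `segment_end`,
#'   `score_rprime`, `accepted`, `reason`, and a list-column `map_we` of
#'   per-exon-position target positions (`NA` = unmapped).
#' @export
realign_exons <- function(aln, exons, target, ref, target_genome,
                          cap = 100000L, baseline = NULL) {
  cands <- find_syntenic_unaligned(aln, exons, target)
  empty <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                      target = character(0), segment_contig = character(0),
                      segment_start = integer(0), segment_end = integer(0),
                      score_rprime = numeric(0), accepted = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  empty$map_we <- list()
  if (nrow(cands) == 0L) return(empty)
  if (is.null(baseline)) {
    baseline <- tryCatch(score_baseline(aln, exons, target), error = function(e) NULL)
  }
  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cd <- cands[i, ]
    seg <- target_segment(
      aln,
      list(contig = cd$contig, start = cd$flank_a_start, end = cd$flank_a_end),
      list(contig = cd$contig, start = cd$flank_b_start, end = cd$flank_b_end),
      target)
    row <- data.frame(contig = cd$contig, start = cd$start, end = cd$end,
                      target = target, segment_contig = NA_character_,
                      segment_start = NA_integer_, segment_end = NA_integer_,
                      score_rprime = NA_real_, accepted = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    row$map_we <- list(NULL)
    if (is.null(seg)) {
      row$reason <- "invalid-segment"
    } else if (seg$end - seg$start + 1L >= cap) {
      row$segment_contig <- seg$contig
      row$segment_start <- seg$start; row$segment_end <- seg$end
      row$reason <- "segment-too-long"
    } else if (is.null(baseline)) {
      row$reason <- "baseline-undefined"
    } else {
      eseq <- genome_segment(ref, cd$contig, cd$start, cd$end)
      sseq <- genome_segment(target_genome, seg$contig, seg$start, seg$end + 1L)
      ra <- realign_exon(eseq, sseq, cap = cap)
      row$segment_contig <- seg$contig
      row$segment_start <- seg$start; row$segment_end <- seg$end
      row$score_rprime <- ra$score
      row$accepted <- accept_candidate(ra$score, baseline)
      row$reason <- if (row$accepted) "accepted" else "below-threshold"
      row$map_we <- list(ifelse(is.na(ra$map), NA_integer_,
                                as.integer(seg$start + ra$map)))
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Merge accepted realignments into the alignment
#'
#' Produces the extended alignment function w': positions that were unaligned
#' in w adopt the candidate mapping with provenance `"recovered"`; positions
#' already mapped in w are never overwritten (conflicts are kept original and
#' counted in a message).
#'
#' @param aln A `ref_alignment`.
#' @param candidates Data frame from [realign_exons()] (only rows with
#'   `accepted == TRUE` are used); may combine several targets.
#' @return A new `ref_alignment`.
#' @export
merge_alignment <- function(aln, candidates) {
  acc <- candidates[candidates$accepted, , drop = FALSE]
  n_conflict <- 0L
  grp <- interaction(acc$contig, acc$target, drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    mm <- get_map(aln, acc$contig[rows[1L]], acc$target[rows[1L]])
    for (i in rows) {
      cd <- acc[i, ]
      ci <- match(cd$segment_contig, mm$tcontigs)
      if (is.na(ci)) {
        mm$tcontigs <- c(mm$tcontigs, cd$segment_contig)
        ci <- length(mm$tcontigs)
      }
      k <- seq.int(cd$start, cd$end - 1L)
      we <- cd$map_we[[1L]]
      ok <- !is.na(we)
      free <- is.na(mm$pos[k + 1L])
      n_conflict <- n_conflict + sum(ok & !free)
      take <- ok & free
      if (any(take)) {
        kk <- k[take] + 1L
        mm$pos[kk] <- we[take]
        mm$cidx[kk] <- ci
        mm$minus[kk] <- FALSE
        mm$prov[kk] <- as.raw(1L)
      }
    }
    aln$maps[[acc$contig[rows[1L]]]][[acc$target[rows[1L]]]] <- mm
  }
  if (n_conflict > 0L)
    message(n_conflict, " recovered position(s) conflicted with existing mappings; ",
            "originals kept")
  aln
}

#' Alignment completeness report
#'
#' Per stratum (chromosome label x gene type): s_a = number of aligned
#' (exon, genome) pairs, s_m = number of missing pairs in the original
#' alignment, and s_r = number of pairs missing before but aligned after
#' realignment.
#'
#' @param aln_before,aln_after `ref_alignment` objects over the same exon set
#'   (pass the same object twice if no recovery was run).
#' @param exons Data frame with `contig`, `start`, `end`, and optionally
#'   `chromosome` and `gene_type` columns for stratification.
#' @param targets Character vector of target genome ids.
#' @return Data frame with columns `chromosome`, `gene_type`, `s_a`, `s_m`,
#'   `s_r`.
#' @export
completeness_report <- function(aln_before, aln_after, exons, targets) {
  if (is.null(exons$chromosome)) exons$chromosome <- exons$contig
  if (is.null(exons$gene_type)) exons$gene_type <- "all"
  w0 <- matrix(FALSE, nrow(exons), length(targets))
  w1 <- matrix(FALSE, nrow(exons), length(targets))
  for (j in seq_along(targets)) {
    w0[, j] <- exon_alignment_status(aln_before, exons$contig, exons$start,
                                     exons$end, targets[j]) == "aligned"
    w1[, j] <- exon_alignment_status(aln_after, exons$contig, exons$start,
                                     exons$end, targets[j]) == "aligned"
  }
  strata <- interaction(exons$chromosome, exons$gene_type, drop = TRUE, sep = "\r")
  out <- lapply(levels(strata), function(s) {
    sel <- strata == s
    parts <- strsplit(s, "\r", fixed = TRUE)[[1L]]
    data.frame(chromosome = parts[1L], gene_type = parts[2L],
               s_a = sum(w0[sel, , drop = FALSE]),
               s_m = sum(!w0[sel, , drop = FALSE]),
               s_r = sum(!w0[sel, , drop = FALSE] & w1[sel, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
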