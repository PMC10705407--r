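#' The unaligned sentinel
#'
#' Reference positions with no homolog in a target genome map to `UNALIGNED`
#' (`NA_integer_`), a typed sentinel distinct from every valid coordinate
#' (coordinates are 0-based, so 0 is a valid position).
#' @export
UNALIGNED <- NA_integer_

new_ref_alignment <- function(reference_id, targets, ref_lengths, target_lengths) {
  maps <- list()
  structure(
    list(reference_id = reference_id,
         targets = targets,
         ref_lengths = ref_lengths,
         target_lengths = target_lengths,
         maps = maps,
         n_conflicts = 0L),
    class = "ref_alignment")
}

## allocate dense per-position vectors for one (ref contig, target) pair
alloc_map <- function(len) {
  list(pos = rep(NA_integer_, len),
       cidx = rep(NA_integer_, len),
       minus = logical(len),
       prov = raw(len),      # 0x00 original, 0x01 recovered
       tcontigs = character(0))
}

#' @export
print.ref_alignment <- function(x, ...) {
  n_mapped <- sum(vapply(x$maps, function(m)
    sum(vapply(m, function(mm) sum(!is.na(mm$pos)), 0)), 0))
  cat("<ref_alignment> reference ", x$reference_id, ", ",
      length(x$targets), " target genome(s), ",
      length(x$maps), " reference contig(s), ",
      format(n_mapped, big.mark = ","), " mapped (position, target) pairs\n",
      sep = "")
  invisible(x)
}

split_src <- function(src) {
  i <- regexpr(".", src, fixed = TRUE)
  bad <- i < 0L
  g <- ifelse(bad, src, substr(src, 1L, i - 1L))
  ctg <- ifelse(bad, src, substring(src, i + 1L))
  list(genome = g, contig = ctg)
}

#' Load a MultiZ-style MAF file into a reference-anchored alignment
#'
#' Builds the per-position alignment function w(k, g_t): for every alignment
#' block, each column in which both the reference row and a target row carry a
#' non-gap character yields one mapping entry from the reference position to
#' the target position. Minus-strand target rows are converted to
#' forward-strand coordinates (pos' = srcSize - pos - 1). When two blocks map
#' the same reference position for the same target genome, the first block
#' encountered wins and a warning reports the number of conflicts.
#'
#' @param path MAF file. Only `a` and `s` lines are interpreted; `i`/`e`/`q`
#'   lines are tolerated and skipped. `src` fields must be of the form
#'   `genome.contig`.
#' @param reference_id Genome id of the reference; every block must contain a
#'   row for it (blocks without one are skipped with a warning).
#' @param targets Optional character vector restricting which target genomes
#'   are ingested; default: all non-reference genomes seen in the file.
#' @return An object of class `ref_alignment`.
#' @seealso [map_position()], [write_maf()]
#' @export
load_maf <- function(path, reference_id, targets = NULL) {
  lines <- readLines(path)
  is_s <- startsWith(lines, "s")
  is_a <- startsWith(lines, "a")
  block_id <- cumsum(is_a)
  keep <- which(is_s & block_id > 0L)
  if (length(keep) == 0L) stop("no alignment blocks found in ", path)

  fld <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fld)
  if (any(nf != 7L))
    stop("malformed MAF 's' line at line ", keep[which(nf != 7L)[1L]], " of ", path)
  src     <- vapply(fld, `[[`, "", 2L)
  start   <- as.integer(vapply(fld, `[[`, "", 3L))
  size    <- as.integer(vapply(fld, `[[`, "", 4L))
  strand  <- vapply(fld, `[[`, "", 5L)
  srcsize <- as.integer(vapply(fld, `[[`, "", 6L))
  text    <- vapply(fld, `[[`, "", 7L)
  if (anyNA(start) || anyNA(size) || anyNA(srcsize) || any(!strand %in% c("+", "-")))
    stop("malformed MAF 's' line at line ",
         keep[which(is.na(start) | is.na(size) | is.na(srcsize) |
                      !strand %in% c("+", "-"))[1L]], " of ", path)
  sp <- split_src(src)
  bid <- block_id[keep]

  all_targets <- setdiff(unique(sp$genome), reference_id)
  if (is.null(targets)) targets <- all_targets
  ref_lengths <- integer(0)
  target_lengths <- stats::setNames(
    replicate(length(targets), integer(0), simplify = FALSE), targets)
  # per (ref contig, target) chunk accumulators; dense vectors are built once
  # at the end (per-block in-place updates would copy them at every block)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  n_skipped <- 0L

  for (b in unique(bid)) {
    rows <- which(bid == b)
    iref <- rows[sp$genome[rows] == reference_id]
    if (length(iref) == 0L) { n_skipped <- n_skipped + 1L; next }
    iref <- iref[1L]
    if (strand[iref] == "-")
      stop("reference row on minus strand at line ", keep[iref], " of ", path)
    rchars <- strsplit(text[iref], "", fixed = TRUE)[[1L]]
    if (sum(rchars != "-") != size[iref])
      stop("row size does not match non-gap count at line ", keep[iref], " of ", path)
    rctg <- sp$contig[iref]
    if (!rctg %in% names(ref_lengths)) ref_lengths[[rctg]] <- srcsize[iref]
    rgap <- rchars == "-"
    rpos <- start[iref] + cumsum(!rgap) - 1L  # 0-based ref position per column

    for (j in setdiff(rows, iref)) {
      g <- sp$genome[j]
      if (!g %in% targets) next
      tchars <- strsplit(text[j], "", fixed = TRUE)[[1L]]
      if (length(tchars) != length(rchars))
        stop("ragged block: row length mismatch at line ", keep[j], " of ", path)
      if (sum(tchars != "-") != size[j])
        stop("row size does not match non-gap count at line ", keep[j], " of ", path)
      tgap <- tchars == "-"
      praw <- start[j] + cumsum(!tgap) - 1L
      if (strand[j] == "-") praw <- srcsize[j] - 1L - praw
      colmask <- !rgap & !tgap
      if (!any(colmask)) next
      tctg <- sp$contig[j]
      target_lengths[[g]][[tctg]] <- srcsize[j]
      key <- paste0(rctg, "\r", g)
      chunks <- acc[[key]]
      if (is.null(chunks)) chunks <- list()
      chunks[[length(chunks) + 1L]] <- list(k = rpos[colmask], p = praw[colmask],
                                            tctg = tctg,
                                            minus = strand[j] == "-")
      acc[[key]] <- chunks
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " block(s) without a reference row skipped")

  maps <- list()
  n_conflict <- 0L
  for (rctg in names(ref_lengths)) {
    maps[[rctg]] <- stats::setNames(vector("list", length(targets)), targets)
    for (g in targets) {
      m <- alloc_map(ref_lengths[[rctg]])
      chunks <- acc[[paste0(rctg, "\r", g)]]
      if (!is.null(chunks)) {
        m$tcontigs <- unique(vapply(chunks, `[[`, "", "tctg"))
        K <- unlist(lapply(chunks, `[[`, "k")) + 1L
        P <- unlist(lapply(chunks, `[[`, "p"))
        CI <- unlist(lapply(chunks, function(ch)
          rep(match(ch$tctg, m$tcontigs), length(ch$k))))
        MI <- unlist(lapply(chunks, function(ch) rep(ch$minus, length(ch$k))))
        dup <- duplicated(K)          # first block encountered wins
        n_conflict <- n_conflict + sum(dup)
        m$pos[K[!dup]] <- P[!dup]
        m$cidx[K[!dup]] <- CI[!dup]
        m$minus[K[!dup]] <- MI[!dup]
      }
      maps[[rctg]][[g]] <- m
    }
  }
  if (n_conflict > 0L)
    warning(n_conflict, " reference position(s) multiply mapped across blocks; ",
            "first block kept")
  out <- new_ref_alignment(reference_id, targets, ref_lengths, target_lengths)
  out$maps <- maps
  out$n_conflicts <- n_conflict
  out
}

get_map <- function(aln, contig, target) {
  m <- aln$maps[[contig]]
  if (is.null(m)) stop("unknown reference contig: ", contig)
  mm <- m[[target]]
  if (is.null(mm)) stop("unknown target genome: ", target)
  mm
}

#' Map reference positions to a target genome
#'
#' The alignment function w(k, g_t): returns for each 0-based reference
#' position its homologous forward-strand position in the target genome, or
#' [UNALIGNED] (`NA`) where no homolog is aligned.
#'
#' @param aln A `ref_alignment`.
#' @param contig Reference contig name.
#' @param k Integer vector of 0-based reference positions.
#' @param target Target genome id.
#' @return Integer vector of target positions (`NA` = unaligned).
#' @export
map_position <- function(aln, contig, k, target) {
  mm <- get_map(aln, contig, target)
  len <- length(mm$pos)
  if (any(k < 0L | k >= len, na.rm = TRUE))
    stop("position out of range for contig ", contig)
  mm$pos[k + 1L]
}

## Full per-position lookup, clamping out-of-range to unaligned (used by the
## conservation window, which may overhang contig ends).
map_lookup <- function(aln, contig, k, target) {
  mm <- get_map(aln, contig, target)
  len <- length(mm$pos)
  ok <- !is.na(k) & k >= 0L & k < len
  idx <- ifelse(ok, k + 1L, NA_integer_)
  list(pos = mm$pos[idx],
       contig = mm$tcontigs[mm$cidx[idx]],
       minus = mm$minus[idx],
       prov = mm$prov[idx])
}

#' Aligned positions of an exon in a target genome
#'
#' The set A(e) = { w(k, g_t) : k in e, w(k, g_t) != UNALIGNED } of
#' forward-strand target positions; empty for unaligned exons.
#'
#' @inheritParams map_position
#' @param start,end Exon interval, 0-based half-open.
#' @return Sorted integer vector of target positions.
#' @export
aligned_positions <- function(aln, contig, start, end, target) {
  stopifnot(start < end)
  p <- map_position(aln, contig, seq.int(start, end - 1L), target)
  sort(p[!is.na(p)])
}

#' Alignment status of exons in a target genome
#'
#' W(e, g) = 1 iff at least one position of the exon is aligned somewhere in
#' the target genome.
#'
#' @inheritParams map_position
#' @param start,end Integer vectors of exon intervals (0-based half-open),
#'   recycled against each other; `contig` may be a vector too.
#' @return Character vector, `"aligned"` or `"unaligned"`, one per exon.
#' @export
exon_alignment_status <- function(aln, contig, start, end, target) {
  n <- max(length(contig), length(start), length(end))
  contig <- rep_len(contig, n); start <- rep_len(start, n); end <- rep_len(end, n)
  out <- character(n)
  for (ctg in unique(contig)) {
    mm <- get_map(aln, ctg, target)
    sel <- which(contig == ctg)
    notna <- !is.na(mm$pos)
    cs <- c(0L, cumsum(notna))
    any_aligned <- cs[pmin(end[sel], length(mm$pos)) + 1L] - cs[pmax(start[sel], 0L) + 1L] > 0L
    out[sel] <- ifelse(any_aligned, "aligned", "unaligned")
  }
  out
}

#' Alignment score of an exon
#'
#' r(e): the fraction of an exon's positions aligned in the target genome.
#'
#' @inheritParams aligned_positions
#' @return A number in [0, 1].
#' @export
alignment_score <- function(aln, contig, start, end, target) {
  stopifnot(start < end)
  p <- map_position(aln, contig, seq.int(start, end - 1L), target)
  sum(!is.na(p)) / (end - start)
}

#' Write a reference-anchored alignment back to MAF
#'
#' Emits one pairwise block per maximal colinear run of the mapping (same
#' target contig/strand, consecutive positions on both genomes). Round-trips
#' through [load_maf()] to an identical mapping.
#'
#' @param aln A `ref_alignment`.
#' @param ref Reference [genome()].
#' @param targets Named list of target [genome()] objects (names = genome ids).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(aln, ref, targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (ctg in names(aln$maps)) {
    reflen <- aln$ref_lengths[[ctg]]
    for (tg in names(aln$maps[[ctg]])) {
      mm <- aln$maps[[ctg]][[tg]]
      idx <- which(!is.na(mm$pos))
      if (length(idx) == 0L) next
      step <- ifelse(mm$minus[idx], -1L, 1L)
      newrun <- c(TRUE,
                  diff(idx) != 1L |
                  diff(mm$pos[idx]) != step[-length(idx)] |
                  diff(mm$cidx[idx]) != 0L |
                  diff(mm$minus[idx]) != 0L)
      run <- cumsum(newrun)
      for (r in split(idx, run)) {
        k0 <- r[1L] - 1L; len <- length(r)
        tctg <- mm$tcontigs[mm$cidx[r[1L]]]
        tlen <- aln$target_lengths[[tg]][[tctg]]
        rseq <- genome_segment(ref, ctg, k0, k0 + len)
        if (!mm$minus[r[1L]]) {
          tstart <- mm$pos[r[1L]]
          tseq <- genome_segment(targets[[tg]], tctg, tstart, tstart + len)
          srow <- sprintf("s %s.%s %d %d + %d %s", tg, tctg, tstart, len, tlen, tseq)
        } else {
          fwd_hi <- mm$pos[r[1L]]          # forward positions run fwd_hi..fwd_lo
          fwd_lo <- mm$pos[r[len]]
          tseq <- revcomp(genome_segment(targets[[tg]], tctg, fwd_lo, fwd_hi + 1L))
          srow <- sprintf("s %s.%s %d %d - %d %s",
                          tg, tctg, tlen - 1L - fwd_hi, len, tlen, tseq)
        }
        writeLines(c("a score=0",
                     sprintf("s %s.%s %d %d + %d %s",
                             aln$reference_id, ctg, k0, len, reflen, rseq),
                     srow, ""), con)
      }
    }
  }
  invisible(path)
}
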