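#' Read a per-tissue junction coverage table
#'
#' The table has one row per donor-acceptor junction with 1-based inclusive
#' intron coordinates (`contig`, `intron_start`, `intron_end`, `strand`)
#' followed by one read-count column per tissue. Coordinates are normalised
#' to the internal 0-based convention and the donor/acceptor origins are
#' derived in transcript orientation; `max_coverage` is the maximum count
#' across tissues. Malformed rows are skipped with a warning.
#'
#' @param path TSV file.
#' @return Data frame `contig`, `strand`, `intron_start`, `intron_end`
#'   (0-based half-open), `donor_origin`, `acceptor_origin`, the tissue
#'   columns, and `max_coverage`. The tissue column names are kept in
#'   `attr(, "tissues")`.
#' @export
load_junction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("contig", "intron_start", "intron_end", "strand")
  if (!all(need %in% names(df)))
    stop("junction table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  tissues <- setdiff(names(df), need)
  if (length(tissues) == 0L) stop("junction table has no tissue columns")
  bad <- is.na(df$intron_start) | is.na(df$intron_end) |
    !df$strand %in% c("+", "-") | df$intron_end < df$intron_start
  for (tc in tissues) {
    df[[tc]] <- suppressWarnings(as.numeric(df[[tc]]))
    bad <- bad | is.na(df[[tc]])
  }
  if (any(bad))
    warning(sum(bad), " malformed junction row(s) skipped")
  df <- df[!bad, , drop = FALSE]
  start0 <- as.integer(df$intron_start) - 1L  # -> 0-based half-open
  end0 <- as.integer(df$intron_end)
  plus <- df$strand == "+"
  out <- data.frame(contig = df$contig, strand = df$strand,
                    intron_start = start0, intron_end = end0,
                    donor_origin = ifelse(plus, start0, end0 - 1L),
                    acceptor_origin = ifelse(plus, end0 - 2L, start0 + 1L),
                    stringsAsFactors = FALSE)
  out <- cbind(out, df[, tissues, drop = FALSE])
  out$max_coverage <- do.call(pmax, out[tissues])
  attr(out, "tissues") <- tissues
  out
}

#' Write a junction coverage table
#'
#' Inverse of [load_junction_table()] (coordinates back to 1-based
#' inclusive).
#'
#' @param junctions Data frame as returned by [load_junction_table()], or one
#'   with `contig`, `strand`, `intron_start`, `intron_end` (0-based
#'   half-open) and tissue columns.
#' @param path Output file.
#' @param tissues Tissue column names; default `attr(junctions, "tissues")`.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path,
                                 tissues = attr(junctions, "tissues")) {
  out <- data.frame(contig = junctions$contig,
                    intron_start = junctions$intron_start + 1L,
                    intron_end = junctions$intron_end,
                    strand = junctions$strand,
                    stringsAsFactors = FALSE)
  out <- cbind(out, junctions[, tissues, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Junction coverage by intron conservation category
#'
#' Summarises the maximum cross-tissue read coverage of junctions per intron
#' category (from [intron_categories()]): median, quartiles, interquartile
#' range, and whisker bounds at +/- 1.5 IQR clamped to the observed range
#' (box-plot convention). Junctions are matched to introns by exact
#' coordinate and strand equality; unmatched junctions are counted
#' separately.
#'
#' @param junctions Data frame from [load_junction_table()].
#' @param introns Intron data frame with `category` (and optionally
#'   `gene_type`) from [intron_categories()].
#' @return `list(summary, n_unmatched)`; `summary` has one row per
#'   (gene_type x category) with `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_lo`, `whisker_hi` (`NA` for empty categories).
#' @export
coverage_by_category <- function(junctions, introns) {
  jkey <- paste(junctions$contig, junctions$strand, junctions$intron_start,
                junctions$intron_end, sep = ":")
  ikey <- paste(introns$contig, introns$strand, introns$start, introns$end,
                sep = ":")
  m <- match(jkey, ikey)
  matched <- !is.na(m)
  gt <- if (!is.null(introns$gene_type)) introns$gene_type[m[matched]] else "all"
  d <- data.frame(max_coverage = junctions$max_coverage[matched],
                  category = introns$category[m[matched]],
                  gene_type = gt, stringsAsFactors = FALSE)
  grid <- expand.grid(gene_type = unique(d$gene_type), category = 1:4,
                      stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- d$max_coverage[d$gene_type == grid$gene_type[i] &
                          d$category == grid$category[i]]
    if (length(v) == 0L)
      return(data.frame(gene_type = grid$gene_type[i],
                        category = grid$category[i], n = 0L,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        iqr = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(gene_type = grid$gene_type[i], category = grid$category[i],
               n = length(v), median = q[2L], q1 = q[1L], q3 = q[3L],
               iqr = iqr,
               whisker_lo = min(v[v >= q[1L] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3L] + 1.5 * iqr]))
  }))
  list(summary = summary, n_unmatched = sum(!matched))
}
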