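# Independent brute-force oracles. These deliberately use naive per-column /
# per-cell loops rather than the package's vectorised or compiled paths.

# Column-walking MAF oracle: returns an environment keyed
# "contig:k:target" -> c(pos, minus). First block encountered wins.
oracle_maf_mapping <- function(path, reference_id) {
  lines <- readLines(path)
  env <- new.env(hash = TRUE, parent = emptyenv())
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "a")) {
      j <- i + 1L
      rows <- list()
      while (j <= length(lines) && startsWith(lines[j], "s")) {
        f <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
        rows[[length(rows) + 1L]] <- list(
          src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
          strand = f[5], srcsize = as.integer(f[6]), text = f[7])
        j <- j + 1L
      }
      gs <- sub("\\..*$", "", vapply(rows, `[[`, "", "src"))
      ir <- which(gs == reference_id)[1]
      if (!is.na(ir)) {
        rr <- rows[[ir]]
        rctg <- sub("^[^.]*\\.", "", rr$src)
        for (tr_i in seq_along(rows)) {
          if (tr_i == ir) next
          tr <- rows[[tr_i]]
          tg <- gs[tr_i]
          tctg <- sub("^[^.]*\\.", "", tr$src)
          rpos <- rr$start; tpos <- tr$start
          rch <- strsplit(rr$text, "")[[1]]
          tch <- strsplit(tr$text, "")[[1]]
          for (col in seq_along(rch)) {
            rgap <- rch[col] == "-"; tgap <- tch[col] == "-"
            if (!rgap && !tgap) {
              fw <- if (tr$strand == "-") tr$srcsize - 1L - tpos else tpos
              key <- paste(rctg, rpos, tg, sep = ":")
              if (is.null(env[[key]]))
                env[[key]] <- list(pos = fw, minus = tr$strand == "-",
                                   contig = tctg,
                                   ref_char = toupper(rch[col]),
                                   tgt_char = toupper(tch[col]))
            }
            if (!rgap) rpos <- rpos + 1L
            if (!tgap) tpos <- tpos + 1L
          }
        }
      }
      i <- j
    } else i <- i + 1L
  }
  env
}

oracle_map_position <- function(env, contig, k, target) {
  e <- env[[paste(contig, k, target, sep = ":")]]
  if (is.null(e)) NA_integer_ else e$pos
}

# Full quadratic DP with the same leftmost-start tie-break as the compiled
# aligner, written independently in plain R (small instances only).
oracle_infix_align <- function(query, segment) {
  q <- strsplit(tolower(query), "")[[1]]
  s <- strsplit(tolower(segment), "")[[1]]
  n <- length(q); m <- length(s)
  D <- matrix(0L, n + 1, m + 1)
  S <- matrix(0L, n + 1, m + 1)
  D[1, ] <- 0L; S[1, ] <- 0:m
  for (i in 1:n) {
    D[i + 1, 1] <- i; S[i + 1, 1] <- 0L
    for (j in 1:m) {
      cost <- as.integer(q[i] != s[j])
      cand <- c(D[i, j] + cost, D[i, j + 1] + 1L, D[i + 1, j] + 1L)
      d <- min(cand)
      st <- Inf
      if (cand[1] == d) st <- min(st, S[i, j])
      if (cand[2] == d) st <- min(st, S[i, j + 1])
      if (cand[3] == d) st <- min(st, S[i + 1, j])
      D[i + 1, j + 1] <- d; S[i + 1, j + 1] <- st
    }
  }
  bd <- min(D[n + 1, ])
  cands <- which(D[n + 1, ] == bd)
  bs <- min(S[n + 1, cands])
  bj <- cands[S[n + 1, cands] == bs][1] - 1L
  # traceback (diagonal > up > left among moves optimal for both D and S)
  map <- rep(NA_integer_, n)
  i <- n; j <- bj
  while (i > 0) {
    d <- D[i + 1, j + 1]; st <- S[i + 1, j + 1]
    cost <- if (j > 0) as.integer(q[i] != s[j]) else NA_integer_
    if (j > 0 && D[i, j] + cost == d && S[i, j] == st) {
      map[i] <- j - 1L; i <- i - 1L; j <- j - 1L
    } else if (D[i, j + 1] + 1L == d && S[i, j + 1] == st) {
      i <- i - 1L
    } else if (j > 0 && D[i + 1, j] + 1L == d && S[i + 1, j] == st) {
      j <- j - 1L
    } else if (j > 0 && D[i, j] + cost == d) {
      map[i] <- j - 1L; i <- i - 1L; j <- j - 1L
    } else if (D[i, j + 1] + 1L == d) {
      i <- i - 1L
    } else j <- j - 1L
  }
  list(distance = as.integer(bd), start = as.integer(bs), map = map)
}

# Trapezoid ROC/AUC oracle from raw scores.
oracle_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(c(Inf, thr, -Inf), function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(c(Inf, thr, -Inf), function(t) mean(scores[labels == 0] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Random multi-block MAF fixture with gaps and both strands, consistent with
# generated reference/target genomes (column characters equal genome bases).
make_maf_fixture <- function(seed = 1L, n_blocks = 20L, dir = tempfile()) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE)
  ref <- genome("ref", c(c1 = random_dna(600), c2 = random_dna(400)))
  t1 <- genome("t1", c(k1 = random_dna(700)))
  t2 <- genome("t2", c(k2 = random_dna(500), k3 = random_dna(300)))
  targets <- list(t1 = t1, t2 = t2)
  lines <- "##maf version=1"
  for (b in seq_len(n_blocks)) {
    rctg <- sample(names(ref$contigs), 1)
    tg <- sample(names(targets), 1)
    tgen <- targets[[tg]]
    tctg <- sample(names(tgen$contigs), 1)
    ncol_ <- sample(10:40, 1)
    # choose column types ensuring enough sequence remains
    rstart <- sample(0:(ref$lengths[[rctg]] - ncol_ - 1), 1)
    tstart <- sample(0:(tgen$lengths[[tctg]] - ncol_ - 1), 1)
    strand <- sample(c("+", "-"), 1)
    type <- sample(c("m", "rg", "tg"), ncol_, replace = TRUE,
                   prob = c(0.8, 0.1, 0.1))
    rpos <- rstart; tpos <- tstart
    rch <- character(0); tch <- character(0)
    for (ty in type) {
      rc <- substring(ref$contigs[[rctg]], rpos + 1, rpos + 1)
      if (strand == "+") {
        tc <- substring(tgen$contigs[[tctg]], tpos + 1, tpos + 1)
      } else {
        fw <- tgen$lengths[[tctg]] - 1L - tpos
        tc <- chartr("ACGT", "TGCA",
                     substring(tgen$contigs[[tctg]], fw + 1, fw + 1))
      }
      if (ty == "m") { rch <- c(rch, rc); tch <- c(tch, tc)
                       rpos <- rpos + 1L; tpos <- tpos + 1L }
      if (ty == "rg") { rch <- c(rch, "-"); tch <- c(tch, tc); tpos <- tpos + 1L }
      if (ty == "tg") { rch <- c(rch, rc); tch <- c(tch, "-"); rpos <- rpos + 1L }
    }
    lines <- c(lines, "a score=0",
               sprintf("s ref.%s %d %d + %d %s", rctg, rstart, rpos - rstart,
                       ref$lengths[[rctg]], paste(rch, collapse = "")),
               sprintf("s %s.%s %d %d %s %d %s", tg, tctg, tstart,
                       tpos - tstart, strand, tgen$lengths[[tctg]],
                       paste(tch, collapse = "")),
               "")
  }
  path <- file.path(dir, "fixture.maf")
  writeLines(lines, path)
  list(path = path, ref = ref, targets = targets)
}
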