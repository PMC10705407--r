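# A three-exon gene on one contig with the middle exon unaligned.
three_exon_fixture <- function() {
  p <- tempfile(fileext = ".maf")
  writeLines(c(
    "##maf version=1",
    "a", "s ref.c1 0 20 + 200 AAAAAAAAAACCCCCCCCCC",
    "s t1.k1 100 20 + 1000 AAAAAAAAAACCCCCCCCCC", "",
    "a", "s ref.c1 80 20 + 200 GGGGGGGGGGTTTTTTTTTT",
    "s t1.k1 300 20 + 1000 GGGGGGGGGGTTTTTTTTTT", ""), p)
  exons <- data.frame(contig = "c1",
                      start = c(0L, 40L, 80L), end = c(20L, 60L, 100L))
  list(aln = load_maf(p, "ref"), exons = exons)
}

test_that("syntenic unaligned exons are found with nearest aligned flanks", {
  fx <- three_exon_fixture()
  cand <- find_syntenic_unaligned(fx$aln, fx$exons, "t1")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 40L)
  expect_equal(cand$flank_a_start, 0L)
  expect_equal(cand$flank_b_start, 80L)
  # a first/last exon with no flank on one side is omitted
  ex2 <- data.frame(contig = "c1", start = c(120L, 150L), end = c(140L, 170L))
  expect_equal(nrow(find_syntenic_unaligned(fx$aln, rbind(fx$exons, ex2), "t1")), 1L)
})

test_that("target segment is the interval between anchor extremes", {
  fx <- three_exon_fixture()
  seg <- target_segment(fx$aln, list(contig = "c1", start = 0L, end = 20L),
                        list(contig = "c1", start = 80L, end = 100L), "t1")
  # A(e_a) = 100..119, A(e_b) = 300..319 -> u = [120, 299]
  expect_equal(seg$start, 120L)
  expect_equal(seg$end, 299L)
  # inverted anchors -> INVALID
  expect_null(target_segment(fx$aln, list(contig = "c1", start = 80L, end = 100L),
                             list(contig = "c1", start = 0L, end = 20L), "t1"))
})

test_that("target segment matches a set-min/max oracle on random fixtures", {
  fx <- make_maf_fixture(seed = 21, n_blocks = 20)
  aln <- suppressWarnings(load_maf(fx$path, "ref"))
  set.seed(3)
  for (i in 1:40) {
    a0 <- sample(0:500, 1); a1 <- a0 + sample(5:20, 1)
    b0 <- a1 + sample(5:40, 1); b1 <- b0 + sample(5:20, 1)
    if (b1 >= fx$ref$lengths[["c1"]]) next
    fa <- list(contig = "c1", start = a0, end = a1)
    fb <- list(contig = "c1", start = b0, end = b1)
    for (tg in c("t1", "t2")) {
      seg <- target_segment(aln, fa, fb, tg)
      pa <- map_position(aln, "c1", a0:(a1 - 1L), tg)
      pb <- map_position(aln, "c1", b0:(b1 - 1L), tg)
      # oracle: both anchors single-contig aligned and non-inverted
      lka <- splicecons:::map_lookup(aln, "c1", a0:(a1 - 1L), tg)
      lkb <- splicecons:::map_lookup(aln, "c1", b0:(b1 - 1L), tg)
      ca <- unique(lka$contig[!is.na(lka$pos)])
      cb <- unique(lkb$contig[!is.na(lkb$pos)])
      valid <- any(!is.na(pa)) && any(!is.na(pb)) &&
        length(ca) == 1L && length(cb) == 1L && identical(ca, cb) &&
        max(pa, na.rm = TRUE) + 1L <= min(pb, na.rm = TRUE) - 1L
      if (valid) {
        expect_equal(seg$start, max(pa, na.rm = TRUE) + 1L)
        expect_equal(seg$end, min(pb, na.rm = TRUE) - 1L)
      } else {
        expect_null(seg)
      }
    }
  }
})

test_that("realign_exon handles exact, substituted and capped segments", {
  r <- realign_exon("ACGTAC", "TTACGTACTT")
  expect_equal(r$score, 1)
  expect_equal(r$map, 2:7)
  r2 <- realign_exon("ACGTAC", "TTACGAACTT")   # one substitution still maps
  expect_equal(r2$score, 1)
  expect_equal(r2$map, 2:7)
  expect_equal(r2$distance, 1L)
  expect_error(realign_exon("ACGT", random_dna(300), cap = 200L),
               "segment-too-long")
})

test_that("realign_exon agrees with the quadratic DP oracle on random edits", {
  set.seed(4)
  for (i in 1:200) {
    n <- sample(8:50, 1)
    exon <- random_dna(n)
    seg_len <- sample((n + 5):500, 1)
    seg <- random_dna(seg_len)
    # plant a mutated copy of the exon somewhere
    at <- sample(0:(seg_len - n), 1)
    copy <- strsplit(exon, "")[[1]]
    for (e in seq_len(sample(0:3, 1))) {
      op <- sample(c("sub", "del", "ins"), 1)
      pos <- sample(length(copy), 1)
      if (op == "sub") copy[pos] <- sample(c("A", "C", "G", "T"), 1)
      if (op == "del" && length(copy) > 4) copy <- copy[-pos]
      if (op == "ins") copy <- append(copy, sample(c("A", "C", "G", "T"), 1), pos)
    }
    seg <- paste0(substr(seg, 1, at), paste(copy, collapse = ""),
                  substr(seg, at + 1, seg_len))
    got <- realign_exon(exon, seg)
    want <- oracle_infix_align(exon, seg)
    expect_identical(got$distance, want$distance)
    expect_identical(got$start, want$start)
    expect_identical(got$map, want$map)
  }
})

test_that("score baseline reproduces textbook mean and sd", {
  fx <- three_exon_fixture()
  bl <- score_baseline(fx$aln, fx$exons, "t1")
  expect_equal(bl$mean, 1)
  expect_equal(bl$sd, 0)
  # random score sets against the closed form
  set.seed(5)
  for (i in 1:20) {
    s <- runif(sample(3:30, 1))
    bl2 <- structure(list(scores = s, mean = mean(s),
                          sd = sqrt(mean((s - mean(s))^2))),
                     class = "score_baseline")
    expect_equal(bl2$mean, sum(s) / length(s))
    expect_equal(bl2$sd^2 * length(s), sum((s - mean(s))^2))
  }
  expect_error(score_baseline(fx$aln, fx$exons[2, , drop = FALSE], "t1"),
               "baseline undefined")
})

test_that("acceptance filter is strict at mean - sd", {
  bl <- structure(list(mean = 0.8, sd = 0.1), class = "score_baseline")
  expect_true(accept_candidate(0.9, bl))
  expect_false(accept_candidate(0.7, bl))            # exactly mu - sigma
  expect_true(accept_candidate(0.7 + 1e-9, bl))
  set.seed(6)
  for (i in 1:50) {
    mu <- runif(1); sd <- runif(1, 0, 0.3); r <- runif(1)
    bl2 <- structure(list(mean = mu, sd = sd), class = "score_baseline")
    expect_identical(accept_candidate(r, bl2), r > mu - sd)
  }
})

test_that("merge adopts recovered positions without overwriting and is monotone", {
  fx <- three_exon_fixture()
  # pretend the middle exon realigned to 150..169
  cand <- data.frame(contig = "c1", start = 40L, end = 60L, target = "t1",
                     segment_contig = "k1", segment_start = 121L,
                     segment_end = 298L, score_rprime = 1, accepted = TRUE,
                     reason = "accepted", stringsAsFactors = FALSE)
  cand$map_we <- list(150:169)
  aln2 <- merge_alignment(fx$aln, cand)
  expect_equal(map_position(aln2, "c1", 40:59, "t1"), 150:169)
  expect_equal(exon_alignment_status(aln2, "c1", 40L, 60L, "t1"), "aligned")
  # untouched elsewhere
  expect_identical(map_position(aln2, "c1", 0:19, "t1"),
                   map_position(fx$aln, "c1", 0:19, "t1"))
  # empty candidate set is the identity
  aln3 <- merge_alignment(fx$aln, cand[cand$accepted == FALSE, ])
  expect_identical(aln3$maps, fx$aln$maps)
  # monotonicity: every previously mapped position is unchanged
  before <- fx$aln$maps$c1$t1$pos
  after <- aln2$maps$c1$t1$pos
  idx <- which(!is.na(before))
  expect_identical(after[idx], before[idx])
  expect_gte(sum(!is.na(after)), sum(!is.na(before)))
  # conflicting recovered positions keep the original
  cand2 <- cand
  cand2$start <- 0L; cand2$end <- 20L
  cand2$map_we <- list(rep(500L, 20L))
  expect_message(aln4 <- merge_alignment(fx$aln, cand2), "conflicted")
  expect_identical(map_position(aln4, "c1", 0:19, "t1"),
                   map_position(fx$aln, "c1", 0:19, "t1"))
})

test_that("completeness report counts aligned, missing and recovered pairs", {
  fx <- three_exon_fixture()
  rep0 <- completeness_report(fx$aln, fx$aln, fx$exons, "t1")
  expect_equal(rep0$s_a, 2L)
  expect_equal(rep0$s_m, 1L)
  expect_equal(rep0$s_r, 0L)
  expect_equal(rep0$s_a + rep0$s_m, nrow(fx$exons) * 1L)
  cand <- data.frame(contig = "c1", start = 40L, end = 60L, target = "t1",
                     segment_contig = "k1", segment_start = 121L,
                     segment_end = 298L, score_rprime = 1, accepted = TRUE,
                     reason = "accepted", stringsAsFactors = FALSE)
  cand$map_we <- list(150:169)
  rep1 <- completeness_report(fx$aln, merge_alignment(fx$aln, cand),
                              fx$exons, "t1")
  expect_equal(rep1$s_r, 1L)
})

test_that("realignment recovers withheld exons in the small world", {
  sw <- small_world()
  ex <- sw$world$truth$exon_universe
  wh <- sw$world$truth$withheld
  cands <- do.call(rbind, lapply(names(sw$targets), function(sp)
    realign_exons(sw$aln, ex, sp, sw$ref, sw$targets[[sp]])))
  # every candidate about a withheld pair; ground truth from the generator
  got <- paste(cands$contig, cands$start, cands$end, cands$target)
  want <- paste(wh$contig, wh$start, wh$end, wh$species)
  expect_true(all(got %in% want))
  aln2 <- merge_alignment(sw$aln, cands)
  acc <- cands[cands$accepted, ]
  st <- mapply(function(ctg, s, e, sp)
    exon_alignment_status(aln2, ctg, s, e, sp),
    acc$contig, acc$start, acc$end, acc$target)
  expect_true(all(st == "aligned"))
  # recovery monotonicity over every exon/species pair
  for (sp in names(sw$targets)) {
    w0 <- exon_alignment_status(sw$aln, ex$contig, ex$start, ex$end, sp)
    w1 <- exon_alignment_status(aln2, ex$contig, ex$start, ex$end, sp)
    expect_true(all(w1[w0 == "aligned"] == "aligned"))
  }
})
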