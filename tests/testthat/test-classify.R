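fake_vectors <- function(joint, m = 25L) {
  n <- length(joint)
  shifts <- setdiff(-30:31, 0:1)
  x <- matrix(0L, n, 1L + length(shifts),
              dimnames = list(NULL, c("joint", paste0("p_", shifts))))
  x[, "joint"] <- joint
  for (j in 2:ncol(x)) x[, j] <- pmin(m, pmax(0L, joint + sample(-2:2, n, TRUE)))
  x
}

test_that("predict is the logistic of the linear predictor", {
  m <- structure(list(coefficients = c(`(Intercept)` = 0, joint = 1),
                      kind = "dinuc", site_kind = "donor"),
                 class = "splice_classifier")
  x <- matrix(0, 1, 1, dimnames = list(NULL, "joint"))
  expect_equal(predict(m, x), 0.5)
  # all-zero vector -> logistic(alpha0)
  m$coefficients <- c(`(Intercept)` = -1.3, joint = 2)
  expect_equal(predict(m, x), plogis(-1.3))
  # random vectors against a hand-computed dot product
  set.seed(12)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    beta <- rnorm(k + 1)
    names(beta) <- c("(Intercept)", paste0("f", 1:k))
    mm <- structure(list(coefficients = beta), class = "splice_classifier")
    v <- matrix(rnorm(k), 1, k, dimnames = list(NULL, paste0("f", 1:k)))
    expect_equal(unname(predict(mm, v)),
                 unname(1 / (1 + exp(-(beta[1] + sum(beta[-1] * v))))),
                 tolerance = 1e-9)
  }
  expect_error(predict(m, matrix(0, 1, 1, dimnames = list(NULL, "other"))),
               "lacks columns")
})

test_that("training separates separable classes and is null on shuffled labels", {
  set.seed(13)
  pos <- fake_vectors(sample(23:25, 300, TRUE))
  neg <- fake_vectors(sample(0:8, 300, TRUE))
  m <- suppressWarnings(train_classifier(pos, neg, "full", "donor", seed = 1))
  expect_equal(m$eval$auroc, 1)
  md <- suppressWarnings(train_classifier(pos, neg, "dinuc", "donor", seed = 1))
  expect_equal(md$eval$auroc, 1)
  expect_length(md$coefficients, 2L)
  expect_length(m$coefficients, 62L)
  # shuffled labels: AUROC near 0.5
  all_ <- rbind(pos, neg)
  set.seed(14)
  idx <- sample(nrow(all_))
  m0 <- suppressWarnings(
    train_classifier(all_[idx[1:300], ], all_[idx[301:600], ], "dinuc",
                     "donor", seed = 2))
  expect_lt(abs(m0$eval$auroc - 0.5), 0.1)
})

test_that("held-out AUROC matches the trapezoid oracle on overlapping classes", {
  set.seed(15)
  pos <- fake_vectors(pmin(25L, pmax(0L, round(rnorm(400, 18, 4)))))
  neg <- fake_vectors(pmin(25L, pmax(0L, round(rnorm(400, 10, 4)))))
  m <- suppressWarnings(train_classifier(pos, neg, "dinuc", "donor", seed = 3))
  expect_equal(m$eval$auroc, oracle_auc(m$eval$scores, m$eval$labels),
               tolerance = 0.02)
})

test_that("labels follow the threshold with a well-inclusive boundary", {
  m <- structure(list(coefficients = c(`(Intercept)` = 0, joint = 1)),
                 class = "splice_classifier")
  x <- matrix(c(-3, 0, 3), 3, 1, dimnames = list(c("a", "b", "c"), "joint"))
  lab <- label_sites(m, x)
  expect_equal(lab$label, c("less", "well", "well"))  # p = 0.5 labelled well
  expect_equal(lab$key, c("a", "b", "c"))
})

test_that("well-supported transcripts require every site accepted", {
  introns <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t3"),
    donor_key = c("d1", "d2", "d3", "d4"),
    acceptor_key = c("a1", "a2", "a3", "a4"), stringsAsFactors = FALSE)
  labels <- data.frame(key = c("d2", "a2", "d3", "a3", "d4", "a4"),
                       probability = c(.9, .9, .9, .2, .9, .9),
                       label = c("well", "well", "well", "less", "well", "well"))
  out <- well_supported_transcripts(introns, labels, mane_keys = c("d1", "a1"))
  expect_setequal(out$transcripts, c("t1", "t3"))       # t2 has a less acceptor
  expect_equal(out$counts$n_transcripts[out$counts$n_introns == 2], 1L)
  expect_error(well_supported_transcripts(introns, labels[-1, ],
                                          mane_keys = c("a1")),
               "unlabelled")
  # antitone in the less set: flipping any site well -> less never adds
  for (k in labels$key[labels$label == "well"]) {
    lab2 <- labels
    lab2$label[lab2$key == k] <- "less"
    out2 <- well_supported_transcripts(introns, lab2, mane_keys = c("d1", "a1"))
    expect_true(all(out2$transcripts %in% out$transcripts))
  }
})

test_that("aggregation operations match brute-force oracles on random catalogs", {
  set.seed(16)
  for (rep_i in 1:10) {
    n_tx <- sample(20:60, 1)
    introns <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
      k <- sample(1:4, 1)
      data.frame(transcript_id = sprintf("t%03d", t),
                 donor_key = sprintf("d%04d", sample(1:80, k)),
                 acceptor_key = sprintf("a%04d", sample(1:80, k)))
    }))
    keys <- unique(c(introns$donor_key, introns$acceptor_key))
    mane_keys <- sample(keys, round(0.2 * length(keys)))
    rest <- setdiff(keys, mane_keys)
    labels <- data.frame(key = rest, probability = runif(length(rest)))
    labels$label <- ifelse(labels$probability >= 0.5, "well", "less")
    out <- well_supported_transcripts(introns, labels, mane_keys)
    ok_keys <- c(mane_keys, labels$key[labels$label == "well"])
    for (t in unique(introns$transcript_id)) {
      it <- introns[introns$transcript_id == t, ]
      want <- all(c(it$donor_key, it$acceptor_key) %in% ok_keys)
      expect_identical(t %in% out$transcripts, want)
    }
    ic <- intron_categories(introns, labels, mane_keys)
    for (i in seq_len(nrow(ic))) {
      d <- ic$donor_key[i] %in% ok_keys
      a <- ic$acceptor_key[i] %in% ok_keys
      want <- if (!d && !a) 1L else if (d && !a) 2L else if (!d && a) 3L else 4L
      expect_identical(ic$category[i], want)
    }
  }
})

test_that("intron categories follow the four-way enumeration", {
  introns <- data.frame(transcript_id = "t", donor_key = c("d", "d2"),
                        acceptor_key = c("a", "a2"))
  labels <- data.frame(key = c("d", "a", "d2", "a2"),
                       probability = c(.9, .1, .9, .9),
                       label = c("well", "less", "well", "well"))
  ic <- intron_categories(introns, labels)
  expect_equal(ic$category, c(2L, 4L))   # donor-only -> 2, both -> 4
})

test_that("MANE-exon stratification equals an interval-overlap oracle", {
  set.seed(17)
  mane_exons <- data.frame(contig = "c1",
                           start = c(100L, 300L, 600L),
                           end = c(200L, 400L, 650L))
  sites <- data.frame(contig = "c1", origin = sample(0:700, 200, TRUE))
  sites$key <- sprintf("s%03d", seq_len(nrow(sites)))
  labels <- data.frame(key = sites$key,
                       probability = runif(nrow(sites)))
  labels$label <- ifelse(labels$probability >= 0.5, "well", "less")
  out <- stratify_by_mane_exon(sites, mane_exons, labels)
  for (i in seq_len(nrow(sites))) {
    o <- sites$origin[i]
    want <- any(o >= mane_exons$start & o < mane_exons$end)
    expect_identical(out$sites$inside_mane_exon[i], want)
  }
  expect_equal(sum(out$table), nrow(sites))
})

test_that("isoform sharing counts transcript membership per site", {
  sites <- data.frame(key = c("s1", "s2", "s3"), n_transcripts = c(3L, 1L, 2L))
  labels <- data.frame(key = c("s1", "s2"), probability = c(.9, .1),
                       label = c("well", "less"))
  out <- isoform_sharing(sites, labels)
  expect_equal(out$per_site$n_isoforms, c(3L, 1L, 2L))
  expect_equal(out$summary$median[out$summary$label == "well"], 3)
  expect_true(is.na(out$per_site$label[3]))
})

test_that("probability/score correlation matches the closed-form Pearson", {
  p <- c(0.1, 0.5, 0.9)
  expect_equal(score_probability_correlation(p, p, p + 1), 1)
  expect_equal(score_probability_correlation(p, rev(p), rev(p)), -1)
  set.seed(18)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    prob <- runif(n); s0 <- runif(n); s1 <- runif(n)
    mn <- pmin(s0, s1)
    want <- sum((mn - mean(mn)) * (prob - mean(prob))) /
      sqrt(sum((mn - mean(mn))^2) * sum((prob - mean(prob))^2))
    expect_equal(score_probability_correlation(prob, s0, s1), want,
                 tolerance = 1e-9)
  }
  expect_warning(r <- score_probability_correlation(0.5, 0.1, 0.2), "fewer")
  expect_true(is.na(r))
})

test_that("fitted models are monotone in the joint count when its weight is positive", {
  set.seed(19)
  pos <- fake_vectors(sample(20:25, 200, TRUE))
  neg <- fake_vectors(sample(0:10, 200, TRUE))
  m <- suppressWarnings(train_classifier(pos, neg, "dinuc", "donor", seed = 4))
  expect_gt(coef(m)["joint"], 0)
  x <- matrix(0:25, 26, 1, dimnames = list(NULL, "joint"))
  p <- predict(m, x)
  expect_true(all(diff(p) >= 0))          # probabilities may saturate at 1
  expect_gt(p[26], p[1])
})
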