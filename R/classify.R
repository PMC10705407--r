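#' Train a splice-site conservation classifier
#'
#' Fits, by maximum likelihood, the logistic model for the log-odds of a site
#' having MANE-like ("well-supported") rather than neutral-like
#' ("less-supported") conservation. The `"full"` model uses the joint
#' canonical-dinucleotide species count plus one coefficient per positional
#' shift; the `"dinuc"` model uses the joint count only. A seeded stratified
#' split holds out `test_fraction` of each class; held-out ROC points, AUROC
#' and the F-score at the 0.5 threshold are stored with the model. Donor and
#' acceptor models are trained separately by passing the corresponding
#' feature matrices.
#'
#' @param pos_vectors,neg_vectors Feature matrices from [feature_vectors()]
#'   for the positive (MANE) and negative (Random) classes.
#' @param kind `"full"` or `"dinuc"`.
#' @param site_kind Label stored with the model (`"donor"`/`"acceptor"`).
#' @param seed RNG seed for the train/test split.
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @param threshold Probability threshold used for the stored F-score.
#' @return An object of class `splice_classifier` with `coefficients`
#'   (intercept first), `kind`, `site_kind`, `meta` (seed, split sizes,
#'   ridge = 0 recorded for transparency) and `eval` (`roc` data frame,
#'   `auroc`, `f_score`, held-out scores).
#' @seealso [predict.splice_classifier()], [label_sites()]
#' @export
train_classifier <- function(pos_vectors, neg_vectors, kind = c("full", "dinuc"),
                             site_kind = "donor", seed = 1L,
                             test_fraction = 0.2, threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(nrow(pos_vectors) > 0L, nrow(neg_vectors) > 0L,
            ncol(pos_vectors) == ncol(neg_vectors))
  cols <- if (kind == "dinuc") "joint" else colnames(pos_vectors)
  x <- rbind(pos_vectors[, cols, drop = FALSE], neg_vectors[, cols, drop = FALSE])
  y <- rep(c(1L, 0L), c(nrow(pos_vectors), nrow(neg_vectors)))
  set.seed(seed)
  test <- logical(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    test[sample(idx, max(1L, floor(test_fraction * length(idx))))] <- TRUE
  }
  xtrain <- cbind(`(Intercept)` = 1, x[!test, , drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(xtrain, y[!test], family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0            # rank-deficient columns contribute nothing
  names(beta) <- c("(Intercept)", cols)
  degenerate <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  if (degenerate)
    warning("near-separated or degenerate training data; coefficients may be large")

  model <- structure(
    list(coefficients = beta, kind = kind, site_kind = site_kind,
         meta = list(seed = seed, test_fraction = test_fraction,
                     n_pos = nrow(pos_vectors), n_neg = nrow(neg_vectors),
                     ridge = 0, converged = fit$converged),
         eval = NULL),
    class = "splice_classifier")
  scores <- predict(model, x[test, , drop = FALSE])
  ytest <- y[test]
  roc <- pROC::roc(response = ytest, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  roc_df <- data.frame(threshold = rev(roc$thresholds),
                       tpr = rev(roc$sensitivities),
                       fpr = rev(1 - roc$specificities))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & ytest == 1L)
  fp <- sum(pred == 1L & ytest == 0L)
  fn <- sum(pred == 0L & ytest == 1L)
  f <- if (2 * tp + fp + fn == 0L) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  model$eval <- list(auroc = as.numeric(pROC::auc(roc)), f_score = f,
                     roc = roc_df, threshold = threshold,
                     scores = scores, labels = ytest)
  model
}

#' @export
print.splice_classifier <- function(x, ...) {
  cat("<splice_classifier> ", x$kind, " model for ", x$site_kind, " sites: ",
      length(x$coefficients) - 1L, " feature(s) + intercept\n",
      "  trained on ", x$meta$n_pos, " positive / ", x$meta$n_neg,
      " negative sites (", 100 * x$meta$test_fraction, "% held out, seed ",
      x$meta$seed, ")\n", sep = "")
  if (!is.null(x$eval))
    cat("  held-out AUROC ", round(x$eval$auroc, 4), ", F-score ",
        round(x$eval$f_score, 4), " at threshold ", x$eval$threshold, "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.splice_classifier <- function(object, ...) {
  print(object)
  cat("  intercept ", signif(object$coefficients[1L], 4),
      "; joint coefficient ", signif(object$coefficients["joint"], 4), "\n",
      sep = "")
  invisible(object)
}

#' @export
coef.splice_classifier <- function(object, ...) object$coefficients

#' Predict well-supported probabilities
#'
#' The logistic of the fitted linear predictor for each site's feature
#' vector.
#'
#' @param object A `splice_classifier`.
#' @param newdata Feature matrix with the columns the model was trained on
#'   (a `"dinuc"` model only needs `joint`).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.splice_classifier <- function(object, newdata, ...) {
  cols <- names(object$coefficients)[-1L]
  if (!all(cols %in% colnames(newdata)))
    stop("feature matrix lacks columns: ",
         paste(setdiff(cols, colnames(newdata)), collapse = ", "))
  eta <- drop(cbind(1, newdata[, cols, drop = FALSE]) %*% object$coefficients)
  stats::plogis(eta)
}

#' Label sites as well- or less-supported
#'
#' Sites with predicted probability >= `threshold` (boundary inclusive) are
#' labelled `"well"`, the rest `"less"`.
#'
#' @param model A `splice_classifier`.
#' @param vectors Feature matrix (rownames = site keys).
#' @param threshold Probability threshold, default 0.5.
#' @return Data frame `key`, `probability`, `label`, `threshold`.
#' @export
label_sites <- function(model, vectors, threshold = 0.5) {
  p <- predict(model, vectors)
  data.frame(key = rownames(vectors) %||% as.character(seq_along(p)),
             probability = p,
             label = ifelse(p >= threshold, "well", "less"),
             threshold = threshold,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

well_keys <- function(labels) labels$key[labels$label == "well"]

#' Well-supported transcripts
#'
#' Transcripts (with at least one intron) whose every donor and acceptor site
#' is either shared with MANE or labelled well-supported. MANE-shared sites
#' are accepted by membership and are not required to carry a label.
#'
#' @param introns Intron data frame from [extract_sites()] (one row per
#'   transcript/intron with `donor_key`/`acceptor_key`).
#' @param labels Site labels from [label_sites()] (possibly spanning both
#'   kinds).
#' @param mane_keys Character vector of MANE site keys.
#' @return `list(transcripts, counts)`: the qualifying transcript ids, and a
#'   data frame of all/well-supported transcript counts stratified by intron
#'   count.
#' @export
well_supported_transcripts <- function(introns, labels, mane_keys = character(0)) {
  keys <- unique(c(introns$donor_key, introns$acceptor_key))
  known <- keys %in% mane_keys | keys %in% labels$key
  if (any(!known))
    stop("unlabelled non-MANE site(s): ",
         paste(utils::head(keys[!known], 3L), collapse = ", "),
         if (sum(!known) > 3L) " ..." else "")
  ok_keys <- unique(c(mane_keys, well_keys(labels)))
  site_ok <- function(k) k %in% ok_keys
  tx_ok <- tapply(site_ok(introns$donor_key) & site_ok(introns$acceptor_key),
                  introns$transcript_id, all)
  n_introns <- tapply(introns$transcript_id, introns$transcript_id, length)
  ids <- names(tx_ok)[tx_ok]
  counts <- data.frame(n_introns = as.integer(names(table(n_introns))))
  counts$n_transcripts <- as.integer(table(n_introns))
  counts$n_well_supported <- vapply(counts$n_introns, function(k)
    sum(tx_ok[n_introns == k]), integer(1))
  list(transcripts = ids, counts = counts)
}

#' Intron conservation categories
#'
#' Category 1: neither site well-supported; 2: only the donor; 3: only the
#' acceptor; 4: both. MANE-shared sites count as well-supported.
#'
#' @inheritParams well_supported_transcripts
#' @return The intron data frame with `donor_ok`, `acceptor_ok` and
#'   `category` columns appended.
#' @export
intron_categories <- function(introns, labels, mane_keys = character(0)) {
  ok_keys <- unique(c(mane_keys, well_keys(labels)))
  introns$donor_ok <- introns$donor_key %in% ok_keys
  introns$acceptor_ok <- introns$acceptor_key %in% ok_keys
  introns$category <- 1L + introns$donor_ok + 2L * introns$acceptor_ok
  introns
}

#' Stratify sites by MANE-exon overlap
#'
#' A site is "inside" iff its origin lies within any MANE exon interval.
#'
#' @param sites Site data frame (`contig`, `origin`, `key`).
#' @param mane_exons Data frame of MANE exon intervals (`contig`, `start`,
#'   `end`; 0-based half-open).
#' @param labels Site labels from [label_sites()].
#' @return `list(sites, table)`: the sites annotated with `inside_mane_exon`
#'   and `label`, and the 2x2 count table (inside/outside x well/less).
#' @export
stratify_by_mane_exon <- function(sites, mane_exons, labels) {
  inside <- logical(nrow(sites))
  for (ctg in unique(sites$contig)) {
    sel <- sites$contig == ctg
    me <- mane_exons[mane_exons$contig == ctg, , drop = FALSE]
    if (nrow(me) == 0L) next
    q <- IRanges::IRanges(sites$origin[sel] + 1L, sites$origin[sel] + 1L)
    s <- IRanges::IRanges(me$start + 1L, me$end)
    inside[sel] <- IRanges::overlapsAny(q, s)
  }
  lab <- labels$label[match(sites$key, labels$key)]
  sites$inside_mane_exon <- inside
  sites$label <- lab
  tab <- table(location = ifelse(inside, "inside", "outside"),
               label = factor(lab, levels = c("well", "less")))
  list(sites = sites, table = tab)
}

#' Isoform sharing of splice sites
#'
#' Number of isoforms using each site, summarised by label class.
#'
#' @param sites Site data frame with `key` and `n_transcripts` (from
#'   [extract_sites()]).
#' @param labels Site labels from [label_sites()].
#' @return `list(per_site, summary)`: per-site usage with label, and per-label
#'   median/mean usage.
#' @export
isoform_sharing <- function(sites, labels) {
  lab <- labels$label[match(sites$key, labels$key)]
  per_site <- data.frame(key = sites$key, n_isoforms = sites$n_transcripts,
                         label = lab, stringsAsFactors = FALSE)
  keep <- !is.na(per_site$label)
  s <- per_site[keep, , drop = FALSE]
  summary <- do.call(rbind, lapply(split(s$n_isoforms, s$label), function(v)
    data.frame(n_sites = length(v), median = stats::median(v), mean = mean(v))))
  summary$label <- rownames(summary)
  rownames(summary) <- NULL
  list(per_site = per_site, summary = summary[, c("label", "n_sites", "median", "mean")])
}

#' Correlation between classifier probability and per-position scores
#'
#' For each site, the minimum of the two per-position conservation scores at
#' its canonical dinucleotide positions is correlated (Pearson) with the
#' model probability. Sites lacking scores are excluded.
#'
#' @param probabilities Numeric vector of model probabilities.
#' @param score0,score1 Per-site scores at shifts 0 and 1 (`NA` = missing).
#' @return Pearson r, or `NA` with a warning when fewer than 2 complete pairs
#'   remain.
#' @export
score_probability_correlation <- function(probabilities, score0, score1) {
  m <- pmin(score0, score1)
  ok <- !is.na(m) & !is.na(probabilities)
  if (sum(ok) < 2L) {
    warning("fewer than 2 sites with scores; correlation undefined")
    return(NA_real_)
  }
  stats::cor(m[ok], probabilities[ok])
}

#' False-positive rate at a matched true-positive rate
#'
#' The smallest held-out FPR among ROC points achieving TPR >= `tpr`; used to
#' compare the full and dinucleotide-only models at equal sensitivity.
#'
#' @param model A trained `splice_classifier`.
#' @param tpr Target true-positive rate.
#' @return FPR in [0, 1].
#' @export
fpr_at_tpr <- function(model, tpr = 0.95) {
  roc <- model$eval$roc
  ok <- roc$tpr >= tpr
  if (!any(ok)) return(1)
  min(roc$fpr[ok])
}
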