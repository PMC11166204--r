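#' Apply the high-confidence filter stack
#'
#' A record survives iff `avg_p >= avgPMin`, `avg_spec >=
#' avgSpecMin[cell_line]`, `caax_ratio >= caaxRatioMin` and its prey is not
#' on the blocklist (all comparisons inclusive). The surviving set is
#' order-free (a conjunction); the attrition report attributes each dropped
#' record to the first failing filter in the order AvgP, AvgSpec, CAAX
#' ratio, blocklist.
#'
#' @param scored scored table from [scoreInteractions()] (needs `prey`,
#'   `cell_line`, `avg_p`, `avg_spec`, `caax_ratio`).
#' @param config a [FilterConfig-class].
#' @return list with `records` (surviving rows), `attrition`
#'   (data.frame(filter, removed)) and `n_in`/`n_out`.
#' @export
applyFilters <- function(scored, config = FilterConfig()) {
  scored <- as.data.frame(scored)
  need <- c("prey", "cell_line", "avg_p", "avg_spec", "caax_ratio")
  miss <- setdiff(need, names(scored))
  if (length(miss))
    stop("scored table is missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(scored$cell_line), names(config@avgSpecMin))
  if (length(unknown))
    stop("no AvgSpec threshold configured for cell line(s): ",
         paste(unknown, collapse = ", "))

  pass_p <- scored$avg_p >= config@avgPMin
  pass_s <- scored$avg_spec >= config@avgSpecMin[scored$cell_line]
  pass_r <- scored$caax_ratio >= config@caaxRatioMin
  pass_b <- !scored$prey %in% config@blocklist

  fail_first <- rep(NA_character_, nrow(scored))
  fail_first[!pass_b] <- "blocklist"
  fail_first[!pass_r] <- "caax_ratio"
  fail_first[!pass_s] <- "avg_spec"
  fail_first[!pass_p] <- "avg_p"

  keep <- pass_p & pass_s & pass_r & pass_b
  attrition <- data.frame(
    filter = c("avg_p", "avg_spec", "caax_ratio", "blocklist"),
    removed = c(sum(fail_first == "avg_p", na.rm = TRUE),
                sum(fail_first == "avg_spec", na.rm = TRUE),
                sum(fail_first == "caax_ratio", na.rm = TRUE),
                sum(fail_first == "blocklist", na.rm = TRUE)))
  out <- scored[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, attrition = attrition,
       n_in = nrow(scored), n_out = nrow(out))
}

#' Label records against a gold standard for recall calibration
#'
#' Restricts the table to the calibration baits and labels each record 1 iff
#' its (bait, prey) pair is a gold-standard edge.
#'
#' @param scored table with `bait` and `prey` columns.
#' @param gold a [GoldStandard-class]; its `baitSubset` (when nonempty)
#'   defines the calibration baits.
#' @return `scored` restricted to calibration baits, with an integer
#'   `label` column.
#' @export
labelRecall <- function(scored, gold) {
  scored <- as.data.frame(scored)
  subset <- if (length(gold@baitSubset)) gold@baitSubset
            else unique(gold@edges$bait)
  out <- scored[scored$bait %in% subset, , drop = FALSE]
  out$label <- as.integer(pairKey(out$bait, out$prey) %in%
                          pairKey(gold@edges$bait, gold@edges$prey))
  if (!nrow(out) || !any(out$label == 1))
    stop("no positive labels: the gold standard does not intersect the ",
         "calibration baits' records")
  rownames(out) <- NULL
  out
}

#' ROC cutpoint by the Youden index
#'
#' Builds the ROC over all distinct observed thresholds (keep iff
#' `score >= t`): sensitivity is the fraction of positives at or above `t`,
#' specificity the fraction of negatives below `t`. The cutpoint maximizes
#' Youden's J = sensitivity + specificity - 1 (ties resolved to the
#' smallest threshold); the AUC is the trapezoidal area under the
#' (FPR, TPR) curve.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @param scoreName label stored in the report.
#' @return A [CutpointReport-class] with the ROC slots filled.
#' @export
rocCutpoint <- function(scores, labels, scoreName = "score") {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    stop("both classes must be present to build a ROC curve")
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  cut <- thr[min(best)]
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("CutpointReport", scoreName = scoreName,
      rocPoints = data.frame(threshold = thr, sensitivity = sens,
                             specificity = spec, j = j),
      auc = auc, rocCutpoint = cut,
      cdaCurve = data.frame(), cdaCutpoint = NA_real_)
}

#' Cumulative-distribution (CDA) cutpoint
#'
#' Compares the empirical CDFs of positive and negative scores and places
#' the cutpoint at the observed score maximizing the gap
#' \eqn{F^-(s) - F^+(s)} (the Kolmogorov-Smirnov location); ties resolve to
#' the smallest score. Identical distributions trigger a warning.
#'
#' @inheritParams rocCutpoint
#' @return A [CutpointReport-class] with the CDA slots filled.
#' @export
cdaCutpoint <- function(scores, labels, scoreName = "score") {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    stop("both classes must be present for a CDA comparison")
  s <- sort(unique(scores))
  Fp <- stats::ecdf(pos)
  Fn <- stats::ecdf(neg)
  gap <- Fn(s) - Fp(s)
  best <- which(gap >= max(gap) - 1e-12)
  cut <- s[min(best)]
  if (max(gap) <= 1e-12)
    warning("positive and negative score distributions are ",
            "indistinguishable; CDA cutpoint is arbitrary")
  new("CutpointReport", scoreName = scoreName,
      rocPoints = data.frame(), auc = NA_real_, rocCutpoint = NA_real_,
      cdaCurve = data.frame(score = s, cdf_pos = Fp(s), cdf_neg = Fn(s),
                            gap = gap),
      cdaCutpoint = cut)
}

mergeCutpointReports <- function(roc, cda) {
  new("CutpointReport", scoreName = roc@scoreName,
      rocPoints = roc@rocPoints, auc = roc@auc,
      rocCutpoint = roc@rocCutpoint,
      cdaCurve = cda@cdaCurve, cdaCutpoint = cda@cdaCutpoint)
}

#' Calibrate AvgSpec / CAAX-ratio cutpoints against a gold standard
#'
#' Labels the calibration baits' records by gold-standard recall, derives
#' ROC and CDA cutpoint reports for the average spectral count and the CAAX
#' ratio, and ranks a grid of candidate threshold pairs by recall at a fixed
#' precision floor (pairs missing the floor rank below all pairs meeting
#' it, ordered by precision). The final choice of thresholds remains the
#' analyst's decision.
#'
#' @param scored scored table (with `bait`, `prey`, `avg_spec`,
#'   `caax_ratio`); apply any AvgP prefilter beforehand if desired.
#' @param gold a [GoldStandard-class].
#' @param avgSpecGrid candidate AvgSpec thresholds.
#' @param caaxGrid candidate CAAX-ratio thresholds.
#' @param precisionTarget precision floor for the ranking (default 0.9).
#' @return list with `reports` (named [CutpointReport-class]s for
#'   `avg_spec` and `caax_ratio`) and `grid` (ranked data.frame with
#'   precision/recall/F1 per threshold pair).
#' @export
calibrate <- function(scored, gold,
                      avgSpecGrid = seq(1, 15, by = 0.5),
                      caaxGrid = c(1, 1.5, 1.7, 2, 3),
                      precisionTarget = 0.9) {
  if (!length(avgSpecGrid) || !length(caaxGrid))
    stop("empty calibration grid")
  lab <- labelRecall(scored, gold)
  if (all(lab$label == 1))
    stop("all records are labeled positive; calibration is degenerate")
  reports <- list(
    avg_spec = mergeCutpointReports(
      rocCutpoint(lab$avg_spec, lab$label, "avg_spec"),
      cdaCutpoint(lab$avg_spec, lab$label, "avg_spec")),
    caax_ratio = mergeCutpointReports(
      rocCutpoint(lab$caax_ratio, lab$label, "caax_ratio"),
      cdaCutpoint(lab$caax_ratio, lab$label, "caax_ratio")))

  grid <- expand.grid(avg_spec_min = avgSpecGrid, caax_ratio_min = caaxGrid)
  P <- sum(lab$label == 1)
  stats_ <- t(apply(grid, 1, function(g) {
    keep <- lab$avg_spec >= g[1] & lab$caax_ratio >= g[2]
    tp <- sum(lab$label[keep] == 1)
    prec <- if (any(keep)) tp / sum(keep) else 0
    rec <- tp / P
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }))
  grid <- cbind(grid, as.data.frame(stats_))
  meets <- grid$precision >= precisionTarget
  o <- order(!meets,
             ifelse(meets, -grid$recall, -grid$precision),
             grid$avg_spec_min, grid$caax_ratio_min)
  grid <- grid[o, , drop = FALSE]
  grid$rank <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  list(reports = reports, grid = grid)
}
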