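#' CompPASS-style WD specificity score for one cell line
#'
#' For each bait-prey record of the given cell line the WD score is
#' \deqn{WD(b,p) = \sqrt{\bar{X}(b,p) \left(\frac{K}{f(p)}\,\omega(p)\right)^{n(b,p)}}}
#' where \eqn{\bar{X}} is the average spectral count, \eqn{K} the number of
#' non-control baits in the cell line, \eqn{f(p)} the number of non-control
#' baits detecting prey \eqn{p} (\eqn{\bar{X} > 0}), \eqn{n(b,p)} the number
#' of replicates of \eqn{b} detecting \eqn{p} (1 when replicate-level data
#' are absent), and \eqn{\omega(p) = \max(1, \mathrm{sd}/\mathrm{mean})} of
#' \eqn{\bar{X}(\cdot,p)} over the \eqn{f(p)} detecting baits
#' (\eqn{\omega = 1} when \eqn{f(p) = 1}). Control purifications never enter
#' \eqn{K}, \eqn{f} or \eqn{\omega}; records with \eqn{\bar{X} = 0} score 0.
#'
#' @param screen a [BioidScreen-class].
#' @param cellLine the cell line to score.
#' @return data.frame(bait, prey, wd) with attribute `cell_line`.
#' @export
computeWD <- function(screen, cellLine) {
  rec <- interactions(screen)
  rec <- rec[rec$cell_line == cellLine & !rec$is_control, ]
  K <- length(unique(rec$bait))
  if (K == 0) stop("no non-control baits in cell line ", cellLine)

  det <- rec$avg_spec > 0
  f <- tapply(det, rec$prey, sum)
  omega <- vapply(split(rec$avg_spec[det], rec$prey[det]), function(v) {
    if (length(v) < 2) 1 else max(1, stats::sd(v) / mean(v))
  }, numeric(1))

  n_det <- mapply(function(specs, xbar) {
    if (is.null(specs)) 1L else sum(specs > 0)
  }, rec$replicate_specs, rec$avg_spec)

  fp <- as.numeric(f[rec$prey])
  om <- rep(1, nrow(rec))
  om[rec$prey %in% names(omega)] <-
    omega[rec$prey[rec$prey %in% names(omega)]]
  wd <- ifelse(rec$avg_spec > 0,
               sqrt(rec$avg_spec * ((K / fp) * om)^n_det),
               0)
  out <- data.frame(bait = rec$bait, prey = rec$prey, wd = wd)
  rownames(out) <- NULL
  attr(out, "cell_line") <- cellLine
  out
}

#' Sum WD scores across two cell lines (WDS score)
#'
#' Pools the interaction specificities of the two cell lines by summing the
#' WD scores per bait-prey pair; a pair missing from one cell line
#' contributes 0 there, and pairs absent from both are not emitted.
#'
#' @param wd1,wd2 outputs of [computeWD()] for two distinct cell lines;
#'   `wd2` may be `NULL` for single-cell-line screens, in which case
#'   WDS = WD.
#' @return data.frame(bait, prey, wds).
#' @export
sumWDS <- function(wd1, wd2 = NULL) {
  if (is.null(wd2)) {
    out <- data.frame(bait = wd1$bait, prey = wd1$prey, wds = wd1$wd)
    return(out[order(out$bait, out$prey), , drop = FALSE])
  }
  cl1 <- attr(wd1, "cell_line")
  cl2 <- attr(wd2, "cell_line")
  if (!is.null(cl1) && !is.null(cl2) && identical(cl1, cl2))
    stop("both WD tables come from the same cell line: ", cl1)
  m <- merge(wd1[, c("bait", "prey", "wd")], wd2[, c("bait", "prey", "wd")],
             by = c("bait", "prey"), all = TRUE, suffixes = c("_1", "_2"))
  m$wd_1[is.na(m$wd_1)] <- 0
  m$wd_2[is.na(m$wd_2)] <- 0
  out <- data.frame(bait = m$bait, prey = m$prey, wds = m$wd_1 + m$wd_2)
  out <- out[order(out$bait, out$prey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Membrane-control (CAAX) enrichment ratio
#'
#' Ratio of a bait's average spectral count to that of the membrane-targeted
#' CAAX control for the same prey and cell line. A prey undetected in the
#' CAAX control yields `Inf` (maximal enrichment, passes any finite cutoff).
#'
#' @param screen a [BioidScreen-class] whose `controlBaits` include `caax`.
#' @param cellLine cell line to compute ratios for (default: all present).
#' @return data.frame(bait, prey, cell_line, caax_ratio) for non-control
#'   records.
#' @export
caaxRatio <- function(screen, cellLine = cellLines(screen)) {
  cb <- controlBaits(screen)
  if (!"caax" %in% names(cb))
    stop("no CAAX control configured for this screen")
  rec <- interactions(screen)
  out <- list()
  for (cl in cellLine) {
    sub <- rec[rec$cell_line == cl, ]
    caax <- sub[sub$bait == cb[["caax"]], ]
    if (!nrow(caax))
      stop("CAAX control has no records in cell line ", cl)
    caax_spec <- stats::setNames(caax$avg_spec, caax$prey)
    tgt <- sub[!sub$is_control, ]
    denom <- caax_spec[tgt$prey]
    denom[is.na(denom)] <- 0
    out[[cl]] <- data.frame(bait = tgt$bait, prey = tgt$prey,
                            cell_line = cl,
                            caax_ratio = ifelse(denom > 0,
                                                tgt$avg_spec / denom, Inf))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log2 fold change against the mean of the negative controls
#'
#' \eqn{\log_2((\bar{X}(b,p) + c)/(\overline{\bar{X}_{ctrl}}(p) + c))} with
#' pseudocount \eqn{c} (default 1), where the denominator averages the
#' non-CAAX negative-control purifications (empty-vector BirA* and
#' BirA*-eGFP), treating a prey absent from a control as 0.
#'
#' @param screen a [BioidScreen-class] with at least one non-CAAX negative
#'   control configured.
#' @param pseudocount added to numerator and denominator (default 1).
#' @return data.frame(bait, prey, cell_line, log2fc) for non-control records.
#' @export
log2fcControls <- function(screen, pseudocount = 1) {
  cb <- controlBaits(screen)
  neg <- cb[names(cb) %in% c("empty_vector", "gfp")]
  if (!length(neg))
    stop("no non-CAAX negative control configured")
  rec <- interactions(screen)
  out <- list()
  for (cl in cellLines(screen)) {
    sub <- rec[rec$cell_line == cl, ]
    ctrl <- sub[sub$bait %in% neg, ]
    preys <- unique(sub$prey)
    ctrl_mean <- vapply(preys, function(p) {
      v <- ctrl$avg_spec[ctrl$prey == p]
      sum(v) / length(neg)   # absent control rows count as 0
    }, numeric(1))
    tgt <- sub[!sub$is_control, ]
    out[[cl]] <- data.frame(
      bait = tgt$bait, prey = tgt$prey, cell_line = cl,
      log2fc = log2((tgt$avg_spec + pseudocount) /
                    (ctrl_mean[tgt$prey] + pseudocount)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Complexity-based normalized spectral counts (CBNP)
#'
#' Rescales each bait's average spectral counts by the ratio of the median
#' per-bait prey inventory to that bait's own inventory:
#' \eqn{CBNP(b,p) = \bar{X}(b,p)\, \mathrm{median}_b N(b') / N(b)} where
#' \eqn{N(b)} is the number of distinct preys identified with bait \eqn{b}
#' in the cell line. Baits identifying no preys are skipped with a warning.
#'
#' @param screen a [BioidScreen-class].
#' @return data.frame(bait, prey, cell_line, cbnp) for non-control records.
#' @export
cbnp <- function(screen) {
  rec <- interactions(screen)
  out <- list()
  for (cl in cellLines(screen)) {
    sub <- rec[rec$cell_line == cl & !rec$is_control, ]
    N <- tapply(sub$avg_spec > 0, sub$bait, sum)
    empty <- names(N)[N == 0]
    if (length(empty)) {
      warning("bait(s) with no identified preys skipped in ", cl, ": ",
              paste(empty, collapse = ", "))
      sub <- sub[!sub$bait %in% empty, ]
      N <- N[N > 0]
    }
    medN <- stats::median(as.numeric(N))
    out[[cl]] <- data.frame(bait = sub$bait, prey = sub$prey, cell_line = cl,
                            cbnp = sub$avg_spec * medN / as.numeric(N[sub$bait]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compute all per-interaction derived scores
#'
#' Convenience wrapper producing the long-format scored table: WD per cell
#' line, WDS summed over cell lines (WDS = WD in single-cell-line screens),
#' CAAX ratio, log2 fold change against the negative controls and CBNP.
#'
#' @param screen a [BioidScreen-class] with controls configured.
#' @param pseudocount pseudocount for the log2 fold change.
#' @return data.frame(bait, prey, cell_line, avg_spec, avg_p, wd, wds,
#'   caax_ratio, log2fc, cbnp), one row per non-control record.
#' @export
scoreInteractions <- function(screen, pseudocount = 1) {
  lines <- cellLines(screen)
  if (length(lines) > 2)
    stop("at most two cell lines are supported")
  wd_list <- lapply(lines, function(cl) computeWD(screen, cl))
  names(wd_list) <- lines
  wds <- if (length(lines) == 2) sumWDS(wd_list[[1]], wd_list[[2]])
         else sumWDS(wd_list[[1]])

  rec <- interactions(screen)
  tgt <- rec[!rec$is_control,
             c("bait", "prey", "cell_line", "avg_spec", "avg_p")]
  for (cl in lines) {
    w <- wd_list[[cl]]
    idx <- tgt$cell_line == cl
    tgt$wd[idx] <- w$wd[match(pairKey(tgt$bait[idx], tgt$prey[idx]),
                              pairKey(w$bait, w$prey))]
  }
  tgt$wds <- wds$wds[match(pairKey(tgt$bait, tgt$prey),
                           pairKey(wds$bait, wds$prey))]
  cr <- caaxRatio(screen)
  tgt$caax_ratio <- cr$caax_ratio[match(
    pairKey(tgt$bait, tgt$prey, tgt$cell_line),
    pairKey(cr$bait, cr$prey, cr$cell_line))]
  fc <- log2fcControls(screen, pseudocount)
  tgt$log2fc <- fc$log2fc[match(
    pairKey(tgt$bait, tgt$prey, tgt$cell_line),
    pairKey(fc$bait, fc$prey, fc$cell_line))]
  cb <- cbnp(screen)
  tgt$cbnp <- cb$cbnp[match(
    pairKey(tgt$bait, tgt$prey, tgt$cell_line),
    pairKey(cb$bait, cb$prey, cb$cell_line))]
  rownames(tgt) <- NULL
  tgt
}
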