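#' Build the prey x replicate spectral-count matrix for one bait
#'
#' @param screen a [BioidScreen-class] with replicate-level counts.
#' @param bait bait identifier.
#' @param cellLine cell line to restrict to.
#' @return integer matrix, rows = preys, columns = replicates
#'   (`<bait>_r1`, `<bait>_r2`, ...).
#' @export
replicateMatrix <- function(screen, bait, cellLine) {
  rec <- interactions(screen)
  rec <- rec[rec$bait == bait & rec$cell_line == cellLine, ]
  if (!nrow(rec)) stop("no records for bait ", bait, " in ", cellLine)
  has <- !vapply(rec$replicate_specs, is.null, logical(1))
  if (!any(has)) stop("no replicate-level counts for bait ", bait)
  rec <- rec[has, ]
  nrep <- unique(lengths(rec$replicate_specs))
  if (length(nrep) != 1)
    stop("inconsistent replicate counts for bait ", bait)
  m <- do.call(rbind, rec$replicate_specs)
  rownames(m) <- rec$prey
  colnames(m) <- paste0(bait, "_r", seq_len(nrep))
  m
}

#' Pairwise Spearman correlation of replicates
#'
#' Spearman rank correlation between replicate spectral-count columns over
#' the union of preys detected in any replicate (zeros retained for
#' undetected preys); ties are mid-ranked.
#'
#' @param counts prey x replicate nonnegative count matrix (>= 2 columns,
#'   >= 3 preys with nonzero counts).
#' @return list with `pairwise_rho` (replicate x replicate matrix).
#' @export
replicateCorrelation <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two replicates")
  if (sum(rowSums(counts) > 0) < 3)
    stop("need at least three preys with nonzero counts")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("replicate with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  rho <- stats::cor(counts, method = "spearman")
  list(pairwise_rho = rho)
}

#' Flag replicates failing the Spearman correlation gate
#'
#' A replicate is flagged if and only if its correlation with every sibling
#' replicate falls below the threshold: a pair below the gate with no other
#' partner flags both members, while one aberrant replicate among three is
#' flagged alone.
#'
#' @param report output of [replicateCorrelation()] (or a correlation
#'   matrix).
#' @param threshold minimum acceptable Spearman rho (default 0.9).
#' @return character vector of flagged replicate labels.
#' @export
qcGate <- function(report, threshold = 0.9) {
  rho <- if (is.list(report)) report$pairwise_rho else as.matrix(report)
  n <- ncol(rho)
  if (n < 2) return(character())
  labels <- colnames(rho)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  flagged <- vapply(seq_len(n), function(i) all(rho[i, -i] < threshold),
                    logical(1))
  labels[flagged]
}

#' Classical MDS embedding of replicates
#'
#' Torgerson (classical) multidimensional scaling of replicates on the
#' dissimilarity 1 - Spearman rho, used to check that biological replicates
#' of the same bait group together. Coordinates are centered at the origin.
#'
#' @param counts prey x replicate count matrix pooled across baits
#'   (>= 3 columns), or a precomputed replicate correlation matrix when
#'   `isRho = TRUE`.
#' @param isRho interpret `counts` as a correlation matrix.
#' @return replicate x 2 coordinate matrix.
#' @export
mdsEmbed <- function(counts, isRho = FALSE) {
  rho <- if (isRho) as.matrix(counts)
  else replicateCorrelation(counts)$pairwise_rho
  if (ncol(rho) < 3) stop("need at least three replicates for MDS")
  d <- 1 - rho
  labels <- colnames(rho)
  if (all(abs(d) < 1e-12)) {
    warning("all replicate profiles are rank-identical; zero embedding")
    xy <- matrix(0, nrow = ncol(rho), ncol = 2)
    rownames(xy) <- labels
    colnames(xy) <- c("x", "y")
    return(xy)
  }
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  rownames(xy) <- labels
  colnames(xy) <- c("x", "y")
  xy
}

#' Flag replicates that embed away from their siblings
#'
#' In the MDS embedding, a replicate is flagged when its nearest neighbor is
#' not a replicate of the same bait.
#'
#' @param coords replicate x 2 coordinate matrix (rownames = labels).
#' @param groups bait assignment per replicate (same order as rows).
#' @return character vector of flagged replicate labels.
#' @export
replicateGroupingCheck <- function(coords, groups) {
  coords <- as.matrix(coords)
  groups <- as.character(groups)
  if (nrow(coords) != length(groups))
    stop("one group label per embedded replicate is required")
  labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons))
    warning("singleton group(s) skipped: ", paste(singletons, collapse = ", "))
  dd <- as.matrix(stats::dist(coords))
  diag(dd) <- Inf
  flagged <- character()
  for (i in seq_len(nrow(coords))) {
    if (groups[i] %in% singletons) next
    nn <- which.min(dd[i, ])
    if (groups[nn] != groups[i]) flagged <- c(flagged, labels[i])
  }
  flagged
}

#' Replicate QC over a whole screen
#'
#' Runs the Spearman correlation gate for every bait with replicate-level
#' counts and reports, per replicate, its weakest sibling correlation and
#' flag status.
#'
#' @param screen a [BioidScreen-class].
#' @param threshold Spearman gate (default 0.9).
#' @return data.frame(replicate, bait, cell_line, min_rho, flag).
#' @export
qcScreen <- function(screen, threshold = 0.9) {
  rec <- interactions(screen)
  out <- list()
  for (cl in cellLines(screen)) {
    sub <- rec[rec$cell_line == cl, ]
    for (b in unique(sub$bait)) {
      has <- !vapply(sub$replicate_specs[sub$bait == b], is.null, logical(1))
      if (!any(has)) next
      m <- replicateMatrix(screen, b, cl)
      if (ncol(m) < 2) next
      rho <- replicateCorrelation(m)$pairwise_rho
      flags <- qcGate(rho, threshold)
      min_rho <- vapply(seq_len(ncol(rho)), function(i) min(rho[i, -i]),
                        numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        replicate = colnames(rho), bait = b, cell_line = cl,
        min_rho = min_rho, flag = colnames(rho) %in% flags)
    }
  }
  if (!length(out))
    return(data.frame(replicate = character(), bait = character(),
                      cell_line = character(), min_rho = numeric(),
                      flag = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
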