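#' Build the bait x prey WDS effector matrix
#'
#' Spreads the filtered WDS scores into a bait x prey matrix (absent pairs
#' are 0) after removing regulator preys (GAPs and GEFs), leaving candidate
#' effectors only. All-zero prey columns are dropped.
#'
#' @param wdsTable data.frame with `bait`, `prey` and `wds` (e.g. filtered
#'   records from [applyFilters()]; duplicate bait-prey rows from two cell
#'   lines are collapsed to their single WDS value).
#' @param gapIds,gefIds prey symbols to exclude as regulators.
#' @return numeric matrix, rows = baits, columns = preys.
#' @export
buildEffectorMatrix <- function(wdsTable, gapIds = character(),
                                gefIds = character()) {
  tab <- unique(as.data.frame(wdsTable)[, c("bait", "prey", "wds")])
  tab <- tab[!tab$prey %in% c(gapIds, gefIds), , drop = FALSE]
  if (!nrow(tab))
    stop("no effector preys remain after removing GAPs/GEFs")
  key <- pairKey(tab$bait, tab$prey)
  if (anyDuplicated(key))
    stop("conflicting WDS values for the same bait-prey pair")
  baits <- sort(unique(tab$bait))
  preys <- sort(unique(tab$prey))
  m <- matrix(0, nrow = length(baits), ncol = length(preys),
              dimnames = list(baits, preys))
  m[cbind(match(tab$bait, baits), match(tab$prey, preys))] <- tab$wds
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (!ncol(m)) stop("effector matrix is empty (all-zero preys)")
  m
}

#' Canberra distances between prey WDS profiles
#'
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / (|x_i| + |y_i|)} over the bait axis,
#' with both-zero terms contributing 0.
#'
#' @param m bait x prey matrix from [buildEffectorMatrix()].
#' @return a `dist` object over preys.
#' @export
preyDistances <- function(m) {
  if (ncol(m) < 2) stop("need at least two preys")
  stats::dist(t(m), method = "canberra")
}

#' Correlation distances between bait WDS profiles
#'
#' \eqn{d = 1 - r} with \eqn{r} the Pearson correlation of the two baits'
#' prey profiles.
#'
#' @param m bait x prey matrix.
#' @return a `dist` object over baits.
#' @export
baitDistances <- function(m) {
  if (nrow(m) < 2) stop("need at least two baits")
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance bait profile(s): ",
         paste(rownames(m)[v == 0], collapse = ", "))
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Ward agglomeration on unsquared dissimilarities
#'
#' Lance-Williams agglomeration with Ward update coefficients applied to the
#' dissimilarities as given (not squared) - the historical `ward.D` variant.
#'
#' @param d a `dist` object (square symmetric, zero diagonal, nonnegative).
#' @return an `hclust` dendrogram.
#' @export
wardCluster <- function(d) {
  if (anyNA(d)) stop("NA/NaN in the distance matrix")
  if (any(d < 0)) stop("negative dissimilarities")
  stats::hclust(stats::as.dist(d), method = "ward.D")
}

#' Select the number of clusters by mean silhouette width
#'
#' Cuts the dendrogram at each candidate k, computes the mean silhouette
#' width against the same distance matrix used for clustering, and returns
#' the argmax (ties resolve to the smallest k). Singleton clusters have
#' silhouette width 0.
#'
#' @param d the `dist` the dendrogram was built from.
#' @param dend an `hclust` object from [wardCluster()].
#' @param kRange candidate cluster counts (default 2:20; clipped to the
#'   leaf count minus one).
#' @return list with `k`, `labels` (named cluster assignment at the chosen
#'   k) and `silhouetteProfile` (named numeric, mean width per k).
#' @export
selectK <- function(d, dend, kRange = 2:20) {
  n <- attr(d, "Size")
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) stop("kRange has no admissible values")
  profile <- vapply(kRange, function(k) {
    labs <- stats::cutree(dend, k = k)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  names(profile) <- kRange
  best <- kRange[which.max(profile)]   # which.max takes the first (smallest k)
  if (max(profile) < 0.25)
    warning("weak cluster structure: best mean silhouette width is ",
            format(max(profile), digits = 3))
  list(k = best, labels = stats::cutree(dend, k = best),
       silhouetteProfile = profile)
}

#' Cluster the effector matrix on both axes
#'
#' Prey clustering uses Canberra distances between prey profiles across the
#' joint bait axis; bait clustering uses 1 - Pearson correlation. Both use
#' Ward (unsquared) linkage with silhouette-guided selection of the number
#' of clusters.
#'
#' @param m bait x prey WDS matrix.
#' @param kRangePreys,kRangeBaits candidate cluster counts per axis.
#' @return list with elements `preys` and `baits`, each holding `dist`,
#'   `dendrogram` and the [selectK()] result.
#' @export
clusterEffectors <- function(m, kRangePreys = 2:20, kRangeBaits = 2:20) {
  dp <- preyDistances(m)
  db <- baitDistances(m)
  hp <- wardCluster(dp)
  hb <- wardCluster(db)
  list(preys = list(dist = dp, dendrogram = hp,
                    clusters = selectK(dp, hp, kRangePreys)),
       baits = list(dist = db, dendrogram = hb,
                    clusters = selectK(db, hb, kRangeBaits)))
}
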