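#' @import methods
NULL

#' BioidScreen: a SAINT-style bait-prey interaction table
#'
#' Container for the post-SAINT results of one or more proximity-labeling
#' screens. Each row of `records` is one bait x prey x cell-line observation
#' carrying the average spectral count (`avg_spec`), the per-replicate
#' spectral counts (`replicate_specs`, a list column of integer vectors, may
#' be `NULL` per row when replicate-level data are unavailable) and the SAINT
#' average probability (`avg_p`). Control purifications (empty-vector BirA*,
#' BirA*-eGFP, and the membrane-targeted BirA*-eGFP-CAAX) are identified by
#' configured bait identifiers, never by name matching.
#'
#' @slot records data.frame with columns `bait`, `prey`, `cell_line`,
#'   `avg_spec`, `avg_p`, `is_control` and list column `replicate_specs`.
#' @slot controlBaits named character vector; names among
#'   `"empty_vector"`, `"gfp"`, `"caax"`, values are bait identifiers.
#'
#' @seealso [readInteractionTable()], [scoreInteractions()]
#' @exportClass BioidScreen
setClass("BioidScreen",
  representation(records = "data.frame", controlBaits = "character"))

setValidity("BioidScreen", function(object) {
  rec <- object@records
  need <- c("bait", "prey", "cell_line", "avg_spec", "avg_p",
            "is_control", "replicate_specs")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("records is missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(rec)) {
    if (any(!nzchar(rec$bait))) return("bait ids must be nonempty")
    if (any(rec$avg_p < 0 | rec$avg_p > 1, na.rm = TRUE))
      return("avg_p must lie in [0, 1]")
    if (any(rec$avg_spec < 0, na.rm = TRUE))
      return("avg_spec must be nonnegative")
    key <- paste(rec$bait, rec$prey, rec$cell_line, sep = "\r")
    if (anyDuplicated(key))
      return("(bait, prey, cell_line) must be unique")
    has <- !vapply(rec$replicate_specs, is.null, logical(1))
    if (any(has)) {
      mu <- vapply(rec$replicate_specs[has], mean, numeric(1))
      if (any(abs(mu - rec$avg_spec[has]) > 1e-9))
        return("avg_spec must equal mean(replicate_specs) where replicates are present")
    }
  }
  cb <- object@controlBaits
  if (length(cb)) {
    if (!all(names(cb) %in% c("empty_vector", "gfp", "caax")))
      return("controlBaits names must be among empty_vector, gfp, caax")
    if (anyDuplicated(names(cb))) return("controlBaits names must be distinct")
  }
  TRUE
})

#' Construct a BioidScreen
#'
#' @param records data.frame with at least `bait`, `prey`, `cell_line`,
#'   `avg_spec`, `avg_p`. An optional `replicate_specs` column may be a list
#'   of integer vectors or a character column of delimiter-joined counts
#'   (e.g. `"4|6"`).
#' @param controlBaits named character vector mapping control roles
#'   (`empty_vector`, `gfp`, `caax`) to bait identifiers.
#' @param specDelim delimiter used when `replicate_specs` is character.
#' @return A [BioidScreen-class] object.
#' @examples
#' rec <- data.frame(bait = "ARF1", prey = "GBF1", cell_line = "HEK293",
#'                   avg_spec = 5, avg_p = 0.99)
#' BioidScreen(rec)
#' @export
BioidScreen <- function(records, controlBaits = character(), specDelim = "|") {
  records <- as.data.frame(records)
  if (is.null(records$replicate_specs)) {
    records$replicate_specs <- replicate(nrow(records), NULL, simplify = FALSE)
  } else if (is.character(records$replicate_specs)) {
    records$replicate_specs <- parseSpecStrings(records$replicate_specs, specDelim)
  } else if (is.list(records$replicate_specs)) {
    records$replicate_specs <- unclass(records$replicate_specs)
  } else {
    stop("replicate_specs must be a character or list column")
  }
  records$cell_line <- as.character(records$cell_line)
  records$bait <- as.character(records$bait)
  records$prey <- as.character(records$prey)
  records$is_control <- records$bait %in% controlBaits
  rownames(records) <- NULL
  new("BioidScreen", records = records, controlBaits = controlBaits)
}

setMethod("show", "BioidScreen", function(object) {
  rec <- object@records
  cat("BioidScreen with", nrow(rec), "records\n")
  cat("  cell lines:", paste(unique(rec$cell_line), collapse = ", "), "\n")
  cat("  baits:", length(unique(rec$bait[!rec$is_control])),
      "(+", length(object@controlBaits), "controls )\n")
  cat("  preys:", length(unique(rec$prey)), "\n")
  if (length(object@controlBaits))
    cat("  controls:", paste(names(object@controlBaits),
        object@controlBaits, sep = "=", collapse = ", "), "\n")
})

#' Gold-standard physical-interaction edge list
#'
#' Known bait-prey edges (e.g. from BioGRID) used as positive labels when
#' calibrating spectral-count and control-ratio cutpoints.
#'
#' @slot edges data.frame with columns `bait`, `prey`.
#' @slot sourceTag character, provenance label (database name + version).
#' @slot baitSubset character, the baits used for calibration.
#' @exportClass GoldStandard
setClass("GoldStandard",
  representation(edges = "data.frame", sourceTag = "character",
                 baitSubset = "character"))

setValidity("GoldStandard", function(object) {
  if (!all(c("bait", "prey") %in% names(object@edges)))
    return("edges must have columns bait, prey")
  if (length(object@baitSubset) &&
      !all(object@baitSubset %in% object@edges$bait))
    return("baitSubset must be a subset of the baits present in edges")
  TRUE
})

#' @param edges data.frame with columns `bait`, `prey`.
#' @param sourceTag provenance label.
#' @param baitSubset baits retained for calibration.
#' @rdname GoldStandard-class
#' @export
GoldStandard <- function(edges, sourceTag = "unspecified",
                         baitSubset = character()) {
  edges <- unique(as.data.frame(edges)[, c("bait", "prey")])
  rownames(edges) <- NULL
  new("GoldStandard", edges = edges, sourceTag = sourceTag,
      baitSubset = as.character(baitSubset))
}

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", nrow(object@edges), "edges from", object@sourceTag, "\n")
  if (length(object@baitSubset))
    cat("  calibration baits:", paste(object@baitSubset, collapse = ", "), "\n")
})

#' High-confidence filter configuration
#'
#' Thresholds of the filter stack: minimum SAINT average probability,
#' per-cell-line minimum average spectral count, minimum membrane-control
#' (CAAX) enrichment ratio, and a contaminant blocklist. Comparisons are
#' inclusive (record kept at exactly the threshold).
#'
#' @slot avgPMin numeric, minimum AvgP (default 0.95).
#' @slot avgSpecMin named numeric, minimum AvgSpec per cell line
#'   (defaults: HEK293 = 4.5, HeLa = 6).
#' @slot caaxRatioMin numeric, minimum CAAX ratio (default 1.7).
#' @slot blocklist character, prey symbols removed as contaminants.
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(avgPMin = "numeric", avgSpecMin = "numeric",
                 caaxRatioMin = "numeric", blocklist = "character"))

setValidity("FilterConfig", function(object) {
  if (object@avgPMin < 0 || object@avgPMin > 1)
    return("avgPMin must lie in [0, 1]")
  if (any(object@avgSpecMin < 0) || object@caaxRatioMin < 0)
    return("thresholds must be nonnegative")
  if (is.null(names(object@avgSpecMin)) || any(!nzchar(names(object@avgSpecMin))))
    return("avgSpecMin must be named by cell line")
  TRUE
})

#' @param avgPMin minimum AvgP.
#' @param avgSpecMin named numeric, per-cell-line minimum AvgSpec.
#' @param caaxRatioMin minimum CAAX enrichment ratio.
#' @param blocklist contaminant prey symbols (see [defaultBlocklist()]).
#' @rdname FilterConfig-class
#' @export
FilterConfig <- function(avgPMin = 0.95,
                         avgSpecMin = c(HEK293 = 4.5, HeLa = 6),
                         caaxRatioMin = 1.7,
                         blocklist = defaultBlocklist()) {
  new("FilterConfig", avgPMin = avgPMin, avgSpecMin = avgSpecMin,
      caaxRatioMin = caaxRatioMin, blocklist = blocklist)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: AvgP >=", object@avgPMin, "\n")
  cat("  AvgSpec >=", paste(names(object@avgSpecMin), object@avgSpecMin,
      sep = ": ", collapse = ", "), "\n")
  cat("  CAAX ratio >=", object@caaxRatioMin, "\n")
  cat("  blocklist:", length(object@blocklist), "symbols\n")
})

#' Default contaminant blocklist
#'
#' Prey symbols removed as non-specific contaminants of streptavidin
#' purifications: keratins, the BirA* ligase itself, the endogenous
#' biotin-dependent carboxylases, and beta-galactosidase.
#'
#' @return character vector of prey symbols.
#' @export
defaultBlocklist <- function() {
  c(sprintf("KRT%d", c(1:10, 12:20, 23:28, 31:40, 71:86)),
    "BIRA", "BirA", "BirA*",
    "PC", "PCCA", "PCCB", "MCCC1", "MCCC2", "ACACA", "ACACB",
    "LACZ", "lacZ")
}

#' Cutpoint calibration report
#'
#' Evidence behind a spectral-count or control-ratio cutpoint: the full ROC
#' grid with the Youden-optimal threshold and trapezoidal AUC, and/or the
#' positive/negative empirical CDFs with the maximum-gap
#' (Kolmogorov-Smirnov location) cutpoint.
#'
#' @slot scoreName character, the score that was thresholded.
#' @slot rocPoints data.frame(threshold, sensitivity, specificity, j).
#' @slot auc numeric in [0, 1].
#' @slot rocCutpoint numeric, Youden-optimal threshold.
#' @slot cdaCurve data.frame(score, cdf_pos, cdf_neg, gap).
#' @slot cdaCutpoint numeric, maximum-ECDF-gap score.
#' @exportClass CutpointReport
setClass("CutpointReport",
  representation(scoreName = "character", rocPoints = "data.frame",
                 auc = "numeric", rocCutpoint = "numeric",
                 cdaCurve = "data.frame", cdaCutpoint = "numeric"),
  prototype(rocPoints = data.frame(), auc = NA_real_,
            rocCutpoint = NA_real_, cdaCurve = data.frame(),
            cdaCutpoint = NA_real_))

setMethod("show", "CutpointReport", function(object) {
  cat("CutpointReport for score:", object@scoreName, "\n")
  if (!is.na(object@auc))
    cat("  ROC: AUC =", format(object@auc, digits = 4),
        "; Youden cutpoint =", object@rocCutpoint, "\n")
  if (!is.na(object@cdaCutpoint))
    cat("  CDA: max ECDF gap cutpoint =", object@cdaCutpoint, "\n")
})

#' Synthetic screen with planted ground truth
#'
#' @slot screen a [BioidScreen-class] holding the simulated tables
#'   (both cell lines, controls included).
#' @slot truth list with `true_edges` (data.frame bait/prey/cell_line),
#'   `membrane_preys` and `planted_avg_spec_threshold` (the Youden-optimal
#'   separation of the generating count distributions).
#' @slot config the generating [simConfig()] list.
#' @exportClass SimScreen
setClass("SimScreen",
  representation(screen = "BioidScreen", truth = "list", config = "list"))

setMethod("show", "SimScreen", function(object) {
  cat("SimScreen:", nrow(object@screen@records), "records;",
      nrow(object@truth$true_edges), "planted true edges\n")
  cat("  planted AvgSpec threshold:",
      object@truth$planted_avg_spec_threshold, "\n")
})
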