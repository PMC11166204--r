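#' Configuration for the synthetic-screen generator
#'
#' Defaults describe a two-cell-line proximity-labeling screen run in
#' biological duplicate with three control purifications (empty-vector
#' BirA*, BirA*-eGFP, and membrane-targeted BirA*-eGFP-CAAX): per-bait
#' planted true preys with negative-binomial replicate counts around
#' `mu_true`, zero-inflated frequency-graded background around `mu_bg`,
#' membrane preys mildly elevated everywhere and strongly boosted in the
#' CAAX control, and SAINT-like average probabilities drawn from separated
#' Beta distributions.
#'
#' @param n_baits number of real (non-control) baits.
#' @param n_preys size of the prey universe.
#' @param frac_true_per_bait fraction of the prey universe planted as true
#'   preys per bait.
#' @param shared_edge_prob probability a true edge exists in both cell
#'   lines (otherwise it is assigned to one line at random).
#' @param mu_true,mu_bg negative-binomial replicate-count means for true
#'   and background detections.
#' @param dispersion negative-binomial size parameter per replicate.
#' @param detect_prob_bg baseline probability a background prey is detected
#'   at all in a purification (zero inflation); scaled per prey by its
#'   abundance grade.
#' @param bg_grade_shape shape of the per-prey Gamma abundance grade (mean
#'   1, rate = shape) that makes the background frequency-graded: sticky
#'   preys are both more abundant and more often detected across baits.
#' @param n_membrane_preys number of membrane-enriched preys.
#' @param caax_boost count multiplier for membrane preys in the CAAX
#'   control (> 1).
#' @param membrane_elev mild count elevation of membrane preys in all
#'   non-CAAX purifications.
#' @param n_replicates biological replicates per bait per cell line.
#' @param avgp_true_beta,avgp_bg_beta Beta (shape1, shape2) pairs for the
#'   simulated average probabilities of true and background records.
#' @param cell_lines cell-line labels.
#' @param seed integer seed; the whole screen is reproducible from it.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(n_baits = 20, n_preys = 1000,
                      frac_true_per_bait = 0.02, shared_edge_prob = 0.6,
                      mu_true = 25, mu_bg = 3, dispersion = 4,
                      detect_prob_bg = 0.15, bg_grade_shape = 2,
                      n_membrane_preys = max(1L, round(0.05 * n_preys)),
                      caax_boost = 3, membrane_elev = 1.5,
                      n_replicates = 2,
                      avgp_true_beta = c(50, 1), avgp_bg_beta = c(1, 20),
                      cell_lines = c("HEK293", "HeLa"), seed = 1) {
  cfg <- list(n_baits = n_baits, n_preys = n_preys,
              frac_true_per_bait = frac_true_per_bait,
              shared_edge_prob = shared_edge_prob, mu_true = mu_true,
              mu_bg = mu_bg, dispersion = dispersion,
              detect_prob_bg = detect_prob_bg,
              bg_grade_shape = bg_grade_shape,
              n_membrane_preys = n_membrane_preys, caax_boost = caax_boost,
              membrane_elev = membrane_elev, n_replicates = n_replicates,
              avgp_true_beta = avgp_true_beta, avgp_bg_beta = avgp_bg_beta,
              cell_lines = cell_lines, seed = seed)
  if (frac_true_per_bait * n_preys < 1)
    stop("infeasible config: frac_true_per_bait x n_preys < 1")
  if (any(c(mu_true, mu_bg, dispersion) <= 0))
    stop("negative-binomial means and dispersion must be positive")
  if (detect_prob_bg < 0 || detect_prob_bg > 1 ||
      shared_edge_prob < 0 || shared_edge_prob > 1)
    stop("probabilities must lie in [0, 1]")
  if (caax_boost <= 1) stop("caax_boost must exceed 1")
  class(cfg) <- c("SimConfig", "list")
  cfg
}

# Youden-optimal separation of the generating replicate-mean distributions:
# true counts are NB sums; background counts are a zero-truncated NB mixed
# over the per-prey Gamma abundance grade (quadrature over its quantiles,
# weighted by each grade's chance of producing a detected record).
plantedAvgSpecThreshold <- function(cfg) {
  nrep <- cfg$n_replicates
  size <- nrep * cfg$dispersion
  m <- 40
  g <- stats::qgamma((seq_len(m) - 0.5) / m, shape = cfg$bg_grade_shape,
                     rate = cfg$bg_grade_shape)
  mu_g <- nrep * cfg$mu_bg * g
  p0 <- stats::pnbinom(0, size = size, mu = mu_g)
  w <- pmin(1, cfg$detect_prob_bg * g) * (1 - p0)
  w <- w / sum(w)
  grid <- seq(0.5, 2 * cfg$mu_true, by = 0.5)
  j <- vapply(grid, function(t) {
    k <- ceiling(nrep * t) - 1
    sens <- 1 - stats::pnbinom(k, size = size, mu = nrep * cfg$mu_true)
    cdf_b <- sum(w * (stats::pnbinom(k, size = size, mu = mu_g) - p0) /
                   (1 - p0))
    sens + cdf_b - 1
  }, numeric(1))
  grid[which.max(j)]
}

#' Simulate a two-cell-line SAINT-style BioID screen with planted truth
#'
#' @param cfg a [simConfig()] list.
#' @return a [SimScreen-class] holding the generated [BioidScreen-class]
#'   (controls included) and the planted ground truth (`true_edges`,
#'   `membrane_preys`, `planted_avg_spec_threshold`, plus the bait and prey
#'   universes).
#' @export
simulateScreen <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  baits <- sprintf("BAIT%02d", seq_len(cfg$n_baits))
  preys <- sprintf("PREY%04d", seq_len(cfg$n_preys))
  controls <- c(empty_vector = "CTRL_EMPTY", gfp = "CTRL_GFP",
                caax = "CTRL_CAAX")
  membrane_idx <- sort(sample.int(cfg$n_preys, cfg$n_membrane_preys))
  # per-prey background abundance grade (frequency-graded background)
  bg_grade <- stats::rgamma(cfg$n_preys, shape = cfg$bg_grade_shape,
                            rate = cfg$bg_grade_shape)
  n_true <- round(cfg$frac_true_per_bait * cfg$n_preys)

  # plant true edges and decide per edge which cell line(s) carry it
  edge_list <- list()
  for (b in baits) {
    tp <- sample.int(cfg$n_preys, n_true)
    u <- stats::runif(n_true)
    both <- u < cfg$shared_edge_prob
    line1 <- !both & stats::runif(n_true) < 0.5
    for (cl in cfg$cell_lines) {
      in_line <- both | if (cl == cfg$cell_lines[1]) line1 else (!both & !line1)
      if (length(cfg$cell_lines) == 1) in_line <- rep(TRUE, n_true)
      if (!any(in_line)) next
      edge_list[[length(edge_list) + 1L]] <- data.frame(
        bait = b, prey = preys[tp[in_line]], cell_line = cl)
    }
  }
  true_edges <- do.call(rbind, edge_list)
  true_key <- pairKey(true_edges$bait, true_edges$prey, true_edges$cell_line)

  all_baits <- c(baits, unname(controls))
  rec_list <- list()
  for (cl in cfg$cell_lines) {
    for (b in all_baits) {
      is_caax <- identical(b, controls[["caax"]])
      det <- stats::runif(cfg$n_preys) < pmin(1, cfg$detect_prob_bg * bg_grade)
      mu <- cfg$mu_bg * bg_grade
      if (is_caax) {
        det[membrane_idx] <- TRUE
        mu[membrane_idx] <- cfg$mu_bg * cfg$caax_boost
      } else {
        mu[membrane_idx] <- cfg$mu_bg * cfg$membrane_elev
      }
      is_true <- rep(FALSE, cfg$n_preys)
      if (b %in% baits) {
        tp <- true_edges$prey[true_edges$bait == b &
                              true_edges$cell_line == cl]
        ti <- match(tp, preys)
        det[ti] <- TRUE
        mu[ti] <- cfg$mu_true
        is_true[ti] <- TRUE
      }
      idx <- which(det)
      if (!length(idx)) next
      counts <- matrix(stats::rnbinom(length(idx) * cfg$n_replicates,
                                      size = cfg$dispersion,
                                      mu = rep(mu[idx],
                                               each = cfg$n_replicates)),
                       ncol = cfg$n_replicates, byrow = TRUE)
      keep <- rowSums(counts) > 0
      idx <- idx[keep]
      counts <- counts[keep, , drop = FALSE]
      if (!length(idx)) next
      tr <- is_true[idx]
      avg_p <- numeric(length(idx))
      avg_p[tr] <- stats::rbeta(sum(tr), cfg$avgp_true_beta[1],
                                cfg$avgp_true_beta[2])
      avg_p[!tr] <- stats::rbeta(sum(!tr), cfg$avgp_bg_beta[1],
                                 cfg$avgp_bg_beta[2])
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        bait = b, prey = preys[idx], cell_line = cl,
        avg_spec = rowMeans(counts), avg_p = avg_p,
        replicate_specs = I(lapply(seq_len(nrow(counts)),
                                   function(i) counts[i, ])))
    }
  }
  records <- do.call(rbind, rec_list)
  screen <- BioidScreen(records, controlBaits = controls)
  truth <- list(true_edges = true_edges,
                membrane_preys = preys[membrane_idx],
                planted_avg_spec_threshold = plantedAvgSpecThreshold(cfg),
                baits = baits, preys = preys)
  new("SimScreen", screen = screen, truth = truth, config = unclass(cfg))
}

#' Benchmark pipeline recovery against planted truth
#'
#' Precision, recall and F1 of a filtered interaction set against the
#' planted true edges (matched on bait, prey and cell line), optionally the
#' absolute error of a calibrated AvgSpec cutpoint against the planted
#' separation, and optionally the adjusted Rand index of recovered versus
#' planted cluster labels.
#'
#' @param filtered filtered records with `bait`, `prey`, `cell_line`.
#' @param truth the `simTruth()` list of a [SimScreen-class].
#' @param calibratedCutpoint optional calibrated AvgSpec threshold.
#' @param clusterLabels,plantedLabels optional label vectors (same order)
#'   for cluster-recovery scoring.
#' @return list with `precision`, `recall`, `f1`, `n_filtered`, `n_true`,
#'   and when requested `cutpoint_error` and `ari`.
#' @export
benchmarkRecovery <- function(filtered, truth, calibratedCutpoint = NULL,
                              clusterLabels = NULL, plantedLabels = NULL) {
  filtered <- as.data.frame(filtered)
  extra <- setdiff(unique(filtered$bait), truth$baits)
  if (length(extra))
    stop("filtered records contain baits absent from the truth: ",
         paste(utils::head(extra, 3), collapse = ", "))
  got <- unique(pairKey(filtered$bait, filtered$prey, filtered$cell_line))
  want <- unique(pairKey(truth$true_edges$bait, truth$true_edges$prey,
                         truth$true_edges$cell_line))
  tp <- sum(got %in% want)
  precision <- if (length(got)) tp / length(got) else 0
  recall <- tp / length(want)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  out <- list(precision = precision, recall = recall, f1 = f1,
              n_filtered = length(got), n_true = length(want))
  if (!is.null(calibratedCutpoint))
    out$cutpoint_error <- abs(calibratedCutpoint -
                              truth$planted_avg_spec_threshold)
  if (!is.null(clusterLabels)) {
    if (is.null(plantedLabels) ||
        length(clusterLabels) != length(plantedLabels))
      stop("clusterLabels and plantedLabels must be given together, ",
           "same length")
    out$ari <- mclust::adjustedRandIndex(clusterLabels, plantedLabels)
  }
  out
}

#' Simulate a WDS effector matrix with planted block structure
#'
#' Builds a bait x prey WDS-like matrix with planted prey modules and bait
#' families. Each prey module is active in a distinct pair of bait families
#' (so modules stay distinguishable even when they outnumber the families):
#' within-block entries are strong positive scores, off-block entries are
#' sparse weak noise.
#'
#' @param nBaits,nPreys matrix dimensions.
#' @param nBaitFamilies,nPreyModules planted cluster counts
#'   (`nPreyModules` must not exceed `choose(nBaitFamilies, 2)` when
#'   `nBaitFamilies > 1`).
#' @param signalMean mean within-block WDS.
#' @param noiseRate fraction of off-block cells carrying weak noise.
#' @param noiseMean mean off-block WDS where present.
#' @param seed integer seed.
#' @return list with `wds` (matrix), `preyModules` and `baitFamilies`
#'   (named integer vectors of planted labels).
#' @export
simulateEffectorMatrix <- function(nBaits = 20, nPreys = 100,
                                   nBaitFamilies = 4, nPreyModules = 5,
                                   signalMean = 30, noiseRate = 0.05,
                                   noiseMean = 1.5, seed = 1) {
  set.seed(seed)
  baits <- sprintf("BAIT%02d", seq_len(nBaits))
  preys <- sprintf("PREY%03d", seq_len(nPreys))
  baitFam <- rep(seq_len(nBaitFamilies), length.out = nBaits)
  preyMod <- sort(rep(seq_len(nPreyModules), length.out = nPreys))
  if (nBaitFamilies > 1) {
    pairs <- utils::combn(nBaitFamilies, 2)
    if (nPreyModules > ncol(pairs))
      stop("nPreyModules must not exceed choose(nBaitFamilies, 2)")
    activeFam <- lapply(seq_len(nPreyModules), function(mod) pairs[, mod])
  } else {
    activeFam <- replicate(nPreyModules, 1L, simplify = FALSE)
  }
  m <- matrix(0, nBaits, nPreys, dimnames = list(baits, preys))
  for (i in seq_len(nBaits)) {
    for (j in seq_len(nPreys)) {
      if (baitFam[i] %in% activeFam[[preyMod[j]]]) {
        m[i, j] <- stats::rgamma(1, shape = 16,
                                 scale = signalMean / 16)
      } else if (stats::runif(1) < noiseRate) {
        m[i, j] <- stats::rgamma(1, shape = 2, scale = noiseMean / 2)
      }
    }
  }
  list(wds = m,
       preyModules = stats::setNames(preyMod, preys),
       baitFamilies = stats::setNames(baitFam, baits))
}

#' Simulate a compartment marker atlas
#'
#' Disjoint marker sets of equal size with systematic names
#' (`COMP01`, ...) and marker symbols (`MARK0001`, ...).
#'
#' @param nCompartments number of compartments.
#' @param nMarkers markers per compartment.
#' @return named list of character vectors.
#' @export
simulateMarkerAtlas <- function(nCompartments = 20, nMarkers = 30) {
  syms <- sprintf("MARK%04d", seq_len(nCompartments * nMarkers))
  atlas <- split(syms, rep(seq_len(nCompartments), each = nMarkers))
  names(atlas) <- sprintf("COMP%02d", seq_len(nCompartments))
  atlas
}

#' Simulate marker-biased bait prey sets
#'
#' For each synthetic bait, draws a prey set with a fixed fraction sampled
#' from one target compartment's markers and the remainder sampled from the
#' other compartments' markers, for benchmarking localization calls.
#'
#' @param atlas named list of marker sets.
#' @param nBaits number of synthetic baits.
#' @param targetFrac fraction of each prey set drawn from the target
#'   compartment (default 0.8).
#' @param preySetSize preys per bait.
#' @param seed integer seed.
#' @return list with `preySets` (named list of character vectors) and
#'   `targets` (named character vector of the planted compartment per bait).
#' @export
simulateLocalizationPreySets <- function(atlas, nBaits = 200,
                                         targetFrac = 0.8,
                                         preySetSize = 20, seed = 1) {
  set.seed(seed)
  comps <- names(atlas)
  targets <- sample(comps, nBaits, replace = TRUE)
  n_in <- round(targetFrac * preySetSize)
  preySets <- lapply(seq_len(nBaits), function(i) {
    own <- sample(atlas[[targets[i]]], n_in)
    pool <- unlist(atlas[setdiff(comps, targets[i])], use.names = FALSE)
    unique(c(own, sample(pool, preySetSize - n_in)))
  })
  names(preySets) <- names(targets) <- sprintf("SIMBAIT%03d", seq_len(nBaits))
  list(preySets = preySets, targets = targets)
}
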