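#' Overlap of filtered interaction sets between cell lines
#'
#' @param filtered filtered records with `bait`, `prey`, `cell_line`
#'   (exactly two cell lines).
#' @return list with per-line and shared counts of bait-prey pairs, and the
#'   unique-prey variants of each count.
#' @export
summarizeOverlap <- function(filtered) {
  filtered <- as.data.frame(filtered)
  lines <- sort(unique(filtered$cell_line))
  if (length(lines) != 2)
    stop("overlap summary requires exactly two cell lines")
  pairs <- lapply(lines, function(cl)
    unique(pairKey(filtered$bait[filtered$cell_line == cl],
                   filtered$prey[filtered$cell_line == cl])))
  preysets <- lapply(lines, function(cl)
    unique(filtered$prey[filtered$cell_line == cl]))
  names(pairs) <- names(preysets) <- lines
  list(cell_lines = lines,
       pairs_per_line = lengths(pairs),
       pairs_shared = length(intersect(pairs[[1]], pairs[[2]])),
       preys_per_line = lengths(preysets),
       preys_shared = length(intersect(preysets[[1]], preysets[[2]])))
}

writeTsv <- function(df, path) {
  drop <- vapply(df, is.list, logical(1))
  utils::write.table(df[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full post-SAINT pipeline
#'
#' Orchestrates replicate QC, scoring (WD/WDS, CAAX ratio, log2 fold
#' change, CBNP), the high-confidence filter stack, effector clustering and
#' marker-based localization, writing plain TSV/JSON artifacts under
#' `outDir` (subdirectories `qc/`, `scores/`, `filtered/`, `clusters/`,
#' `localization/`, plus `report.json`). The run is deterministic given the
#' screen and configuration; a stage failure aborts with the stage name,
#' retaining completed outputs and a `MANIFEST` marking incompleteness.
#' Single-cell-line screens are supported (WDS = WD; the between-line
#' overlap summary is suppressed).
#'
#' @param screen a [BioidScreen-class].
#' @param outDir output directory (created if missing).
#' @param filterConfig a [FilterConfig-class].
#' @param atlas optional named list of compartment marker sets; when given,
#'   localization calls are produced.
#' @param gapIds,gefIds regulator preys removed before effector clustering.
#' @param kRange candidate cluster counts for both axes.
#' @param qcThreshold Spearman gate for replicate QC.
#' @return the report list, invisibly (also written as `report.json`).
#' @export
runPipeline <- function(screen, outDir, filterConfig = FilterConfig(),
                        atlas = NULL, gapIds = character(),
                        gefIds = character(), kRange = 2:20,
                        qcThreshold = 0.9) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  done <- character()
  report <- list()
  fail <- function(stage, e) {
    writeLines(c("INCOMPLETE", paste("completed:", paste(done, collapse = " "))),
               file.path(outDir, "MANIFEST"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) fail(name, e))
    done <<- c(done, name)
    res
  }

  qc <- stage("qc", function() {
    d <- file.path(outDir, "qc"); dir.create(d, showWarnings = FALSE)
    rep_qc <- qcScreen(screen, threshold = qcThreshold)
    writeTsv(rep_qc, file.path(d, "qc_report.tsv"))
    rep_qc
  })
  report$qc <- list(n_replicates = nrow(qc), n_flagged = sum(qc$flag))

  scored <- stage("scores", function() {
    d <- file.path(outDir, "scores"); dir.create(d, showWarnings = FALSE)
    s <- scoreInteractions(screen)
    writeTsv(s, file.path(d, "scores.tsv"))
    writeDotplotTable(s, file.path(d, "dotplot.tsv"))
    s
  })
  report$scores <- list(records_in = nrow(scored))

  flt <- stage("filtered", function() {
    d <- file.path(outDir, "filtered"); dir.create(d, showWarnings = FALSE)
    f <- applyFilters(scored, filterConfig)
    writeTsv(f$records, file.path(d, "interactions.tsv"))
    writeTsv(f$attrition, file.path(d, "attrition.tsv"))
    writeNetwork(f$records, file.path(d, "network.tsv"), "edge_tsv")
    f
  })
  report$filtered <- list(
    records_in = flt$n_in, records_out = flt$n_out,
    removed = stats::setNames(as.list(flt$attrition$removed),
                              flt$attrition$filter))

  if (length(cellLines(screen)) == 2 && nrow(flt$records)) {
    ov <- stage("overlap", function() summarizeOverlap(flt$records))
    report$overlap <- ov[c("pairs_per_line", "pairs_shared",
                           "preys_per_line", "preys_shared")]
  }

  if (nrow(flt$records)) {
    cl <- stage("clusters", function() {
      d <- file.path(outDir, "clusters"); dir.create(d, showWarnings = FALSE)
      m <- buildEffectorMatrix(flt$records, gapIds, gefIds)
      res <- clusterEffectors(m, kRange, kRange)
      writeTsv(data.frame(id = names(res$preys$clusters$labels),
                          axis = "prey",
                          cluster = unname(res$preys$clusters$labels)),
               file.path(d, "prey_clusters.tsv"))
      writeTsv(data.frame(id = names(res$baits$clusters$labels),
                          axis = "bait",
                          cluster = unname(res$baits$clusters$labels)),
               file.path(d, "bait_clusters.tsv"))
      writeTsv(data.frame(
        axis = rep(c("prey", "bait"),
                   c(length(res$preys$clusters$silhouetteProfile),
                     length(res$baits$clusters$silhouetteProfile))),
        k = c(names(res$preys$clusters$silhouetteProfile),
              names(res$baits$clusters$silhouetteProfile)),
        mean_silhouette = c(res$preys$clusters$silhouetteProfile,
                            res$baits$clusters$silhouetteProfile)),
        file.path(d, "silhouette_profile.tsv"))
      ord <- m[res$baits$dendrogram$order, res$preys$dendrogram$order,
               drop = FALSE]
      utils::write.table(ord, file.path(d, "wds_matrix_ordered.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      res
    })
    report$clusters <- list(k_preys = cl$preys$clusters$k,
                            k_baits = cl$baits$clusters$k)
  }

  if (!is.null(atlas) && nrow(flt$records)) {
    loc <- stage("localization", function() {
      d <- file.path(outDir, "localization")
      dir.create(d, showWarnings = FALSE)
      lc <- localizeBaits(flt$records, atlas)
      writeTsv(lc, file.path(d, "localization.tsv"))
      lc
    })
    top1 <- loc[loc$rank == 1, ]
    report$localization <- stats::setNames(as.list(top1$compartment),
                                           top1$bait)
  }

  writeLines(c("COMPLETE", paste("completed:", paste(done, collapse = " "))),
             file.path(outDir, "MANIFEST"))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
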