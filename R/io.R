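#' Read a SAINT-style bait-prey interaction table
#'
#' Parses a tab-delimited SAINT output table into a [BioidScreen-class].
#' The `saint_tsv` dialect expects the SAINT column names (`Bait`,
#' `PreyGene` or `Prey`, `Spec`, `AvgSpec`, `AvgP`, optionally `CellLine`);
#' `generic_tsv` expects lower-case `bait`, `prey`, `cell_line`,
#' `replicate_specs`, `avg_spec`, `avg_p`. Prey identity is the gene-symbol
#' column; replicate spectral counts are split on `specDelim`.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect `"saint_tsv"` or `"generic_tsv"`.
#' @param controlBaits named character vector mapping control roles
#'   (`empty_vector`, `gfp`, `caax`) to bait ids as they appear in the file.
#' @param cellLine cell line assigned to all rows when the file carries no
#'   cell-line column.
#' @param specDelim delimiter inside the replicate spectral-count column.
#' @return A [BioidScreen-class].
#' @export
readInteractionTable <- function(path,
                                 dialect = c("saint_tsv", "generic_tsv"),
                                 controlBaits = character(),
                                 cellLine = "HEK293",
                                 specDelim = "|") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  cols <- if (dialect == "saint_tsv") {
    prey_col <- if ("PreyGene" %in% names(raw)) "PreyGene" else "Prey"
    c(bait = "Bait", prey = prey_col, avg_spec = "AvgSpec", avg_p = "AvgP",
      spec = "Spec", cell_line = "CellLine")
  } else {
    c(bait = "bait", prey = "prey", avg_spec = "avg_spec", avg_p = "avg_p",
      spec = "replicate_specs", cell_line = "cell_line")
  }
  mandatory <- cols[c("bait", "prey", "avg_spec", "avg_p")]
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))

  rec <- data.frame(bait = raw[[cols["bait"]]], prey = raw[[cols["prey"]]],
                    stringsAsFactors = FALSE)
  rec$cell_line <- if (cols["cell_line"] %in% names(raw))
    raw[[cols["cell_line"]]] else cellLine
  rec$avg_spec <- parseNumeric(raw[[cols["avg_spec"]]], cols["avg_spec"])
  rec$avg_p <- parseNumeric(raw[[cols["avg_p"]]], cols["avg_p"])
  bad_p <- which(rec$avg_p < 0 | rec$avg_p > 1)
  if (length(bad_p))
    stop("AvgP outside [0, 1] at data row ", bad_p[1])
  if (cols["spec"] %in% names(raw))
    rec$replicate_specs <- raw[[cols["spec"]]]
  BioidScreen(rec, controlBaits = controlBaits, specDelim = specDelim)
}

#' Write a BioidScreen back to a SAINT-style TSV
#'
#' Inverse of [readInteractionTable()]; `saint_tsv` round trips are exact for
#' the record multiset.
#'
#' @param screen a [BioidScreen-class].
#' @param path output path.
#' @param dialect output dialect (see [readInteractionTable()]).
#' @param specDelim delimiter for the replicate spectral-count column.
#' @return `path`, invisibly.
#' @export
writeInteractionTable <- function(screen, path,
                                  dialect = c("saint_tsv", "generic_tsv"),
                                  specDelim = "|") {
  dialect <- match.arg(dialect)
  rec <- interactions(screen)
  spec <- joinSpecStrings(rec$replicate_specs, specDelim)
  out <- if (dialect == "saint_tsv") {
    data.frame(Bait = rec$bait, PreyGene = rec$prey, CellLine = rec$cell_line,
               Spec = spec, AvgSpec = rec$avg_spec, AvgP = rec$avg_p)
  } else {
    data.frame(bait = rec$bait, prey = rec$prey, cell_line = rec$cell_line,
               replicate_specs = spec, avg_spec = rec$avg_spec,
               avg_p = rec$avg_p)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard physical-interaction edge list
#'
#' Reads a BioGRID-style tab-delimited edge file. Symbol columns named
#' `Official Symbol Interactor A`/`B` are used when present, otherwise the
#' first two columns. Symmetric duplicates are collapsed. When `baitSubset`
#' is given, edges are oriented so the subset member is the bait and edges
#' touching no subset member are dropped.
#'
#' @param path path to the edge file.
#' @param baitSubset bait ids used for calibration (e.g.
#'   `c("ARF1", "ARF6", "SAR1A", "SAR1B")`).
#' @param sourceTag provenance label stored with the edges.
#' @return A [GoldStandard-class].
#' @export
readGoldStandard <- function(path, baitSubset = character(),
                             sourceTag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("edge file must have two identifier columns")
  ca <- grep("Official Symbol Interactor A", names(raw), fixed = TRUE)
  cb <- grep("Official Symbol Interactor B", names(raw), fixed = TRUE)
  a <- if (length(ca)) raw[[ca[1]]] else raw[[1]]
  b <- if (length(cb)) raw[[cb[1]]] else raw[[2]]
  edges <- data.frame(bait = a, prey = b, stringsAsFactors = FALSE)
  if (length(baitSubset)) {
    keep_a <- edges$bait %in% baitSubset
    keep_b <- edges$prey %in% baitSubset
    oriented <- rbind(edges[keep_a, ],
                      data.frame(bait = edges$prey[keep_b],
                                 prey = edges$bait[keep_b]))
    oriented <- oriented[oriented$bait != oriented$prey, ]
    edges <- unique(oriented)
    if (!nrow(edges))
      stop("no gold-standard edges match the requested baits; calibration ",
           "is usually restricted to well-characterized baits such as ",
           "ARF1, ARF6, SAR1A and SAR1B")
    baitSubset <- intersect(baitSubset, edges$bait)
  } else {
    # collapse symmetric duplicates keeping the first orientation seen
    key <- vapply(seq_len(nrow(edges)), function(i)
      paste(sort(c(edges$bait[i], edges$prey[i])), collapse = "\r"),
      character(1))
    edges <- edges[!duplicated(key), ]
  }
  GoldStandard(edges, sourceTag = sourceTag, baitSubset = baitSubset)
}

#' Read compartment marker sets from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are deduplicated per compartment.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (the compartment atlas).
#' @export
readMarkerSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  atlas <- lapply(fgsea::gmtPathways(path), unique)
  if (anyDuplicated(names(atlas)))
    stop("duplicated compartment name: ",
         names(atlas)[duplicated(names(atlas))][1])
  if (any(lengths(atlas) == 0)) stop("empty marker set in GMT")
  atlas
}

#' Read a one-column annotation list (GAPs, GEFs, extra contaminants)
#'
#' @param path text file; first tab-delimited field of each non-empty,
#'   non-comment (`#`) line is taken as an identifier.
#' @return character vector of unique ids.
#' @export
readAnnotationList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1))
}

#' Write a filtered interaction set as a network file
#'
#' @param records data.frame with columns `bait` and `prey` (additional
#'   columns are carried into `edge_tsv` output).
#' @param path output path.
#' @param format `"edge_tsv"` (full table) or `"sif"` (Cytoscape SIF; the
#'   relation is `proximity`).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(records, path, format = c("edge_tsv", "sif")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (!nrow(records)) {
    warning("writing an empty network")
    if (format == "edge_tsv")
      utils::write.table(records[, intersect(c("bait", "prey"), names(records)),
                                 drop = FALSE],
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    else writeLines(character(), path)
    return(invisible(path))
  }
  if (format == "edge_tsv") {
    drop <- vapply(records, is.list, logical(1))
    utils::write.table(records[, !drop, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(records$bait, "proximity", records$prey), path)
  }
  invisible(path)
}

#' Write a dot-plot table of scored interactions
#'
#' Long-format TSV with, per bait x prey (and cell line when present), the
#' average spectral count, the relative abundance (AvgSpec divided by the
#' maximum AvgSpec of that prey over all baits) and the average probability.
#' Pairs absent from the table are omitted, not zero-filled.
#'
#' @param scored data.frame with `bait`, `prey`, `avg_spec`, `avg_p` and
#'   optionally `cell_line`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDotplotTable <- function(scored, path) {
  scored <- as.data.frame(scored)
  grp <- if ("cell_line" %in% names(scored))
    paste(scored$prey, scored$cell_line, sep = "\r") else scored$prey
  mx <- stats::ave(scored$avg_spec, grp, FUN = max)
  rel <- ifelse(mx > 0, scored$avg_spec / mx, 0)
  out <- data.frame(bait = scored$bait, prey = scored$prey)
  if ("cell_line" %in% names(scored)) out$cell_line <- scored$cell_line
  out$AvgSpec <- scored$avg_spec
  out$relative_abundance <- rel
  out$AvgP <- scored$avg_p
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
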