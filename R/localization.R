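#' Overlap distances between a prey set and compartment marker sets
#'
#' For each compartment, distance = 1 - |preys intersect markers| /
#' min(|preys|, |markers|) (the overlap-coefficient distance). Compartments
#' are ranked by ascending distance with alphabetical tie-breaking. This is
#' a locally reproducible surrogate for database-side "shortest distance"
#' localization scoring; downstream calls carry a surrogate flag.
#'
#' @param preySet character vector of prey symbols (nonempty).
#' @param atlas named list of marker sets from [readMarkerSets()].
#' @return data.frame(compartment, distance) sorted ascending.
#' @export
compartmentDistances <- function(preySet, atlas) {
  preySet <- unique(as.character(preySet))
  if (!length(preySet)) stop("empty prey set")
  if (!length(atlas)) stop("empty compartment atlas")
  d <- vapply(atlas, function(markers) {
    ov <- length(intersect(preySet, markers))
    1 - ov / min(length(preySet), length(markers))
  }, numeric(1))
  if (all(d >= 1 - 1e-12))
    warning("prey set overlaps no compartment marker set")
  out <- data.frame(compartment = names(d), distance = unname(d))
  out <- out[order(out$distance, out$compartment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report the top compartments of a ranked distance list
#'
#' Reports the top three compartments, extended to four when the third and
#' fourth distances tie (within 1e-12). Atlases with fewer than three
#' compartments are reported in full with a warning.
#'
#' @param ranked output of [compartmentDistances()].
#' @return data.frame(rank, compartment, distance).
#' @export
assignTop <- function(ranked) {
  n <- nrow(ranked)
  if (n < 3) {
    warning("fewer than three compartments available; reporting all")
    take <- n
  } else {
    take <- 3
    if (n >= 4 && abs(ranked$distance[4] - ranked$distance[3]) <= 1e-12)
      take <- 4
  }
  out <- ranked[seq_len(take), , drop = FALSE]
  out <- cbind(rank = seq_len(take), out)
  rownames(out) <- NULL
  out
}

#' Assign top subcellular compartments to every bait
#'
#' Collapses each bait's filtered prey set (across cell lines) and ranks
#' compartments by the overlap-coefficient distance, reporting the top three
#' (four on a tie).
#'
#' @param filtered filtered interaction records with `bait` and `prey`.
#' @param atlas named list of marker sets.
#' @return data.frame(bait, rank, compartment, distance, surrogate_flag).
#' @export
localizeBaits <- function(filtered, atlas) {
  filtered <- as.data.frame(filtered)
  out <- lapply(sort(unique(filtered$bait)), function(b) {
    preys <- unique(filtered$prey[filtered$bait == b])
    top <- assignTop(compartmentDistances(preys, atlas))
    cbind(bait = b, top, surrogate_flag = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
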