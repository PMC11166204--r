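#' Run the pipeline from a declarative YAML configuration
#'
#' Reads a YAML file describing the inputs and thresholds and calls
#' [runPipeline()]. Recognized keys:
#' \preformatted{
#' inputs:              # one entry per cell line
#'   HEK293: {path: hek.tsv, dialect: saint_tsv}
#'   HeLa:   {path: hela.tsv, dialect: saint_tsv}
#' control_baits: {empty_vector: CTRL_EMPTY, gfp: CTRL_GFP, caax: CTRL_CAAX}
#' filter:
#'   avg_p_min: 0.95
#'   avg_spec_min: {HEK293: 4.5, HeLa: 6}
#'   caax_ratio_min: 1.7
#'   blocklist_extra: [MYCONTAM]
#' atlas_gmt: markers.gmt        # optional
#' gap_list: gaps.txt            # optional
#' gef_list: gefs.txt            # optional
#' k_range: [2, 20]
#' qc_threshold: 0.9
#' out_dir: results/
#' }
#'
#' @param path path to the YAML configuration.
#' @return the pipeline report list, invisibly.
#' @export
runPipelineFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$inputs) || !length(cfg$inputs))
    stop("config must list at least one input table under 'inputs'")
  if (is.null(cfg$out_dir)) stop("config must set 'out_dir'")
  cb <- unlist(cfg$control_baits)
  screens <- lapply(names(cfg$inputs), function(cl) {
    inp <- cfg$inputs[[cl]]
    readInteractionTable(inp$path,
                         dialect = if (is.null(inp$dialect)) "saint_tsv"
                                   else inp$dialect,
                         controlBaits = cb, cellLine = cl)
  })
  rec <- do.call(rbind, lapply(screens, interactions))
  screen <- BioidScreen(rec, controlBaits = cb)

  f <- cfg$filter
  fc <- FilterConfig(
    avgPMin = if (is.null(f$avg_p_min)) 0.95 else f$avg_p_min,
    avgSpecMin = if (is.null(f$avg_spec_min)) c(HEK293 = 4.5, HeLa = 6)
                 else unlist(f$avg_spec_min),
    caaxRatioMin = if (is.null(f$caax_ratio_min)) 1.7 else f$caax_ratio_min,
    blocklist = c(defaultBlocklist(), unlist(f$blocklist_extra)))

  atlas <- if (!is.null(cfg$atlas_gmt)) readMarkerSets(cfg$atlas_gmt)
  gaps <- if (!is.null(cfg$gap_list)) readAnnotationList(cfg$gap_list)
          else character()
  gefs <- if (!is.null(cfg$gef_list)) readAnnotationList(cfg$gef_list)
          else character()
  kr <- if (is.null(cfg$k_range)) 2:20 else seq(cfg$k_range[1], cfg$k_range[2])
  runPipeline(screen, cfg$out_dir, filterConfig = fc, atlas = atlas,
              gapIds = gaps, gefIds = gefs, kRange = kr,
              qcThreshold = if (is.null(cfg$qc_threshold)) 0.9
                            else cfg$qc_threshold)
}
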