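# internal helpers shared across modules

# parse "4|6"-style replicate count strings into integer vectors; empty or NA
# strings become NULL (no replicate-level data for that row)
parseSpecStrings <- function(x, delim = "|") {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- strsplit(s, delim, fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) stop("non-numeric replicate spectral count: '", s, "'")
    v
  })
}

joinSpecStrings <- function(x, delim = "|") {
  vapply(x, function(v) {
    if (is.null(v) || !length(v)) "" else paste(v, collapse = delim)
  }, character(1))
}

# strict locale-independent numeric parsing: decimal point only, no
# thousands separators
parseNumeric <- function(x, column) {
  x <- as.character(x)
  bad <- grepl(",", x, fixed = TRUE)
  v <- suppressWarnings(as.numeric(x))
  bad <- bad | (is.na(v) & !is.na(x) & nzchar(x))
  if (any(bad))
    stop("column '", column, "' contains unparseable numbers (row ",
         which(bad)[1], "): '", x[which(bad)[1]], "'")
  v
}

pairKey <- function(bait, prey, cell_line = NULL) {
  if (is.null(cell_line)) paste(bait, prey, sep = "\r")
  else paste(bait, prey, cell_line, sep = "\r")
}
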