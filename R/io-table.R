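## Delimited variant-table exports -------------------------------------------
##
## Annotation platforms export one row per variant in .txt/.csv form with
## platform-specific headers. A ColumnMap declares, rather than sniffs, how
## those headers map onto the canonical variant model.

#' ColumnMap: declared mapping from canonical fields to source columns
#'
#' @slot mapping Named character vector: names are canonical field names
#'   ([canonicalVariantColumns()]), values are source column headers.
#'   `chrom`, `pos`, `ref`, `alt` and `gene` must be mapped; `patient_id`
#'   may instead be supplied to [readVariantTable()] as a constant.
#' @slot delimiter Field delimiter (default tab).
#' @slot header Whether the file carries a header row (default `TRUE`).
#' @export
setClass("ColumnMap",
         representation(mapping = "character", delimiter = "character",
                        header = "logical"))

setValidity("ColumnMap", function(object) {
  need <- c("chrom", "pos", "ref", "alt", "gene")
  missing <- setdiff(need, names(object@mapping))
  if (length(missing))
    return(sprintf("required fields unmapped: %s",
                   paste(missing, collapse = ", ")))
  unknown <- setdiff(names(object@mapping), canonicalVariantColumns())
  if (length(unknown))
    return(sprintf("unknown canonical fields in mapping: %s",
                   paste(unknown, collapse = ", ")))
  TRUE
})

#' Construct a ColumnMap
#'
#' @param mapping,delimiter,header see [ColumnMap-class].
#' @return A [ColumnMap-class].
#' @export
#' @examples
#' columnMap(c(chrom = "Chr", pos = "Position", ref = "Ref", alt = "Alt",
#'             gene = "Gene"), delimiter = ",")
columnMap <- function(mapping, delimiter = "\t", header = TRUE) {
  methods::new("ColumnMap", mapping = mapping, delimiter = delimiter,
               header = header)
}

#' Identity column map for canonical exports
#'
#' Maps every canonical column onto a source column of the same name — the
#' dialect written by [writeVariantTable()].
#'
#' @param delimiter field delimiter (default tab).
#' @return A [ColumnMap-class].
#' @export
defaultColumnMap <- function(delimiter = "\t") {
  cols <- canonicalVariantColumns()
  columnMap(stats::setNames(cols, cols), delimiter = delimiter)
}

setMethod("show", "ColumnMap", function(object) {
  cat(sprintf("ColumnMap: %d mapped field(s), delimiter '%s'\n",
              length(object@mapping),
              gsub("\t", "\\\\t", object@delimiter)))
})

#' Read a delimited variant-table export
#'
#' Reads a platform `.txt`/`.csv` export using a declared [ColumnMap-class]
#' and returns the normalized variant table. Unmapped optional fields
#' default to absent. Numeric cells that fail to parse (e.g. a frequency
#' written as `"0.5%"`) raise an error naming the row and cell; with
#' `permissive = TRUE` the offending rows are skipped with a warning
#' instead.
#'
#' @param path Path to the delimited file.
#' @param colmap A [ColumnMap-class].
#' @param patientId Constant patient identifier used when the file does not
#'   carry a patient column.
#' @param permissive Skip unparseable rows instead of failing
#'   (default `FALSE`).
#' @return An [AnnotatedVariants-class]; the `source_row` column retains
#'   each record's 1-based data-row index in the file.
#' @export
readVariantTable <- function(path, colmap = defaultColumnMap(),
                             patientId = NULL, permissive = FALSE) {
  stopifnot(methods::is(colmap, "ColumnMap"))
  if (!file.exists(path))
    stop("variant table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = colmap@delimiter,
                           header = colmap@header, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), comment.char = "",
                           quote = "\"")
  if (!colmap@header)
    names(raw) <- paste0("V", seq_along(raw))
  mapped <- colmap@mapping
  missing_src <- setdiff(unname(mapped), names(raw))
  if (length(missing_src))
    stop("mapped source column(s) not present in ", path, ": ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  df <- stats::setNames(raw[, unname(mapped), drop = FALSE], names(mapped))
  df$source_row <- seq_len(nrow(df))
  if (!"patient_id" %in% names(df)) {
    if (is.null(patientId))
      stop("no patient_id column mapped and no patientId supplied",
           call. = FALSE)
    df$patient_id <- patientId
  }

  ## numeric conversion with row-level diagnostics
  drop_rows <- integer(0)
  for (col in intersect(.numericColumns, names(df))) {
    x <- df[[col]]
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad)) {
      msg <- sprintf("row %d: cannot parse %s value '%s'",
                     df$source_row[bad[1]], col, x[bad[1]])
      if (!permissive) stop(msg, " in ", path, call. = FALSE)
      warning(msg, "; row(s) skipped", call. = FALSE)
      drop_rows <- union(drop_rows, bad)
    }
    df[[col]] <- val
  }
  if (length(drop_rows)) df <- df[-drop_rows, , drop = FALSE]
  AnnotatedVariants(df)
}

#' Write a variant table in the canonical dialect
#'
#' Writes every canonical column as tab-separated UTF-8 text readable back
#' with [defaultColumnMap()]; reading then writing preserves every mapped
#' field.
#'
#' @param variants An [AnnotatedVariants-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  df <- variantData(variants)[, canonicalVariantColumns(), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

## Virtual gene panels --------------------------------------------------------

#' Read virtual gene panel files
#'
#' Each panel file lists one gene symbol per line; `#` starts a comment and
#' blank lines are ignored. Symbols are upper-cased and deduplicated. An
#' empty panel file yields an empty set with a warning.
#'
#' @param paths Named character vector of file paths; names become panel
#'   names.
#' @return A [PanelSet-class].
#' @export
#' @examples
#' f <- tempfile(); writeLines(c("BRCA1", "brca2", "# comment"), f)
#' readPanels(c(hereditary_cancer = f))
readPanels <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("panel paths must be named by panel", call. = FALSE)
  panels <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (!file.exists(p))
      stop("panel file not found: ", p, call. = FALSE)
    lines <- readLines(p, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    genes <- unique(toupper(lines[nzchar(lines)]))
    if (!length(genes))
      warning("panel file is empty: ", p, call. = FALSE)
    genes
  })
  names(panels) <- names(paths)
  PanelSet(panels)
}

#' Bundled illustrative mini-panels
#'
#' Loads the six ~20-gene illustrative panels shipped with the package
#' (cardiovascular, hereditary cancer, neurodegenerative/psychiatric,
#' diabetes, immune, ACMG59 secondary-findings genes). These are compact
#' teaching/testing subsets of what a clinical lab would curate, chosen to
#' include every gene used by the bundled worked examples; they are not
#' exhaustive clinical panels.
#'
#' @return A [PanelSet-class] with six panels.
#' @export
#' @examples
#' panelNames(miniPanels())
miniPanels <- function() {
  dir <- system.file("extdata", "panels", package = "VariantTriage")
  names <- c("cardiovascular", "hereditary_cancer", "neuro_psychiatric",
             "diabetes", "immune", "acmg59")
  paths <- stats::setNames(file.path(dir, paste0(names, ".txt")), names)
  readPanels(paths)
}
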