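## YAML run configuration -----------------------------------------------------
##
## One YAML file carries the whole run: input location and column map, panel
## paths, quality thresholds, tier settings and report options. Unknown keys
## are rejected rather than silently ignored, so a typo in a threshold name
## cannot slip through as a default.

.allowedConfigKeys <- list(
  top = c("input", "thresholds", "panels", "tier_a", "tier_b", "tier_c",
          "report", "output_dir", "log_level", "seed"),
  input = c("path", "format", "delimiter", "patient_id", "column_map",
            "permissive"),
  thresholds = c("min_qual", "min_depth", "min_qd", "min_callers",
                 "het_min_fraction", "hom_min_fraction"),
  tier_a = c("max_af_carrier", "keep_rare"),
  tier_b = c("pm2_max_af", "ba1_min_af", "bs1_min_af", "lof_genes_path",
             "min_available", "min_damaging_fraction"),
  tier_c = c("max_af", "lof_consequences", "require_region",
             "penetrance_genes_path"),
  report = c("high_confidence_only")
)

.checkKeys <- function(block, section) {
  unknown <- setdiff(names(block), .allowedConfigKeys[[section]])
  if (length(unknown))
    stop("unknown configuration key(s) in '", section, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
}

.readGeneList <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  unique(toupper(lines[nzchar(lines)]))
}

#' Read and validate a YAML run configuration
#'
#' Parses a run configuration with sections `input`, `thresholds`,
#' `panels`, `tier_a`, `tier_b`, `tier_c` and `report`; every key is
#' validated against the known vocabulary and unknown keys raise an error.
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `config` (a [TriageConfig-class]),
#'   `input` (path, format, column map, patient id, permissive flag),
#'   `panel_paths` (named character vector), `output_dir`, `log_level` and
#'   `seed`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  .checkKeys(raw, "top")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }

  th <- raw$thresholds
  .checkKeys(th, "thresholds")
  quality <- qualityThresholds(
    minQual = th$min_qual %||% 100, minDepth = th$min_depth %||% 10,
    minQd = th$min_qd %||% 10, minCallers = th$min_callers %||% 2,
    hetMinFraction = th$het_min_fraction %||% 0.25,
    homMinFraction = th$hom_min_fraction %||% 0.75)

  ta <- raw$tier_a; .checkKeys(ta, "tier_a")
  tb <- raw$tier_b; .checkKeys(tb, "tier_b")
  tc <- raw$tier_c; .checkKeys(tc, "tier_c")
  rp <- raw$report; .checkKeys(rp, "report")

  consensus <- consensusConfig(
    minAvailable = tb$min_available %||% 3,
    minDamagingFraction = tb$min_damaging_fraction %||% NA_real_)
  vus <- vusConfig(
    lofConsequences = unlist(tc$lof_consequences) %||%
      c("nonsense", "frameshift", "splice_donor", "splice_acceptor"),
    maxAf = tc$max_af %||% 0.001,
    penetranceGenes = if (!is.null(tc$penetrance_genes_path))
      .readGeneList(resolve(tc$penetrance_genes_path)) else character(0),
    requireRegion = unlist(tc$require_region) %||%
      c("exonic", "splice_site"))
  lofGenes <- if (!is.null(tb$lof_genes_path))
    .readGeneList(resolve(tb$lof_genes_path)) else character(0)

  config <- triageConfig(
    quality = quality, consensus = consensus, vus = vus,
    maxAfCarrier = ta$max_af_carrier %||% 0.05,
    carrierKeepRare = ta$keep_rare %||% TRUE,
    pm2MaxAf = tb$pm2_max_af %||% 1e-4,
    ba1MinAf = tb$ba1_min_af %||% 0.05,
    bs1MinAf = tb$bs1_min_af %||% 0.01,
    lofGenes = lofGenes,
    highConfidenceOnly = rp$high_confidence_only %||% FALSE)

  input <- NULL
  if (!is.null(raw$input)) {
    .checkKeys(raw$input, "input")
    cm <- raw$input$column_map
    colmap <- if (is.null(cm)) {
      defaultColumnMap(delimiter = raw$input$delimiter %||% "\t")
    } else {
      columnMap(unlist(cm), delimiter = raw$input$delimiter %||% "\t")
    }
    input <- list(path = resolve(raw$input$path),
                  format = raw$input$format %||% "table",
                  colmap = colmap,
                  patient_id = raw$input$patient_id,
                  permissive = isTRUE(raw$input$permissive))
  }

  panel_paths <- NULL
  if (!is.null(raw$panels)) {
    panel_paths <- vapply(raw$panels, function(p) resolve(p), character(1))
    names(panel_paths) <- names(raw$panels)
  }

  list(config = config, input = input, panel_paths = panel_paths,
       output_dir = resolve(raw$output_dir) %||% ".",
       log_level = raw$log_level %||% "info",
       seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
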