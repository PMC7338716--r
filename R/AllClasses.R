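## ---------------------------------------------------------------------------
## Controlled vocabularies shared across the package
## ---------------------------------------------------------------------------

#' Controlled vocabularies used by the variant model
#'
#' Canonical value sets for the enum-like character columns of an
#' [AnnotatedVariants] table: functional consequence, genomic region,
#' zygosity, PharmGKB clinical-annotation level, inheritance mode and the
#' analyst override flag.
#'
#' @return A named list of character vectors.
#' @export
#' @examples
#' variantVocabularies()$consequence
variantVocabularies <- function() {
  list(
    consequence = c("nonsense", "frameshift", "missense", "splice_donor",
                    "splice_acceptor", "synonymous", "inframe_indel",
                    "intronic", "utr5", "utr3", "other"),
    region = c("exonic", "splice_site", "intronic", "utr", "intergenic"),
    zygosity = c("het", "hom", "low_fraction", "unknown"),
    pharmgkb_level = c("1A", "1B", "2A", "2B", "3", "4", "none"),
    inheritance = c("AD", "AR", "XL", "other", "unknown"),
    analyst_override = c("none", "include", "exclude")
  )
}

## canonical column model for a variant table -------------------------------

.requiredColumns <- c("patient_id", "chrom", "pos", "ref", "alt", "gene")

.characterColumns <- c(
  "patient_id", "chrom", "ref", "alt", "gene", "hgvs_c", "hgvs_p", "rsid",
  "consequence", "region", "zygosity", "clinvar", "callers",
  "mutation_taster_call", "sift_call", "polyphen2_call",
  "mutation_assessor_call", "fathmm_call",
  "pharmgkb_level", "inheritance", "analyst_override", "reference_note"
)

.numericColumns <- c(
  "pos", "qual", "depth", "qd", "alt_fraction",
  "af_g1000", "af_exac", "af_esp5400", "odds_ratio",
  "sift_score", "polyphen2_score", "mutation_taster_score",
  "mutation_assessor_score", "fathmm_score", "dbscsnv_ada_score",
  "gerp_score", "genocanyon_score", "fitcons_score"
)

#' Canonical column names of a normalized variant table
#'
#' @return Character vector of all canonical column names, required ones
#'   first.
#' @export
canonicalVariantColumns <- function() {
  unique(c(.requiredColumns, .characterColumns, .numericColumns))
}

## ---------------------------------------------------------------------------
## AnnotatedVariants
## ---------------------------------------------------------------------------

#' AnnotatedVariants: a normalized table of annotated germline variants
#'
#' One row per (patient, allele). The constructor fills every missing
#' optional canonical column (character columns with `NA` or their neutral
#' vocabulary value, numeric columns with `NA_real_`) so downstream tier
#' logic can rely on the full schema. Coordinates are 1-based (VCF
#' convention) on GRCh37/hg19; the build label is metadata and never
#' validated against a reference.
#'
#' @slot data A `data.frame` holding the canonical columns (see
#'   [canonicalVariantColumns()]).
#'
#' @export
setClass("AnnotatedVariants", representation(data = "data.frame"))

setValidity("AnnotatedVariants", function(object) {
  df <- object@data
  msgs <- character(0)
  missing <- setdiff(canonicalVariantColumns(), names(df))
  if (length(missing))
    return(sprintf("missing canonical columns: %s",
                   paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (anyNA(df$pos) || any(df$pos < 1))
      msgs <- c(msgs, "pos must be >= 1 and non-missing")
    bad <- !is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt
    if (any(bad))
      msgs <- c(msgs, sprintf("ref == alt in row(s) %s",
                              paste(utils::head(which(bad), 5), collapse = ", ")))
    for (col in c("af_g1000", "af_exac", "af_esp5400", "alt_fraction")) {
      x <- df[[col]]
      if (any(!is.na(x) & (x < 0 | x > 1)))
        msgs <- c(msgs, sprintf("%s outside [0, 1]", col))
    }
    vocab <- variantVocabularies()
    for (col in names(vocab)) {
      x <- df[[col]]
      bad <- !is.na(x) & !(x %in% vocab[[col]])
      if (any(bad))
        msgs <- c(msgs, sprintf("invalid %s value(s): %s", col,
                                paste(unique(x[bad]), collapse = ", ")))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an AnnotatedVariants object
#'
#' @param data A `data.frame` with at least the required columns
#'   `patient_id`, `chrom`, `pos`, `ref`, `alt`, `gene`. Optional canonical
#'   columns are completed; extra columns are preserved.
#'
#' @return An [AnnotatedVariants-class] object.
#' @export
#' @examples
#' av <- AnnotatedVariants(data.frame(
#'   patient_id = "P1", chrom = "7", pos = 117559590,
#'   ref = "T", alt = "G", gene = "CFTR"))
#' length(av)
AnnotatedVariants <- function(data = data.frame()) {
  stopifnot(is.data.frame(data))
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(df)) {
    missing_req <- setdiff(.requiredColumns, names(df))
    if (length(missing_req))
      stop("required variant columns missing: ",
           paste(missing_req, collapse = ", "), call. = FALSE)
  }
  for (col in .characterColumns) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
    df[[col]] <- as.character(df[[col]])
  }
  for (col in .numericColumns) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
    df[[col]] <- as.numeric(df[[col]])
  }
  ## neutral defaults for enum columns that have an explicit "unknown" value
  df$zygosity[is.na(df$zygosity)] <- "unknown"
  df$pharmgkb_level[is.na(df$pharmgkb_level)] <- "none"
  df$inheritance[is.na(df$inheritance)] <- "unknown"
  df$analyst_override[is.na(df$analyst_override)] <- "none"
  df$consequence[is.na(df$consequence)] <- "other"
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df$gene <- toupper(df$gene)
  df <- df[c(canonicalVariantColumns(),
             setdiff(names(df), canonicalVariantColumns()))]
  rownames(df) <- NULL
  methods::new("AnnotatedVariants", data = df)
}

#' @describeIn AnnotatedVariants Number of variant records.
#' @param x An `AnnotatedVariants` object.
#' @export
setMethod("length", "AnnotatedVariants", function(x) nrow(x@data))

#' Extract the underlying variant data.frame
#'
#' @param x An [AnnotatedVariants-class] object.
#' @return The canonical `data.frame`.
#' @export
variantData <- function(x) {
  stopifnot(methods::is(x, "AnnotatedVariants"))
  x@data
}

#' @export
#' @describeIn AnnotatedVariants Coerce to `data.frame`.
#' @param row.names,optional,... passed on for S3 compatibility (unused).
as.data.frame.AnnotatedVariants <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  x@data
}

setMethod("show", "AnnotatedVariants", function(object) {
  df <- object@data
  cat(sprintf("AnnotatedVariants with %d record(s), %d patient(s)\n",
              nrow(df), length(unique(df$patient_id))))
  if (nrow(df)) {
    shown <- utils::head(df[, c("patient_id", "chrom", "pos", "ref", "alt",
                                "gene", "consequence", "clinvar")], 6)
    print(shown)
    if (nrow(df) > 6) cat("...\n")
  }
})

#' @describeIn AnnotatedVariants Subset records by row index or logical mask.
#' @param i row index.
#' @param j,drop unused.
#' @export
setMethod("[", "AnnotatedVariants", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, data = x@data[i, , drop = FALSE])
})

## per-record key used to merge tier hits and truth tables
variantKey <- function(df) {
  paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

## ---------------------------------------------------------------------------
## PanelSet
## ---------------------------------------------------------------------------

#' PanelSet: named virtual gene panels
#'
#' A virtual gene panel is an in-silico restriction of exome/genome variants
#' to a curated gene list, applied after sequencing. The canonical panel
#' names are `cardiovascular`, `hereditary_cancer`, `neuro_psychiatric`,
#' `diabetes`, `immune` and `acmg59`; additional panels are allowed and
#' panels may overlap.
#'
#' @slot panels Named list of upper-case gene-symbol character vectors.
#' @export
setClass("PanelSet", representation(panels = "list"))

setValidity("PanelSet", function(object) {
  p <- object@panels
  if (length(p) && (is.null(names(p)) || any(!nzchar(names(p)))))
    return("every panel must be named")
  for (nm in names(p)) {
    g <- p[[nm]]
    if (!is.character(g))
      return(sprintf("panel '%s' is not a character vector", nm))
    if (any(!nzchar(g)) || anyNA(g))
      return(sprintf("panel '%s' contains empty gene symbols", nm))
    if (any(g != toupper(g)))
      return(sprintf("panel '%s' contains non-upper-case symbols", nm))
  }
  TRUE
})

#' Construct a PanelSet
#'
#' @param panels Named list of character vectors of gene symbols; symbols
#'   are upper-cased and deduplicated.
#' @return A [PanelSet-class].
#' @export
#' @examples
#' ps <- PanelSet(list(cardiovascular = c("KCNQ1", "scn5a")))
#' panelGenes(ps, "cardiovascular")
PanelSet <- function(panels = list()) {
  panels <- lapply(panels, function(g) sort(unique(toupper(trimws(g)))))
  methods::new("PanelSet", panels = panels)
}

#' @describeIn PanelSet Number of panels.
#' @param x A `PanelSet`.
#' @export
setMethod("length", "PanelSet", function(x) length(x@panels))

#' Panel names of a PanelSet
#' @param x A [PanelSet-class].
#' @return Character vector of panel names.
#' @export
panelNames <- function(x) names(x@panels)

#' Genes of one panel, or the union over all panels
#'
#' @param x A [PanelSet-class].
#' @param name Panel name; `NULL` returns the union of all panels.
#' @return Character vector of gene symbols.
#' @export
panelGenes <- function(x, name = NULL) {
  stopifnot(methods::is(x, "PanelSet"))
  if (is.null(name)) return(sort(unique(unlist(x@panels, use.names = FALSE))))
  if (!name %in% names(x@panels))
    stop("no panel named '", name, "'", call. = FALSE)
  x@panels[[name]]
}

setMethod("show", "PanelSet", function(object) {
  cat(sprintf("PanelSet with %d panel(s)\n", length(object@panels)))
  for (nm in names(object@panels))
    cat(sprintf("  %-18s %d genes\n", nm, length(object@panels[[nm]])))
})

## ---------------------------------------------------------------------------
## QualityThresholds
## ---------------------------------------------------------------------------

#' QualityThresholds: retention rules for the high-confidence pass
#'
#' High-confidence retention requires quality score > `minQual`, read depth
#' > `minDepth`, quality-by-depth > `minQd` (all strict, as the protocol
#' states them) and detection by at least `minCallers` distinct variant
#' callers. Alleles supported by more than `hetMinFraction` of the covering
#' reads are called heterozygous; at or above `homMinFraction` they are
#' called homozygous; at or below `hetMinFraction` they are flagged
#' `low_fraction`.
#'
#' @slot minQual exclusive variant quality threshold (default 100).
#' @slot minDepth exclusive read-depth threshold (default 10).
#' @slot minQd exclusive quality-by-depth threshold (default 10).
#' @slot minCallers minimum number of distinct callers (default 2).
#' @slot hetMinFraction exclusive lower alt-read fraction for het (0.25).
#' @slot homMinFraction inclusive lower alt-read fraction for hom (0.75).
#' @export
setClass("QualityThresholds",
         representation(minQual = "numeric", minDepth = "numeric",
                        minQd = "numeric", minCallers = "numeric",
                        hetMinFraction = "numeric",
                        homMinFraction = "numeric"))

setValidity("QualityThresholds", function(object) {
  if (object@hetMinFraction <= 0 ||
      object@hetMinFraction >= object@homMinFraction ||
      object@homMinFraction > 1)
    return("need 0 < hetMinFraction < homMinFraction <= 1")
  if (any(c(object@minQual, object@minDepth, object@minQd,
            object@minCallers) < 0))
    return("all minima must be >= 0")
  TRUE
})

#' Construct quality retention thresholds
#'
#' @param minQual,minDepth,minQd,minCallers,hetMinFraction,homMinFraction
#'   see [QualityThresholds-class].
#' @return A [QualityThresholds-class].
#' @export
#' @examples
#' qualityThresholds()
qualityThresholds <- function(minQual = 100, minDepth = 10, minQd = 10,
                              minCallers = 2, hetMinFraction = 0.25,
                              homMinFraction = 0.75) {
  methods::new("QualityThresholds", minQual = minQual, minDepth = minDepth,
               minQd = minQd, minCallers = minCallers,
               hetMinFraction = hetMinFraction,
               homMinFraction = homMinFraction)
}

setMethod("show", "QualityThresholds", function(object) {
  cat(sprintf(paste0("QualityThresholds: QUAL > %g, DP > %g, QD > %g, ",
                     ">= %g callers; het > %g, hom >= %g\n"),
              object@minQual, object@minDepth, object@minQd,
              object@minCallers, object@hetMinFraction,
              object@homMinFraction))
})

## ---------------------------------------------------------------------------
## ConsensusConfig
## ---------------------------------------------------------------------------

#' Default per-predictor damaging cutoffs
#'
#' One row per in-silico predictor: the canonical score column, an optional
#' categorical-call column (a call takes precedence over a score), the
#' damaging threshold and its direction, and the categorical calls counted
#' as damaging. Defaults follow each predictor's published cutoff: SIFT
#' < 0.05, PolyPhen-2 >= 0.446, MutationTaster call A/D, MutationAssessor
#' >= 1.9, FATHMM < -1.5, dbscSNV-Ada >= 0.6, GERP >= 2.0, GenoCanyon
#' >= 0.5, fitCons >= 0.4.
#'
#' @return A `data.frame` with columns `name`, `score_col`, `call_col`,
#'   `threshold`, `direction` (`"lt"` or `"ge"`), `damaging_calls`
#'   (comma-separated).
#' @export
defaultPredictorTable <- function() {
  data.frame(
    name = c("sift", "polyphen2", "mutation_taster", "mutation_assessor",
             "fathmm", "dbscsnv_ada", "gerp", "genocanyon", "fitcons"),
    score_col = c("sift_score", "polyphen2_score", "mutation_taster_score",
                  "mutation_assessor_score", "fathmm_score",
                  "dbscsnv_ada_score", "gerp_score", "genocanyon_score",
                  "fitcons_score"),
    call_col = c("sift_call", "polyphen2_call", "mutation_taster_call",
                 "mutation_assessor_call", "fathmm_call", NA, NA, NA, NA),
    threshold = c(0.05, 0.446, 0.5, 1.9, -1.5, 0.6, 2.0, 0.5, 0.4),
    direction = c("lt", "ge", "ge", "ge", "lt", "ge", "ge", "ge", "ge"),
    damaging_calls = c("D", "D,P", "A,D", "H,M", "D", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' ConsensusConfig: nine-predictor deleteriousness consensus settings
#'
#' @slot predictors per-predictor cutoff table, see
#'   [defaultPredictorTable()].
#' @slot minAvailable minimum number of predictors with a usable score or
#'   call; below it the verdict is `insufficient` (default 3).
#' @slot minDamagingFraction fraction of available predictors that must be
#'   damaging; `NA` (the default) means a strict majority
#'   (damaging > available / 2).
#' @export
setClass("ConsensusConfig",
         representation(predictors = "data.frame", minAvailable = "numeric",
                        minDamagingFraction = "numeric"))

setValidity("ConsensusConfig", function(object) {
  need <- c("name", "score_col", "call_col", "threshold", "direction",
            "damaging_calls")
  if (!all(need %in% names(object@predictors)))
    return("predictor table lacks required columns")
  if (!all(object@predictors$direction %in% c("lt", "ge")))
    return("predictor direction must be 'lt' or 'ge'")
  if (object@minAvailable < 1) return("minAvailable must be >= 1")
  f <- object@minDamagingFraction
  if (!is.na(f) && (f <= 0 || f > 1))
    return("minDamagingFraction must be in (0, 1]")
  TRUE
})

#' Construct a deleteriousness-consensus configuration
#'
#' @param predictors per-predictor cutoff table
#'   (default [defaultPredictorTable()]).
#' @param minAvailable minimum available predictors (default 3).
#' @param minDamagingFraction damaging fraction cutoff; `NA` = strict
#'   majority.
#' @return A [ConsensusConfig-class].
#' @export
consensusConfig <- function(predictors = defaultPredictorTable(),
                            minAvailable = 3,
                            minDamagingFraction = NA_real_) {
  methods::new("ConsensusConfig", predictors = predictors,
               minAvailable = minAvailable,
               minDamagingFraction = as.numeric(minDamagingFraction))
}

setMethod("show", "ConsensusConfig", function(object) {
  frac <- if (is.na(object@minDamagingFraction)) "strict majority"
          else sprintf(">= %g of available", object@minDamagingFraction)
  cat(sprintf("ConsensusConfig: %d predictors, minAvailable = %g, rule: %s\n",
              nrow(object@predictors), object@minAvailable, frac))
})

## ---------------------------------------------------------------------------
## VusConfig
## ---------------------------------------------------------------------------

#' VusConfig: third-tier loss-of-function VUS selection settings
#'
#' @slot lofConsequences consequences counted as loss-of-function (default
#'   nonsense, frameshift, splice_donor, splice_acceptor; splice sites are
#'   the two canonical intronic bases each side).
#' @slot maxAf maximum population allele frequency (default 0.001); absent
#'   frequency passes.
#' @slot penetranceGenes medium/high-penetrance disease gene symbols; empty
#'   means "use the union of the supplied panels".
#' @slot requireRegion admissible genomic regions (default exonic,
#'   splice_site).
#' @export
setClass("VusConfig",
         representation(lofConsequences = "character", maxAf = "numeric",
                        penetranceGenes = "character",
                        requireRegion = "character"))

setValidity("VusConfig", function(object) {
  if (!length(object@lofConsequences))
    return("lofConsequences must be non-empty")
  if (object@maxAf <= 0 || object@maxAf > 1)
    return("maxAf must be in (0, 1]")
  TRUE
})

#' Construct a VUS-tier configuration
#'
#' @param lofConsequences,maxAf,penetranceGenes,requireRegion see
#'   [VusConfig-class].
#' @return A [VusConfig-class].
#' @export
vusConfig <- function(lofConsequences = c("nonsense", "frameshift",
                                          "splice_donor", "splice_acceptor"),
                      maxAf = 0.001, penetranceGenes = character(0),
                      requireRegion = c("exonic", "splice_site")) {
  methods::new("VusConfig", lofConsequences = lofConsequences, maxAf = maxAf,
               penetranceGenes = toupper(penetranceGenes),
               requireRegion = requireRegion)
}

## ---------------------------------------------------------------------------
## TriageConfig
## ---------------------------------------------------------------------------

#' TriageConfig: full run configuration for the triage pipeline
#'
#' @slot quality [QualityThresholds-class] retention rules.
#' @slot consensus [ConsensusConfig-class] predictor-consensus settings.
#' @slot vus [VusConfig-class] third-tier settings.
#' @slot maxAfCarrier carrier-status rarity cutoff on the maximum population
#'   allele frequency (default 0.05). Applies only to first-tier hits
#'   triggered by pathogenic/likely-pathogenic submissions.
#' @slot carrierKeepRare if `TRUE` (default) the rarity rule retains rare
#'   variants; `FALSE` inverts it (kept for the ambiguous reading of
#'   frequency "filtration").
#' @slot pm2MaxAf PM2 absent-from-controls cutoff (default 1e-4).
#' @slot ba1MinAf BA1 stand-alone benign frequency (default 0.05).
#' @slot bs1MinAf BS1 strong benign frequency (default 0.01).
#' @slot lofGenes genes with an established loss-of-function disease
#'   mechanism (PVS1 applies only there); empty means "union of the supplied
#'   panels".
#' @slot highConfidenceOnly if `TRUE`, reports are built from the
#'   high-confidence pass only (default `FALSE`: both passes are triaged and
#'   every hit carries its confidence label).
#' @export
setClass("TriageConfig",
         representation(quality = "QualityThresholds",
                        consensus = "ConsensusConfig",
                        vus = "VusConfig",
                        maxAfCarrier = "numeric",
                        carrierKeepRare = "logical",
                        pm2MaxAf = "numeric", ba1MinAf = "numeric",
                        bs1MinAf = "numeric", lofGenes = "character",
                        highConfidenceOnly = "logical"))

setValidity("TriageConfig", function(object) {
  for (s in c("maxAfCarrier", "pm2MaxAf", "ba1MinAf", "bs1MinAf")) {
    v <- methods::slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single frequency in [0, 1]", s))
  }
  TRUE
})

#' Construct a triage run configuration
#'
#' @param quality,consensus,vus,maxAfCarrier,carrierKeepRare,pm2MaxAf,ba1MinAf,bs1MinAf,lofGenes,highConfidenceOnly
#'   see [TriageConfig-class].
#' @return A [TriageConfig-class].
#' @export
#' @examples
#' triageConfig()
triageConfig <- function(quality = qualityThresholds(),
                         consensus = consensusConfig(),
                         vus = vusConfig(),
                         maxAfCarrier = 0.05, carrierKeepRare = TRUE,
                         pm2MaxAf = 1e-4, ba1MinAf = 0.05, bs1MinAf = 0.01,
                         lofGenes = character(0),
                         highConfidenceOnly = FALSE) {
  methods::new("TriageConfig", quality = quality, consensus = consensus,
               vus = vus, maxAfCarrier = maxAfCarrier,
               carrierKeepRare = carrierKeepRare, pm2MaxAf = pm2MaxAf,
               ba1MinAf = ba1MinAf, bs1MinAf = bs1MinAf,
               lofGenes = toupper(lofGenes),
               highConfidenceOnly = highConfidenceOnly)
}

setMethod("show", "TriageConfig", function(object) {
  cat("TriageConfig\n")
  cat("  carrier rarity cutoff:", object@maxAfCarrier, "\n")
  cat("  PM2/BA1/BS1 cutoffs:  ", object@pm2MaxAf, "/", object@ba1MinAf,
      "/", object@bs1MinAf, "\n")
  methods::show(object@quality)
  methods::show(object@consensus)
})

## ---------------------------------------------------------------------------
## CohortSpec
## ---------------------------------------------------------------------------

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' The defaults emulate the study conditions the pipeline was designed for:
#' a mean of four planted recessive pathogenic carrier variants per patient
#' (so that essentially every patient is a carrier of at least one), about a
#' third of patients carrying a level-1A/1B pharmacogenetic allele at common
#' frequency, a third carrying an actionable in-panel variant, a fifth
#' carrying a rare loss-of-function VUS, and a benign/common background of
#' 200 variants per patient with mixed quality.
#'
#' @slot nPatients number of patients (>= 1).
#' @slot seed RNG seed; a fixed seed yields byte-identical cohorts.
#' @slot lambdaCarrier Poisson mean of planted carrier variants (default 4).
#' @slot pPgx1a probability of a planted level-1A/1B pharmacogenetic allele
#'   (default 0.35).
#' @slot pPgxAnnex probability of a planted lower-level (2A/2B/3)
#'   pharmacogenetic allele, routed to the annex (default 0.4).
#' @slot pActionable probability of a planted actionable in-panel variant
#'   (default 0.33).
#' @slot pVusLof probability of a planted rare LoF VUS (default 0.2).
#' @slot nBackground benign-background variants per patient (default 200).
#' @slot fracLowQual,fracLowDepth,fracSingleCaller fractions of background
#'   records degraded below each quality threshold (default 0.1 each).
#' @export
setClass("CohortSpec",
         representation(nPatients = "numeric", seed = "numeric",
                        lambdaCarrier = "numeric", pPgx1a = "numeric",
                        pPgxAnnex = "numeric", pActionable = "numeric",
                        pVusLof = "numeric", nBackground = "numeric",
                        fracLowQual = "numeric", fracLowDepth = "numeric",
                        fracSingleCaller = "numeric"))

setValidity("CohortSpec", function(object) {
  if (object@nPatients < 1) return("nPatients must be >= 1")
  if (object@lambdaCarrier < 0) return("lambdaCarrier must be >= 0")
  probs <- c(object@pPgx1a, object@pPgxAnnex, object@pActionable,
             object@pVusLof, object@fracLowQual, object@fracLowDepth,
             object@fracSingleCaller)
  if (any(probs < 0 | probs > 1))
    return("probabilities must lie in [0, 1]")
  if (object@nBackground < 0) return("nBackground must be >= 0")
  TRUE
})

#' Construct a synthetic cohort specification
#'
#' @param nPatients,seed,lambdaCarrier,pPgx1a,pPgxAnnex,pActionable,pVusLof,nBackground,fracLowQual,fracLowDepth,fracSingleCaller
#'   see [CohortSpec-class].
#' @return A [CohortSpec-class].
#' @export
#' @examples
#' cohortSpec(nPatients = 5, seed = 1)
cohortSpec <- function(nPatients, seed = 1, lambdaCarrier = 4,
                       pPgx1a = 0.35, pPgxAnnex = 0.4, pActionable = 0.33,
                       pVusLof = 0.2, nBackground = 200,
                       fracLowQual = 0.1, fracLowDepth = 0.1,
                       fracSingleCaller = 0.1) {
  methods::new("CohortSpec", nPatients = nPatients, seed = seed,
               lambdaCarrier = lambdaCarrier, pPgx1a = pPgx1a,
               pPgxAnnex = pPgxAnnex, pActionable = pActionable,
               pVusLof = pVusLof, nBackground = nBackground,
               fracLowQual = fracLowQual, fracLowDepth = fracLowDepth,
               fracSingleCaller = fracSingleCaller)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d patient(s), seed %d; lambdaCarrier = ",
                     "%g, pPgx1a = %g, pActionable = %g, pVusLof = %g, ",
                     "%d background/patient\n"),
              object@nPatients, object@seed, object@lambdaCarrier,
              object@pPgx1a, object@pActionable, object@pVusLof,
              object@nBackground))
})
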