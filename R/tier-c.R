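## Tier C — rare loss-of-function VUS for the annex --------------------------
##
## The third filtering tier picks up nonsense/frameshift (and canonical
## splice-site) variants of uncertain significance at rare population
## frequency in medium/high-penetrance disease genes, and forwards them to
## the report annex without further interpretation, so their significance
## can be reassessed when their function is determined.

#' Is a variant of uncertain significance?
#'
#' A variant counts as a VUS when it has no ClinVar record at all, when its
#' signature carries no pathogenic / likely-pathogenic / benign /
#' likely-benign submissions, or when "Uncertain significance" is the
#' strict plurality class of the signature.
#'
#' @param x An [AnnotatedVariants-class] or canonical `data.frame`.
#' @return Logical vector, one value per record.
#' @export
#' @examples
#' av <- AnnotatedVariants(data.frame(
#'   patient_id = "P1", chrom = "8", pos = 90983443, ref = "T", alt = "C",
#'   gene = "NBN",
#'   clinvar = "Benign(3);Likely benign(1);Uncertain significance(11);Pathogenic(1);Risk factor(1)"))
#' isVus(av)
isVus <- function(x) {
  df <- if (methods::is(x, "AnnotatedVariants")) variantData(x) else x
  assessed <- c("Pathogenic", "Likely pathogenic", "Benign", "Likely benign")
  vapply(df$clinvar, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(TRUE)
    sig <- suppressWarnings(parseClinvarSignature(s))
    if (!any(names(sig) %in% assessed)) return(TRUE)
    us <- sig["Uncertain significance"]
    if (is.na(us)) return(FALSE)
    all(us > sig[setdiff(names(sig), "Uncertain significance")])
  }, logical(1), USE.NAMES = FALSE)
}

#' Third-tier (VUS-centric) loss-of-function selection
#'
#' Emits a hit for every VUS with a loss-of-function consequence in an
#' admissible region (exonic or canonical splice site), at rare population
#' frequency (at most `maxAf`, absent passes), in a medium/high-penetrance
#' gene. Hits are destined for the annex unconditionally.
#'
#' @param variants An [AnnotatedVariants-class].
#' @param config A [VusConfig-class]. An empty `penetranceGenes` slot means
#'   "restrict to `panels`" when a panel set is given, otherwise no gene
#'   restriction.
#' @param panels Optional [PanelSet-class] supplying the default
#'   penetrance-gene list.
#' @return A `data.frame` of hits with identification, `rules`
#'   (`TIER_C_LOF_VUS`) and `destination` (`"annex"`) columns.
#' @export
selectTierC <- function(variants, config = vusConfig(), panels = NULL) {
  stopifnot(methods::is(config, "VusConfig"))
  df <- variantData(variants)
  if (!nrow(df)) return(.emptyTierCHits())
  genes <- config@penetranceGenes
  if (!length(genes) && !is.null(panels)) genes <- panelGenes(panels)

  maxAf <- maxPopulationFrequency(df)
  ## a variant with any pathogenic-side submission belongs to tier A, never
  ## here, even when uncertainty is the plurality interpretation
  nPath <- .signatureClassCounts(df$clinvar,
                                 c("Pathogenic", "Likely pathogenic"))
  sel <- isVus(df) & nPath == 0 &
    df$consequence %in% config@lofConsequences &
    !is.na(df$region) & df$region %in% config@requireRegion &
    (is.na(maxAf) | maxAf <= config@maxAf)
  if (length(genes)) sel <- sel & df$gene %in% genes
  if (!any(sel)) return(.emptyTierCHits())

  sub <- df[sel, , drop = FALSE]
  data.frame(
    key = variantKey(sub),
    patient_id = sub$patient_id, chrom = sub$chrom, pos = sub$pos,
    ref = sub$ref, alt = sub$alt, gene = sub$gene,
    tier = "C",
    rules = "TIER_C_LOF_VUS",
    destination = "annex",
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.emptyTierCHits <- function() {
  data.frame(key = character(0), patient_id = character(0),
             chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), gene = character(0), tier = character(0),
             rules = character(0), destination = character(0),
             stringsAsFactors = FALSE)
}
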