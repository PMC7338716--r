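## Tier A — variant-centric ClinVar-term selection ---------------------------
##
## The first filtering tier selects variants whose ClinVar aggregate
## signature carries at least one qualifying submission: pathogenic, likely
## pathogenic, protective, risk factor or drug response. A single
## qualifying submission triggers candidacy even against a benign majority
## (the protocol reports such variants with a conflict flag). Carrier-status
## candidacy additionally applies a rarity filter that exempts hits
## triggered solely by risk-factor / protective / drug-response
## submissions, because common pharmacogenetic alleles must survive.

.tierAQualifying <- c("Pathogenic", "Likely pathogenic", "Protective",
                      "Risk factor", "Drug response")
.tierABenign <- c("Benign", "Likely benign")

.tierARule <- function(class) {
  paste0("TIER_A_CLINVAR_",
         toupper(gsub("[[:space:]]+", "_", class)))
}

#' Carrier-status rarity filter
#'
#' A pathogenic / likely-pathogenic first-tier hit is kept as a
#' carrier-status finding iff its maximum population allele frequency is at
#' most `maxAfCarrier`, or no source reports the allele. With
#' `keepRare = FALSE` the reading inverts (retain common instead).
#'
#' @param maxAf Numeric vector of maximum population allele frequencies
#'   (`NA` = not observed in any source).
#' @param maxAfCarrier Frequency cutoff (default 0.05).
#' @param keepRare Retain rare (default) or invert.
#' @return Logical vector: keep as carrier finding.
#' @export
#' @examples
#' carrierFrequencyFilter(c(0.001, 0.20, NA))
carrierFrequencyFilter <- function(maxAf, maxAfCarrier = 0.05,
                                   keepRare = TRUE) {
  if (keepRare) is.na(maxAf) | maxAf <= maxAfCarrier
  else is.na(maxAf) | maxAf > maxAfCarrier
}

#' First-tier (variant-centric) selection by ClinVar signature
#'
#' Emits a hit for every variant whose ClinVar aggregate signature contains
#' at least one submission in a qualifying class (pathogenic, likely
#' pathogenic, protective, risk factor, drug response). Selection depends
#' only on the signature; variants with benign-only signatures or no
#' signature are never selected. Each hit records which classes triggered
#' it, a benign-majority conflict flag, and whether it survives the
#' carrier-status rarity filter.
#'
#' @param variants An [AnnotatedVariants-class].
#' @param config A [TriageConfig-class] (only `maxAfCarrier` /
#'   `carrierKeepRare` are used here).
#' @return A `data.frame` of hits with columns `key`, `patient_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `tier` (`"A"`), `rules`
#'   (`;`-joined rule identifiers), `trigger_classes`, `n_qualifying`,
#'   `n_benign`, `conflict`, `pathogenic_trigger`,
#'   `drug_response_trigger`, `risk_or_protective_only` and
#'   `carrier_candidate`.
#' @export
selectTierA <- function(variants, config = triageConfig()) {
  df <- variantData(variants)
  n <- nrow(df)
  if (!n) return(.emptyTierAHits())

  sigs <- lapply(df$clinvar, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
    suppressWarnings(parseClinvarSignature(s))
  })
  trigger <- lapply(sigs, function(sig)
    intersect(.tierAQualifying, names(sig)[sig >= 1]))
  selected <- lengths(trigger) > 0
  if (!any(selected)) return(.emptyTierAHits())

  idx <- which(selected)
  sigs <- sigs[idx]
  trigger <- trigger[idx]
  sub <- df[idx, , drop = FALSE]

  n_qual <- vapply(sigs, function(sig)
    sum(sig[intersect(names(sig), .tierAQualifying)]), numeric(1))
  n_ben <- vapply(sigs, function(sig)
    sum(sig[intersect(names(sig), .tierABenign)]), numeric(1))
  path_trig <- vapply(trigger, function(tr)
    any(tr %in% c("Pathogenic", "Likely pathogenic")), logical(1))
  dr_trig <- vapply(trigger, function(tr)
    "Drug response" %in% tr, logical(1))
  rp_only <- vapply(trigger, function(tr)
    all(tr %in% c("Risk factor", "Protective")), logical(1))
  maxAf <- maxPopulationFrequency(sub)
  carrier <- path_trig &
    carrierFrequencyFilter(maxAf, config@maxAfCarrier,
                           config@carrierKeepRare)

  data.frame(
    key = variantKey(sub),
    patient_id = sub$patient_id, chrom = sub$chrom, pos = sub$pos,
    ref = sub$ref, alt = sub$alt, gene = sub$gene,
    tier = "A",
    rules = vapply(trigger, function(tr)
      paste(.tierARule(tr), collapse = ";"), character(1)),
    trigger_classes = vapply(trigger, paste, character(1), collapse = ","),
    n_qualifying = as.integer(n_qual),
    n_benign = as.integer(n_ben),
    conflict = n_ben > n_qual,
    pathogenic_trigger = path_trig,
    drug_response_trigger = dr_trig,
    risk_or_protective_only = rp_only,
    carrier_candidate = carrier,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.emptyTierAHits <- function() {
  data.frame(key = character(0), patient_id = character(0),
             chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), gene = character(0), tier = character(0),
             rules = character(0), trigger_classes = character(0),
             n_qualifying = integer(0), n_benign = integer(0),
             conflict = logical(0), pathogenic_trigger = logical(0),
             drug_response_trigger = logical(0),
             risk_or_protective_only = logical(0),
             carrier_candidate = logical(0), stringsAsFactors = FALSE)
}

#' Per-patient carrier summary
#'
#' Counts, per patient, the distinct carrier-status findings (first-tier
#' pathogenic / likely-pathogenic hits surviving the rarity filter);
#' duplicate rows for the same allele count once. A patient is a carrier
#' iff that count is at least one.
#'
#' @param hits A tier-A hit `data.frame` from [selectTierA()], or the
#'   merged hit table from [triageVariants()].
#' @param patients Optional character vector of patient identifiers to
#'   report (so non-carriers with zero hits appear in the denominator).
#' @return A `data.frame` with columns `patient_id`, `carrier`,
#'   `n_pathogenic`.
#' @export
carrierSummary <- function(hits, patients = NULL) {
  ch <- hits[hits$carrier_candidate %in% TRUE, , drop = FALSE]
  ## distinct alleles only: the same variant listed twice counts once
  akey <- paste(ch$patient_id, ch$chrom, ch$pos, ch$ref, ch$alt, sep = ":")
  ch <- ch[!duplicated(akey), , drop = FALSE]
  counts <- table(ch$patient_id)
  ids <- if (is.null(patients)) sort(unique(hits$patient_id))
         else unique(as.character(patients))
  n <- as.integer(counts[match(ids, names(counts))])
  n[is.na(n)] <- 0L
  data.frame(patient_id = ids, carrier = n >= 1, n_pathogenic = n,
             stringsAsFactors = FALSE, row.names = NULL)
}
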