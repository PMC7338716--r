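## End-to-end triage pipeline -------------------------------------------------
##
## Wires the dual quality pass, the three filtering tiers, category
## assignment and main/annex routing into one deterministic run. A variant
## hit by several tiers yields a single hit whose tier set, rule list and
## provenance are merged, so each variant is reported once.

## merge per-tier hit tables into one hit per variant key
.mergeTierHits <- function(a, b, c3) {
  keys <- unique(c(a$key, b$key, c3$key))
  if (!length(keys)) return(.emptyMergedHits())
  ia <- match(keys, a$key)
  ib <- match(keys, b$key)
  ic <- match(keys, c3$key)
  pick <- function(df, i, col, default) {
    out <- rep(default, length(keys))
    has <- !is.na(i)
    out[has] <- df[[col]][i[has]]
    out
  }
  first <- function(col) {
    out <- pick(a, ia, col, NA)
    miss <- is.na(out)
    out[miss] <- pick(b, ib, col, NA)[miss]
    miss <- is.na(out)
    out[miss] <- pick(c3, ic, col, NA)[miss]
    out
  }
  tiers <- vapply(seq_along(keys), function(j) {
    paste(c("A"[!is.na(ia[j])], "B"[!is.na(ib[j])], "C"[!is.na(ic[j])]),
          collapse = ",")
  }, character(1))
  rules <- vapply(seq_along(keys), function(j) {
    r <- c(if (!is.na(ia[j])) a$rules[ia[j]],
           if (!is.na(ib[j])) b$rules[ib[j]],
           if (!is.na(ic[j])) c3$rules[ic[j]])
    paste(r, collapse = ";")
  }, character(1))
  data.frame(
    key = keys,
    patient_id = first("patient_id"), chrom = first("chrom"),
    pos = as.numeric(first("pos")), ref = first("ref"),
    alt = first("alt"), gene = first("gene"),
    tiers = tiers, rules = rules,
    trigger_classes = pick(a, ia, "trigger_classes", NA_character_),
    n_qualifying = pick(a, ia, "n_qualifying", NA_integer_),
    n_benign = pick(a, ia, "n_benign", NA_integer_),
    conflict = pick(a, ia, "conflict", FALSE),
    pathogenic_trigger = pick(a, ia, "pathogenic_trigger", FALSE),
    drug_response_trigger = pick(a, ia, "drug_response_trigger", FALSE),
    risk_or_protective_only = pick(a, ia, "risk_or_protective_only", FALSE),
    carrier_candidate = pick(a, ia, "carrier_candidate", FALSE),
    panels = pick(b, ib, "panels", NA_character_),
    acmg_criteria = pick(b, ib, "acmg_criteria", NA_character_),
    acmg_class = pick(b, ib, "acmg_class", "not_assessed"),
    consensus = pick(b, ib, "consensus", NA_character_),
    vus_flag = pick(b, ib, "vus_flag", FALSE) | !is.na(ic),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.emptyMergedHits <- function() {
  df <- data.frame(key = character(0), patient_id = character(0),
                   chrom = character(0), pos = numeric(0),
                   ref = character(0), alt = character(0),
                   gene = character(0), tiers = character(0),
                   rules = character(0), trigger_classes = character(0),
                   n_qualifying = integer(0), n_benign = integer(0),
                   conflict = logical(0), pathogenic_trigger = logical(0),
                   drug_response_trigger = logical(0),
                   risk_or_protective_only = logical(0),
                   carrier_candidate = logical(0), panels = character(0),
                   acmg_criteria = character(0), acmg_class = character(0),
                   consensus = character(0), vus_flag = logical(0),
                   stringsAsFactors = FALSE)
  df
}

## annotation columns carried from the variant table onto hits
.hitAnnotationColumns <- c(
  "consequence", "region", "zygosity", "rsid", "hgvs_c", "hgvs_p",
  "clinvar", "af_g1000", "af_exac", "af_esp5400", "pharmgkb_level",
  "inheritance", "analyst_override", "odds_ratio", "reference_note",
  "confidence", "qual", "depth", "qd")

#' Run the three filtering tiers over a variant table
#'
#' Applies the dual all-variants / high-confidence quality pass, then the
#' variant-centric (A), gene-centric (B) and VUS-centric (C) tiers, merges
#' per-variant hits across tiers, assigns report categories, routes each
#' hit to the main report or the annex, and applies analyst overrides
#' (`exclude` drops a hit; `include` forces the main report). The result
#' is independent of input row order up to sorting.
#'
#' @param variants An [AnnotatedVariants-class].
#' @param panels A [PanelSet-class].
#' @param config A [TriageConfig-class].
#' @return A `data.frame` of routed hits, one row per selected variant,
#'   sorted by patient, category rank, gene and position, carrying full
#'   provenance (`tiers`, `rules`, `acmg_criteria`, `consensus`,
#'   `confidence`, `categories`, `destination`).
#' @export
triageVariants <- function(variants, panels, config = triageConfig()) {
  passes <- dualPass(variants, config@quality)
  scope <- if (config@highConfidenceOnly) passes$high_confidence
           else passes$all
  df <- variantData(scope)

  hitsA <- selectTierA(scope, config)
  hitsB <- selectTierB(scope, panels, config)
  hitsC <- selectTierC(scope, config@vus, panels)
  hits <- .mergeTierHits(hitsA, hitsB, hitsC)

  ## join annotation columns back by variant key
  i <- match(hits$key, variantKey(df))
  for (col in .hitAnnotationColumns)
    hits[[col]] <- df[[col]][i]

  hits <- hits[!(hits$analyst_override %in% "exclude"), , drop = FALSE]
  hits <- assignCategories(hits, panels)
  hits <- routeDestination(hits)
  ord <- order(hits$patient_id,
               vapply(splitTokens(hits$categories), function(cc) {
                 m <- match(cc, reportCategories())
                 if (!length(m) || all(is.na(m))) Inf else min(m, na.rm = TRUE)
               }, numeric(1)),
               hits$gene, hits$pos)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Run the full triage pipeline and build per-patient reports
#'
#' @param variants An [AnnotatedVariants-class] (typically from
#'   [readVariantTable()] or [readVcfVariants()]).
#' @param panels A [PanelSet-class] (e.g. [miniPanels()] or
#'   [readPanels()]).
#' @param config A [TriageConfig-class].
#' @return A list with `hits` (the routed hit table), `reports` (named
#'   list of `TriageReport`, one per patient present in the input) and
#'   `summary` (from [summarizeCohort()], `NULL` for an empty input).
#' @export
#' @examples
#' fix <- workedExampleFixture()
#' res <- runTriage(fix, miniPanels())
#' res$summary$n_patients
runTriage <- function(variants, panels, config = triageConfig()) {
  hits <- triageVariants(variants, panels, config)
  patients <- sort(unique(variantData(variants)$patient_id))
  reports <- lapply(patients, function(pid)
    buildReport(hits[hits$patient_id == pid, , drop = FALSE],
                patientId = pid, config = config, panels = panels))
  names(reports) <- patients
  summary <- if (length(reports)) summarizeCohort(reports) else NULL
  list(hits = hits, reports = reports, summary = summary)
}

#' Write the routed hit table as TSV
#'
#' Every row carries the rule identifiers that fired, sufficient to
#' recompute its selection by hand.
#'
#' @param hits Hit table from [triageVariants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTriageHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
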