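## Category assignment, main/annex routing, report construction --------------
##
## Every surviving hit is distributed into one or more fixed reporting
## categories and routed to either the concise main report (actionable,
## medium/high-penetrance findings and level-1A/1B pharmacogenetic
## annotations) or the tabulated annex (everything else, including every
## third-tier VUS). The split aims at the protocol's balance between
## under- and over-reporting.

#' Canonical report category vocabulary, in report order
#'
#' @return Character vector of category names.
#' @export
reportCategories <- function() {
  c("carrier_status", "cardiovascular", "hereditary_cancer",
    "pharmacogenetics", "acmg59", "immune", "diabetes", "neuro_psychiatric",
    "uncategorized_risks", "gwas")
}

## categories whose findings are main-report eligible (medium/high
## penetrance); pharmacogenetics routes by evidence level instead, and
## gwas / uncategorized findings stay in the annex
.mainEligibleCategories <- function() {
  c("carrier_status", "cardiovascular", "hereditary_cancer", "acmg59",
    "immune", "diabetes", "neuro_psychiatric")
}

#' Assign report categories to triage hits
#'
#' Category rules: `pharmacogenetics` for hits triggered by a drug-response
#' submission or carrying a PharmGKB level; `carrier_status` for
#' first-tier pathogenic / likely-pathogenic hits with recessive (or
#' unknown) inheritance that survive the rarity filter; each disease panel
#' containing the gene contributes its category, with `acmg59` co-assigned
#' on top; risk-factor-only hits with an attached effect size go to
#' `gwas`; anything left lands in `uncategorized_risks`. Assignment is
#' total: every hit receives at least one category.
#'
#' @param hits Merged hit `data.frame` from [triageVariants()].
#' @param panels A [PanelSet-class].
#' @return `hits` with a `categories` column (`,`-joined, in canonical
#'   order).
#' @export
assignCategories <- function(hits, panels) {
  stopifnot(methods::is(panels, "PanelSet"))
  if (!nrow(hits)) {
    hits$categories <- character(0)
    return(hits)
  }
  vocab <- reportCategories()
  panelCats <- intersect(panelNames(panels), setdiff(vocab, "acmg59"))
  cats <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    out <- character(0)
    if (isTRUE(h$drug_response_trigger) ||
        (!is.na(h$pharmgkb_level) && h$pharmgkb_level != "none"))
      out <- c(out, "pharmacogenetics")
    if (isTRUE(h$carrier_candidate) && h$inheritance %in% c("AR", "unknown"))
      out <- c(out, "carrier_status")
    for (p in panelCats)
      if (h$gene %in% panelGenes(panels, p)) out <- c(out, p)
    if ("acmg59" %in% panelNames(panels) &&
        h$gene %in% panelGenes(panels, "acmg59"))
      out <- c(out, "acmg59")
    if (isTRUE(h$risk_or_protective_only) && !is.na(h$odds_ratio))
      out <- c(out, "gwas")
    if (!length(out)) out <- "uncategorized_risks"
    intersect(vocab, out)  # canonical order
  })
  hits$categories <- joinTokens(cats)
  hits
}

#' Route each hit to the main report or the annex
#'
#' Routing rules, in order: an analyst exclusion drops the hit upstream; a
#' hit carrying tier C in its tier set goes to the annex always (VUS are
#' reported without further interpretation); pharmacogenetic findings go to
#' the main report iff their PharmGKB level is 1A or 1B; any other hit goes
#' to the main report iff it is pathogenic-side (combined ACMG class
#' pathogenic / likely pathogenic, or a pathogenic / likely-pathogenic
#' ClinVar submission triggered it) and at least one of its categories is
#' medium/high-penetrance eligible; everything else stays in the annex. An
#' analyst `include` override forces the main report.
#'
#' @param hits Hit `data.frame` with `categories` assigned.
#' @return `hits` with a `destination` column (`"main"` / `"annex"`).
#' @export
routeDestination <- function(hits) {
  if (!nrow(hits)) {
    hits$destination <- character(0)
    return(hits)
  }
  cats <- splitTokens(hits$categories)
  tiers <- splitTokens(hits$tiers)
  pgx <- vapply(cats, function(cc) "pharmacogenetics" %in% cc, logical(1))
  level <- hits$pharmgkb_level
  pgx_main <- pgx & !is.na(level) & level %in% c("1A", "1B")
  path_side <- hits$acmg_class %in% c("pathogenic", "likely_pathogenic") |
    hits$pathogenic_trigger %in% TRUE
  eligible <- vapply(cats, function(cc)
    any(cc %in% .mainEligibleCategories()), logical(1))
  main <- pgx_main | (path_side & eligible)
  tier_c <- vapply(tiers, function(tt) "C" %in% tt, logical(1))
  main[tier_c] <- FALSE
  main[hits$analyst_override %in% "include"] <- TRUE
  hits$destination <- ifelse(main, "main", "annex")
  hits
}

## classify allele type from ref/alt strings
.variantType <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
         ifelse(nchar(ref) == nchar(alt), "MNV", "indel"))
}

## one tabular annex/main row per hit, in the annex field layout
.annexRows <- function(hits) {
  if (!nrow(hits)) return(.emptyAnnexRows())
  sig <- vapply(hits$clinvar, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    formatClinvarSignature(suppressWarnings(parseClinvarSignature(s)))
  }, character(1), USE.NAMES = FALSE)
  gwas <- vapply(splitTokens(hits$categories), function(cc)
    "gwas" %in% cc, logical(1))
  out <- data.frame(
    gene = hits$gene,
    variant_type = .variantType(hits$ref, hits$alt),
    functional_consequence = hits$consequence,
    genomic_region = hits$region,
    chrom = hits$chrom,
    pos = hits$pos,
    ref = hits$ref,
    alt = hits$alt,
    rsid = hits$rsid,
    hgvs_c = hits$hgvs_c,
    hgvs_p = hits$hgvs_p,
    af_g1000 = hits$af_g1000,
    af_exac = hits$af_exac,
    af_esp5400 = hits$af_esp5400,
    clinvar_signature = sig,
    inheritance = hits$inheritance,
    pharmgkb_level = hits$pharmgkb_level,
    ## effect sizes are pass-through annotations, reported only for
    ## common/GWAS findings
    effect_size = ifelse(gwas, hits$odds_ratio, NA_real_),
    reference_note = hits$reference_note,
    zygosity = hits$zygosity,
    confidence = hits$confidence,
    tiers = hits$tiers,
    rules = hits$rules,
    acmg_criteria = hits$acmg_criteria,
    acmg_class = hits$acmg_class,
    categories = hits$categories,
    conflict = hits$conflict,
    destination = hits$destination,
    stringsAsFactors = FALSE, row.names = NULL
  )
  ## deterministic ordering: category order, then gene, then position
  rank <- vapply(splitTokens(out$categories), function(cc) {
    m <- match(cc, reportCategories())
    if (!length(m) || all(is.na(m))) length(reportCategories()) + 1L
    else min(m, na.rm = TRUE)
  }, numeric(1))
  out[order(rank, out$gene, out$pos), , drop = FALSE]
}

.emptyAnnexRows <- function() {
  .annexRowTemplate <- data.frame(
    gene = character(0), variant_type = character(0),
    functional_consequence = character(0), genomic_region = character(0),
    chrom = character(0), pos = numeric(0), ref = character(0),
    alt = character(0), rsid = character(0), hgvs_c = character(0),
    hgvs_p = character(0), af_g1000 = numeric(0), af_exac = numeric(0),
    af_esp5400 = numeric(0), clinvar_signature = character(0),
    inheritance = character(0), pharmgkb_level = character(0),
    effect_size = numeric(0), reference_note = character(0),
    zygosity = character(0), confidence = character(0),
    tiers = character(0), rules = character(0),
    acmg_criteria = character(0), acmg_class = character(0),
    categories = character(0), conflict = logical(0),
    destination = character(0), stringsAsFactors = FALSE)
  .annexRowTemplate
}

#' Build a per-patient report
#'
#' Assembles the two-part report (concise main findings plus the full
#' tabulated annex) from one patient's routed hits, with run provenance
#' (configuration digest, thresholds, panel inventory, package version).
#' Output is deterministic: same input, byte-identical JSON.
#'
#' @param hits Routed hit `data.frame` (one patient; rows for other
#'   patients raise an error).
#' @param patientId Patient identifier (required when `hits` is empty).
#' @param metadata Optional named list of patient metadata passed through.
#' @param config A [TriageConfig-class] recorded in provenance.
#' @param panels The [PanelSet-class] used, recorded in provenance.
#' @return A `TriageReport` (S3 list) with elements `patient`,
#'   `main_findings`, `annex`, `provenance`.
#' @export
buildReport <- function(hits, patientId = NULL, metadata = list(),
                        config = triageConfig(), panels = NULL) {
  if (nrow(hits)) {
    ids <- unique(hits$patient_id)
    if (length(ids) > 1)
      stop("buildReport expects hits of a single patient; got: ",
           paste(ids, collapse = ", "), call. = FALSE)
    if (is.null(patientId)) patientId <- ids
  }
  if (is.null(patientId))
    stop("patientId required for an empty report", call. = FALSE)
  rows <- .annexRows(hits)
  provenance <- list(
    tool = "VariantTriage",
    tool_version = as.character(utils::packageVersion("VariantTriage")),
    config_digest = objectDigest(slotList(config)),
    thresholds = slotList(config@quality),
    max_af_carrier = config@maxAfCarrier,
    panels = if (is.null(panels)) NULL else
      lapply(stats::setNames(nm = panelNames(panels)), function(p)
        length(panelGenes(panels, p))),
    schema_version = "1.0"
  )
  structure(list(
    patient = c(list(patient_id = patientId), metadata),
    main_findings = rows[rows$destination == "main", , drop = FALSE],
    annex = rows[rows$destination == "annex", , drop = FALSE],
    provenance = provenance
  ), class = "TriageReport")
}

#' @export
print.TriageReport <- function(x, ...) {
  cat(sprintf("TriageReport for %s: %d main finding(s), %d annex row(s)\n",
              x$patient$patient_id, nrow(x$main_findings), nrow(x$annex)))
  invisible(x)
}

#' Write a report as structured JSON
#'
#' @param report A `TriageReport` from [buildReport()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Read a report written by [writeReportJson()]
#'
#' @param path Path to a `report.json`.
#' @return A `TriageReport`.
#' @export
readReportJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  sv <- x$provenance$schema_version
  if (is.null(sv) || !identical(sv, "1.0"))
    stop("unsupported report schema version in ", path, ": ",
         if (is.null(sv)) "<missing>" else sv, call. = FALSE)
  if (is.null(x$main_findings) || length(x$main_findings) == 0)
    x$main_findings <- .emptyAnnexRows()
  if (is.null(x$annex) || length(x$annex) == 0) x$annex <- .emptyAnnexRows()
  structure(x, class = "TriageReport")
}

#' Render a report as human-readable Markdown
#'
#' @param report A `TriageReport`.
#' @return Character vector of Markdown lines.
#' @export
renderReportMarkdown <- function(report) {
  fmtRow <- function(r) {
    sprintf("| %s | %s | %s | %s:%s %s>%s | %s | %s | %s | %s |",
            r$gene, r$variant_type, r$functional_consequence,
            r$chrom, format(r$pos, scientific = FALSE), r$ref, r$alt,
            ifelse(is.na(r$rsid), "", r$rsid),
            ifelse(is.na(r$clinvar_signature), "", r$clinvar_signature),
            r$inheritance, r$categories)
  }
  header <- c("| Gene | Type | Consequence | Variant | rsID | ClinVar signature | Inheritance | Categories |",
              "|---|---|---|---|---|---|---|---|")
  section <- function(df) {
    if (!nrow(df)) return("*(none)*")
    c(header, vapply(seq_len(nrow(df)), function(i) fmtRow(df[i, ]),
                     character(1)))
  }
  c(sprintf("# Genomic findings report — patient %s",
            report$patient$patient_id),
    "", "## Main report", "",
    section(report$main_findings),
    "", "## Annex", "",
    section(report$annex),
    "", sprintf("*Generated by %s %s (config %s)*",
                report$provenance$tool, report$provenance$tool_version,
                report$provenance$config_digest))
}

#' Cohort-level summary statistics
#'
#' Computes the carrier fraction (patients with at least one carrier-status
#' finding), the median carrier-variant count among carriers, the fraction
#' of patients with a level-1A/1B pharmacogenetic main-report finding, and
#' per-category patient fractions.
#'
#' @param reports A non-empty list of `TriageReport` objects.
#' @return A list with `n_patients`, `carrier_fraction`,
#'   `median_carrier_variants`, `pgx_main_fraction` and
#'   `category_fractions` (named numeric over [reportCategories()]).
#' @export
summarizeCohort <- function(reports) {
  if (!length(reports))
    stop("cannot summarize an empty cohort", call. = FALSE)
  perPatient <- lapply(reports, function(r) {
    stopifnot(inherits(r, "TriageReport"))
    findings <- rbind(r$main_findings, r$annex)
    cats <- splitTokens(findings$categories)
    has <- vapply(stats::setNames(nm = reportCategories()), function(cat)
      any(vapply(cats, function(cc) cat %in% cc, logical(1))), logical(1))
    nCarrier <- sum(vapply(cats, function(cc) "carrier_status" %in% cc,
                           logical(1)))
    pgxMain <- nrow(r$main_findings) > 0 &&
      any(r$main_findings$pharmgkb_level %in% c("1A", "1B"))
    list(has = has, nCarrier = nCarrier, pgxMain = pgxMain)
  })
  n <- length(perPatient)
  nCarrier <- vapply(perPatient, `[[`, numeric(1), "nCarrier")
  hasMat <- do.call(rbind, lapply(perPatient, `[[`, "has"))
  list(
    n_patients = n,
    carrier_fraction = mean(nCarrier >= 1),
    median_carrier_variants = if (any(nCarrier >= 1))
      stats::median(nCarrier[nCarrier >= 1]) else NA_real_,
    pgx_main_fraction = mean(vapply(perPatient, `[[`, logical(1),
                                    "pgxMain")),
    category_fractions = colMeans(hasMat)
  )
}

#' Write a cohort summary as TSV
#'
#' @param summary Result of [summarizeCohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCohortSummaryTsv <- function(summary, path) {
  rows <- data.frame(
    metric = c("n_patients", "carrier_fraction", "median_carrier_variants",
               "pgx_main_fraction",
               paste0("fraction_", names(summary$category_fractions))),
    value = c(summary$n_patients, summary$carrier_fraction,
              summary$median_carrier_variants, summary$pgx_main_fraction,
              unname(summary$category_fractions)),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
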