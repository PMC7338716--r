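## Synthetic cohorts with planted ground truth -------------------------------
##
## The generator emulates per-patient annotated variant tables carrying the
## attribute signatures each pipeline stage keys on: recessive pathogenic
## carrier alleles at rare frequency, common pharmacogenetic alleles with a
## PharmGKB level, actionable in-panel variants, rare loss-of-function VUS,
## and a benign/common background with mixed quality. Every planted signal
## variant maps to its intended tier, category and destination in a truth
## table, so full-pipeline recall and precision are exactly checkable.

.carrierGenes <- c("CFTR", "HBB", "PAH", "GJB2", "HEXA", "ACADM", "GALT",
                   "GBA", "IDUA", "DHCR7", "SLC26A4", "PKHD1", "CPT2",
                   "ASPA", "MCOLN1", "FANCC", "GAA", "SMPD1", "ALDOB",
                   "BCKDHA")

.pgxGenes <- c("CYP2D6", "CYP2C19", "CYP2C9", "SLCO1B1", "TPMT", "DPYD",
               "VKORC1", "UGT1A1", "NUDT15", "CYP3A5")

.backgroundGenes <- c("TTN", "MUC16", "OBSCN", "SYNE1", "NEB", "CSMD1",
                      "FLG", "AHNAK2", "PLEC", "HYDIN", "USH2A", "DNAH5",
                      "LAMA5", "PKD1L1", "FSIP2", "RYR3", "DST", "FAT1",
                      "GPR98", "ZFHX4")

.pickDistinctBases <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

## high-confidence quality block for n records
.goodQuality <- function(n) {
  data.frame(qual = round(stats::runif(n, 150, 2000), 1),
             depth = sample(20:120, n, replace = TRUE),
             qd = round(stats::runif(n, 12, 30), 2),
             alt_fraction = round(stats::runif(n, 0.35, 0.6), 3),
             callers = "gatk_haplotype_caller;freebayes",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Given a [CohortSpec-class], returns per-patient variant tables
#' (concatenated into one [AnnotatedVariants-class]) plus a truth table
#' mapping every planted signal variant to its intended tier set, primary
#' category and report destination. Generation is fully deterministic for
#' a fixed seed and restores the caller's RNG state.
#'
#' Planted classes and their attribute signatures:
#' \describe{
#'   \item{carrier}{recessive inheritance, pathogenic ClinVar signature,
#'     allele frequency 1e-5–1e-3, off-panel gene; expected tier A,
#'     category carrier_status, main report.}
#'   \item{pgx_main / pgx_annex}{drug-response ClinVar signature at common
#'     frequency (0.05–0.4) with PharmGKB level 1A/1B (main) or 2A/2B/3
#'     (annex); expected tier A, category pharmacogenetics.}
#'   \item{actionable}{in-panel gene with pathogenic ClinVar signature at
#'     rare frequency, either a frameshift (null-mechanism evidence) or a
#'     predictor-damaging missense; expected tiers A+B, panel category,
#'     main report.}
#'   \item{vus}{in-panel loss-of-function variant without any ClinVar
#'     record and with no frequency entry; expected to surface via tiers
#'     B+C and route to the annex.}
#'   \item{background}{benign ClinVar signatures or common alleles without
#'     a record, non-LoF consequences, mixed quality per the noise model;
#'     must produce no hit.}
#' }
#'
#' @param spec A [CohortSpec-class].
#' @param panels A [PanelSet-class] used for planting in-panel variants
#'   (default [miniPanels()]).
#' @return A list with `variants` (an [AnnotatedVariants-class]),
#'   `truth` (a `data.frame` with `key`, `patient_id`, `class`,
#'   `expected_tiers`, `expected_category`, `expected_destination`) and
#'   `spec`.
#' @export
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 3, seed = 7))
#' table(cohort$truth$class)
generateCohort <- function(spec, panels = miniPanels()) {
  stopifnot(methods::is(spec, "CohortSpec"))
  methods::validObject(spec)
  actionableGenes <- sort(unique(c(panelGenes(panels, "cardiovascular"),
                                   panelGenes(panels, "hereditary_cancer"))))
  vusGenes <- panelGenes(panels)

  withSeed(spec@seed, {
    perPatient <- lapply(seq_len(spec@nPatients), function(i) {
      pid <- sprintf("P%03d", i)
      rows <- list()
      truth <- list()

      nCarrier <- stats::rpois(1, spec@lambdaCarrier)
      if (nCarrier > 0) {
        b <- .pickDistinctBases(nCarrier)
        rows$carrier <- data.frame(
          patient_id = pid, gene = sample(.carrierGenes, nCarrier,
                                          replace = TRUE),
          ref = b$ref, alt = b$alt,
          consequence = sample(c("missense", "nonsense"), nCarrier,
                               replace = TRUE),
          region = "exonic",
          clinvar = sprintf("Pathogenic(%d)", sample(2:9, nCarrier,
                                                     replace = TRUE)),
          af_exac = signif(stats::runif(nCarrier, 1e-5, 1e-3), 3),
          inheritance = "AR", pharmgkb_level = "none",
          .goodQuality(nCarrier),
          class = "carrier", stringsAsFactors = FALSE)
      }

      plantPgx <- function(levels, cls) {
        b <- .pickDistinctBases(1)
        data.frame(
          patient_id = pid, gene = sample(.pgxGenes, 1),
          ref = b$ref, alt = b$alt,
          consequence = "missense", region = "exonic",
          clinvar = sprintf("Drug response(%d)", sample(2:6, 1)),
          af_exac = round(stats::runif(1, 0.05, 0.4), 3),
          inheritance = "other", pharmgkb_level = sample(levels, 1),
          .goodQuality(1), class = cls, stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < spec@pPgx1a)
        rows$pgx_main <- plantPgx(c("1A", "1B"), "pgx_main")
      if (stats::runif(1) < spec@pPgxAnnex)
        rows$pgx_annex <- plantPgx(c("2A", "2B", "3"), "pgx_annex")

      if (stats::runif(1) < spec@pActionable) {
        b <- .pickDistinctBases(1)
        frameshift <- stats::runif(1) < 0.5
        act <- data.frame(
          patient_id = pid, gene = sample(actionableGenes, 1),
          ref = b$ref, alt = if (frameshift) paste0(b$ref, "A") else b$alt,
          consequence = if (frameshift) "frameshift" else "missense",
          region = "exonic",
          clinvar = sprintf("Pathogenic(%d);Uncertain significance(%d)",
                            sample(2:9, 1), sample(1:3, 1)),
          af_exac = if (frameshift) signif(stats::runif(1, 1e-5, 9e-5), 3)
                    else signif(stats::runif(1, 1e-5, 1e-3), 3),
          inheritance = "AD", pharmgkb_level = "none",
          .goodQuality(1), class = "actionable", stringsAsFactors = FALSE)
        if (!frameshift) {
          act$sift_score <- 0.001; act$polyphen2_score <- 0.98
          act$mutation_taster_call <- "D"; act$mutation_assessor_score <- 3.2
          act$fathmm_score <- -3.1; act$gerp_score <- 5.1
        }
        rows$actionable <- act
      }

      if (stats::runif(1) < spec@pVusLof) {
        b <- .pickDistinctBases(1)
        cons <- sample(c("nonsense", "frameshift", "splice_donor",
                         "splice_acceptor"), 1)
        rows$vus <- data.frame(
          patient_id = pid, gene = sample(vusGenes, 1),
          ref = b$ref,
          alt = if (cons == "frameshift") paste0(b$ref, "T") else b$alt,
          consequence = cons,
          region = if (cons %in% c("splice_donor", "splice_acceptor"))
            "splice_site" else "exonic",
          clinvar = NA_character_,
          af_exac = NA_real_,
          inheritance = "AD", pharmgkb_level = "none",
          .goodQuality(1), class = "vus", stringsAsFactors = FALSE)
      }

      nBg <- spec@nBackground
      if (nBg > 0) {
        b <- .pickDistinctBases(nBg)
        cons <- sample(c("missense", "synonymous", "intronic"), nBg,
                       replace = TRUE)
        withSig <- stats::runif(nBg) < 0.5
        q <- .goodQuality(nBg)
        lowq <- stats::runif(nBg) < spec@fracLowQual
        lowd <- stats::runif(nBg) < spec@fracLowDepth
        onec <- stats::runif(nBg) < spec@fracSingleCaller
        q$qual[lowq] <- round(stats::runif(sum(lowq), 10, 90), 1)
        q$depth[lowd] <- sample(1:9, sum(lowd), replace = TRUE)
        q$callers[onec] <- "gatk_haplotype_caller"
        rows$background <- data.frame(
          patient_id = pid,
          gene = sample(c(.backgroundGenes, vusGenes), nBg, replace = TRUE),
          ref = b$ref, alt = b$alt,
          consequence = cons,
          region = ifelse(cons == "intronic", "intronic", "exonic"),
          clinvar = ifelse(withSig,
                           sprintf("Benign(%d);Likely benign(%d)",
                                   sample(2:8, nBg, replace = TRUE),
                                   sample(1:5, nBg, replace = TRUE)),
                           NA_character_),
          af_exac = ifelse(withSig, NA_real_,
                           round(stats::runif(nBg, 0.1, 0.5), 3)),
          inheritance = "unknown", pharmgkb_level = "none",
          q, class = "background", stringsAsFactors = FALSE)
      }

      df <- do.call(rbind, lapply(rows, function(r) {
        common <- c("patient_id", "gene", "ref", "alt", "consequence",
                    "region", "clinvar", "af_exac", "inheritance",
                    "pharmgkb_level", "qual", "depth", "qd",
                    "alt_fraction", "callers", "class")
        extra <- setdiff(names(r), common)
        for (col in c("sift_score", "polyphen2_score",
                      "mutation_taster_call", "mutation_assessor_score",
                      "fathmm_score", "gerp_score"))
          if (!col %in% names(r)) r[[col]] <- NA
        r[c(common, "sift_score", "polyphen2_score",
            "mutation_taster_call", "mutation_assessor_score",
            "fathmm_score", "gerp_score")]
      }))
      n <- nrow(df)
      df$chrom <- as.character(sample(1:22, n, replace = TRUE))
      df$pos <- sample.int(49000000L, n, replace = FALSE) + 1000000L
      rownames(df) <- NULL
      df
    })

    all <- do.call(rbind, perPatient)
    classes <- all$class
    all$class <- NULL
    variants <- AnnotatedVariants(all)

    key <- variantKey(variantData(variants))
    planted <- classes != "background"
    truthClass <- classes[planted]
    sub <- variantData(variants)[planted, , drop = FALSE]
    actionableTiers <- "A,B"
    truth <- data.frame(
      key = key[planted],
      patient_id = sub$patient_id,
      gene = sub$gene,
      class = truthClass,
      expected_tiers = c(carrier = "A", pgx_main = "A", pgx_annex = "A",
                         actionable = actionableTiers,
                         vus = "B,C")[truthClass],
      expected_category = c(carrier = "carrier_status",
                            pgx_main = "pharmacogenetics",
                            pgx_annex = "pharmacogenetics",
                            actionable = "panel",
                            vus = "panel")[truthClass],
      expected_destination = c(carrier = "main", pgx_main = "main",
                               pgx_annex = "annex", actionable = "main",
                               vus = "annex")[truthClass],
      stringsAsFactors = FALSE, row.names = NULL)
    list(variants = variants, truth = truth, spec = spec)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes one canonical variant TSV per patient plus a `truth.json` file
#' with the planted ground truth.
#'
#' @param cohort Result of [generateCohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- variantData(cohort$variants)
  for (pid in unique(df$patient_id)) {
    sub <- AnnotatedVariants(df[df$patient_id == pid, , drop = FALSE])
    writeVariantTable(sub, file.path(dir, paste0(pid, ".tsv")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(dir)
}

#' The printed worked-example fixture of actionable variants
#'
#' Loads the bundled transcription of the representative actionable-variant
#' table: 19 variant rows over 13 patients, with gene, HGVS notation, rsID
#' and the verbatim ClinVar aggregate signature strings. The source table
#' prints no genomic coordinates; the fixture carries each gene's true
#' chromosome with documented placeholder positions, and inheritance
#' assigned from standard gene-disease knowledge. Population frequencies
#' are absent.
#'
#' @return An [AnnotatedVariants-class] with 19 records.
#' @export
#' @examples
#' length(workedExampleFixture())
workedExampleFixture <- function() {
  path <- system.file("extdata", "worked_example_variants.csv",
                      package = "VariantTriage")
  fields <- c("patient_id", "chrom", "pos", "ref", "alt", "gene", "hgvs_c",
              "hgvs_p", "rsid", "consequence", "region", "clinvar",
              "inheritance", "reference_note")
  colmap <- columnMap(stats::setNames(fields, fields), delimiter = ",")
  readVariantTable(path, colmap)
}
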