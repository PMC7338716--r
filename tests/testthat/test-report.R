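## a small crafted cohort exercising every category and routing rule
craftedCohort <- function() {
  makeVariants(
    ## in-panel pathogenic dominant arrhythmia variant -> cardiovascular
    makeVariant(patient_id = "P1", pos = 1, gene = "KCNQ1",
                clinvar = "Pathogenic(2);Likely pathogenic(1)",
                inheritance = "AD"),
    ## recessive pathogenic rare off-panel variant -> carrier status
    makeVariant(patient_id = "P1", pos = 2, gene = "CFTR",
                clinvar = "Pathogenic(3)", af_exac = 1e-4,
                inheritance = "AR"),
    ## level-1A drug-response allele -> pharmacogenetics, main
    makeVariant(patient_id = "P1", pos = 3, gene = "CYP2C19",
                clinvar = "Drug response(4)", af_exac = 0.3,
                pharmgkb_level = "1A", inheritance = "other"),
    ## level-2A drug-response allele -> pharmacogenetics, annex
    makeVariant(patient_id = "P1", pos = 4, gene = "CYP2D6",
                clinvar = "Drug response(2)", af_exac = 0.2,
                pharmgkb_level = "2A", inheritance = "other"),
    ## risk-factor-only hit with an effect size -> gwas, annex
    makeVariant(patient_id = "P1", pos = 5, gene = "ZZZ9",
                clinvar = "Risk factor(3)", af_exac = 0.25,
                odds_ratio = 1.4, inheritance = "other"),
    ## risk-factor-only hit without effect size -> uncategorized, annex
    makeVariant(patient_id = "P1", pos = 6, gene = "ZZZ8",
                clinvar = "Protective(2)", inheritance = "other"),
    ## rare in-panel LoF VUS -> annex always
    makeVariant(patient_id = "P1", pos = 7, gene = "MLH3",
                consequence = "frameshift", clinvar = NA,
                inheritance = "AD"))
}

test_that("category assignment matches the reporting rules", {
  hits <- triageVariants(craftedCohort(), miniPanels())
  byGene <- function(g) strsplit(hits$categories[hits$gene == g], ",")[[1]]
  expect_setequal(byGene("KCNQ1"), c("cardiovascular", "acmg59"))
  expect_identical(byGene("CFTR"), "carrier_status")
  expect_identical(byGene("CYP2C19"), "pharmacogenetics")
  expect_identical(byGene("CYP2D6"), "pharmacogenetics")
  expect_identical(byGene("ZZZ9"), "gwas")
  expect_identical(byGene("ZZZ8"), "uncategorized_risks")
  expect_identical(byGene("MLH3"), "hereditary_cancer")
  ## assignment is total
  expect_true(all(nzchar(hits$categories)))
})

test_that("destinations follow evidence level, penetrance and the VUS rule", {
  hits <- triageVariants(craftedCohort(), miniPanels())
  dest <- function(g) hits$destination[hits$gene == g]
  expect_identical(dest("KCNQ1"), "main")
  expect_identical(dest("CFTR"), "main")
  expect_identical(dest("CYP2C19"), "main")   # level 1A
  expect_identical(dest("CYP2D6"), "annex")   # level 2A
  expect_identical(dest("ZZZ9"), "annex")
  expect_identical(dest("ZZZ8"), "annex")
  expect_identical(dest("MLH3"), "annex")     # tier C, always annex
  ## every hit lands in exactly one of main/annex
  expect_true(all(hits$destination %in% c("main", "annex")))
})

test_that("analyst overrides force inclusion or drop hits", {
  df <- variantData(craftedCohort())
  df$analyst_override[df$gene == "ZZZ9"] <- "include"
  df$analyst_override[df$gene == "KCNQ1"] <- "exclude"
  hits <- triageVariants(AnnotatedVariants(df), miniPanels())
  expect_false("KCNQ1" %in% hits$gene)
  expect_identical(hits$destination[hits$gene == "ZZZ9"], "main")
})

test_that("reports are deterministic and split main/annex exhaustively", {
  res <- runTriage(craftedCohort(), miniPanels())
  rep1 <- res$reports[["P1"]]
  expect_s3_class(rep1, "TriageReport")
  expect_equal(nrow(rep1$main_findings) + nrow(rep1$annex), nrow(res$hits))
  expect_true(all(rep1$main_findings$destination == "main"))
  expect_true(all(rep1$annex$destination == "annex"))
  ## effect sizes are populated only for common/GWAS findings
  allRows <- rbind(rep1$main_findings, rep1$annex)
  expect_true(all(is.na(allRows$effect_size) |
                    grepl("gwas", allRows$categories)))
  ## byte-identical JSON on identical input
  f1 <- tempfile(); f2 <- tempfile()
  writeReportJson(rep1, f1)
  writeReportJson(runTriage(craftedCohort(), miniPanels())$reports[["P1"]],
                  f2)
  expect_identical(readLines(f1), readLines(f2))
  ## and the JSON roundtrips through the reader
  back <- readReportJson(f1)
  expect_equal(back$main_findings$gene, rep1$main_findings$gene)
  md <- renderReportMarkdown(rep1)
  expect_true(any(grepl("## Main report", md)))
})

test_that("an empty report is valid and carries provenance", {
  rep0 <- buildReport(triageVariants(AnnotatedVariants(), miniPanels()),
                      patientId = "P0")
  expect_equal(nrow(rep0$main_findings), 0)
  expect_equal(nrow(rep0$annex), 0)
  expect_match(rep0$provenance$config_digest, "^[0-9a-f]{32}$")
  expect_identical(rep0$provenance$schema_version, "1.0")
})

test_that("the worked example routes its cancer findings to the main
          report", {
  ## the fixture carries no caller provenance; the concordance rule warns
  res <- suppressWarnings(runTriage(workedExampleFixture(), miniPanels()))
  expect_equal(length(res$reports), 13)
  p52 <- res$reports[["52"]]
  expect_true(all(c("CHEK2", "MUTYH") %in% p52$main_findings$gene))
  ## every fixture variant carries a qualifying submission, so all 19
  ## records surface as first-tier hits
  expect_equal(nrow(res$hits), 19)
  expect_true(all(grepl("A", res$hits$tiers)))
})

test_that("cohort summaries compute carrier fraction and medians", {
  ## nine carriers with {1,...} planted carrier variants, one non-carrier
  rows <- list()
  counts <- c(1, 4, 6, 2, 1, 3, 5, 1, 2)
  for (p in 1:9) for (k in seq_len(counts[p]))
    rows <- c(rows, list(makeVariant(
      patient_id = sprintf("P%02d", p), pos = k * 50,
      gene = paste0("CG", k), clinvar = "Pathogenic(2)",
      af_exac = 1e-4, inheritance = "AR")))
  rows <- c(rows, list(makeVariant(patient_id = "P10", pos = 1,
                                   gene = "TTN", clinvar = "Benign(3)")))
  res <- runTriage(do.call(makeVariants, rows), miniPanels())
  expect_equal(res$summary$n_patients, 10)
  expect_equal(res$summary$carrier_fraction, 0.9)
  expect_equal(res$summary$median_carrier_variants, 2)
  expect_equal(unname(res$summary$category_fractions["carrier_status"]),
               0.9)
  expect_error(summarizeCohort(list()), "empty")
  ## single-patient cohort: medians equal that patient's values
  one <- runTriage(craftedCohort(), miniPanels())
  expect_equal(one$summary$median_carrier_variants, 1)
  expect_equal(one$summary$pgx_main_fraction, 1)
  f <- tempfile()
  writeCohortSummaryTsv(res$summary, f)
  tsv <- utils::read.delim(f)
  expect_equal(tsv$value[tsv$metric == "carrier_fraction"], 0.9)
})
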