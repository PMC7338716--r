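test_that("cohort generation is deterministic for a fixed seed", {
  a <- generateCohort(cohortSpec(nPatients = 4, seed = 7))
  b <- generateCohort(cohortSpec(nPatients = 4, seed = 7))
  expect_identical(variantData(a$variants), variantData(b$variants))
  expect_identical(a$truth, b$truth)
  c2 <- generateCohort(cohortSpec(nPatients = 4, seed = 8))
  expect_false(identical(variantData(a$variants), variantData(c2$variants)))
  ## generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generateCohort(cohortSpec(nPatients = 2, seed = 7)))
  expect_identical(runif(1), before)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(nPatients = 0), "nPatients")
  expect_error(cohortSpec(nPatients = 5, pPgx1a = 1.5), "probabilities")
})

test_that("a zero carrier rate plants no carrier variants", {
  co <- generateCohort(cohortSpec(nPatients = 10, seed = 3,
                                  lambdaCarrier = 0))
  expect_false("carrier" %in% co$truth$class)
  res <- runTriage(co$variants, miniPanels())
  expect_false(any(grepl("carrier_status", res$hits$categories)))
})

test_that("the planted carrier fraction matches the Poisson zero-class
          prediction", {
  co <- generateCohort(cohortSpec(nPatients = 100, seed = 17))
  carriers <- unique(co$truth$patient_id[co$truth$class == "carrier"])
  frac <- length(carriers) / 100
  p <- 1 - exp(-4)  # P(at least one planted carrier variant)
  ## 99% binomial interval around the expected fraction
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / 100)
  expect_gte(frac, p - half)
  expect_lte(frac, min(1, p + half))
})

test_that("noise-model variants failing thresholds never reach the
          high-confidence pass", {
  co <- generateCohort(cohortSpec(nPatients = 6, seed = 5))
  passes <- dualPass(co$variants)
  hc <- variantData(passes$high_confidence)
  expect_true(all(isHighConfidence(hc)))
  ## the degraded background records exist and are excluded
  expect_lt(length(passes$high_confidence), length(passes$all))
})

test_that("cohorts write as per-patient tables plus a truth file", {
  co <- generateCohort(cohortSpec(nPatients = 3, seed = 2,
                                  nBackground = 10))
  dir <- tempfile()
  writeCohort(co, dir)
  expect_setequal(list.files(dir),
                  c("P001.tsv", "P002.tsv", "P003.tsv", "truth.json"))
  back <- readVariantTable(file.path(dir, "P001.tsv"), defaultColumnMap())
  df <- variantData(co$variants)
  expect_equal(length(back), sum(df$patient_id == "P001"))
})

test_that("the bundled worked-example fixture matches its printed shape", {
  fix <- workedExampleFixture()
  df <- variantData(fix)
  expect_equal(nrow(df), 19)
  expect_equal(length(unique(df$patient_id)), 13)
  ## the factor V Leiden allele recurs in two patients
  f5 <- df[df$rsid == "rs6025", ]
  expect_setequal(f5$patient_id, c("43", "56"))
  expect_equal(unique(f5$gene), "F5")
})
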