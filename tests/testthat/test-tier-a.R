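kcne1_sig <- paste0("Benign(5);Likely benign(5);risk factor(3);",
                    "Pathogenic(1);Likely pathogenic(1);",
                    "Uncertain significance(2)")

test_that("any single qualifying submission triggers first-tier candidacy", {
  av <- makeVariants(
    makeVariant(pos = 1, gene = "KCNE1", clinvar = kcne1_sig),
    makeVariant(pos = 2, gene = "HABP2",
                clinvar = "Risk factor(2);Likely benign(1);Benign(1)"),
    makeVariant(pos = 3, gene = "X1", clinvar = "Benign(3)"),
    makeVariant(pos = 4, gene = "X2", clinvar = NA))
  hits <- selectTierA(av)
  expect_setequal(hits$gene, c("KCNE1", "HABP2"))
  kcne1 <- hits[hits$gene == "KCNE1", ]
  ## selected against a benign majority, with the conflict flagged
  expect_true(kcne1$conflict)
  expect_true(kcne1$pathogenic_trigger)
  expect_match(kcne1$rules, "TIER_A_CLINVAR_RISK_FACTOR")
  habp2 <- hits[hits$gene == "HABP2", ]
  expect_true(habp2$risk_or_protective_only)
  expect_false(habp2$pathogenic_trigger)
})

test_that("selection depends on the signature only", {
  sig <- "Pathogenic(2);Benign(1)"
  a <- makeVariants(makeVariant(clinvar = sig))
  b <- makeVariants(makeVariant(clinvar = sig, gene = "OTHER",
                                chrom = "9", pos = 5, consequence = "intronic",
                                region = "intronic", qual = 1, depth = 1,
                                af_exac = 0.5, inheritance = "XL"))
  expect_equal(nrow(selectTierA(a)), 1)
  expect_equal(nrow(selectTierA(b)), 1)
})

test_that("adding a pathogenic submission never deselects", {
  set.seed(5)
  for (i in 1:50) {
    sig <- randomSignature()
    av1 <- makeVariants(makeVariant(clinvar = formatClinvarSignature(sig)))
    sig2 <- sig
    sig2["Pathogenic"] <- if ("Pathogenic" %in% names(sig2))
      sig2["Pathogenic"] + 1 else 1
    av2 <- makeVariants(makeVariant(clinvar = formatClinvarSignature(sig2)))
    expect_gte(nrow(selectTierA(av2)), nrow(selectTierA(av1)))
  }
})

test_that("the carrier rarity filter keeps rare or unobserved alleles", {
  expect_identical(carrierFrequencyFilter(c(0.001, 0.20, NA)),
                   c(TRUE, FALSE, TRUE))
  ## the boundary is inclusive and the cutoff configurable
  expect_true(carrierFrequencyFilter(0.05))
  expect_false(carrierFrequencyFilter(0.02, maxAfCarrier = 0.01))
  ## the ambiguous reading can be inverted by configuration
  expect_identical(carrierFrequencyFilter(c(0.001, 0.2), keepRare = FALSE),
                   c(FALSE, TRUE))
})

test_that("common drug-response alleles are exempt from the rarity filter", {
  av <- makeVariants(
    makeVariant(pos = 1, gene = "CYP2C19", clinvar = "Drug response(4)",
                af_exac = 0.30, pharmgkb_level = "1A"),
    makeVariant(pos = 2, gene = "CFTR", clinvar = "Pathogenic(3)",
                af_exac = 0.20))
  hits <- selectTierA(av)
  expect_setequal(hits$gene, c("CYP2C19", "CFTR"))
  ## the common pathogenic hit is dropped from carrier status only
  expect_false(hits$carrier_candidate[hits$gene == "CFTR"])
  expect_true(hits$drug_response_trigger[hits$gene == "CYP2C19"])
})

test_that("carrier summaries count distinct carrier findings per patient", {
  rows <- c(lapply(1:4, function(i)
    makeVariant(pos = i * 100, gene = paste0("G", i),
                clinvar = "Pathogenic(2)", af_exac = 1e-4,
                inheritance = "AR")),
    ## duplicated row for the same allele
    list(makeVariant(pos = 100, gene = "G1", clinvar = "Pathogenic(2)",
                     af_exac = 1e-4, inheritance = "AR")))
  av <- do.call(makeVariants, rows)
  hits <- selectTierA(av)
  s <- carrierSummary(hits)
  expect_identical(s$carrier, TRUE)
  expect_identical(s$n_pathogenic, 4L)
  s0 <- carrierSummary(hits[0, ], patients = "P1")
  expect_identical(s0$carrier, FALSE)
  expect_identical(s0$n_pathogenic, 0L)
})
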