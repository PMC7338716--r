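test_that("uncertain-significance status follows the signature rules", {
  av <- makeVariants(
    makeVariant(pos = 1, clinvar = NA),
    makeVariant(pos = 2, clinvar = paste0(
      "Benign(3);Likely benign(1);Uncertain significance(11);",
      "Pathogenic(1);Risk factor(1)")),
    makeVariant(pos = 3, clinvar = "Pathogenic(2)"),
    makeVariant(pos = 4, clinvar = "Risk factor(3)"),
    makeVariant(pos = 5, clinvar = "Benign(4);Uncertain significance(2)"))
  expect_identical(isVus(av), c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("only rare in-scope loss-of-function VUS reach tier C", {
  genes <- c("MLH3", "FBN1")
  cfg <- vusConfig(penetranceGenes = genes)
  av <- makeVariants(
    makeVariant(pos = 1, gene = "MLH3", consequence = "frameshift",
                clinvar = NA),                            # hit
    makeVariant(pos = 2, gene = "MLH3", consequence = "missense",
                clinvar = NA),                            # not LoF
    makeVariant(pos = 3, gene = "MLH3", consequence = "nonsense",
                clinvar = NA, af_exac = 0.02),            # too common
    makeVariant(pos = 4, gene = "OFFLIST", consequence = "nonsense",
                clinvar = NA),                            # off gene list
    makeVariant(pos = 5, gene = "FBN1", consequence = "splice_donor",
                region = "splice_site", clinvar = NA,
                af_exac = 5e-4),                          # hit
    makeVariant(pos = 6, gene = "FBN1", consequence = "nonsense",
                region = "intronic", clinvar = NA))       # wrong region
  hits <- selectTierC(av, cfg)
  expect_setequal(hits$pos, c(1, 5))
  expect_identical(unique(hits$destination), "annex")
  expect_identical(unique(hits$rules), "TIER_C_LOF_VUS")
})

test_that("tier C never selects variants with pathogenic-side submissions", {
  set.seed(23)
  cfg <- vusConfig(penetranceGenes = "G1")
  for (i in 1:40) {
    sig <- randomSignature()
    av <- makeVariants(makeVariant(
      gene = "G1", consequence = "nonsense",
      clinvar = formatClinvarSignature(sig)))
    hits <- selectTierC(av, cfg)
    if (any(names(sig) %in% c("Pathogenic", "Likely pathogenic")))
      expect_equal(nrow(hits), 0)
  }
})

test_that("shrinking the rarity cutoff never grows the tier-C hit set", {
  set.seed(31)
  rows <- lapply(1:50, function(i)
    makeVariant(pos = i, gene = "G1", consequence = "nonsense",
                clinvar = NA,
                af_exac = sample(c(NA, 10^runif(1, -5, -1)), 1)))
  av <- do.call(makeVariants, rows)
  for (afs in list(c(0.01, 0.001), c(0.001, 1e-4))) {
    h1 <- selectTierC(av, vusConfig(maxAf = afs[1], penetranceGenes = "G1"))
    h2 <- selectTierC(av, vusConfig(maxAf = afs[2], penetranceGenes = "G1"))
    expect_true(all(h2$key %in% h1$key))
  }
})

test_that("the penetrance gene list defaults to the panel union", {
  panels <- PanelSet(list(p1 = "AAA", p2 = "BBB"))
  av <- makeVariants(
    makeVariant(pos = 1, gene = "AAA", consequence = "nonsense",
                clinvar = NA),
    makeVariant(pos = 2, gene = "CCC", consequence = "nonsense",
                clinvar = NA))
  hits <- selectTierC(av, vusConfig(), panels = panels)
  expect_identical(hits$gene, "AAA")
  ## with neither a gene list nor panels, no gene restriction applies
  hitsAll <- selectTierC(av, vusConfig())
  expect_setequal(hitsAll$gene, c("AAA", "CCC"))
})
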