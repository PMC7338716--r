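test_that("predictor consensus counts damaging calls over available
          predictors", {
  ## nine predictors scored, seven damaging
  v7 <- data.frame(sift_score = 0.01, polyphen2_score = 0.9,
                   mutation_taster_call = "D", mutation_assessor_score = 2.5,
                   fathmm_score = -2.5, dbscsnv_ada_score = 0.8,
                   gerp_score = 4.0, genocanyon_score = 0.1,
                   fitcons_score = 0.1)
  expect_identical(predictorConsensus(v7), "damaging")
  ## two available predictors fall below the availability floor
  v2 <- data.frame(sift_score = 0.01, gerp_score = 5)
  expect_identical(predictorConsensus(v2), "insufficient")
  ## four available, two damaging: not a strict majority
  v4 <- data.frame(sift_score = 0.01, gerp_score = 5,
                   genocanyon_score = 0.1, fitcons_score = 0.1)
  expect_identical(predictorConsensus(v4), "tolerated")
  ## a categorical call takes precedence over its raw score
  vc <- data.frame(sift_score = 0.9, sift_call = "D", gerp_score = 5,
                   polyphen2_score = 0.9)
  expect_identical(predictorConsensus(vc), "damaging")
})

test_that("turning a tolerated vote damaging never flips damaging to
          tolerated", {
  set.seed(13)
  pt <- defaultPredictorTable()
  for (i in 1:40) {
    n_avail <- sample(3:9, 1)
    cols <- sample(pt$score_col, n_avail)
    dmg <- runif(n_avail) < 0.5
    mk <- function(d) {
      vals <- lapply(seq_along(cols), function(j) {
        row <- pt[pt$score_col == cols[j], ]
        if (d[j]) { if (row$direction == "lt") row$threshold - 0.01
                    else row$threshold + 0.01 }
        else { if (row$direction == "lt") row$threshold + 0.01
               else row$threshold - 0.01 }
      })
      stats::setNames(as.data.frame(vals), cols)
    }
    v1 <- predictorConsensus(mk(dmg))
    tol <- which(!dmg)
    if (!length(tol)) next
    dmg2 <- dmg; dmg2[sample(tol, 1)] <- TRUE
    v2 <- predictorConsensus(mk(dmg2))
    if (v1 == "damaging") expect_identical(v2, "damaging")
  }
})

test_that("automatic criteria derive from annotations alone", {
  cfg <- triageConfig()
  av <- makeVariants(
    makeVariant(pos = 1, gene = "BRCA1", consequence = "frameshift"),
    makeVariant(pos = 2, gene = "BRCA1", af_exac = 0.30,
                sift_score = 0.9, polyphen2_score = 0.1, gerp_score = 0.1),
    makeVariant(pos = 3, gene = "BRCA1", af_exac = 2e-5, sift_score = 0.001,
                polyphen2_score = 0.99, gerp_score = 5))
  crit <- assignAcmgCriteria(av, lofGenes = "BRCA1", config = cfg)
  expect_setequal(crit[[1]], c("PVS1", "PM2"))      # LoF gene, AF absent
  expect_setequal(crit[[2]], c("BA1", "BS1", "BP4")) # common + tolerated
  expect_setequal(crit[[3]], c("PM2", "PP3"))        # rare + damaging
  ## outside the LoF-mechanism gene list PVS1 never fires
  critOff <- assignAcmgCriteria(av, lofGenes = "OTHER", config = cfg)
  expect_false("PVS1" %in% critOff[[1]])
  ## supplied curated criteria merge in, deduplicated
  df <- variantData(av)[1, ]
  df$supplied_criteria <- "PS4,PM2"
  expect_setequal(assignAcmgCriteria(df, lofGenes = "BRCA1",
                                     config = cfg)[[1]],
                  c("PVS1", "PM2", "PS4"))
})

test_that("evidence combination matches the independent rule-table oracle on
          spot cases", {
  ## expected values computed with the scalar oracle transcription
  expect_identical(acmgOracle(1, 0, 1, 0, 0, 0, 0), "likely_pathogenic")
  expect_identical(combineAcmg(c("PVS1", "PM2")), "likely_pathogenic")
  expect_identical(acmgOracle(0, 0, 0, 0, 1, 0, 0), "benign")
  expect_identical(combineAcmg("BA1"), "benign")
  expect_identical(acmgOracle(1, 1, 0, 0, 1, 0, 0), "vus")
  expect_identical(combineAcmg(c("PVS1", "PS1", "BA1")), "vus")
  expect_identical(combineAcmg(character(0)), "vus")
  expect_identical(combineAcmg(c("PVS1", "PS2")), "pathogenic")
  expect_identical(combineAcmg(c("BS1", "BP4")), "likely_benign")
  ## duplicates deduplicate silently; unknown codes are rejected
  expect_identical(combineAcmg(c("PM2", "PM2")), "vus")
  expect_error(combineAcmg("PX9"), "unknown")
})

test_that("panel restriction and the two selection arms drive tier B", {
  panels <- PanelSet(list(hereditary_cancer = c("BRCA1", "MLH1"),
                          acmg59 = "BRCA1"))
  av <- makeVariants(
    makeVariant(pos = 1, gene = "BRCA1", consequence = "frameshift"),
    makeVariant(pos = 2, gene = "NOTINPANEL", consequence = "frameshift"),
    makeVariant(pos = 3, gene = "MLH1", af_exac = 5e-4, sift_score = 0.001,
                polyphen2_score = 0.99, mutation_taster_call = "D",
                gerp_score = 5),
    makeVariant(pos = 4, gene = "MLH1", af_exac = 0.3, sift_score = 0.9,
                polyphen2_score = 0.05, gerp_score = 0.5))
  hits <- selectTierB(av, panels)
  expect_setequal(hits$pos, c(1, 3))
  b1 <- hits[hits$pos == 1, ]
  expect_identical(b1$acmg_class, "likely_pathogenic")
  expect_match(b1$rules, "TIER_B_ACMG")
  expect_setequal(strsplit(b1$panels, ",")[[1]],
                  c("hereditary_cancer", "acmg59"))
  ## consensus-damaging arm keeps an ACMG-vus variant, flagged as VUS
  b3 <- hits[hits$pos == 3, ]
  expect_identical(b3$consensus, "damaging")
  expect_true(b3$vus_flag)
  expect_match(b3$rules, "TIER_B_CONSENSUS_DAMAGING")
  ## all hit genes lie inside the panel union
  expect_true(all(hits$gene %in% panelGenes(panels)))
  expect_error(selectTierB(av, PanelSet()), "empty")
})

test_that("tier-B output is invariant under input permutation", {
  set.seed(3)
  panels <- PanelSet(list(p = paste0("G", 1:10)))
  rows <- lapply(1:30, function(i)
    makeVariant(pos = i, gene = sample(paste0("G", 1:15), 1),
                consequence = sample(c("frameshift", "missense"), 1),
                af_exac = sample(c(NA, 1e-5, 0.2), 1)))
  av <- do.call(makeVariants, rows)
  h1 <- selectTierB(av, panels)
  perm <- sample(length(av))
  h2 <- selectTierB(av[perm], panels)
  expect_setequal(h1$key, h2$key)
  h2 <- h2[match(h1$key, h2$key), ]
  rownames(h2) <- NULL
  expect_equal(h1, h2)
})
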