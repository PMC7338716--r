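test_that("zygosity follows the read-fraction rule with strict boundaries", {
  expect_identical(assignZygosity(c(0.26, 0.25, 0.80, 0.75, 0.10, NA)),
                   c("het", "low_fraction", "hom", "hom", "low_fraction",
                     "unknown"))
  expect_error(assignZygosity(1.2), "\\[0, 1\\]")
})

test_that("every fraction maps to exactly one zygosity class", {
  grid <- seq(0, 1, by = 0.005)
  z <- assignZygosity(grid)
  expect_true(all(z %in% c("low_fraction", "het", "hom")))
  ## partition boundaries under non-default thresholds too
  t2 <- qualityThresholds(hetMinFraction = 0.3, homMinFraction = 0.9)
  z2 <- assignZygosity(grid, t2)
  expect_identical(unique(z2[grid <= 0.3]), "low_fraction")
  expect_identical(unique(z2[grid > 0.3 & grid < 0.9]), "het")
  expect_identical(unique(z2[grid >= 0.9]), "hom")
})

test_that("high-confidence retention applies strict thresholds and caller
          concordance", {
  q <- data.frame(qual = c(150, 100, 150, 150, NA, 150),
                  depth = c(20, 20, 10, 20, 20, 20),
                  qd = c(15, 15, 15, 10, 15, 15),
                  callers = c("a;b", "a;b", "a;b", "a;b", "a;b", "a"))
  expect_identical(isHighConfidence(q),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  ## caller rule can be disabled for exports without provenance
  expect_true(isHighConfidence(q, checkCallers = FALSE)[6])
})

test_that("the dual pass labels confidence and subsets consistently", {
  set.seed(7)
  rows <- lapply(1:40, function(i)
    makeVariant(pos = i * 10, qual = runif(1, 50, 500),
                depth = sample(5:60, 1), qd = runif(1, 5, 25)))
  av <- do.call(makeVariants, rows)
  res <- dualPass(av)
  expect_equal(length(res$all), 40)
  df <- variantData(res$all)
  expect_setequal(unique(df$confidence), c("high", "low"))
  expect_equal(length(res$high_confidence), sum(df$confidence == "high"))
  ## high-confidence pass is a subset of the labelled full pass
  expect_true(all(variantKey(variantData(res$high_confidence)) %in%
                    variantKey(df)))
  ## empty input yields two empty passes
  empty <- dualPass(AnnotatedVariants())
  expect_equal(length(empty$all), 0)
  expect_equal(length(empty$high_confidence), 0)
})

test_that("tightening any threshold never grows the retained set", {
  set.seed(11)
  rows <- lapply(1:60, function(i)
    makeVariant(pos = i, qual = runif(1, 0, 400), depth = sample(0:40, 1),
                qd = runif(1, 0, 30),
                callers = sample(c("a", "a;b"), 1)))
  av <- do.call(makeVariants, rows)
  base <- qualityThresholds()
  kept0 <- which(isHighConfidence(variantData(av), base))
  for (tighter in list(qualityThresholds(minQual = 250),
                       qualityThresholds(minDepth = 25),
                       qualityThresholds(minQd = 18))) {
    kept <- which(isHighConfidence(variantData(av), tighter))
    expect_true(all(kept %in% kept0))
  }
  ## retention is invariant under input ordering
  perm <- sample(length(av))
  keptP <- isHighConfidence(variantData(av)[perm, ], base)
  expect_identical(keptP, isHighConfidence(variantData(av), base)[perm])
})

test_that("inputs without caller provenance skip the concordance rule with a
          warning", {
  av <- makeVariants(makeVariant(callers = NA))
  expect_warning(res <- dualPass(av), "concordance")
  expect_equal(length(res$high_confidence), 1)
})
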