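## shared builders and independent oracles for the suite

## minimal variant row builder with sensible high-quality defaults
makeVariant <- function(patient_id = "P1", chrom = "1", pos = 1000000,
                        ref = "A", alt = "G", gene = "GENE1", ...) {
  base <- list(patient_id = patient_id, chrom = chrom, pos = pos, ref = ref,
               alt = alt, gene = gene, consequence = "missense",
               region = "exonic", qual = 500, depth = 50, qd = 20,
               alt_fraction = 0.5, callers = "gatk;freebayes")
  dots <- list(...)
  base[names(dots)] <- dots
  as.data.frame(base, stringsAsFactors = FALSE)
}

makeVariants <- function(...) {
  rows <- list(...)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA
    r[cols]
  })
  AnnotatedVariants(do.call(rbind, rows))
}

## independent, deliberately scalar transcription of the published
## ACMG/AMP evidence-combination table (the implementation under test is a
## separate vectorized boolean-algebra formulation)
acmgOracle <- function(pvs, ps, pm, pp, ba, bs, bp) {
  pathogenic <- FALSE
  if (pvs >= 1) {
    if (ps >= 1) pathogenic <- TRUE
    if (pm >= 2) pathogenic <- TRUE
    if (pm >= 1 && pp >= 1) pathogenic <- TRUE
    if (pp >= 2) pathogenic <- TRUE
  }
  if (ps >= 2) pathogenic <- TRUE
  if (ps >= 1) {
    if (pm >= 3) pathogenic <- TRUE
    if (pm >= 2 && pp >= 2) pathogenic <- TRUE
    if (pm >= 1 && pp >= 4) pathogenic <- TRUE
  }
  likely <- FALSE
  if (pvs >= 1 && pm >= 1) likely <- TRUE
  if (ps >= 1 && pm >= 1) likely <- TRUE
  if (ps >= 1 && pp >= 2) likely <- TRUE
  if (pm >= 3) likely <- TRUE
  if (pm >= 2 && pp >= 2) likely <- TRUE
  if (pm >= 1 && pp >= 4) likely <- TRUE
  benign <- (ba >= 1) || (bs >= 2)
  likely_benign <- (bs >= 1 && bp >= 1) || (bp >= 2)

  if ((pathogenic || likely) && (benign || likely_benign)) return("vus")
  if (pathogenic) return("pathogenic")
  if (likely) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "vus"
}

## build a concrete criteria set realizing one evidence-count vector
criteriaFromCounts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  c(if (pvs >= 1) "PVS1",
    if (ps > 0) paste0("PS", seq_len(ps)),
    if (pm > 0) paste0("PM", seq_len(pm)),
    if (pp > 0) paste0("PP", seq_len(pp)),
    if (ba >= 1) "BA1",
    if (bs > 0) paste0("BS", seq_len(bs)),
    if (bp > 0) paste0("BP", seq_len(bp)))
}

## random valid ClinVar signature (named positive counts)
randomSignature <- function() {
  k <- sample(1:6, 1)
  stats::setNames(sample(1:25, k, replace = TRUE),
                  sample(clinvarClasses(), k))
}
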