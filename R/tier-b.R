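## Tier B — gene-centric virtual-panel filtering -----------------------------
##
## The second filtering tier restricts variants to the virtual gene panels
## and keeps those that either classify pathogenic / likely pathogenic
## under the ACMG/AMP evidence-combination rules or reach a damaging
## consensus across the nine in-silico predictors. The two arms are OR-ed:
## a panel variant classified VUS but consensus-damaging is still a hit
## (flagged as such), mirroring "ACMG criteria OR deleteriousness
## criteria".

#' The ACMG/AMP evidence-code vocabulary
#'
#' @return Character vector of the 28 evidence codes.
#' @export
acmgVocabulary <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

## counts per strength class from a criteria set
.acmgCounts <- function(criteria) {
  criteria <- unique(criteria)
  bad <- setdiff(criteria, acmgVocabulary())
  if (length(bad))
    stop("unknown ACMG criterion code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  c(pvs = sum(criteria == "PVS1"),
    ps = sum(grepl("^PS", criteria)),
    pm = sum(grepl("^PM", criteria)),
    pp = sum(grepl("^PP", criteria)),
    ba = sum(criteria == "BA1"),
    bs = sum(grepl("^BS", criteria)),
    bp = sum(grepl("^BP", criteria)))
}

#' Combine ACMG evidence counts into a classification (vectorized core)
#'
#' Applies the published evidence-combination rules to counts per strength
#' class. Conditions of the form "1 moderate and 1 supporting" are read as
#' at-least: additional evidence of the same strength never weakens a
#' classification. A pathogenic-side and a benign-side rule firing together
#' yields `vus` (conflicting evidence), as does no rule firing at all.
#'
#' @param pvs,ps,pm,pp,ba,bs,bp Integer vectors (recycled): counts of
#'   very-strong, strong, moderate and supporting pathogenic evidence, and
#'   stand-alone, strong and supporting benign evidence.
#' @return Character vector over `pathogenic`, `likely_pathogenic`, `vus`,
#'   `likely_benign`, `benign`.
#' @export
#' @examples
#' combineAcmgCounts(pvs = 1, ps = 0, pm = 1, pp = 0, ba = 0, bs = 0, bp = 0)
combineAcmgCounts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  n <- max(lengths(list(pvs, ps, pm, pp, ba, bs, bp)))
  pvs <- rep_len(pvs, n); ps <- rep_len(ps, n); pm <- rep_len(pm, n)
  pp <- rep_len(pp, n); ba <- rep_len(ba, n); bs <- rep_len(bs, n)
  bp <- rep_len(bp, n)

  pathogenic <-
    (pvs >= 1 & (ps >= 1 | pm >= 2 | (pm >= 1 & pp >= 1) | pp >= 2)) |
    (ps >= 2) |
    (ps >= 1 & (pm >= 3 | (pm >= 2 & pp >= 2) | (pm >= 1 & pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 & pm >= 1) |
    (ps >= 1 & pm >= 1) |
    (ps >= 1 & pp >= 2) |
    (pm >= 3) |
    (pm >= 2 & pp >= 2) |
    (pm >= 1 & pp >= 4)
  benign <- (ba >= 1) | (bs >= 2)
  likely_benign <- (bs >= 1 & bp >= 1) | (bp >= 2)

  path_side <- pathogenic | likely_pathogenic
  benign_side <- benign | likely_benign

  out <- rep("vus", n)
  out[pathogenic] <- "pathogenic"
  out[!pathogenic & likely_pathogenic] <- "likely_pathogenic"
  out[benign] <- "benign"
  out[!benign & likely_benign] <- "likely_benign"
  out[path_side & benign_side] <- "vus"
  out
}

#' Combine a set of ACMG criteria into a classification
#'
#' @param criteria Character vector of evidence codes from
#'   [acmgVocabulary()]; duplicates are deduplicated silently.
#' @return One of `pathogenic`, `likely_pathogenic`, `vus`,
#'   `likely_benign`, `benign`.
#' @export
#' @examples
#' combineAcmg(c("PVS1", "PM2"))
#' combineAcmg("BA1")
combineAcmg <- function(criteria) {
  k <- .acmgCounts(criteria)
  combineAcmgCounts(k["pvs"], k["ps"], k["pm"], k["pp"], k["ba"], k["bs"],
                    k["bp"])
}

## per-predictor damaging calls -----------------------------------------------

## logical matrix (records x predictors): TRUE damaging, FALSE tolerated,
## NA unavailable. A categorical call takes precedence over a raw score.
predictorCallMatrix <- function(df, config = consensusConfig()) {
  pt <- config@predictors
  out <- matrix(NA, nrow = nrow(df), ncol = nrow(pt),
                dimnames = list(NULL, pt$name))
  for (i in seq_len(nrow(pt))) {
    verdict <- rep(NA, nrow(df))
    sc <- pt$score_col[i]
    if (!is.na(sc) && sc %in% names(df)) {
      s <- as.numeric(df[[sc]])
      verdict <- ifelse(is.na(s), NA,
                        if (pt$direction[i] == "lt") s < pt$threshold[i]
                        else s >= pt$threshold[i])
    }
    cc <- pt$call_col[i]
    if (!is.na(cc) && cc %in% names(df)) {
      calls <- toupper(trimws(as.character(df[[cc]])))
      dmg <- toupper(trimws(strsplit(pt$damaging_calls[i], ",")[[1]]))
      has_call <- !is.na(calls) & nzchar(calls)
      verdict[has_call] <- calls[has_call] %in% dmg
    }
    out[, i] <- verdict
  }
  out
}

#' Nine-predictor deleteriousness consensus
#'
#' Each predictor votes damaging / tolerated via its configured cutoff (or
#' categorical call); absent predictors are excluded from the denominator,
#' never imputed. With fewer than `minAvailable` usable predictors the
#' verdict is `insufficient`; otherwise `damaging` iff the damaging votes
#' reach the configured fraction of available predictors (default: strict
#' majority), else `tolerated`.
#'
#' @param x An [AnnotatedVariants-class] or a `data.frame` carrying the
#'   predictor score/call columns.
#' @param config A [ConsensusConfig-class].
#' @return Character vector over `damaging`, `tolerated`, `insufficient`.
#' @export
#' @examples
#' df <- data.frame(sift_score = 0.01, polyphen2_score = 0.99,
#'                  gerp_score = 5.2)
#' predictorConsensus(df)
predictorConsensus <- function(x, config = consensusConfig()) {
  df <- if (methods::is(x, "AnnotatedVariants")) variantData(x) else x
  if (!nrow(df)) return(character(0))
  m <- predictorCallMatrix(df, config)
  available <- rowSums(!is.na(m))
  damaging <- rowSums(m, na.rm = TRUE)
  frac <- config@minDamagingFraction
  hit <- if (is.na(frac)) damaging > available / 2
         else damaging / available >= frac
  out <- ifelse(available < config@minAvailable, "insufficient",
                ifelse(hit, "damaging", "tolerated"))
  unname(out)
}

#' Automatic ACMG criteria assignment from annotations
#'
#' Auto-assigns the honest-automation subset of criteria derivable from
#' annotations alone: `PVS1` (null consequence in a gene with an
#' established loss-of-function mechanism), `PM2` (absent from population
#' controls or below `pm2MaxAf`), `PP3` / `BP4` (predictor consensus
#' damaging / tolerated), `BA1` and `BS1` (frequency above the stand-alone
#' / strong benign cutoffs). Curated criteria supplied per variant (a
#' `supplied_criteria` column, comma-separated) merge in; duplicates are
#' deduplicated silently.
#'
#' @param x An [AnnotatedVariants-class] or canonical `data.frame`.
#' @param lofGenes Character vector of loss-of-function-mechanism genes.
#' @param consensus Character vector from [predictorConsensus()]
#'   (recomputed when `NULL`).
#' @param config A [TriageConfig-class] (frequency cutoffs, consensus
#'   settings).
#' @return List of character vectors, one criteria set per record.
#' @export
assignAcmgCriteria <- function(x, lofGenes = character(0), consensus = NULL,
                               config = triageConfig()) {
  df <- if (methods::is(x, "AnnotatedVariants")) variantData(x) else x
  n <- nrow(df)
  if (!n) return(list())
  if (is.null(consensus))
    consensus <- predictorConsensus(df, config@consensus)
  maxAf <- maxPopulationFrequency(df)
  lof <- c("nonsense", "frameshift", "splice_donor", "splice_acceptor")
  pvs1 <- df$consequence %in% lof & df$gene %in% toupper(lofGenes)
  pm2 <- is.na(maxAf) | maxAf < config@pm2MaxAf
  pp3 <- consensus == "damaging"
  bp4 <- consensus == "tolerated"
  ba1 <- !is.na(maxAf) & maxAf > config@ba1MinAf
  bs1 <- !is.na(maxAf) & maxAf > config@bs1MinAf
  supplied <- if ("supplied_criteria" %in% names(df))
    splitTokens(df$supplied_criteria) else rep(list(character(0)), n)
  lapply(seq_len(n), function(i) {
    auto <- c("PVS1"[pvs1[i]], "PM2"[pm2[i]], "PP3"[pp3[i]], "BP4"[bp4[i]],
              "BA1"[ba1[i]], "BS1"[bs1[i]])
    sup <- intersect(supplied[[i]], acmgVocabulary())
    unique(c(auto, sup))
  })
}

#' Second-tier (gene-centric) panel selection
#'
#' For every variant whose gene belongs to at least one virtual panel,
#' emits a hit iff the combined ACMG classification is pathogenic / likely
#' pathogenic OR the predictor consensus is damaging. Each hit records the
#' matching panels, the criteria, the classification and the consensus
#' verdict; consensus-only hits whose classification is `vus` carry a
#' `vus_flag`.
#'
#' @param variants An [AnnotatedVariants-class].
#' @param panels A non-empty [PanelSet-class].
#' @param config A [TriageConfig-class]. An empty `lofGenes` slot defaults
#'   to the union of the supplied panels.
#' @return A `data.frame` of hits with identification, `panels`
#'   (`,`-joined), `acmg_criteria`, `acmg_class`, `consensus`, `rules` and
#'   `vus_flag` columns.
#' @export
selectTierB <- function(variants, panels, config = triageConfig()) {
  stopifnot(methods::is(panels, "PanelSet"))
  if (!length(panels) || !length(panelGenes(panels)))
    stop("empty PanelSet: tier-B selection needs at least one non-empty ",
         "panel", call. = FALSE)
  df <- variantData(variants)
  inPanel <- df$gene %in% panelGenes(panels)
  if (!any(inPanel)) return(.emptyTierBHits())
  sub <- df[inPanel, , drop = FALSE]

  lofGenes <- if (length(config@lofGenes)) config@lofGenes
              else panelGenes(panels)
  consensus <- predictorConsensus(sub, config@consensus)
  criteria <- assignAcmgCriteria(sub, lofGenes, consensus, config)
  cls <- vapply(criteria, function(cr)
    if (length(cr)) combineAcmg(cr) else "vus", character(1))

  acmg_arm <- cls %in% c("pathogenic", "likely_pathogenic")
  consensus_arm <- consensus == "damaging"
  hit <- acmg_arm | consensus_arm
  if (!any(hit)) return(.emptyTierBHits())

  sub <- sub[hit, , drop = FALSE]
  criteria <- criteria[hit]
  cls <- cls[hit]
  consensus <- consensus[hit]
  acmg_arm <- acmg_arm[hit]
  consensus_arm <- consensus_arm[hit]

  panelHits <- vapply(sub$gene, function(g) {
    paste(panelNames(panels)[vapply(panelNames(panels), function(p)
      g %in% panelGenes(panels, p), logical(1))], collapse = ",")
  }, character(1), USE.NAMES = FALSE)

  rules <- mapply(function(a, c) {
    paste(c("TIER_B_ACMG"[a], "TIER_B_CONSENSUS_DAMAGING"[c]),
          collapse = ";")
  }, acmg_arm, consensus_arm)

  data.frame(
    key = variantKey(sub),
    patient_id = sub$patient_id, chrom = sub$chrom, pos = sub$pos,
    ref = sub$ref, alt = sub$alt, gene = sub$gene,
    tier = "B",
    rules = unname(rules),
    panels = panelHits,
    acmg_criteria = vapply(criteria, paste, character(1), collapse = ","),
    acmg_class = cls,
    consensus = consensus,
    vus_flag = !acmg_arm & consensus_arm,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.emptyTierBHits <- function() {
  data.frame(key = character(0), patient_id = character(0),
             chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), gene = character(0), tier = character(0),
             rules = character(0), panels = character(0),
             acmg_criteria = character(0), acmg_class = character(0),
             consensus = character(0), vus_flag = logical(0),
             stringsAsFactors = FALSE)
}
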