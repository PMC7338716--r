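## Quality retention and the dual all-variants / high-confidence pass --------
##
## The protocol triages every detected variant twice: once over all calls
## (low and high confidence) and once restricted to calls retained by the
## quality rules (QUAL > 100, DP > 10, QD > 10, seen by >= 2 callers).
## Every record keeps its confidence label so report rows stay auditable.

#' Assign zygosity from the alternate-allele read fraction
#'
#' Alleles supported by more than `hetMinFraction` (default 25%) of the
#' covering reads are heterozygous; at or above `homMinFraction` (default
#' 75%) homozygous; at or below `hetMinFraction` they are flagged
#' `low_fraction`. `NA` fractions map to `unknown`.
#'
#' @param altFraction Numeric vector of alt-read fractions in \[0, 1\].
#' @param thresholds A [QualityThresholds-class].
#' @return Character vector over `het`, `hom`, `low_fraction`, `unknown`.
#' @export
#' @examples
#' assignZygosity(c(0.26, 0.25, 0.80, NA))
assignZygosity <- function(altFraction, thresholds = qualityThresholds()) {
  if (any(!is.na(altFraction) & (altFraction < 0 | altFraction > 1)))
    stop("alt-allele fraction outside [0, 1]", call. = FALSE)
  out <- rep("unknown", length(altFraction))
  ok <- !is.na(altFraction)
  out[ok & altFraction <= thresholds@hetMinFraction] <- "low_fraction"
  out[ok & altFraction > thresholds@hetMinFraction &
        altFraction < thresholds@homMinFraction] <- "het"
  out[ok & altFraction >= thresholds@homMinFraction] <- "hom"
  out
}

## number of distinct caller names in a delimited provenance string
callerCount <- function(callers) {
  lengths(splitTokens(callers))
}

#' High-confidence retention test
#'
#' A record is retained as high confidence iff quality score >
#' `minQual`, read depth > `minDepth`, quality-by-depth > `minQd` (all
#' strict) and it was detected by at least `minCallers` distinct callers.
#' Any absent metric fails the test. The caller-concordance rule can be
#' switched off for exports that carry no caller provenance.
#'
#' @param x An [AnnotatedVariants-class] or a `data.frame` with columns
#'   `qual`, `depth`, `qd`, `callers`.
#' @param thresholds A [QualityThresholds-class].
#' @param checkCallers Apply the multi-caller concordance rule
#'   (default `TRUE`).
#' @return Logical vector, one value per record.
#' @export
isHighConfidence <- function(x, thresholds = qualityThresholds(),
                             checkCallers = TRUE) {
  df <- if (methods::is(x, "AnnotatedVariants")) variantData(x) else x
  ok <- !is.na(df$qual) & df$qual > thresholds@minQual &
    !is.na(df$depth) & df$depth > thresholds@minDepth &
    !is.na(df$qd) & df$qd > thresholds@minQd
  if (checkCallers)
    ok <- ok & callerCount(df$callers) >= thresholds@minCallers
  ok
}

#' Dual all-variants / high-confidence pass
#'
#' Attaches a `confidence` label (`"high"`/`"low"`) and a zygosity call to
#' every record and returns both the full set and the high-confidence
#' subset, so the entire triage protocol can be run on each. When no record
#' in the input carries caller provenance, the concordance rule is skipped
#' with a warning rather than failing everything.
#'
#' @param variants An [AnnotatedVariants-class].
#' @param thresholds A [QualityThresholds-class].
#' @return A list with elements `all` (every record, labelled) and
#'   `high_confidence` (the retained subset), both
#'   [AnnotatedVariants-class] objects whose tables carry a `confidence`
#'   column.
#' @export
dualPass <- function(variants, thresholds = qualityThresholds()) {
  df <- variantData(variants)
  checkCallers <- TRUE
  if (nrow(df) && all(callerCount(df$callers) == 0)) {
    warning("no caller provenance in input; ",
            "multi-caller concordance rule skipped", call. = FALSE)
    checkCallers <- FALSE
  }
  hc <- if (nrow(df)) isHighConfidence(df, thresholds, checkCallers)
        else logical(0)
  df$confidence <- ifelse(hc, "high", "low")
  known <- !is.na(df$alt_fraction)
  df$zygosity[known] <- assignZygosity(df$alt_fraction[known], thresholds)
  all <- AnnotatedVariants(df)
  list(all = all, high_confidence = all[which(hc)])
}
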