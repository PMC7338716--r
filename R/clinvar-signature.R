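## ClinVar aggregate interpretation signatures -------------------------------
##
## A "signature" is the per-variant tally of submitter interpretations as
## annotation platforms print it, e.g. "Pathogenic(4);Risk factor(4);Benign(1)".
## Internally a signature is a named integer vector over the canonical class
## vocabulary; parsing is case-insensitive and tolerant of spelling variants
## such as "Drug-response".

#' Canonical ClinVar interpretation classes
#'
#' Classes in canonical formatting order: descending clinical severity
#' first, then the non-Mendelian classes.
#'
#' @return Character vector of class labels.
#' @export
clinvarClasses <- function() {
  c("Pathogenic", "Likely pathogenic", "Uncertain significance",
    "Likely benign", "Benign", "Risk factor", "Protective", "Drug response",
    "Other")
}

## normalize one vector of raw labels to canonical classes; unknown labels
## map to "Other"
.normalizeClinvarLabel <- function(label) {
  canon <- clinvarClasses()
  key <- tolower(gsub("[-_]+", " ", trimws(label)))
  key <- gsub("[[:space:]]+", " ", key)
  idx <- match(key, tolower(canon))
  out <- canon[idx]
  out[is.na(idx)] <- "Other"
  out
}

#' Parse a ClinVar aggregate signature string
#'
#' Accepts the semicolon-separated `Label(count)` format, e.g.
#' `"Pathogenic(4);Risk factor(4);Benign(1)"`. Labels are matched
#' case-insensitively with internal whitespace and hyphen variants
#' tolerated (`"Drug-response"` normalizes to `"Drug response"`). Labels
#' outside the canonical vocabulary are bucketed into `Other` with a
#' warning. Counts for the same canonical class are summed.
#'
#' @param s A single signature string.
#' @return Named integer vector of interpretation counts, in canonical
#'   class order.
#' @export
#' @examples
#' parseClinvarSignature("Pathogenic(4);Risk factor(4)")
#' parseClinvarSignature("risk factor(3)")
parseClinvarSignature <- function(s) {
  if (length(s) != 1 || is.na(s) || !nzchar(trimws(s)))
    stop("empty ClinVar signature string", call. = FALSE)
  tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    stop("empty ClinVar signature string", call. = FALSE)
  m <- regmatches(tokens, regexec("^(.*)\\(([0-9]+)\\)$", tokens))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("cannot parse ClinVar signature token: '", tokens[bad][1], "'",
         call. = FALSE)
  labels <- vapply(m, `[`, character(1), 2)
  counts <- as.integer(vapply(m, `[`, character(1), 3))
  if (any(counts < 1))
    stop("cannot parse ClinVar signature token: '",
         tokens[counts < 1][1], "' (count must be a positive integer)",
         call. = FALSE)
  canon <- .normalizeClinvarLabel(labels)
  if (any(canon == "Other" &
          tolower(trimws(labels)) != "other"))
    warning("unknown ClinVar class label(s) mapped to 'Other': ",
            paste(unique(trimws(labels[canon == "Other" &
                                      tolower(trimws(labels)) != "other"])),
                  collapse = ", "), call. = FALSE)
  tab <- tapply(counts, factor(canon, levels = clinvarClasses()), sum)
  out <- as.integer(tab[!is.na(tab)])
  names(out) <- names(tab[!is.na(tab)])
  out
}

#' Format a ClinVar signature canonically
#'
#' Renders a counts vector as `Label(count)` tokens joined by `";"`, with
#' classes in the fixed canonical order ([clinvarClasses()]), so that
#' `parseClinvarSignature(formatClinvarSignature(x))` is the identity
#' regardless of input order.
#'
#' @param sig Named integer/numeric vector of counts (names are class
#'   labels, normalized before formatting).
#' @return A single signature string.
#' @export
#' @examples
#' formatClinvarSignature(c(Benign = 5, Pathogenic = 1))
formatClinvarSignature <- function(sig) {
  if (!length(sig) || is.null(names(sig)))
    stop("signature must be a named vector with at least one class",
         call. = FALSE)
  if (any(is.na(sig)) || any(sig < 1) || any(sig != round(sig)))
    stop("signature counts must be positive integers", call. = FALSE)
  canon <- .normalizeClinvarLabel(names(sig))
  tab <- tapply(as.integer(sig), factor(canon, levels = clinvarClasses()),
                sum)
  tab <- tab[!is.na(tab)]
  paste0(names(tab), "(", as.integer(tab), ")", collapse = ";")
}

## vectorized helper: counts for a subset of classes across a character
## vector of signature strings (NA string -> 0)
.signatureClassCounts <- function(strings, classes) {
  vapply(strings, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(0L)
    sig <- suppressWarnings(parseClinvarSignature(s))
    sum(sig[intersect(names(sig), classes)])
  }, integer(1), USE.NAMES = FALSE)
}

#' Maximum population allele frequency of variant records
#'
#' The maximum over the reported allele-frequency sources (1000 Genomes,
#' ExAC, ESP5400); `NA` when no source reports the allele.
#'
#' @param x An [AnnotatedVariants-class] object or a `data.frame` with
#'   columns `af_g1000`, `af_exac`, `af_esp5400`.
#' @return Numeric vector, one value per record (`NA` = not observed in any
#'   source).
#' @export
#' @examples
#' av <- AnnotatedVariants(data.frame(
#'   patient_id = "P1", chrom = "1", pos = 1000, ref = "A", alt = "G",
#'   gene = "F5", af_g1000 = 0.01, af_exac = 0.03))
#' maxPopulationFrequency(av)
maxPopulationFrequency <- function(x) {
  df <- if (methods::is(x, "AnnotatedVariants")) variantData(x) else x
  cols <- c("af_g1000", "af_exac", "af_esp5400")
  missing <- setdiff(cols, names(df))
  for (col in missing) df[[col]] <- NA_real_
  m <- as.matrix(df[, cols, drop = FALSE])
  out <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  unname(out)
}
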