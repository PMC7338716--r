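## VCF ingestion --------------------------------------------------------------
##
## Upstream callers emit VCF 4.x; annotations travel in INFO fields under a
## declared dialect. Reading goes through Bioconductor's VariantAnnotation;
## multi-allelic records are decomposed into one record per alternate
## allele, conserving the total allele count.

#' Default VCF annotation dialect
#'
#' Maps canonical variant-model fields onto INFO keys. Override entries (or
#' drop them) to match the annotation pipeline that produced the VCF.
#' `QUAL` comes from the VCF QUAL column, depth from `DP`,
#' quality-by-depth from `QD`, the alternate-allele read fraction from an
#' `AF_READS` INFO field when present, and the caller set from a
#' comma-separated `CALLERS` INFO field.
#'
#' @return Named character vector mapping canonical fields to INFO keys.
#' @export
defaultVcfDialect <- function() {
  c(gene = "GENE", consequence = "CONSEQUENCE", region = "REGION",
    clinvar = "CLNSIG", hgvs_c = "HGVSC", hgvs_p = "HGVSP",
    pharmgkb_level = "PHARMGKB", inheritance = "INHERITANCE",
    af_g1000 = "AF_G1000", af_exac = "AF_EXAC", af_esp5400 = "AF_ESP5400",
    qd = "QD", alt_fraction = "AF_READS", callers = "CALLERS",
    sift_score = "SIFT", polyphen2_score = "POLYPHEN2",
    mutation_taster_call = "MT_CALL", mutation_assessor_score = "MA",
    fathmm_score = "FATHMM", dbscsnv_ada_score = "DBSCSNV",
    gerp_score = "GERP", genocanyon_score = "GENOCANYON",
    fitcons_score = "FITCONS")
}

#' Read annotated variants from a VCF file
#'
#' Loads a VCF 4.x file, decomposes multi-allelic records into one record
#' per alternate allele, and maps INFO annotations onto the canonical
#' variant model through a declared dialect. Records lacking an annotation
#' (e.g. no `DP`) are still loaded with that field absent.
#'
#' @param path Path to a VCF (optionally bgzipped) file.
#' @param dialect Named character vector mapping canonical fields to INFO
#'   keys (default [defaultVcfDialect()]); unmapped fields stay absent.
#' @param patientId Patient identifier; defaults to the first sample name
#'   in the VCF, or `"sample1"` for a site-only file.
#' @return An [AnnotatedVariants-class].
#' @export
readVcfVariants <- function(path, dialect = defaultVcfDialect(),
                            patientId = NULL) {
  if (!file.exists(path))
    stop("VCF file not found: ", path, call. = FALSE)
  vcf0 <- VariantAnnotation::readVcf(path, genome = "hg19")
  ## record identifiers, replicated per alternate allele before expansion
  ids0 <- names(SummarizedExperiment::rowRanges(vcf0))
  nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf0))
  ids <- if (is.null(ids0)) NULL else rep(ids0, nAlt)
  vcf <- VariantAnnotation::expand(vcf0)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (is.null(patientId)) {
    smp <- colnames(vcf)
    patientId <- if (length(smp)) smp[1] else "sample1"
  }
  rsid <- rep(NA_character_, n)
  if (!is.null(ids)) {
    isRs <- grepl("^rs[0-9]+$", ids)
    rsid[isRs] <- ids[isRs]
  }
  df <- data.frame(
    patient_id = rep(patientId, n),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    gene = rep(NA_character_, n),
    rsid = rsid,
    qual = as.numeric(rr$QUAL),
    stringsAsFactors = FALSE
  )
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(key) {
    if (!key %in% names(info)) return(NULL)
    v <- info[[key]]
    if (methods::is(v, "List")) v <- vapply(v, function(e) {
      if (!length(e)) NA else as.character(e[1])
    }, character(1))
    as.vector(v)
  }
  for (field in names(dialect)) {
    v <- getInfo(dialect[[field]])
    if (!is.null(v)) df[[field]] <- v
  }
  dp <- getInfo("DP")
  if (!is.null(dp)) df$depth <- as.numeric(dp)
  ## genotype DP as a fallback for per-sample depth
  if (is.null(dp) && "DP" %in% names(VariantAnnotation::geno(vcf))) {
    g <- VariantAnnotation::geno(vcf)$DP
    if (ncol(g) >= 1) df$depth <- as.numeric(g[, 1])
  }
  AnnotatedVariants(df)
}
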