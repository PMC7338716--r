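## small internal helpers shared across modules

## run expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## split a delimited provenance field ("gatk;freebayes") into distinct
## non-empty tokens
splitTokens <- function(x, split = "[;,|]") {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, split), function(t) {
    t <- trimws(t)
    unique(t[nzchar(t)])
  })
}

joinTokens <- function(x, collapse = ",") {
  vapply(x, function(t) paste(t, collapse = collapse), character(1))
}

## stable digest of an R object (configuration provenance); md5 of its
## canonical JSON rendering
objectDigest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

## named list of the public slots of an S4 config object, for provenance
slotList <- function(object) {
  nm <- methods::slotNames(class(object))
  out <- lapply(nm, function(s) {
    v <- methods::slot(object, s)
    if (methods::isVirtualClass(class(v)) || isS4(v)) slotList(v) else v
  })
  names(out) <- nm
  out
}
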