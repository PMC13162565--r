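# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Round half-up to integer; seconds-to-milliseconds conversions must not
# depend on the platform's banker's rounding.
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

secToMs <- function(sec) roundHalfUp(sec * 1000)

clampNum <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# MD5 content digest of a file (audit trail; see artifact ledger).
fileDigest <- function(path) {
  stopifnot(file.exists(path))
  unname(tools::md5sum(path))
}

# Digest of an arbitrary R object via its canonical JSON rendering.
objectDigest <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  fileDigest(tmp)
}
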