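## Deterministic 31-bit string hash (FNV-style fold), used to derive
## per-record seeds from (master seed, genotype, replicate) so that results
## do not depend on execution order.
stableHash <- function(...) {
  s <- paste(..., sep = "\r")
  h <- 2166136261
  for (c in utf8ToInt(s)) {
    h <- (h * 16777619) %% 2147483629
    h <- bitwXor(as.integer(h), c)
  }
  as.integer(h %% 2147483629L) + 1L
}

#' Derive the seed of one simulated competition
#'
#' Stable hash of (master seed, plasmid label, mutation label, replicate
#' index), so each record's random stream is reproducible independently of
#' the order in which records are generated.
#'
#' @param master integer master seed.
#' @param plasmid,mutation genotype labels (`"none"` for absent).
#' @param replicate replicate index.
#' @return an integer seed in \[1, 2^31).
#' @export
deriveSeed <- function(master, plasmid, mutation, replicate) {
  stableHash(master, plasmid, mutation, replicate)
}

genotypeKey <- function(plasmid, mutation) paste(plasmid, mutation, sep = ":")

isWildtype <- function(plasmid, mutation) {
  plasmid == NONE_LABEL & mutation == NONE_LABEL
}

## Short deterministic hex digest of an R object's deparsed form, used to
## stamp output files so a report can be matched to its configuration.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = ";")
  h1 <- stableHash("a", s)
  h2 <- stableHash("b", s)
  sprintf("%08x%08x", h1, h2)
}

stopIfNot <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}
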