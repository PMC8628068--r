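# Independent oracles used across tests. These deliberately avoid the code
# paths (and helper packages) used by the implementation.

# Brute-force CAI: explicit product of weights, n-th root, manual codon split.
bruteForceCai <- function(seqChar, table) {
  w <- codonWeights(table)
  code <- Biostrings::GENETIC_CODE
  n <- nchar(seqChar) / 3
  prodW <- 1
  count <- 0
  for (i in seq_len(n)) {
    codon <- substr(seqChar, 3 * i - 2, 3 * i)
    if (!(codon %in% names(code))) next
    if (code[[codon]] == "*") next
    prodW <- prodW * w[[codon]]
    count <- count + 1
  }
  prodW^(1 / count)
}

# Recursive permutation enumerator (independent of pracma).
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPerms(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# Brute-force exact two-sided Spearman permutation p value.
bruteSpearmanP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  ps <- allPerms(length(y))
  hits <- vapply(ps, function(p) abs(cor(rx, ry[p])) >= obs - 1e-12,
                 logical(1))
  mean(hits)
}

# A tiny fitness table with known structure: one plasmid, one mutation,
# fixed replicate values (already normalized to the plasmid-free wild type).
tinyFitnessTable <- function(wWt, wP, wM, wC) {
  data.frame(
    plasmid = rep(c("none", "pA", "none", "pA"),
                  times = c(length(wWt), length(wP), length(wM), length(wC))),
    mutation = rep(c("none", "none", "m1", "m1"),
                   times = c(length(wWt), length(wP), length(wM),
                             length(wC))),
    replicate = c(seq_along(wWt), seq_along(wP), seq_along(wM),
                  seq_along(wC)),
    w = c(wWt, wP, wM, wC),
    level = "vs_plasmid_free_wildtype")
}
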