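## Floor applied to zero-frequency sense codons before the geometric mean,
## following the standard relative-adaptiveness convention: keeps CAI > 0.
CAI_WEIGHT_FLOOR <- 0.01

#' Build a relative-adaptiveness table from codon frequencies
#'
#' Within each synonymous family of the standard genetic code, each codon's
#' weight is its frequency divided by the family's maximal frequency, so the
#' most used codon gets weight 1. Zero-frequency sense codons are floored at
#' 0.01 (a CAI of exactly 0 from one unused codon would be uninformative);
#' a family with no observed usage at all gets uniform weight 1. Single
#' codon families (ATG, TGG) have weight 1 by construction. Stop codons get
#' `NA` and are excluded from CAI.
#'
#' @param frequencies named numeric vector of codon counts or frequencies
#'   over all 64 DNA triplets (zeros allowed); T and U spellings both
#'   accepted.
#' @param source label for the reference set.
#' @return a [CodonUsageTable-class].
#' @examples
#' freq <- stats::setNames(rep(1, 64), names(Biostrings::GENETIC_CODE))
#' buildWeightTable(freq)  # uniform usage: every sense weight is 1
#' @export
buildWeightTable <- function(frequencies, source = "custom") {
  stopIfNot(is.numeric(frequencies) && !is.null(names(frequencies)),
            "frequencies must be a named numeric vector")
  names(frequencies) <- toupper(chartr("Uu", "Tt", names(frequencies)))
  code <- Biostrings::GENETIC_CODE
  missing <- setdiff(names(code), names(frequencies))
  stopIfNot(length(missing) == 0,
            "missing codons: ", paste(head(missing, 5), collapse = ", "))
  stopIfNot(all(frequencies >= 0), "frequencies must be nonnegative")
  freq <- frequencies[names(code)]
  w <- stats::setNames(rep(NA_real_, 64), names(code))
  for (aa in setdiff(unique(code), "*")) {
    codons <- names(code)[code == aa]
    top <- max(freq[codons])
    if (top == 0) {
      w[codons] <- 1
    } else {
      w[codons] <- pmax(freq[codons] / top, CAI_WEIGHT_FLOOR)
    }
  }
  new("CodonUsageTable", weights = w, source = source)
}

#' Read a codon-usage table file
#'
#' Auto-detects the dialect: either the EMBOSS `.cut` layout (columns codon,
#' amino acid, fraction, frequency per 1000, count — the count column is
#' used) or a 2-column TSV of codon and count. Lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @param source label; defaults to the file name.
#' @return a [CodonUsageTable-class].
#' @export
readCodonTable <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  stopIfNot(length(lines) > 0, "no data lines in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  ncols <- lengths(fields)
  if (all(ncols >= 5)) {
    codons <- vapply(fields, `[`, character(1), 1)
    counts <- as.numeric(vapply(fields, `[`, character(1), 5))
  } else if (all(ncols == 2)) {
    codons <- vapply(fields, `[`, character(1), 1)
    counts <- as.numeric(vapply(fields, `[`, character(1), 2))
  } else {
    stop("unrecognized codon table dialect in ", path,
         " (expected EMBOSS .cut or 2-column TSV)", call. = FALSE)
  }
  stopIfNot(!anyNA(counts), "non-numeric counts in ", path)
  buildWeightTable(stats::setNames(counts, codons), source = source)
}

#' A synthetic default reference codon-usage table
#'
#' Deterministic stand-in for a highly-expressed-gene reference set of a
#' GC-moderate enterobacterium: within each synonymous family, codons are
#' ranked by a fixed preference for C/G-ending triplets and assigned
#' geometrically decaying counts. It is a synthetic construction (not
#' measured usage of any organism) intended for simulations and tests;
#' supply a real table via [readCodonTable()] for analyses of real plasmids.
#'
#' @return a [CodonUsageTable-class].
#' @export
defaultCodonTable <- function() {
  code <- Biostrings::GENETIC_CODE
  freq <- stats::setNames(numeric(64), names(code))
  for (aa in unique(code)) {
    codons <- sort(names(code)[code == aa])
    ## deterministic preference: GC-richer third position first
    third <- substr(codons, 3, 3)
    pref <- order(match(third, c("C", "G", "T", "A")), codons)
    freq[codons[pref]] <- 1000 * 0.4^(seq_along(codons) - 1)
  }
  buildWeightTable(freq, source = "synthetic_enterobacterial_reference")
}

#' Codon adaptation index of an ORF
#'
#' Geometric mean of the relative-adaptiveness weights over the ORF's
#' codons: `exp(mean(log w))`. The terminal stop codon is excluded; internal
#' stop codons are excluded with a warning; codons containing ambiguous
#' bases are skipped and their number reported in attribute
#' `skippedAmbiguous`. Values lie in (0, 1], with 1 meaning every codon is
#' its family's most used codon.
#'
#' @param orfSequence a [Biostrings::DNAString] or character string whose
#'   length is divisible by 3.
#' @param table a [CodonUsageTable-class].
#' @return the CAI (numeric scalar) with attribute `skippedAmbiguous`.
#' @examples
#' tab <- defaultCodonTable()
#' cai("ATGGGC", tab)
#' @export
cai <- function(orfSequence, table) {
  s <- toupper(as.character(orfSequence))
  stopIfNot(nchar(s) > 0, "empty ORF sequence")
  stopIfNot(nchar(s) %% 3 == 0,
            "ORF length ", nchar(s), " not divisible by 3")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  code <- Biostrings::GENETIC_CODE
  ambiguous <- !(codons %in% names(code))
  codons2 <- codons[!ambiguous]
  isStop <- !is.na(code[codons2]) & code[codons2] == "*"
  ## terminal stop is expected; any others are flagged
  if (length(codons2) && isStop[length(codons2)])
    isStop[length(codons2)] <- NA  # marker: silently drop
  internalStops <- sum(isStop, na.rm = TRUE)
  if (internalStops > 0)
    warning(internalStops, " internal stop codon(s) excluded from CAI")
  keep <- codons2[is.na(isStop) == FALSE & !isStop]
  stopIfNot(length(keep) > 0, "no scorable codons in ORF")
  w <- codonWeights(table)[keep]
  out <- exp(mean(log(w)))
  attr(out, "skippedAmbiguous") <- sum(ambiguous)
  out
}
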