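#' GC content of a nucleotide sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes are excluded from both
#' numerator and denominator. Strand-invariant (complementation swaps A/T
#' and G/C).
#'
#' @param sequence a [Biostrings::DNAString], character string, or
#'   [PlasmidRecord-class].
#' @return GC percentage.
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(sequence) {
  if (is(sequence, "PlasmidRecord")) sequence <- plasmidSequence(sequence)
  s <- Biostrings::DNAString(toupper(as.character(sequence)))
  stopIfNot(length(s) > 0, "empty sequence")
  counts <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  total <- sum(counts)
  stopIfNot(total > 0, "sequence has no unambiguous bases")
  100 * sum(counts[c("G", "C")]) / total
}

#' Plasmid copy number from the sequencing-depth ratio
#'
#' Mean per-position sequencing depth of the plasmid divided by the mean
#' depth of the chromosome, the standard read-depth proxy for plasmid copy
#' number. Invariant to uniform depth scaling.
#'
#' @param plasmid,chromosome [DepthProfile-class] objects.
#' @return copies per chromosome (dimensionless).
#' @export
copyNumberProxy <- function(plasmid, chromosome) {
  stopIfNot(is(plasmid, "DepthProfile") && is(chromosome, "DepthProfile"),
            "inputs must be DepthProfile objects")
  cm <- meanDepth(chromosome)
  stopIfNot(cm > 0, "chromosome mean depth must be > 0")
  meanDepth(plasmid) / cm
}

#' Extract ORF sequences from an annotated record
#'
#' Strand-aware extraction of every coding feature: minus-strand features
#' are reverse-complemented; features whose end coordinate exceeds the
#' record length wrap around the origin of a circular record and are
#' returned as one contiguous codon string. Coordinates are 1-based
#' inclusive.
#'
#' @param record a [PlasmidRecord-class].
#' @return a [Biostrings::DNAStringSet] named by feature id.
#' @export
extractOrfs <- function(record) {
  stopIfNot(is(record, "PlasmidRecord"), "record must be a PlasmidRecord")
  seq <- plasmidSequence(record)
  len <- length(seq)
  f <- orfFeatures(record)
  out <- Biostrings::DNAStringSet()
  if (nrow(f) == 0) return(out)
  seqs <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    start <- f$start[i]; end <- f$end[i]
    if (start < 1 || end < start || end - start + 1 > len)
      stop("feature '", f$id[i], "' has invalid coordinates ", start, "..",
           end, call. = FALSE)
    if (end <= len) {
      s <- Biostrings::subseq(seq, start, end)
    } else {
      stopIfNot(record@circular,
                "feature '", f$id[i],
                "' spans the origin of a linear record")
      s <- Biostrings::xscat(Biostrings::subseq(seq, start, len),
                             Biostrings::subseq(seq, 1, end - len))
    }
    if (f$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[[i]] <- s
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- f$id
  out
}

#' Per-ORF feature table of a plasmid record
#'
#' Extracts every annotated ORF and computes its length in codons and its
#' codon adaptation index against a reference table.
#'
#' @param record a [PlasmidRecord-class].
#' @param table a [CodonUsageTable-class].
#' @return data.frame with columns `id`, `start`, `end`, `strand`,
#'   `lengthCodons`, `cai`.
#' @export
orfFeatureTable <- function(record, table = defaultCodonTable()) {
  orfs <- extractOrfs(record)
  f <- orfFeatures(record)
  if (length(orfs) == 0)
    return(cbind(f, lengthCodons = integer(), cai = numeric()))
  caiVal <- vapply(seq_along(orfs), function(i)
    as.numeric(cai(orfs[[i]], table)), numeric(1))
  cbind(f,
        lengthCodons = as.integer(Biostrings::width(orfs) / 3L),
        cai = caiVal)
}

#' Summary features of a plasmid
#'
#' The per-plasmid quantities screened against fitness cost: replicon size,
#' GC content, mean per-ORF CAI, and (when depth profiles are supplied) the
#' depth-ratio copy-number proxy.
#'
#' @param record a [PlasmidRecord-class].
#' @param table a [CodonUsageTable-class].
#' @param plasmidDepth,chromosomeDepth optional [DepthProfile-class] objects
#'   for the copy-number proxy.
#' @return one-row data.frame with `plasmid`, `sizeBp`, `gcPercent`,
#'   `meanCai`, `copyNumber` (NA if no depths given).
#' @export
plasmidFeatureSummary <- function(record, table = defaultCodonTable(),
                                  plasmidDepth = NULL,
                                  chromosomeDepth = NULL) {
  orfTab <- orfFeatureTable(record, table)
  cn <- if (!is.null(plasmidDepth) && !is.null(chromosomeDepth))
    copyNumberProxy(plasmidDepth, chromosomeDepth) else NA_real_
  data.frame(plasmid = record@name,
             sizeBp = length(plasmidSequence(record)),
             gcPercent = gcContent(record),
             meanCai = if (nrow(orfTab)) mean(orfTab$cai) else NA_real_,
             copyNumber = cn)
}
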