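#' Extract the record table from a competition assay set
#' @param x a `CompetitionAssaySet`
#' @return data.frame of per-replicate competition records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "CompetitionAssaySet", function(x) x@records)

#' Codon weights of a codon usage table
#' @param x a `CodonUsageTable`
#' @return named numeric vector over the 64 codons (stop codons `NA`)
#' @export
setGeneric("codonWeights", function(x) standardGeneric("codonWeights"))

#' @rdname codonWeights
#' @export
setMethod("codonWeights", "CodonUsageTable", function(x) x@weights)

#' Mean per-position sequencing depth
#' @param x a `DepthProfile`
#' @return mean depth (reads per position)
#' @export
setGeneric("meanDepth", function(x) standardGeneric("meanDepth"))

#' @rdname meanDepth
#' @export
setMethod("meanDepth", "DepthProfile", function(x) mean(x@depth))

#' Replicon label
#' @param x a `DepthProfile`
#' @return character label
#' @export
setGeneric("replicon", function(x) standardGeneric("replicon"))

#' @rdname replicon
#' @export
setMethod("replicon", "DepthProfile", function(x) x@replicon)

#' Coding features of a plasmid record
#' @param x a `PlasmidRecord`
#' @return data.frame with columns id, start, end, strand
#' @export
setGeneric("orfFeatures", function(x) standardGeneric("orfFeatures"))

#' @rdname orfFeatures
#' @export
setMethod("orfFeatures", "PlasmidRecord", function(x) x@features)

#' Nucleotide sequence of a plasmid record
#' @param x a `PlasmidRecord`
#' @return a [Biostrings::DNAString]
#' @export
setGeneric("plasmidSequence", function(x) standardGeneric("plasmidSequence"))

#' @rdname plasmidSequence
#' @export
setMethod("plasmidSequence", "PlasmidRecord", function(x) x@sequence)

setMethod("show", "SimulationConfig", function(object) {
  g <- object@genotypes
  cat("SimulationConfig:", nrow(g), "genotypes\n")
  cat("  replicates:", object@replicates,
      "(wild type:", paste0(object@wildtypeReplicates, ")"), "\n")
  cat("  expansion factor:", object@expansionFactor,
      " events/measurement:", object@eventsPerMeasurement, "\n")
  cat("  growth noise sd:", object@growthNoiseSd,
      " seed:", object@seed, "\n")
})

setMethod("show", "CompetitionAssaySet", function(object) {
  r <- object@records
  cat("CompetitionAssaySet:", nrow(r), "competition records,",
      length(unique(paste(r$plasmid, r$mutation))), "genotypes\n")
  if (!is.null(object@metadata$seed))
    cat("  simulated (seed ", object@metadata$seed, ")\n", sep = "")
})

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable from reference set '", object@source, "'\n", sep = "")
  w <- object@weights
  cat("  sense codons:", sum(!is.na(w)),
      " optimal (w = 1):", sum(!is.na(w) & w == 1), "\n")
})

setMethod("show", "PlasmidRecord", function(object) {
  cat("PlasmidRecord '", object@name, "': ",
      length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", ", ",
      nrow(object@features), " coding features\n", sep = "")
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile '", object@replicon, "': ",
      length(object@depth), " positions, mean depth ",
      format(mean(object@depth), digits = 5), "\n", sep = "")
})
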