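#' @import methods
#' @importFrom stats median aov TukeyHSD pf pt rnorm rmultinom rlnorm runif
#' @importFrom utils read.table write.table head
NULL

## Label used for an absent determinant: a genotype is a (plasmid, mutation)
## pair and the wild type is (NONE_LABEL, NONE_LABEL).
NONE_LABEL <- "none"

#' Simulation configuration for synthetic competition experiments
#'
#' Describes the true fitness landscape and the experimental design that the
#' generator emulates: pairwise competitions of a GFP-negative test strain
#' against a GFP-positive reference, started from a 1:1 mixture diluted
#' 1:400 into fresh medium, with 10,000 cytometry events recorded per
#' measurement, six replicates per genotype and 36 for the wild type.
#'
#' @slot genotypes data.frame with columns `plasmid` and `mutation`; the
#'   label `"none"` marks an absent determinant and the wild type is
#'   `("none", "none")`.
#' @slot trueW named numeric vector of true marginal relative fitness values,
#'   one per plasmid and per mutation label (dimensionless, > 0). Combination
#'   genotypes get `trueW[plasmid] * trueW[mutation] + epistasisShift`; the
#'   wild type has fitness 1 by construction.
#' @slot epistasisShift named numeric vector of additive deviations from the
#'   multiplicative expectation, named `"plasmid:mutation"`; absent entries
#'   mean 0.
#' @slot replicates integer, replicates per non-wild-type genotype.
#' @slot wildtypeReplicates integer, replicates for the wild type.
#' @slot expansionFactor numeric, total fold-growth of the reference
#'   competitor over one competition cycle (> 1).
#' @slot eventsPerMeasurement integer, cytometry events per measurement.
#' @slot growthNoiseSd numeric, standard deviation of mean-one lognormal
#'   noise applied to each competitor's fold-expansion per replicate.
#' @slot seed integer master seed; per-record seeds are derived from it.
#' @export
setClass("SimulationConfig",
  representation(
    genotypes = "data.frame",
    trueW = "numeric",
    epistasisShift = "numeric",
    replicates = "integer",
    wildtypeReplicates = "integer",
    expansionFactor = "numeric",
    eventsPerMeasurement = "integer",
    growthNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  g <- object@genotypes
  if (!all(c("plasmid", "mutation") %in% names(g)))
    msg <- c(msg, "genotypes must have columns 'plasmid' and 'mutation'")
  if (any(object@trueW <= 0))
    msg <- c(msg, "all true fitness values must be > 0")
  if (object@expansionFactor <= 1)
    msg <- c(msg, "expansionFactor must be > 1")
  if (object@eventsPerMeasurement < 1)
    msg <- c(msg, "eventsPerMeasurement must be >= 1")
  if (object@replicates < 1 || object@wildtypeReplicates < 1)
    msg <- c(msg, "replicate counts must be >= 1")
  if (object@growthNoiseSd < 0)
    msg <- c(msg, "growthNoiseSd must be >= 0")
  if (length(object@epistasisShift)) {
    combos <- paste(g$plasmid, g$mutation, sep = ":")
    bad <- setdiff(names(object@epistasisShift), combos)
    if (length(bad))
      msg <- c(msg, paste0("epistasisShift names not among genotypes: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' A set of competition assay records
#'
#' Thin container for the table of per-replicate competition records
#' (initial/final cell numbers of the GFP-negative test strain and the
#' GFP-positive reference, on a common scale) together with the metadata of
#' the run that produced them.
#'
#' @slot records data.frame with design columns `plasmid`, `mutation`,
#'   `replicate` and count columns `n_initial_gfp_neg`, `n_initial_gfp_pos`,
#'   `n_final_gfp_neg`, `n_final_gfp_pos` (plus latent-count columns when the
#'   set came from the simulator).
#' @slot metadata list of run metadata (seed, configuration echo).
#' @export
setClass("CompetitionAssaySet",
  representation(records = "data.frame", metadata = "list")
)

setValidity("CompetitionAssaySet", function(object) {
  need <- c("plasmid", "mutation", "replicate",
            "n_initial_gfp_neg", "n_initial_gfp_pos",
            "n_final_gfp_neg", "n_final_gfp_pos")
  missing <- setdiff(need, names(object@records))
  if (length(missing))
    return(paste0("records missing columns: ", paste(missing, collapse = ", ")))
  cnt <- object@records[, need[-(1:3)]]
  if (any(unlist(cnt) < 0))
    return("counts must be nonnegative")
  TRUE
})

#' Codon relative-adaptiveness weights
#'
#' Per-codon relative adaptiveness derived from a reference gene set: within
#' each synonymous family the most used codon gets weight 1 and the others
#' their usage ratio to it. Stop codons carry `NA` and are excluded from CAI.
#'
#' @slot weights named numeric vector over the 64 DNA codons; sense codons in
#'   (0, 1], stop codons `NA`.
#' @slot source label of the reference set the weights came from.
#' @export
setClass("CodonUsageTable",
  representation(weights = "numeric", source = "character")
)

setValidity("CodonUsageTable", function(object) {
  w <- object@weights
  if (length(w) != 64 || is.null(names(w)))
    return("weights must be a named vector over the 64 codons")
  code <- Biostrings::GENETIC_CODE
  if (!setequal(names(w), names(code)))
    return("weight names must be the 64 DNA triplets")
  sense <- names(code)[code != "*"]
  ws <- w[sense]
  if (any(is.na(ws)) || any(ws <= 0) || any(ws > 1))
    return("sense-codon weights must lie in (0, 1]")
  fam <- split(ws, code[sense])
  if (!all(vapply(fam, function(x) isTRUE(all.equal(max(x), 1)), logical(1))))
    return("each synonymous family must have maximum weight 1")
  TRUE
})

#' An annotated (circular) plasmid sequence record
#'
#' @slot name record name.
#' @slot sequence a [Biostrings::DNAString] with the replicon sequence.
#' @slot circular logical, whether the molecule is circular.
#' @slot features data.frame of coding features with columns `id`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates; `end` may exceed the
#'   sequence length on a circular record to denote an origin-spanning
#'   feature).
#' @export
setClass("PlasmidRecord",
  representation(name = "character", sequence = "DNAString",
                 circular = "logical", features = "data.frame")
)

setValidity("PlasmidRecord", function(object) {
  f <- object@features
  if (nrow(f) == 0) return(TRUE)
  need <- c("id", "start", "end", "strand")
  if (!all(need %in% names(f)))
    return("features must have columns id, start, end, strand")
  len <- length(object@sequence)
  if (any(f$start < 1) || any(f$end < f$start))
    return("feature coordinates must satisfy 1 <= start <= end")
  if (!object@circular && any(f$end > len))
    return("feature end beyond sequence length on a linear record")
  if (any(f$end - f$start + 1 > len))
    return("feature longer than the replicon")
  if (!all(f$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  TRUE
})

#' Per-position sequencing depth of one replicon
#'
#' @slot replicon replicon label.
#' @slot depth numeric vector of per-position depths (position i is base i,
#'   1-based).
#' @export
setClass("DepthProfile",
  representation(replicon = "character", depth = "numeric")
)

setValidity("DepthProfile", function(object) {
  if (length(object@depth) < 1) return("depth must be non-empty")
  if (any(object@depth < 0)) return("depths must be nonnegative")
  TRUE
})
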