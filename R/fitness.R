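#' Relative fitness of the GFP-negative strain in one competition
#'
#' Ratio of the log fold-changes of the two competitors over the cycle,
#' \deqn{W = \frac{\log(N_{final,gfp-}/N_{initial,gfp-})}
#'               {\log(N_{final,gfp+}/N_{initial,gfp+})},}
#' where the N are cell numbers on one common scale. W = 1 is neutrality.
#' Natural logs are used; any base gives the same W. The value is invariant
#' to multiplying all four counts by one positive constant; it is *not*
#' invariant to rescaling one timepoint relative to the other, so initial and
#' final counts must share the same cells-per-volume scale (total growth
#' included).
#'
#' @param nInitialGfpNeg,nInitialGfpPos,nFinalGfpNeg,nFinalGfpPos cell
#'   numbers before/after the competition (vectors are accepted and handled
#'   element-wise).
#' @param pseudocount if `TRUE`, add one event to every count before the
#'   computation instead of erroring on zero counts. Off by default because
#'   silent pseudocounts distort small competitions.
#' @param label optional record label(s) used in error messages.
#' @return numeric vector of relative fitness values W (> 0).
#' @examples
#' relativeFitness(1000, 1000, 1600000, 400000)  # log(1600)/log(400)
#' @export
relativeFitness <- function(nInitialGfpNeg, nInitialGfpPos,
                            nFinalGfpNeg, nFinalGfpPos,
                            pseudocount = FALSE, label = NULL) {
  counts <- cbind(nInitialGfpNeg, nInitialGfpPos, nFinalGfpNeg, nFinalGfpPos)
  stopIfNot(all(counts >= 0), "counts must be nonnegative")
  if (pseudocount) counts <- counts + 1
  lab <- if (is.null(label)) seq_len(nrow(counts)) else label
  zero <- which(apply(counts == 0, 1, any))
  stopIfNot(length(zero) == 0,
            "zero count in record(s) ", paste(lab[zero], collapse = ", "),
            " (set pseudocount = TRUE to add one event)")
  denom <- log(counts[, 4] / counts[, 2])
  degenerate <- which(denom == 0)
  stopIfNot(length(degenerate) == 0,
            "reference fold-change of 1 (zero denominator) in record(s) ",
            paste(lab[degenerate], collapse = ", "))
  as.numeric(log(counts[, 3] / counts[, 1]) / denom)
}

#' Per-replicate fitness table of an assay set
#'
#' Applies [relativeFitness()] to every record, yielding the first level of
#' the normalization cascade: fitness relative to the common GFP-tagged
#' reference competitor.
#'
#' @param assays a [CompetitionAssaySet-class] or a data.frame with the
#'   record columns.
#' @param counts `"observed"` (default) or `"latent"` (noise-free latent
#'   counts, available for simulated data).
#' @param pseudocount passed to [relativeFitness()].
#' @return data.frame with columns `plasmid`, `mutation`, `replicate`, `w`,
#'   `level = "vs_gfp_reference"`.
#' @export
fitnessTable <- function(assays, counts = c("observed", "latent"),
                         pseudocount = FALSE) {
  counts <- match.arg(counts)
  rec <- if (is(assays, "CompetitionAssaySet")) records(assays) else assays
  cols <- if (counts == "latent")
    c("latent_initial_gfp_neg", "latent_initial_gfp_pos",
      "latent_final_gfp_neg", "latent_final_gfp_pos")
  else
    c("n_initial_gfp_neg", "n_initial_gfp_pos",
      "n_final_gfp_neg", "n_final_gfp_pos")
  stopIfNot(all(cols %in% names(rec)),
            "records lack count columns: ",
            paste(setdiff(cols, names(rec)), collapse = ", "))
  lab <- paste0(rec$plasmid, ":", rec$mutation, "/", rec$replicate)
  w <- relativeFitness(rec[[cols[1]]], rec[[cols[2]]],
                       rec[[cols[3]]], rec[[cols[4]]],
                       pseudocount = pseudocount, label = lab)
  data.frame(plasmid = rec$plasmid, mutation = rec$mutation,
             replicate = rec$replicate, w = w, level = "vs_gfp_reference")
}

#' Normalize replicate fitness values to the plasmid-free wild type
#'
#' Second level of the cascade: the median of the test strain's replicates is
#' divided by the median of the plasmid-free wild-type control replicates
#' (both measured against the same GFP reference). Per-replicate normalized
#' values divide each test replicate by the control *median* (the cascade
#' pairs medians, not replicates). The median of an even number of
#' replicates is the mean of the two central order statistics.
#'
#' @param test numeric vector of test-strain replicate fitness values.
#' @param control numeric vector of control (plasmid-free wild type)
#'   replicate fitness values.
#' @return list with `w` (median ratio), `replicates` (per-replicate
#'   normalized values) and `controlMedian`.
#' @examples
#' normalizeToPlasmidFree(c(0.72, 0.70, 0.74, 0.71, 0.73, 0.70),
#'                        rep(0.8, 6))$w  # 0.715 / 0.8
#' @export
normalizeToPlasmidFree <- function(test, control) {
  stopIfNot(length(test) > 0 && length(control) > 0,
            "test and control replicate sets must be non-empty")
  m <- median(control)
  stopIfNot(m > 0, "control median must be > 0")
  list(w = median(test) / m, replicates = test / m, controlMedian = m)
}

#' Normalize combination fitness to the plasmid-carrying wild type
#'
#' Third, presentational level of the cascade: fitness values of a
#' plasmid-mutant combination (already relative to the plasmid-free wild
#' type) divided by the fitness of the wild type carrying the same plasmid,
#' element-wise, preserving replicate structure.
#'
#' @param combination numeric vector (replicates or an aggregate).
#' @param carrier fitness of the plasmid-carrying wild type (> 0).
#' @return numeric vector of the same length as `combination`.
#' @export
normalizeToPlasmidCarrier <- function(combination, carrier) {
  stopIfNot(length(carrier) == 1 && carrier > 0,
            "carrier fitness must be a single positive value")
  combination / carrier
}

#' Fitness cost as a percentage
#'
#' `(1 - w) * 100`: a strain with relative fitness 0.70 pays a 30% cost;
#' negative values denote a fitness advantage (w = 1.51 is a 51% benefit).
#'
#' @param w relative fitness value(s), > 0.
#' @return percentage reduction(s) in fitness.
#' @export
percentCost <- function(w) {
  stopIfNot(all(w > 0), "fitness values must be > 0")
  (1 - w) * 100
}

#' Full two-level fitness estimation for an assay set
#'
#' Runs [fitnessTable()] and then normalizes every genotype's replicates by
#' the median of the plasmid-free wild-type control group, producing the
#' per-replicate table on which epistasis statistics operate.
#'
#' @inheritParams fitnessTable
#' @param controlPlasmid,controlMutation labels of the control genotype
#'   (default the `"none"`/`"none"` wild type).
#' @return data.frame with columns `plasmid`, `mutation`, `replicate`, `w`,
#'   `level = "vs_plasmid_free_wildtype"`; the control median is attached as
#'   attribute `controlMedian`.
#' @examples
#' cfg <- simulationConfig(plasmidFitness = c(pA = 0.8), seed = 2,
#'                         replicates = 3L, wildtypeReplicates = 6L)
#' head(estimateFitness(simulateExperiment(cfg)))
#' @export
estimateFitness <- function(assays, counts = c("observed", "latent"),
                            pseudocount = FALSE,
                            controlPlasmid = NONE_LABEL,
                            controlMutation = NONE_LABEL) {
  ft <- fitnessTable(assays, counts = counts, pseudocount = pseudocount)
  ctrl <- ft$w[ft$plasmid == controlPlasmid & ft$mutation == controlMutation]
  stopIfNot(length(ctrl) > 0, "no control records for genotype (",
            controlPlasmid, ", ", controlMutation, ")")
  m <- median(ctrl)
  stopIfNot(m > 0, "control median must be > 0")
  out <- data.frame(plasmid = ft$plasmid, mutation = ft$mutation,
                    replicate = ft$replicate, w = ft$w / m,
                    level = "vs_plasmid_free_wildtype")
  attr(out, "controlMedian") <- m
  out
}
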