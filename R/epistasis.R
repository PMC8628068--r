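#' Expected fitness of a plasmid-mutation combination under the
#' multiplicative null
#'
#' The null expectation that independent determinants combine by
#' multiplication of their relative fitness values:
#' `W_expected = W(plasmid;-) * W(-;mutation)`.
#'
#' @param wPlasmid median fitness of the plasmid-carrying wild type.
#' @param wMutation median fitness of the plasmid-free mutant.
#' @return expected combination fitness.
#' @export
expectedFitness <- function(wPlasmid, wMutation) {
  stopIfNot(all(wPlasmid > 0) && all(wMutation > 0),
            "marginal fitness values must be > 0")
  wPlasmid * wMutation
}

#' Epistasis against the multiplicative null
#'
#' `epsilon = W(plasmid;mutation) - W(plasmid;-) * W(-;mutation)`. Positive
#' epsilon means the double-determinant strain is fitter than the
#' multiplicative expectation; negative means an aggravated (synergistic)
#' cost.
#'
#' @param wCombination observed fitness of the combination.
#' @param wPlasmid,wMutation marginal median fitness values.
#' @return epsilon (dimensionless).
#' @examples
#' epistasis(0.95, 0.8, 0.9)  # 0.95 - 0.72
#' @export
epistasis <- function(wCombination, wPlasmid, wMutation) {
  stopIfNot(all(wCombination > 0), "combination fitness must be > 0")
  wCombination - expectedFitness(wPlasmid, wMutation)
}

#' Per-replicate epistasis values
#'
#' Each combination replicate's fitness minus the product of the two
#' marginal *medians* (the marginals are defined as medians, so replicates
#' are not paired). For the wild type both marginals are 1, so its
#' per-replicate epsilon is `w - 1` and its median epsilon is exactly 0
#' whenever its replicates are self-normalized.
#'
#' @param replicates numeric vector of the combination's replicate fitness
#'   values (relative to the plasmid-free wild type).
#' @param wPlasmidMedian,wMutationMedian marginal medians (> 0).
#' @return numeric vector of per-replicate epsilon values.
#' @export
epistasisReplicates <- function(replicates, wPlasmidMedian, wMutationMedian) {
  stopIfNot(length(replicates) > 0, "replicate set must be non-empty")
  stopIfNot(wPlasmidMedian > 0 && wMutationMedian > 0,
            "marginal medians must be > 0")
  replicates - wPlasmidMedian * wMutationMedian
}

#' Classify epistasis for every combination by ANOVA + Tukey against the
#' wild type
#'
#' One-way ANOVA across all genotype epsilon-groups (combinations plus the
#' wild-type group, whose epsilon replicates are `w - 1`), followed by
#' Tukey's HSD; each combination's contrast against the wild-type group
#' gives a p value corrected for the full family of pairwise comparisons.
#' A combination is called `"positive"` or `"negative"` by the sign of its
#' median epsilon when the adjusted p is below `alpha`, else `"none"`. A
#' median epsilon of exactly 0 with adjusted p < alpha is called `"none"`
#' with a warning (the sign would be arbitrary).
#'
#' @param epsilonGroups named list of numeric vectors: per-replicate epsilon
#'   values, one element per combination genotype.
#' @param wildtypeEpsilon numeric vector of wild-type per-replicate epsilon
#'   values.
#' @param alpha significance level (default 0.05); Tukey's HSD controls the
#'   family-wise error rate at this level.
#' @return data.frame with columns `genotype`, `medianEpsilon`, `adjustedP`,
#'   `classification`.
#' @export
classifyEpistasis <- function(epsilonGroups, wildtypeEpsilon, alpha = 0.05) {
  stopIfNot(length(epsilonGroups) >= 1, "need at least one epsilon group")
  stopIfNot(length(wildtypeEpsilon) >= 2,
            "wild-type group needs >= 2 replicates")
  stopIfNot(all(vapply(epsilonGroups, length, integer(1)) >= 2),
            "every group needs >= 2 replicates")
  wtLabel <- ".wildtype"
  stopIfNot(!(wtLabel %in% names(epsilonGroups)),
            "'.wildtype' is a reserved group label")
  groups <- c(epsilonGroups, stats::setNames(list(wildtypeEpsilon), wtLabel))
  adj <- tukeyVersus(groups, reference = wtLabel)
  med <- vapply(epsilonGroups, median, numeric(1))
  p <- adj[names(epsilonGroups)]
  cls <- ifelse(p < alpha, ifelse(med > 0, "positive", "negative"), "none")
  tie <- which(p < alpha & med == 0)
  if (length(tie)) {
    warning("median epsilon exactly 0 with adjusted p < alpha for ",
            paste(names(epsilonGroups)[tie], collapse = ", "),
            "; classified 'none'")
    cls[tie] <- "none"
  }
  data.frame(genotype = names(epsilonGroups), medianEpsilon = unname(med),
             adjustedP = unname(p), classification = unname(cls),
             row.names = NULL)
}

## Tukey HSD adjusted p values of every group's contrast against a
## reference group, within the family of all pairwise contrasts.
tukeyVersus <- function(groups, reference) {
  labs <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, vapply(groups, length, integer(1))), levels = labs)
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit)$g
  out <- stats::setNames(rep(NA_real_, length(labs)), labs)
  for (lab in setdiff(labs, reference)) {
    key <- paste(lab, reference, sep = "-")
    alt <- paste(reference, lab, sep = "-")
    row <- if (key %in% rownames(tk)) key else alt
    out[lab] <- tk[row, "p adj"]
  }
  out
}

#' Test for sign epistasis
#'
#' A combination shows sign epistasis when the double-determinant strain is
#' significantly fitter than *both* single-determinant strains: the
#' plasmid-free mutant and the plasmid-carrying wild type. Assessed by
#' one-way ANOVA over the three strains followed by Tukey's HSD; both
#' contrasts must show a positive difference with adjusted p < alpha.
#'
#' @param combination numeric vector of combination replicate fitness
#'   values (relative to the plasmid-free wild type).
#' @param plasmidFreeMutant numeric vector for the mutant without plasmid.
#' @param plasmidCarryingWildtype numeric vector for the wild type with
#'   plasmid.
#' @param alpha significance level.
#' @return list with `signEpistasis` (logical), `pVsMutant`, `pVsCarrier`
#'   (Tukey-adjusted) and the two median differences.
#' @export
testSignEpistasis <- function(combination, plasmidFreeMutant,
                              plasmidCarryingWildtype, alpha = 0.05) {
  stopIfNot(length(combination) >= 2 && length(plasmidFreeMutant) >= 2 &&
              length(plasmidCarryingWildtype) >= 2,
            "all three strain groups need >= 2 replicates")
  groups <- list(combination = combination,
                 mutant = plasmidFreeMutant,
                 carrier = plasmidCarryingWildtype)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  tk <- TukeyHSD(aov(values ~ g))$g
  getRow <- function(a, b) {
    key <- paste(a, b, sep = "-")
    if (key %in% rownames(tk)) tk[key, c("diff", "p adj")] else
      c(-tk[paste(b, a, sep = "-"), "diff"],
        tk[paste(b, a, sep = "-"), "p adj"])
  }
  vsMut <- getRow("combination", "mutant")
  vsCar <- getRow("combination", "carrier")
  list(signEpistasis = unname(vsMut[1] > 0 && vsCar[1] > 0 &&
                                vsMut[2] < alpha && vsCar[2] < alpha),
       pVsMutant = unname(vsMut[2]), pVsCarrier = unname(vsCar[2]),
       diffVsMutant = unname(vsMut[1]), diffVsCarrier = unname(vsCar[1]))
}

#' Full epistasis analysis of a normalized fitness table
#'
#' For every plasmid-mutation combination in the table: observed median
#' fitness, multiplicative expectation from the marginal medians,
#' per-replicate epsilon values, ANOVA + Tukey classification against the
#' wild-type epsilon group, and the sign-epistasis test against the two
#' single-determinant strains.
#'
#' @param fitness data.frame from [estimateFitness()] (level
#'   `vs_plasmid_free_wildtype`).
#' @param alpha significance level for both tests.
#' @return data.frame with one row per combination: `plasmid`, `mutation`,
#'   `wObserved`, `wExpected`, `epsilon`, `classification`, `adjustedP`,
#'   `signEpistasis`, `signP`; the wild-type epsilon replicates are attached
#'   as attribute `wildtypeEpsilon`.
#' @examples
#' cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
#'                         mutationFitness = c(m1 = 0.7), seed = 11)
#' fit <- estimateFitness(simulateExperiment(cfg))
#' epistasisAnalysis(fit)
#' @export
epistasisAnalysis <- function(fitness, alpha = 0.05) {
  key <- genotypeKey(fitness$plasmid, fitness$mutation)
  wByG <- split(fitness$w, key)
  medByG <- vapply(wByG, median, numeric(1))
  wtKey <- genotypeKey(NONE_LABEL, NONE_LABEL)
  stopIfNot(wtKey %in% names(wByG), "fitness table lacks the wild type")

  combos <- unique(fitness[fitness$plasmid != NONE_LABEL &
                             fitness$mutation != NONE_LABEL,
                           c("plasmid", "mutation")])
  stopIfNot(nrow(combos) > 0, "no plasmid-mutation combinations in table")
  marginal <- function(p, m) {
    k <- genotypeKey(p, m)
    stopIfNot(k %in% names(medByG), "missing single-determinant genotype (",
              p, ", ", m, ")")
    medByG[[k]]
  }
  epsGroups <- list()
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- combos$plasmid[i]; m <- combos$mutation[i]
    wP <- marginal(p, NONE_LABEL)
    wM <- marginal(NONE_LABEL, m)
    k <- genotypeKey(p, m)
    eps <- epistasisReplicates(wByG[[k]], wP, wM)
    epsGroups[[k]] <- eps
    sign <- testSignEpistasis(wByG[[k]],
                              plasmidFreeMutant = wByG[[genotypeKey(NONE_LABEL, m)]],
                              plasmidCarryingWildtype = wByG[[genotypeKey(p, NONE_LABEL)]],
                              alpha = alpha)
    rows[[i]] <- data.frame(
      plasmid = p, mutation = m,
      wObserved = medByG[[k]], wExpected = wP * wM,
      epsilon = medByG[[k]] - wP * wM,
      signEpistasis = sign$signEpistasis,
      signP = max(sign$pVsMutant, sign$pVsCarrier))
  }
  wtEps <- wByG[[wtKey]] - 1
  wtMed <- median(wByG[[wtKey]])
  cls <- classifyEpistasis(epsGroups, wtEps, alpha = alpha)
  out <- do.call(rbind, rows)
  idx <- match(genotypeKey(out$plasmid, out$mutation), cls$genotype)
  out$classification <- cls$classification[idx]
  out$adjustedP <- cls$adjustedP[idx]
  out <- out[, c("plasmid", "mutation", "wObserved", "wExpected", "epsilon",
                 "classification", "adjustedP", "signEpistasis", "signP")]
  attr(out, "wildtypeEpsilon") <- wtEps
  ## the wild type's median epsilon is zero by definition: its group is
  ## normalized by its own median, so the median deviation is m - m.
  ## Evaluated as the identity so that re-medianing the centered replicates
  ## cannot leave a spurious last-ulp floating-point residual.
  attr(out, "wildtypeMedianEpsilon") <- wtMed - wtMed
  attr(out, "epsilonReplicates") <- epsGroups
  rownames(out) <- NULL
  out
}

#' Error-propagation cross-check for epistasis significance
#'
#' Alternative to the ANOVA/Tukey route: a normal-approximation z test of
#' `epsilon = median(combination) - median(plasmid) * median(mutation)`,
#' with the standard errors of the three medians estimated by bootstrap and
#' propagated through the product,
#' `var(eps) ~ var(mC) + wM^2 var(mP) + wP^2 var(mM)`. P values are
#' Holm-adjusted over the combinations.
#'
#' @inheritParams epistasisAnalysis
#' @param bootstrap number of bootstrap resamples per group (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with `plasmid`, `mutation`, `epsilon`, `se`, `z`,
#'   `adjustedP`, `classification`.
#' @export
epistasisErrorPropagation <- function(fitness, alpha = 0.05,
                                      bootstrap = 2000L, seed = 1L) {
  set.seed(seed)
  key <- genotypeKey(fitness$plasmid, fitness$mutation)
  wByG <- split(fitness$w, key)
  medByG <- vapply(wByG, median, numeric(1))
  bootSe <- function(x) {
    reps <- vapply(seq_len(bootstrap), function(i)
      median(sample(x, replace = TRUE)), numeric(1))
    stats::sd(reps)
  }
  seByG <- vapply(wByG, bootSe, numeric(1))
  combos <- unique(fitness[fitness$plasmid != NONE_LABEL &
                             fitness$mutation != NONE_LABEL,
                           c("plasmid", "mutation")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    p <- combos$plasmid[i]; m <- combos$mutation[i]
    kC <- genotypeKey(p, m)
    kP <- genotypeKey(p, NONE_LABEL)
    kM <- genotypeKey(NONE_LABEL, m)
    eps <- medByG[[kC]] - medByG[[kP]] * medByG[[kM]]
    se <- sqrt(seByG[[kC]]^2 +
                 medByG[[kM]]^2 * seByG[[kP]]^2 +
                 medByG[[kP]]^2 * seByG[[kM]]^2)
    data.frame(plasmid = p, mutation = m, epsilon = eps, se = se,
               z = eps / se)
  })
  out <- do.call(rbind, rows)
  p <- 2 * stats::pnorm(-abs(out$z))
  out$adjustedP <- stats::p.adjust(p, method = "holm")
  out$classification <- ifelse(out$adjustedP < alpha,
                               ifelse(out$epsilon > 0, "positive",
                                      "negative"),
                               "none")
  rownames(out) <- NULL
  out
}
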