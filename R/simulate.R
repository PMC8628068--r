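#' Build a simulation configuration
#'
#' Defines the true fitness landscape and design of a synthetic competition
#' experiment. Marginal fitness values are given per determinant (plasmid or
#' mutation); a combination genotype's true fitness is the product of its two
#' marginals plus any configured epistatic shift, and the wild type has
#' fitness 1 by construction. The defaults reproduce the standard assay
#' design: 1:1 initial mixture, 1:400 dilution into fresh medium (so the
#' reference expands about 400-fold per cycle), 10,000 cytometry events per
#' measurement, six replicates per genotype and 36 for the wild type.
#'
#' @param plasmidFitness named numeric vector of true relative fitness of
#'   each plasmid-carrying wild type (e.g. `c(pA = 0.8)`).
#' @param mutationFitness named numeric vector of true relative fitness of
#'   each plasmid-free mutant.
#' @param genotypes optional data.frame with columns `plasmid`, `mutation`
#'   naming the strains to simulate; default is the full factorial of all
#'   plasmids and mutations, all single determinants, and the wild type.
#' @param epistasisShift named numeric vector of additive deviations from the
#'   multiplicative expectation, names of the form `"plasmid:mutation"`.
#' @param replicates replicates per genotype (default 6).
#' @param wildtypeReplicates replicates for the wild type (default 36).
#' @param expansionFactor total fold-growth of the reference per competition
#'   cycle (default 400, the dilution factor regrown to saturation).
#' @param eventsPerMeasurement cytometry events per measurement (default
#'   10000).
#' @param growthNoiseSd sd of mean-one lognormal noise on each competitor's
#'   fold-expansion (default 0, i.e. deterministic growth).
#' @param seed integer master seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
#'                         mutationFitness = c(m1 = 0.7), seed = 1)
#' cfg
#' @export
simulationConfig <- function(plasmidFitness = numeric(),
                             mutationFitness = numeric(),
                             genotypes = NULL,
                             epistasisShift = numeric(),
                             replicates = 6L,
                             wildtypeReplicates = 36L,
                             expansionFactor = 400,
                             eventsPerMeasurement = 10000L,
                             growthNoiseSd = 0,
                             seed = 1L) {
  pl <- names(plasmidFitness)
  mu <- names(mutationFitness)
  stopIfNot(length(plasmidFitness) == 0 || !is.null(pl),
            "plasmidFitness must be a named vector")
  stopIfNot(length(mutationFitness) == 0 || !is.null(mu),
            "mutationFitness must be a named vector")
  dup <- intersect(pl, mu)
  stopIfNot(length(dup) == 0,
            "labels used for both a plasmid and a mutation: ",
            paste(dup, collapse = ", "))
  stopIfNot(!(NONE_LABEL %in% c(pl, mu)),
            "'", NONE_LABEL, "' is reserved for the absent determinant")
  if (is.null(genotypes)) {
    genotypes <- rbind(
      data.frame(plasmid = NONE_LABEL, mutation = NONE_LABEL),
      if (length(pl)) data.frame(plasmid = pl, mutation = NONE_LABEL),
      if (length(mu)) data.frame(plasmid = NONE_LABEL, mutation = mu),
      if (length(pl) && length(mu))
        expand.grid(plasmid = pl, mutation = mu,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    )
  }
  genotypes$plasmid <- as.character(genotypes$plasmid)
  genotypes$mutation <- as.character(genotypes$mutation)
  trueW <- c(plasmidFitness, mutationFitness)
  used <- setdiff(unique(c(genotypes$plasmid, genotypes$mutation)), NONE_LABEL)
  missing <- setdiff(used, names(trueW))
  stopIfNot(length(missing) == 0,
            "no true fitness given for: ", paste(missing, collapse = ", "))
  new("SimulationConfig",
      genotypes = genotypes, trueW = trueW,
      epistasisShift = epistasisShift,
      replicates = as.integer(replicates),
      wildtypeReplicates = as.integer(wildtypeReplicates),
      expansionFactor = as.numeric(expansionFactor),
      eventsPerMeasurement = as.integer(eventsPerMeasurement),
      growthNoiseSd = as.numeric(growthNoiseSd),
      seed = as.integer(seed))
}

#' True fitness of a genotype under a configuration
#'
#' Marginal fitness for single-determinant genotypes, the product of the two
#' marginals plus the configured epistatic shift for combinations, and 1 for
#' the wild type.
#'
#' @param config a [SimulationConfig-class].
#' @param plasmid,mutation genotype labels.
#' @return the true relative fitness (dimensionless).
#' @export
trueFitness <- function(config, plasmid, mutation) {
  w <- 1
  if (plasmid != NONE_LABEL) w <- w * config@trueW[[plasmid]]
  if (mutation != NONE_LABEL) w <- w * config@trueW[[mutation]]
  if (plasmid != NONE_LABEL && mutation != NONE_LABEL) {
    key <- genotypeKey(plasmid, mutation)
    if (key %in% names(config@epistasisShift))
      w <- w + config@epistasisShift[[key]]
  }
  stopIfNot(w > 0, "true fitness of genotype (", plasmid, ", ", mutation,
            ") is not positive")
  unname(w)
}

#' Simulate one head-to-head competition
#'
#' Generative model of a single competition cycle: the two competitors start
#' as a 1:1 mixture; over the cycle the GFP-positive reference expands by the
#' factor `G` (`expansionFactor`) and the GFP-negative test strain by
#' `G^trueW`, so that the relative-fitness estimator is exact in the
#' noise-free limit. Optional mean-one lognormal noise perturbs each
#' competitor's fold-expansion. Each measurement is then emulated by drawing
#' `eventsPerMeasurement` cytometry events from the latent proportions
#' (two-class multinomial) and rescaling the event counts back to the latent
#' cell-number scale, so that initial and final counts share one
#' cells-per-volume scale as the fitness formula requires.
#'
#' @param trueW true relative fitness of the test strain (> 0).
#' @param config a [SimulationConfig-class] (supplies `G`, events, noise sd).
#' @param seed integer seed for this record.
#' @param sampling if `FALSE`, skip the cytometry subsampling and record the
#'   latent counts as the observed ones (useful for exactness checks).
#' @return one-row data.frame with observed counts `n_initial_gfp_neg`,
#'   `n_initial_gfp_pos`, `n_final_gfp_neg`, `n_final_gfp_pos` and latent
#'   counts `latent_*` on the same scale.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' simulateCompetition(0.9, cfg, seed = 42)
#' @export
simulateCompetition <- function(trueW, config, seed, sampling = TRUE) {
  x <- simCompetitionCounts(trueW, config, seed, sampling)
  data.frame(
    n_initial_gfp_neg = x[1], n_initial_gfp_pos = x[2],
    n_final_gfp_neg = x[3], n_final_gfp_pos = x[4],
    latent_initial_gfp_neg = x[5], latent_initial_gfp_pos = x[6],
    latent_final_gfp_neg = x[7], latent_final_gfp_pos = x[8]
  )
}

## numeric(8) fast path: observed then latent counts, gfp- before gfp+
simCompetitionCounts <- function(trueW, config, seed, sampling = TRUE) {
  stopIfNot(is.numeric(trueW) && length(trueW) == 1 && trueW > 0,
            "trueW must be a single positive number")
  G <- config@expansionFactor
  stopIfNot(G > 1, "expansionFactor must be > 1")
  ev <- config@eventsPerMeasurement
  set.seed(seed)
  ## latent counts on the scale of one measurement's events
  latInit <- c(ev / 2, ev / 2)
  fNeg <- G^trueW
  fPos <- G
  if (config@growthNoiseSd > 0) {
    sdl <- config@growthNoiseSd
    noise <- rlnorm(2, meanlog = -sdl^2 / 2, sdlog = sdl)  # mean 1
    fNeg <- fNeg * noise[1]
    fPos <- fPos * noise[2]
  }
  latFin <- c(latInit[1] * fNeg, latInit[2] * fPos)
  if (sampling) {
    sInit <- rmultinom(1, ev, latInit / sum(latInit))[, 1]
    sFin <- rmultinom(1, ev, latFin / sum(latFin))[, 1]
    ## rescale event counts to the latent cell-number scale so that the
    ## total expansion is preserved across timepoints
    obsInit <- sInit * sum(latInit) / ev
    obsFin <- sFin * sum(latFin) / ev
  } else {
    obsInit <- latInit
    obsFin <- latFin
  }
  c(obsInit, obsFin, latInit, latFin)
}

#' Simulate a full competition experiment
#'
#' One block of replicates per genotype in the configuration, each record
#' with its own seed derived from the master seed, the genotype labels and
#' the replicate index, so the output is deterministic and independent of
#' generation order.
#'
#' @param config a [SimulationConfig-class].
#' @param sampling passed to [simulateCompetition()].
#' @return a [CompetitionAssaySet-class] whose records carry the design
#'   columns `plasmid`, `mutation`, `replicate` plus observed and latent
#'   counts.
#' @examples
#' cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
#'                         mutationFitness = c(m1 = 0.7),
#'                         replicates = 3L, wildtypeReplicates = 6L, seed = 7)
#' simulateExperiment(cfg)
#' @export
simulateExperiment <- function(config, sampling = TRUE) {
  validObject(config)
  g <- config@genotypes
  nrep <- ifelse(isWildtype(g$plasmid, g$mutation),
                 config@wildtypeReplicates, config@replicates)
  total <- sum(nrep)
  counts <- matrix(NA_real_, nrow = total, ncol = 8)
  plasmid <- mutation <- character(total)
  replicate <- integer(total)
  k <- 0L
  for (i in seq_len(nrow(g))) {
    w <- trueFitness(config, g$plasmid[i], g$mutation[i])
    for (r in seq_len(nrep[i])) {
      k <- k + 1L
      seed <- deriveSeed(config@seed, g$plasmid[i], g$mutation[i], r)
      counts[k, ] <- simCompetitionCounts(w, config, seed,
                                          sampling = sampling)
      plasmid[k] <- g$plasmid[i]
      mutation[k] <- g$mutation[i]
      replicate[k] <- r
    }
  }
  recs <- data.frame(plasmid = plasmid, mutation = mutation,
                     replicate = replicate, counts)
  names(recs)[-(1:3)] <- c(
    "n_initial_gfp_neg", "n_initial_gfp_pos",
    "n_final_gfp_neg", "n_final_gfp_pos",
    "latent_initial_gfp_neg", "latent_initial_gfp_pos",
    "latent_final_gfp_neg", "latent_final_gfp_pos")
  new("CompetitionAssaySet", records = recs,
      metadata = list(seed = config@seed, config = config))
}

#' Simulate an annotated circular plasmid record
#'
#' Random circular nucleotide sequence with a target GC fraction carrying
#' non-overlapping ORFs (start ATG, stop codon at the end, length divisible
#' by 3, random strand). ORF codons are chosen against a codon-usage table:
#' with probability `codonBiasStrength` the family's maximal-weight codon is
#' used, otherwise a uniformly random synonymous codon. The intergenic
#' backbone's base composition is adjusted so the whole record meets the
#' target GC in expectation.
#'
#' @param lengthBp total record length in bp.
#' @param gcFraction target GC fraction in (0, 1).
#' @param nOrfs number of ORFs to place (>= 0).
#' @param codonBiasStrength in \[0, 1\]; 1 forces every codon to its family
#'   optimum (so CAI = 1 downstream).
#' @param seed integer seed.
#' @param table a [CodonUsageTable-class]; default [defaultCodonTable()].
#' @param orfLengthCodons ORF length in codons including start and stop
#'   (default 101, i.e. 303 bp).
#' @param name record name.
#' @return a [PlasmidRecord-class].
#' @examples
#' rec <- simulatePlasmidRecord(20000, 0.5, nOrfs = 5, codonBiasStrength = 0.5,
#'                              seed = 3)
#' rec
#' @export
simulatePlasmidRecord <- function(lengthBp, gcFraction, nOrfs,
                                  codonBiasStrength, seed,
                                  table = defaultCodonTable(),
                                  orfLengthCodons = 101L,
                                  name = "synthetic_plasmid") {
  stopIfNot(gcFraction > 0 && gcFraction < 1, "gcFraction must be in (0, 1)")
  stopIfNot(nOrfs >= 0, "nOrfs must be >= 0")
  stopIfNot(codonBiasStrength >= 0 && codonBiasStrength <= 1,
            "codonBiasStrength must be in [0, 1]")
  orfBp <- orfLengthCodons * 3L
  ## each ORF needs at least one spacer base so annotations do not abut
  needed <- nOrfs * (orfBp + 1L)
  stopIfNot(needed <= lengthBp,
            "cannot pack ", nOrfs, " ORFs of ", orfBp, " bp into ", lengthBp,
            " bp")
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  w <- codonWeights(table)
  aas <- setdiff(unique(code), "*")
  fam <- split(names(code), code)
  famMax <- vapply(fam[aas], function(cs) cs[which.max(w[cs])], character(1))
  stops <- fam[["*"]]

  makeOrf <- function() {
    aaSeq <- sample(aas, orfLengthCodons - 2L, replace = TRUE)
    useMax <- runif(length(aaSeq)) < codonBiasStrength
    codons <- character(length(aaSeq))
    codons[useMax] <- famMax[aaSeq[useMax]]
    if (any(!useMax))
      codons[!useMax] <- vapply(aaSeq[!useMax], function(a) {
        cs <- fam[[a]]
        cs[sample.int(length(cs), 1)]
      }, character(1))
    paste0("ATG", paste(codons, collapse = ""), stops[sample.int(3, 1)])
  }
  orfSeqs <- if (nOrfs > 0) vapply(seq_len(nOrfs), function(i) makeOrf(),
                                   character(1)) else character()

  ## backbone base probabilities compensating the GC contributed by ORFs
  orfChars <- if (nOrfs > 0) strsplit(paste(orfSeqs, collapse = ""), "")[[1]]
              else character()
  orfGc <- sum(orfChars %in% c("G", "C"))
  backboneLen <- lengthBp - nOrfs * orfBp
  targetGcBackbone <- (gcFraction * lengthBp - orfGc) / backboneLen
  stopIfNot(targetGcBackbone > 0 && targetGcBackbone < 1,
            "target GC fraction infeasible with this ORF load")
  pg <- targetGcBackbone / 2
  pa <- (1 - targetGcBackbone) / 2
  backbone <- sample(c("A", "C", "G", "T"), backboneLen, replace = TRUE,
                     prob = c(pa, pg, pg, pa))

  ## lay out ORFs evenly with the remaining backbone split into spacers
  spacer <- floor(backboneLen / max(nOrfs, 1))
  seqParts <- character()
  feats <- list()
  pos <- 1L
  bbUsed <- 0L
  for (i in seq_len(nOrfs)) {
    gap <- if (i < nOrfs || nOrfs == 0) spacer else backboneLen - bbUsed
    gapSeq <- paste(backbone[seq_len(gap) + bbUsed], collapse = "")
    bbUsed <- bbUsed + gap
    strand <- sample(c("+", "-"), 1)
    orf <- orfSeqs[i]
    placed <- if (strand == "+") orf else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
    seqParts <- c(seqParts, gapSeq, placed)
    start <- pos + gap
    feats[[i]] <- data.frame(id = sprintf("orf%03d", i), start = start,
                             end = start + orfBp - 1L, strand = strand)
    pos <- start + orfBp
  }
  if (bbUsed < backboneLen)
    seqParts <- c(seqParts,
                  paste(backbone[(bbUsed + 1L):backboneLen], collapse = ""))
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(id = character(), start = integer(), end = integer(),
               strand = character())
  new("PlasmidRecord", name = name,
      sequence = Biostrings::DNAString(paste(seqParts, collapse = "")),
      circular = TRUE, features = features)
}

#' Simulate a chromosome/plasmid sequencing-depth pair
#'
#' Per-position depths for a chromosome and one plasmid replicon whose mean
#' ratio equals the given copy number in expectation. Depths are lognormal
#' with the requested coefficient of variation (`noiseCv = 0` gives constant
#' depth, so the downstream ratio is exact).
#'
#' @param copyNumber plasmid copies per chromosome (> 0).
#' @param chromMeanDepth mean chromosomal depth (> 0).
#' @param noiseCv per-position coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param chromPositions,plasmidPositions number of positions simulated.
#' @return named list of two [DepthProfile-class] objects, `chromosome` and
#'   `plasmid`.
#' @examples
#' dp <- simulateDepthTable(15, 100, noiseCv = 0, seed = 1)
#' copyNumberProxy(dp$plasmid, dp$chromosome)
#' @export
simulateDepthTable <- function(copyNumber, chromMeanDepth, noiseCv, seed,
                               chromPositions = 5000L,
                               plasmidPositions = 1000L) {
  stopIfNot(copyNumber > 0, "copyNumber must be > 0")
  stopIfNot(chromMeanDepth > 0, "chromMeanDepth must be > 0")
  stopIfNot(noiseCv >= 0, "noiseCv must be >= 0")
  set.seed(seed)
  draw <- function(n, mu) {
    if (noiseCv == 0) return(rep(mu, n))
    sdl <- sqrt(log(1 + noiseCv^2))
    rlnorm(n, meanlog = log(mu) - sdl^2 / 2, sdlog = sdl)
  }
  list(
    chromosome = new("DepthProfile", replicon = "chromosome",
                     depth = draw(chromPositions, chromMeanDepth)),
    plasmid = new("DepthProfile", replicon = "plasmid",
                  depth = draw(plasmidPositions, copyNumber * chromMeanDepth))
  )
}
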