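## Evenly spaced per-plasmid feature parameters emulating the diversity of
## natural resistance plasmids: GC spanning the mid-40s to low-60s percent,
## sizes from ~8 to ~147 kb and copy numbers from single-copy to multicopy.
defaultFeatureParams <- function(plasmids) {
  n <- length(plasmids)
  ramp <- function(a, b) if (n == 1) (a + b) / 2 else seq(a, b, length.out = n)
  data.frame(plasmid = plasmids,
             lengthBp = as.integer(round(ramp(8000, 147000))),
             gcFraction = ramp(0.46, 0.61),
             nOrfs = as.integer(round(ramp(8, 40))),
             codonBiasStrength = ramp(0.2, 0.8),
             copyNumber = ramp(1, 60))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end: obtain competition data (simulated
#' from a configured fitness landscape, or read from a CSV), estimate
#' per-replicate relative fitness and normalize to the plasmid-free wild
#' type, classify epistasis for every plasmid-mutation combination, compute
#' per-plasmid sequence features, and screen features against plasmid cost
#' by Spearman correlation. The pipeline is a pure function of the
#' configuration: rerunning with the same configuration yields byte
#' identical outputs.
#'
#' Configuration keys (list or YAML file): `mode` ("simulate" or "real");
#' for simulate mode `plasmids` and `mutations` (named fitness maps),
#' optional `epistasisShift` (named "plasmid:mutation"), `replicates`,
#' `wildtypeReplicates`, `expansionFactor`, `events`, `growthNoiseSd`,
#' `seed`; for real mode `countsPath` (competition CSV), optional
#' `recordPaths` (named GenBank paths per plasmid), `depthPaths` (named
#' depth-TSV paths per plasmid, each with a `chromosome` and a `plasmid`
#' replicon), optional `codonTablePath`. Common: `alpha` (default 0.05).
#'
#' @param config named list or path to a YAML file.
#' @param outputDir optional directory; when given, writes `fitness.csv`,
#'   `epistasis.csv`, `features.csv`, `correlation.csv` and `report.txt`,
#'   each stamped with the configuration hash and seed.
#' @return (invisibly when writing) a result bundle: list with `fitness`,
#'   `epistasis`, `features`, `correlation`, `report`, `log`, `configHash`.
#' @examples
#' cfg <- list(mode = "simulate",
#'             plasmids = list(pA = 0.8, pB = 0.75),
#'             mutations = list(m1 = 0.7),
#'             replicates = 6, wildtypeReplicates = 12, seed = 5)
#' res <- runPipeline(cfg)
#' res$epistasis
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  mode <- match.arg(config$mode, c("simulate", "real"))
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  hash <- configHash(config)

  ## --- stage 1: competition data -------------------------------------
  codonTable <- if (!is.null(config$codonTablePath))
    readCodonTable(config$codonTablePath) else defaultCodonTable()
  if (mode == "simulate") {
    stopIfNot(!is.null(config$seed), "simulate mode requires a seed")
    seed <- as.integer(config$seed)
    simCfg <- simulationConfig(
      plasmidFitness = unlist(config$plasmids),
      mutationFitness = unlist(config$mutations),
      epistasisShift = if (is.null(config$epistasisShift)) numeric()
                       else unlist(config$epistasisShift),
      replicates = if (is.null(config$replicates)) 6L
                   else as.integer(config$replicates),
      wildtypeReplicates = if (is.null(config$wildtypeReplicates)) 36L
                           else as.integer(config$wildtypeReplicates),
      expansionFactor = if (is.null(config$expansionFactor)) 400
                        else config$expansionFactor,
      eventsPerMeasurement = if (is.null(config$events)) 10000L
                             else as.integer(config$events),
      growthNoiseSd = if (is.null(config$growthNoiseSd)) 0
                      else config$growthNoiseSd,
      seed = seed)
    assays <- simulateExperiment(simCfg)
    note("simulate: ", nrow(records(assays)), " competition records, seed ",
         seed)
  } else {
    stopIfNot(!is.null(config$countsPath), "real mode requires countsPath")
    stopIfNot(file.exists(config$countsPath),
              "countsPath does not exist: ", config$countsPath)
    assays <- readCompetitionCsv(config$countsPath)
    seed <- if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
    note("ingest: ", nrow(records(assays)), " competition records from ",
         config$countsPath)
  }

  ## --- stage 2: fitness -----------------------------------------------
  fitness <- tryCatch(
    estimateFitness(assays),
    error = function(e) stop("stage fitness: ", conditionMessage(e),
                             call. = FALSE))
  note("fitness: ", nrow(fitness), " per-replicate estimates; control median ",
       format(attr(fitness, "controlMedian"), digits = 6))

  ## --- stage 3: epistasis ---------------------------------------------
  plasmids <- setdiff(unique(fitness$plasmid), NONE_LABEL)
  mutations <- setdiff(unique(fitness$mutation), NONE_LABEL)
  hasCombos <- length(plasmids) > 0 && length(mutations) > 0 &&
    any(fitness$plasmid != NONE_LABEL & fitness$mutation != NONE_LABEL)
  epi <- if (hasCombos) {
    tryCatch(epistasisAnalysis(fitness, alpha = alpha),
             error = function(e) stop("stage epistasis: ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    note("epistasis: no plasmid-mutation combinations; skipped")
    NULL
  }
  if (!is.null(epi))
    note("epistasis: ", nrow(epi), " combinations classified at alpha ",
         alpha)

  ## --- stage 4: plasmid features --------------------------------------
  features <- NULL
  if (mode == "simulate" && length(plasmids) > 0) {
    pars <- defaultFeatureParams(plasmids)
    rows <- lapply(seq_len(nrow(pars)), function(i) {
      recSeed <- deriveSeed(seed, "plasmid_record", pars$plasmid[i], 0)
      rec <- simulatePlasmidRecord(pars$lengthBp[i], pars$gcFraction[i],
                                   pars$nOrfs[i], pars$codonBiasStrength[i],
                                   seed = recSeed, table = codonTable,
                                   name = pars$plasmid[i])
      dp <- simulateDepthTable(pars$copyNumber[i], 100, noiseCv = 0.1,
                               seed = deriveSeed(seed, "depth",
                                                 pars$plasmid[i], 0))
      plasmidFeatureSummary(rec, codonTable, dp$plasmid, dp$chromosome)
    })
    features <- do.call(rbind, rows)
  } else if (mode == "real" && !is.null(config$recordPaths)) {
    rows <- lapply(names(config$recordPaths), function(lab) {
      rec <- readGenBank(config$recordPaths[[lab]])
      rec@name <- lab
      dp <- if (!is.null(config$depthPaths[[lab]]))
        readDepthTable(config$depthPaths[[lab]]) else NULL
      plasmidFeatureSummary(rec, codonTable,
                            plasmidDepth = dp$plasmid,
                            chromosomeDepth = dp$chromosome)
    })
    features <- do.call(rbind, rows)
  }
  if (!is.null(features)) {
    rownames(features) <- NULL
    note("features: ", nrow(features), " plasmids")
  } else {
    note("features: no plasmid records; skipped")
  }

  ## --- stage 5: feature-cost correlation screen ------------------------
  correlation <- NULL
  if (!is.null(features) && nrow(features) >= 3) {
    costs <- vapply(features$plasmid, function(p) {
      w <- fitness$w[fitness$plasmid == p & fitness$mutation == NONE_LABEL]
      percentCost(median(w))
    }, numeric(1))
    correlation <- do.call(rbind, lapply(
      c("sizeBp", "gcPercent", "meanCai", "copyNumber"), function(feat) {
        v <- features[[feat]]
        if (anyNA(v)) return(NULL)
        s <- spearmanRho(v, costs)
        data.frame(feature = feat, rho = s$rho, p = s$p, n = s$n,
                   method = s$method)
      }))
    rownames(correlation) <- NULL
    note("correlate: ", nrow(correlation), " features vs plasmid cost over ",
         nrow(features), " plasmids")
  } else {
    note("correlate: fewer than 3 plasmids with features; skipped")
  }

  bundle <- list(fitness = fitness, epistasis = epi, features = features,
                 correlation = correlation, log = log, configHash = hash,
                 seed = seed, alpha = alpha)
  bundle$report <- summaryReport(bundle)

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(paste0("config_hash: ", hash), paste0("seed: ", seed))
    writeTableWithHeader(fitness, file.path(outputDir, "fitness.csv"), hdr)
    if (!is.null(epi))
      writeTableWithHeader(epi, file.path(outputDir, "epistasis.csv"), hdr)
    if (!is.null(features))
      writeTableWithHeader(features, file.path(outputDir, "features.csv"),
                           hdr)
    if (!is.null(correlation))
      writeTableWithHeader(correlation,
                           file.path(outputDir, "correlation.csv"), hdr)
    writeLines(bundle$report, file.path(outputDir, "report.txt"))
    writeLines(paste0("# config_hash: ", hash), file.path(outputDir,
                                                          "run.log"))
    cat(log, file = file.path(outputDir, "run.log"), sep = "\n",
        append = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' Plain-text summary report of a pipeline result bundle
#'
#' Per-genotype cost table (% reduction in fitness relative to the
#' plasmid-free wild type), epistasis class counts in "x/y combinations"
#' form, sign-epistasis count, and the feature-cost correlation table.
#' Every number is re-derivable from the bundle's CSV tables.
#'
#' @param bundle result list from [runPipeline()].
#' @return character vector of report lines.
#' @export
summaryReport <- function(bundle) {
  fitness <- bundle$fitness
  lines <- c("Competition fitness and epistasis report",
             paste0("config_hash: ", bundle$configHash),
             "",
             "Genotype costs (% reduction vs plasmid-free wild type):")
  key <- genotypeKey(fitness$plasmid, fitness$mutation)
  for (k in unique(key)) {
    w <- median(fitness$w[key == k])
    lines <- c(lines, sprintf("  %-24s W = %7.4f  cost = %6.1f%%",
                              k, w, percentCost(w)))
  }
  epi <- bundle$epistasis
  if (!is.null(epi)) {
    n <- nrow(epi)
    cnt <- table(factor(epi$classification,
                        levels = c("positive", "negative", "none")))
    lines <- c(lines, "",
               "Epistasis against the multiplicative null:",
               sprintf("  %d/%d combinations positive", cnt[["positive"]], n),
               sprintf("  %d/%d combinations negative", cnt[["negative"]], n),
               sprintf("  %d/%d combinations without significant epistasis",
                       cnt[["none"]], n),
               sprintf("  %d/%d combinations with sign epistasis",
                       sum(epi$signEpistasis), n))
  } else {
    lines <- c(lines, "", "No plasmid-mutation combinations: marginals only.")
  }
  if (!is.null(bundle$correlation)) {
    lines <- c(lines, "", "Feature-cost Spearman screen:")
    cr <- bundle$correlation
    for (i in seq_len(nrow(cr)))
      lines <- c(lines, sprintf("  %-12s rho = %6.2f  p = %6.4f  (n = %d, %s)",
                                cr$feature[i], cr$rho[i], cr$p[i], cr$n[i],
                                cr$method[i]))
  }
  lines
}
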