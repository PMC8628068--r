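test_that("noise-free simulated competitions return the true fitness exactly", {
  cfg <- simulationConfig(expansionFactor = 400, seed = 1)
  for (w in seq(0.35, 1.95, by = 0.2)) {
    rec <- simulateCompetition(w, cfg, seed = 10, sampling = FALSE)
    est <- relativeFitness(rec$n_initial_gfp_neg, rec$n_initial_gfp_pos,
                           rec$n_final_gfp_neg, rec$n_final_gfp_pos)
    expect_equal(est, w, tolerance = 1e-12)
  }
  # the closed form behind the construction: log(G^w)/log(G) = w
  rec <- simulateCompetition(0.9, cfg, seed = 10, sampling = FALSE)
  expect_equal(rec$latent_final_gfp_neg / rec$latent_initial_gfp_neg, 400^0.9)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
                          mutationFitness = c(m1 = 0.7),
                          growthNoiseSd = 0.02, seed = 42)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(records(a), records(b))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeCompetitionCsv(a, f1)
  writeCompetitionCsv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("experiment layout has one replicate block per genotype", {
  g <- data.frame(plasmid = c("none", "pA", "pA"),
                  mutation = c("none", "m1", "m2"))
  cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
                          mutationFitness = c(m1 = 0.7, m2 = 0.9),
                          genotypes = g, replicates = 6L,
                          wildtypeReplicates = 36L, seed = 3)
  rec <- records(simulateExperiment(cfg))
  combo <- rec$plasmid != "none" & rec$mutation != "none"
  expect_equal(sum(combo), 12)  # two combination genotypes x 6 replicates
  expect_equal(sum(!combo), 36) # the wild-type block
  expect_true(all(table(rec$replicate[combo]) == 2L))
})

test_that("combination genotypes get multiplicative fitness plus the shift", {
  cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
                          mutationFitness = c(m1 = 0.7),
                          epistasisShift = c("pA:m1" = 0.1), seed = 1)
  expect_equal(trueFitness(cfg, "pA", "m1"), 0.8 * 0.7 + 0.1)
  expect_equal(trueFitness(cfg, "pA", "none"), 0.8)
  expect_equal(trueFitness(cfg, "none", "none"), 1)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulationConfig(plasmidFitness = c(pA = -0.2), seed = 1),
               "true fitness")
  expect_error(simulationConfig(expansionFactor = 1, seed = 1),
               "expansionFactor")
  expect_error(simulationConfig(plasmidFitness = c(pA = 0.8),
                                epistasisShift = c("pB:m9" = 0.1), seed = 1),
               "epistasisShift")
  cfg <- simulationConfig(seed = 1)
  expect_error(simulateCompetition(-1, cfg, seed = 1), "positive")
})

test_that("cytometry sampling is unbiased in proportion", {
  cfg <- simulationConfig(eventsPerMeasurement = 10000L, seed = 1)
  n <- 3000
  fracInit <- fracFin <- numeric(n)
  for (i in seq_len(n)) {
    r <- simulateCompetition(0.8, cfg, seed = i)
    fracInit[i] <- r$n_initial_gfp_neg /
      (r$n_initial_gfp_neg + r$n_initial_gfp_pos)
    fracFin[i] <- r$n_final_gfp_neg /
      (r$n_final_gfp_neg + r$n_final_gfp_pos)
  }
  latent <- 400^0.8 / (400^0.8 + 400)
  # binomial standard errors of the mean of n draws at 10,000 events each
  expect_lt(abs(mean(fracInit) - 0.5), 3 * sqrt(0.25 / 10000 / n))
  expect_lt(abs(mean(fracFin) - latent),
            3 * sqrt(latent * (1 - latent) / 10000 / n))
})

test_that("mean estimated fitness is centred on truth under sampling noise", {
  cfg <- simulationConfig(eventsPerMeasurement = 10000L, seed = 1)
  ws <- vapply(1:1000, function(i) {
    r <- simulateCompetition(0.8, cfg, seed = 20000 + i)
    relativeFitness(r$n_initial_gfp_neg, r$n_initial_gfp_pos,
                    r$n_final_gfp_neg, r$n_final_gfp_pos)
  }, numeric(1))
  se <- sd(ws) / sqrt(length(ws))
  expect_lt(abs(mean(ws) - 0.8), 3 * se)
})

test_that("simulated plasmid records meet their GC target and ORF grammar", {
  rec <- simulatePlasmidRecord(20000, 0.5, nOrfs = 5,
                               codonBiasStrength = 0.5, seed = 7)
  expect_gte(gcContent(rec), 49)
  expect_lte(gcContent(rec), 51)
  orfs <- extractOrfs(rec)
  expect_length(orfs, 5)
  for (i in seq_along(orfs)) {
    s <- as.character(orfs[[i]])
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
  }
  # determinism
  rec2 <- simulatePlasmidRecord(20000, 0.5, nOrfs = 5,
                                codonBiasStrength = 0.5, seed = 7)
  expect_identical(as.character(plasmidSequence(rec)),
                   as.character(plasmidSequence(rec2)))
  expect_identical(orfFeatures(rec), orfFeatures(rec2))
})

test_that("maximal codon bias yields CAI exactly 1 for every ORF", {
  tab <- defaultCodonTable()
  rec <- simulatePlasmidRecord(12000, 0.5, nOrfs = 4,
                               codonBiasStrength = 1, seed = 9, table = tab)
  feats <- orfFeatureTable(rec, tab)
  expect_equal(feats$cai, rep(1, 4))
})

test_that("impossible ORF packing is rejected", {
  expect_error(simulatePlasmidRecord(1000, 0.5, nOrfs = 10,
                                     codonBiasStrength = 0.5, seed = 1),
               "pack")
  expect_error(simulatePlasmidRecord(5000, 1.2, nOrfs = 0,
                                     codonBiasStrength = 0, seed = 1),
               "gcFraction")
})

test_that("depth simulation gives the exact ratio without noise and an
           unbiased ratio with noise", {
  dp <- simulateDepthTable(15, 100, noiseCv = 0, seed = 1)
  expect_equal(meanDepth(dp$plasmid), 1500)
  expect_equal(copyNumberProxy(dp$plasmid, dp$chromosome), 15)
  dp1 <- simulateDepthTable(1, 80, noiseCv = 0, seed = 1)
  expect_equal(copyNumberProxy(dp1$plasmid, dp1$chromosome), 1)

  # hash-derived seeds: consecutive small integers seed correlated
  # Mersenne-Twister streams, which distorts a 3-SE Monte-Carlo check
  ratios <- vapply(1:100, function(s) {
    d <- simulateDepthTable(15, 100, noiseCv = 0.1,
                            seed = deriveSeed(7, "depth", "mc", s),
                            chromPositions = 2000L, plasmidPositions = 500L)
    copyNumberProxy(d$plasmid, d$chromosome)
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 15), 3 * se)
})
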