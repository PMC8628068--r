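test_that("expected fitness is the product of the marginals", {
  expect_equal(expectedFitness(1, 1), 1)
  expect_equal(expectedFitness(0.8, 0.9), 0.72)
  expect_equal(expectedFitness(0.7, 1.0), 0.7)
  expect_error(expectedFitness(-1, 0.5), "> 0")
})

test_that("epsilon is the deviation from the multiplicative null", {
  expect_equal(epistasis(0.72, 0.8, 0.9), 0)
  expect_equal(epistasis(0.95, 0.8, 0.9), 0.23)
  expect_equal(epistasis(1, 1, 1), 0)
  # antisymmetry under exchanging observed and expected
  set.seed(3)
  for (i in 1:25) {
    a <- runif(1, 0.3, 1.5); b <- runif(1, 0.3, 1.5); c <- runif(1, 0.3, 1.5)
    expect_equal(epistasis(a, b, c), -(b * c - a))
  }
})

test_that("per-replicate epsilon subtracts the marginal-median product", {
  expect_equal(epistasisReplicates(c(0.72, 0.70), 0.8, 0.9), c(0, -0.02))
  expect_equal(epistasisReplicates(rep(0.56, 5), 0.8, 0.7), rep(0, 5))
  # wild type: marginals are 1, so epsilon replicates are w - 1
  wt <- c(0.98, 1.01, 1.00, 1.02)
  expect_equal(epistasisReplicates(wt, 1, 1), wt - 1)
  expect_error(epistasisReplicates(numeric(), 1, 1), "non-empty")
  expect_error(epistasisReplicates(1:3, 0, 1), "marginal")
})

test_that("classification calls sign of the median epsilon only when the
           Tukey contrast against the wild type is significant", {
  wtEps <- c(-0.010, 0.005, -0.003, 0.008, 0.000, -0.002)
  same <- wtEps                      # identical to the wild-type group
  up <- wtEps + 0.3                  # far above
  down <- wtEps - 0.3                # far below
  res <- classifyEpistasis(list(same = same, up = up, down = down),
                           wtEps, alpha = 0.05)
  expect_equal(res$classification[res$genotype == "same"], "none")
  expect_equal(res$adjustedP[res$genotype == "same"], 1, tolerance = 1e-12)
  expect_equal(res$classification[res$genotype == "up"], "positive")
  expect_equal(res$classification[res$genotype == "down"], "negative")
  expect_error(classifyEpistasis(list(a = 1:3), c(1)), ">= 2")
})

test_that("sign epistasis requires beating both single-determinant strains", {
  mut <- c(0.70, 0.71, 0.69, 0.70, 0.72, 0.70)
  car <- c(0.80, 0.79, 0.81, 0.80, 0.78, 0.80)
  above <- c(1.09, 1.11, 1.10, 1.12, 1.10, 1.09)
  between <- c(0.75, 0.74, 0.76, 0.75, 0.74, 0.76)
  oneSided <- c(0.90, 0.91, 0.89, 0.90, 0.92, 0.90)  # above mut, above car?
  expect_true(testSignEpistasis(above, mut, car)$signEpistasis)
  expect_false(testSignEpistasis(between, mut, car)$signEpistasis)
  # above one single but below the other is not sign epistasis
  mid <- testSignEpistasis(oneSided, mut, c(1.20, 1.19, 1.21, 1.2, 1.18, 1.2))
  expect_false(mid$signEpistasis)
  expect_error(testSignEpistasis(1, mut, car), ">= 2")
})

test_that("full epistasis analysis recovers injected epistasis and the
           multiplicative null", {
  # strong injected positive epistasis at low noise
  cfg <- simulationConfig(plasmidFitness = c(pA = 0.8),
                          mutationFitness = c(m1 = 0.7),
                          epistasisShift = c("pA:m1" = 0.2), seed = 31)
  epi <- epistasisAnalysis(estimateFitness(simulateExperiment(cfg)))
  expect_equal(epi$classification, "positive")
  expect_equal(epi$epsilon, 0.2, tolerance = 0.02)
  expect_equal(epi$wExpected, 0.56, tolerance = 0.02)
  # epsilon column equals observed minus expected to machine precision
  expect_equal(epi$epsilon, epi$wObserved - epi$wExpected)

  # negative epistasis
  cfgNeg <- simulationConfig(plasmidFitness = c(pA = 0.8),
                             mutationFitness = c(m1 = 0.7),
                             epistasisShift = c("pA:m1" = -0.15), seed = 32)
  epiNeg <- epistasisAnalysis(estimateFitness(simulateExperiment(cfgNeg)))
  expect_equal(epiNeg$classification, "negative")
})

test_that("reported wild-type median epsilon is zero by definition", {
  for (seed in c(1, 17, 99)) {
    cfg <- simulationConfig(plasmidFitness = c(pA = 0.85),
                            mutationFitness = c(m1 = 0.75), seed = seed)
    epi <- epistasisAnalysis(estimateFitness(simulateExperiment(cfg)))
    expect_identical(attr(epi, "wildtypeMedianEpsilon"), 0)
    expect_lt(abs(median(attr(epi, "wildtypeEpsilon"))), 2^-50)
  }
})

test_that("error-propagation mode agrees with Tukey on clear effects", {
  cfg <- simulationConfig(plasmidFitness = c(pA = 0.8, pB = 0.9),
                          mutationFitness = c(m1 = 0.7),
                          epistasisShift = c("pA:m1" = 0.2), seed = 55)
  fit <- estimateFitness(simulateExperiment(cfg))
  tukey <- epistasisAnalysis(fit)
  ep <- epistasisErrorPropagation(fit, seed = 2)
  key <- paste(ep$plasmid, ep$mutation)
  expect_equal(ep$classification[key == "pA m1"], "positive")
  expect_equal(tukey$classification[paste(tukey$plasmid, tukey$mutation) ==
                                      "pA m1"], "positive")
  expect_equal(ep$epsilon, tukey$epsilon, tolerance = 1e-12)
})
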