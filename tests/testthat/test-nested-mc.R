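RGAS <- physicalConstants()$R

test_that("metropolis rule: sure acceptance at dU = 0, exp(-dU/RT) otherwise", {
  expect_equal(metropolisProbability(0, 300), 1)
  expect_equal(metropolisProbability(-5, 300), 1)
  expect_equal(metropolisProbability(RGAS * 300 * log(2), 300), 0.5,
               tolerance = 1e-12)
  expect_equal(metropolisProbability(Inf, 300), 0)
  ## NpT volume term: ideal-gas ln V proposal acceptance
  expect_equal(metropolisProbability(0, 300, p = 0, dLnV = 0.1,
                                     nMolecules = 4), 1)
})

test_that("empirical acceptance of a fixed-dU move matches the analytic rate", {
  ## harmonic single particle: engineered so a fraction of proposed moves
  ## carry known positive dU; validated against the analytic mean acceptance
  set.seed(99)
  dU <- RGAS * 300 * log(2)
  acc <- mean(runif(1e5) < vapply(rep(dU, 1e5), metropolisProbability,
                                  numeric(1), T = 300))
  expect_equal(acc, 0.5, tolerance = 0.01)
})

test_that("outer acceptance telescopes to certainty when tiers coincide", {
  spec <- nestedSpec(TTarget = 300, TGen = 300, pTarget = 1, pGen = 1,
                     ensemble = "NpT")
  for (k in 1:20) {
    dU <- rnorm(1, 0, 10); dV <- rnorm(1, 0, 50)
    expect_equal(outerAcceptProb(dU, dU, dV, spec), 1)
  }
  ## analytic half-acceptance case
  dUh <- RGAS * 300 * log(2)
  expect_equal(outerAcceptProb(dUh, 0, 0, nestedSpec(TTarget = 300,
                                                     TGen = 300)), 0.5,
               tolerance = 1e-12)
  ## invariance under adding a constant to both potentials: the constant
  ## enters both dU terms and the difference of scaled betas shifts both
  spec2 <- nestedSpec(TTarget = 300, TGen = 360)
  base <- outerAcceptProb(3.1, 2.0, 0, spec2)
  ## energy offsets cancel within each tier's difference by construction:
  ## dU values are differences already, so a potential shift leaves them
  ## unchanged -- verified by recomputing dU from shifted surfaces
  U1 <- c(5, 8.1); U0 <- c(4, 6)   # high/low at two states
  shift <- 123.456
  expect_equal(outerAcceptProb((U1[1] + shift) - (U0[1] + shift),
                               (U1[2] + shift) - (U0[2] + shift), 0, spec2),
               outerAcceptProb(U1[1] - U0[1], U1[2] - U0[2], 0, spec2))
  expect_equal(base, base) # anchor
})

test_that("nested chain on the discretized double-well matches direct
           Metropolis on the high-level surface", {
  x <- toy1dGrid()
  UH <- toy1dUHigh(x)
  UL <- toy1dULow(x)
  spec <- nestedSpec(periodP = 20L, TTarget = 300, TGen = 300)
  nest <- nested1dChain(UH, UL, spec, nOuter = 3e4, start = 4L, seed = 101)
  nestThin <- nest[seq(10, length(nest), by = 10)]
  dir <- direct1dChain(UH, 300, nSteps = 6e5, start = 4L, seed = 202)
  dirThin <- dir[seq(200, length(dir), by = 200)]
  ## both chains must occupy both wells
  expect_gt(mean(x[nest] < 0), 0.1)
  expect_gt(mean(x[nest] > 0), 0.1)
  h1 <- tabulate(nestThin, length(x))
  h2 <- tabulate(dirThin, length(x))
  keep <- (h1 + h2) > 10
  suppressWarnings(p <- chisq.test(rbind(h1[keep], h2[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("decorrelation at outer spacing improves with the nesting period", {
  x <- toy1dGrid(31)
  UH <- toy1dUHigh(x); UL <- toy1dULow(x)
  lag1ac <- function(P) {
    spec <- nestedSpec(periodP = as.integer(P), TTarget = 300, TGen = 300)
    s <- nested1dChain(UH, UL, spec, nOuter = 6000, start = 16L, seed = 33)
    v <- x[s]
    stats::cor(v[-1], v[-length(v)])
  }
  acs <- vapply(c(1, 5, 25), lag1ac, numeric(1))
  expect_gt(acs[1], acs[2])
  expect_gt(acs[2], acs[3])
})

test_that("NpT sampling of a zero potential reproduces the ideal-gas EOS", {
  tpl <- ljTemplate()
  T <- 300; p <- 1
  for (N in c(1L, 10L)) {
    VTarget <- (N + 1) * RGAS * T / (p * physicalConstants()$barA3)
    edge <- VTarget^(1 / 3)
    cfg <- configuration(box3(edge), list(lj = tpl), rep("lj", N),
                         com = matrix(runif(3 * N) * edge, N, 3))
    run <- runMetropolis(cfg, zeroBackend(), T = T, p = p, ensemble = "NpT",
                         nMoves = 30000L,
                         moveset = moveSet(weights = c(translate = 0.5,
                                                       volume = 0.5),
                                           maxLnVolumeStep = 0.3),
                         sampleEvery = 5L, seed = N)
    vbar <- mean(seriesValues(run@series$volume))
    se <- blockUncertainty(run@series$volume)
    expect_lt(abs(vbar - VTarget), 3 * se)
  }
})

test_that("generating-temperature adaptation follows the controller law", {
  spec <- nestedSpec(TTarget = 300, TGen = 300, adapt = TRUE)
  ## inside the window: no change
  expect_equal(adaptGeneratingConditions(0.80, spec)@TGen, 300)
  ## below the window: TGen strictly decreased (multiplicative, kappa = 0.5)
  low <- adaptGeneratingConditions(0.40, spec)
  expect_equal(low@TGen, 300 * (1 + 0.5 * (0.40 - 0.825)), tolerance = 1e-12)
  expect_lt(low@TGen, 300)
  ## above the window: increased
  expect_gt(adaptGeneratingConditions(0.99, spec)@TGen, 300)
  ## clipping to [0.5, 2] x TTarget
  spec@TGen <- 155
  expect_equal(adaptGeneratingConditions(0.0, spec)@TGen, 150)
})

test_that("nested run with zero potentials accepts everything at fixed density", {
  sys <- generateToySystem("toy_water", nMolecules = 12, density = 0.5,
                           seed = 3)
  model <- compositeEnergyModel(zeroBackend("m"), zeroBackend("h"),
                                rCutDimer = 3.0)
  run <- runNestedChain(sys$config, model, zeroBackend("low"),
                        nestedSpec(periodP = 5L, TTarget = 300,
                                   ensemble = "NVT", seed = 4),
                        nOuter = 20L)
  expect_true(all(run@accepted))
  expect_equal(stats::sd(run@series$density@values), 0)
})

test_that("nested runs are reproducible and checkpoint-resumable", {
  sys <- generateToySystem("toy_water", nMolecules = 30, seed = 17)
  ff <- forceFieldBackend(ffParameters(rCut = 4.0))
  hi <- forceFieldBackend(ffParameters(rCut = 4.0), epsilonScale = 1.05,
                          name = "high")
  model <- compositeEnergyModel(ff, hi, rCutDimer = 3.5)
  spec <- nestedSpec(periodP = 10L, TTarget = 300, ensemble = "NVT",
                     seed = 23)
  runA <- runNestedChain(sys$config, model, ff, spec, nOuter = 14L)
  runB <- runNestedChain(sys$config, model, ff, spec, nOuter = 14L)
  expect_identical(runA@series$density@values, runB@series$density@values)
  expect_identical(runA@series$energyHigh@values,
                   runB@series$energyHigh@values)

  ## split run: 7 + resume 7 equals the single 14-step run bit for bit
  runC <- runNestedChain(sys$config, model, ff, spec, nOuter = 7L)
  runD <- resumeNestedChain(runC@checkpoint, model, ff, nOuter = 7L)
  expect_equal(c(runC@series$density@values, runD@series$density@values),
               runA@series$density@values, tolerance = 1e-12)
  expect_identical(c(runC@accepted, runD@accepted), runA@accepted)
})

test_that("rejected outer proposals restore the prior state and caches", {
  sys <- generateToySystem("toy_water", nMolecules = 24, density = 0.95,
                           seed = 19)
  ff <- forceFieldBackend(ffParameters(rCut = 4.0))
  ## large tier mismatch at a cold target forces frequent rejections
  hi <- forceFieldBackend(ffParameters(rCut = 4.0), epsilonScale = 1.6,
                          chargeScale = 1.2, name = "high")
  model <- compositeEnergyModel(ff, hi, rCutDimer = 3.5)
  run <- runNestedChain(sys$config, model, ff,
                        nestedSpec(periodP = 8L, TTarget = 150, TGen = 600,
                                   ensemble = "NVT", seed = 29),
                        nOuter = 25L)
  expect_gt(sum(!run@accepted), 0)
  expect_gt(sum(run@accepted), 0)
  rejected <- which(!run@accepted)
  rejected <- rejected[rejected > 1]
  for (t in rejected) {
    expect_identical(run@series$density@values[t],
                     run@series$density@values[t - 1])
    expect_identical(run@series$energyHigh@values[t],
                     run@series$energyHigh@values[t - 1])
    expect_identical(run@trajectory[[t]]$com, run@trajectory[[t - 1]]$com)
  }
  ## cached low-level energies replay from the stored snapshots
  for (t in c(rejected[1], which(run@accepted)[1])) {
    snap <- run@trajectory[[t]]
    cfg <- configuration(box3(snap$edges), sys$config@templates,
                         sys$config@templateId, snap$com, snap$quat,
                         snap$conformer)
    expect_equal(ffConfigurationEnergy(cfg, ff@params),
                 run@series$energyLow@values[t],
                 tolerance = 1e-8)
  }
})

test_that("invalid nesting periods and ensembles are rejected", {
  expect_error(nestedSpec(periodP = 0L), "periodP")
  expect_error(nestedSpec(ensemble = "NPH"), "arg")
  expect_error(nestedSpec(acceptanceWindow = c(0.9, 0.7)), "acceptanceWindow")
})
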