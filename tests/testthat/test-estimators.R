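RGAS <- physicalConstants()$R

test_that("running average is the cumulative mean past burn-in", {
  s <- scalarSeries(c(10, 10, 1, 2, 3, 4), burnIn = 2L)
  expect_equal(seriesValues(s), c(1, 2, 3, 4))
  expect_equal(runningAverage(s), cumsum(c(1, 2, 3, 4)) / 1:4)
  expect_equal(tail(runningAverage(s), 1), mean(seriesValues(s)))
})

test_that("block uncertainty: constant, i.i.d. and AR(1) series", {
  expect_equal(blockUncertainty(scalarSeries(rep(3.14, 100))), 0)
  expect_error(blockUncertainty(scalarSeries(rnorm(10))), "insufficient")

  ## i.i.d.: estimate ~ sigma/sqrt(n); every seed within 20%, mean much closer
  set.seed(5)
  n <- 1e4; sigma <- 2.5
  ratios <- replicate(100, {
    blockUncertainty(rnorm(n, sd = sigma)) / (sigma / sqrt(n))
  })
  expect_true(all(abs(ratios - 1) < 0.2))
  expect_lt(abs(mean(ratios) - 1), 0.05)

  ## AR(1) with phi = 0.9: inflation over the naive SEM approaches
  ## sqrt((1+phi)/(1-phi))
  phi <- 0.9
  inflTrue <- sqrt((1 + phi) / (1 - phi))
  set.seed(11)
  infl <- replicate(20, {
    n <- 2^15
    x <- as.numeric(stats::arima.sim(list(ar = phi), n))
    blockUncertainty(x) / (sd(x) / sqrt(n))
  })
  expect_lt(abs(mean(infl) - inflTrue) / inflTrue, 0.25)
})

test_that("mass density follows the molar-mass / volume arithmetic", {
  tpl <- toyTemplate("toy_water") # M = 18.015 g/mol
  cfg <- configuration(box3(10), list(toy_water = tpl), "toy_water",
                       com = matrix(5, 1, 3))
  ## hand conversion: M / (N_A V) with V in cm^3
  handRho <- 18.015 / (6.02214076e23 * 1000e-24)
  expect_equal(massDensity(cfg), handRho, tolerance = 1e-6)
  ## doubling V at fixed N halves the density exactly
  big <- configuration(box3(10 * 2^(1 / 3)), list(toy_water = tpl),
                       "toy_water", com = matrix(5, 1, 3))
  expect_equal(massDensity(big), massDensity(cfg) / 2, tolerance = 1e-12)
  ## empty box
  empty <- configuration(box3(10), list(toy_water = tpl), character(0),
                         com = matrix(0, 0, 3))
  expect_equal(massDensity(empty), 0)
})

test_that("vaporization enthalpy: analytic non-interacting limit", {
  T <- 300; N <- 20
  uLiq <- scalarSeries(rep(0, 100))
  vol <- scalarSeries(rep(600, 100)) # dense box: pV term ~ 1e-6 kJ/mol
  dv <- vaporizationEnthalpy(uLiq, vol, N, p = 1, T = T)
  expect_equal(dv$value, RGAS * T - 1 * 600 * physicalConstants()$barA3 / N,
               tolerance = 1e-12)
  expect_equal(dv$value, 2.494, tolerance = 1e-3)
  expect_equal(dv$se, 0)
  expect_error(vaporizationEnthalpy(uLiq, vol, N, 1, 300, TGas = 310),
               "mismatched temperatures")
})

test_that("vaporization enthalpy replays from stored trajectory energies", {
  sys <- generateToySystem("toy_water", nMolecules = 24, density = 0.95,
                           seed = 31)
  ff <- forceFieldBackend(ffParameters(rCut = 4.0))
  run <- runMetropolis(sys$config, ff, T = 300, p = 1, ensemble = "NpT",
                       nMoves = 600L, sampleEvery = 10L, seed = 7)
  dv <- vaporizationEnthalpy(run@series$energy, run@series$volume, 24,
                             p = 1, T = 300)
  ## independent recomputation: rebuild each stored frame and re-evaluate
  cfgs <- trajectoryConfigurations(run, sys$config)
  burn <- run@series$energy@burnIn
  cfgs <- cfgs[-seq_len(burn)]
  uBar <- mean(vapply(cfgs, function(c) ffConfigurationEnergy(c, ff@params),
                      numeric(1)))
  vBar <- mean(vapply(cfgs, boxVolume, numeric(1)))
  expected <- (0 + RGAS * 300) -
    (uBar / 24 + 1 * vBar * physicalConstants()$barA3 / 24)
  expect_equal(dv$value, expected, tolerance = 1e-9)
})

test_that("thermal expansivity recovers analytic and noisy ground truth", {
  T <- seq(240, 320, by = 10)
  ## constant density: zero expansivity
  expect_equal(thermalExpansivity(T, rep(0.9, length(T)))$alpha,
               rep(0, length(T)))
  ## exponential density profile: alpha = a exactly (up to truncation)
  a <- 1.2e-3
  rho <- 0.95 * exp(-a * T)
  al <- thermalExpansivity(T, rho)
  expect_equal(al$alpha[2:(length(T) - 1)], rep(a, length(T) - 2),
               tolerance = 1e-4)
  expect_error(thermalExpansivity(c(300, 290, 310), rho[1:3]),
               "strictly increasing")
  expect_error(thermalExpansivity(c(300, 310), c(1, 1)), "at least 3")

  ## simulation study: recovery within the propagated uncertainty in >= 90%
  ## of 200 seeds at the central grid point (1.96 sigma ~ 95% nominal)
  set.seed(77)
  sigma <- 0.002
  mid <- 5L
  hits <- replicate(200, {
    rhoNoisy <- rho + rnorm(length(T), sd = sigma)
    alN <- thermalExpansivity(T, rhoNoisy, rhoErr = rep(sigma, length(T)))
    abs(alN$alpha[mid] - a) <= 1.96 * alN$alphaErr[mid]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("heat-capacity difference is exact on polynomial enthalpies", {
  T <- seq(250, 330, by = 10)
  ## linear dvapH: slope recovered exactly everywhere
  hLin <- 60 - 0.05 * T
  cp <- heatCapacityDifference(T, hLin)
  expect_equal(cp$dvapCp, rep(-0.05, length(T)), tolerance = 1e-12)
  ## constant: zero
  expect_equal(heatCapacityDifference(T, rep(41, length(T)))$dvapCp,
               rep(0, length(T)))
  ## quadratic: central differences are exact at interior points
  hQ <- 80 - 0.04 * T + 2e-5 * T^2
  cpQ <- heatCapacityDifference(T, hQ)
  inner <- 2:(length(T) - 1)
  expect_equal(cpQ$dvapCp[inner], -0.04 + 4e-5 * T[inner], tolerance = 1e-10)

  ## noisy recovery within propagated uncertainty in >= 90% of 200 seeds
  set.seed(78)
  sigma <- 0.15
  mid <- 5L
  hits <- replicate(200, {
    hN <- hQ + rnorm(length(T), sd = sigma)
    cpN <- heatCapacityDifference(T, hN, dvapHErr = rep(sigma, length(T)))
    abs(cpN$dvapCp[mid] - (-0.04 + 4e-5 * T[mid])) <=
      1.96 * cpN$dvapCpErr[mid]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("radial distribution: frozen pair, conservation, uniform ideal gas", {
  tpl <- ljTemplate()
  ## two frozen molecules at distance d: a single occupied bin containing d
  d <- 3.33
  cfg <- configuration(box3(12), list(lj = tpl), c("lj", "lj"),
                       com = rbind(c(2, 2, 2), c(2 + d, 2, 2)))
  rdf <- radialDistribution(list(cfg), pair = c("Ar", "Ar"),
                            binWidth = 0.1, rMax = 5)
  occupied <- which(rdf@counts > 0)
  expect_length(occupied, 1)
  expect_true(rdf@edges[occupied] <= d && d < rdf@edges[occupied + 1])
  expect_equal(sum(rdf@counts), 1)

  ## bin-count conservation on a liquid-like box
  sys <- generateToySystem("toy_water", nMolecules = 20, density = 0.8,
                           seed = 41)
  rMax <- min(sys$config@box@edges) / 2 - 0.05
  rdfW <- radialDistribution(list(sys$config), pair = c("O", "O"),
                             binWidth = 0.05, rMax = rMax)
  st <- fragmc:::siteTable(sys$config)
  iO <- which(st$label == "O")
  pairs <- utils::combn(iO, 2)
  dd <- fragmc:::.minImage(st$coords[pairs[2, ], ] - st$coords[pairs[1, ], ],
                           sys$config@box@edges)
  nIn <- sum(sqrt(rowSums(dd^2)) < max(rdfW@edges))
  expect_equal(sum(rdfW@counts), nIn)

  ## ideal-gas frames: g(r) ~ 1 in every bin (binomial noise)
  set.seed(55)
  frames <- lapply(1:60, function(k)
    configuration(box3(14), list(lj = tpl), rep("lj", 25),
                  com = matrix(runif(75) * 14, 25, 3)))
  rdfI <- radialDistribution(frames, pair = c("Ar", "Ar"), binWidth = 0.25,
                             rMax = 6.5)
  sel <- rdfI@edges[-length(rdfI@edges)] > 1 # skip near-empty core shells
  expect_lt(max(abs(rdfI@g[sel] - 1)), 0.2)
  expect_equal(mean(rdfI@g[sel]), 1, tolerance = 0.02)
})

test_that("radial distribution matches the brute-force histogram bit for bit", {
  sys <- generateToySystem("toy_water", nMolecules = 30, seed = 43)
  ff <- forceFieldBackend(ffParameters(rCut = 4.0))
  run <- runMetropolis(sys$config, ff, T = 300, ensemble = "NVT",
                       nMoves = 200L, sampleEvery = 50L, seed = 3,
                       burnInFraction = 0)
  cfgs <- trajectoryConfigurations(run, sys$config)
  rMax <- min(sys$config@box@edges) / 2 - 0.01
  for (pair in list(c("O", "O"), c("O", "H1"))) {
    rdf <- radialDistribution(cfgs, pair = pair, binWidth = 0.1, rMax = rMax)
    expect_identical(rdf@counts,
                     naiveRdfCounts(cfgs, pair, 0.1, rMax))
    expect_true(all(rdf@g >= 0))
  }
})

test_that("thermo table assembles the full observable grid", {
  sys <- generateToySystem("toy_water", nMolecules = 24, density = 0.95,
                           seed = 51)
  ff <- forceFieldBackend(ffParameters(rCut = 4.0))
  hi <- forceFieldBackend(ffParameters(rCut = 4.0), epsilonScale = 1.05,
                          name = "h")
  model <- compositeEnergyModel(ff, hi, rCutDimer = 3.5)
  Ts <- c(280, 300, 320)
  runs <- lapply(seq_along(Ts), function(k)
    runNestedChain(sys$config, model, ff,
                   nestedSpec(periodP = 5L, TTarget = Ts[k], ensemble = "NVT",
                              seed = 60 + k), nOuter = 25L))
  tab <- thermoTable(runs, Ts, nMolecules = 24, p = 1)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$rho)) && all(tab$rhoErr >= 0))
  ## the finite-difference columns replay from the reported rho / dvapH
  alHand <- -(tab$rho[3] - tab$rho[1]) / (Ts[3] - Ts[1]) / tab$rho[2]
  expect_equal(tab$alpha[2], alHand, tolerance = 1e-12)
  cpHand <- (tab$dvapH[3] - tab$dvapH[1]) / (Ts[3] - Ts[1])
  expect_equal(tab$dvapCp[2], cpHand, tolerance = 1e-12)
})
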