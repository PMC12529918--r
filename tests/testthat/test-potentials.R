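test_that("LJ pair energy has its root at sigma and minimum at 2^(1/6) sigma", {
  expect_equal(ljPairEnergy(3.15, 3.15, 0.636), 0)
  expect_equal(ljPairEnergy(2^(1 / 6) * 3.15, 3.15, 0.636), -0.636,
               tolerance = 1e-12)
  ## closed form at an arbitrary point
  expect_equal(ljPairEnergy(3 * 3.15, 3.15, 0.636),
               oracleLJ(3 * 3.15, 3.15, 0.636), tolerance = 1e-12)
  expect_error(ljPairEnergy(0, 3, 1), "overlap")
})

test_that("DSF Coulomb vanishes smoothly at the cutoff", {
  rc <- 4.5; a <- 0.2
  expect_equal(dsfCoulombEnergy(2.0, 0, 0.4, a, rc), 0)
  expect_equal(dsfCoulombEnergy(rc, 0.4, -0.8, a, rc), 0, tolerance = 1e-14)
  expect_equal(dsfCoulombEnergy(rc + 0.5, 0.4, -0.8, a, rc), 0)
  ## continuous first derivative at the cutoff: numeric slope -> 0
  h <- 1e-6
  slope <- (dsfCoulombEnergy(rc - h, 0.4, -0.8, a, rc) -
              dsfCoulombEnergy(rc - 2 * h, 0.4, -0.8, a, rc)) / h
  expect_lt(abs(slope), 1e-4)
  ## zero-damping limit approaches plain Coulomb minus its shift terms
  k <- physicalConstants()$coulomb
  r <- 1.5
  plain <- k * 0.4 * -0.8 * (1 / r - 1 / rc + (r - rc) / rc^2)
  expect_equal(dsfCoulombEnergy(r, 0.4, -0.8, damping = 1e-12, rc), plain,
               tolerance = 1e-8)
  ## agrees with the independently coded closed form with damping on
  expect_equal(dsfCoulombEnergy(r, 0.4, -0.8, a, rc),
               oracleDSF(r, 0.4 * -0.8, a, rc), tolerance = 1e-12)
})

test_that("configuration energy: single molecule, LJ dimer, oracle match", {
  sys <- generateToySystem("toy_water", nMolecules = 1, density = 0.02,
                           seed = 1)
  expect_equal(ffConfigurationEnergy(sys$config, ffParameters(rCut = 4.0)), 0)

  cfg <- ljDimerConfig(2^(1 / 6) * 3.0)
  expect_equal(ffConfigurationEnergy(cfg, ffParameters(rCut = 10)), -1.0,
               tolerance = 1e-12)

  ## 20-molecule random box vs the O(N^2) double-loop oracle
  sys <- generateToySystem("toy_water", nMolecules = 20, density = 0.7,
                           seed = 9)
  p <- ffParameters(rCut = 4.5, damping = 0.2)
  expect_equal(ffConfigurationEnergy(sys$config, p),
               naiveFFEnergy(sys$config, rCut = 4.5, damping = 0.2),
               tolerance = 1e-9)
  ## geometric combining rule path
  pg <- ffParameters("geometric", rCut = 4.5)
  expect_equal(ffConfigurationEnergy(sys$config, pg),
               naiveFFEnergy(sys$config, rCut = 4.5,
                             combining = "geometric"),
               tolerance = 1e-9)
})

test_that("cutoff validity and overlap errors are enforced", {
  sys <- generateToySystem("toy_water", nMolecules = 16, seed = 2)
  expect_error(ffConfigurationEnergy(sys$config, ffParameters(rCut = 4.5)),
               "half the smallest box edge")
  tpl <- ljTemplate()
  cfg <- configuration(box3(30), list(lj = tpl), c("lj", "lj"),
                       com = rbind(c(1, 1, 1), c(1.05, 1, 1)))
  expect_error(ffConfigurationEnergy(cfg, ffParameters(rCut = 10)),
               "degenerate")
})

test_that("energy is invariant under rigid whole-box translation", {
  sys <- generateToySystem("toy_water", nMolecules = 20, density = 0.8,
                           seed = 4)
  p <- ffParameters(rCut = 4.5)
  e0 <- ffConfigurationEnergy(sys$config, p)
  shifted <- sys$config
  shifted@com <- sweep(shifted@com, 2, c(1.7, -4.2, 0.9), "+")
  expect_lt(abs(ffConfigurationEnergy(shifted, p) - e0), 1e-8)
})

test_that("two half-boxes beyond the cutoff are energetically independent", {
  tpl <- ljTemplate(sigma = 3.0, epsilon = 1.0)
  mk <- function(coms) configuration(box3(60), list(lj = tpl),
                                     rep("lj", nrow(coms)), com = coms)
  A <- rbind(c(5, 5, 5), c(8, 5, 5), c(5, 8, 5))
  B <- rbind(c(35, 35, 35), c(38, 35, 35))
  p <- ffParameters(rCut = 9)
  eTot <- ffConfigurationEnergy(mk(rbind(A, B)), p)
  expect_equal(eTot, ffConfigurationEnergy(mk(A), p) +
                 ffConfigurationEnergy(mk(B), p), tolerance = 1e-12)
})

test_that("LJ tail correction scales as 1/V and lowers the energy", {
  tpl <- ljTemplate()
  coms <- rbind(c(2, 2, 2), c(6, 2, 2), c(2, 6, 2), c(6, 6, 6))
  cfg <- configuration(box3(20), list(lj = tpl), rep("lj", 4), com = coms)
  eOff <- ffConfigurationEnergy(cfg, ffParameters(rCut = 8, tailCorrection = FALSE))
  eOn <- ffConfigurationEnergy(cfg, ffParameters(rCut = 8, tailCorrection = TRUE))
  tail1 <- eOn - eOff
  expect_lt(tail1, 0)
  big <- configuration(box3(40), list(lj = tpl), rep("lj", 4), com = coms)
  tail2 <- ffConfigurationEnergy(big, ffParameters(rCut = 8, tailCorrection = TRUE)) -
    ffConfigurationEnergy(big, ffParameters(rCut = 8, tailCorrection = FALSE))
  expect_equal(tail1 / tail2, 8, tolerance = 1e-9) # V ratio
})

test_that("pair interaction energy is symmetric and matches cross terms", {
  zero <- zeroBackend()
  sys <- generateToySystem("toy_water", nMolecules = 4, density = 0.05,
                           seed = 3)
  expect_equal(pairInteractionEnergy(zero, sys$config, 1, 2), 0)

  cfg <- ljDimerConfig(2^(1 / 6) * 3.0)
  ff <- forceFieldBackend(ffParameters(rCut = 10))
  expect_equal(pairInteractionEnergy(ff, cfg, 1, 2), -1, tolerance = 1e-12)
  expect_identical(pairInteractionEnergy(ff, cfg, 1, 2),
                   pairInteractionEnergy(ff, cfg, 2, 1))

  ## random-orientation water dimer at interaction range: interaction equals
  ## the full FF energy restricted to the cross terms (monomers carry no
  ## intermolecular pairs)
  set.seed(8)
  tpl <- toyTemplate("toy_water")
  dim2 <- configuration(box3(12), list(toy_water = tpl),
                        c("toy_water", "toy_water"),
                        com = rbind(c(4, 4, 4), c(4 + 3.0, 4.4, 3.7)),
                        quat = rbind(fragmc:::quatRandom(runif(3)),
                                     fragmc:::quatRandom(runif(3))))
  ffb <- forceFieldBackend(ffParameters(rCut = 4.5))
  expect_equal(pairInteractionEnergy(ffb, dim2, 1, 2),
               ffConfigurationEnergy(dim2, ffb@params),
               tolerance = 1e-9)
})

test_that("scaled force-field backends rescale epsilon uniformly", {
  cfg <- ljDimerConfig(2^(1 / 6) * 3.0)
  hi <- forceFieldBackend(ffParameters(rCut = 10), epsilonScale = 1.05)
  expect_equal(fullEnergy(hi, cfg), -1.05, tolerance = 1e-12)
})

test_that("external engine adapter dispatches, caches, and reports failures", {
  ## mock engine: an Rscript that reads the XYZ and prints a constant
  constScript <- tempfile(fileext = ".R")
  writeLines('cat("energy: -12.5\n")', constScript)
  eng <- externalEngineBackend(sprintf("Rscript %s {xyz}", constScript),
                               name = "mock-const")
  frag <- makeFragment(ljDimerConfig(3.4), c(1, 2))
  expect_equal(fragmentEnergy(eng, frag), -12.5)
  expect_equal(engineDispatchCount(eng), 1L)
  ## identical geometry: served from cache, no new dispatch
  expect_equal(fragmentEnergy(eng, frag), -12.5)
  expect_equal(engineDispatchCount(eng), 1L)

  failScript <- tempfile(fileext = ".R")
  writeLines("quit(status = 3)", failScript)
  bad <- externalEngineBackend(sprintf("Rscript %s {xyz}", failScript),
                               name = "mock-fail")
  expect_error(fragmentEnergy(bad, frag), "status 3.*fragment")

  noparse <- externalEngineBackend(sprintf("Rscript %s {xyz}", constScript),
                                   energyPattern = "FINAL=(\\S+)",
                                   name = "mock-noparse")
  expect_error(fragmentEnergy(noparse, frag), "parse failure")
})

test_that("external engine computing LJ agrees with the builtin form", {
  ljScript <- tempfile(fileext = ".R")
  writeLines(c(
    'args <- commandArgs(trailingOnly = TRUE)',
    'lines <- readLines(args[1])',
    'n <- as.integer(lines[1])',
    'xyz <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2+n)]), "\\\\s+"),',
    '  function(t) as.numeric(t[2:4])))',
    'r <- sqrt(sum((xyz[1,] - xyz[2,])^2))',
    'e <- 4 * 1.0 * ((3.0/r)^12 - (3.0/r)^6)',
    'cat(sprintf("energy: %.12f\n", e))'), ljScript)
  eng <- externalEngineBackend(sprintf("Rscript %s {xyz}", ljScript),
                               name = "mock-lj")
  cfg <- ljDimerConfig(3.7)
  frag <- makeFragment(cfg, c(1, 2))
  expect_equal(fragmentEnergy(eng, frag), ljPairEnergy(3.7, 3.0, 1.0),
               tolerance = 1e-9)
})
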