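## shared fixture: a short recorded toy-water run with a two-tier model
makeRecordedRun <- function(nMol = 20, nOuter = 8L, seed = 71) {
  sys <- generateToySystem("toy_water", nMolecules = nMol, density = 0.95,
                           seed = seed)
  med <- forceFieldBackend(ffParameters(rCut = 4.0), name = "medium-ff")
  hi <- forceFieldBackend(ffParameters(rCut = 4.0), epsilonScale = 1.05,
                          name = "high-ff")
  model <- compositeEnergyModel(med, hi, rCutDimer = 3.5)
  run <- runNestedChain(sys$config, model, med,
                        nestedSpec(periodP = 5L, TTarget = 300,
                                   ensemble = "NVT", seed = seed),
                        nOuter = nOuter, recordGeometry = TRUE)
  list(sys = sys, model = model, run = run, high = hi, med = med)
}

test_that("pair-record extraction counts one entry per snapshot dimer", {
  fx <- makeRecordedRun()
  entries <- extractPairRecords(fx$run, fx$model, material = "toy_water")
  expect_equal(length(entries), nrow(fx$run@dimerRecords))
  ## count equals an independent re-enumeration over the stored trajectory
  cfgs <- trajectoryConfigurations(fx$run, fx$sys$config)
  reEnum <- sum(vapply(cfgs, function(c)
    nrow(enumerateProximateDimers(c, 3.5)), numeric(1)))
  expect_equal(length(entries), reEnum)
  ## no duplicates within a snapshot
  keys <- vapply(entries, function(e)
    paste(e$record$snapshot, e$record$i, e$record$j), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  ## provenance carries the backend names and conditions
  expect_equal(entries[[1]]$provenance$backendHigh, "high-ff")
  expect_equal(entries[[1]]$provenance$T, 300)
})

test_that("extraction demands a recorded breakdown", {
  sys <- generateToySystem("toy_water", nMolecules = 10, density = 0.9,
                           seed = 2)
  ff <- forceFieldBackend(ffParameters(rCut = 3.2))
  model <- compositeEnergyModel(ff, ff, rCutDimer = 3.0)
  run <- runNestedChain(sys$config, model, ff,
                        nestedSpec(periodP = 3L, ensemble = "NVT", seed = 5),
                        nOuter = 3L, recordGeometry = FALSE)
  expect_error(extractPairRecords(run, model), "recordGeometry")
})

test_that("two molecules always in contact give one entry per snapshot", {
  tpl <- toyTemplate("toy_water")
  cfg <- configuration(box3(14), list(toy_water = tpl),
                       rep("toy_water", 2),
                       com = rbind(c(5, 5, 5), c(7.8, 5, 5)))
  ff <- forceFieldBackend(ffParameters(rCut = 4.5))
  model <- compositeEnergyModel(ff, ff, rCutDimer = 4.0)
  ## frozen moveset: nothing moves, the pair stays within the cutoff
  ms <- moveSet(maxTranslation = 1e-6, maxRotation = 1e-6,
                weights = c(translate = 0.5, rotate = 0.5))
  run <- runNestedChain(cfg, model, ff,
                        nestedSpec(periodP = 2L, ensemble = "NVT", seed = 9),
                        nOuter = 10L, moveset = ms, recordGeometry = TRUE)
  entries <- extractPairRecords(run, model)
  expect_length(entries, 10)
})

test_that("library round-trips losslessly and rewrites byte-stably", {
  ## empty library
  p0 <- tempfile(fileext = ".extxyz")
  writeLibrary(list(), p0)
  expect_length(readLibrary(p0), 0)

  fx <- makeRecordedRun()
  entries <- extractPairRecords(fx$run, fx$model, material = "toy_water")
  expect_gt(length(entries), 50)
  p1 <- tempfile(fileext = ".extxyz")
  writeLibrary(entries, p1)
  back <- readLibrary(p1)
  expect_length(back, length(entries))
  for (k in c(1L, 7L, length(entries))) {
    expect_lt(abs(back[[k]]$record$eIntHigh - entries[[k]]$record$eIntHigh),
              1e-8)
    expect_lt(abs(back[[k]]$record$eIntMedium -
                    entries[[k]]$record$eIntMedium), 1e-8)
    expect_equal(back[[k]]$record$contactClass,
                 entries[[k]]$record$contactClass)
    expect_equal(back[[k]]$record$snapshot, entries[[k]]$record$snapshot)
    expect_equal(back[[k]]$geometry$coords, entries[[k]]$geometry$coords,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_identical(back[[k]]$geometry$elements,
                     entries[[k]]$geometry$elements)
    expect_identical(back[[k]]$provenance$backendHigh,
                     entries[[k]]$provenance$backendHigh)
  }
  ## byte stability: write(read(write(x))) == write(x)
  p2 <- tempfile(fileext = ".extxyz")
  writeLibrary(back, p2)
  expect_identical(readLines(p2), readLines(p1))

  ## malformed frame: truncated file is refused with the frame index
  lines <- readLines(p1)
  writeLines(lines[1:(length(lines) - 3)], p2)
  expect_error(readLibrary(p2), "frame")
})

test_that("library entries replay their stored interaction energies", {
  fx <- makeRecordedRun(nOuter = 5L)
  entries <- extractPairRecords(fx$run, fx$model)
  tm <- fx$sys$config@templates
  for (e in entries[seq(1, length(entries), by = 7)]) {
    expect_equal(replayInteractionEnergy(e, fx$high, tm), e$record$eIntHigh,
                 tolerance = 1e-6)
    expect_equal(replayInteractionEnergy(e, fx$med, tm), e$record$eIntMedium,
                 tolerance = 1e-6)
    ## stored dimers are contiguous (no split across the boundary)
    expect_lt(max(dist(e$geometry$coords)), 12)
  }
})

test_that("library size is monotone in the dimer cutoff", {
  sys <- generateToySystem("toy_water", nMolecules = 20, density = 0.95,
                           seed = 83)
  med <- forceFieldBackend(ffParameters(rCut = 4.0))
  sizes <- vapply(c(2.8, 3.3, 3.8), function(rc) {
    model <- compositeEnergyModel(med, med, rCutDimer = rc)
    run <- runNestedChain(sys$config, model, med,
                          nestedSpec(periodP = 4L, ensemble = "NVT",
                                     seed = 13),
                          nOuter = 5L, recordGeometry = TRUE)
    length(extractPairRecords(run, model))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("library summary counts classes and orders their energies", {
  ## synthetic mixed-class library with known proportions
  mk <- function(class, e, n) replicate(n, list(
    record = list(i = 1L, j = 2L, contactDistance = runif(1, 2, 4),
                  contactClass = class, labelI = "O", labelJ = "H",
                  eIntHigh = e + rnorm(1, 0, 0.1), eIntMedium = e,
                  snapshot = 1L),
    geometry = NULL, provenance = NULL), simplify = FALSE)
  entries <- c(mk("O_H...H_O", -20, 30), mk("O_H...H_C", -3, 50),
               mk("O_H...O_H", +5, 20))
  s <- summarizeLibrary(entries)
  expect_equal(sum(s$table$count), 100)
  expect_equal(s$table$count[s$table$class == "O_H...H_C"], 50)
  expect_equal(sum(vapply(s$histograms, sum, numeric(1))), 100)

  ## methanol-like run: the hydrogen-bonded class has the most negative
  ## median high-level interaction energy among the populated classes
  sysM <- generateToySystem("toy_methanol", nMolecules = 16, density = 0.85,
                            seed = 91)
  med <- forceFieldBackend(ffParameters(rCut = 4.6), name = "med")
  hi <- forceFieldBackend(ffParameters(rCut = 4.6), epsilonScale = 1.05,
                          name = "hi")
  model <- compositeEnergyModel(med, hi, rCutDimer = 4.0)
  run <- runNestedChain(sysM$config, model, med,
                        nestedSpec(periodP = 25L, TTarget = 300,
                                   ensemble = "NVT", seed = 17),
                        nOuter = 40L, recordGeometry = TRUE)
  entries <- extractPairRecords(run, model, material = "toy_methanol")
  sm <- summarizeLibrary(entries)
  tab <- sm$table[sm$table$count >= 10, ]
  hb <- tab[tab$class == "O_H...H_O", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$medianEIntHigh, min(tab$medianEIntHigh))
})
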