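#' @include mbe.R
NULL

#' Construct a Monte Carlo move set
#'
#' @param maxTranslation Maximum center-of-mass displacement per axis, A.
#' @param maxRotation Maximum rotation angle, rad.
#' @param maxLnVolumeStep Maximum |delta ln V| per volume move.
#' @param weights Named attempt weights over `translate`, `rotate`,
#'   `conformer`, `volume`; normalized to sum to 1.
#' @return A [MoveSet].
#' @export
moveSet <- function(maxTranslation = 0.25, maxRotation = 0.35,
                    maxLnVolumeStep = 0.02,
                    weights = c(translate = 0.45, rotate = 0.45,
                                conformer = 0.05, volume = 0.05)) {
  full <- c(translate = 0, rotate = 0, conformer = 0, volume = 0)
  full[names(weights)] <- weights
  full <- full / sum(full)
  methods::new("MoveSet", maxTranslation = maxTranslation,
               maxRotation = maxRotation, maxLnVolumeStep = maxLnVolumeStep,
               weights = full)
}

#' Default move set for an ensemble
#' @param ensemble `"NVT"` or `"NpT"`.
#' @param hasConformers Any template with more than one conformer?
#' @return A [MoveSet] with volume moves only in NpT and conformer swaps
#'   only when the system has a conformer pool.
#' @export
defaultMoveSet <- function(ensemble = "NVT", hasConformers = FALSE) {
  w <- c(translate = 0.475, rotate = 0.475,
         conformer = if (hasConformers) 0.02 else 0,
         volume = if (ensemble == "NpT") 0.03 else 0)
  moveSet(weights = w / sum(w))
}

## map a backend onto the incremental FF kernel
.asKernelBackend <- function(backend) {
  if (methods::is(backend, "ForceFieldBackend")) return(backend)
  if (methods::is(backend, "ZeroBackend"))
    return(forceFieldBackend(epsilonScale = 0, chargeScale = 0,
                             name = backend@name))
  stop("the inner MC kernel requires a ForceFieldBackend or ZeroBackend ",
       "as its generating potential; got ", class(backend))
}

## ---------------------------------------------------------------------------
## Kernel state: a mutable environment with flat coordinates and an
## incrementally tracked force-field energy.
## ---------------------------------------------------------------------------
.buildKernelState <- function(config, ffb) {
  st <- siteTable(config)
  topo <- pairTopology(st, ffb@params, ffb@epsilonScale, ffb@chargeScale)
  n <- nMolecules(config)
  molRows <- vector("list", n)
  if (length(topo$pi)) {
    mi <- st$mol[topo$pi]; mj <- st$mol[topo$pj]
    for (i in seq_len(n)) {
      r <- which(mi == i | mj == i)
      molRows[[i]] <- list(pi = topo$pi[r], pj = topo$pj[r],
                           sigma = topo$sigma[r], epsilon = topo$epsilon[r],
                           qq = topo$qq[r])
    }
  } else {
    for (i in seq_len(n)) molRows[[i]] <- list(pi = integer(0), pj = integer(0),
                                               sigma = numeric(0),
                                               epsilon = numeric(0),
                                               qq = numeric(0))
  }
  molSiteIdx <- lapply(seq_len(n), function(i) which(st$mol == i))
  tailNum <- if (ffb@params@tailCorrection)
    .ljTailCorrection(st, ffb@params, 1, ffb@epsilonScale) else 0
  env <- new.env(parent = emptyenv())
  env$L <- config@box@edges
  env$com <- config@com
  env$quat <- config@quat
  env$conformer <- config@conformer
  env$coords <- st$coords
  env$st <- st
  env$topo <- topo
  env$molRows <- molRows
  env$molSiteIdx <- molSiteIdx
  env$templates <- config@templates
  env$templateId <- config@templateId
  env$params <- ffb@params
  env$tailNum <- tailNum
  env$n <- n
  env$nConf <- vapply(config@templates[config@templateId],
                      function(t) length(t@conformers), integer(1))
  env$eLow <- .kernelFullEnergy(env)
  env
}

.kernelFullEnergy <- function(state, coords = state$coords, L = state$L) {
  res <- .pairEnergySum(coords, state$topo, state$params, L)
  if (res$overlap) return(Inf)
  res$energy + state$tailNum / prod(L)
}

## energy of molecule i with the rest, for given full coordinate matrix
.molPartialEnergy <- function(state, i, coords, L = state$L) {
  res <- .pairEnergySum(coords, state$molRows[[i]], state$params, L)
  if (res$overlap) return(Inf)
  res$energy
}

## lab-frame site coordinates of molecule i from quaternion + com
.molCoords <- function(state, i, q = state$quat[i, ], com = state$com[i, ],
                       conformer = state$conformer[i]) {
  tpl <- state$templates[[state$templateId[i]]]
  g <- tpl@conformers[[conformer]]
  sweep(g %*% t(quatToMatrix(q)), 2, com, "+")
}

## deep-copyable snapshot of the mutable kernel state
.kernelSnapshot <- function(state) {
  list(L = state$L, com = state$com, quat = state$quat,
       conformer = state$conformer, coords = state$coords, eLow = state$eLow)
}

.kernelRestore <- function(state, snap) {
  state$L <- snap$L; state$com <- snap$com; state$quat <- snap$quat
  state$conformer <- snap$conformer; state$coords <- snap$coords
  state$eLow <- snap$eLow
  invisible(state)
}

## configuration view of the kernel state
.kernelConfiguration <- function(state) {
  configuration(box3(state$L), state$templates, state$templateId,
                state$com, state$quat, state$conformer)
}

#' Metropolis acceptance probability for a single move
#'
#' Standard Metropolis rule; NpT volume moves proposed uniformly in ln V are
#' accepted with `min(1, exp(-(dU + p dV)/RT + (N + 1) dlnV))`.
#'
#' @param dU Energy change, kJ/mol.
#' @param T Temperature, K.
#' @param p Pressure, bar (volume moves).
#' @param dV Volume change, Angstrom^3.
#' @param dLnV Log-volume change.
#' @param nMolecules Molecule count N (volume moves).
#' @return Acceptance probability in [0, 1].
#' @export
metropolisProbability <- function(dU, T, p = 0, dV = 0, dLnV = 0,
                                  nMolecules = 0) {
  if (!is.finite(dU)) return(0)
  beta <- 1 / (.const$R * T)
  lnA <- -beta * (dU + p * dV * .const$barA3) + (nMolecules + 1) * dLnV
  min(1, exp(lnA))
}

## One attempted move.  Updates `state` in place; returns a record.
## streams: RNG substream environment with "moveSelect", "moves", "accept".
.attemptMove <- function(state, moveset, T, p, ensemble, streams) {
  w <- moveset@weights
  type <- withStream(streams, "moveSelect",
                     sample(names(w), 1L, prob = w))
  accepted <- FALSE; dU <- 0; dV <- 0
  if (type == "volume") {
    dLnV <- withStream(streams, "moves",
                       stats::runif(1, -moveset@maxLnVolumeStep,
                                    moveset@maxLnVolumeStep))
    s <- exp(dLnV / 3)
    newL <- state$L * s
    V0 <- prod(state$L); V1 <- prod(newL)
    if (min(newL) / 2 < state$params@rCut) {
      ## shrinking below the cutoff's validity: reject outright
      prob <- 0; u <- withStream(streams, "accept", stats::runif(1))
    } else {
      shift <- (s - 1) * state$com[state$st$mol, , drop = FALSE]
      newCoords <- state$coords + shift
      eNew <- .kernelFullEnergy(state, newCoords, newL)
      dU <- eNew - state$eLow
      dV <- V1 - V0
      prob <- metropolisProbability(dU, T, p, dV, dLnV, state$n)
      u <- withStream(streams, "accept", stats::runif(1))
      if (u < prob) {
        state$L <- newL; state$com <- state$com * s
        state$coords <- newCoords; state$eLow <- eNew
        accepted <- TRUE
      }
    }
  } else if (type == "conformer") {
    i <- withStream(streams, "moves", sample.int(state$n, 1L))
    draw <- withStream(streams, "moves", stats::runif(1))
    if (state$nConf[i] > 1L) {
      others <- setdiff(seq_len(state$nConf[i]), state$conformer[i])
      newConf <- others[ceiling(draw * length(others))]
      newXyz <- .molCoords(state, i, conformer = newConf)
      cs <- state$coords
      idx <- state$molSiteIdx[[i]]
      eOld <- .molPartialEnergy(state, i, cs)
      cs[idx, ] <- newXyz
      eNew <- .molPartialEnergy(state, i, cs)
      dU <- eNew - eOld
      prob <- metropolisProbability(dU, T)
      u <- withStream(streams, "accept", stats::runif(1))
      if (u < prob) {
        state$conformer[i] <- newConf
        state$coords <- cs
        state$eLow <- state$eLow + dU
        accepted <- TRUE
      }
    } else {
      u <- withStream(streams, "accept", stats::runif(1)) # keep draws aligned
    }
  } else {
    i <- withStream(streams, "moveSelect", sample.int(state$n, 1L))
    if (type == "translate") {
      dr <- withStream(streams, "moves",
                       stats::runif(3, -moveset@maxTranslation,
                                    moveset@maxTranslation))
      newCom <- state$com[i, ] + dr
      newXyz <- sweep(state$coords[state$molSiteIdx[[i]], , drop = FALSE],
                      2, dr, "+")
    } else { # rotate
      u3 <- withStream(streams, "moves", stats::runif(3))
      axis <- c(cos(2 * pi * u3[2]) * sqrt(1 - (2 * u3[1] - 1)^2),
                sin(2 * pi * u3[2]) * sqrt(1 - (2 * u3[1] - 1)^2),
                2 * u3[1] - 1)
      ang <- (2 * u3[3] - 1) * moveset@maxRotation
      newQ <- quatNormalize(quatMultiply(quatFromAxisAngle(axis, ang),
                                         state$quat[i, ]))
      newCom <- state$com[i, ]
      newXyz <- .molCoords(state, i, q = newQ)
    }
    cs <- state$coords
    idx <- state$molSiteIdx[[i]]
    eOld <- .molPartialEnergy(state, i, cs)
    cs[idx, ] <- newXyz
    eNew <- .molPartialEnergy(state, i, cs)
    dU <- eNew - eOld
    if (!is.finite(dU)) {
      warning("energy overflow in trial move; treated as rejection")
      dU <- Inf
    }
    prob <- metropolisProbability(dU, T)
    u <- withStream(streams, "accept", stats::runif(1))
    if (is.finite(dU) && u < prob) {
      if (type == "translate") state$com[i, ] <- newCom
      else state$quat[i, ] <- newQ
      state$coords <- cs
      state$eLow <- state$eLow + dU
      accepted <- TRUE
    }
  }
  list(type = type, accepted = accepted, dU = dU, dV = dV)
}

## run nAttempts moves; returns per-type attempt/accept counts
.runMoves <- function(state, nAttempts, moveset, T, p, ensemble, streams,
                      stats = NULL) {
  if (is.null(stats))
    stats <- list(attempt = c(translate = 0, rotate = 0, conformer = 0,
                              volume = 0),
                  accept = c(translate = 0, rotate = 0, conformer = 0,
                             volume = 0))
  for (k in seq_len(nAttempts)) {
    rec <- .attemptMove(state, moveset, T, p, ensemble, streams)
    stats$attempt[rec$type] <- stats$attempt[rec$type] + 1
    if (rec$accepted) stats$accept[rec$type] <- stats$accept[rec$type] + 1
  }
  stats
}

.moveStatsFrame <- function(stats) {
  data.frame(move = names(stats$attempt),
             attempts = as.numeric(stats$attempt),
             accepted = as.numeric(stats$accept),
             rate = ifelse(stats$attempt > 0,
                           stats$accept / pmax(stats$attempt, 1), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plain single-potential Metropolis sampling
#'
#' Reference sampler: ordinary Metropolis on one potential at fixed (T, p).
#' Serves as the exactness oracle for the nested chain.
#'
#' @param config Starting [Configuration].
#' @param backend Generating potential ([ForceFieldBackend] or
#'   [ZeroBackend]).
#' @param T Temperature, K.
#' @param p Pressure, bar (NpT only).
#' @param ensemble `"NVT"` or `"NpT"`.
#' @param nMoves Attempted moves.
#' @param moveset A [MoveSet]; default [defaultMoveSet()].
#' @param sampleEvery Record observables every this many attempts.
#' @param seed Master seed.
#' @param burnInFraction Leading fraction of samples marked as burn-in.
#' @return A [MetropolisRun] with `density` (g/cm^3), `energy` (kJ/mol) and
#'   `volume` (A^3) series.
#' @export
runMetropolis <- function(config, backend, T, p = 1, ensemble = c("NVT", "NpT"),
                          nMoves = 1000L, moveset = NULL, sampleEvery = 10L,
                          seed = 1L, burnInFraction = 0.1) {
  ensemble <- match.arg(ensemble)
  ffb <- .asKernelBackend(backend)
  if (is.null(moveset))
    moveset <- defaultMoveSet(ensemble,
                              any(vapply(config@templates,
                                         function(t) length(t@conformers) > 1,
                                         logical(1))))
  state <- .buildKernelState(config, ffb)
  streams <- makeRngStreams(seed, c("moveSelect", "moves", "accept"))
  molarMassTotal <- sum(vapply(config@templates[config@templateId],
                               function(t) t@molarMass, numeric(1)))
  nSamples <- nMoves %/% sampleEvery
  dens <- ener <- vol <- numeric(nSamples)
  traj <- vector("list", nSamples)
  stats <- NULL
  for (s in seq_len(nSamples)) {
    stats <- .runMoves(state, sampleEvery, moveset, T, p, ensemble, streams,
                       stats)
    V <- prod(state$L)
    dens[s] <- molarMassTotal / (.const$avogadroGcm3 * V)
    ener[s] <- state$eLow
    vol[s] <- V
    traj[[s]] <- list(com = state$com, quat = state$quat,
                      conformer = state$conformer, edges = state$L)
  }
  burn <- as.integer(floor(burnInFraction * nSamples))
  mk <- function(v, u) methods::new("ScalarSeries", values = v, units = u,
                                    burnIn = burn)
  methods::new("MetropolisRun",
               series = list(density = mk(dens, "g/cm^3"),
                             energy = mk(ener, "kJ/mol"),
                             volume = mk(vol, "A^3")),
               trajectory = traj, moveStats = .moveStatsFrame(stats))
}
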