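#' @include mc-kernel.R
NULL

#' Construct a nested-chain specification
#'
#' @param periodP Attempted inner moves per outer proposal (default 100).
#' @param TTarget Target temperature, K.
#' @param pTarget Target pressure, bar.
#' @param TGen,pGen Generating conditions of the inner chain; default the
#'   target conditions.
#' @param ensemble `"NVT"` or `"NpT"`.
#' @param adapt Enable adaptive scaling of `TGen`?
#' @param acceptanceWindow Outer-acceptance window the controller steers
#'   into; default `c(0.75, 0.90)`.
#' @param adaptKappa Controller gain.
#' @param adaptWindowSize Outer proposals per adaptation window.
#' @param adaptMaxCycles Hard cap on adaptation windows.
#' @param seed Master seed.
#' @return A [NestedSpec].
#' @export
nestedSpec <- function(periodP = 100L, TTarget = 300, pTarget = 1,
                       TGen = TTarget, pGen = pTarget,
                       ensemble = c("NVT", "NpT"), adapt = FALSE,
                       acceptanceWindow = c(0.75, 0.90), adaptKappa = 0.5,
                       adaptWindowSize = 50L, adaptMaxCycles = 40L,
                       seed = 1L) {
  ensemble <- match.arg(ensemble)
  methods::new("NestedSpec", periodP = as.integer(periodP), TTarget = TTarget,
               pTarget = pTarget, TGen = TGen, pGen = pGen,
               ensemble = ensemble, adapt = adapt,
               acceptanceWindow = acceptanceWindow, adaptKappa = adaptKappa,
               adaptWindowSize = as.integer(adaptWindowSize),
               adaptMaxCycles = as.integer(adaptMaxCycles),
               seed = as.integer(seed))
}

#' Outer-loop acceptance probability of the nested chain
#'
#' Detailed-balance correction for a sequence of inner moves equilibrated
#' under the low-level potential at the generating conditions
#' `(TGen, pGen)`, assessed against the high-level (composite) potential at
#' the target conditions:
#' `min(1, exp(-(dUHigh + pTarget dV)/(R TTarget) + (dULow + pGen dV)/(R TGen)))`.
#' When high and low potentials and conditions coincide the exponent
#' telescopes to zero and every outer proposal is accepted.
#'
#' @param dUHigh High-level (composite) energy change over the inner
#'   sequence, kJ/mol.
#' @param dULow Low-level energy change over the inner sequence, kJ/mol.
#' @param dV Volume change over the inner sequence, Angstrom^3.
#' @param spec A [NestedSpec].
#' @return Acceptance probability in [0, 1].
#' @export
outerAcceptProb <- function(dUHigh, dULow, dV = 0, spec) {
  R <- .const$R
  pT <- if (spec@ensemble == "NpT") spec@pTarget else 0
  pG <- if (spec@ensemble == "NpT") spec@pGen else 0
  lnA <- -(dUHigh + pT * dV * .const$barA3) / (R * spec@TTarget) +
    (dULow + pG * dV * .const$barA3) / (R * spec@TGen)
  if (!is.finite(lnA)) return(0)
  min(1, exp(lnA))
}

#' One adaptation update of the generating temperature
#'
#' Multiplicative controller: if the observed outer acceptance `aObs` lies
#' inside the acceptance window the spec is unchanged; otherwise
#' `TGen <- TGen * (1 + kappa * (aObs - aMid))` with `aMid` the window
#' midpoint, clipped to `[0.5, 2] * TTarget`.
#'
#' @param aObs Observed outer acceptance rate over the last window.
#' @param spec A [NestedSpec].
#' @return The updated [NestedSpec].
#' @export
adaptGeneratingConditions <- function(aObs, spec) {
  w <- spec@acceptanceWindow
  if (aObs > w[1] && aObs < w[2]) return(spec)
  aMid <- mean(w)
  TGen <- spec@TGen * (1 + spec@adaptKappa * (aObs - aMid))
  spec@TGen <- min(max(TGen, 0.5 * spec@TTarget), 2 * spec@TTarget)
  spec
}

#' Run one inner generating sequence
#'
#' Performs exactly `spec@periodP` attempted low-level moves at the
#' generating conditions, mutating the kernel state, and reports the exact
#' low-level energy and volume changes relative to the sequence start.
#'
#' @param state Kernel state environment (internal; see [runNestedChain()]).
#' @param spec A [NestedSpec].
#' @param moveset A [MoveSet].
#' @param streams RNG substream environment.
#' @param stats Optional running move statistics.
#' @return List with `dULow`, `dV`, `stats`.
#' @keywords internal
runInnerSequence <- function(state, spec, moveset, streams, stats = NULL) {
  e0 <- state$eLow
  V0 <- prod(state$L)
  stats <- .runMoves(state, spec@periodP, moveset, spec@TGen, spec@pGen,
                     spec@ensemble, streams, stats)
  list(dULow = state$eLow - e0, dV = prod(state$L) - V0, stats = stats)
}

## shared driver for fresh runs and checkpoint resumes
.nestedDrive <- function(state, model, spec, moveset, streams, nOuter,
                         adapt, stats, recordGeometry, startStep = 0L) {
  molarMassTotal <- sum(vapply(state$templates[state$templateId],
                               function(t) t@molarMass, numeric(1)))
  state$eLow <- .kernelFullEnergy(state)
  compCurr <- compositeEnergy(.kernelConfiguration(state), model,
                              recordGeometry)
  dens <- eHigh <- eLowS <- vol <- tGenS <- numeric(nOuter)
  accepted <- logical(nOuter)
  traj <- vector("list", nOuter)
  dimerRows <- vector("list", nOuter)
  dimerGeoms <- if (recordGeometry) vector("list", nOuter) else NULL
  for (step in seq_len(nOuter)) {
    pre <- .kernelSnapshot(state)
    compPre <- compCurr
    inner <- runInnerSequence(state, spec, moveset, streams, stats)
    stats <- inner$stats
    compCand <- compositeEnergy(.kernelConfiguration(state), model,
                                recordGeometry)
    dUHigh <- compCand$total - compPre$total
    prob <- outerAcceptProb(dUHigh, inner$dULow, inner$dV, spec)
    u <- withStream(streams, "outer", stats::runif(1))
    if (u < prob) {
      compCurr <- compCand
      accepted[step] <- TRUE
    } else {
      .kernelRestore(state, pre)
      compCurr <- compPre
    }
    ## adaptation bookkeeping (updates apply between outer proposals)
    adapt$buffer <- c(adapt$buffer, accepted[step])
    if (spec@adapt && length(adapt$buffer) >= spec@adaptWindowSize) {
      aObs <- mean(adapt$buffer)
      adapt$buffer <- logical(0)
      adapt$cycles <- adapt$cycles + 1L
      globalStep <- startStep + step
      w <- spec@acceptanceWindow
      inWin <- aObs > w[1] && aObs < w[2]
      if (!adapt$frozen) {
        if (inWin) {
          adapt$inWindow <- adapt$inWindow + 1L
          if (adapt$inWindow >= 2L) {
            adapt$frozen <- TRUE; adapt$frozenAt <- globalStep
          }
        } else {
          adapt$inWindow <- 0L
          spec <- adaptGeneratingConditions(aObs, spec)
        }
        if (!adapt$frozen && adapt$cycles >= spec@adaptMaxCycles) {
          adapt$frozen <- TRUE; adapt$frozenAt <- globalStep
          adapt$cappedOut <- TRUE
        }
      }
      adapt$log[[length(adapt$log) + 1L]] <-
        data.frame(window = adapt$cycles, outerStep = globalStep,
                   acceptance = aObs, TGen = spec@TGen,
                   frozen = adapt$frozen)
    }
    V <- prod(state$L)
    dens[step] <- molarMassTotal / (.const$avogadroGcm3 * V)
    eHigh[step] <- compCurr$total
    eLowS[step] <- state$eLow
    vol[step] <- V
    tGenS[step] <- spec@TGen
    traj[[step]] <- list(com = state$com, quat = state$quat,
                         conformer = state$conformer, edges = state$L)
    dr <- compCurr$dimers
    if (nrow(dr)) dr$snapshot <- startStep + step
    dimerRows[[step]] <- dr
    if (recordGeometry) dimerGeoms[[step]] <- compCurr$geometries
  }
  list(spec = spec, stats = stats, density = dens, eHigh = eHigh,
       eLow = eLowS, volume = vol, tGen = tGenS, accepted = accepted,
       trajectory = traj, dimerRows = dimerRows, dimerGeoms = dimerGeoms)
}

.assembleNestedRun <- function(drv, state, streams, adapt, spec, moveset,
                               model, startStep = 0L) {
  nOuter <- length(drv$accepted)
  burn <- if (spec@adapt && !is.na(adapt$frozenAt) && startStep == 0L) {
    frozenLocal <- min(adapt$frozenAt, nOuter)
    as.integer(frozenLocal + floor(0.1 * (nOuter - frozenLocal)))
  } else as.integer(floor(0.1 * nOuter))
  mk <- function(v, u) methods::new("ScalarSeries", values = v, units = u,
                                    burnIn = min(burn, length(v)))
  records <- do.call(rbind, drv$dimerRows)
  if (is.null(records))
    records <- data.frame(i = integer(0), j = integer(0),
                          contactDistance = numeric(0), labelI = character(0),
                          labelJ = character(0), contactClass = character(0),
                          eIntHigh = numeric(0), eIntMedium = numeric(0),
                          snapshot = integer(0))
  geoms <- if (!is.null(drv$dimerGeoms)) do.call(c, drv$dimerGeoms) else list()
  adaptLog <- if (length(adapt$log)) do.call(rbind, adapt$log) else
    data.frame(window = integer(0), outerStep = integer(0),
               acceptance = numeric(0), TGen = numeric(0), frozen = logical(0))
  checkpoint <- list(
    com = state$com, quat = state$quat, conformer = state$conformer,
    edges = state$L, templateId = state$templateId,
    templates = state$templates, spec = drv$spec, moveset = moveset,
    streams = streamsToList(streams),
    adapt = list(buffer = adapt$buffer, cycles = adapt$cycles,
                 inWindow = adapt$inWindow, frozen = adapt$frozen,
                 frozenAt = adapt$frozenAt,
                 cappedOut = isTRUE(adapt$cappedOut), log = adapt$log),
    outerStep = startStep + nOuter,
    stats = drv$stats)
  methods::new("NestedRun",
               series = list(density = mk(drv$density, "g/cm^3"),
                             energyHigh = mk(drv$eHigh, "kJ/mol"),
                             energyLow = mk(drv$eLow, "kJ/mol"),
                             volume = mk(drv$volume, "A^3"),
                             TGen = mk(drv$tGen, "K")),
               accepted = drv$accepted, trajectory = drv$trajectory,
               dimerRecords = records, dimerGeometries = geoms %||% list(),
               adaptation = adaptLog,
               frozenAt = as.integer(adapt$frozenAt),
               spec = drv$spec, moveStats = .moveStatsFrame(drv$stats),
               checkpoint = checkpoint)
}

#' Run the nested multipotential Monte Carlo chain
#'
#' Alternates inner generating sequences (`spec@periodP` attempted moves on
#' the low-level potential at `(TGen, pGen)`), composite many-body-expansion
#' energy evaluation of the resulting candidate, and the outer
#' accept/reject step at the target conditions.  On rejection the whole
#' inner sequence is discarded and the pre-sequence state (energy caches
#' included) is restored.  Streams density, composite energy and volume per
#' outer proposal, and emits the two-level dimer interaction records of
#' every snapshot's composite-energy breakdown.  Fully reproducible per
#' seed.
#'
#' @param config Starting [Configuration].
#' @param model A [CompositeEnergyModel] (the high-level assessment).
#' @param lowBackend Generating potential ([ForceFieldBackend] or
#'   [ZeroBackend]).
#' @param spec A [NestedSpec].
#' @param nOuter Number of outer proposals.
#' @param moveset A [MoveSet]; default [defaultMoveSet()] for the ensemble.
#' @param recordGeometry Keep dimer fragment geometries (needed to build a
#'   pair library with stored coordinates)?
#' @return A [NestedRun].
#' @export
runNestedChain <- function(config, model, lowBackend = forceFieldBackend(),
                           spec = nestedSpec(), nOuter = 100L, moveset = NULL,
                           recordGeometry = FALSE) {
  ffb <- .asKernelBackend(lowBackend)
  if (is.null(moveset))
    moveset <- defaultMoveSet(spec@ensemble,
                              any(vapply(config@templates,
                                         function(t) length(t@conformers) > 1,
                                         logical(1))))
  state <- .buildKernelState(config, ffb)
  streams <- makeRngStreams(spec@seed,
                            c("moveSelect", "moves", "accept", "outer"))
  adapt <- new.env(parent = emptyenv())
  adapt$buffer <- logical(0); adapt$cycles <- 0L; adapt$inWindow <- 0L
  adapt$frozen <- !spec@adapt; adapt$frozenAt <- NA_integer_
  adapt$log <- list()
  drv <- .nestedDrive(state, model, spec, moveset, streams, nOuter, adapt,
                      NULL, recordGeometry)
  .assembleNestedRun(drv, state, streams, adapt, drv$spec, moveset, model)
}

#' Resume a nested chain from a checkpoint
#'
#' Continues the chain saved in a [NestedRun]'s `checkpoint` slot; for a
#' fixed seed the continuation is identical to having run the longer chain
#' in one piece.
#'
#' @param checkpoint The `checkpoint` list of a [NestedRun].
#' @param model The [CompositeEnergyModel] used for the original run.
#' @param lowBackend The generating potential used for the original run.
#' @param nOuter Additional outer proposals.
#' @param recordGeometry Keep dimer fragment geometries?
#' @return A [NestedRun] covering the continuation segment.
#' @export
resumeNestedChain <- function(checkpoint, model, lowBackend, nOuter,
                              recordGeometry = FALSE) {
  spec <- checkpoint$spec
  config <- configuration(box3(checkpoint$edges), checkpoint$templates,
                          checkpoint$templateId, checkpoint$com,
                          checkpoint$quat, checkpoint$conformer)
  state <- .buildKernelState(config, .asKernelBackend(lowBackend))
  streams <- streamsFromList(checkpoint$streams)
  adapt <- new.env(parent = emptyenv())
  for (n in names(checkpoint$adapt)) assign(n, checkpoint$adapt[[n]],
                                            envir = adapt)
  drv <- .nestedDrive(state, model, spec, checkpoint$moveset, streams, nOuter,
                      adapt, checkpoint$stats, recordGeometry,
                      startStep = checkpoint$outerStep)
  .assembleNestedRun(drv, state, streams, adapt, drv$spec,
                     checkpoint$moveset, model,
                     startStep = checkpoint$outerStep)
}

#' Outer acceptance rate of a nested run
#'
#' @param run A [NestedRun].
#' @param window `"all"`, `"postFreeze"` (proposals after the adaptation
#'   controller froze), or `"last"` combined with `n`.
#' @param n Number of trailing proposals for `window = "last"`.
#' @return Fraction of outer proposals accepted.
#' @export
outerAcceptanceRate <- function(run, window = c("all", "postFreeze", "last"),
                                n = 500L) {
  window <- match.arg(window)
  acc <- run@accepted
  if (window == "postFreeze") {
    if (is.na(run@frozenAt)) stop("adaptation never froze in this run")
    acc <- acc[seq_along(acc) > run@frozenAt]
  } else if (window == "last") {
    acc <- utils::tail(acc, n)
  }
  mean(acc)
}
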