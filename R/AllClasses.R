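#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Geometry / state classes
## ---------------------------------------------------------------------------

#' Rigid molecule template
#'
#' A molecule species: ordered interaction sites (element, site label, partial
#' charge, Lennard-Jones sigma/epsilon, mass), bond topology, and one or more
#' alternative rigid body-frame geometries (the conformer pool).  Conformer 1
#' is the reference geometry.  All conformer geometries are stored centered on
#' their center of mass, so a [MoleculeInstance]'s `com` is the molecular
#' center of mass.
#'
#' @slot name Species name.
#' @slot sites data.frame with columns `element`, `label`, `charge` (e),
#'   `sigma` (Angstrom), `epsilon` (kJ/mol), `mass` (g/mol).
#' @slot bonds Integer matrix, two columns of site indices.
#' @slot conformers List of n_sites x 3 body-frame coordinate matrices (A).
#' @slot molarMass Molar mass, g/mol.
#' @slot netCharge Declared net charge, e.
#' @export
setClass("MoleculeTemplate",
  representation(name = "character", sites = "data.frame", bonds = "matrix",
                 conformers = "list", molarMass = "numeric",
                 netCharge = "numeric"))

setValidity("MoleculeTemplate", function(object) {
  s <- object@sites
  msgs <- character()
  need <- c("element", "label", "charge", "sigma", "epsilon", "mass")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  if (!all(isValidElement(s$element)))
    msgs <- c(msgs, "invalid element symbol in sites")
  if (any(s$sigma < 0) || any(s$epsilon < 0))
    msgs <- c(msgs, "lj sigma and epsilon must be >= 0")
  if (abs(sum(s$mass) - object@molarMass) > 1e-6)
    msgs <- c(msgs, "molarMass must equal the sum of site masses (1e-6)")
  if (abs(sum(s$charge) - object@netCharge) > 1e-8)
    msgs <- c(msgs, "site charges must sum to the declared net charge")
  if (length(object@conformers) < 1)
    msgs <- c(msgs, "at least one conformer geometry required")
  for (k in seq_along(object@conformers)) {
    g <- object@conformers[[k]]
    if (!is.matrix(g) || nrow(g) != nrow(s) || ncol(g) != 3) {
      msgs <- c(msgs, sprintf("conformer %d must be a %d x 3 matrix", k, nrow(s)))
      next
    }
    com <- colSums(g * s$mass) / sum(s$mass)
    if (max(abs(com)) > 1e-8)
      msgs <- c(msgs, sprintf("conformer %d is not center-of-mass centered", k))
  }
  if (nrow(object@bonds) > 0 &&
      (any(object@bonds < 1) || any(object@bonds > nrow(s))))
    msgs <- c(msgs, "bond indices out of range")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Orthorhombic periodic box
#'
#' @slot edges Numeric length-3 edge lengths, Angstrom.
#' @export
setClass("Box", representation(edges = "numeric"))

setValidity("Box", function(object) {
  if (length(object@edges) != 3) return("edges must have length 3")
  if (any(!is.finite(object@edges)) || any(object@edges <= 0))
    return("all box edges must be positive and finite")
  TRUE
})

#' Markov-chain state: a periodic box of rigid molecule instances
#'
#' The state sampled by the Monte Carlo chains: an orthorhombic [Box], a set
#' of rigid-molecule instances (center of mass, unit-quaternion orientation,
#' conformer index, template id), the template table, and optional cached
#' low-level / high-level energies.
#'
#' @slot box A [Box].
#' @slot templates Named list of [MoleculeTemplate]s.
#' @slot templateId Character vector: template name per molecule.
#' @slot com N x 3 matrix of centers of mass, Angstrom.
#' @slot quat N x 4 matrix of unit quaternions (w, x, y, z).
#' @slot conformer Integer vector of conformer indices.
#' @slot cachedEnergyLow,cachedEnergyHigh Cached energies in kJ/mol
#'   (`NA_real_` when absent).
#' @export
setClass("Configuration",
  representation(box = "Box", templates = "list", templateId = "character",
                 com = "matrix", quat = "matrix", conformer = "integer",
                 cachedEnergyLow = "numeric", cachedEnergyHigh = "numeric"))

setValidity("Configuration", function(object) {
  n <- length(object@templateId)
  msgs <- character()
  if (nrow(object@com) != n || ncol(object@com) != 3)
    msgs <- c(msgs, "com must be n x 3")
  if (nrow(object@quat) != n || ncol(object@quat) != 4)
    msgs <- c(msgs, "quat must be n x 4")
  if (length(object@conformer) != n)
    msgs <- c(msgs, "conformer must have one entry per molecule")
  if (!all(object@templateId %in% names(object@templates)))
    msgs <- c(msgs, "unknown template id")
  if (n > 0) {
    norms <- sqrt(rowSums(object@quat^2))
    if (max(abs(norms - 1)) > 1e-10)
      msgs <- c(msgs, "orientation quaternions must be unit norm (1e-10)")
    nconf <- vapply(object@templates[object@templateId],
                    function(t) length(t@conformers), integer(1))
    if (any(object@conformer < 1L) || any(object@conformer > nconf))
      msgs <- c(msgs, "conformer index out of range")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---------------------------------------------------------------------------
## Potentials
## ---------------------------------------------------------------------------

#' Force-field parameters
#'
#' Parameters of the built-in classical force field: truncated 12-6
#' Lennard-Jones with optional analytic tail correction, plus damped
#' shifted-force (Wolf-type) Coulomb electrostatics that go smoothly to zero
#' at the cutoff.
#'
#' @slot combiningRule `"lorentz_berthelot"` or `"geometric"`.
#' @slot rCut Pair cutoff, Angstrom; must not exceed half the smallest box
#'   edge at evaluation time.
#' @slot damping Coulomb damping parameter, 1/Angstrom.
#' @slot tailCorrection Apply the analytic LJ tail correction (homogeneous
#'   liquid boxes only)?
#' @export
setClass("FFParameters",
  representation(combiningRule = "character", rCut = "numeric",
                 damping = "numeric", tailCorrection = "logical"))

setValidity("FFParameters", function(object) {
  if (!object@combiningRule %in% c("lorentz_berthelot", "geometric"))
    return("combiningRule must be 'lorentz_berthelot' or 'geometric'")
  if (object@rCut <= 0) return("rCut must be positive")
  if (object@damping < 0) return("damping must be >= 0")
  TRUE
})

#' Energy backend (virtual)
#'
#' Contract for energy engines: a backend may evaluate full periodic systems,
#' and/or open-boundary fragments (monomers, dimers, ...).  Fragment energies
#' are pure functions of geometry and symmetric under molecule reordering.
#'
#' @slot name Backend name used in provenance records.
#' @export
setClass("EnergyBackend", representation("VIRTUAL", name = "character"))

#' Built-in classical force-field backend
#'
#' Lennard-Jones + damped shifted-force Coulomb.  `epsilonScale` and
#' `chargeScale` uniformly rescale the template LJ well depths and partial
#' charges; a scaled copy of the force field serves as a surrogate
#' higher-level theory in tests and desk-scale experiments.
#'
#' @slot params [FFParameters].
#' @slot epsilonScale Multiplier on every LJ epsilon.
#' @slot chargeScale Multiplier on every partial charge.
#' @export
setClass("ForceFieldBackend", contains = "EnergyBackend",
  representation(params = "FFParameters", epsilonScale = "numeric",
                 chargeScale = "numeric"))

#' Zero (non-interacting) backend
#'
#' Returns 0 for every evaluation; the ideal-gas reference engine.
#' @export
setClass("ZeroBackend", contains = "EnergyBackend")

#' Function-valued backend
#'
#' Wraps arbitrary R functions as an energy backend; used to build surrogate
#' theories and test oracles.
#'
#' @slot fullFn `function(config) -> kJ/mol` or NULL if unsupported.
#' @slot fragmentFn `function(fragment) -> kJ/mol` or NULL if unsupported.
#' @export
setClass("FunctionBackend", contains = "EnergyBackend",
  representation(fullFn = "ANY", fragmentFn = "ANY"))

#' External energy-engine adapter
#'
#' Generic command-line contract: the fragment is written as a plain XYZ file,
#' a templated command is run, and one energy is parsed from its standard
#' output with a regular expression.  Results are cached by a geometry hash
#' (coordinates rounded to 1e-6 Angstrom in canonical atom order), so an
#' identical geometry is never re-dispatched.
#'
#' @slot command Command template; `{xyz}` is replaced by the fragment file.
#' @slot energyPattern Regular expression with one capture group matching the
#'   energy in the command's output.
#' @slot workdir Scratch directory for fragment files.
#' @slot timeout Seconds before a dispatch is abandoned.
#' @slot cache Environment mapping geometry hash to energy.
#' @slot dispatchCount Environment counter of actual command launches.
#' @export
setClass("ExternalEngineBackend", contains = "EnergyBackend",
  representation(command = "character", energyPattern = "character",
                 workdir = "character", timeout = "numeric",
                 cache = "environment", dispatchCount = "environment"))

## ---------------------------------------------------------------------------
## Composite many-body-expansion energy
## ---------------------------------------------------------------------------

#' Composite many-body-expansion energy model
#'
#' The two-tier composite bulk energy: a medium-level full-system term plus
#' high-minus-medium pairwise interaction corrections for every proximate
#' dimer (closest intermolecular site-site contact within `rCutDimer`).  The
#' default 4 Angstrom dimer cutoff selects the first solvation shell.
#'
#' @slot medium Medium-level [EnergyBackend] (must support full system and
#'   fragments).
#' @slot high High-level [EnergyBackend] (must support fragments).
#' @slot rCutDimer Dimer contact cutoff, Angstrom (default 4.0).
#' @slot monomerCache Environment caching rigid-monomer energies per
#'   (backend, template, conformer).
#' @slot trimerHook Optional `function(config, trimerCutoff) -> kJ/mol`
#'   three-body correction hook; NULL (pairs only) by default.
#' @export
setClass("CompositeEnergyModel",
  representation(medium = "EnergyBackend", high = "EnergyBackend",
                 rCutDimer = "numeric", monomerCache = "environment",
                 trimerHook = "ANY"))

setValidity("CompositeEnergyModel", function(object) {
  if (object@rCutDimer <= 0) return("rCutDimer must be positive")
  capM <- backendCapabilities(object@medium)
  capH <- backendCapabilities(object@high)
  if (!capM[["full_system"]] || !capM[["dimer"]])
    return("medium backend must support full_system and fragment evaluation")
  if (!capH[["dimer"]]) return("high backend must support fragment evaluation")
  TRUE
})

## ---------------------------------------------------------------------------
## Sampling classes
## ---------------------------------------------------------------------------

#' Monte Carlo move set
#'
#' Maximum step sizes and per-move attempt weights for rigid-body
#' translation, rotation, conformer-swap and (NpT) log-volume moves.
#'
#' @slot maxTranslation Angstrom.
#' @slot maxRotation Radians.
#' @slot maxLnVolumeStep Maximum |delta ln V| per volume move.
#' @slot weights Named numeric weights over
#'   `c("translate", "rotate", "conformer", "volume")`; must sum to 1.
#' @export
setClass("MoveSet",
  representation(maxTranslation = "numeric", maxRotation = "numeric",
                 maxLnVolumeStep = "numeric", weights = "numeric"))

setValidity("MoveSet", function(object) {
  w <- object@weights
  need <- c("translate", "rotate", "conformer", "volume")
  if (!all(need %in% names(w))) return("weights must name all four move types")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) return("weights must be >= 0 and sum to 1")
  sizes <- c(translate = object@maxTranslation, rotate = object@maxRotation,
             volume = object@maxLnVolumeStep)
  for (m in c("translate", "rotate", "volume"))
    if (w[[m]] > 0 && sizes[[m]] <= 0)
      return(sprintf("step size for active move '%s' must be > 0", m))
  TRUE
})

#' Nested-chain specification
#'
#' Conditions of the nested multipotential chain: the target ensemble
#' (`TTarget`, `pTarget`), the generating conditions of the inner low-level
#' chain (`TGen`, `pGen`), the nesting period `periodP` (attempted inner
#' moves per outer proposal), and the adaptive temperature-scaling
#' controller.  The acceptance window defaults to (0.75, 0.90), the outer
#' acceptance regime at which the composite-energy assessment is economical.
#'
#' @slot periodP Inner attempts per outer proposal (>= 1).
#' @slot TTarget,TGen Kelvin.
#' @slot pTarget,pGen bar (ignored in NVT).
#' @slot ensemble `"NVT"` or `"NpT"`.
#' @slot adapt Enable on-the-fly adaptation of `TGen`?
#' @slot acceptanceWindow Numeric length-2 open interval in (0, 1].
#' @slot adaptKappa Controller gain (default 0.5).
#' @slot adaptWindowSize Outer proposals per adaptation window (default 50).
#' @slot adaptMaxCycles Hard cap on adaptation windows before the controller
#'   freezes regardless (default 40).
#' @slot seed Master seed.
#' @export
setClass("NestedSpec",
  representation(periodP = "integer", TTarget = "numeric", pTarget = "numeric",
                 TGen = "numeric", pGen = "numeric", ensemble = "character",
                 adapt = "logical", acceptanceWindow = "numeric",
                 adaptKappa = "numeric", adaptWindowSize = "integer",
                 adaptMaxCycles = "integer", seed = "integer"))

setValidity("NestedSpec", function(object) {
  if (object@periodP < 1L) return("periodP must be >= 1")
  if (object@TTarget <= 0 || object@TGen <= 0) return("temperatures must be > 0")
  if (!object@ensemble %in% c("NVT", "NpT")) return("ensemble must be NVT or NpT")
  w <- object@acceptanceWindow
  if (length(w) != 2 || w[1] <= 0 || w[2] > 1 || w[1] >= w[2])
    return("acceptanceWindow must be (lo, hi) within (0, 1]")
  if (object@adaptWindowSize < 1L) return("adaptWindowSize must be >= 1")
  TRUE
})

#' A sampled scalar observable stream
#'
#' Ordered samples of one observable with units and a burn-in index; all
#' statistics (mean, running average, block uncertainty) are computed on the
#' post-burn-in samples only.
#'
#' @slot values Numeric samples in chain order.
#' @slot units Unit string.
#' @slot burnIn Number of leading samples excluded from statistics.
#' @export
setClass("ScalarSeries",
  representation(values = "numeric", units = "character", burnIn = "integer"))

setValidity("ScalarSeries", function(object) {
  if (object@burnIn < 0L || object@burnIn > length(object@values))
    return("burnIn must be between 0 and length(values)")
  TRUE
})

#' Radial distribution function result
#'
#' @slot pair Character length-2 site-label pair.
#' @slot edges Bin edges, Angstrom.
#' @slot g Radial distribution values per bin.
#' @slot counts Raw intermolecular pair counts per bin (summed over frames).
#' @slot coordination Cumulative coordination-number integral per bin.
#' @export
setClass("RdfResult",
  representation(pair = "character", edges = "numeric", g = "numeric",
                 counts = "numeric", coordination = "numeric"))

setValidity("RdfResult", function(object) {
  if (length(object@edges) != length(object@g) + 1)
    return("edges must have length(g) + 1")
  if (any(object@g < 0)) return("g must be >= 0")
  TRUE
})

#' Result of a nested multipotential MC run
#'
#' @slot series Named list of [ScalarSeries] (density, energyHigh, energyLow,
#'   volume, TGen).
#' @slot accepted Logical vector of outer decisions.
#' @slot trajectory List of per-outer-step snapshots (com, quat, conformer,
#'   box edges) of the accepted state.
#' @slot dimerRecords data.frame of per-(snapshot, dimer) two-level
#'   interaction energies and contact metadata.
#' @slot dimerGeometries List of reassembled dimer fragments parallel to
#'   `dimerRecords` (present when geometry recording is on).
#' @slot adaptation data.frame log of the adaptation controller.
#' @slot frozenAt Outer-proposal index at which adaptation froze (NA if
#'   adaptation was off or never froze).
#' @slot spec The [NestedSpec] used (with the final TGen).
#' @slot moveStats data.frame of per-move-type attempt/accept counts.
#' @slot checkpoint Self-contained restart state (see [resumeNestedChain()]).
#' @export
setClass("NestedRun",
  representation(series = "list", accepted = "logical", trajectory = "list",
                 dimerRecords = "data.frame", dimerGeometries = "list",
                 adaptation = "data.frame", frozenAt = "integer",
                 spec = "NestedSpec", moveStats = "data.frame",
                 checkpoint = "list"))

#' Result of a plain single-potential Metropolis run
#'
#' @slot series Named list of [ScalarSeries].
#' @slot trajectory List of per-sample snapshots.
#' @slot moveStats data.frame of per-move-type attempt/accept counts.
#' @export
setClass("MetropolisRun",
  representation(series = "list", trajectory = "list", moveStats = "data.frame"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "MoleculeTemplate", function(object) {
  cat(sprintf("MoleculeTemplate '%s': %d sites, %d bond(s), %d conformer(s), M = %.3f g/mol\n",
              object@name, nrow(object@sites), nrow(object@bonds),
              length(object@conformers), object@molarMass))
})

setMethod("show", "Box", function(object) {
  cat(sprintf("Box: %.4f x %.4f x %.4f A, V = %.2f A^3\n",
              object@edges[1], object@edges[2], object@edges[3],
              prod(object@edges)))
})

setMethod("show", "Configuration", function(object) {
  tab <- table(object@templateId)
  cat(sprintf("Configuration: %d molecule(s) [%s] in ", length(object@templateId),
              paste(sprintf("%s x %d", names(tab), tab), collapse = ", ")))
  show(object@box)
})

setMethod("show", "EnergyBackend", function(object) {
  cap <- backendCapabilities(object)
  cat(sprintf("<%s> '%s' (full_system=%s, fragments=%s)\n", class(object),
              object@name, cap[["full_system"]], cap[["dimer"]]))
})

setMethod("show", "CompositeEnergyModel", function(object) {
  cat(sprintf("CompositeEnergyModel: medium='%s' + [high='%s' - medium] dimer corrections within %.2f A\n",
              object@medium@name, object@high@name, object@rCutDimer))
})

setMethod("show", "ScalarSeries", function(object) {
  v <- seriesValues(object)
  cat(sprintf("ScalarSeries [%s]: %d samples (%d burn-in), mean %.6g\n",
              object@units, length(object@values), object@burnIn,
              if (length(v)) mean(v) else NA_real_))
})

setMethod("show", "NestedRun", function(object) {
  cat(sprintf("NestedRun: %d outer proposals, acceptance %.1f%%, ensemble %s\n",
              length(object@accepted), 100 * mean(object@accepted),
              object@spec@ensemble))
  if (!is.na(object@frozenAt))
    cat(sprintf("  adaptation froze after %d outer proposals (TGen = %.2f K)\n",
                object@frozenAt, object@spec@TGen))
  cat(sprintf("  series: %s; %d dimer records\n",
              paste(names(object@series), collapse = ", "),
              nrow(object@dimerRecords)))
})

setMethod("show", "RdfResult", function(object) {
  cat(sprintf("RdfResult %s...%s: %d bins to %.2f A, max g = %.3f\n",
              object@pair[1], object@pair[2], length(object@g),
              max(object@edges), max(object@g)))
})
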