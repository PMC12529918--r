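#' @include xyz-io.R
NULL

#' Lennard-Jones 12-6 pair energy
#'
#' @param r Distance(s), Angstrom (> 0).
#' @param sigma LJ sigma, Angstrom.
#' @param epsilon LJ well depth, kJ/mol.
#' @return `4 * epsilon * ((sigma/r)^12 - (sigma/r)^6)`, kJ/mol.
#' @examples
#' ljPairEnergy(2^(1/6) * 3.15, 3.15, 0.636) # -epsilon
#' @export
ljPairEnergy <- function(r, sigma, epsilon) {
  if (any(r <= 0)) stop("overlapping sites: r must be > 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6 * sr6 - sr6)
}

#' Damped shifted-force (Wolf-type) Coulomb pair energy
#'
#' Cutoff electrostatics with both the potential and its first derivative
#' shifted to zero at `rCut`; at zero damping this reduces to plain Coulomb
#' minus its shift terms.  Returns 0 for `r > rCut` by contract.
#'
#' @param r Distance(s), Angstrom (> 0).
#' @param qA,qB Partial charges, elementary charge units.
#' @param damping Damping parameter alpha, 1/Angstrom.
#' @param rCut Cutoff, Angstrom.
#' @return Pair energy, kJ/mol.
#' @export
dsfCoulombEnergy <- function(r, qA, qB, damping = 0.2, rCut = 4.5) {
  if (any(r <= 0)) stop("overlapping sites: r must be > 0")
  k <- .const$coulomb
  eShift <- erfc(damping * rCut) / rCut
  fShift <- eShift / rCut +
    (2 * damping / sqrt(pi)) * exp(-damping^2 * rCut^2) / rCut
  e <- k * qA * qB * (erfc(damping * r) / r - eShift + fShift * (r - rCut))
  e[r > rCut] <- 0
  e
}

#' Default force-field parameters
#'
#' @param combiningRule `"lorentz_berthelot"` (default) or `"geometric"`.
#' @param rCut Pair cutoff, Angstrom.
#' @param damping Coulomb damping, 1/Angstrom.
#' @param tailCorrection Apply the analytic LJ tail correction?
#' @return An [FFParameters] object.
#' @export
ffParameters <- function(combiningRule = "lorentz_berthelot", rCut = 4.5,
                         damping = 0.2, tailCorrection = FALSE) {
  methods::new("FFParameters", combiningRule = combiningRule, rCut = rCut,
               damping = damping, tailCorrection = tailCorrection)
}

## combined sigma / epsilon for site-parameter vectors
.combineLJ <- function(sigA, sigB, epsA, epsB, rule) {
  sig <- if (rule == "geometric") sqrt(sigA * sigB) else (sigA + sigB) / 2
  list(sigma = sig, epsilon = sqrt(epsA * epsB))
}

## Intermolecular pair topology of a site table: index vectors (pi, pj) with
## mol[pi] < mol[pj], plus combined LJ parameters and charge products.
pairTopology <- function(st, params, epsilonScale = 1, chargeScale = 1) {
  n <- nrow(st$coords)
  if (n < 2) {
    return(list(pi = integer(0), pj = integer(0), sigma = numeric(0),
                epsilon = numeric(0), qq = numeric(0)))
  }
  idx <- which(outer(st$mol, st$mol, "<"), arr.ind = TRUE)
  pi <- idx[, 1]; pj <- idx[, 2]
  lj <- .combineLJ(st$sigma[pi], st$sigma[pj],
                   st$epsilon[pi] * epsilonScale, st$epsilon[pj] * epsilonScale,
                   params@combiningRule)
  list(pi = pi, pj = pj, sigma = lj$sigma, epsilon = lj$epsilon,
       qq = (st$charge[pi] * chargeScale) * (st$charge[pj] * chargeScale))
}

## Vectorized pair-energy sum over a topology.  Periodic when L is given.
## Returns list(energy, overlap).  Overlap = any pair closer than 0.1 A.
.pairEnergySum <- function(coords, topo, params, L = NULL) {
  if (length(topo$pi) == 0) return(list(energy = 0, overlap = FALSE))
  d <- coords[topo$pj, , drop = FALSE] - coords[topo$pi, , drop = FALSE]
  if (!is.null(L)) d <- .minImage(d, L)
  r2 <- rowSums(d * d)
  overlap <- any(r2 < 0.01)
  rc <- params@rCut
  sel <- which(r2 <= rc * rc)
  if (!length(sel)) return(list(energy = 0, overlap = overlap))
  r <- sqrt(r2[sel])
  sr6 <- (topo$sigma[sel] / r)^6
  eLJ <- 4 * topo$epsilon[sel] * (sr6 * sr6 - sr6)
  a <- params@damping
  k <- .const$coulomb
  eShift <- erfc(a * rc) / rc
  fShift <- eShift / rc + (2 * a / sqrt(pi)) * exp(-a^2 * rc^2) / rc
  eC <- k * topo$qq[sel] * (erfc(a * r) / r - eShift + fShift * (r - rc))
  list(energy = sum(eLJ) + sum(eC), overlap = overlap)
}

## Analytic LJ tail correction for a homogeneous periodic box.
.ljTailCorrection <- function(st, params, V, epsilonScale = 1) {
  key <- paste(st$sigma, st$epsilon)
  groups <- split(seq_along(key), key)
  types <- data.frame(sigma = vapply(groups, function(g) st$sigma[g[1]], 0),
                      epsilon = vapply(groups, function(g) st$epsilon[g[1]], 0),
                      n = vapply(groups, length, 0L))
  rc <- params@rCut
  tot <- 0
  for (a in seq_len(nrow(types))) for (b in seq_len(nrow(types))) {
    if (types$epsilon[a] == 0 || types$epsilon[b] == 0) next
    lj <- .combineLJ(types$sigma[a], types$sigma[b],
                     types$epsilon[a] * epsilonScale,
                     types$epsilon[b] * epsilonScale, params@combiningRule)
    s3 <- lj$sigma^3
    integ <- 4 * lj$epsilon * s3 * ((lj$sigma / rc)^9 / 9 - (lj$sigma / rc)^3 / 3)
    tot <- tot + types$n[a] * types$n[b] * integ
  }
  2 * pi * tot / V
}

#' Full force-field energy of a periodic configuration
#'
#' Sum over intermolecular site pairs, under the minimum-image convention,
#' of truncated Lennard-Jones (optional analytic tail correction) plus
#' damped shifted-force Coulomb energies.  Intramolecular pairs are
#' excluded (rigid molecules carry no internal energy).
#'
#' @param config A [Configuration].
#' @param params [FFParameters]; `rCut` must not exceed half the smallest
#'   box edge.
#' @param epsilonScale,chargeScale Uniform parameter rescalings.
#' @return Energy, kJ/mol.
#' @export
ffConfigurationEnergy <- function(config, params = ffParameters(),
                                  epsilonScale = 1, chargeScale = 1) {
  L <- config@box@edges
  if (params@rCut > min(L) / 2)
    stop(sprintf("rCut (%g A) exceeds half the smallest box edge (%g A)",
                 params@rCut, min(L) / 2))
  st <- siteTable(config)
  topo <- pairTopology(st, params, epsilonScale, chargeScale)
  res <- .pairEnergySum(st$coords, topo, params, L)
  if (res$overlap)
    stop("degenerate configuration: intermolecular site distance < 0.1 A")
  e <- res$energy
  if (params@tailCorrection)
    e <- e + .ljTailCorrection(st, params, prod(L), epsilonScale)
  e
}

## ---------------------------------------------------------------------------
## Fragments: contiguous open-boundary geometries of one or more molecules.
## ---------------------------------------------------------------------------

#' Extract a contiguous fragment (monomer, dimer, ...) from a configuration
#'
#' Molecules after the first are shifted by whole lattice vectors so the
#' fragment is minimum-image reassembled relative to the first molecule's
#' center of mass, i.e. contiguous in free space as an external engine
#' requires.
#'
#' @param config A [Configuration].
#' @param molIds Molecule indices.
#' @return A fragment: list with `elements`, `labels`, `coords` (n x 3, A),
#'   `mol` (1-based molecule index per site), `sigma`, `epsilon`, `charge`,
#'   `templateId`, `conformer`, `sourceMolIds`.
#' @export
makeFragment <- function(config, molIds) {
  st <- siteTable(config)
  L <- config@box@edges
  anchor <- config@com[molIds[1], ]
  keep <- list()
  for (m in seq_along(molIds)) {
    idx <- which(st$mol == molIds[m])
    xyz <- st$coords[idx, , drop = FALSE]
    if (m > 1) {
      rel <- config@com[molIds[m], ] - anchor
      shift <- minimumImageDisplacement(rep(0, 3), rel, config@box) - rel
      xyz <- sweep(xyz, 2, shift, "+")
    }
    keep[[m]] <- idx
    st$coords[idx, ] <- xyz
  }
  idx <- unlist(keep)
  list(elements = st$element[idx], labels = st$label[idx],
       coords = st$coords[idx, , drop = FALSE],
       mol = rep(seq_along(molIds), times = vapply(keep, length, 0L)),
       sigma = st$sigma[idx], epsilon = st$epsilon[idx],
       charge = st$charge[idx],
       templateId = config@templateId[molIds],
       conformer = config@conformer[molIds],
       sourceMolIds = molIds)
}

## open-boundary FF energy of a fragment (same cutoff forms, no tail)
ffFragmentEnergy <- function(fragment, params = ffParameters(),
                             epsilonScale = 1, chargeScale = 1) {
  topo <- pairTopology(fragment, params, epsilonScale, chargeScale)
  res <- .pairEnergySum(fragment$coords, topo, params, L = NULL)
  if (res$overlap)
    stop("degenerate fragment: intermolecular site distance < 0.1 A")
  res$energy
}

## ---------------------------------------------------------------------------
## Backends
## ---------------------------------------------------------------------------

#' @describeIn backendName Name of any backend.
#' @export
setMethod("backendName", "EnergyBackend", function(x) x@name)

#' Built-in force-field backend
#'
#' @param params [FFParameters].
#' @param epsilonScale,chargeScale Uniform parameter rescalings; a scaled
#'   copy serves as a surrogate higher-level theory.
#' @param name Backend name.
#' @return A [ForceFieldBackend].
#' @export
forceFieldBackend <- function(params = ffParameters(), epsilonScale = 1,
                              chargeScale = 1,
                              name = sprintf("ff(eps*%g,q*%g)", epsilonScale,
                                             chargeScale)) {
  methods::new("ForceFieldBackend", name = name, params = params,
               epsilonScale = epsilonScale, chargeScale = chargeScale)
}

#' Zero-potential backend
#' @param name Backend name.
#' @return A [ZeroBackend].
#' @export
zeroBackend <- function(name = "zero") methods::new("ZeroBackend", name = name)

#' Function-valued backend
#' @param name Backend name.
#' @param fullFn `function(config)` full-system energy, or NULL.
#' @param fragmentFn `function(fragment)` fragment energy, or NULL.
#' @return A [FunctionBackend].
#' @export
functionBackend <- function(name, fullFn = NULL, fragmentFn = NULL) {
  methods::new("FunctionBackend", name = name, fullFn = fullFn,
               fragmentFn = fragmentFn)
}

#' @describeIn backendCapabilities Force field: full system and fragments.
#' @export
setMethod("backendCapabilities", "ForceFieldBackend", function(x)
  c(full_system = TRUE, monomer = TRUE, dimer = TRUE))

#' @describeIn backendCapabilities Zero potential: everything (trivially).
#' @export
setMethod("backendCapabilities", "ZeroBackend", function(x)
  c(full_system = TRUE, monomer = TRUE, dimer = TRUE))

#' @describeIn backendCapabilities Depends on which functions are set.
#' @export
setMethod("backendCapabilities", "FunctionBackend", function(x)
  c(full_system = !is.null(x@fullFn), monomer = !is.null(x@fragmentFn),
    dimer = !is.null(x@fragmentFn)))

#' @describeIn fullEnergy Force-field evaluation.
#' @export
setMethod("fullEnergy", "ForceFieldBackend", function(backend, config)
  ffConfigurationEnergy(config, backend@params, backend@epsilonScale,
                        backend@chargeScale))

#' @describeIn fullEnergy Always 0.
#' @export
setMethod("fullEnergy", "ZeroBackend", function(backend, config) 0)

#' @describeIn fullEnergy Calls the wrapped function.
#' @export
setMethod("fullEnergy", "FunctionBackend", function(backend, config) {
  if (is.null(backend@fullFn))
    stop(sprintf("backend '%s' does not support full-system evaluation",
                 backend@name))
  backend@fullFn(config)
})

#' @describeIn fragmentEnergy Force-field evaluation (open boundary).
#' @export
setMethod("fragmentEnergy", "ForceFieldBackend", function(backend, fragment)
  ffFragmentEnergy(fragment, backend@params, backend@epsilonScale,
                   backend@chargeScale))

#' @describeIn fragmentEnergy Always 0.
#' @export
setMethod("fragmentEnergy", "ZeroBackend", function(backend, fragment) 0)

#' @describeIn fragmentEnergy Calls the wrapped function.
#' @export
setMethod("fragmentEnergy", "FunctionBackend", function(backend, fragment) {
  if (is.null(backend@fragmentFn))
    stop(sprintf("backend '%s' does not support fragment evaluation",
                 backend@name))
  backend@fragmentFn(fragment)
})

#' Pair interaction energy of two molecules under a backend
#'
#' `E_int = E(dimer) - E(monomer i) - E(monomer j)` with the dimer at its
#' minimum-image reassembled geometry; symmetric in `(i, j)`.
#'
#' @param backend An [EnergyBackend] supporting fragments.
#' @param config A [Configuration].
#' @param i,j Molecule indices.
#' @return Interaction energy, kJ/mol.
#' @export
pairInteractionEnergy <- function(backend, config, i, j) {
  ids <- sort(c(i, j))
  eD <- tryCatch(fragmentEnergy(backend, makeFragment(config, ids)),
                 error = function(e) stop(sprintf(
                   "backend '%s' failed on dimer (%d, %d): %s",
                   backend@name, ids[1], ids[2], conditionMessage(e)),
                   call. = FALSE))
  eI <- fragmentEnergy(backend, makeFragment(config, ids[1]))
  eJ <- fragmentEnergy(backend, makeFragment(config, ids[2]))
  eD - eI - eJ
}
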