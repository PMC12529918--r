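## Physical constants and small numeric helpers shared across the package.
## Units throughout: coordinates in Angstrom, energies in kJ/mol, T in K,
## p in bar.

#' Physical constants used by the package
#'
#' Unit system: Angstrom, kJ/mol, K, bar.  `R` is the molar gas constant in
#' kJ/(mol K); `barA3` converts a pressure-volume product in bar * Angstrom^3
#' to kJ/mol; `coulomb` is e^2 * N_A / (4 pi eps0) in kJ/mol * Angstrom so that
#' `coulomb * q1 * q2 / r` is a Coulomb pair energy for charges in elementary
#' charge units; `avogadroGcm3` converts (g/mol) / Angstrom^3 to g/cm^3.
#'
#' @return A named list of numeric constants.
#' @examples
#' physicalConstants()$R
#' @export
physicalConstants <- function() {
  list(
    R = 8.31446e-3,          # kJ mol^-1 K^-1
    barA3 = 6.02214e-5,      # kJ mol^-1 per (bar * A^3), per molecule count
    coulomb = 1389.35458,    # kJ mol^-1 A (e^2 N_A / 4 pi eps0)
    avogadroGcm3 = 0.602214076 # N_A * 1e-24: rho[g/cm3] = M[g/mol] / (this * V[A^3])
  )
}

.const <- physicalConstants()

## Atomic masses (g/mol) for the elements the toy systems use, plus a few
## common ones. Pseudo-site symbols map to united-atom masses.
.atomicMasses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  S = 32.06, Cl = 35.45, P = 30.974, Ar = 39.948, He = 4.0026,
  Me = 15.035 # united-atom methyl pseudo-site (CH3)
)

atomicMass <- function(element) {
  m <- .atomicMasses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

isValidElement <- function(element) element %in% names(.atomicMasses)

## complementary error function (base R has none exported)
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

## ---- quaternion helpers -------------------------------------------------
## Quaternions stored as length-4 numeric (w, x, y, z), scalar first.

quatNormalize <- function(q) q / sqrt(sum(q * q))

quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

## 3x3 rotation matrix of a unit quaternion
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

quatFromAxisAngle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis * axis))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

## Shoemake's method: uniform random unit quaternion from three U(0,1) draws
quatRandom <- function(u = stats::runif(3)) {
  s <- u[1]
  c(sqrt(s) * cos(2 * pi * u[3]),
    sqrt(1 - s) * sin(2 * pi * u[2]),
    sqrt(1 - s) * cos(2 * pi * u[2]),
    sqrt(s) * sin(2 * pi * u[3]))
}

## ---- reproducible per-purpose random substreams -------------------------
## One master seed spawns independent L'Ecuyer-CMRG streams so that, e.g.,
## changing the number of inner moves does not shift the draws used for
## outer-acceptance decisions.

#' Create named independent random substreams from one master seed
#'
#' Uses L'Ecuyer-CMRG streams (via [parallel::nextRNGStream()]) so each named
#' purpose draws from its own stream.  The returned object is an environment;
#' use [withStream()] to evaluate an expression under a given stream.
#'
#' @param seed Integer master seed.
#' @param purposes Character vector of stream names.
#' @return An environment holding one RNG state per purpose.
#' @keywords internal
makeRngStreams <- function(seed, purposes) {
  stopifnot(length(purposes) >= 1)
  env <- new.env(parent = emptyenv())
  old <- globalenv()$.Random.seed
  oldKind <- RNGkind()
  on.exit({
    RNGkind(oldKind[1], oldKind[2], oldKind[3])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- globalenv()$.Random.seed
  for (p in purposes) {
    s <- parallel::nextRNGStream(s)
    assign(p, s, envir = env)
  }
  env
}

## Evaluate `expr` with the RNG state of stream `name`, saving the advanced
## state back into the stream afterwards.
withStream <- function(streams, name, expr) {
  old <- globalenv()$.Random.seed
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  res <- expr
  assign(name, globalenv()$.Random.seed, envir = streams)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  res
}

## serialize / restore stream states (for checkpointing)
streamsToList <- function(streams) as.list(streams)
streamsFromList <- function(lst) {
  env <- new.env(parent = emptyenv())
  for (n in names(lst)) assign(n, lst[[n]], envir = env)
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a
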