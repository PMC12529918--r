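#' @include nested-mc.R
NULL

#' Construct a scalar observable series
#'
#' @param values Numeric samples in chain order.
#' @param units Unit string.
#' @param burnIn Leading samples excluded from all statistics.
#' @return A [ScalarSeries].
#' @export
scalarSeries <- function(values, units = "", burnIn = 0L) {
  methods::new("ScalarSeries", values = as.numeric(values), units = units,
               burnIn = as.integer(burnIn))
}

#' @describeIn seriesValues Post-burn-in (default) or all samples.
#' @export
setMethod("seriesValues", "ScalarSeries", function(x, postBurnIn = TRUE) {
  if (postBurnIn && x@burnIn > 0) x@values[-seq_len(x@burnIn)] else x@values
})

#' @describeIn runningAverage Cumulative mean of the post-burn-in samples.
#' @export
setMethod("runningAverage", "ScalarSeries", function(x, ...) {
  v <- seriesValues(x)
  cumsum(v) / seq_along(v)
})

#' @describeIn runningAverage Cumulative mean of a numeric vector.
#' @export
setMethod("runningAverage", "numeric", function(x, ...)
  cumsum(x) / seq_along(x))

## block-doubling estimates: SEM estimate per block size 1, 2, 4, ...
.blockDoublingCurve <- function(v, minBlocks = 4L) {
  n <- length(v)
  out <- data.frame(blockSize = integer(0), sem = numeric(0))
  b <- 1L
  while (n %/% b >= minBlocks) {
    nb <- n %/% b
    means <- colMeans(matrix(v[seq_len(nb * b)], nrow = b))
    out <- rbind(out, data.frame(blockSize = b,
                                 sem = sqrt(stats::var(means) / nb)))
    b <- b * 2L
  }
  out
}

#' @describeIn blockUncertainty Numeric-vector method.
#' @param minSamples Minimum post-burn-in samples required.
#' @export
setMethod("blockUncertainty", "numeric", function(x, minSamples = 16L, ...) {
  if (length(x) < minSamples)
    stop(sprintf("insufficient sampling: %d samples, need at least %d",
                 length(x), minSamples))
  if (stats::var(x) == 0) return(0)
  crv <- .blockDoublingCurve(x)
  s <- crv$sem
  K <- length(s)
  for (k in seq_len(max(K - 2L, 0L))) {
    if (abs(s[k + 1] - s[k]) < 0.1 * s[k] &&
        abs(s[k + 2] - s[k + 1]) < 0.1 * s[k + 1])
      return(s[k + 2])
  }
  s[K]
})

#' @describeIn blockUncertainty Applies to the post-burn-in samples.
#' @export
setMethod("blockUncertainty", "ScalarSeries", function(x, ...)
  blockUncertainty(seriesValues(x), ...))

## standard error with a naive fallback: block doubling needs a minimum
## series length; shorter streams get sd/sqrt(n), which underestimates for
## correlated data and is only used for quick-look tables
.seriesSE <- function(x) {
  v <- if (methods::is(x, "ScalarSeries")) seriesValues(x) else x
  if (length(v) >= 16) blockUncertainty(v)
  else stats::sd(v) / sqrt(length(v))
}

#' @describeIn massDensity Instantaneous density of a configuration.
#' @export
setMethod("massDensity", "Configuration", function(x, ...) {
  if (nMolecules(x) == 0) return(0)
  m <- sum(vapply(x@templates[x@templateId], function(t) t@molarMass,
                  numeric(1)))
  m / (.const$avogadroGcm3 * boxVolume(x))
})

#' @describeIn massDensity Post-burn-in mean density of a nested run.
#' @export
setMethod("massDensity", "NestedRun", function(x, ...)
  mean(seriesValues(x@series$density)))

#' @describeIn massDensity Post-burn-in mean density of a Metropolis run.
#' @export
setMethod("massDensity", "MetropolisRun", function(x, ...)
  mean(seriesValues(x@series$density)))

#' Vaporization enthalpy from liquid and single-molecule vapor runs
#'
#' The vapor phase is treated as an ideal gas sampled in a single-molecule
#' box: `dvapH = (<U_gas> + R T) - (<U_liq>/N + p <V>/N)`, all terms per
#' mole of molecules; for a rigid non-interacting monomer `<U_gas>` is 0 and
#' the expression reduces to `R T - p <V>/N`.  Uncertainties are block
#' standard errors combined in quadrature.
#'
#' @param liquidEnergy [ScalarSeries] of total liquid potential energy,
#'   kJ/mol (for the whole box).
#' @param liquidVolume [ScalarSeries] of box volume, Angstrom^3.
#' @param nMolecules Molecules in the liquid box.
#' @param p Pressure, bar.
#' @param T Liquid-run temperature, K.
#' @param gasEnergy [ScalarSeries] of vapor monomer energy, kJ/mol, or NULL
#'   for a rigid non-interacting monomer (constant 0).
#' @param TGas Vapor-run temperature; must equal `T`.
#' @return List with `value` and `se`, kJ/mol.
#' @export
vaporizationEnthalpy <- function(liquidEnergy, liquidVolume, nMolecules, p, T,
                                 gasEnergy = NULL, TGas = T) {
  if (abs(TGas - T) > 1e-9)
    stop(sprintf("mismatched temperatures: liquid %g K, vapor %g K", T, TGas))
  uGas <- if (is.null(gasEnergy)) 0 else mean(seriesValues(gasEnergy))
  seGas <- if (is.null(gasEnergy)) 0 else .seriesSE(gasEnergy)
  uLiq <- mean(seriesValues(liquidEnergy)) / nMolecules
  seLiq <- .seriesSE(liquidEnergy) / nMolecules
  pv <- p * mean(seriesValues(liquidVolume)) * .const$barA3 / nMolecules
  sePV <- p * .seriesSE(liquidVolume) * .const$barA3 / nMolecules
  list(value = (uGas + .const$R * T) - (uLiq + pv),
       se = sqrt(seGas^2 + seLiq^2 + sePV^2))
}

## finite-difference slope on a (possibly non-uniform) grid:
## central differences at interior points, one-sided at the ends.
.gridSlope <- function(T, y, yErr = NULL) {
  n <- length(T)
  if (n < 3) stop("need at least 3 temperatures")
  if (any(diff(T) <= 0)) stop("temperature grid must be strictly increasing")
  slope <- numeric(n)
  err <- numeric(n)
  if (is.null(yErr)) yErr <- rep(0, n)
  for (i in seq_len(n)) {
    if (i == 1) { a <- 1; b <- 2 } else if (i == n) { a <- n - 1; b <- n }
    else { a <- i - 1; b <- i + 1 }
    dT <- T[b] - T[a]
    slope[i] <- (y[b] - y[a]) / dT
    err[i] <- sqrt(yErr[b]^2 + yErr[a]^2) / dT
  }
  list(slope = slope, err = err)
}

#' Thermal expansivity from densities on a temperature grid
#'
#' `alpha(T) = -(1/rho) (d rho / d T)` at constant pressure, by central
#' finite differences (one-sided at the grid ends), with uncertainties
#' propagated from the density errors.
#'
#' @param T Strictly increasing temperature grid, K (>= 3 points).
#' @param rho Densities, g/cm^3.
#' @param rhoErr Optional density standard errors.
#' @return data.frame with `T`, `alpha` (1/K), `alphaErr`.
#' @export
thermalExpansivity <- function(T, rho, rhoErr = NULL) {
  sl <- .gridSlope(T, rho, rhoErr)
  alpha <- -sl$slope / rho
  aErr <- if (is.null(rhoErr)) rep(0, length(T)) else
    sqrt((sl$err / rho)^2 + (sl$slope * rhoErr / rho^2)^2)
  data.frame(T = T, alpha = alpha, alphaErr = aErr)
}

#' Vapor-liquid heat-capacity difference from the enthalpy slope
#'
#' `dvapCp(T) = d(dvapH)/dT`, the difference between the isobaric heat
#' capacities of vapor and liquid, by the same finite-difference stencil as
#' [thermalExpansivity()].
#'
#' @param T Strictly increasing temperature grid, K (>= 3 points).
#' @param dvapH Vaporization enthalpies, kJ/mol.
#' @param dvapHErr Optional standard errors.
#' @return data.frame with `T`, `dvapCp` (kJ/mol/K), `dvapCpErr`.
#' @export
heatCapacityDifference <- function(T, dvapH, dvapHErr = NULL) {
  sl <- .gridSlope(T, dvapH, dvapHErr)
  data.frame(T = T, dvapCp = sl$slope, dvapCpErr = sl$err)
}

#' Thermodynamic summary over a temperature grid of runs
#'
#' Assembles the derived-observable table (density, vaporization enthalpy,
#' thermal expansivity, vapor-liquid heat-capacity difference, each with
#' uncertainties) from one liquid run per temperature.
#'
#' @param runs List of [NestedRun] or [MetropolisRun] objects, one per
#'   temperature, ordered by temperature.
#' @param T Temperature grid, K.
#' @param nMolecules Molecules in the liquid box.
#' @param p Pressure, bar.
#' @param gasEnergies Optional list of vapor monomer energy series.
#' @return data.frame with columns `T`, `rho`, `rhoErr`, `dvapH`,
#'   `dvapHErr`, `alpha`, `alphaErr`, `dvapCp`, `dvapCpErr`.
#' @export
thermoTable <- function(runs, T, nMolecules, p = 1, gasEnergies = NULL) {
  stopifnot(length(runs) == length(T))
  rho <- vapply(runs, massDensity, numeric(1))
  rhoErr <- vapply(runs, function(r) .seriesSE(r@series$density),
                   numeric(1))
  dv <- lapply(seq_along(runs), function(k) {
    en <- runs[[k]]@series[["energyHigh"]] %||% runs[[k]]@series[["energy"]]
    vaporizationEnthalpy(en, runs[[k]]@series$volume, nMolecules, p, T[k],
                         gasEnergy = if (is.null(gasEnergies)) NULL
                                     else gasEnergies[[k]])
  })
  dvapH <- vapply(dv, `[[`, numeric(1), "value")
  dvapHErr <- vapply(dv, `[[`, numeric(1), "se")
  al <- thermalExpansivity(T, rho, rhoErr)
  cp <- heatCapacityDifference(T, dvapH, dvapHErr)
  data.frame(T = T, rho = rho, rhoErr = rhoErr, dvapH = dvapH,
             dvapHErr = dvapHErr, alpha = al$alpha, alphaErr = al$alphaErr,
             dvapCp = cp$dvapCp, dvapCpErr = cp$dvapCpErr)
}
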