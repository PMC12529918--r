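#' @include utils.R
NULL

#' Backend name accessor
#' @param x An energy backend.
#' @return Character scalar.
#' @export
setGeneric("backendName", function(x) standardGeneric("backendName"))

#' Full-system energy of a periodic configuration
#'
#' Evaluates the backend's energy for a whole periodic [Configuration]
#' (minimum-image convention).  Not every backend supports this; see
#' [backendCapabilities()].
#'
#' @param backend An [EnergyBackend].
#' @param config A [Configuration].
#' @return Energy in kJ/mol.
#' @export
setGeneric("fullEnergy", function(backend, config) standardGeneric("fullEnergy"))

#' Fragment (monomer/dimer/...) energy under open boundaries
#'
#' @param backend An [EnergyBackend].
#' @param fragment A fragment as built by [makeFragment()]: contiguous
#'   free-space geometry of one or more molecules.
#' @return Energy in kJ/mol.
#' @export
setGeneric("fragmentEnergy",
           function(backend, fragment) standardGeneric("fragmentEnergy"))

#' Capabilities of an energy backend
#' @param x An energy backend.
#' @return Named logical vector with entries `full_system`, `monomer`, `dimer`.
#' @export
setGeneric("backendCapabilities",
           function(x) standardGeneric("backendCapabilities"))

#' Number of molecules in a configuration
#' @param x A [Configuration].
#' @return Integer.
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' Box volume
#' @param x A [Box] or [Configuration].
#' @return Volume in Angstrom^3.
#' @export
setGeneric("boxVolume", function(x) standardGeneric("boxVolume"))

#' Mass density
#'
#' For a [Configuration], the instantaneous density; for a [NestedRun] or
#' [MetropolisRun], the post-burn-in mean of the sampled density series.
#'
#' @param x Object to compute the density of.
#' @param ... Passed to methods.
#' @return Density in g/cm^3.
#' @export
setGeneric("massDensity", function(x, ...) standardGeneric("massDensity"))

#' Sample values of a scalar series
#' @param x A [ScalarSeries].
#' @param postBurnIn Drop the burn-in prefix?
#' @return Numeric vector.
#' @export
setGeneric("seriesValues",
           function(x, postBurnIn = TRUE) standardGeneric("seriesValues"))

#' Block-doubling standard error of the mean
#'
#' Flyvbjerg-Petersen style estimate for correlated samples: the variance of
#' block means is tracked over successive block-size doublings and the value
#' is read off the plateau.
#'
#' @param x A [ScalarSeries] or numeric vector.
#' @param ... Passed to methods.
#' @return Standard error of the mean (same units as the series).
#' @export
setGeneric("blockUncertainty", function(x, ...) standardGeneric("blockUncertainty"))

#' Cumulative running average of a series
#' @param x A [ScalarSeries] or numeric vector.
#' @param ... Passed to methods.
#' @return Numeric vector of cumulative means over post-burn-in samples.
#' @export
setGeneric("runningAverage", function(x, ...) standardGeneric("runningAverage"))
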