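#' @include potentials.R
NULL

#' External energy-engine adapter
#'
#' Wraps any command-line energy engine behind the [EnergyBackend] contract:
#' the fragment geometry is written as plain XYZ, `command` is run with
#' `{xyz}` substituted by the file path, and a single energy (kJ/mol) is
#' parsed from the command's standard output using `energyPattern`.  Results
#' are cached by a geometry hash (coordinates rounded to 1e-6 Angstrom in
#' canonical atom order), so an identical geometry is never dispatched twice.
#'
#' @param command Command template containing the placeholder `{xyz}`.
#' @param energyPattern Regular expression with one capture group for the
#'   energy; default matches `energy: <number>` anywhere in the output.
#' @param workdir Scratch directory (default a session temp dir).
#' @param timeout Dispatch timeout in seconds.
#' @param name Backend name.
#' @return An [ExternalEngineBackend].
#' @export
externalEngineBackend <- function(command,
                                  energyPattern = "energy:\\s*(-?[0-9.eE+-]+)",
                                  workdir = tempfile("engine"),
                                  timeout = 60, name = "external") {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  methods::new("ExternalEngineBackend", name = name, command = command,
               energyPattern = energyPattern, workdir = workdir,
               timeout = timeout, cache = new.env(parent = emptyenv()),
               dispatchCount = local({
                 e <- new.env(parent = emptyenv()); e$n <- 0L; e
               }))
}

#' @describeIn backendCapabilities Fragments only.
#' @export
setMethod("backendCapabilities", "ExternalEngineBackend", function(x)
  c(full_system = FALSE, monomer = TRUE, dimer = TRUE))

#' @describeIn fullEnergy Unsupported for external engines.
#' @export
setMethod("fullEnergy", "ExternalEngineBackend", function(backend, config)
  stop(sprintf("backend '%s' does not support full-system evaluation",
               backend@name)))

## geometry hash: element order + coordinates rounded to 1e-6 A
geometryHash <- function(fragment) {
  coords <- round(fragment$coords, 6)
  paste(c(fragment$elements, sprintf("%.6f", t(coords))), collapse = "|")
}

#' Number of actual command dispatches an external engine has performed
#' @param backend An [ExternalEngineBackend].
#' @return Integer count (cache hits excluded).
#' @export
engineDispatchCount <- function(backend) backend@dispatchCount$n

#' @describeIn fragmentEnergy Dispatch to the external command (cached).
#' @export
setMethod("fragmentEnergy", "ExternalEngineBackend", function(backend, fragment) {
  key <- geometryHash(fragment)
  hit <- backend@cache[[key]]
  if (!is.null(hit)) return(hit)
  fragId <- sprintf("fragment[%s; %d sites]",
                    paste(fragment$templateId, collapse = "+"),
                    length(fragment$elements))
  xyz <- tempfile("frag", tmpdir = backend@workdir, fileext = ".xyz")
  on.exit(unlink(xyz), add = TRUE)
  writeFragmentXYZ(fragment, xyz, comment = fragId)
  cmd <- gsub("{xyz}", xyz, backend@command, fixed = TRUE)
  out <- tryCatch(
    suppressWarnings(system(cmd, intern = TRUE, timeout = backend@timeout)),
    error = function(e) stop(sprintf("engine '%s' failed on %s: %s",
                                     backend@name, fragId,
                                     conditionMessage(e)), call. = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status == 124L)
    stop(sprintf("engine '%s' timed out after %gs on %s", backend@name,
                 backend@timeout, fragId))
  if (status != 0L)
    stop(sprintf("engine '%s' exited with status %d on %s", backend@name,
                 status, fragId))
  m <- regmatches(out, regexec(backend@energyPattern, out))
  vals <- unlist(lapply(m, function(x) if (length(x) >= 2) x[2] else NULL))
  if (length(vals) == 0)
    stop(sprintf("engine '%s' output parse failure on %s: pattern '%s' not found",
                 backend@name, fragId, backend@energyPattern))
  e <- as.numeric(vals[length(vals)])
  if (!is.finite(e))
    stop(sprintf("engine '%s' returned a non-finite energy on %s",
                 backend@name, fragId))
  backend@cache[[key]] <- e
  backend@dispatchCount$n <- backend@dispatchCount$n + 1L
  e
})
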