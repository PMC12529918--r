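#' @include presets.R
NULL

## ---------------------------------------------------------------------------
## YAML run-configuration schema (version 1):
##
## schema_version: 1
## system:      {preset, n_molecules, density?, min_separation?}
## simulation:  {ensemble, temperature (scalar or list), pressure?,
##               outer_steps, period?, dimer_cutoff?, adapt?, seed?,
##               t_gen?, p_gen?}
## potentials:  {low: {...}, medium: {...}, high: {...}} with each backend
##              {type: ff|zero, epsilon_scale?, charge_scale?, r_cut?,
##               damping?, tail_correction?, combining_rule?}
## moves:       {max_translation?, max_rotation?, max_ln_volume_step?,
##               weights?}
## output:      {directory, trajectory?, library?, series?}
## analysis:    {rdf: [{pair: [A, B], bin_width?, r_max?}], vaporization?}
## ---------------------------------------------------------------------------

.cfgGet <- function(cfg, path, required = FALSE, default = NULL) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) {
      if (required) stop(sprintf("config error at '%s': field is required",
                                 path), call. = FALSE)
      return(default)
    }
    node <- node[[p]]
  }
  node
}

#' Validate a run configuration
#'
#' Checks the schema before any compute; violations are reported with the
#' offending field path.
#'
#' @param cfg Parsed configuration list (see [runFromConfig()]).
#' @return The validated configuration, invisibly.
#' @export
validateRunConfig <- function(cfg) {
  preset <- .cfgGet(cfg, "system.preset", required = TRUE)
  if (!preset %in% c("lj_fluid", "toy_water", "toy_methanol", "toy_ether"))
    stop(sprintf("config error at 'system.preset': unknown preset '%s'",
                 preset), call. = FALSE)
  n <- .cfgGet(cfg, "system.n_molecules", required = TRUE)
  if (!is.numeric(n) || n < 1)
    stop("config error at 'system.n_molecules': must be a positive integer",
         call. = FALSE)
  ens <- .cfgGet(cfg, "simulation.ensemble", required = TRUE)
  if (!is.character(ens) || !ens %in% c("NVT", "NpT"))
    stop(sprintf("config error at 'simulation.ensemble': must be 'NVT' or 'NpT', got '%s'",
                 ens), call. = FALSE)
  .cfgGet(cfg, "simulation.temperature", required = TRUE)
  steps <- .cfgGet(cfg, "simulation.outer_steps", required = TRUE)
  if (!is.numeric(steps) || steps < 1)
    stop("config error at 'simulation.outer_steps': must be >= 1",
         call. = FALSE)
  for (tier in c("low", "medium", "high")) {
    ty <- .cfgGet(cfg, paste0("potentials.", tier, ".type"), default = "ff")
    if (!ty %in% c("ff", "zero"))
      stop(sprintf("config error at 'potentials.%s.type': must be 'ff' or 'zero'",
                   tier), call. = FALSE)
  }
  invisible(cfg)
}

.backendFromConfig <- function(node, name) {
  node <- node %||% list()
  if ((node$type %||% "ff") == "zero") return(zeroBackend(name))
  params <- ffParameters(
    combiningRule = node$combining_rule %||% "lorentz_berthelot",
    rCut = node$r_cut %||% 4.5,
    damping = node$damping %||% 0.2,
    tailCorrection = isTRUE(node$tail_correction))
  forceFieldBackend(params, epsilonScale = node$epsilon_scale %||% 1,
                    chargeScale = node$charge_scale %||% 1, name = name)
}

.movesFromConfig <- function(node, ensemble, hasConformers) {
  if (is.null(node)) return(defaultMoveSet(ensemble, hasConformers))
  base <- defaultMoveSet(ensemble, hasConformers)
  w <- base@weights
  if (!is.null(node$weights)) { w[names(node$weights)] <- unlist(node$weights) }
  moveSet(maxTranslation = node$max_translation %||% base@maxTranslation,
          maxRotation = node$max_rotation %||% base@maxRotation,
          maxLnVolumeStep = node$max_ln_volume_step %||% base@maxLnVolumeStep,
          weights = w / sum(w))
}

## minimal flat JSON-lines encoder for the structured log channel
.jsonLine <- function(rec) {
  enc <- vapply(names(rec), function(k) {
    v <- rec[[k]]
    val <- if (is.character(v)) sprintf('"%s"', v)
           else if (is.logical(v)) tolower(as.character(v))
           else sprintf("%.10g", v)
    sprintf('"%s":%s', k, val)
  }, character(1))
  paste0("{", paste(enc, collapse = ","), "}")
}

#' Run the full pipeline from a configuration file
#'
#' Reads a YAML run configuration, validates the schema, generates the toy
#' system, runs the nested multipotential chain (per temperature for a
#' temperature grid), analyzes the observables, optionally extracts the
#' pair library, and writes all requested artifacts under the output
#' directory.  Every output carries the config hash and seed in its header
#' line(s).
#'
#' @param path Path to a YAML configuration file.
#' @param outputDir Override of `output.directory`.
#' @param seed Override of `simulation.seed`.
#' @param outerSteps Override of `simulation.outer_steps`.
#' @return List with `runs` (one [NestedRun] per temperature), `results`
#'   (observable table), `artifacts` (paths written), and `config`.
#' @export
runFromConfig <- function(path, outputDir = NULL, seed = NULL,
                          outerSteps = NULL) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
  cfgHash <- unname(tools::md5sum(path))
  seed <- as.integer(seed %||% .cfgGet(cfg, "simulation.seed", default = 1L))
  outerSteps <- as.integer(outerSteps %||%
                             .cfgGet(cfg, "simulation.outer_steps",
                                     required = TRUE))
  outDir <- outputDir %||% .cfgGet(cfg, "output.directory", default = "out")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# config_md5=%s seed=%d", cfgHash, seed)

  ensemble <- .cfgGet(cfg, "simulation.ensemble", required = TRUE)
  Ts <- as.numeric(.cfgGet(cfg, "simulation.temperature", required = TRUE))
  p <- .cfgGet(cfg, "simulation.pressure", default = 1)
  nMol <- as.integer(.cfgGet(cfg, "system.n_molecules", required = TRUE))
  low <- .backendFromConfig(.cfgGet(cfg, "potentials.low"), "low")
  medium <- .backendFromConfig(.cfgGet(cfg, "potentials.medium"), "medium")
  high <- .backendFromConfig(.cfgGet(cfg, "potentials.high"), "high")
  model <- compositeEnergyModel(medium, high,
                                rCutDimer = .cfgGet(cfg, "simulation.dimer_cutoff",
                                                    default = 4.0))
  wantLibrary <- isTRUE(.cfgGet(cfg, "output.library", default = FALSE))
  wantTraj <- isTRUE(.cfgGet(cfg, "output.trajectory", default = FALSE))
  logPath <- file.path(outDir, "run.log.jsonl")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  writeLines(.jsonLine(list(event = "start", config_md5 = cfgHash,
                            seed = seed, ensemble = ensemble,
                            outer_steps = outerSteps)), logCon)

  runs <- list(); artifacts <- c(log = logPath)
  for (k in seq_along(Ts)) {
    Tk <- Ts[k]
    sys <- generateToySystem(.cfgGet(cfg, "system.preset", required = TRUE),
                             nMolecules = nMol,
                             density = .cfgGet(cfg, "system.density"),
                             T = Tk, p = p, seed = seed + k - 1L,
                             minSeparation = .cfgGet(cfg, "system.min_separation",
                                                     default = 1.5))
    spec <- nestedSpec(
      periodP = .cfgGet(cfg, "simulation.period", default = 20L),
      TTarget = Tk, pTarget = p,
      TGen = .cfgGet(cfg, "simulation.t_gen", default = Tk),
      pGen = .cfgGet(cfg, "simulation.p_gen", default = p),
      ensemble = ensemble,
      adapt = isTRUE(.cfgGet(cfg, "simulation.adapt", default = FALSE)),
      seed = seed + 1000L * k)
    moveset <- .movesFromConfig(.cfgGet(cfg, "moves"), ensemble,
                                length(sys$template@conformers) > 1)
    run <- runNestedChain(sys$config, model, low, spec, nOuter = outerSteps,
                          moveset = moveset, recordGeometry = wantLibrary)
    runs[[k]] <- run
    writeLines(.jsonLine(list(event = "run_done", T = Tk,
                              acceptance = mean(run@accepted),
                              TGen = run@spec@TGen,
                              density = massDensity(run))), logCon)

    if (isTRUE(.cfgGet(cfg, "output.series", default = TRUE))) {
      sp <- file.path(outDir, sprintf("series_T%g.tsv", Tk))
      tab <- data.frame(step = seq_along(run@accepted),
                        accepted = run@accepted,
                        density = run@series$density@values,
                        energy_high = run@series$energyHigh@values,
                        energy_low = run@series$energyLow@values,
                        volume = run@series$volume@values,
                        t_gen = run@series$TGen@values)
      writeLines(header, sp)
      suppressWarnings(utils::write.table(tab, sp, sep = "\t", quote = FALSE,
                                          row.names = FALSE, append = TRUE))
      artifacts[sprintf("series_T%g", Tk)] <- sp
    }
    if (wantTraj) {
      tp <- file.path(outDir, sprintf("trajectory_T%g.extxyz", Tk))
      cfgs <- trajectoryConfigurations(run, sys$config)
      if (file.exists(tp)) unlink(tp)
      con <- file(tp, "w")
      for (fc in cfgs) {
        st <- siteTable(fc)
        L <- fc@box@edges
        .writeExtXYZFrame(con, st$element, st$coords,
                          info = list(Lattice = sprintf("%.8f 0 0 0 %.8f 0 0 0 %.8f",
                                                        L[1], L[2], L[3]),
                                      config_md5 = cfgHash,
                                      seed = as.character(seed)),
                          extra = data.frame(site_label = st$label,
                                             mol_id = st$mol),
                          coordFmt = "%.6f")
      }
      close(con)
      artifacts[sprintf("trajectory_T%g", Tk)] <- tp
    }
    if (wantLibrary) {
      lp <- file.path(outDir, sprintf("pair_library_T%g.extxyz", Tk))
      entries <- extractPairRecords(run, model,
                                    material = .cfgGet(cfg, "system.preset"))
      writeLibrary(entries, lp)
      artifacts[sprintf("library_T%g", Tk)] <- lp
      sump <- file.path(outDir, sprintf("pair_summary_T%g.tsv", Tk))
      writeLibrarySummary(summarizeLibrary(entries), sump)
      artifacts[sprintf("library_summary_T%g", Tk)] <- sump
    }
    for (rspec in .cfgGet(cfg, "analysis.rdf", default = list())) {
      cfgs <- trajectoryConfigurations(run, sys$config)
      burn <- run@series$density@burnIn
      if (burn > 0 && burn < length(cfgs)) cfgs <- cfgs[-seq_len(burn)]
      rdf <- radialDistribution(cfgs, pair = unlist(rspec$pair),
                                binWidth = rspec$bin_width %||% 0.05,
                                rMax = rspec$r_max %||% NULL)
      rp <- file.path(outDir, sprintf("rdf_%s_%s_T%g.tsv", rdf@pair[1],
                                      rdf@pair[2], Tk))
      writeRdfTable(rdf, rp)
      artifacts[sprintf("rdf_%s_%s_T%g", rdf@pair[1], rdf@pair[2], Tk)] <- rp
    }
  }

  results <- thermoTableSafe(runs, Ts, nMol, p)
  rp <- file.path(outDir, "results.tsv")
  writeLines(header, rp)
  suppressWarnings(utils::write.table(results, rp, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  artifacts["results"] <- rp
  writeLines(.jsonLine(list(event = "done", temperatures = length(Ts))),
             logCon)
  list(runs = runs, results = results, artifacts = artifacts, config = cfg)
}

## thermoTable needs >= 3 temperatures for the response properties; fall
## back to the per-temperature columns when the grid is shorter.
thermoTableSafe <- function(runs, T, nMolecules, p) {
  if (length(T) >= 3) return(thermoTable(runs, T, nMolecules, p))
  rho <- vapply(runs, massDensity, numeric(1))
  rhoErr <- vapply(runs, function(r) .seriesSE(r@series$density),
                   numeric(1))
  dv <- lapply(seq_along(runs), function(k)
    vaporizationEnthalpy(runs[[k]]@series$energyHigh, runs[[k]]@series$volume,
                         nMolecules, p, T[k]))
  data.frame(T = T, rho = rho, rhoErr = rhoErr,
             dvapH = vapply(dv, `[[`, numeric(1), "value"),
             dvapHErr = vapply(dv, `[[`, numeric(1), "se"),
             alpha = NA_real_, alphaErr = NA_real_, dvapCp = NA_real_,
             dvapCpErr = NA_real_)
}
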