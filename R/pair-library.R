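#' @include rdf.R
NULL

#' Extract the pair-interaction library from a nested run
#'
#' One entry per (snapshot, proximate dimer) of the run's composite-energy
#' breakdowns: the two-level interaction energies, the closest-contact
#' metadata, the minimum-image reassembled dimer geometry, and provenance.
#'
#' @param run A [NestedRun] produced with `recordGeometry = TRUE`.
#' @param model The [CompositeEnergyModel] used for the run (names the
#'   backends in the provenance).
#' @param material Material tag for provenance.
#' @return List of pair-library entries; each entry is a list with
#'   `record` (energies + contact metadata), `geometry` (elements, labels,
#'   coords, per-site molecule index, per-molecule template ids) and
#'   `provenance`.
#' @export
extractPairRecords <- function(run, model, material = "unknown") {
  rec <- run@dimerRecords
  if (nrow(rec) > 0 && length(run@dimerGeometries) != nrow(rec))
    stop("missing breakdown geometries: the run was not recorded with ",
         "recordGeometry = TRUE")
  lapply(seq_len(nrow(rec)), function(k) {
    g <- run@dimerGeometries[[k]]
    list(record = list(i = rec$i[k], j = rec$j[k],
                       contactDistance = rec$contactDistance[k],
                       contactClass = rec$contactClass[k],
                       labelI = rec$labelI[k], labelJ = rec$labelJ[k],
                       eIntHigh = rec$eIntHigh[k],
                       eIntMedium = rec$eIntMedium[k],
                       snapshot = rec$snapshot[k]),
         geometry = list(elements = g$elements, labels = g$labels,
                         coords = g$coords, mol = g$mol,
                         templateId = g$templateId),
         provenance = list(material = material, T = run@spec@TTarget,
                           p = run@spec@pTarget,
                           backendHigh = model@high@name,
                           backendMedium = model@medium@name))
  })
}

#' Write a pair-interaction library as multi-frame extended XYZ
#'
#' One frame per dimer; energies, contact metadata and provenance are
#' comment-line key-value pairs.  Coordinates are written to 1e-6 Angstrom
#' and energies to 1e-8 kJ/mol with canonical formatting, so a
#' read-write cycle is byte-stable.
#'
#' @param entries Library entries (see [extractPairRecords()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    r <- e$record; g <- e$geometry; p <- e$provenance
    info <- list(
      e_int_high = sprintf("%.8f", r$eIntHigh),
      e_int_medium = sprintf("%.8f", r$eIntMedium),
      contact_distance = sprintf("%.6f", r$contactDistance),
      contact_class = r$contactClass,
      contact_labels = paste(r$labelI, r$labelJ),
      mol_ids = paste(r$i, r$j),
      snapshot = as.character(r$snapshot),
      templates = paste(g$templateId, collapse = " "),
      material = p$material,
      T = sprintf("%.6f", p$T), p = sprintf("%.6f", p$p),
      backend_high = p$backendHigh, backend_medium = p$backendMedium)
    .writeExtXYZFrame(con, g$elements, g$coords, info = info,
                      extra = data.frame(site_label = g$labels,
                                         mol_id = g$mol),
                      coordFmt = "%.6f")
  }
  invisible(path)
}

#' Read a pair-interaction library written by [writeLibrary()]
#'
#' Malformed frames are reported with their frame index; partial frames
#' refuse the whole read.
#'
#' @param path File path.
#' @return List of library entries.
#' @export
readLibrary <- function(path) {
  frames <- readExtXYZ(path)
  lapply(frames, function(fr) {
    info <- fr$info
    ids <- as.integer(strsplit(info$mol_ids, " ")[[1]])
    labs <- strsplit(info$contact_labels, " ")[[1]]
    list(record = list(i = ids[1], j = ids[2],
                       contactDistance = as.numeric(info$contact_distance),
                       contactClass = info$contact_class,
                       labelI = labs[1], labelJ = labs[2],
                       eIntHigh = as.numeric(info$e_int_high),
                       eIntMedium = as.numeric(info$e_int_medium),
                       snapshot = as.integer(info$snapshot)),
         geometry = list(elements = fr$elements, labels = fr$extra$site_label,
                         coords = fr$coords, mol = fr$extra$mol_id,
                         templateId = strsplit(info$templates, " ")[[1]]),
         provenance = list(material = info$material,
                           T = as.numeric(info$T), p = as.numeric(info$p),
                           backendHigh = info$backend_high,
                           backendMedium = info$backend_medium))
  })
}

#' Recompute a library entry's interaction energy from its stored geometry
#'
#' Replay check: builds monomer and dimer fragments from the entry's stored
#' coordinates (looking site parameters up in the templates) and returns
#' `E(dimer) - E(monomer 1) - E(monomer 2)` under the given backend.
#'
#' @param entry A library entry.
#' @param backend An [EnergyBackend] supporting fragments.
#' @param templates Named list of [MoleculeTemplate]s covering the entry's
#'   template ids.
#' @return Interaction energy, kJ/mol.
#' @export
replayInteractionEnergy <- function(entry, backend, templates) {
  g <- entry$geometry
  mkFrag <- function(which) {
    sel <- g$mol %in% which
    molIds <- unique(g$mol[sel])
    tpls <- templates[g$templateId[molIds]]
    list(elements = g$elements[sel], labels = g$labels[sel],
         coords = g$coords[sel, , drop = FALSE],
         mol = match(g$mol[sel], molIds),
         sigma = unlist(lapply(tpls, function(t) t@sites$sigma)),
         epsilon = unlist(lapply(tpls, function(t) t@sites$epsilon)),
         charge = unlist(lapply(tpls, function(t) t@sites$charge)),
         templateId = g$templateId[molIds],
         conformer = rep(1L, length(molIds)), sourceMolIds = molIds)
  }
  fragmentEnergy(backend, mkFrag(c(1L, 2L))) -
    fragmentEnergy(backend, mkFrag(1L)) - fragmentEnergy(backend, mkFrag(2L))
}

#' Summarize a pair-interaction library by contact class
#'
#' Per-class entry counts and 2D (contact distance x high-level interaction
#' energy) histograms — the numeric content of a contact-class scatter of
#' the library.
#'
#' @param entries Library entries.
#' @param distanceBreaks Histogram breaks for contact distance, Angstrom.
#' @param energyBreaks Histogram breaks for the high-level interaction
#'   energy, kJ/mol.
#' @return List with `counts` (named, sums to the library size), `table`
#'   (data.frame: class, count, medianEIntHigh, medianContact) and
#'   `histograms` (per-class matrices, distance x energy).
#' @export
summarizeLibrary <- function(entries, distanceBreaks = NULL,
                             energyBreaks = NULL) {
  if (!length(entries))
    return(list(counts = integer(0),
                table = data.frame(class = character(0), count = integer(0),
                                   medianEIntHigh = numeric(0),
                                   medianContact = numeric(0)),
                histograms = list()))
  cls <- vapply(entries, function(e) e$record$contactClass, character(1))
  dst <- vapply(entries, function(e) e$record$contactDistance, numeric(1))
  eh <- vapply(entries, function(e) e$record$eIntHigh, numeric(1))
  if (is.null(distanceBreaks))
    distanceBreaks <- pretty(range(dst), n = 12)
  if (is.null(energyBreaks))
    energyBreaks <- pretty(range(eh), n = 12)
  counts <- table(cls)
  histograms <- lapply(sort(unique(cls)), function(cl) {
    sel <- cls == cl
    tab <- table(cut(dst[sel], distanceBreaks, include.lowest = TRUE),
                 cut(eh[sel], energyBreaks, include.lowest = TRUE))
    unclass(tab)
  })
  names(histograms) <- sort(unique(cls))
  tabDf <- data.frame(
    class = names(counts), count = as.integer(counts),
    medianEIntHigh = vapply(names(counts),
                            function(cl) stats::median(eh[cls == cl]),
                            numeric(1)),
    medianContact = vapply(names(counts),
                           function(cl) stats::median(dst[cls == cl]),
                           numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, table = tabDf, histograms = histograms)
}

#' Write a library summary as TSV
#' @param summary Result of [summarizeLibrary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLibrarySummary <- function(summary, path) {
  utils::write.table(summary$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
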