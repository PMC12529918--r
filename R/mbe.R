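#' @include external-engine.R
NULL

#' Construct a composite many-body-expansion energy model
#'
#' @param medium Medium-level [EnergyBackend] (full system + fragments).
#' @param high High-level [EnergyBackend] (fragments).
#' @param rCutDimer Dimer contact cutoff for the explicit high-level
#'   treatment, Angstrom; default 4.0 selects the first solvation shell.
#' @param trimerHook Optional `function(config) -> kJ/mol` three-body
#'   correction hook (reserved; default NULL, pairs only).
#' @return A [CompositeEnergyModel].
#' @export
compositeEnergyModel <- function(medium, high, rCutDimer = 4.0,
                                 trimerHook = NULL) {
  methods::new("CompositeEnergyModel", medium = medium, high = high,
               rCutDimer = rCutDimer,
               monomerCache = new.env(parent = emptyenv()),
               trimerHook = trimerHook)
}

## internal: fragment built from a precomputed site table (fast path)
.fragmentFromST <- function(st, config, molIds) {
  L <- config@box@edges
  anchor <- config@com[molIds[1], ]
  idxList <- lapply(molIds, function(m) which(st$mol == m))
  coords <- st$coords
  for (m in seq_along(molIds)[-1]) {
    rel <- config@com[molIds[m], ] - anchor
    shift <- (rel - L * floor(rel / L + 0.5)) - rel
    coords[idxList[[m]], ] <- sweep(coords[idxList[[m]], , drop = FALSE],
                                    2, shift, "+")
  }
  idx <- unlist(idxList)
  list(elements = st$element[idx], labels = st$label[idx],
       coords = coords[idx, , drop = FALSE],
       mol = rep(seq_along(molIds), times = lengths(idxList)),
       sigma = st$sigma[idx], epsilon = st$epsilon[idx],
       charge = st$charge[idx],
       templateId = config@templateId[molIds],
       conformer = config@conformer[molIds],
       sourceMolIds = molIds)
}

#' Enumerate proximate dimers
#'
#' All unordered molecule pairs whose closest intermolecular site-site
#' distance under the minimum-image convention is at most `rCut`, each
#' reported once with the contact distance, the contact site labels, and the
#' canonical contact-class label.
#'
#' @param config A [Configuration].
#' @param rCut Contact cutoff, Angstrom; must be below half the smallest box
#'   edge.
#' @return data.frame with columns `i`, `j` (i < j), `contactDistance`,
#'   `labelI`, `labelJ`, `contactClass`.
#' @export
enumerateProximateDimers <- function(config, rCut = 4.0) {
  L <- config@box@edges
  if (rCut >= min(L) / 2)
    stop(sprintf("dimer cutoff (%g A) must be below half the smallest box edge (%g A)",
                 rCut, min(L) / 2))
  st <- siteTable(config)
  .enumerateDimersST(st, config, rCut)
}

.enumerateDimersST <- function(st, config, rCut) {
  L <- config@box@edges
  n <- nrow(st$coords)
  empty <- data.frame(i = integer(0), j = integer(0),
                      contactDistance = numeric(0), labelI = character(0),
                      labelJ = character(0), contactClass = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  idx <- which(outer(st$mol, st$mol, "<"), arr.ind = TRUE)
  pi <- idx[, 1]; pj <- idx[, 2]
  d <- .minImage(st$coords[pj, , drop = FALSE] - st$coords[pi, , drop = FALSE], L)
  r2 <- rowSums(d * d)
  key <- (st$mol[pi] - 1) * nMolecules(config) + st$mol[pj]
  ord <- order(key, r2)
  first <- ord[!duplicated(key[ord])]       # argmin site pair per molecule pair
  sel <- first[r2[first] <= rCut * rCut]
  if (!length(sel)) return(empty)
  res <- data.frame(i = st$mol[pi[sel]], j = st$mol[pj[sel]],
                    contactDistance = sqrt(r2[sel]),
                    labelI = st$label[pi[sel]], labelJ = st$label[pj[sel]],
                    stringsAsFactors = FALSE)
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res$contactClass <- vapply(seq_len(nrow(res)), function(k) {
    .contactClassFromSites(config, res$i[k], res$labelI[k],
                           res$j[k], res$labelJ[k])
  }, character(1))
  res
}

## contact token for one site: element subscripted by the element of its
## nearest bonded neighbor ("." when the site has no bonds)
.siteContactToken <- function(tpl, siteIdx, conformer = 1L) {
  b <- tpl@bonds
  nb <- c(b[b[, 1] == siteIdx, 2], b[b[, 2] == siteIdx, 1])
  if (length(nb) == 0)
    return(paste0(tpl@sites$element[siteIdx], "_."))
  g <- tpl@conformers[[conformer]]
  dd <- sqrt(rowSums((g[nb, , drop = FALSE] -
                        matrix(g[siteIdx, ], length(nb), 3, byrow = TRUE))^2))
  paste0(tpl@sites$element[siteIdx], "_", tpl@sites$element[nb[which.min(dd)]])
}

.contactClassFromSites <- function(config, i, labelI, j, labelJ) {
  tokOf <- function(m, lab) {
    tpl <- config@templates[[config@templateId[m]]]
    siteIdx <- which(tpl@sites$label == lab)[1]
    .siteContactToken(tpl, siteIdx, config@conformer[m])
  }
  toks <- sort(c(tokOf(i, labelI), tokOf(j, labelJ)), decreasing = TRUE)
  paste(toks, collapse = "...")
}

#' Contact class of a molecular pair
#'
#' Classifies a dimer by the elements of its two closest-contact sites, each
#' subscripted by the element of its nearest bonded neighbor — e.g. a
#' hydroxyl-O to hydroxyl-H hydrogen bond is `"O_H...H_O"`.  The label is
#' canonicalized (tokens sorted) so swapping the two molecules does not
#' change it; a site with no bonded neighbor gets subscript `"."`.
#'
#' @param config A [Configuration].
#' @param i,j Molecule indices.
#' @return Character contact-class label.
#' @export
classifyContact <- function(config, i, j) {
  cc <- closestContact(config, i, j)
  .contactClassFromSites(config, i, cc$labelI, j, cc$labelJ)
}

## cached rigid-monomer energy per (backend, template, conformer)
.monomerEnergy <- function(backend, config, molId, cache, st = NULL) {
  key <- paste(backend@name, config@templateId[molId],
               config@conformer[molId], sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  frag <- if (is.null(st)) makeFragment(config, molId)
          else .fragmentFromST(st, config, molId)
  e <- tryCatch(fragmentEnergy(backend, frag),
                error = function(er) stop(sprintf(
                  "backend '%s' failed on monomer %d (%s): %s", backend@name,
                  molId, config@templateId[molId], conditionMessage(er)),
                  call. = FALSE))
  cache[[key]] <- e
  e
}

#' Composite many-body-expansion energy of a configuration
#'
#' `E = E_medium(full system) + sum over proximate dimers of
#' [E_int_high(dimer) - E_int_medium(dimer)]`, where each interaction energy
#' is the dimer energy minus the two rigid-monomer energies, evaluated at
#' the minimum-image reassembled geometry.  The per-dimer breakdown feeds
#' the pair-interaction library.
#'
#' @param config A [Configuration].
#' @param model A [CompositeEnergyModel].
#' @param recordGeometry Keep each dimer's reassembled fragment geometry in
#'   the breakdown (needed for pair-library extraction)?
#' @return List with `total` (kJ/mol), `eMediumFull`, `dimers` (data.frame
#'   breakdown with `eIntHigh`, `eIntMedium` and contact metadata), and
#'   `geometries` (list of fragments, empty unless `recordGeometry`).
#' @export
compositeEnergy <- function(config, model, recordGeometry = FALSE) {
  st <- siteTable(config)
  eMed <- tryCatch(fullEnergy(model@medium, config),
                   error = function(e) stop(sprintf(
                     "medium backend '%s' failed on the full system: %s",
                     model@medium@name, conditionMessage(e)), call. = FALSE))
  dimers <- .enumerateDimersST(st, config, model@rCutDimer)
  nd <- nrow(dimers)
  eIntHigh <- eIntMed <- numeric(nd)
  geoms <- if (recordGeometry) vector("list", nd) else list()
  for (k in seq_len(nd)) {
    ids <- c(dimers$i[k], dimers$j[k])
    frag <- .fragmentFromST(st, config, ids)
    evalPair <- function(backend) {
      eD <- tryCatch(fragmentEnergy(backend, frag),
                     error = function(e) stop(sprintf(
                       "backend '%s' failed on dimer (%d, %d): %s",
                       backend@name, ids[1], ids[2], conditionMessage(e)),
                       call. = FALSE))
      eD - .monomerEnergy(backend, config, ids[1], model@monomerCache, st) -
        .monomerEnergy(backend, config, ids[2], model@monomerCache, st)
    }
    eIntHigh[k] <- evalPair(model@high)
    eIntMed[k] <- evalPair(model@medium)
    if (recordGeometry) geoms[[k]] <- frag
  }
  dimers$eIntHigh <- eIntHigh
  dimers$eIntMedium <- eIntMed
  total <- eMed + sum(eIntHigh) - sum(eIntMed)
  if (!is.null(model@trimerHook)) total <- total + model@trimerHook(config)
  list(total = total, eMediumFull = eMed, dimers = dimers, geometries = geoms)
}

#' Write a per-snapshot fragment-evaluation manifest
#'
#' Audit record of which fragments a composite-energy evaluation touched and
#' at which level, as a columnar text file.
#'
#' @param breakdown Result of [compositeEnergy()].
#' @param path Output path (TSV).
#' @param snapshot Snapshot identifier written into each row.
#' @return `path`, invisibly.
#' @export
writeFragmentManifest <- function(breakdown, path, snapshot = 0L) {
  d <- breakdown$dimers
  rows <- data.frame(snapshot = snapshot,
                     fragment = c("full_system",
                                  sprintf("dimer_%d_%d", d$i, d$j)),
                     level = c("medium", rep("high+medium", nrow(d))),
                     energy = c(breakdown$eMediumFull, d$eIntHigh),
                     stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
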