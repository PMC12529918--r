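#' @include AllClasses.R
NULL

#' Construct a rigid molecule template
#'
#' Site masses are looked up from the element symbols; every conformer
#' geometry is re-centered on its center of mass so a molecule instance's
#' `com` slot is the true molecular center of mass.
#'
#' @param name Species name.
#' @param sites data.frame with columns `element`, `label`, `charge`,
#'   `sigma`, `epsilon` (an optional `mass` column overrides the element
#'   lookup, e.g. for united-atom pseudo-sites).
#' @param geometry n_sites x 3 body-frame coordinate matrix, Angstrom
#'   (reference conformer).
#' @param bonds Two-column integer matrix of bonded site-index pairs.
#' @param conformers Optional list of additional body-frame geometries.
#' @param netCharge Declared net charge (default: sum of site charges,
#'   rounded to nearest integer must match within 1e-8 is not enforced here;
#'   the declared value is validated against the site sum).
#' @return A [MoleculeTemplate].
#' @examples
#' tpl <- moleculeTemplate("argon",
#'   data.frame(element = "Ar", label = "Ar", charge = 0,
#'              sigma = 3.4, epsilon = 0.996),
#'   geometry = matrix(0, 1, 3))
#' @export
moleculeTemplate <- function(name, sites, geometry,
                             bonds = matrix(integer(), 0, 2),
                             conformers = list(),
                             netCharge = sum(sites$charge)) {
  if (is.null(sites$mass)) sites$mass <- atomicMass(sites$element)
  geoms <- c(list(geometry), conformers)
  geoms <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    com <- colSums(g * sites$mass) / sum(sites$mass)
    sweep(g, 2, com)
  })
  storage.mode(bonds) <- "integer"
  methods::new("MoleculeTemplate", name = name, sites = sites,
               bonds = bonds, conformers = geoms,
               molarMass = sum(sites$mass), netCharge = netCharge)
}

#' Construct an orthorhombic box
#' @param edges Numeric length-3 (or scalar, replicated) edge lengths, A.
#' @return A [Box].
#' @export
box3 <- function(edges) {
  if (length(edges) == 1) edges <- rep(edges, 3)
  methods::new("Box", edges = as.numeric(edges))
}

#' @describeIn boxVolume Volume of a box.
#' @export
setMethod("boxVolume", "Box", function(x) prod(x@edges))

#' @describeIn boxVolume Volume of a configuration's box.
#' @export
setMethod("boxVolume", "Configuration", function(x) prod(x@box@edges))

#' @describeIn nMolecules Molecule count of a configuration.
#' @export
setMethod("nMolecules", "Configuration", function(x) length(x@templateId))

#' Construct a configuration
#'
#' @param box A [Box].
#' @param templates Named list of [MoleculeTemplate]s.
#' @param templateId Character vector naming each molecule's template.
#' @param com N x 3 center-of-mass matrix, A.
#' @param quat N x 4 unit-quaternion matrix; default identity orientations.
#' @param conformer Integer conformer indices; default 1.
#' @return A [Configuration].
#' @export
configuration <- function(box, templates, templateId, com,
                          quat = NULL, conformer = NULL) {
  n <- length(templateId)
  if (is.null(quat)) quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  if (is.null(conformer)) conformer <- rep(1L, n)
  if (is.null(names(templates)))
    names(templates) <- vapply(templates, function(t) t@name, character(1))
  methods::new("Configuration", box = box, templates = templates,
               templateId = templateId, com = as.matrix(com),
               quat = as.matrix(quat), conformer = as.integer(conformer),
               cachedEnergyLow = NA_real_, cachedEnergyHigh = NA_real_)
}

#' Minimum-image displacement in an orthorhombic box
#'
#' Returns `rB - rA` shifted by integer multiples of the box edges so each
#' component lies in `[-L/2, L/2)`.  Vectorized: `rA`/`rB` may be n x 3
#' matrices.
#'
#' @param rA,rB Position(s), Angstrom: length-3 vectors or n x 3 matrices.
#' @param box A [Box].
#' @return Displacement(s) with the same shape as the inputs.
#' @examples
#' minimumImageDisplacement(c(0, 0, 0), c(9, 0, 0), box3(10)) # (-1, 0, 0)
#' @export
minimumImageDisplacement <- function(rA, rB, box) {
  d <- rB - rA
  L <- box@edges
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - L[k] * floor(d[, k] / L[k] + 0.5)
  } else {
    d <- d - L * floor(d / L + 0.5)
  }
  d
}

## minimum-image applied to a displacement matrix in place
.minImage <- function(d, L) {
  d[, 1] <- d[, 1] - L[1] * floor(d[, 1] / L[1] + 0.5)
  d[, 2] <- d[, 2] - L[2] * floor(d[, 2] / L[2] + 0.5)
  d[, 3] <- d[, 3] - L[3] * floor(d[, 3] / L[3] + 0.5)
  d
}

#' Laboratory-frame site positions of one molecule
#'
#' Rotates the molecule's body-frame conformer geometry by its orientation
#' quaternion and translates by its center of mass.
#'
#' @param config A [Configuration].
#' @param i Molecule index.
#' @return data.frame with columns `label`, `element`, `x`, `y`, `z`.
#' @export
sitePositions <- function(config, i) {
  tpl <- config@templates[[config@templateId[i]]]
  if (is.null(tpl)) stop("unknown template id: ", config@templateId[i])
  g <- tpl@conformers[[config@conformer[i]]]
  R <- quatToMatrix(config@quat[i, ])
  lab <- g %*% t(R)
  lab <- sweep(lab, 2, config@com[i, ], "+")
  data.frame(label = tpl@sites$label, element = tpl@sites$element,
             x = lab[, 1], y = lab[, 2], z = lab[, 3],
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Fast flat site table used by the energy kernels.
## Returns a list with per-site vectors/matrices in template order:
##   coords (nSites x 3), mol (molecule index), label, element,
##   sigma, epsilon, charge, mass, siteOfMol (index within molecule),
##   molFirst/molCount bookkeeping.
## ---------------------------------------------------------------------------
siteTable <- function(config) {
  n <- nMolecules(config)
  tpls <- config@templates[config@templateId]
  counts <- vapply(tpls, function(t) nrow(t@sites), integer(1))
  total <- sum(counts)
  coords <- matrix(0, total, 3)
  mol <- integer(total); lab <- character(total); ele <- character(total)
  sig <- numeric(total); eps <- numeric(total); chg <- numeric(total)
  mas <- numeric(total)
  off <- 0L
  for (i in seq_len(n)) {
    tpl <- tpls[[i]]
    k <- counts[i]
    idx <- off + seq_len(k)
    g <- tpl@conformers[[config@conformer[i]]]
    Rm <- quatToMatrix(config@quat[i, ])
    coords[idx, ] <- sweep(g %*% t(Rm), 2, config@com[i, ], "+")
    mol[idx] <- i
    lab[idx] <- tpl@sites$label
    ele[idx] <- tpl@sites$element
    sig[idx] <- tpl@sites$sigma
    eps[idx] <- tpl@sites$epsilon
    chg[idx] <- tpl@sites$charge
    mas[idx] <- tpl@sites$mass
    off <- off + k
  }
  list(coords = coords, mol = mol, label = lab, element = ele,
       sigma = sig, epsilon = eps, charge = chg, mass = mas,
       molFirst = c(0L, cumsum(counts))[seq_len(n)] + 1L, molCount = counts)
}

#' Randomly place molecules in a periodic box without close contacts
#'
#' Sequential random insertion with rejection: each molecule gets a uniform
#' center-of-mass position and a uniform random orientation; an insertion is
#' retried until its closest intermolecular site-site distance (minimum
#' image) is at least `minSeparation`.  Deterministic for a fixed seed.
#'
#' @param templates Named list of [MoleculeTemplate]s.
#' @param counts Named integer vector: molecules per template.
#' @param box A [Box].
#' @param minSeparation Minimum allowed intermolecular site-site distance, A.
#' @param seed Integer seed.
#' @param maxAttempts Insertion attempts per molecule before giving up.
#' @return A [Configuration].
#' @export
placeMolecules <- function(templates, counts, box, minSeparation = 1.5,
                           seed = 1L, maxAttempts = 5000L) {
  if (is.null(names(templates)))
    names(templates) <- vapply(templates, function(t) t@name, character(1))
  stopifnot(all(names(counts) %in% names(templates)))
  templateId <- rep(names(counts), times = counts)
  n <- length(templateId)
  streams <- makeRngStreams(seed, "placement")
  com <- matrix(0, n, 3); quat <- matrix(0, n, 4)
  placedCoords <- NULL # accumulated lab-frame site coords of placed molecules
  L <- box@edges
  for (i in seq_len(n)) {
    tpl <- templates[[templateId[i]]]
    g <- tpl@conformers[[1]]
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      pos <- withStream(streams, "placement", stats::runif(3)) * L
      q <- withStream(streams, "placement", quatRandom(stats::runif(3)))
      lab <- sweep(g %*% t(quatToMatrix(q)), 2, pos, "+")
      if (is.null(placedCoords)) { ok <- TRUE } else {
        ## closest contact of candidate sites to all placed sites
        ok <- TRUE
        for (s in seq_len(nrow(lab))) {
          d <- .minImage(sweep(placedCoords, 2, lab[s, ]), L)
          if (min(rowSums(d * d)) < minSeparation^2) { ok <- FALSE; break }
        }
      }
      if (ok) {
        com[i, ] <- pos; quat[i, ] <- q
        placedCoords <- rbind(placedCoords, lab)
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "packing failure: could not place molecule %d of %d after %d attempts; box too small for minSeparation = %g",
        i, n, maxAttempts, minSeparation))
  }
  configuration(box, templates, templateId, com, quat)
}

#' Wrap molecule centers of mass back into the primary box
#'
#' Sites may protrude past the box faces; wrapping is by center of mass.
#'
#' @param config A [Configuration].
#' @return The configuration with all `com` components in `[0, L)`.
#' @export
wrapConfiguration <- function(config) {
  L <- config@box@edges
  for (k in 1:3)
    config@com[, k] <- config@com[, k] - L[k] * floor(config@com[, k] / L[k])
  config
}

#' Closest intermolecular site-site contact between two molecules
#'
#' @param config A [Configuration].
#' @param i,j Molecule indices.
#' @return List with `distance` (A), `siteI`, `siteJ` (site indices within
#'   each molecule), `labelI`, `labelJ`.
#' @export
closestContact <- function(config, i, j) {
  st <- siteTable(config)
  .closestContactST(st, config@box@edges, i, j)
}

.closestContactST <- function(st, L, i, j) {
  ii <- which(st$mol == i); jj <- which(st$mol == j)
  best <- Inf; bi <- bj <- NA_integer_
  for (a in seq_along(ii)) {
    d <- .minImage(sweep(st$coords[jj, , drop = FALSE], 2, st$coords[ii[a], ]), L)
    r2 <- rowSums(d * d)
    m <- which.min(r2)
    if (r2[m] < best) { best <- r2[m]; bi <- a; bj <- m }
  }
  list(distance = sqrt(best), siteI = bi, siteJ = bj,
       labelI = st$label[ii[bi]], labelJ = st$label[jj[bj]])
}
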