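#' @include pair-library.R
NULL

## Built-in toy-model parameter tables.  Qualitative analogs of a
## hydrogen-bonding 3-site water-like liquid, an amphiphilic 3-site
## methanol-like liquid (hydroxyl + united-atom methyl), a non-protic bent
## ether-like liquid, and a single-site LJ fluid.  Values are in the
## TIP3P/OPLS family so the hydrogen-bond vs dispersion vs repulsive contact
## phenomenology is exercised; hydrogens carry a small LJ core so that
## sigma-less sites cannot collapse onto charged neighbors under truncated
## electrostatics.

.presetDefaults <- list(
  lj_fluid = list(density = 1.40, T = 90, p = 1),
  toy_water = list(density = 1.00, T = 300, p = 1),
  toy_methanol = list(density = 0.79, T = 300, p = 1),
  toy_ether = list(density = 0.74, T = 250, p = 1)
)

.waterGeometry <- function(rOH = 0.9572, angleDeg = 104.52) {
  a <- angleDeg * pi / 180
  rbind(c(0, 0, 0),
        c(rOH, 0, 0),
        c(rOH * cos(a), rOH * sin(a), 0))
}

.methanolGeometry <- function(rCO = 1.425, rOH = 0.945, angleDeg = 108.5) {
  a <- angleDeg * pi / 180
  o <- c(rCO, 0, 0)
  h <- o + rOH * c(-cos(a), sin(a), 0)
  rbind(c(0, 0, 0), o, h)
}

.etherGeometry <- function(rCO = 1.41, angleDeg = 112) {
  a <- angleDeg * pi / 180
  rbind(c(0, 0, 0),
        c(rCO, 0, 0),
        c(rCO * cos(a), rCO * sin(a), 0))
}

#' Built-in toy molecule template
#'
#' @param preset One of `"lj_fluid"`, `"toy_water"`, `"toy_methanol"`,
#'   `"toy_ether"`.
#' @return A [MoleculeTemplate].  The methanol-like template carries a
#'   two-member conformer pool (two hydroxyl bend angles) so conformer-swap
#'   moves are exercisable.
#' @export
toyTemplate <- function(preset = c("lj_fluid", "toy_water", "toy_methanol",
                                   "toy_ether")) {
  preset <- match.arg(preset)
  switch(preset,
    lj_fluid = moleculeTemplate("lj_fluid",
      data.frame(element = "Ar", label = "Ar", charge = 0,
                 sigma = 3.405, epsilon = 0.996),
      geometry = matrix(0, 1, 3)),
    toy_water = moleculeTemplate("toy_water",
      data.frame(element = c("O", "H", "H"), label = c("O", "H1", "H2"),
                 charge = c(-0.834, 0.417, 0.417),
                 sigma = c(3.1506, 1.0, 1.0),
                 epsilon = c(0.6364, 0.10, 0.10)),
      geometry = .waterGeometry(),
      bonds = rbind(c(1L, 2L), c(1L, 3L))),
    toy_methanol = moleculeTemplate("toy_methanol",
      data.frame(element = c("Me", "O", "H"), label = c("C", "O", "H"),
                 charge = c(0.265, -0.700, 0.435),
                 sigma = c(3.775, 3.070, 1.0),
                 epsilon = c(0.867, 0.711, 0.10)),
      geometry = .methanolGeometry(),
      bonds = rbind(c(1L, 2L), c(2L, 3L)),
      conformers = list(.methanolGeometry(angleDeg = 104.5))),
    toy_ether = moleculeTemplate("toy_ether",
      data.frame(element = c("Me", "O", "Me"), label = c("C1", "O", "C2"),
                 charge = c(0.195, -0.390, 0.195),
                 sigma = c(3.80, 2.90, 3.80),
                 epsilon = c(0.732, 0.586, 0.732)),
      geometry = .etherGeometry(),
      bonds = rbind(c(1L, 2L), c(2L, 3L))))
}

#' Generate a toy liquid system
#'
#' Builds a cubic box sized from the molecule count, molar mass and target
#' density, and fills it by random sequential insertion with a
#' closest-contact exclusion.  Deterministic per seed.
#'
#' @param preset Toy preset name (see [toyTemplate()]).
#' @param nMolecules Molecule count.  At 100-120 molecules of the 3-site
#'   presets the box holds 300-360 atoms, the production box size; tests use
#'   about 30 molecules.
#' @param density Target density, g/cm^3; default per preset.
#' @param T Temperature, K (stored in the returned spec; default per preset).
#' @param p Pressure, bar.
#' @param seed Integer seed.
#' @param minSeparation Minimum intermolecular site-site distance during
#'   insertion, Angstrom.
#' @return List with `config` (a [Configuration]), `template`, and `spec`
#'   (the fully-resolved generation parameters).
#' @examples
#' sys <- generateToySystem("toy_water", nMolecules = 8, seed = 1)
#' massDensity(sys$config)
#' @export
generateToySystem <- function(preset = c("lj_fluid", "toy_water",
                                         "toy_methanol", "toy_ether"),
                              nMolecules = 30L, density = NULL, T = NULL,
                              p = NULL, seed = 1L, minSeparation = 1.5) {
  preset <- match.arg(preset)
  def <- .presetDefaults[[preset]]
  density <- density %||% def$density
  T <- T %||% def$T
  p <- p %||% def$p
  if (density <= 0) stop("infeasible density: must be > 0")
  tpl <- toyTemplate(preset)
  V <- nMolecules * tpl@molarMass / (.const$avogadroGcm3 * density)
  edge <- V^(1 / 3)
  counts <- stats::setNames(as.integer(nMolecules), tpl@name)
  cfg <- placeMolecules(stats::setNames(list(tpl), tpl@name), counts,
                        box3(edge), minSeparation = minSeparation,
                        seed = seed)
  list(config = cfg, template = tpl,
       spec = list(preset = preset, nMolecules = as.integer(nMolecules),
                   density = density, T = T, p = p, seed = as.integer(seed),
                   minSeparation = minSeparation, edge = edge))
}
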