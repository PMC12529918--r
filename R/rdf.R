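#' @include estimators.R
NULL

#' Rebuild configurations from a run's trajectory snapshots
#'
#' @param run A [NestedRun] or [MetropolisRun].
#' @param config The starting [Configuration] of the run (supplies templates
#'   and template ids).
#' @param every Keep every `every`-th snapshot.
#' @return List of [Configuration] objects.
#' @export
trajectoryConfigurations <- function(run, config, every = 1L) {
  snaps <- run@trajectory[seq(1, length(run@trajectory), by = every)]
  lapply(snaps, function(s)
    configuration(box3(s$edges), config@templates, config@templateId,
                  s$com, s$quat, s$conformer))
}

#' Intermolecular radial distribution function
#'
#' Histogram of minimum-image distances between intermolecular site pairs
#' with the requested labels, normalized by the ideal-gas expectation using
#' exact spherical-shell volumes, so `g(r) -> 1` for uniform random
#' placements.  Intramolecular contacts are excluded.  Also reports the
#' cumulative coordination number (mean count of `pair[2]` sites within `r`
#' of a `pair[1]` site).
#'
#' @param configs List of [Configuration] frames (see
#'   [trajectoryConfigurations()]).
#' @param pair Character length-2 site-label pair, e.g. `c("O", "O")`.
#' @param binWidth Bin width, Angstrom.
#' @param rMax Histogram range, Angstrom; must not exceed half the smallest
#'   box edge of any frame.  Trimmed to a whole number of bins.
#' @return An [RdfResult].
#' @export
radialDistribution <- function(configs, pair = c("O", "O"), binWidth = 0.05,
                               rMax = NULL) {
  stopifnot(length(configs) >= 1, length(pair) == 2)
  minHalf <- min(vapply(configs, function(c) min(c@box@edges) / 2, numeric(1)))
  if (is.null(rMax)) rMax <- minHalf
  if (rMax > minHalf + 1e-9)
    stop(sprintf("rMax (%g A) exceeds half the smallest box edge (%g A)",
                 rMax, minHalf))
  nBins <- floor(rMax / binWidth + 1e-9)
  edges <- (0:nBins) * binWidth
  rEff <- edges[nBins + 1]
  counts <- numeric(nBins)      # unordered pair counts
  ordered <- numeric(nBins)     # ordered A->B counts (coordination)
  idealSum <- 0
  nASum <- 0
  shellVol <- (4 / 3) * pi * (edges[-1]^3 - edges[-(nBins + 1)]^3)
  same <- pair[1] == pair[2]
  for (cfg in configs) {
    st <- siteTable(cfg)
    L <- cfg@box@edges
    iA <- which(st$label == pair[1])
    iB <- which(st$label == pair[2])
    if (!length(iA) || !length(iB)) next
    grid <- expand.grid(a = iA, b = iB)
    keep <- st$mol[grid$a] != st$mol[grid$b]
    if (same) keep <- keep & grid$a < grid$b
    grid <- grid[keep, , drop = FALSE]
    nPairs <- nrow(grid)
    if (nPairs) {
      d <- .minImage(st$coords[grid$b, , drop = FALSE] -
                       st$coords[grid$a, , drop = FALSE], L)
      r <- sqrt(rowSums(d * d))
      bin <- floor(r / binWidth) + 1L
      sel <- which(r < rEff)
      tb <- tabulate(bin[sel], nbins = nBins)
      counts <- counts + tb
      ordered <- ordered + if (same) 2 * tb else tb
    }
    idealSum <- idealSum + nPairs * shellVol / prod(L)
    nASum <- nASum + length(iA)
  }
  g <- ifelse(idealSum > 0, counts / idealSum, 0)
  methods::new("RdfResult", pair = pair, edges = edges, g = g,
               counts = counts,
               coordination = cumsum(ordered) / max(nASum, 1))
}

#' Write an RDF table as plain text
#'
#' @param rdf An [RdfResult].
#' @param path Output path (TSV with columns r, g, coordination, counts).
#' @return `path`, invisibly.
#' @export
writeRdfTable <- function(rdf, path) {
  mid <- (rdf@edges[-1] + rdf@edges[-length(rdf@edges)]) / 2
  utils::write.table(
    data.frame(r = mid, g = rdf@g, coordination = rdf@coordination,
               counts = rdf@counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
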