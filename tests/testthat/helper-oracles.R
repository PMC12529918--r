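## Independent oracles used across the suite.  Everything here is written
## against first principles (explicit loops, closed forms, brute-force
## enumeration), never by calling the code paths under test.

## brute-force minimum image: smallest-norm displacement over all 27
## neighbor images
bruteMinImage <- function(rA, rB, L) {
  best <- NULL; bestN <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- (rB + c(sx, sy, sz) * L) - rA
    n <- sum(d * d)
    if (n < bestN) { bestN <- n; best <- d }
  }
  best
}

oracleErfc <- function(x) 2 * pnorm(-sqrt(2) * x)

## plain-Coulomb DSF form, independently coded
oracleDSF <- function(r, qq, a, rc) {
  k <- 1389.35458
  es <- oracleErfc(a * rc) / rc
  fs <- es / rc + (2 * a / sqrt(pi)) * exp(-a^2 * rc^2) / rc
  ifelse(r > rc, 0, k * qq * (oracleErfc(a * r) / r - es + fs * (r - rc)))
}

oracleLJ <- function(r, sig, eps) 4 * eps * ((sig / r)^12 - (sig / r)^6)

## O(N^2 sites^2) double-loop force-field energy (LJ truncated + DSF, no
## tail), minimum image by 27-image enumeration
naiveFFEnergy <- function(config, rCut = 4.5, damping = 0.2,
                          combining = "lorentz_berthelot") {
  n <- nMolecules(config)
  L <- config@box@edges
  sp <- lapply(seq_len(n), function(i) {
    df <- sitePositions(config, i)
    tpl <- config@templates[[config@templateId[i]]]
    cbind(df, sigma = tpl@sites$sigma, epsilon = tpl@sites$epsilon,
          charge = tpl@sites$charge)
  })
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A <- sp[[i]]; B <- sp[[j]]
    for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B))) {
      d <- bruteMinImage(c(A$x[a], A$y[a], A$z[a]),
                         c(B$x[b], B$y[b], B$z[b]), L)
      r <- sqrt(sum(d * d))
      if (r > rCut) next
      sig <- if (combining == "geometric") sqrt(A$sigma[a] * B$sigma[b])
             else (A$sigma[a] + B$sigma[b]) / 2
      eps <- sqrt(A$epsilon[a] * B$epsilon[b])
      e <- e + oracleLJ(r, sig, eps) +
        oracleDSF(r, A$charge[a] * B$charge[b], damping, rCut)
    }
  }
  e
}

## exhaustive proximate-dimer scan: per molecule pair, minimum site-site
## distance via 27-image enumeration
naiveDimerScan <- function(config, rCut) {
  n <- nMolecules(config)
  L <- config@box@edges
  sp <- lapply(seq_len(n), function(i) sitePositions(config, i))
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A <- sp[[i]]; B <- sp[[j]]
    best <- Inf
    for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B))) {
      d <- bruteMinImage(c(A$x[a], A$y[a], A$z[a]),
                         c(B$x[b], B$y[b], B$z[b]), L)
      best <- min(best, sqrt(sum(d * d)))
    }
    if (best <= rCut)
      out <- rbind(out, data.frame(i = i, j = j, contactDistance = best))
  }
  out
}

## direct intermolecular distance histogram for the RDF oracle: explicit
## loop over unordered site pairs with matching labels on distinct molecules
naiveRdfCounts <- function(configs, pair, binWidth, rMax) {
  nBins <- floor(rMax / binWidth + 1e-9)
  counts <- numeric(nBins)
  for (cfg in configs) {
    n <- nMolecules(cfg)
    L <- cfg@box@edges
    allSites <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(sitePositions(cfg, i), mol = i)))
    m <- nrow(allSites)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      if (allSites$mol[a] == allSites$mol[b]) next
      la <- allSites$label[a]; lb <- allSites$label[b]
      match <- if (pair[1] == pair[2]) la == pair[1] && lb == pair[1]
               else (la == pair[1] && lb == pair[2]) ||
                    (la == pair[2] && lb == pair[1])
      if (!match) next
      d <- bruteMinImage(c(allSites$x[a], allSites$y[a], allSites$z[a]),
                         c(allSites$x[b], allSites$y[b], allSites$z[b]), L)
      r <- sqrt(sum(d * d))
      if (r < nBins * binWidth)
        counts[floor(r / binWidth) + 1] <- counts[floor(r / binWidth) + 1] + 1
    }
  }
  counts
}

## single LJ-site template for pared-down energy tests
ljTemplate <- function(sigma = 3.0, epsilon = 1.0, charge = 0,
                       name = "lj", element = "Ar") {
  moleculeTemplate(name,
    data.frame(element = element, label = element, charge = charge,
               sigma = sigma, epsilon = epsilon),
    geometry = matrix(0, 1, 3))
}

## two single-site LJ molecules at separation r in a large box
ljDimerConfig <- function(r, sigma = 3.0, epsilon = 1.0, edge = 40) {
  tpl <- ljTemplate(sigma, epsilon)
  configuration(box3(edge), list(lj = tpl), c("lj", "lj"),
                com = rbind(c(1, 1, 1), c(1 + r, 1, 1)))
}

## ---------------------------------------------------------------------------
## 1D discretized double-well toy: the independent ground for chain-exactness
## tests.  State space is a finite grid; proposals are +/-1 steps (reject at
## the walls).
## ---------------------------------------------------------------------------
## 13 states over [-1.8, 1.8]: coarse enough that local +/-1 proposals mix
## the wells within a few hundred steps, so thinned histograms are close to
## independent draws
toy1dGrid <- function(nGrid = 13) seq(-1.8, 1.8, length.out = nGrid)

toy1dUHigh <- function(x) 2 * (x^2 - 1)^2 + 0.5 * x  # tilted double well
toy1dULow <- function(x) 1.5 * x^2                   # harmonic surrogate

## direct Metropolis on an energy vector over grid states
direct1dChain <- function(U, T, nSteps, start = 1L, seed = 1L) {
  set.seed(seed)
  RT <- 8.31446e-3 * T
  K <- length(U)
  states <- integer(nSteps)
  s <- start
  prop <- sample(c(-1L, 1L), nSteps, replace = TRUE)
  us <- runif(nSteps)
  for (t in seq_len(nSteps)) {
    cand <- s + prop[t]
    if (cand >= 1L && cand <= K) {
      if (us[t] < exp(-(U[cand] - U[s]) / RT)) s <- cand
    }
    states[t] <- s
  }
  states
}

## nested chain: P inner steps on ULow at TGen, outer assessment on UHigh at
## TTarget through the package's outer acceptance rule
nested1dChain <- function(UHigh, ULow, spec, nOuter, start = 1L, seed = 1L) {
  set.seed(seed)
  RTgen <- 8.31446e-3 * spec@TGen
  K <- length(UHigh)
  P <- spec@periodP
  states <- integer(nOuter)
  s <- start
  for (t in seq_len(nOuter)) {
    x <- s
    for (k in seq_len(P)) {
      cand <- x + sample(c(-1L, 1L), 1L)
      if (cand >= 1L && cand <= K &&
          runif(1) < exp(-(ULow[cand] - ULow[x]) / RTgen)) x <- cand
    }
    dUHigh <- UHigh[x] - UHigh[s]
    dULow <- ULow[x] - ULow[s]
    if (runif(1) < outerAcceptProb(dUHigh, dULow, 0, spec)) s <- x
    states[t] <- s
  }
  states
}
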