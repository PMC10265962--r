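#' @include task_design.R
NULL

## ---------------------------------------------------------------------
## Synthetic geometry: source shell, sensor array, forward gains.
## ---------------------------------------------------------------------

## Quasi-uniform points on (part of) a unit sphere via the Fibonacci lattice.
fibonacciSphere <- function(n, zmin = -1, zmax = 1) {
  i <- seq_len(n) - 0.5
  z <- zmin + (zmax - zmin) * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build a quasi-uniform source space
#'
#' Places `nSources` locations on a spherical shell (default about 7 mm
#' beneath a 10 cm skull, i.e. a 9.3 cm radius), labels hemispheres by the
#' lateral (x) coordinate with a median split so the two counts differ by at
#' most one, builds the immediate-neighbor graph from a distance threshold
#' (1.5 times the median nearest-neighbor spacing, with the nearest
#' neighbor always included so no source is isolated), and draws a fixed
#' random unit dipole orientation per source.
#'
#' @param nSources number of locations (>= 10; 457 at full scale).
#' @param seed orientation seed.
#' @param radius shell radius in metres.
#' @return a [SourceSpace-class].
#' @examples
#' sp <- makeSourceSpace(60, seed = 1)
#' table(hemispheres(sp))
#' @export
makeSourceSpace <- function(nSources, seed = 1L, radius = 0.093) {
  stopIfNot(nSources >= 10, "need at least 10 sources")
  pos <- fibonacciSphere(nSources) * radius
  hemi <- ifelse(rank(pos[, "x"], ties.method = "first") <=
                   floor(nSources / 2), "left", "right")
  dd <- as.matrix(stats::dist(pos))
  diag(dd) <- Inf
  nn <- apply(dd, 1L, min)
  thr <- 1.5 * stats::median(nn)
  neighbors <- lapply(seq_len(nSources), function(i) {
    nb <- which(dd[i, ] <= max(thr, nn[i]))
    as.integer(nb)
  })
  orient <- withSeed(deriveSeed(seed, "orientations", nSources), {
    o <- matrix(stats::rnorm(nSources * 3L), nSources, 3L)
    o / sqrt(rowSums(o^2))
  })
  new("SourceSpace", positions = pos, hemisphere = hemi,
      neighbors = neighbors, orientations = orient,
      radius = radius, seed = as.integer(seed))
}

## Sensor positions on an upper spherical cap just outside the head.
channelPositions <- function(nChannels, radius = 0.12) {
  pos <- fibonacciSphere(nChannels, zmin = 0.05, zmax = 0.95) * radius
  data.frame(name = sprintf("MEG%03d", seq_len(nChannels)),
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
}

#' Build a synthetic leadfield
#'
#' Smooth forward gains from every source orientation to every sensor: each
#' channel carries a fixed random unit sensitivity direction, and the gain
#' from source `s`, orientation `k`, to channel `c` is
#' `exp(-d_sc / decayScale) * orient_ck`, so the gain magnitude (norm over
#' the three orientations) decays monotonically with source-channel
#' distance.
#'
#' @param space a [SourceSpace-class].
#' @param nChannels number of sensors (>= 3; 273 at full scale).
#' @param seed channel-direction seed.
#' @param decayScale spatial decay scale (m).
#' @return a [Leadfield-class] (`gain` is `sources x 3 x channels`).
#' @export
makeLeadfield <- function(space, nChannels, seed = 1L, decayScale = 0.05) {
  stopIfNot(nChannels >= 3, "need at least 3 channels")
  chans <- channelPositions(nChannels)
  chanOrient <- withSeed(deriveSeed(seed, "chan-orient", nChannels), {
    o <- matrix(stats::rnorm(nChannels * 3L), nChannels, 3L)
    o / sqrt(rowSums(o^2))
  })
  gain <- gainFromGeometry(space@positions, chans, chanOrient, decayScale)
  new("Leadfield", gain = gain, channels = chans, chanOrient = chanOrient,
      decayScale = decayScale, seed = as.integer(seed))
}

gainFromGeometry <- function(srcPos, chans, chanOrient, decayScale) {
  nS <- nrow(srcPos); nC <- nrow(chans)
  cp <- as.matrix(chans[, c("x", "y", "z")])
  d2 <- outer(rowSums(srcPos^2), rep(1, nC)) +
    outer(rep(1, nS), rowSums(cp^2)) - 2 * srcPos %*% t(cp)
  decay <- exp(-sqrt(pmax(d2, 0)) / decayScale)
  gain <- array(0, dim = c(nS, 3L, nC))
  for (k in 1:3) gain[, k, ] <- decay * rep(chanOrient[, k], each = nS)
  gain
}

#' Perturb a leadfield for a second recording session
#'
#' Emulates head repositioning between sessions: the source cloud is rotated
#' rigidly about the vertical axis by `angleDeg`, every channel's
#' sensitivity direction is tilted by an independent random rotation of the
#' same magnitude, and every channel's gain is scaled by a factor drawn
#' from `N(1, gainSd^2)`.  The perturbed gains are recomputed from the
#' altered geometry, so the perturbation is structured, not additive noise.
#'
#' @param leadfield a [Leadfield-class].
#' @param space the [SourceSpace-class] the leadfield was built from.
#' @param gainSd per-channel gain-scale SD.
#' @param angleDeg rotation angle in degrees (rigid and per-channel).
#' @param seed perturbation seed.
#' @return a [Leadfield-class].
#' @export
perturbLeadfield <- function(leadfield, space, gainSd = 0.05, angleDeg = 3,
                             seed = 1L) {
  a <- angleDeg * pi / 180
  R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  pos <- space@positions %*% t(R)
  orient <- leadfield@chanOrient
  nC <- nrow(orient)
  withSeed(deriveSeed(seed, "session2"), {
    ## tilt each channel's sensitivity direction by ~angleDeg
    tilt <- matrix(stats::rnorm(nC * 3L, sd = a), nC, 3L)
    orient <- orient + tilt * sqrt(rowSums(orient^2))
    orient <- orient / sqrt(rowSums(orient^2))
    gscale <- stats::rnorm(nC, mean = 1, sd = gainSd)
  })
  gain <- gainFromGeometry(pos, leadfield@channels, orient,
                           leadfield@decayScale)
  nS <- dim(gain)[1L]
  for (k in 1:3) gain[, k, ] <- gain[, k, ] * rep(gscale, each = nS)
  new("Leadfield", gain = gain, channels = leadfield@channels,
      chanOrient = orient, decayScale = leadfield@decayScale,
      seed = as.integer(seed))
}

## Collapse the 3-orientation gain onto the space's fixed dipole
## orientations: returns a sources x channels matrix.
collapseLeadfield <- function(leadfield, space) {
  g <- leadfield@gain
  o <- space@orientations
  o[, 1L] * g[, 1L, ] + o[, 2L] * g[, 2L, ] + o[, 3L] * g[, 3L, ]
}
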