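# Seeded synthetic-study generator.
#
# The synthetic "head" is a spherical shell: a white-matter core, a
# gray-matter shell and CSF outside, all defined by radial ramps of the
# tissue probabilities. Hubs are balls inside the shell whose voxels
# share a latent BOLD series; long-range pairs add a second latent shared
# between two spatially disjoint hubs. With hub-latent loading
# sqrt(rho_w - sum(rho_b)), pair-latent loading sqrt(rho_b) and noise
# loading sqrt(1 - rho_w), the planted population correlations are
# exactly rho_w within a hub and rho_b across a pair (which is why the
# configuration requires rho_w >= sum of rho_b for any hub). All latent
# and noise series are bandpass-shaped to the resting-state passband
# before mixing, so the pipeline's optional bandpass is a near no-op on
# synthetic data. The molecular (SUVR-like) volume couples to the
# planted total degree with slope beta plus Gaussian voxel noise.

.validateSyntheticConfig <- function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    return("gridShape must be 3 integers >= 4")
  if (object@nTimepoints < 16L) return("nTimepoints must be >= 16")
  if (object@samplingInterval <= 0) return("samplingInterval must be > 0")
  if (object@nParticipants < 1L) return("nParticipants must be >= 1")
  h <- object@hubs
  needH <- c("cx", "cy", "cz", "radius", "rhoWithin")
  if (nrow(h) > 0L && !all(needH %in% names(h)))
    return("hubs needs columns cx, cy, cz, radius, rhoWithin")
  if (nrow(h) > 0L) {
    if (any(h$rhoWithin < 0 | h$rhoWithin > 1))
      return("rhoWithin must lie in [0, 1]")
    shapes <- if ("shape" %in% names(h)) h$shape else rep("ball", nrow(h))
    if (!all(shapes %in% c("ball", "cube")))
      return("hub shape must be 'ball' or 'cube'")
    for (i in seq_len(nrow(h))) {
      c0 <- c(h$cx[i], h$cy[i], h$cz[i])
      r <- h$radius[i]
      lo <- if (shapes[i] == "cube") c0 else c0 - r
      hi <- if (shapes[i] == "cube") c0 + 2 * r - 1 else c0 + r
      if (any(lo < 1) || any(hi > object@gridShape))
        return(sprintf("hub %d exceeds the grid", i))
    }
    vox <- hubVoxelIndices(object)
    lin <- unlist(vox)
    if (anyDuplicated(lin))
      return("hubs overlap; hub balls must be pairwise disjoint")
  }
  p <- object@pairs
  if (nrow(p) > 0L) {
    if (!all(c("a", "b", "rhoBetween") %in% names(p)))
      return("pairs needs columns a, b, rhoBetween")
    if (any(p$a == p$b)) return("a pair must join two distinct hubs")
    if (any(p$a > nrow(h) | p$b > nrow(h) | p$a < 1 | p$b < 1))
      return("pair hub index out of range")
    if (any(p$rhoBetween < 0 | p$rhoBetween > 1))
      return("rhoBetween must lie in [0, 1]")
    for (i in seq_len(nrow(h))) {
      tot <- sum(p$rhoBetween[p$a == i | p$b == i])
      if (tot > h$rhoWithin[i] + 1e-12)
        return(sprintf(
          "hub %d: summed rhoBetween (%.3g) exceeds rhoWithin (%.3g)",
          i, tot, h$rhoWithin[i]))
    }
    # paired hubs must be spatially disjoint in the adjacency sense:
    # touching hubs would merge into one contiguous cluster and the
    # pair would stop being long-range
    vox <- hubVoxelIndices(object)
    for (q in seq_len(nrow(p))) {
      ca <- arrayInd(vox[[p$a[q]]], object@gridShape)
      cb <- arrayInd(vox[[p$b[q]]], object@gridShape)
      cheb <- Inf
      for (k in seq_len(nrow(ca)))
        cheb <- min(cheb,
                    min(apply(abs(sweep(cb, 2L, ca[k, ], "-")), 1L, max)))
      if (cheb < 2)
        return(sprintf("pair %d joins spatially adjacent hubs %d and %d",
                       q, p$a[q], p$b[q]))
    }
  }
  if (object@beta < 0) return("beta must be >= 0")
  if (object@suvrNoiseSd < 0) return("suvrNoiseSd must be >= 0")
  if (object@noiseSmoothFwhmVox < 0) return("noiseSmoothFwhmVox must be >= 0")
  if (!(object@bandLowHz >= 0 &&
        object@bandLowHz < object@bandHighHz &&
        object@bandHighHz < 1 / (2 * object@samplingInterval)))
    return("need 0 <= bandLowHz < bandHighHz < Nyquist")
  TRUE
}

#' Default hub layout for a synthetic study
#'
#' Twelve hub balls of radii 1-3 voxels placed on the gray-matter shell
#' along icosahedral directions (maximally spread), so planted local
#' degree varies across hubs (6, 32 or 122). Hubs whose nominal shell
#' position would leave the grid are pulled inward.
#'
#' @param gridShape integer(3).
#' @param shellRadius distance of hub centres from the grid centre,
#'   voxels.
#' @param rhoWithin within-hub correlation shared by all hubs.
#' @param radii integer(12) hub radii (default `c(1,1,3,2,2,1,1,3,2,3,2,3)`,
#'   chosen so the antipodal long-range pairs join partners of sizes
#'   (1,2), (1,3), (2,3), (1,1), (2,2) and (3,3) voxel radii, varying
#'   planted long-range degree across hubs).
#' @return data.frame with columns cx, cy, cz, radius, rhoWithin.
#' @export
defaultHubs <- function(gridShape, shellRadius, rhoWithin = 0.9,
                        radii = c(1, 1, 3, 2, 2, 1, 1, 3, 2, 3, 2, 3)) {
  ctr0 <- (gridShape + 1) / 2
  phi <- (1 + sqrt(5)) / 2
  dirs <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  centers <- t(vapply(seq_along(radii), function(i) {
    off <- shellRadius
    repeat {
      ctr <- round(ctr0 + off * dirs[i, ])
      if (all(ctr - radii[i] >= 1) && all(ctr + radii[i] <= gridShape))
        return(ctr)
      off <- off - 0.5
      if (off < 1) stop("grid too small for the default hub layout")
    }
  }, numeric(3)))
  data.frame(cx = centers[, 1L], cy = centers[, 2L], cz = centers[, 3L],
             radius = radii, rhoWithin = rhoWithin)
}

#' Construct a synthetic-study configuration
#'
#' Defaults describe the reference synthetic study: a 24^3 grid of 2 mm
#' voxels, 120 frames at 2.5 s, 10 participants, twelve hubs of graded
#' size at within-hub correlation 0.9 with six antipodal long-range
#' pairs at 0.7, and degree-SUVR coupling beta = 0.8 with voxel noise
#' SD 0.1.
#'
#' @param gridShape integer(3) (default 24^3).
#' @param voxelSizeMm isotropic voxel size (default 2 mm).
#' @param nTimepoints frames per participant (default 120).
#' @param samplingInterval seconds between frames (default 2.5).
#' @param nParticipants default 10.
#' @param hubs data.frame (see [defaultHubs()]); NULL for the default
#'   layout.
#' @param pairs data.frame with columns a, b, rhoBetween; NULL gives the
#'   six antipodal default pairs at 0.7 (or no pairs when custom hubs
#'   are supplied).
#' @param beta coupling between planted total degree and the molecular
#'   volume (default 0.8).
#' @param suvrNoiseSd molecular voxel noise SD (default 0.1).
#' @param bandLowHz,bandHighHz passband (defaults 0.01 and 0.08 Hz).
#' @param noiseSmoothFwhmVox spatial FWHM (voxels) of the noise field
#'   (default 2.2, giving adjacent-voxel noise correlation about 0.75,
#'   the intrinsic smoothness that makes voxel-wise FCD well defined
#'   throughout gray matter; 0 = independent voxel noise).
#' @param wmCoreRadius,gmInnerRadius,gmOuterRadius tissue geometry in
#'   voxels from the grid centre; NULL scales them to the grid
#'   (0.21, 0.29 and 0.42 of the smallest axis).
#' @param seed master seed (default 42).
#' @return a [SyntheticConfig].
#' @export
syntheticConfig <- function(gridShape = c(24L, 24L, 24L), voxelSizeMm = 2,
                            nTimepoints = 120L, samplingInterval = 2.5,
                            nParticipants = 10L, hubs = NULL, pairs = NULL,
                            beta = 0.8, suvrNoiseSd = 0.1,
                            bandLowHz = 0.01, bandHighHz = 0.08,
                            noiseSmoothFwhmVox = 2.2,
                            wmCoreRadius = NULL, gmInnerRadius = NULL,
                            gmOuterRadius = NULL, seed = 42L) {
  gridShape <- as.integer(gridShape)
  ms <- min(gridShape)
  if (is.null(wmCoreRadius)) wmCoreRadius <- round(0.21 * ms)
  if (is.null(gmInnerRadius)) gmInnerRadius <- wmCoreRadius + 2
  if (is.null(gmOuterRadius)) gmOuterRadius <- round(0.42 * ms)
  hubsGiven <- !is.null(hubs)
  if (is.null(hubs))
    hubs <- defaultHubs(gridShape,
                        shellRadius = (gmInnerRadius + gmOuterRadius) / 2)
  if (is.null(pairs)) {
    pairs <- if (hubsGiven)
      data.frame(a = integer(0), b = integer(0), rhoBetween = numeric(0))
    else  # antipodal direction pairs: maximal spatial separation
      data.frame(a = c(1L, 2L, 5L, 6L, 9L, 10L),
                 b = c(4L, 3L, 8L, 7L, 11L, 12L), rhoBetween = 0.7)
  }
  new("SyntheticConfig", gridShape = gridShape,
      voxelSizeMm = as.numeric(voxelSizeMm),
      nTimepoints = as.integer(nTimepoints),
      samplingInterval = as.numeric(samplingInterval),
      nParticipants = as.integer(nParticipants),
      hubs = hubs, pairs = pairs, beta = as.numeric(beta),
      suvrNoiseSd = as.numeric(suvrNoiseSd),
      bandLowHz = as.numeric(bandLowHz),
      bandHighHz = as.numeric(bandHighHz),
      noiseSmoothFwhmVox = as.numeric(noiseSmoothFwhmVox),
      wmCoreRadius = as.numeric(wmCoreRadius),
      gmInnerRadius = as.numeric(gmInnerRadius),
      gmOuterRadius = as.numeric(gmOuterRadius),
      seed = as.integer(seed))
}

syntheticGrid <- function(config) {
  volumeGrid(config@gridShape, config@voxelSizeMm)
}

# Linear voxel indices of each hub (Euclidean ball by default, so hubs
# of radius >= 1 are 26-connected by construction; an optional "cube"
# shape anchors a (2r)^3 block at the centre voxel, used by contiguity
# fixtures).
hubVoxelIndices <- function(config) {
  shape <- config@gridShape
  shapes <- if ("shape" %in% names(config@hubs)) config@hubs$shape else
    rep("ball", nrow(config@hubs))
  lapply(seq_len(nrow(config@hubs)), function(i) {
    h <- config@hubs[i, ]
    r <- h$radius
    off <- if (shapes[i] == "cube") {
      as.matrix(expand.grid(dx = 0:(2 * r - 1), dy = 0:(2 * r - 1),
                            dz = 0:(2 * r - 1)))
    } else {
      o <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
      o[rowSums(o^2) <= r^2 + 1e-9, , drop = FALSE]
    }
    vox <- sweep(off, 2L, c(h$cx, h$cy, h$cz), "+")
    as.integer(vox[, 1L] + (vox[, 2L] - 1L) * shape[1L] +
                 (vox[, 3L] - 1L) * shape[1L] * shape[2L])
  })
}

radialDistance <- function(config) {
  shape <- config@gridShape
  c0 <- (shape + 1) / 2
  dx <- (seq_len(shape[1L]) - c0[1L])^2
  dy <- (seq_len(shape[2L]) - c0[2L])^2
  dz <- (seq_len(shape[3L]) - c0[3L])^2
  sqrt(outer(outer(dx, dy, "+"), dz, "+"))
}

#' Ground truth of a synthetic study
#'
#' Planted local degree (hub size - 1 inside a hub, 0 outside), planted
#' long-range degree (sum of partner-hub sizes for voxels of paired
#' hubs), the coupling used, and the per-participant seeds derived from
#' the master seed.
#'
#' @param config a [SyntheticConfig].
#' @return a [GroundTruth].
#' @export
studyGroundTruth <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  shape <- config@gridShape
  vox <- hubVoxelIndices(config)
  localDeg <- array(0L, shape)
  longDeg <- array(0L, shape)
  for (i in seq_along(vox))
    localDeg[vox[[i]]] <- length(vox[[i]]) - 1L
  if (nrow(config@pairs) > 0L) {
    for (q in seq_len(nrow(config@pairs))) {
      a <- config@pairs$a[q]; b <- config@pairs$b[q]
      longDeg[vox[[a]]] <- longDeg[vox[[a]]] + length(vox[[b]])
      longDeg[vox[[b]]] <- longDeg[vox[[b]]] + length(vox[[a]])
    }
  }
  set.seed(config@seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config@nParticipants)
  new("GroundTruth", plantedLocalDegree = localDeg,
      plantedLongDegree = longDeg, beta = config@beta,
      participantSeeds = as.integer(seeds))
}

standardizeCols <- function(m) {
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu, "-")
  s <- sqrt(colMeans(m^2))
  s[s == 0] <- 1
  sweep(m, 2L, s, "/")
}

# The bandpass filter is linear, so for repeated use on matrices with a
# fixed frame count it is applied as one precomputed (nt x nt) operator.
.filterCache <- new.env(parent = emptyenv())
bandpassOperator <- function(nt, tr, lowHz, highHz) {
  key <- paste(nt, tr, lowHz, highHz, sep = "|")
  hit <- get0(key, envir = .filterCache)
  if (!is.null(hit)) return(hit)
  F <- bandpassMatrix(diag(nt), tr, lowHz, highHz)
  assign(key, F, envir = .filterCache)
  F
}

#' Generate one participant's BOLD series
#'
#' Latent-factor construction: every hub's voxels share a hub latent;
#' long-range-paired hubs additionally share a pair latent; the rest is
#' independent voxel noise. Loadings are chosen so the population
#' within-hub correlation equals `rhoWithin` and the cross-pair
#' correlation equals `rhoBetween`. All series are bandpass-shaped to
#' the configured passband and standardized. Deterministic given
#' (config seed, participant).
#'
#' @param config a [SyntheticConfig].
#' @param participant integer(1) in 1..nParticipants.
#' @param truth optional precomputed [studyGroundTruth()] (for speed in
#'   loops).
#' @return a [BoldSeries].
#' @export
generateBold <- function(config, participant, truth = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  if (participant < 1L || participant > config@nParticipants)
    stop("participant index out of range")
  if (is.null(truth)) truth <- studyGroundTruth(config)
  set.seed(truth@participantSeeds[participant])
  shape <- config@gridShape
  V <- prod(shape)
  nt <- config@nTimepoints
  tr <- config@samplingInterval
  nH <- nrow(config@hubs)
  nQ <- nrow(config@pairs)
  F <- bandpassOperator(nt, tr, config@bandLowHz, config@bandHighHz)
  lat <- if (nH + nQ > 0L)
    standardizeCols(F %*% matrix(stats::rnorm(nt * (nH + nQ)), nt)) else NULL
  X <- F %*% matrix(stats::rnorm(nt * V), nt, V)
  if (config@noiseSmoothFwhmVox > 0) {
    Ks <- convolutionMatrices(volumeGrid(shape, 1), config@noiseSmoothFwhmVox)
    for (t in seq_len(nt))
      X[t, ] <- as.vector(convolveSeparable(array(X[t, ], shape), Ks))
  }
  X <- standardizeCols(X)
  vox <- hubVoxelIndices(config)
  for (i in seq_len(nH)) {
    rw <- config@hubs$rhoWithin[i]
    qsel <- which(config@pairs$a == i | config@pairs$b == i)
    rbs <- if (length(qsel)) config@pairs$rhoBetween[qsel] else numeric(0)
    a <- sqrt(max(rw - sum(rbs), 0))
    cn <- sqrt(1 - rw)
    mix <- cn * X[, vox[[i]], drop = FALSE] +
      a * matrix(lat[, i], nt, length(vox[[i]]))
    for (k in seq_along(qsel))
      mix <- mix + sqrt(rbs[k]) * matrix(lat[, nH + qsel[k]], nt,
                                         length(vox[[i]]))
    X[, vox[[i]]] <- mix
  }
  X <- standardizeCols(X)
  new("BoldSeries", grid = syntheticGrid(config),
      data = array(t(X), c(shape, nt)), samplingInterval = tr)
}

#' Generate the tissue probability maps
#'
#' Radial ramps produce a white-matter core (wm >= 0.95 well inside), a
#' gray-matter shell (gm = 0.9 plateau), and CSF outside, with
#' probabilities in \[0, 1\] summing to at most 1 per voxel.
#' Deterministic (geometry only, no randomness).
#'
#' @param config a [SyntheticConfig] with grid >= 16 voxels per axis.
#' @return list with [Volume3D] elements `gm`, `wm`, `csf`.
#' @export
generateTissueMaps <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  if (min(config@gridShape) < 16L)
    stop("grid too small for a core + shell head model (need >= 16 per axis)")
  d <- radialDistance(config)
  rw <- config@wmCoreRadius; ri <- config@gmInnerRadius
  ro <- config@gmOuterRadius
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  wm <- 0.98 * clamp01((ri - d) / (ri - rw))
  gm <- 0.9 * pmin(clamp01((d - rw) / (ri - rw)), clamp01((ro + 2 - d) / 2))
  csf <- 0.8 * clamp01((d - ro) / 2) * (1 - gm / 0.9)
  grid <- syntheticGrid(config)
  list(gm = new("Volume3D", grid = grid, values = gm),
       wm = new("Volume3D", grid = grid, values = wm),
       csf = new("Volume3D", grid = grid, values = csf))
}

#' Generate the molecular (SUVR-like) volume for one participant
#'
#' value = anatomy baseline + beta * normalized planted total degree +
#' Gaussian noise, where the normalized degree is (local + long-range)
#' planted degree divided by its maximum. The gray-matter region is then
#' shifted, if needed, so its minimum strictly exceeds the white-matter
#' core mean — the generator's guarantee that the SUVR > 1 restriction
#' removes no gray-matter voxel. Deterministic given (config seed,
#' participant).
#'
#' @param truth a [GroundTruth] from [studyGroundTruth()].
#' @param config the matching [SyntheticConfig].
#' @param participant integer(1), default 1.
#' @return a [Volume3D] of summed-uptake values.
#' @export
generateSuvrVolume <- function(truth, config, participant = 1L) {
  stopifnot(is(truth, "GroundTruth"), is(config, "SyntheticConfig"))
  set.seed(as.integer((as.numeric(truth@participantSeeds[participant]) +
                         500000007) %% .Machine$integer.max))
  tissue <- generateTissueMaps(config)
  wm <- tissue$wm@values
  gmProb <- tissue$gm@values
  gmRegion <- gmProb > 0.1
  deg <- truth@plantedLocalDegree + truth@plantedLongDegree
  normDeg <- if (max(deg) > 0) deg / max(deg) else deg * 0
  # flat uptake baseline inside the gray-matter region (so the noiseless
  # map is exactly monotone in planted degree there), white-matter-like
  # uptake in the core, low uptake outside
  base <- 0.5 + 0.5 * wm
  base[gmRegion] <- 1.3
  vals <- base + truth@beta * normDeg +
    stats::rnorm(length(wm), 0, config@suvrNoiseSd)
  vals <- pmax(vals, 0.01)   # uptake is physically nonnegative
  vals <- array(vals, dim = dim(wm))
  core <- wm > 0.9
  coreMean <- mean(vals[core])
  gmMin <- min(vals[gmRegion])
  if (gmMin <= coreMean)
    vals[gmRegion] <- vals[gmRegion] + (coreMean - gmMin) + 1e-3 * coreMean
  new("Volume3D", grid = syntheticGrid(config), values = vals)
}

#' Generate a synthetic parcellation of the gray-matter shell
#'
#' The shell (gm probability > 0.1) is partitioned into `nRois`
#' connected regions by multi-source breadth-first growth: the first
#' regions start from the hub balls (so each hub lies entirely in one
#' region), the rest from seeded random shell voxels; any shell voxel
#' unreachable by growth is attached to the nearest seed. Groups cycle
#' over seven canonical network names; all regions default to
#' spinnable.
#'
#' @param config a [SyntheticConfig].
#' @param nRois integer(1) >= 2 (>= number of hubs; default 16).
#' @return a [BrainParcellation].
#' @export
generateParcellation <- function(config, nRois = 16L) {
  stopifnot(is(config, "SyntheticConfig"))
  nRois <- as.integer(nRois)
  if (nRois < 2L) stop("nRois must be >= 2")
  tissue <- generateTissueMaps(config)
  shape <- config@gridShape
  gmRegion <- tissue$gm@values > 0.1
  nGm <- sum(gmRegion)
  if (nRois > nGm) stop("nRois exceeds the number of gray-matter voxels")
  vox <- hubVoxelIndices(config)
  nH <- length(vox)
  if (nRois < nH) stop("nRois must be at least the number of hubs")
  labels <- array(0L, shape)
  for (i in seq_len(nH)) {
    inGm <- vox[[i]][gmRegion[vox[[i]]]]
    labels[inGm] <- i
  }
  # additional point seeds on free shell voxels, deterministic
  set.seed(config@seed + 7L)
  free <- which(gmRegion & labels == 0L)
  extra <- nRois - nH
  if (extra > 0L) {
    seeds <- sample(free, extra)
    labels[seeds] <- nH + seq_len(extra)
  }
  labels <- growRegions(labels, gmRegion, shape)
  groups <- c("Visual", "Somatomotor", "DorsalAttention", "Salience",
              "Limbic", "Frontoparietal", "Default")
  tab <- data.frame(
    label = seq_len(nRois),
    name = sprintf("ROI_%02d", seq_len(nRois)),
    group = groups[((seq_len(nRois) - 1L) %% length(groups)) + 1L],
    spinnable = TRUE, stringsAsFactors = FALSE)
  new("BrainParcellation", grid = syntheticGrid(config), labels = labels,
      labelTable = tab)
}

# Multi-source 26-connected BFS over the domain; leftovers go to the
# nearest labeled voxel.
growRegions <- function(labels, domain, shape) {
  offs <- neighborhoodOffsets(26L)
  frontier <- which(labels > 0L)
  while (length(frontier)) {
    fc <- arrayInd(frontier, shape)
    newly <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nc <- sweep(fc, 2L, offs[k, ], "+")
      ok <- nc[, 1L] >= 1L & nc[, 1L] <= shape[1L] &
            nc[, 2L] >= 1L & nc[, 2L] <= shape[2L] &
            nc[, 3L] >= 1L & nc[, 3L] <= shape[3L]
      if (!any(ok)) next
      lin <- nc[ok, 1L] + (nc[ok, 2L] - 1L) * shape[1L] +
        (nc[ok, 3L] - 1L) * shape[1L] * shape[2L]
      src <- frontier[ok]
      take <- domain[lin] & labels[lin] == 0L
      if (any(take)) {
        labels[lin[take]] <- labels[src[take]]
        newly <- c(newly, lin[take])
      }
    }
    frontier <- unique(newly)
  }
  left <- which(domain & labels == 0L)
  if (length(left)) {
    seeded <- which(labels > 0L)
    sc <- arrayInd(seeded, shape)
    lc <- arrayInd(left, shape)
    for (i in seq_along(left)) {
      d2 <- colSums((t(sc) - lc[i, ])^2)
      labels[left[i]] <- labels[seeded[which.min(d2)]]
    }
  }
  labels
}

#' Write a full synthetic study to disk
#'
#' Generates tissue maps, the parcellation, ground-truth degree volumes,
#' and per-participant BOLD and summed-uptake volumes, and writes them
#' (NIfTI + TSV) with a manifest under `dir`.
#'
#' @param config a [SyntheticConfig].
#' @param dir output directory (created if absent).
#' @param nRois regions for the parcellation.
#' @return invisibly the manifest data.frame.
#' @export
simulateStudy <- function(config, dir, nRois = 16L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- studyGroundTruth(config)
  tissue <- generateTissueMaps(config)
  parc <- generateParcellation(config, nRois)
  grid <- syntheticGrid(config)
  rows <- list()
  put <- function(kind, participant, file) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, participant = participant, file = file,
      stringsAsFactors = FALSE)
  }
  for (t in c("gm", "wm", "csf")) {
    f <- file.path(dir, paste0("tissue_", t, ".nii.gz"))
    writeVolume(tissue[[t]], f); put(paste0("tissue_", t), NA, f)
  }
  writeParcellation(parc, file.path(dir, "parcellation.nii.gz"),
                    file.path(dir, "parcellation_labels.tsv"))
  put("parcellation", NA, file.path(dir, "parcellation.nii.gz"))
  for (arrName in c("plantedLocalDegree", "plantedLongDegree")) {
    f <- file.path(dir, paste0(arrName, ".nii.gz"))
    writeVolume(new("Volume3D", grid = grid,
                    values = array(as.double(slot(truth, arrName)),
                                   config@gridShape)), f)
    put(arrName, NA, f)
  }
  for (p in seq_len(config@nParticipants)) {
    fb <- file.path(dir, sprintf("sub%02d_bold.nii.gz", p))
    writeVolume(generateBold(config, p, truth), fb)
    put("bold", p, fb)
    fp <- file.path(dir, sprintf("sub%02d_pet.nii.gz", p))
    writeVolume(generateSuvrVolume(truth, config, p), fp)
    put("pet", p, fp)
  }
  manifest <- do.call(rbind, rows)
  writeResultTable(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
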