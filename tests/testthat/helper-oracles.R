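# Independent oracles and fixture builders. These deliberately share no
# code with the package internals: correlations go through stats::cor on
# the raw series, cluster growing is a naive queue-based BFS over
# coordinate differences, and global counts come from exhaustive pair
# enumeration.

# BoldSeries of plain white noise (no bandpass, no structure).
makeNoiseBold <- function(shape, nt, seed, tr = 2.5) {
  set.seed(seed)
  boldSeries(array(rnorm(prod(shape) * nt), c(shape, nt)), tr,
             volumeGrid(shape))
}

# Full voxel-by-voxel correlation matrix of the masked series.
oracleCorrelationMatrix <- function(bold, mask) {
  d <- dim(voxelValues(bold))
  flat <- matrix(voxelValues(bold), prod(d[1:3]), d[4L])
  stats::cor(t(flat[as.vector(voxelValues(mask)), , drop = FALSE]))
}

# Exhaustive global FCD: count supra-threshold partners per voxel.
oracleGfcd <- function(bold, mask, threshold = 0.6) {
  C <- oracleCorrelationMatrix(bold, mask)
  diag(C) <- -Inf
  rowSums(C > threshold)
}

# Naive BFS local FCD: for each seed, grow the set of voxels that
# correlate with the seed above threshold and touch the cluster through
# the given voxel neighborhood, using explicit coordinate arithmetic.
oracleLfcd <- function(bold, mask, threshold = 0.6, neighborhood = 26) {
  C <- oracleCorrelationMatrix(bold, mask)
  coords <- which(voxelValues(mask), arr.ind = TRUE)
  V <- nrow(coords)
  maxOrd <- switch(as.character(neighborhood), "6" = 1, "18" = 2, "26" = 3)
  adjacent <- function(a, b) {
    d <- abs(coords[a, ] - coords[b, ])
    all(d <= 1) && sum(d) >= 1 && sum(d) <= maxOrd
  }
  counts <- integer(V)
  for (i in seq_len(V)) {
    cand <- setdiff(which(C[i, ] > threshold), i)
    cluster <- i
    queue <- i
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (j in cand) {
        if (!(j %in% cluster) && adjacent(v, j)) {
          cluster <- c(cluster, j)
          queue <- c(queue, j)
        }
      }
    }
    counts[i] <- length(cluster) - 1L
  }
  counts
}

# Random small synthetic config with planted hub structure, used for
# oracle-equivalence runs: 6x6x6 grid, 60 frames, 1-2 small hubs and
# sometimes a long-range pair.
randomOracleConfig <- function(seed) {
  set.seed(seed)
  nHub <- sample(1:2, 1)
  centers <- list(c(2, 2, 2), c(5, 5, 5))
  hubs <- do.call(rbind, lapply(seq_len(nHub), function(i) {
    data.frame(cx = centers[[i]][1], cy = centers[[i]][2],
               cz = centers[[i]][3], radius = 1,
               rhoWithin = runif(1, 0.7, 0.95))
  }))
  pairs <- if (nHub == 2 && runif(1) < 0.5)
    data.frame(a = 1L, b = 2L, rhoBetween = runif(1, 0.3, 0.65)) else
    data.frame(a = integer(0), b = integer(0), rhoBetween = numeric(0))
  syntheticConfig(gridShape = c(6L, 6L, 6L), nTimepoints = 60L,
                  nParticipants = 1L, hubs = hubs, pairs = pairs,
                  seed = seed)
}

# The disjoint two-block contiguity fixture: 2x2x2 cubes in opposite
# corners of a 6x6x6 grid, fully correlated within and across blocks,
# noiseless.
twoBlockConfig <- function(seed = 3L) {
  syntheticConfig(
    gridShape = c(6L, 6L, 6L), nTimepoints = 120L, nParticipants = 1L,
    hubs = data.frame(cx = c(1, 5), cy = c(1, 5), cz = c(1, 5), radius = 1,
                      rhoWithin = 1, shape = "cube"),
    pairs = data.frame(a = 1L, b = 2L, rhoBetween = 1),
    seed = seed)
}

# All-TRUE mask; pass a gridded object to copy its grid, or a shape for
# a unit grid.
fullMask <- function(x) {
  if (is.numeric(x)) return(brainMask(array(TRUE, x), volumeGrid(x)))
  g <- imageGrid(x)
  brainMask(array(TRUE, g@shape), g)
}

# BoldSeries in which all 27 voxels of a 3x3x3 grid carry one series.
identicalSeriesBold <- function(nt = 60) {
  s <- sin(seq_len(nt)) + 0.5 * cos(seq_len(nt) * 0.3)
  boldSeries(array(rep(s, each = 27), c(3, 3, 3, nt)), 2.5)
}

# Scaled synthetic study used for recovery/replicate runs: same design
# as the default (12 graded hubs, 6 long-range pairs) on a 20^3 grid of
# 2.5 mm voxels.
scaledStudyConfig <- function(seed, beta = 0.8) {
  syntheticConfig(gridShape = c(20L, 20L, 20L), voxelSizeMm = 2.5,
                  beta = beta, seed = seed)
}
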