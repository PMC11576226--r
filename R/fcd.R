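# Voxel-wise functional connectivity density (FCD).
#
# Two graphs are built over the masked voxels from the pairwise temporal
# Pearson correlations C_ij:
#   * global graph: an edge joins i and j whenever C_ij > threshold,
#     regardless of spatial position; gFCD(i) is i's degree.
#   * local graph: starting from seed i, a cluster grows by adding any
#     masked voxel j with C_ij > threshold that is spatially adjacent
#     (6/18/26-neighborhood) to a voxel already in the cluster, until no
#     further additions are possible; lFCD(i) is the cluster size - 1
#     under the "edges" convention (every member is connected to the seed
#     by construction).
# The threshold is one-sided: only positive correlations count.
# gFCD - lFCD indexes long-range (interregional) centrality.

#' FCD configuration
#'
#' @param correlationThreshold edge threshold on the pairwise Pearson
#'   correlation, strict and one-sided (default 0.6).
#' @param neighborhood voxel adjacency for spatial contiguity: 6 (faces),
#'   18 (faces+edges) or 26 (faces+edges+corners, default).
#' @param countConvention "edges" (cluster size - 1, default) or
#'   "cluster_size".
#' @param zeroHandling what `logFcd()` does with zero counts:
#'   "mask_missing" (default; log(0) is undefined, the voxel becomes
#'   missing) or "add_one" (log1p).
#' @return an [FcdConfig].
#' @export
fcdConfig <- function(correlationThreshold = 0.6, neighborhood = 26,
                      countConvention = c("edges", "cluster_size"),
                      zeroHandling = c("mask_missing", "add_one")) {
  new("FcdConfig", correlationThreshold = correlationThreshold,
      neighborhood = as.integer(neighborhood),
      countConvention = match.arg(countConvention),
      zeroHandling = match.arg(zeroHandling))
}

#' Pairwise temporal Pearson correlation between two voxels
#'
#' @param bold a [BoldSeries].
#' @param i,j integer(3) 1-based voxel coordinates.
#' @return numeric(1) correlation in \[-1, 1\], symmetric in (i, j).
#' @export
pairwiseCorrelation <- function(bold, i, j) {
  stopifnot(is(bold, "BoldSeries"), length(i) == 3L, length(j) == 3L)
  xi <- bold@data[i[1L], i[2L], i[3L], ]
  xj <- bold@data[j[1L], j[2L], j[3L], ]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0)
    stop("zero-variance series at the requested voxel")
  stats::cor(xi, xj)
}

neighborhoodOffsets <- function(neighborhood) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "6" = ord == 1L, "18" = ord <= 2L, "26" = ord <= 3L,
                 stop("neighborhood must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Rows standardized so that tcrossprod gives Pearson correlations.
# Zero-variance rows become all-zero (correlate with nothing) and are
# reported via a warning.
standardizedSeriesMatrix <- function(bold, mask) {
  d <- dim(bold@data)
  nt <- d[4L]
  if (nt < 16L) stop("FCD requires at least 16 timepoints")
  flat <- matrix(bold@data, prod(d[1:3]), nt)
  Z <- flat[as.vector(mask@membership), , drop = FALSE]
  mu <- rowMeans(Z)
  Zc <- Z - mu
  ss <- sqrt(rowSums(Zc^2))
  bad <- ss == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance voxel(s) inside the mask; ",
            "treated as connected to nothing")
    ss[bad] <- 1
    Zc[bad, ] <- 0
  }
  Zc / ss
}

# Per-masked-voxel neighbor lookup: V x K matrix of mask indices
# (0 = neighbor outside grid or outside mask).
maskNeighborMatrix <- function(mask, neighborhood) {
  coords <- maskCoords(mask@membership)
  V <- nrow(coords)
  shape <- mask@grid@shape
  idxArr <- array(0L, shape)
  idxArr[coords] <- seq_len(V)
  offs <- neighborhoodOffsets(neighborhood)
  nbr <- matrix(0L, V, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nc <- sweep(coords, 2L, offs[k, ], "+")
    ok <- nc[, 1L] >= 1L & nc[, 1L] <= shape[1L] &
          nc[, 2L] >= 1L & nc[, 2L] <= shape[2L] &
          nc[, 3L] >= 1L & nc[, 3L] <= shape[3L]
    nbr[ok, k] <- idxArr[nc[ok, , drop = FALSE]]
  }
  nbr
}

# Supra-threshold partner lists per seed, computed in row blocks so the
# full V x V correlation matrix never has to be held for large masks.
# Returns list(gfcdCounts = integer(V), candidates = list of integer
# vectors (partners of each seed, self excluded)).
supraThresholdPartners <- function(Z, threshold, blockRows = 2048L) {
  V <- nrow(Z)
  Zt <- t(Z)
  counts <- integer(V)
  cands <- vector("list", V)
  for (start in seq(1L, V, by = blockRows)) {
    rows <- start:min(start + blockRows - 1L, V)
    C <- Z[rows, , drop = FALSE] %*% Zt
    sc <- .supraScan(C, threshold, start - 1L)
    counts[rows] <- sc$counts
    cands[rows] <- sc$cands
  }
  list(gfcdCounts = counts, candidates = cands)
}

makeDensityMap <- function(counts, mask, kind) {
  arr <- array(NA_real_, mask@grid@shape)
  arr[mask@membership] <- as.double(counts)
  new("DensityMap", grid = mask@grid, counts = arr, kind = kind)
}

# Both density maps from one correlation pass.
fcdDensityMaps <- function(bold, mask, config) {
  stopifnot(is(bold, "BoldSeries"), is(mask, "BrainMask"),
            is(config, "FcdConfig"))
  checkGridCompatibility(list(bold, mask))
  if (!any(mask@membership)) stop("mask is empty")
  Z <- standardizedSeriesMatrix(bold, mask)
  sup <- supraThresholdPartners(Z, config@correlationThreshold)
  nbr <- maskNeighborMatrix(mask, config@neighborhood)
  lcounts <- .lfcdCounts(sup$candidates, nbr)
  if (config@countConvention == "cluster_size") {
    gcounts <- sup$gfcdCounts + 1L
    lcounts <- lcounts + 1L
  } else {
    gcounts <- sup$gfcdCounts
  }
  list(gfcd = makeDensityMap(gcounts, mask, "gfcd"),
       lfcd = makeDensityMap(lcounts, mask, "lfcd"))
}

#' Global functional connectivity density
#'
#' For each masked voxel, the number of other masked voxels anywhere in
#' the volume whose temporal correlation with it strictly exceeds the
#' threshold (positive correlations only).
#'
#' @param bold a [BoldSeries] (>= 16 timepoints).
#' @param mask a nonempty [BrainMask] on the same grid.
#' @param config an [FcdConfig].
#' @return a [DensityMap] of kind "gfcd".
#' @export
computeGfcd <- function(bold, mask, config = fcdConfig()) {
  stopifnot(is(bold, "BoldSeries"), is(mask, "BrainMask"),
            is(config, "FcdConfig"))
  checkGridCompatibility(list(bold, mask))
  if (!any(mask@membership)) stop("mask is empty")
  Z <- standardizedSeriesMatrix(bold, mask)
  sup <- supraThresholdPartners(Z, config@correlationThreshold)
  counts <- if (config@countConvention == "cluster_size")
    sup$gfcdCounts + 1L else sup$gfcdCounts
  makeDensityMap(counts, mask, "gfcd")
}

#' Local functional connectivity density (cluster growing)
#'
#' For each seed voxel the cluster is initialized at the seed; a masked
#' voxel joins iff its correlation with the seed strictly exceeds the
#' threshold AND it is neighborhood-adjacent to a voxel already in the
#' cluster; growth repeats until no more additions. The count is the
#' cluster size minus one under the "edges" convention.
#'
#' @inheritParams computeGfcd
#' @return a [DensityMap] of kind "lfcd".
#' @export
computeLfcd <- function(bold, mask, config = fcdConfig()) {
  fcdDensityMaps(bold, mask, config)$lfcd
}

#' Long-range FCD map (gFCD - lFCD)
#'
#' Voxel-wise difference between a global and a local density map from
#' the same run. A negative difference signals an implementation
#' inconsistency and aborts.
#'
#' @param gfcd a [DensityMap] of kind "gfcd".
#' @param lfcd a [DensityMap] of kind "lfcd" from the same run (same
#'   grid, same mask).
#' @return a [DensityMap] of kind "long_range".
#' @export
longRangeMap <- function(gfcd, lfcd) {
  stopifnot(is(gfcd, "DensityMap"), is(lfcd, "DensityMap"))
  if (gfcd@kind != "gfcd" || lfcd@kind != "lfcd")
    stop("longRangeMap expects a gfcd map and an lfcd map")
  checkGridCompatibility(list(gfcd, lfcd))
  if (!identical(is.na(gfcd@counts), is.na(lfcd@counts)))
    stop("gfcd and lfcd come from different masks/runs")
  diffArr <- gfcd@counts - lfcd@counts
  if (any(diffArr[!is.na(diffArr)] < 0))
    stop("negative gFCD - lFCD difference: maps are inconsistent")
  new("DensityMap", grid = gfcd@grid, counts = diffArr, kind = "long_range")
}

#' Log-transform an FCD count map
#'
#' Natural log of the counts: srFCD = log(lFCD), lrFCD =
#' log(gFCD - lFCD). Zero counts become missing under the default
#' handling ("mask_missing") or log1p under "add_one". Raw gFCD is not
#' log-transformed in this pipeline; pass `allowGfcd = TRUE` explicitly
#' for a sensitivity analysis.
#'
#' @param map a [DensityMap].
#' @param config an [FcdConfig] (supplies `zeroHandling`).
#' @param allowGfcd logical(1); permit a "gfcd" input.
#' @return an (unsmoothed) [LogFcdMap].
#' @export
logFcd <- function(map, config = fcdConfig(), allowGfcd = FALSE) {
  stopifnot(is(map, "DensityMap"), is(config, "FcdConfig"))
  if (map@kind == "gfcd" && !allowGfcd)
    stop("gfcd is not log-transformed here; set allowGfcd = TRUE to force")
  kind <- switch(map@kind, lfcd = "srfcd", long_range = "lrfcd",
                 gfcd = "log_gfcd")
  vals <- map@counts
  if (config@zeroHandling == "add_one") {
    vals <- log1p(vals)
  } else {
    vals[!is.na(vals) & vals == 0] <- NA_real_
    vals <- log(vals)
  }
  new("LogFcdMap", grid = map@grid, values = vals, kind = kind,
      smoothed = FALSE)
}

#' Spatially smooth a log-FCD map (masked convolution)
#'
#' Gaussian smoothing in which missing voxels are excluded from the
#' kernel: weights are renormalized over present voxels, so a constant
#' map stays constant and an isolated present voxel keeps its value.
#' Smoothing an already-smoothed map is an error.
#'
#' @param map an unsmoothed [LogFcdMap].
#' @param fwhmMm kernel FWHM in mm (default 8).
#' @return a smoothed [LogFcdMap].
#' @export
smoothLogFcd <- function(map, fwhmMm = 8) {
  stopifnot(is(map, "LogFcdMap"))
  if (map@smoothed) stop("map is already smoothed")
  vals <- if (all(is.na(map@values))) map@values else
    maskedGaussianSmooth(map@values, map@grid, fwhmMm)
  new("LogFcdMap", grid = map@grid, values = vals, kind = map@kind,
      smoothed = TRUE)
}

#' Per-participant FCD pipeline
#'
#' Deterministic composition: gFCD and lFCD from one correlation pass,
#' long-range difference, log transforms, masked smoothing. The raw
#' count maps are returned alongside the smoothed log maps so they can
#' be checked against independent oracles.
#'
#' @inheritParams computeGfcd
#' @param smoothingFwhmMm FWHM for the masked smoothing of the log maps
#'   (default 8 mm).
#' @return list with elements `srfcd`, `lrfcd` (smoothed [LogFcdMap]s)
#'   and `gfcd`, `lfcd`, `longRange` (raw [DensityMap]s).
#' @export
participantFcd <- function(bold, mask, config = fcdConfig(),
                           smoothingFwhmMm = 8) {
  maps <- fcdDensityMaps(bold, mask, config)
  lr <- longRangeMap(maps$gfcd, maps$lfcd)
  sr <- smoothLogFcd(logFcd(maps$lfcd, config), smoothingFwhmMm)
  lrLog <- smoothLogFcd(logFcd(lr, config), smoothingFwhmMm)
  list(srfcd = sr, lrfcd = lrLog, gfcd = maps$gfcd, lfcd = maps$lfcd,
       longRange = lr)
}
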