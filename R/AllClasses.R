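#' @import methods
NULL

.GRID_TOL <- 1e-6

#' VolumeGrid: the sampling geometry of a volumetric image
#'
#' An axis-aligned voxel grid: the number of voxels per axis, the voxel
#' size in mm, and the spatial position (in mm) of the centre of the first
#' voxel. Voxel indices are 1-based, following R array conventions; the
#' centre of voxel (i, j, k) lies at `origin + (c(i, j, k) - 1) * voxelSize`.
#' Oblique orientations are not represented: every image entering an
#' analysis is assumed to live on one common grid.
#'
#' @slot shape integer(3), voxels per axis (all >= 1).
#' @slot voxelSize numeric(3), voxel edge length per axis in mm (all > 0).
#' @slot origin numeric(3), mm coordinate of the first voxel centre.
#' @export
setClass("VolumeGrid",
  representation(shape = "integer", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be 3 positive integers")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive reals (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite reals (mm)")
    TRUE
  })

#' Volume3D: a scalar volumetric image
#'
#' A 3D array of real values on a [VolumeGrid]. `NA` marks voxels where
#' the quantity is undefined (outside an analysis mask, or log-undefined);
#' missing values are propagated, never silently zero-filled.
#'
#' @slot grid a [VolumeGrid].
#' @slot values numeric 3D array matching the grid shape.
#' @export
setClass("Volume3D",
  representation(grid = "VolumeGrid", values = "array"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
      return("values array shape must equal grid shape")
    TRUE
  })

#' BoldSeries: a 4D BOLD-like time-series volume
#'
#' Per-voxel time series on a common grid, time as the last axis, with the
#' sampling interval (repetition time) in seconds.
#'
#' @slot grid a [VolumeGrid].
#' @slot data numeric 4D array, dims = c(grid shape, n timepoints).
#' @slot samplingInterval numeric(1), seconds between frames.
#' @export
setClass("BoldSeries",
  representation(grid = "VolumeGrid", data = "array",
                 samplingInterval = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L || !identical(d[1:3], as.integer(object@grid@shape)))
      return("data must be 4D with spatial dims equal to grid shape")
    if (length(object@samplingInterval) != 1L || object@samplingInterval <= 0)
      return("samplingInterval must be a single positive number of seconds")
    TRUE
  })

#' BrainMask: a boolean voxel-membership volume
#'
#' @slot grid a [VolumeGrid].
#' @slot membership logical 3D array; TRUE voxels belong to the mask.
#' @export
setClass("BrainMask",
  representation(grid = "VolumeGrid", membership = "array"),
  validity = function(object) {
    if (!is.logical(object@membership))
      return("membership must be a logical array")
    if (!identical(dim(object@membership), as.integer(object@grid@shape)))
      return("membership array shape must equal grid shape")
    if (anyNA(object@membership))
      return("membership must not contain NA")
    TRUE
  })

#' BrainParcellation: an integer label volume plus its label table
#'
#' Label 0 is background. Every nonzero label present in the volume must
#' have a row in the label table, which carries a display name, a grouping
#' (e.g. functional network or lobe), and whether the region is covered by
#' the spherical projection used for spin permutation (`spinnable`).
#'
#' @slot grid a [VolumeGrid].
#' @slot labels integer 3D array of region labels (0 = background).
#' @slot labelTable data.frame with columns label, name, group, spinnable.
#' @export
setClass("BrainParcellation",
  representation(grid = "VolumeGrid", labels = "array",
                 labelTable = "data.frame"),
  validity = function(object) {
    if (!identical(dim(object@labels), as.integer(object@grid@shape)))
      return("labels array shape must equal grid shape")
    if (anyNA(object@labels) || any(object@labels < 0))
      return("labels must be nonnegative integers without NA")
    need <- c("label", "name", "group", "spinnable")
    if (!all(need %in% names(object@labelTable)))
      return("labelTable must have columns label, name, group, spinnable")
    present <- setdiff(unique(as.integer(object@labels)), 0L)
    missing <- setdiff(present, object@labelTable$label)
    if (length(missing))
      return(paste("labels present in volume but absent from table:",
                   paste(missing, collapse = ", ")))
    if (anyDuplicated(object@labelTable$label))
      return("duplicate labels in labelTable")
    TRUE
  })

#' SuvrMap: a reference-normalized uptake ratio image
#'
#' Voxel values divided by the mean of a white-matter reference region;
#' `NA` outside the analysis domain. After `thresholdSuvr()` all present
#' values exceed the retention threshold (1 by default).
#'
#' @slot grid a [VolumeGrid].
#' @slot values numeric 3D array of unitless ratios (NA = missing).
#' @slot referenceMean numeric(1), the reference-region mean divided by.
#' @export
setClass("SuvrMap",
  contains = "Volume3D",
  representation(referenceMean = "numeric"),
  validity = function(object) {
    if (length(object@referenceMean) != 1L || object@referenceMean <= 0)
      return("referenceMean must be a single positive number")
    v <- object@values
    if (any(v[!is.na(v)] <= 0))
      return("all present SUVR values must be positive")
    TRUE
  })

#' DensityMap: voxel-wise raw FCD edge counts
#'
#' Nonnegative integer counts per masked voxel (`NA` outside the analysis
#' mask). `kind` records which centrality the counts measure: "lfcd"
#' (edges within the contiguous supra-threshold cluster), "gfcd" (all
#' supra-threshold edges), or "long_range" (their difference).
#'
#' @slot grid a [VolumeGrid].
#' @slot counts numeric 3D array of nonnegative integers (NA = missing).
#' @slot kind one of "lfcd", "gfcd", "long_range".
#' @export
setClass("DensityMap",
  representation(grid = "VolumeGrid", counts = "array", kind = "character"),
  validity = function(object) {
    if (!identical(dim(object@counts), as.integer(object@grid@shape)))
      return("counts array shape must equal grid shape")
    cc <- object@counts[!is.na(object@counts)]
    if (any(cc < 0) || any(cc != round(cc)))
      return("counts must be nonnegative integers")
    if (!object@kind %in% c("lfcd", "gfcd", "long_range"))
      return("kind must be one of lfcd, gfcd, long_range")
    TRUE
  })

#' LogFcdMap: a log-transformed (optionally smoothed) FCD map
#'
#' `srfcd` is log(lFCD); `lrfcd` is log(gFCD - lFCD). Voxels whose raw
#' count was 0 are missing under the default zero handling.
#'
#' @slot grid a [VolumeGrid].
#' @slot values numeric 3D array (NA = missing).
#' @slot kind one of "srfcd", "lrfcd", "log_gfcd".
#' @slot smoothed logical(1); whether spatial smoothing was applied.
#' @export
setClass("LogFcdMap",
  representation(grid = "VolumeGrid", values = "array", kind = "character",
                 smoothed = "logical"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
      return("values array shape must equal grid shape")
    if (!object@kind %in% c("srfcd", "lrfcd", "log_gfcd"))
      return("kind must be one of srfcd, lrfcd, log_gfcd")
    if (length(object@smoothed) != 1L || is.na(object@smoothed))
      return("smoothed must be TRUE or FALSE")
    TRUE
  })

#' FcdConfig: parameters of the FCD graph construction
#'
#' @slot correlationThreshold numeric(1) in (0, 1); the bound the pairwise
#'   temporal Pearson correlation must exceed for an edge (default 0.6).
#' @slot neighborhood integer(1); 6, 18 or 26 voxel adjacency used for
#'   "spatially connected" in the local-FCD cluster growing (default 26).
#' @slot countConvention "edges" (cluster size - 1) or "cluster_size".
#' @slot zeroHandling "mask_missing" (log of a zero count is missing) or
#'   "add_one" (log1p).
#' @export
setClass("FcdConfig",
  representation(correlationThreshold = "numeric", neighborhood = "integer",
                 countConvention = "character", zeroHandling = "character"),
  validity = function(object) {
    tc <- object@correlationThreshold
    if (length(tc) != 1L || tc <= 0 || tc >= 1)
      return("correlationThreshold must lie strictly between 0 and 1")
    if (!object@neighborhood %in% c(6L, 18L, 26L))
      return("neighborhood must be 6, 18 or 26")
    if (!object@countConvention %in% c("edges", "cluster_size"))
      return("countConvention must be 'edges' or 'cluster_size'")
    if (!object@zeroHandling %in% c("mask_missing", "add_one"))
      return("zeroHandling must be 'mask_missing' or 'add_one'")
    TRUE
  })

#' SphereMesh: a bilateral icosphere vertex mesh
#'
#' Unit-sphere vertices per hemisphere (an order-`order` subdivided
#' icosahedron, 10 * 4^order + 2 vertices per hemisphere), optionally
#' paired with volume-space mm coordinates for volume-to-vertex sampling.
#'
#' @slot vertices numeric matrix (n x 3) of unit vectors.
#' @slot hemisphere character vector, "L" or "R" per vertex.
#' @slot volumeCoord numeric matrix (n x 3) of mm coordinates (NA until
#'   the mesh is placed in a volume).
#' @slot order integer(1) subdivision order.
#' @export
setClass("SphereMesh",
  representation(vertices = "matrix", hemisphere = "character",
                 volumeCoord = "matrix", order = "integer"),
  validity = function(object) {
    n <- nrow(object@vertices)
    if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
    if (length(object@hemisphere) != n)
      return("hemisphere must have one entry per vertex")
    if (!all(object@hemisphere %in% c("L", "R")))
      return("hemisphere entries must be 'L' or 'R'")
    if (!identical(dim(object@volumeCoord), c(n, 3L)))
      return("volumeCoord must be n x 3")
    nrm <- sqrt(rowSums(object@vertices^2))
    if (any(abs(nrm - 1) > 1e-9))
      return("all vertex vectors must have unit norm (1e-9)")
    nh <- table(factor(object@hemisphere, levels = c("L", "R")))
    expect <- 10L * 4L^object@order + 2L
    if (any(nh != expect))
      return(sprintf("each hemisphere must have %d vertices at order %d",
                     expect, object@order))
    TRUE
  })

#' VertexMap: scalar values carried on a SphereMesh
#'
#' @slot mesh a [SphereMesh].
#' @slot values numeric vector, one per vertex (NA = missing).
#' @slot labels integer vector of region labels per vertex (0 allowed),
#'   or a zero-length vector when unlabeled.
#' @export
setClass("VertexMap",
  representation(mesh = "SphereMesh", values = "numeric", labels = "integer"),
  validity = function(object) {
    n <- nrow(object@mesh@vertices)
    if (length(object@values) != n)
      return("value count must equal vertex count")
    if (length(object@labels) != 0L && length(object@labels) != n)
      return("labels must be empty or one per vertex")
    TRUE
  })

#' SpinResult: outcome of a spin permutation test
#'
#' @slot observed numeric(1) observed statistic.
#' @slot nullStats numeric vector of permutation statistics.
#' @slot p numeric(1), #(null >= observed) / nPerm (one-sided).
#' @slot nPerm integer(1).
#' @slot seed integer(1).
#' @slot status character(1): "ok" or "not covered" (region excluded from
#'   the spherical projection; no p computed).
#' @export
setClass("SpinResult",
  representation(observed = "numeric", nullStats = "numeric", p = "numeric",
                 nPerm = "integer", seed = "integer", status = "character"),
  validity = function(object) {
    if (object@status == "ok") {
      if (length(object@nullStats) != object@nPerm)
        return("nullStats must have length nPerm")
      if (!is.na(object@p) && (object@p < 0 || object@p > 1))
        return("p must lie in [0, 1]")
    }
    TRUE
  })

#' AssociationResult: within-region SUVR-FCD association, pooled over
#' participants
#'
#' Per-participant Spearman correlations between paired voxel values,
#' Fisher z-transformed and pooled with a one-sample two-sided t test of
#' the z values against zero.
#'
#' @slot roi integer(1) region label (or 0 for a network-level result).
#' @slot unit character(1): "roi" or "network".
#' @slot name character(1) display name.
#' @slot metric character(1): which FCD metric was correlated with SUVR.
#' @slot rho numeric vector of per-participant Spearman correlations.
#' @slot z numeric vector of per-participant Fisher z values.
#' @slot meanZ numeric(1) mean of z.
#' @slot meanRho numeric(1) arithmetic mean of rho.
#' @slot meanRhoBack numeric(1) tanh(meanZ) (back-transformed pooled rho).
#' @slot pRaw numeric(1) two-sided t-test p of z against 0.
#' @slot bonferroniPassed logical(1) (NA until the correction step runs).
#' @slot pSpin numeric(1) spin p (NA until the spin step runs).
#' @slot spinStatus character(1): "pending", "ok", "not covered", "skipped".
#' @slot nVoxels integer vector, per-participant voxel counts used.
#' @export
setClass("AssociationResult",
  representation(roi = "integer", unit = "character", name = "character",
                 metric = "character", rho = "numeric", z = "numeric",
                 meanZ = "numeric", meanRho = "numeric",
                 meanRhoBack = "numeric", pRaw = "numeric",
                 bonferroniPassed = "logical", pSpin = "numeric",
                 spinStatus = "character", nVoxels = "integer"),
  validity = function(object) {
    if (any(abs(object@rho) > 1 + 1e-12))
      return("per-participant rho must lie in [-1, 1]")
    if (length(object@rho) != length(object@z))
      return("rho and z must have equal length")
    if (!is.na(object@pRaw) && (object@pRaw < 0 || object@pRaw > 1))
      return("pRaw must lie in [0, 1]")
    TRUE
  })

#' SyntheticConfig: parameters of the synthetic study generator
#'
#' Defines a spherical-shell "head": a white-matter core, a gray-matter
#' shell, and hub regions (balls) inside the shell whose voxels share
#' latent BOLD signal. Long-range pairs add a second latent shared across
#' two spatially disjoint hubs.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot voxelSizeMm numeric(1) isotropic voxel size in mm.
#' @slot nTimepoints integer(1) BOLD frames per participant.
#' @slot samplingInterval numeric(1) seconds.
#' @slot nParticipants integer(1).
#' @slot hubs data.frame with columns cx, cy, cz (centre voxel, 1-based),
#'   radius (voxels), rhoWithin (within-hub pairwise correlation).
#' @slot pairs data.frame with columns a, b (hub indices) and rhoBetween.
#' @slot beta numeric(1) >= 0, coupling between planted total degree and
#'   the molecular (SUVR-like) volume.
#' @slot suvrNoiseSd numeric(1) voxel noise SD of the molecular volume.
#' @slot bandLowHz,bandHighHz numeric(1) passband applied to all latent
#'   and noise series before mixing.
#' @slot noiseSmoothFwhmVox numeric(1) FWHM (voxels) of the spatial
#'   smoothing applied to the noise field, emulating the intrinsic
#'   spatial smoothness of BOLD; 0 gives strictly independent voxel
#'   noise.
#' @slot wmCoreRadius,gmInnerRadius,gmOuterRadius numeric(1) tissue
#'   geometry in voxels from the grid centre.
#' @slot seed integer(1) master seed.
#' @export
setClass("SyntheticConfig",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 nTimepoints = "integer", samplingInterval = "numeric",
                 nParticipants = "integer", hubs = "data.frame",
                 pairs = "data.frame", beta = "numeric",
                 suvrNoiseSd = "numeric", bandLowHz = "numeric",
                 bandHighHz = "numeric", noiseSmoothFwhmVox = "numeric",
                 wmCoreRadius = "numeric",
                 gmInnerRadius = "numeric", gmOuterRadius = "numeric",
                 seed = "integer"),
  validity = function(object) .validateSyntheticConfig(object))

#' GroundTruth: planted centrality exposed by the generator
#'
#' @slot plantedLocalDegree integer 3D array: hub size - 1 inside a hub,
#'   0 outside.
#' @slot plantedLongDegree integer 3D array: sum of partner-hub sizes for
#'   voxels of long-range-paired hubs, 0 otherwise.
#' @slot beta numeric(1) coupling used.
#' @slot participantSeeds integer vector of per-participant seeds.
#' @export
setClass("GroundTruth",
  representation(plantedLocalDegree = "array", plantedLongDegree = "array",
                 beta = "numeric", participantSeeds = "integer"))

#' StudyConfig: configuration of an end-to-end study run
#'
#' @slot synthetic a [SyntheticConfig] (simulate mode).
#' @slot fcd an [FcdConfig].
#' @slot alpha numeric(1) family-wise level (default 0.05).
#' @slot mTests integer(1) Bonferroni divisor; NA means "number of ROIs +
#'   number of networks" taken from the study design.
#' @slot nPerm integer(1) spin permutations.
#' @slot meshOrder integer(1) icosphere subdivision used for spin tests.
#' @slot smoothingFwhmMm numeric(1) smoothing applied to SUVR and log-FCD.
#' @slot suvrMin numeric(1) SUVR retention threshold.
#' @slot gmThreshold numeric(1) gray-matter probability threshold.
#' @slot seed integer(1).
#' @export
setClass("StudyConfig",
  representation(synthetic = "SyntheticConfig", fcd = "FcdConfig",
                 alpha = "numeric", mTests = "integer", nPerm = "integer",
                 meshOrder = "integer", smoothingFwhmMm = "numeric",
                 suvrMin = "numeric", gmThreshold = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@alpha <= 0 || object@alpha >= 1)
      return("alpha must lie strictly between 0 and 1")
    if (object@nPerm < 1L) return("nPerm must be >= 1")
    TRUE
  })

#' StudyReport: all results of one end-to-end study
#'
#' @slot wholeMap data.frame of across-ROI whole-map associations.
#' @slot roiTable data.frame, one row per (region/network, metric).
#' @slot secondLevel data.frame of FCD-magnitude vs coupling correlations.
#' @slot normality data.frame of normality-check statistics.
#' @slot meanMaps list of group-mean maps (suvr, srfcd, lrfcd).
#' @slot groundTruth the [GroundTruth] (simulate mode).
#' @slot manifest list: config echo, seeds, package version.
#' @export
setClass("StudyReport",
  representation(wholeMap = "data.frame", roiTable = "data.frame",
                 secondLevel = "data.frame", normality = "data.frame",
                 meanMaps = "list", groundTruth = "ANY", manifest = "list"))
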