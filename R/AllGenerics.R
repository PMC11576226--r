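#' Grid accessor
#'
#' Returns the [VolumeGrid] a gridded object is sampled on.
#' @param x a gridded object.
#' @return a [VolumeGrid].
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' Voxel/vertex value accessor
#'
#' Returns the scalar values an image-like object carries: a 3D array for
#' volumes, a 4D array for BOLD series, a logical array for masks, an
#' integer array for parcellations, and a vector for vertex maps.
#' @param x an image-like object.
#' @return array or vector of values.
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @describeIn imageGrid grid of a 3D volume
setMethod("imageGrid", "Volume3D", function(x) x@grid)
#' @describeIn imageGrid grid of a BOLD series
setMethod("imageGrid", "BoldSeries", function(x) x@grid)
#' @describeIn imageGrid grid of a mask
setMethod("imageGrid", "BrainMask", function(x) x@grid)
#' @describeIn imageGrid grid of a parcellation
setMethod("imageGrid", "BrainParcellation", function(x) x@grid)
#' @describeIn imageGrid grid of a density map
setMethod("imageGrid", "DensityMap", function(x) x@grid)
#' @describeIn imageGrid grid of a log-FCD map
setMethod("imageGrid", "LogFcdMap", function(x) x@grid)

#' @describeIn voxelValues values of a 3D volume
setMethod("voxelValues", "Volume3D", function(x) x@values)
#' @describeIn voxelValues 4D data of a BOLD series
setMethod("voxelValues", "BoldSeries", function(x) x@data)
#' @describeIn voxelValues membership of a mask
setMethod("voxelValues", "BrainMask", function(x) x@membership)
#' @describeIn voxelValues labels of a parcellation
setMethod("voxelValues", "BrainParcellation", function(x) x@labels)
#' @describeIn voxelValues counts of a density map
setMethod("voxelValues", "DensityMap", function(x) x@counts)
#' @describeIn voxelValues values of a log-FCD map
setMethod("voxelValues", "LogFcdMap", function(x) x@values)
#' @describeIn voxelValues values of a vertex map
setMethod("voxelValues", "VertexMap", function(x) x@values)

#' Number of timepoints in a BOLD series
#' @param x a [BoldSeries].
#' @return integer(1).
#' @export
nTimepoints <- function(x) {
  stopifnot(is(x, "BoldSeries"))
  dim(x@data)[4L]
}

#' Sampling interval of a BOLD series, seconds
#' @param x a [BoldSeries].
#' @return numeric(1).
#' @export
samplingInterval <- function(x) {
  stopifnot(is(x, "BoldSeries"))
  x@samplingInterval
}

#' Label table of a parcellation
#' @param x a [BrainParcellation].
#' @return data.frame with columns label, name, group, spinnable.
#' @export
labelTable <- function(x) {
  stopifnot(is(x, "BrainParcellation"))
  x@labelTable
}

#' Region labels present in a parcellation volume
#' @param x a [BrainParcellation].
#' @return sorted integer vector of nonzero labels.
#' @export
regionLabels <- function(x) {
  stopifnot(is(x, "BrainParcellation"))
  sort(setdiff(unique(as.integer(x@labels)), 0L))
}

#' Reference-region mean recorded in a SUVR map
#' @param x a [SuvrMap].
#' @return numeric(1).
#' @export
referenceMean <- function(x) {
  stopifnot(is(x, "SuvrMap"))
  x@referenceMean
}

#' Kind of an FCD map ("lfcd", "gfcd", "long_range", "srfcd", "lrfcd")
#' @param x a [DensityMap] or [LogFcdMap].
#' @return character(1).
#' @export
fcdKind <- function(x) {
  stopifnot(is(x, "DensityMap") || is(x, "LogFcdMap"))
  x@kind
}

#' Spin p-value of a SpinResult
#' @param x a [SpinResult].
#' @return numeric(1) (NA when the region is not covered).
#' @export
spinP <- function(x) {
  stopifnot(is(x, "SpinResult"))
  x@p
}

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid %s voxels, %s mm, origin (%s) mm\n",
              paste(object@shape, collapse = "x"),
              paste(signif(object@voxelSize, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", ")))
})

setMethod("show", "Volume3D", function(object) {
  v <- object@values
  cat(sprintf("%s on %s voxels (%s mm); %d present, %d missing\n",
              class(object), paste(object@grid@shape, collapse = "x"),
              paste(signif(object@grid@voxelSize, 4), collapse = "x"),
              sum(!is.na(v)), sum(is.na(v))))
})

setMethod("show", "BoldSeries", function(object) {
  cat(sprintf("BoldSeries %s voxels x %d frames, TR %.3g s\n",
              paste(object@grid@shape, collapse = "x"),
              dim(object@data)[4L], object@samplingInterval))
})

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask %s: %d voxels in mask\n",
              paste(object@grid@shape, collapse = "x"),
              sum(object@membership)))
})

setMethod("show", "BrainParcellation", function(object) {
  cat(sprintf("BrainParcellation %s: %d regions, %d labeled voxels\n",
              paste(object@grid@shape, collapse = "x"),
              length(regionLabels(object)), sum(object@labels > 0L)))
})

setMethod("show", "DensityMap", function(object) {
  cc <- object@counts[!is.na(object@counts)]
  cat(sprintf("DensityMap (%s) %s: %d masked voxels, count range [%s, %s]\n",
              object@kind, paste(object@grid@shape, collapse = "x"),
              length(cc),
              if (length(cc)) min(cc) else NA, if (length(cc)) max(cc) else NA))
})

setMethod("show", "LogFcdMap", function(object) {
  cat(sprintf("LogFcdMap (%s%s) %s: %d present voxels\n",
              object@kind, if (object@smoothed) ", smoothed" else "",
              paste(object@grid@shape, collapse = "x"),
              sum(!is.na(object@values))))
})

setMethod("show", "SphereMesh", function(object) {
  cat(sprintf("SphereMesh order %d: %d vertices (%d per hemisphere)%s\n",
              object@order, nrow(object@vertices),
              sum(object@hemisphere == "L"),
              if (all(is.na(object@volumeCoord))) "" else ", placed in volume"))
})

setMethod("show", "SpinResult", function(object) {
  if (object@status == "ok")
    cat(sprintf("SpinResult: observed %.4g, p = %.4g (%d permutations)\n",
                object@observed, object@p, object@nPerm))
  else
    cat(sprintf("SpinResult: %s\n", object@status))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf(
    "AssociationResult %s '%s' (%s): mean z %.3f, p %.3g, n = %d participants\n",
    object@unit, object@name, object@metric, object@meanZ, object@pRaw,
    length(object@rho)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %s grid, %d frames @ %.2g s, %d participants, %d hubs, %d long-range pairs, beta %.3g\n",
    paste(object@gridShape, collapse = "x"), object@nTimepoints,
    object@samplingInterval, object@nParticipants, nrow(object@hubs),
    nrow(object@pairs), object@beta))
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  cat(sprintf("  whole-map associations: %d\n", nrow(object@wholeMap)))
  cat(sprintf("  region/network rows:    %d\n", nrow(object@roiTable)))
  cat(sprintf("  second-level rows:      %d\n", nrow(object@secondLevel)))
})
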