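# Grid construction and compatibility checks. All analyses in this package
# assume every input shares one axis-aligned grid; nothing here resamples
# between grids (the only resampler lives in the spin module and targets a
# finer isotropic grid).

#' Construct a VolumeGrid
#'
#' @param shape integer(3) voxels per axis.
#' @param voxelSize numeric(3) or numeric(1) voxel size in mm.
#' @param origin numeric(3) mm coordinate of the first voxel centre.
#' @return a [VolumeGrid].
#' @examples
#' volumeGrid(c(24, 24, 24), 2)
#' @export
volumeGrid <- function(shape, voxelSize = 1, origin = c(0, 0, 0)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("VolumeGrid", shape = as.integer(shape),
      voxelSize = as.numeric(voxelSize), origin = as.numeric(origin))
}

#' Construct a Volume3D
#'
#' @param values numeric 3D array (NA = missing).
#' @param grid a [VolumeGrid]; defaults to a unit grid matching `values`.
#' @return a [Volume3D].
#' @export
volume3D <- function(values, grid = NULL) {
  values <- asVolumeArray(values)
  if (is.null(grid)) grid <- volumeGrid(dim(values))
  new("Volume3D", grid = grid, values = values)
}

#' Construct a BoldSeries
#'
#' @param data numeric 4D array, time last.
#' @param samplingInterval numeric(1) seconds between frames.
#' @param grid a [VolumeGrid]; defaults to a unit grid.
#' @return a [BoldSeries].
#' @export
boldSeries <- function(data, samplingInterval, grid = NULL) {
  stopifnot(length(dim(data)) == 4L)
  if (is.null(grid)) grid <- volumeGrid(dim(data)[1:3])
  new("BoldSeries", grid = grid, data = data,
      samplingInterval = as.numeric(samplingInterval))
}

#' Construct a BrainMask
#'
#' @param membership logical 3D array.
#' @param grid a [VolumeGrid]; defaults to a unit grid.
#' @return a [BrainMask].
#' @export
brainMask <- function(membership, grid = NULL) {
  storage.mode(membership) <- "logical"
  membership <- asVolumeArray(membership)
  if (is.null(grid)) grid <- volumeGrid(dim(membership))
  new("BrainMask", grid = grid, membership = membership)
}

asVolumeArray <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected a 3D array")
  x
}

#' Are two grids compatible?
#'
#' Two grids are compatible iff shape is identical and voxel size and
#' origin agree within `tol` mm.
#' @param a,b [VolumeGrid] objects.
#' @param tol numeric(1) mm tolerance.
#' @return logical(1).
#' @export
gridsCompatible <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    all(abs(a@voxelSize - b@voxelSize) <= tol) &&
    all(abs(a@origin - b@origin) <= tol)
}

#' Enforce grid compatibility across gridded objects
#'
#' Passes silently iff every object's grid equals the first one's (shape
#' identical; voxel size and origin within `tol` mm). The first
#' incompatible pair is reported with both grids.
#'
#' @param items list of gridded objects (anything with an [imageGrid()]
#'   method) or [VolumeGrid]s.
#' @param tol numeric(1) mm tolerance.
#' @return invisibly TRUE.
#' @export
checkGridCompatibility <- function(items, tol = 1e-6) {
  if (!is.list(items) || length(items) == 0L)
    stop("items must be a nonempty list of gridded objects")
  grids <- lapply(items, function(x) if (is(x, "VolumeGrid")) x else imageGrid(x))
  ref <- grids[[1L]]
  for (i in seq_along(grids)[-1L]) {
    if (!gridsCompatible(ref, grids[[i]], tol = tol)) {
      fmt <- function(g) sprintf("shape %s, voxel %s mm, origin (%s) mm",
                                 paste(g@shape, collapse = "x"),
                                 paste(signif(g@voxelSize, 8), collapse = "x"),
                                 paste(signif(g@origin, 8), collapse = ", "))
      stop(sprintf("incompatible grids: item 1 [%s] vs item %d [%s]",
                   fmt(ref), i, fmt(grids[[i]])))
    }
  }
  invisible(TRUE)
}

#' Voxel-centre mm coordinates of grid indices
#'
#' @param grid a [VolumeGrid].
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxelToMm <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, grid@voxelSize, "*"), 2L, grid@origin, "+")
}

# Integer voxel coordinates (n x 3) of TRUE/masked entries, column-major.
maskCoords <- function(membership) {
  which(membership, arr.ind = TRUE)
}
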