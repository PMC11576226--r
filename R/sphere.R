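# Icosphere meshes and volume-to-vertex sampling.
#
# A hemisphere mesh is a regular icosahedron subdivided `order` times and
# projected to the unit sphere (10 * 4^order + 2 vertices; order 5 gives
# the familiar 10,242-vertex spherical surface). The bilateral mesh
# duplicates the pattern with hemisphere tags; volume-space coordinates
# are attached separately so synthetic shells and file-supplied meshes
# use the same machinery.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivideOnce <- function(vertices, faces) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vertices
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b), sep = ":")
    hit <- get0(key, envir = env)
    if (!is.null(hit)) return(hit)
    m <- verts[a, ] + verts[b, ]
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    idx <- nrow(verts)
    assign(key, idx, envir = env)
    idx
  }
  newFaces <- matrix(0L, nrow(faces) * 4L, 3L)
  for (i in seq_len(nrow(faces))) {
    a <- faces[i, 1L]; b <- faces[i, 2L]; c <- faces[i, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newFaces[(i - 1L) * 4L + 1:4, ] <-
      rbind(c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = verts, faces = newFaces)
}

#' Build a bilateral icosphere mesh
#'
#' Subdivides a regular icosahedron `order` times, projecting new
#' vertices to the unit sphere after each split, with deterministic
#' vertex ordering (creation order). The hemisphere pattern is duplicated
#' with "L" and "R" tags; order 5 yields 10,242 vertices per hemisphere
#' (20,484 bilaterally).
#'
#' @param order integer in \[0, 7\].
#' @return a [SphereMesh] with unplaced (`NA`) volume coordinates.
#' @export
buildIcosphere <- function(order) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 0L || order > 7L)
    stop("order must lie in [0, 7]")
  ico <- icosahedron()
  for (k in seq_len(order)) ico <- subdivideOnce(ico$vertices, ico$faces)
  v <- ico$vertices
  v <- v / sqrt(rowSums(v^2))
  n <- nrow(v)
  new("SphereMesh",
      vertices = rbind(v, v),
      hemisphere = rep(c("L", "R"), each = n),
      volumeCoord = matrix(NA_real_, 2L * n, 3L),
      order = order)
}

#' Attach volume-space coordinates to a sphere mesh
#'
#' Places each hemisphere on a spherical shell of radius `radiusMm`
#' centred at `centerMm`; the left hemisphere is mirrored sagittally
#' (x negated) so the two hemispheres occupy mirror-image positions, as
#' on a real cortical surface.
#'
#' @param mesh a [SphereMesh].
#' @param centerMm numeric(3) shell centre, mm.
#' @param radiusMm numeric(1) shell radius, mm.
#' @return the mesh with `volumeCoord` filled in.
#' @export
placeMeshInVolume <- function(mesh, centerMm, radiusMm) {
  stopifnot(is(mesh, "SphereMesh"), length(centerMm) == 3L, radiusMm > 0)
  v <- mesh@vertices
  left <- mesh@hemisphere == "L"
  v[left, 1L] <- -v[left, 1L]
  vc <- sweep(v * radiusMm, 2L, centerMm, "+")
  initialize(mesh, volumeCoord = vc)
}

#' Sample a volume at mesh vertices
#'
#' The volume is conceptually resampled to a 1 mm isotropic grid by
#' trilinear interpolation (1 mm voxel centres aligned with the original
#' origin), and each vertex reads the value of the 1 mm voxel containing
#' its mm coordinate — a nearest-voxel read on the fine grid. With
#' `interpolation = "nearest"` the original voxel nearest to that point
#' is read instead (for label volumes). Missing volume values propagate
#' to missing vertex values.
#'
#' @param vol a [Volume3D] (or subclass, or [LogFcdMap]).
#' @param mesh a [SphereMesh] with volume coordinates inside the volume.
#' @param interpolation "trilinear" (default) or "nearest".
#' @return a [VertexMap].
#' @export
sampleVolumeAtVertices <- function(vol, mesh,
                                   interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is(mesh, "SphereMesh"))
  grid <- imageGrid(vol)
  vals <- voxelValues(vol)
  storage.mode(vals) <- "double"
  if (any(is.na(mesh@volumeCoord)))
    stop("mesh has no volume coordinates; call placeMeshInVolume first")
  # snap each vertex to the centre of its containing 1 mm voxel
  snapped <- sweep(round(sweep(mesh@volumeCoord, 2L, grid@origin, "-")),
                   2L, grid@origin, "+")
  # continuous 1-based voxel coordinates in the original grid
  u <- sweep(sweep(snapped, 2L, grid@origin, "-"), 2L, grid@voxelSize, "/") + 1
  lo <- floor(u)
  if (any(lo < 1 - 1e-9) || any(lo + 1 > grid@shape + 1e-9)) {
    if (any(u < 1 - 1e-9) || any(u > grid@shape + 1e-9))
      stop("vertex coordinate falls outside the volume")
    lo <- pmin(pmax(lo, 1), matrix(rep(grid@shape - 1L, each = nrow(u)),
                                   ncol = 3L))
  }
  out <- if (interpolation == "nearest") {
    ui <- pmin(pmax(round(u), 1), matrix(rep(grid@shape, each = nrow(u)),
                                         ncol = 3L))
    vals[ui]
  } else {
    f <- u - lo
    acc <- numeric(nrow(u))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[, 1L] else 1 - f[, 1L]) *
           (if (dy) f[, 2L] else 1 - f[, 2L]) *
           (if (dz) f[, 3L] else 1 - f[, 3L])
      corner <- cbind(lo[, 1L] + dx, lo[, 2L] + dy, lo[, 3L] + dz)
      cv <- vals[corner]
      contrib <- w * cv
      contrib[w <= 1e-12] <- 0            # zero-weight corners never count
      acc <- acc + contrib
    }
    acc
  }
  if (all(is.na(out))) stop("all vertex samples are missing")
  new("VertexMap", mesh = mesh, values = as.numeric(out),
      labels = integer(0))
}

#' Sample parcellation labels at mesh vertices
#'
#' Nearest-voxel lookup of the label volume, returned as a [VertexMap]
#' whose `labels` slot carries the region label per vertex.
#'
#' @param parc a [BrainParcellation].
#' @param mesh a placed [SphereMesh].
#' @return a [VertexMap] with integer labels (values mirror the labels).
#' @export
sampleParcellationAtVertices <- function(parc, mesh) {
  lv <- new("Volume3D", grid = parc@grid,
            values = array(as.double(parc@labels), dim = dim(parc@labels)))
  vm <- sampleVolumeAtVertices(lv, mesh, interpolation = "nearest")
  lab <- as.integer(round(vm@values))
  new("VertexMap", mesh = mesh, values = as.numeric(lab), labels = lab)
}

#' Smooth Gaussian random field on a sphere mesh
#'
#' Zero-mean Gaussian field per hemisphere with squared-exponential
#' covariance in chordal distance,
#' `cov(v_i, v_j) = exp(-(c_ij / correlationLength)^2 / 2)` with
#' `c_ij = 2 sin(theta_ij / 2)` — a positive-definite kernel on the
#' sphere whose covariance decays monotonically with the great-circle
#' distance `theta_ij` (and matches it closely at short range).
#' Hemispheres receive independent fields from one seeded stream.
#' Used as a spatially autocorrelated null input when calibrating the
#' spin permutation test.
#'
#' @param mesh a [SphereMesh] (order <= 4 is practical; the covariance
#'   factorization is cubic in the vertex count).
#' @param correlationLength numeric(1) > 0, radians.
#' @param seed integer(1).
#' @return a [VertexMap].
#' @export
generateSmoothVertexMap <- function(mesh, correlationLength, seed) {
  stopifnot(is(mesh, "SphereMesh"), correlationLength > 0)
  set.seed(as.integer(seed))
  vals <- numeric(nrow(mesh@vertices))
  for (h in c("L", "R")) {
    sel <- mesh@hemisphere == h
    V <- mesh@vertices[sel, , drop = FALSE]
    cosang <- pmin(pmax(V %*% t(V), -1), 1)
    chord <- 2 * sin(acos(cosang) / 2)
    K <- exp(-(chord / correlationLength)^2 / 2)
    U <- chol(K + diag(1e-8, nrow(K)))
    vals[sel] <- as.numeric(t(U) %*% stats::rnorm(nrow(K)))
  }
  new("VertexMap", mesh = mesh, values = vals, labels = integer(0))
}

# Exact nearest-neighbor lookup on unit vectors (max dot product),
# chunked over query rows to bound memory; ties resolve to the lowest
# reference index.
nearestVertexIndex <- function(query, ref, chunk = 2048L) {
  n <- nrow(query)
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    D <- query[rows, , drop = FALSE] %*% t(ref)
    out[rows] <- max.col(D, ties.method = "first")
  }
  out
}
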