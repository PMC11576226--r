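# Spin-based spatial permutation testing.
#
# A null map is produced by rotating the spherical projection of a map by
# angles drawn independently and uniformly on [0, 2pi) about the x, y and
# z axes (exactly the printed recipe; this Euler-angle product is not the
# Haar-uniform measure on rotations — `haar = TRUE` draws Haar-uniform
# rotations for sensitivity analysis). Each vertex then receives the
# value of the original vertex nearest to its rotated position; the left
# hemisphere uses the sagittally mirrored rotation by default. Because
# the null maps share the spatial autocorrelation of the observed map,
# the permutation p-value is calibrated for smooth fields where a naive
# value shuffle is anti-conservative.

rotationFromAngles <- function(angles) {
  a <- angles[1L]; b <- angles[2L]; g <- angles[3L]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

haarRotation <- function() {
  # QR of a Gaussian matrix with sign fix, det forced to +1
  M <- matrix(stats::rnorm(9), 3L, 3L)
  qr <- qr(M)
  Q <- qr.Q(qr)
  Q <- Q %*% diag(sign(diag(qr.R(qr))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Draw the rotation for one permutation
#'
#' Deterministic given `(seed, draw)`: the seeded stream yields three
#' angles per draw, and draw `k` uses the k-th triple, so permutation
#' sequences are reproducible and extendable.
#'
#' @param seed integer(1).
#' @param draw integer(1) >= 1, index of the permutation.
#' @param haar logical(1); draw a Haar-uniform rotation instead of the
#'   per-axis uniform Euler angles.
#' @return a 3 x 3 rotation matrix (orthogonal, det +1).
#' @export
randomRotation <- function(seed, draw, haar = FALSE) {
  stopifnot(draw >= 1L)
  set.seed(as.integer(seed))
  if (haar) {
    if (draw > 1L) for (k in seq_len(draw - 1L)) haarRotation()
    return(haarRotation())
  }
  angles <- stats::runif(3L * draw, 0, 2 * pi)
  rotationFromAngles(angles[(3L * draw - 2L):(3L * draw)])
}

# All rotations for a permutation run, sharing randomRotation's stream.
spinRotations <- function(seed, nPerm, haar = FALSE) {
  set.seed(as.integer(seed))
  if (haar) {
    lapply(seq_len(nPerm), function(k) haarRotation())
  } else {
    angles <- matrix(stats::runif(3L * nPerm, 0, 2 * pi), ncol = 3L,
                     byrow = TRUE)
    lapply(seq_len(nPerm), function(k) rotationFromAngles(angles[k, ]))
  }
}

#' Apply a spin (rotation + nearest-vertex reassignment) to a vertex map
#'
#' Each vertex receives the value of the original vertex (same
#' hemisphere) nearest to its rotated position on the unit sphere. The
#' right hemisphere uses `rotation`; the left uses the sagittal mirror
#' `M %*% rotation %*% M` with `M = diag(-1, 1, 1)` unless
#' `mirrorLeft = FALSE`. Missing values travel with their vertices.
#'
#' @param map a [VertexMap].
#' @param rotation 3 x 3 rotation matrix.
#' @param mirrorLeft logical(1), default TRUE.
#' @return a spun [VertexMap].
#' @export
applySpin <- function(map, rotation, mirrorLeft = TRUE) {
  stopifnot(is(map, "VertexMap"))
  mesh <- map@mesh
  vals <- numeric(length(map@values))
  M <- diag(c(-1, 1, 1))
  for (h in c("L", "R")) {
    sel <- mesh@hemisphere == h
    V <- mesh@vertices[sel, , drop = FALSE]
    R <- if (h == "L" && mirrorLeft) M %*% rotation %*% M else rotation
    rotated <- V %*% t(R)
    idx <- nearestVertexIndex(rotated, V)
    vals[sel] <- map@values[which(sel)][idx]
  }
  new("VertexMap", mesh = mesh, values = vals, labels = map@labels)
}

vertexStatistic <- function(a, b, statistic) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (statistic == "spearman") stats::cor(a[ok], b[ok], method = "spearman")
  else stats::cor(a[ok], b[ok])
}

#' Spin permutation p-value for the correlation of two vertex maps
#'
#' The observed statistic correlates the two maps over the restriction
#' (all non-missing vertex pairs by default). For each permutation,
#' `mapA` is spun over the whole sphere and the statistic is recomputed
#' on the restriction; the one-sided p-value is the number of null
#' statistics at least as large as the observed one, divided by `nPerm`
#' (null ties count against the hypothesis). `addOne = TRUE` uses the
#' (k+1)/(n+1) variant instead.
#'
#' @param mapA,mapB [VertexMap]s on the same mesh; only `mapA` is spun.
#' @param nPerm integer(1) >= 1 permutations (default 1000).
#' @param seed integer(1).
#' @param statistic "spearman" (default) or "pearson".
#' @param restrict optional integer vector of vertex indices defining the
#'   region over which the statistic is computed (rotation stays global).
#' @param mirrorLeft passed to [applySpin()].
#' @param haar draw Haar-uniform rotations instead of per-axis uniform
#'   Euler angles.
#' @param addOne logical(1), default FALSE.
#' @return a [SpinResult].
#' @export
spinPvalue <- function(mapA, mapB, nPerm = 1000, seed = 1,
                       statistic = c("spearman", "pearson"),
                       restrict = NULL, mirrorLeft = TRUE, haar = FALSE,
                       addOne = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(is(mapA, "VertexMap"), is(mapB, "VertexMap"))
  if (nrow(mapA@mesh@vertices) != nrow(mapB@mesh@vertices))
    stop("maps live on different meshes")
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  n <- length(mapA@values)
  if (is.null(restrict)) restrict <- seq_len(n)
  a <- mapA@values[restrict]
  b <- mapB@values[restrict]
  if (sum(!is.na(a) & !is.na(b)) < 10L)
    stop("need at least 10 non-missing paired vertices")
  observed <- vertexStatistic(a, b, statistic)
  rots <- spinRotations(seed, nPerm, haar = haar)
  nullStats <- vapply(rots, function(R) {
    spun <- applySpin(mapA, R, mirrorLeft = mirrorLeft)
    vertexStatistic(spun@values[restrict], b, statistic)
  }, numeric(1))
  k <- sum(nullStats >= observed, na.rm = TRUE)
  p <- if (addOne) (k + 1) / (nPerm + 1) else k / nPerm
  new("SpinResult", observed = observed, nullStats = nullStats, p = p,
      nPerm = nPerm, seed = as.integer(seed), status = "ok")
}

#' Spin test restricted to one region
#'
#' Runs [spinPvalue()] with the restriction set to the vertices carrying
#' the requested label; the rotation is still global. Regions flagged
#' `spinnable = FALSE` in the label table (areas the spherical projection
#' does not cover, such as subcortex or cerebellum) are skipped with an
#' explicit "not covered" status unless `force = TRUE`.
#'
#' @param mapA,mapB [VertexMap]s on one mesh.
#' @param labels a [VertexMap] whose `labels` slot holds per-vertex
#'   region labels (see [sampleParcellationAtVertices()]).
#' @param roi integer(1) region label.
#' @param labelTable data.frame with columns label and spinnable; if
#'   omitted every region is treated as spinnable.
#' @param nPerm,seed,statistic,mirrorLeft,haar,addOne as in
#'   [spinPvalue()].
#' @param force logical(1); run even for a non-spinnable region.
#' @return a [SpinResult] (status "not covered" carries no p-value).
#' @export
spinTestRoi <- function(mapA, mapB, labels, roi, labelTable = NULL,
                        nPerm = 1000, seed = 1,
                        statistic = c("spearman", "pearson"),
                        mirrorLeft = TRUE, haar = FALSE, addOne = FALSE,
                        force = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(is(labels, "VertexMap"))
  if (length(labels@labels) == 0L)
    stop("labels vertex map carries no labels")
  if (!is.null(labelTable)) {
    row <- labelTable[labelTable$label == roi, , drop = FALSE]
    if (nrow(row) == 1L && !isTRUE(row$spinnable) && !force) {
      return(new("SpinResult", observed = NA_real_, nullStats = numeric(0),
                 p = NA_real_, nPerm = as.integer(nPerm),
                 seed = as.integer(seed), status = "not covered"))
    }
  }
  restrict <- which(labels@labels == roi)
  if (length(restrict) < 10L)
    stop("fewer than 10 vertices carry label ", roi)
  spinPvalue(mapA, mapB, nPerm = nPerm, seed = seed, statistic = statistic,
             restrict = restrict, mirrorLeft = mirrorLeft, haar = haar,
             addOne = addOne)
}
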