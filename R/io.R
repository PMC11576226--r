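# Volumetric and tabular input/output. Volumes are NIfTI-1 (.nii/.nii.gz)
# read and written through RNifti; tables are tab-separated UTF-8 with a
# header row; sphere meshes use a plain-text one-vertex-per-line format.

#' Read a 3D or 4D NIfTI volume
#'
#' 3D images return a [Volume3D]; 4D images return a [BoldSeries] with
#' time as the last axis and the sampling interval taken from the time
#' pixdim. `NaN` voxels become missing (`NA`). Only axis-aligned,
#' positively oriented affines are supported: once all inputs share a
#' grid the analysis is orientation-free, so oblique headers are rejected
#' rather than silently reinterpreted.
#'
#' @param path file path of a `.nii` or `.nii.gz` image.
#' @return a [Volume3D] or [BoldSeries].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop(sprintf("expected a 3D or 4D image, got %d dimensions in %s",
                 length(d), path))
  grid <- gridFromNifti(img)
  vals <- array(as.numeric(img), dim = d)   # strip the NIfTI attributes
  vals[is.nan(vals)] <- NA_real_
  if (length(d) == 3L) {
    new("Volume3D", grid = grid, values = vals)
  } else {
    tr <- RNifti::pixdim(img)
    tr <- if (length(tr) >= 4L && tr[4L] > 0) tr[4L] else 1
    new("BoldSeries", grid = grid, data = vals, samplingInterval = tr)
  }
}

gridFromNifti <- function(img) {
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop("oblique or axis-permuted orientations are not supported")
  if (any(diag(rot) <= 0))
    stop("negatively oriented axes are not supported")
  volumeGrid(dim(img)[1:3], diag(rot), aff[1:3, 4])
}

#' Write a volume or 4D series as NIfTI
#'
#' Missing voxels are stored as `NaN`. Values are stored in double
#' precision so integer count maps round-trip exactly. The grid is
#' recorded in both the sform and qform.
#'
#' @param vol a [Volume3D], [SuvrMap], [DensityMap], [LogFcdMap],
#'   [BrainMask], [BrainParcellation] or [BoldSeries].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory
#'   must exist.
#' @return invisibly `path`.
#' @export
writeVolume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  grid <- imageGrid(vol)
  vals <- voxelValues(vol)
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- NaN
  img <- RNifti::asNifti(vals)   # double array -> FLOAT64 on disk
  pd <- grid@voxelSize
  if (is(vol, "BoldSeries")) pd <- c(pd, vol@samplingInterval)
  RNifti::pixdim(img) <- pd
  aff <- diag(c(grid@voxelSize, 1))
  aff[1:3, 4] <- grid@origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parcellation volume plus its label table
#'
#' The label volume must be integer-valued (0 = background); the table is
#' tab-separated with columns `label`, `name`, `group`, `spinnable`.
#' Every nonzero label present in the volume must appear in the table.
#'
#' @param volumePath NIfTI label volume.
#' @param tablePath TSV label table.
#' @return a [BrainParcellation].
#' @export
readParcellation <- function(volumePath, tablePath) {
  vol <- readVolume(volumePath)
  if (!is(vol, "Volume3D")) stop("parcellation volume must be 3D")
  lab <- vol@values
  lab[is.na(lab)] <- 0
  if (any(abs(lab - round(lab)) > 1e-6))
    stop("parcellation volume contains non-integer labels")
  storage.mode(lab) <- "integer"
  tab <- utils::read.delim(tablePath, sep = "\t", stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  need <- c("label", "name", "group", "spinnable")
  if (!all(need %in% names(tab)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  tab$label <- as.integer(tab$label)
  tab$spinnable <- as.logical(tab$spinnable)
  new("BrainParcellation", grid = vol@grid, labels = lab, labelTable = tab)
}

#' Write a parcellation volume and its label table
#'
#' @param parc a [BrainParcellation].
#' @param volumePath output NIfTI path.
#' @param tablePath output TSV path.
#' @return invisibly NULL.
#' @export
writeParcellation <- function(parc, volumePath, tablePath) {
  writeVolume(new("Volume3D", grid = parc@grid,
                  values = array(as.double(parc@labels),
                                 dim = dim(parc@labels))),
              volumePath)
  writeResultTable(parc@labelTable, tablePath)
  invisible(NULL)
}

#' Write a result table as tab-separated UTF-8
#'
#' @param df a data.frame.
#' @param path output path; the parent directory must exist.
#' @return invisibly `path`.
#' @export
writeResultTable <- function(df, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sphere mesh from a plain-text vertex file
#'
#' One vertex per line: `x y z hemisphere` with optional trailing
#' `vx vy vz` volume-space mm coordinates; whitespace separated, lines
#' starting with `#` ignored. The subdivision order is inferred from the
#' per-hemisphere vertex count (10 * 4^order + 2).
#'
#' @param path input text file.
#' @return a [SphereMesh].
#' @export
readSphereMesh <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1L || !ncols %in% c(4L, 7L))
    stop("each vertex line must have 4 or 7 whitespace-separated fields")
  m <- do.call(rbind, parts)
  verts <- matrix(as.numeric(m[, 1:3]), ncol = 3L)
  hemi <- toupper(m[, 4L])
  vc <- if (ncols == 7L) matrix(as.numeric(m[, 5:7]), ncol = 3L) else
    matrix(NA_real_, nrow(verts), 3L)
  nL <- sum(hemi == "L")
  ord <- log((nL - 2) / 10) / log(4)
  if (abs(ord - round(ord)) > 1e-9)
    stop("per-hemisphere vertex count is not 10 * 4^order + 2")
  new("SphereMesh", vertices = verts, hemisphere = hemi, volumeCoord = vc,
      order = as.integer(round(ord)))
}

#' Write a sphere mesh as a plain-text vertex file
#'
#' @param mesh a [SphereMesh].
#' @param path output path.
#' @return invisibly `path`.
#' @export
writeSphereMesh <- function(mesh, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  hasVc <- !all(is.na(mesh@volumeCoord))
  fmtv <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- vapply(seq_len(nrow(mesh@vertices)), function(i) {
    base <- paste(c(fmtv(mesh@vertices[i, ]), mesh@hemisphere[i]),
                  collapse = " ")
    if (hasVc) paste(c(base, fmtv(mesh@volumeCoord[i, ])), collapse = " ")
    else base
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
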