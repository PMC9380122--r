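#' Write a volume or mask to NIfTI
#'
#' Scalar volumes are stored as float64 (bit-exact round trip); masks as
#' uint8. Spacing and origin are stored in the qform (pixdim + qoffset).
#'
#' @param vol an \code{image_volume}.
#' @param path output path; \code{.nii.gz} appended if missing.
#' @return the written path, invisibly.
#' @export
write_volume <- function(vol, path) {
  path <- sub("\\.nii(\\.gz)?$", "", path)
  is_mask <- is.logical(vol$data)
  arr <- vol$data
  if (is_mask) {
    storage.mode(arr) <- "integer"
    img <- oro.nifti::nifti(arr, datatype = 2, bitpix = 8)
  } else {
    storage.mode(arr) <- "double"
    img <- oro.nifti::nifti(arr, datatype = 64, bitpix = 64)
  }
  img@pixdim <- c(1, vol$spacing, rep(0, 4))
  img@qform_code <- 1L
  img@qoffset_x <- vol$origin[1]
  img@qoffset_y <- vol$origin[2]
  img@qoffset_z <- vol$origin[3]
  oro.nifti::writeNIfTI(img, path, gzipped = TRUE)
  invisible(paste0(path, ".nii.gz"))
}

#' Read a volume or mask from NIfTI
#'
#' @param path NIfTI file.
#' @param mask force logical interpretation (\code{NULL}: uint8 images whose
#'   values are all 0/1 become masks automatically).
#' @return an \code{image_volume}.
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(oro.nifti::readNIfTI(path, reorient = FALSE),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- array(img@.Data, dim(img@.Data)[1:3])
  spacing <- img@pixdim[2:4]
  origin <- c(img@qoffset_x, img@qoffset_y, img@qoffset_z)
  if (is.null(mask)) mask <- img@datatype == 2 && all(arr %in% c(0, 1))
  if (mask) arr <- array(arr != 0, dim(arr))
  image_volume(arr, spacing, origin)
}

#' Write a displacement field as a 4D NIfTI (x, y, z, component)
#' @param field a \code{displacement_field}.
#' @param path output path.
#' @return the written path, invisibly.
#' @export
write_dvf <- function(field, path) {
  path <- sub("\\.nii(\\.gz)?$", "", path)
  img <- oro.nifti::nifti(field$v, datatype = 64, bitpix = 64)
  img@pixdim <- c(1, field$spacing, 1, rep(0, 3))
  img@qform_code <- 1L
  img@qoffset_x <- field$origin[1]
  img@qoffset_y <- field$origin[2]
  img@qoffset_z <- field$origin[3]
  oro.nifti::writeNIfTI(img, path, gzipped = TRUE)
  invisible(paste0(path, ".nii.gz"))
}

#' Read a displacement field from a 4D NIfTI
#' @param path NIfTI file with a trailing length-3 dimension.
#' @return a \code{displacement_field} (ROI = whole grid).
#' @export
read_dvf <- function(path) {
  img <- oro.nifti::readNIfTI(path, reorient = FALSE)
  v <- array(img@.Data, dim(img@.Data))
  if (length(dim(v)) != 4 || dim(v)[4] != 3)
    stop("not a displacement field: expected (nx, ny, nz, 3)")
  displacement_field(v, img@pixdim[2:4],
                     c(img@qoffset_x, img@qoffset_y, img@qoffset_z),
                     array(TRUE, dim(v)[1:3]))
}

#' Write a surface mesh as ASCII PLY
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh$vertices, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a rigid transform as a 4 x 4 matrix text file
#' @param tf a \code{rigid_transform}.
#' @param path text file path.
#' @return the path (write) or a \code{rigid_transform} (read).
#' @export
write_rigid <- function(tf, path) {
  write.table(rigid_matrix4(tf), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  m <- as.matrix(read.table(path))
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4], c(0, 0, 0))
}

#' Write a phantom case to a directory
#'
#' All volumes and masks as NIfTI plus a JSON sidecar with the generating
#' spec and the ground-truth rigid offset; the ground-truth displacement
#' field is written as a 4D NIfTI.
#'
#' @param case a \code{phantom_case}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tp in c("pre", "post", "recur")) {
    write_volume(case[[tp]]$volume, file.path(dir, paste0(tp, "_volume")))
    for (nm in names(case[[tp]]$masks))
      write_volume(case[[tp]]$masks[[nm]],
                   file.path(dir, paste0(tp, "_", nm)))
  }
  write_dvf(case$truth$dvf, file.path(dir, "truth_dvf"))
  write_rigid(case$truth$rigid, file.path(dir, "truth_rigid.txt"))
  sidecar <- list(spec = unclass(case$spec),
                  truth = list(
                    rigid_translation = case$truth$rigid$translation,
                    rigid_center = case$truth$rigid$center,
                    ablation_center = case$truth$ablation_center,
                    recurrence_direction = case$truth$recurrence_direction,
                    min_jacobian = case$truth$min_jacobian))
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
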