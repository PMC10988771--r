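#' Volumes: NIfTI-1 read/write and affine helpers
#'
#' A `glio_volume` is a plain list: `data` (3D or 4D numeric array) and
#' `affine` (4x4 matrix mapping 0-based voxel indices to world mm, the NIfTI
#' convention). All world-coordinate arithmetic in the package goes through
#' [voxel_to_world()] / [world_to_voxel()]; in-memory R arrays stay 1-based.
#'
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A `glio_volume`.
#' @export
glio_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (!length(dim(data)) %in% c(3, 4))
    abort("volume must be 3D or 4D", class = "glio_shape_error")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || !all(is.finite(affine)))
    abort("affine must be a finite 4x4 matrix", class = "glio_format_error")
  structure(list(data = data, affine = affine), class = "glio_volume")
}

#' @rdname glio_volume
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param rank Optional expected array rank (3 or 4); mismatch is an error.
#' @export
read_volume <- function(path, rank = NULL) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = "matrix")
  dat <- as.array(img)
  if (!is.null(rank) && length(dim(dat)) != rank)
    abort(sprintf("expected rank-%d volume, got rank %d", rank, length(dim(dat))),
          class = "glio_shape_error")
  glio_volume(dat, aff)
}

#' @rdname glio_volume
#' @param vol A `glio_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "glio_volume"))
  sp <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, c(sp, rep(1, length(dim(vol$data)) - 3)))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert between 0-based voxel indices and world mm
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk0 n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (or indices for the inverse).
#' @export
voxel_to_world <- function(affine, ijk0) {
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3)
  if (!nrow(ijk0)) return(ijk0)
  t(affine %*% rbind(t(ijk0), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# world coordinates of all voxels where mask is TRUE (n x 3 mm), with the
# 1-based array indices as an attribute
mask_world_coords <- function(mask_arr, affine) {
  idx1 <- which(mask_arr != 0, arr.ind = TRUE)
  xyz <- voxel_to_world(affine, idx1 - 1)
  attr(xyz, "idx1") <- idx1
  xyz
}
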