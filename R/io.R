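#' Read and write attenuation volumes as NIfTI-1
#'
#' Volumes, masks and label maps travel as NIfTI-1 files: the voxel spacing
#' is stored in `pixdim` and the origin in the qform translation. Anisotropic
#' spacing is preserved exactly. Only 3D volumes are accepted; a 4D series is
#' rejected rather than silently squeezed.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [read_volume()] returns an [attenuation_volume()];
#'   [read_mask()] a [binary_mask()]; [read_label_map()] a
#'   [cluster_label_map()] (connectivity recorded by the caller).
#' @export
read_volume <- function(path) {
  img <- read_nifti3d(path)
  attenuation_volume(as.array(img$arr), img$spacing, img$origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- read_nifti3d(path)
  binary_mask(array(img$arr != 0, dim(img$arr)), img$spacing, img$origin)
}

#' @rdname read_volume
#' @param connectivity adjacency rule the stored labels were derived under.
#' @export
read_label_map <- function(path, connectivity = 26) {
  img <- read_nifti3d(path)
  arr <- as.array(img$arr)
  storage.mode(arr) <- "integer"
  cluster_label_map(arr, connectivity, img$spacing, img$origin)
}

read_nifti3d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error reading ", path, ": ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] > 1L)
    stop("dimensionality error: ", path, " is a 4D series (",
         paste(d, collapse = "x"), "); expected a single 3D volume")
  if (length(d) == 4L) img <- array(as.array(img)[, , , 1], d[1:3])
  if (length(dim(img)) != 3L)
    stop("dimensionality error: expected a 3D volume, got ",
         length(dim(img)), "D")
  spacing <- abs(RNifti::pixdim(img))[1:3]
  origin <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  list(arr = as.array(img), spacing = spacing, origin = as.numeric(origin))
}

#' @rdname read_volume
#' @param x an [attenuation_volume()], [binary_mask()] or
#'   [cluster_label_map()].
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "calc_grid"))
  arr <- if (inherits(x, "cluster_label_map")) x$labels else x$values
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
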