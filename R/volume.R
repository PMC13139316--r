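#' Grid containers for attenuation volumes, masks and label maps
#'
#' An attenuation volume is a 3D scalar field of CT attenuation in Hounsfield
#' units (HU) on a regular grid. The grid is described by the voxel spacing
#' (mm per axis, anisotropy allowed) and the world coordinate of the centre of
#' voxel `[1,1,1]`. Binary masks and integer cluster label maps share the same
#' grid contract so they can be combined voxelwise.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing in mm (x, y, z); all > 0.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @return An object of class `attenuation_volume` (a list with elements
#'   `values`, `spacing`, `origin`).
#' @examples
#' v <- attenuation_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$values)
#' @export
attenuation_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  check_grid_args(values, spacing, origin)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("attenuation_volume", "calc_grid"))
}

#' @rdname attenuation_volume
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  check_grid_args(values, spacing, origin)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask must not contain NA")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("binary_mask", "calc_grid"))
}

#' @rdname attenuation_volume
#' @param labels 3D integer array, 0 = background, 1..K = clusters with no
#'   gaps.
#' @param connectivity voxel adjacency used to define the components: 6
#'   (faces), 18 (faces + edges) or 26 (faces + edges + corners).
#' @export
cluster_label_map <- function(labels, connectivity, spacing, origin = c(0, 0, 0)) {
  check_grid_args(labels, spacing, origin)
  connectivity <- check_connectivity(connectivity)
  storage.mode(labels) <- "integer"
  k <- max(labels)
  present <- sort(unique(labels[labels > 0L]))
  if (k > 0 && !identical(present, seq_len(k)))
    stop("labels must be consecutive integers 1..K with no gaps")
  structure(list(labels = labels, connectivity = connectivity,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = c("cluster_label_map", "calc_grid"))
}

check_grid_args <- function(values, spacing, origin) {
  if (length(dim(values)) != 3L)
    stop("grid values must be a 3D array, got ", length(dim(values)), " dims")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  invisible(TRUE)
}

check_connectivity <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  connectivity
}

grid_dim <- function(x) dim(if (inherits(x, "cluster_label_map")) x$labels else x$values)

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf("<attenuation_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' @export
print.cluster_label_map <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf("<cluster_label_map> %d x %d x %d voxels, %d clusters, connectivity %d\n",
              d[1], d[2], d[3], max(x$labels), x$connectivity))
  invisible(x)
}

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!identical(grid_dim(a), grid_dim(b)))
    stop(what, " must share the same grid shape (",
         paste(grid_dim(a), collapse = "x"), " vs ",
         paste(grid_dim(b), collapse = "x"), ")")
  if (max(abs(a$spacing - b$spacing)) > 1e-9 || max(abs(a$origin - b$origin)) > 1e-9)
    stop(what, " must share voxel spacing and origin")
  invisible(TRUE)
}

# World coordinates (mm) of the voxel centres at the given array indices
# (n x 3 integer matrix, 1-based). Centre of voxel [1,1,1] is the origin.
voxel_centers <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

voxel_volume <- function(grid) prod(grid$spacing)

#' Validate the structural invariants of a cluster label map
#'
#' Re-derives the connected components of every label's voxel set and checks
#' that (a) each label is a single connected component under the stated
#' connectivity and (b) no two distinct labels touch under it.
#'
#' @param labmap a [cluster_label_map()].
#' @return `TRUE` invisibly; stops with an integrity error otherwise.
#' @export
validate_label_map <- function(labmap, arg_name = "label map") {
  stopifnot(inherits(labmap, "cluster_label_map"))
  lab <- labmap$labels
  k <- max(lab)
  if (k == 0L) return(invisible(TRUE))
  relab <- cc_label_cpp(as.logical(lab > 0L), dim(lab), labmap$connectivity)
  # each re-derived component must map to exactly one stored label and
  # vice versa, otherwise a label is split or two labels are adjacent
  tab <- unique(cbind(relab[relab > 0L], lab[lab > 0L]))
  if (nrow(tab) != k || length(unique(tab[, 1])) != k || length(unique(tab[, 2])) != k)
    stop("integrity error: ", arg_name,
         " is not a valid component partition under connectivity ",
         labmap$connectivity)
  invisible(TRUE)
}
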