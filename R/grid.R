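#' Construct a 3D study grid
#'
#' A regular voxel grid with anisotropic spacings, a brain (domain) mask and
#' per-voxel tissue labels. All fields in the package are plain 3D arrays
#' living on such a grid; the mask defines where the PDEs are integrated and
#' where no-flux / slip boundary conditions apply.
#'
#' @param nx,ny,nz Voxel counts along each axis.
#' @param dx,dy,dz Voxel spacings in mm. Defaults follow the acquisition
#'   geometry the model targets (250 x 250 x 1000 micrometre voxels).
#' @param brain_mask Logical 3D array of dimension `c(nx, ny, nz)` marking the
#'   tissue domain. Defaults to the full grid.
#' @param tissue_labels Character or factor 3D array with values `"white"`,
#'   `"gray"` or `"other"` wherever `brain_mask` is `TRUE`. Defaults to
#'   `"gray"` everywhere in the mask.
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(nx, ny, nz, dx = 0.25, dy = 0.25, dz = 1.0,
                   brain_mask = NULL, tissue_labels = NULL) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  if (any(c(dx, dy, dz) <= 0)) stop("voxel spacings must be positive")
  dims <- c(nx, ny, nz)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dims)
  brain_mask <- array(as.logical(brain_mask), dims)
  if (!any(brain_mask)) stop("brain_mask must contain at least one voxel")
  if (is.null(tissue_labels)) {
    tissue_labels <- array("other", dims)
    tissue_labels[brain_mask] <- "gray"
  }
  tissue_labels <- array(as.character(tissue_labels), dims)
  if (any(is.na(tissue_labels[brain_mask])))
    stop("tissue_labels must be defined wherever brain_mask is TRUE")
  structure(list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
                 brain_mask = brain_mask, tissue_labels = tissue_labels),
            class = "grid3d")
}

#' @export
#' @method print grid3d
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d in mask\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz, sum(x$brain_mask)))
  invisible(x)
}

grid_dims <- function(grid) c(grid$nx, grid$ny, grid$nz)

grid_spacings <- function(grid) c(grid$dx, grid$dy, grid$dz)

voxel_volume <- function(grid) grid$dx * grid$dy * grid$dz

#' Make a scalar field on a grid
#'
#' Fields are plain numeric 3D arrays; this helper validates dimensions and
#' recycles scalars.
#'
#' @param values Scalar or array conformable to the grid.
#' @param grid A [grid3d()].
#' @return Numeric 3D array with the grid's dimensions.
#' @export
scalar_field <- function(values, grid) {
  dims <- grid_dims(grid)
  if (length(values) == 1L) return(array(as.numeric(values), dims))
  if (!identical(as.integer(dim(values)), as.integer(dims)))
    stop("field dimensions do not match the grid")
  array(as.numeric(values), dims)
}

check_field <- function(values, grid, name = "field", fraction = FALSE) {
  v <- scalar_field(values, grid)
  inside <- v[grid$brain_mask]
  if (any(!is.finite(inside)))
    stop(sprintf("%s contains non-finite values inside the brain mask", name))
  if (fraction && (any(inside < 0) || any(inside > 1)))
    stop(sprintf("%s must lie in [0, 1] inside the brain mask", name))
  v
}

# linear index <-> (i,j,k) helpers used by several assembly routines
vox_index <- function(i, j, k, dims) i + (j - 1L) * dims[1] + (k - 1L) * dims[1] * dims[2]

# index array of neighbours along axis `axis` offset by `s` (+1/-1); NA outside grid
shift_index <- function(dims, axis, s) {
  ii <- slice.index(array(0L, dims), 1L)
  jj <- slice.index(array(0L, dims), 2L)
  kk <- slice.index(array(0L, dims), 3L)
  if (axis == 1L) ii <- ii + s else if (axis == 2L) jj <- jj + s else kk <- kk + s
  ok <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] & kk >= 1L & kk <= dims[3]
  out <- array(NA_integer_, dims)
  out[ok] <- vox_index(ii[ok], jj[ok], kk[ok], dims)
  out
}
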