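#' Write / read a field as NIfTI-1
#'
#' Volumes carry the grid spacings in their pixdim; masks are written as
#' uint8.
#'
#' @param field Numeric or logical 3D array.
#' @param grid A [grid3d()].
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `write_field_nifti` returns `path` invisibly; `read_field_nifti`
#'   returns a plain array with attribute `pixdim`.
#' @export
write_field_nifti <- function(field, grid, path) {
  img <- RNifti::asNifti(array(as.numeric(field), grid_dims(grid)))
  RNifti::pixdim(img) <- grid_spacings(grid)
  RNifti::writeNifti(img, path, datatype = if (is.logical(field)) "uint8" else "double")
  invisible(path)
}

#' @rdname write_field_nifti
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Write an animal dataset to a directory
#'
#' One NIfTI volume per field per visit plus a JSON manifest (visit days, RT
#' schedule, capacity bounds, file names).
#'
#' @param dataset An [animal_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- dataset$grid
  files <- list()
  for (i in seq_along(dataset$visits)) {
    v <- dataset$visits[[i]]
    base <- sprintf("day%03d", v$day)
    f <- list(phi_T = paste0(base, "_phiT.nii.gz"),
              phi_V = paste0(base, "_phiV.nii.gz"),
              tumor_mask = paste0(base, "_mask.nii.gz"))
    write_field_nifti(v$phi_T, grid, file.path(dir, f$phi_T))
    write_field_nifti(v$phi_V, grid, file.path(dir, f$phi_V))
    write_field_nifti(v$tumor_mask, grid, file.path(dir, f$tumor_mask))
    files[[i]] <- c(day = v$day, f)
  }
  write_field_nifti(grid$brain_mask, grid, file.path(dir, "brain_mask.nii.gz"))
  manifest <- list(
    grid = list(dims = grid_dims(grid), spacing = grid_spacings(grid)),
    visits = files,
    rt_events = dataset$rt_events,
    capacity = unclass(dataset$capacity),
    phi_V_pretreatment_mean = dataset$phi_V_pretreatment_mean)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an animal dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return An [animal_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  dims <- as.integer(manifest$grid$dims)
  sp <- as.numeric(manifest$grid$spacing)
  brain <- read_field_nifti(file.path(dir, "brain_mask.nii.gz")) > 0
  grid <- grid3d(dims[1], dims[2], dims[3], sp[1], sp[2], sp[3], brain_mask = brain)
  vis <- manifest$visits
  visits <- lapply(seq_len(nrow(vis)), function(i) list(
    day = as.numeric(vis$day[i]),
    phi_T = read_field_nifti(file.path(dir, vis$phi_T[i])),
    phi_V = read_field_nifti(file.path(dir, vis$phi_V[i])),
    tumor_mask = read_field_nifti(file.path(dir, vis$tumor_mask[i])) > 0))
  cap <- manifest$capacity
  animal_dataset(grid, visits, manifest$rt_events,
                 capacity = capacity_state(cap$theta_min, cap$theta_max,
                                           cap$theta_V, cap$phi_V_thresh),
                 phi_V_pretreatment_mean = manifest$phi_V_pretreatment_mean)
}
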