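#' 3-D scalar volume container
#'
#' Light container for a 3-D scalar grid: array data plus voxel spacing and
#' origin in mm. World coordinates follow the voxel-centre convention
#' `world = index * spacing + origin` with 0-based indices, axis order
#' left-right x anterior-posterior x foot-head.
#'
#' @param data 3-D numeric array.
#' @param spacing voxel spacing in mm (length 3, > 0).
#' @param origin world position of voxel (0,0,0) in mm.
#' @return An `imio_volume`.
#' @export
imio_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) stop("volume data must be a 3-D array")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "imio_volume")
}

#' @export
print.imio_volume <- function(x, ...) {
  cat(sprintf("Volume %s, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Displacement field container
#'
#' Reference-to-subject displacement in mm on the reference grid (pull
#' convention): the point seen at reference voxel `x` lies at world position
#' `x * spacing + origin + u[x, ]` in the subject.
#'
#' @param u 4-D array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing,origin as in [imio_volume()].
#' @return An `imio_field`.
#' @export
imio_field <- function(u, spacing, origin = c(0, 0, 0)) {
  d <- dim(u)
  if (length(d) != 4 || d[4] != 3)
    stop("field must be an (nx, ny, nz, 3) array of mm displacements")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(u = u, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "imio_field")
}

#' @export
print.imio_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("Displacement field %s, spacing %s mm, |u| max %.2f mm\n",
              paste(dim(x$u)[1:3], collapse = "x"),
              paste(x$spacing, collapse = "x"), max(mag)))
  invisible(x)
}

zero_field <- function(dim3, spacing, origin = c(0, 0, 0)) {
  imio_field(array(0, c(dim3, 3)), spacing, origin)
}

grid_dim <- function(x) {
  if (inherits(x, "imio_volume")) dim(x$data) else dim(x$u)[1:3]
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(grid_dim(a), grid_dim(b)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(what, " are not on the same grid")
  invisible(TRUE)
}

#' Jacobian local-volume map of a displacement field
#'
#' Per-voxel determinant of `I + grad(u)` computed by spacing-aware central
#' finite differences (one-sided at the boundary). Under the pull
#' (reference-to-subject) convention the value is the local subject volume
#' per unit reference volume: > 1 where subject tissue is larger than the
#' reference, exactly 1 for a zero or constant-translation field.
#'
#' @param field an `imio_field`.
#' @return An `imio_volume` of dimensionless volume ratios.
#' @export
jacobian_map <- function(field) {
  stopifnot(inherits(field, "imio_field"))
  d <- dim(field$u)[1:3]
  j <- jacobian_cpp(as.numeric(field$u), as.integer(d), field$spacing)
  imio_volume(array(j, d), field$spacing, field$origin)
}

#' Resample a subject volume into reference space
#'
#' Samples the subject volume at `reference point + displacement` (trilinear
#' by default, nearest-neighbour for label volumes); out-of-bounds positions
#' take `fill`. Both volumes are assumed to share the reference grid, as all
#' volumes of this pipeline do.
#'
#' @param subject_vol an `imio_volume` in subject space.
#' @param field reference-to-subject `imio_field`.
#' @param method `"linear"` or `"nearest"`.
#' @param fill out-of-bounds fill value (default 0).
#' @return An `imio_volume` in reference space.
#' @export
pull_to_reference <- function(subject_vol, field, method = c("linear", "nearest"),
                              fill = 0) {
  method <- match.arg(method)
  check_same_grid(subject_vol, field, "volume and field")
  d <- dim(subject_vol$data)
  out <- warp_volume_cpp(as.numeric(subject_vol$data), as.integer(d),
                         as.numeric(field$u), subject_vol$spacing,
                         if (method == "nearest") 1L else 0L, fill)
  imio_volume(array(out, d), field$spacing, field$origin)
}

smooth_volume <- function(vol, sigma_vox) {
  d <- dim(vol$data)
  out <- smooth3_cpp(as.numeric(vol$data), as.integer(d),
                     rep_len(as.numeric(sigma_vox), 3))
  imio_volume(array(out, d), vol$spacing, vol$origin)
}

smooth_field <- function(field, sigma_vox) {
  d <- dim(field$u)[1:3]
  u <- field$u
  for (c in 1:3)
    u[, , , c] <- array(smooth3_cpp(as.numeric(field$u[, , , c]),
                                    as.integer(d),
                                    rep_len(as.numeric(sigma_vox), 3)), d)
  imio_field(u, field$spacing, field$origin)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse of a smooth, invertible
#' reference-to-subject field: solves `v(y) = -u(y + v(y))` so that
#' `y + v(y)` is the reference point mapped to subject point `y`.
#'
#' @param field an `imio_field`.
#' @param iters fixed-point iterations (default 10).
#' @return An `imio_field` holding the inverse displacement.
#' @export
invert_field <- function(field, iters = 10) {
  d <- dim(field$u)[1:3]
  v <- array(0, c(d, 3))
  for (k in seq_len(iters)) {
    vf <- imio_field(v, field$spacing, field$origin)
    for (c in 1:3) {
      uc <- warp_volume_cpp(as.numeric(field$u[, , , c]), as.integer(d),
                            as.numeric(v), field$spacing, 0L, 0)
      v[, , , c] <- -array(uc, d)
    }
  }
  imio_field(v, field$spacing, field$origin)
}

resample_volume <- function(vol, newdim, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(vol$data)
  out <- resample3_cpp(as.numeric(vol$data), as.integer(d),
                       as.integer(newdim),
                       if (method == "nearest") 1L else 0L)
  newspacing <- vol$spacing * (d - 1) / pmax(newdim - 1, 1)
  imio_volume(array(out, newdim), newspacing, vol$origin)
}

resample_field <- function(field, newdim) {
  d <- dim(field$u)[1:3]
  u <- array(0, c(newdim, 3))
  for (c in 1:3)
    u[, , , c] <- array(resample3_cpp(as.numeric(field$u[, , , c]),
                                      as.integer(d), as.integer(newdim), 0L),
                        newdim)
  imio_field(u, field$spacing * (d - 1) / pmax(newdim - 1, 1), field$origin)
}

#' Read / write volumes and displacement fields as NIfTI-1
#'
#' Volumes are stored as float32 with voxel spacing in the header; fields as
#' 4-D images with three mm-displacement components.
#'
#' @param vol an `imio_volume`; `field` an `imio_field`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return Readers return the container; writers return `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(structure(vol$data, pixdim = vol$spacing),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  imio_volume(array(as.numeric(img), dim(img)[1:3]),
              RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(structure(field$u, pixdim = c(field$spacing, 1)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  imio_field(array(as.numeric(img), d), RNifti::pixdim(img)[1:3])
}
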