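#' Resample a volume onto a new grid through an affine transform
#'
#' Pull-back convention: the output value at world point \code{p} is the
#' input interpolated at \code{t(p)}, i.e. \code{t} maps output-space world
#' coordinates to input-space world coordinates. Points falling outside the
#' input support take the fill value 0 (the dark background of both MR and
#' ultrasound volumes).
#'
#' @param vol a [scalar_volume()] or [label_volume()].
#' @param t 4x4 affine transform (output world -> input world).
#' @param out_grid target [volume_grid()].
#' @param interpolation \code{"linear"} or \code{"nearest"}; label volumes
#'   always use nearest-neighbour.
#' @return resampled volume of the same class, on \code{out_grid}.
#' @export
resample_volume <- function(vol, t = affine_identity(), out_grid = vol$grid,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  check_affine(t)
  is_label <- inherits(vol, "label_volume")
  nearest <- is_label || interpolation == "nearest"
  out <- cpp_resample(as.numeric(vol$values), vol$grid$shape,
                      vol$grid$spacing, vol$grid$origin,
                      out_grid$shape, out_grid$spacing, out_grid$origin,
                      t, nearest, 0)
  vals <- array(out, dim = out_grid$shape)
  if (is_label)
    label_volume(vals, grid = out_grid, scheme = vol$scheme)
  else
    scalar_volume(vals, grid = out_grid)
}

#' Gaussian smoothing in physical units
#'
#' Separable Gaussian filtering with a reflective boundary; \code{sigma_mm}
#' is converted per axis into voxel units by the grid spacing, so the
#' filter is isotropic in millimetres on anisotropic grids.
#'
#' @param vol a [scalar_volume()].
#' @param sigma_mm positive standard deviation in mm.
#' @return smoothed \code{scalar_volume}.
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1 || sigma_mm <= 0)
    stop("sigma_mm must be a single positive number")
  sig_vox <- sigma_mm / vol$grid$spacing
  out <- cpp_gauss_smooth(as.numeric(vol$values), vol$grid$shape, sig_vox)
  scalar_volume(array(out, dim = vol$grid$shape), grid = vol$grid)
}

# smoothing on a raw array, shared by internal callers
smooth_array <- function(arr, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(arr)
  array(cpp_gauss_smooth(as.numeric(arr), dim(arr), sigma_mm / spacing),
        dim = dim(arr))
}

#' Euclidean distance transform in millimetres
#'
#' Exact distance from every voxel to the nearest voxel of the mask,
#' respecting anisotropic spacing; 0 inside the mask.
#'
#' @param mask a [label_volume()], \code{scalar_volume} or logical/numeric
#'   array treated as binary (nonzero = inside).
#' @param grid required when \code{mask} is a bare array.
#' @return a \code{scalar_volume} of distances (mm).
#' @export
distance_map <- function(mask, grid = NULL) {
  if (is.null(grid)) {
    if (is.array(mask) && !inherits(mask, c("label_volume", "scalar_volume")))
      stop("grid must be supplied for bare-array masks")
    grid <- mask$grid
  }
  m <- as_binary_mask(mask)
  if (!any(m)) stop("distance_map: mask is empty")
  d <- cpp_edt(as.integer(m), grid$shape, grid$spacing)
  scalar_volume(array(d, dim = grid$shape), grid = grid)
}

# connected components of a binary array (26- or 6-connectivity)
label_components <- function(mask, connectivity = 26) {
  array(cpp_label_components(as.integer(mask), dim(mask),
                             as.integer(connectivity)), dim = dim(mask))
}
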