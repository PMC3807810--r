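#' Canonical structure label scheme for the ultrasound-visible map
#'
#' @return named integer vector mapping structure names to labels
#'   (0 = background).
#' @export
structure_scheme <- function() {
  c(cortical_hemisphere_L = 1L, cortical_hemisphere_R = 2L, dgm = 3L,
    brainstem = 4L, cerebellum = 5L, cerebellar_wm = 6L, csf = 7L,
    skull = 8L, choroid_plexus = 9L, septum_pellucidum = 10L,
    midline_falx = 11L, brain_surface = 12L)
}

#' Separate the brain into left and right hemispheres
#'
#' White-matter cores are formed by removing WM voxels closer than
#' \code{erosion_mm} to the WM surface and keeping the two largest
#' 26-connected components (ties broken by centroid x; left = smaller x).
#' Euclidean distance maps from each core are regularised with a Gaussian
#' (\code{sigma_reg_mm}), every non-WM brain voxel is assigned to the side
#' with the smaller regularised distance, and voxels whose regularised
#' distances differ by at most the voxel size form the midline, emulating
#' the thin CSF/falx gap visible between the hemispheres on ultrasound.
#'
#' @param wm_mask WM voxels (mask input accepted by [distance_map()]).
#' @param brain_labels [label_volume()] of brain tissue (nonzero inside the
#'   brain) on the same grid.
#' @param voxel_size_mm midline distance threshold (defaults to the largest
#'   grid spacing).
#' @param erosion_mm WM-surface erosion depth (default 1.5 mm).
#' @param sigma_reg_mm distance regularisation (default 10 mm).
#' @return list: \code{d_left}/\code{d_right} (regularised distance
#'   [scalar_volume()]s), \code{core_left}/\code{core_right} (logical
#'   arrays), \code{midline} (logical array), \code{side} (integer array:
#'   1 left, 2 right, 0 outside brain or midline).
#' @export
split_hemispheres <- function(wm_mask, brain_labels, voxel_size_mm = NULL,
                              erosion_mm = 1.5, sigma_reg_mm = 10) {
  grid <- brain_labels$grid
  if (is.null(voxel_size_mm)) voxel_size_mm <- max(grid$spacing)
  wm <- as_binary_mask(wm_mask)
  if (!any(wm)) stop("empty WM mask")
  # distance of WM voxels to the WM surface = EDT of the complement
  d_surf <- distance_map(!wm, grid = grid)$values
  cores_all <- wm & d_surf >= erosion_mm
  comp <- label_components(cores_all, 26)
  sizes <- tabulate(comp[comp > 0])
  if (length(sizes) < 2)
    stop("fewer than 2 WM cores after erosion; reduce erosion_mm")
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  cx <- vapply(top2, function(l) {
    mean(which(comp == l, arr.ind = TRUE)[, 1])
  }, numeric(1))
  left_lab <- top2[which.min(cx)]
  right_lab <- top2[which.max(cx)]
  core_l <- comp == left_lab
  core_r <- comp == right_lab
  d_l <- smooth_array(distance_map(core_l, grid = grid)$values,
                      grid$spacing, sigma_reg_mm)
  d_r <- smooth_array(distance_map(core_r, grid = grid)$values,
                      grid$spacing, sigma_reg_mm)
  brain <- brain_labels$values != 0L
  side <- array(0L, grid$shape)
  side[brain & (d_l < d_r)] <- 1L
  side[brain & (d_l >= d_r)] <- 2L
  midline <- brain & (abs(d_l - d_r) <= voxel_size_mm)
  side[midline] <- 0L
  list(d_left = scalar_volume(d_l, grid = grid),
       d_right = scalar_volume(d_r, grid = grid),
       core_left = core_l, core_right = core_r,
       midline = midline, side = side)
}

#' Skull shell from the brain mask
#'
#' The fetal skull closely follows the brain mask (brain tissues plus
#' CSF); voxels outside the mask at distance up to \code{thickness_mm}
#' (default 2 mm) are labelled skull.
#'
#' @param brain_mask mask input (nonzero = brain + CSF).
#' @param thickness_mm shell thickness (default 2).
#' @param grid required for bare arrays.
#' @return logical array marking skull voxels.
#' @export
estimate_skull_shell <- function(brain_mask, thickness_mm = 2, grid = NULL) {
  if (is.null(grid)) grid <- brain_mask$grid
  m <- as_binary_mask(brain_mask)
  if (!any(m)) stop("empty brain mask")
  d <- distance_map(m, grid = grid)$values
  d > 0 & d <= thickness_mm
}

#' Thin echogenic brain-surface layer
#'
#' Mask voxels within \code{layer_mm} of the mask complement; models the
#' highly echogenic thin tissue layer that makes the brain surface visible
#' on ultrasound.
#'
#' @param brain_mask mask input.
#' @param layer_mm layer depth (default 0.66 mm, two voxels at the 0.33 mm
#'   template resolution).
#' @param grid required for bare arrays.
#' @return logical array marking surface voxels.
#' @export
extract_brain_surface <- function(brain_mask, layer_mm = 0.66, grid = NULL) {
  if (layer_mm <= 0) stop("layer_mm must be positive")
  if (is.null(grid)) grid <- brain_mask$grid
  m <- as_binary_mask(brain_mask)
  if (!any(m)) stop("empty brain mask")
  if (all(m)) {
    # complement empty: the surface is the faces of the volume
    surf <- array(FALSE, grid$shape)
    n <- grid$shape
    surf[c(1, n[1]), , ] <- TRUE
    surf[, c(1, n[2]), ] <- TRUE
    surf[, , c(1, n[3])] <- TRUE
    return(surf)
  }
  d <- distance_map(!m, grid = grid)$values  # distance to complement
  m & d <= max(layer_mm, min(grid$spacing))
}

#' Assemble the ultrasound-visible structure map
#'
#' Merges WM and cortex into left/right cortical hemispheres, adds the
#' skull shell, brain surface, midline/falx and auxiliary labels, and
#' resolves overlaps with a fixed precedence (skull highest, then
#' choroid/septum/midline, surface, cerebellum, DGM/brainstem,
#' hemispheres, CSF). In \code{"old"} gestational-age mode the cerebellum
#' is kept homogeneous and any cerebellar-WM label is ignored; in
#' \code{"young"} mode cerebellar WM is a separate (darker) class.
#'
#' @param em_labels [label_volume()] with tissue classes named among
#'   \code{wm}, \code{cortex}, \code{dgm}, \code{brainstem},
#'   \code{cerebellum}, \code{csf}.
#' @param skull,surface,midline logical arrays (from
#'   [estimate_skull_shell()], [extract_brain_surface()],
#'   [split_hemispheres()]).
#' @param side integer array from [split_hemispheres()] (1 = left,
#'   2 = right).
#' @param aux_labels named list of logical arrays: \code{choroid_plexus},
#'   \code{septum_pellucidum}, optionally \code{cerebellar_wm}.
#' @param ga_mode \code{"young"} or \code{"old"}.
#' @return [label_volume()] with the [structure_scheme()].
#' @export
build_structure_map <- function(em_labels, skull, surface, midline, side,
                                aux_labels = list(),
                                ga_mode = c("young", "old")) {
  ga_mode <- match.arg(ga_mode)
  grid <- em_labels$grid
  for (a in list(skull, surface, midline, side))
    if (!all(dim(a) == grid$shape)) stop("grid mismatch between inputs")
  for (a in aux_labels)
    if (!all(dim(a) == grid$shape)) stop("grid mismatch between inputs")
  sch <- structure_scheme()
  lab <- array(0L, grid$shape)
  paint <- function(mask, name) lab[mask] <<- sch[[name]]
  # lowest precedence first
  paint(label_mask(em_labels, "csf"), "csf")
  hemis <- label_mask(em_labels, c("wm", "cortex"))
  paint(hemis & side == 1L, "cortical_hemisphere_L")
  paint(hemis & side == 2L, "cortical_hemisphere_R")
  paint(label_mask(em_labels, "dgm"), "dgm")
  paint(label_mask(em_labels, "brainstem"), "brainstem")
  paint(label_mask(em_labels, "cerebellum"), "cerebellum")
  if (ga_mode == "young") {
    if (!is.null(aux_labels$cerebellar_wm))
      paint(aux_labels$cerebellar_wm, "cerebellar_wm")
    else
      warning("young mode without cerebellar_wm labels; ",
              "cerebellum kept homogeneous")
  } else if (!is.null(aux_labels$cerebellar_wm)) {
    message("old mode: cerebellar_wm labels ignored")
  }
  paint(surface, "brain_surface")
  if (!is.null(aux_labels$choroid_plexus))
    paint(aux_labels$choroid_plexus, "choroid_plexus")
  if (!is.null(aux_labels$septum_pellucidum))
    paint(aux_labels$septum_pellucidum, "septum_pellucidum")
  paint(midline, "midline_falx")
  paint(skull, "skull")
  label_volume(lab, grid = grid, scheme = sch)
}
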