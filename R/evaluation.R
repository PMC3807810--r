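#' Dice overlap of two binary masks
#'
#' \code{2 |A n B| / (|A| + |B|)}; defined as 0 (with a warning) when both
#' masks are empty.
#'
#' @param a,b mask inputs on the same grid (label/scalar volumes or bare
#'   arrays of equal dimension).
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  ga <- if (is.list(a)) a$grid else NULL
  gb <- if (is.list(b)) b$grid else NULL
  if (!is.null(ga) && !is.null(gb) && !grid_equal(ga, gb))
    stop("masks live on different grids")
  ma <- as_binary_mask(a); mb <- as_binary_mask(b)
  if (!all(dim(ma) == dim(mb))) stop("masks live on different grids")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 0")
    return(0)
  }
  2 * sum(ma & mb) / (na + nb)
}

mask_barycentre <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty mask has no barycentre")
  colMeans(grid_world(grid, idx))
}

#' Distance between transformed mask barycentres
#'
#' The voxel-count-weighted world-coordinate centroid of \code{a} is
#' mapped through \code{t} and compared with the centroid of \code{b};
#' barycentres are computed in mm so anisotropic grids are handled.
#'
#' @param a,b non-empty masks (volume objects carrying their grids, or
#'   bare arrays with \code{grid_a} / \code{grid_b} supplied).
#' @param t 4x4 affine applied to the barycentre of \code{a}.
#' @param grid_a,grid_b grids for bare-array masks.
#' @return distance in mm.
#' @export
barycentre_distance <- function(a, b, t = affine_identity(),
                                grid_a = NULL, grid_b = NULL) {
  if (is.null(grid_a)) grid_a <- a$grid
  if (is.null(grid_b)) grid_b <- b$grid
  ca <- mask_barycentre(as_binary_mask(a), grid_a)
  cb <- mask_barycentre(as_binary_mask(b), grid_b)
  sqrt(sum((affine_apply(t, ca) - cb)^2))
}

#' Landmark sets
#'
#' @param names unique landmark names.
#' @param coords n x 3 matrix of world coordinates (mm).
#' @param image_id source image identifier.
#' @return data.frame of class \code{landmark_set}.
#' @export
landmark_set <- function(names, coords, image_id = "image") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (any(!is.finite(coords))) stop("landmark coordinates must be finite")
  structure(data.frame(name = as.character(names), x = coords[, 1],
                       y = coords[, 2], z = coords[, 3],
                       image_id = image_id),
            class = c("landmark_set", "data.frame"))
}

#' Read / write landmarks as CSV (name, x, y, z)
#' @param path CSV file.
#' @param image_id identifier attached on read.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, image_id = basename(path)) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  landmark_set(d$name, as.matrix(d[, c("x", "y", "z")]), image_id)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  write.csv(lm[, c("name", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' Mean target registration error over matched landmarks
#'
#' Mean of \code{||t(p_moving) - p_fixed||} over landmarks matched by
#' name; the landmark order is irrelevant.
#'
#' @param lm_fixed,lm_moving [landmark_set()]s with equal name sets.
#' @param t 4x4 affine mapping moving-image world coordinates to
#'   fixed-image world coordinates.
#' @return mTRE in mm.
#' @export
mean_tre <- function(lm_fixed, lm_moving, t = affine_identity()) {
  nf <- sort(lm_fixed$name); nm <- sort(lm_moving$name)
  if (!identical(nf, nm))
    stop("landmark name sets differ: only-fixed {",
         paste(setdiff(nf, nm), collapse = ", "), "}, only-moving {",
         paste(setdiff(nm, nf), collapse = ", "), "}")
  f <- as.matrix(lm_fixed[match(nf, lm_fixed$name), c("x", "y", "z")])
  m <- as.matrix(lm_moving[match(nf, lm_moving$name), c("x", "y", "z")])
  mean(sqrt(rowSums((affine_apply(t, m) - f)^2)))
}

#' Alignment metric report
#'
#' Per-structure Dice overlaps and barycentre distances between a
#' transformed source label volume and a reference label volume, plus
#' optional landmark mTRE and the maximum Euler rotation of the
#' transform.
#'
#' @param source_labels,reference_labels [label_volume()]s sharing
#'   structure names (the source is resampled onto the reference grid
#'   through \code{t}).
#' @param t 4x4 affine (source world -> reference world).
#' @param structures structure names to evaluate (default: shared names).
#' @param lm_fixed,lm_moving optional landmark sets for mTRE.
#' @return object of class \code{metric_report}: data.frame \code{per_structure}
#'   (dice, barycentre_mm), \code{mtre_mm}, \code{max_rotation_deg}.
#' @export
metric_report <- function(source_labels, reference_labels,
                          t = affine_identity(), structures = NULL,
                          lm_fixed = NULL, lm_moving = NULL) {
  if (is.null(structures))
    structures <- intersect(names(source_labels$scheme),
                            names(reference_labels$scheme))
  warped <- resample_volume(source_labels, affine_invert(t),
                            reference_labels$grid)
  per <- do.call(rbind, lapply(structures, function(nm) {
    ms <- label_mask(warped, nm)
    mr <- label_mask(reference_labels, nm)
    dice <- if (sum(ms) + sum(mr) == 0) NA_real_ else dice_overlap(ms, mr)
    bc <- if (sum(label_mask(source_labels, nm)) == 0 || sum(mr) == 0)
      NA_real_
    else barycentre_distance(label_mask(source_labels, nm), mr, t,
                             grid_a = source_labels$grid,
                             grid_b = reference_labels$grid)
    data.frame(structure = nm, dice = dice, barycentre_mm = bc)
  }))
  mtre <- if (!is.null(lm_fixed) && !is.null(lm_moving))
    mean_tre(lm_fixed, lm_moving, t) else NA_real_
  structure(list(per_structure = per, mtre_mm = mtre,
                 max_rotation_deg = max_euler_rotation(t)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Alignment metrics\n")
  print(x$per_structure, row.names = FALSE)
  if (!is.na(x$mtre_mm)) cat(sprintf("mTRE: %.2f mm\n", x$mtre_mm))
  cat(sprintf("max Euler rotation: %.2f deg\n", x$max_rotation_deg))
  invisible(x)
}
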