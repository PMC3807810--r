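#' Volumetric grid on a physical coordinate system
#'
#' A grid is axis-aligned: voxel \code{(i, j, k)} (0-based) sits at world
#' position \code{origin + c(i, j, k) * spacing}, in millimetres.
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param spacing positive mm triple.
#' @param origin mm triple, world position of voxel (0, 0, 0).
#' @return An object of class \code{volume_grid}.
#' @export
volume_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of voxel indices
#'
#' @param grid a \code{volume_grid}.
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
grid_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Scalar image volume
#'
#' @param values numeric 3D array (or vector reshaped to \code{grid$shape}).
#' @param grid a \code{volume_grid} (alternatively give \code{spacing} /
#'   \code{origin} and the grid is derived from \code{dim(values)}).
#' @param spacing,origin used when \code{grid} is missing.
#' @return An object of class \code{scalar_volume} with fields \code{grid}
#'   and \code{values}.
#' @export
scalar_volume <- function(values, grid = NULL, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  if (is.null(grid)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      stop("values must be a 3D array when grid is missing")
    grid <- volume_grid(dim(values), spacing, origin)
  }
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values))) stop("scalar_volume values must be finite")
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  print(x$grid)
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Label volume with a structure naming scheme
#'
#' @param values non-negative integer 3D array; 0 is background.
#' @param grid,spacing,origin as in [scalar_volume()].
#' @param scheme named integer vector mapping structure names to labels;
#'   every nonzero label present in \code{values} must appear.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(values, grid = NULL, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), scheme = NULL) {
  if (is.null(grid)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      stop("values must be a 3D array when grid is missing")
    grid <- volume_grid(dim(values), spacing, origin)
  }
  values <- array(as.integer(round(values)), dim = grid$shape)
  if (any(values < 0L)) stop("labels must be non-negative")
  present <- setdiff(sort(unique(as.vector(values))), 0L)
  if (is.null(scheme))
    scheme <- setNames(present, paste0("label_", present))
  scheme <- setNames(as.integer(scheme), names(scheme))
  missing <- setdiff(present, scheme)
  if (length(missing))
    stop("labels present but absent from scheme: ",
         paste(missing, collapse = ", "))
  structure(list(grid = grid, values = values, scheme = scheme),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  print(x$grid)
  nz <- sum(x$values != 0L)
  cat(sprintf("  %d structures in scheme, %d labelled voxels\n",
              length(x$scheme), nz))
  invisible(x)
}

label_mask <- function(lv, names) {
  labs <- lv$scheme[names]
  labs <- labs[!is.na(labs)]
  array(lv$values %in% labs, dim = lv$grid$shape)
}

as_binary_mask <- function(x) {
  if (inherits(x, "label_volume")) x$values != 0L
  else if (inherits(x, "scalar_volume")) x$values != 0
  else if (is.array(x)) x != 0
  else stop("cannot interpret mask input")
}

# ---- affine transforms (4x4 homogeneous world-mm maps) ----

check_affine <- function(t) {
  if (!is.matrix(t) || !all(dim(t) == c(4, 4)))
    stop("transform must be a 4x4 matrix")
  if (max(abs(t[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of an affine transform must be (0, 0, 0, 1)")
  if (abs(det(t[1:3, 1:3])) < 1e-12)
    stop("affine transform has a singular 3x3 block")
  invisible(t)
}

#' Identity affine transform
#' @return 4x4 identity matrix.
#' @export
affine_identity <- function() diag(4)

#' Build an affine transform from rigid/affine parameters
#'
#' Rotation uses the package-wide intrinsic z-y-x Euler convention:
#' \code{R = Rz(a) Ry(b) Rx(c)} with angles in degrees. The map is
#' \code{p -> R S (p - center) + center + translation} where \code{S} is the
#' diagonal scale matrix.
#'
#' @param translation mm triple.
#' @param angles_deg Euler angles (z, y, x) in degrees.
#' @param scales per-axis scale factors.
#' @param center mm triple; rotation/scaling centre.
#' @return 4x4 affine matrix.
#' @export
affine_from_params <- function(translation = c(0, 0, 0),
                               angles_deg = c(0, 0, 0),
                               scales = c(1, 1, 1),
                               center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  Rz <- rbind(c(cos(a[1]), -sin(a[1]), 0),
              c(sin(a[1]),  cos(a[1]), 0),
              c(0, 0, 1))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])),
              c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(a[3]), -sin(a[3])),
              c(0, sin(a[3]),  cos(a[3])))
  A <- Rz %*% Ry %*% Rx %*% diag(scales, 3)
  t <- rbind(cbind(A, center + translation - A %*% center), c(0, 0, 0, 1))
  dimnames(t) <- NULL
  t
}

#' Invert an affine transform
#' @param t 4x4 affine matrix.
#' @return 4x4 inverse.
#' @export
affine_invert <- function(t) {
  check_affine(t)
  solve(t)
}

#' Apply an affine transform to world points
#' @param t 4x4 affine matrix.
#' @param p n x 3 matrix (or length-3 vector) of world points, mm.
#' @return transformed points, same shape.
#' @export
affine_apply <- function(t, p) {
  vec <- is.null(dim(p))
  p <- matrix(as.numeric(p), ncol = 3)
  q <- p %*% t(t[1:3, 1:3])
  q <- sweep(q, 2, t[1:3, 4], "+")
  if (vec) as.numeric(q) else q
}

#' Rotation factor of a linear map (polar decomposition)
#' @param m 3x3 matrix with positive determinant after reflection fix.
#' @return closest rotation matrix (Frobenius sense).
#' @export
polar_rotation <- function(m) {
  if (abs(det(m)) < 1e-12) stop("degenerate 3x3 block")
  s <- svd(m)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

euler_zyx_deg <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  } else { # gimbal lock: fold x rotation into z
    a <- atan2(-R[1, 2], R[2, 2])
    c <- 0
  }
  c(z = a, y = b, x = c) * 180 / pi
}

#' Rigid parameters (translation + Euler angles) of a transform
#'
#' Euler angles follow the intrinsic z-y-x convention (degrees, in
#' (-180, 180]); scaling and shear are removed by polar decomposition.
#'
#' @param t 4x4 affine matrix.
#' @return list with \code{translation} (mm) and \code{euler_deg}.
#' @export
rigid_params <- function(t) {
  check_affine(t)
  R <- polar_rotation(t[1:3, 1:3])
  list(translation = as.numeric(t[1:3, 4]), euler_deg = euler_zyx_deg(R))
}

#' Maximum absolute Euler rotation angle of a transform
#'
#' The rotation factor is extracted by polar decomposition, so pure scaling
#' does not affect the result. Angles use the intrinsic z-y-x convention.
#'
#' @param t 4x4 affine matrix.
#' @return angle in degrees.
#' @export
max_euler_rotation <- function(t) {
  check_affine(t)
  R <- polar_rotation(t[1:3, 1:3])
  max(abs(euler_zyx_deg(R)))
}

#' Read / write 4x4 transforms as whitespace-delimited text
#' @param path file path.
#' @return \code{read_transform} returns a 4x4 matrix.
#' @export
read_transform <- function(path) {
  m <- matrix(scan(path, quiet = TRUE), nrow = 4, byrow = TRUE)
  check_affine(m)
  m
}

#' @rdname read_transform
#' @param t 4x4 affine matrix.
#' @export
write_transform <- function(t, path) {
  check_affine(t)
  writeLines(apply(t, 1, function(r) paste(sprintf("%.12g", r),
                                           collapse = " ")), path)
  invisible(path)
}

# ---- NIfTI I/O ----

#' Read a NIfTI volume
#'
#' Spacing and origin come from the header affine. The direction matrix is
#' applied on load (axis permutations and flips) so the internal grid is
#' axis-aligned with positive spacing; oblique direction matrices are not
#' supported.
#'
#' @param path NIfTI file.
#' @param label read as a [label_volume()] (integer labels)?
#' @param scheme optional label scheme for label volumes.
#' @return a \code{scalar_volume} or \code{label_volume}.
#' @export
read_volume <- function(path, label = FALSE, scheme = NULL) {
  img <- RNifti::readNifti(path)
  X <- RNifti::xform(img)
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  D <- X[1:3, 1:3]
  spacing <- sqrt(colSums(D^2))
  dir <- sweep(D, 2, spacing, "/")
  if (max(abs(abs(dir) - (abs(dir) > 0.5))) > 1e-4)
    stop("oblique NIfTI direction matrices are not supported")
  dir <- round(dir)
  # flip reversed voxel axes, then permute voxel axes into world order
  perm <- apply(abs(dir), 2, which.max)       # world axis of each voxel axis
  flip <- dir[cbind(perm, seq_len(3))] < 0
  n <- dim(vals)
  idx <- lapply(1:3, function(ax) if (flip[ax]) rev(seq_len(n[ax]))
                else seq_len(n[ax]))
  vals <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  corner <- ifelse(flip, n - 1, 0)
  origin <- as.numeric(X[1:3, 4] + D %*% corner)  # world pos of new (0,0,0)
  ord <- order(perm)                               # voxel axis per world axis
  vals <- aperm(vals, ord)
  spacing <- spacing[ord]
  if (label) label_volume(vals, spacing = spacing, origin = origin,
                          scheme = scheme)
  else scalar_volume(vals, spacing = spacing, origin = origin)
}

#' Write a volume as NIfTI
#' @param vol a \code{scalar_volume} or \code{label_volume}.
#' @param path output path (.nii or .nii.gz; plain .nii recommended).
#' @export
write_volume <- function(vol, path) {
  A <- diag(4)
  diag(A)[1:3] <- vol$grid$spacing
  A[1:3, 4] <- vol$grid$origin
  img <- RNifti::asNifti(array(as.numeric(vol$values), dim = vol$grid$shape))
  img <- RNifti::`sform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
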