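#' Block-matching registration settings
#'
#' Defaults follow the reference configuration for fetal pseudo-US to US
#' alignment: 3x3x3-voxel blocks, exhaustive search over 7 voxels in each
#' direction, target-side variance threshold 0.04 x intensity range (all
#' nonzero-variance blocks kept on the pseudo/source side), least trimmed
#' squares keeping 75% of displacements, and a two-level pyramid at 2 mm
#' then 1 mm isotropic spacing, estimating a rigid then an affine map.
#'
#' @param block_radius block half-width in voxels (1 -> 3x3x3).
#' @param search_radius search half-width in voxels per direction.
#' @param block_step lattice step between block centres (voxels).
#' @param variance_threshold_factor fraction of the target intensity range.
#' @param lts_fraction trimming fraction h in (0, 1]; h = 1 is ordinary
#'   least squares.
#' @param levels strictly decreasing isotropic spacings (mm).
#' @param models transform sequence per level.
#' @param similarity \code{"ncc"} or \code{"cr"} (squared NCC).
#' @param max_iter outer match/estimate iterations per level and stage.
#' @param tol_mm corner-displacement convergence tolerance (mm).
#' @return list of class \code{match_settings}.
#' @export
match_settings <- function(block_radius = 1L, search_radius = 7L,
                           block_step = 2L,
                           variance_threshold_factor = 0.04,
                           lts_fraction = 0.75,
                           levels = c(2, 1),
                           models = c("rigid", "affine"),
                           similarity = c("ncc", "cr"),
                           max_iter = 10L, tol_mm = 0.1) {
  similarity <- match.arg(similarity)
  if (block_radius < 1 || search_radius < 0 || block_step < 1)
    stop("radii must be >= 1 and search_radius >= 0")
  if (lts_fraction <= 0 || lts_fraction > 1)
    stop("lts_fraction must lie in (0, 1]")
  if (length(levels) < 1 || any(diff(levels) >= 0))
    stop("levels must be strictly decreasing spacings")
  if (!all(models %in% c("rigid", "affine")))
    stop("models must be 'rigid' or 'affine'")
  structure(list(block_radius = as.integer(block_radius),
                 search_radius = as.integer(search_radius),
                 block_step = as.integer(block_step),
                 variance_threshold_factor = variance_threshold_factor,
                 lts_fraction = lts_fraction, levels = levels,
                 models = models, similarity = similarity,
                 max_iter = as.integer(max_iter), tol_mm = tol_mm),
            class = "match_settings")
}

#' Normalised cross-correlation between two blocks
#'
#' Pearson correlation of the flattened blocks; with
#' \code{similarity = "cr"} returns the squared NCC, the correlation ratio
#' under a local affine intensity model.
#'
#' @param a,b numeric blocks of equal length with positive variance.
#' @param similarity \code{"ncc"} or \code{"cr"}.
#' @return similarity in [-1, 1] (NCC) or [0, 1] (CR).
#' @export
ncc_similarity <- function(a, b, similarity = c("ncc", "cr")) {
  similarity <- match.arg(similarity)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("blocks must have equal size")
  va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
  if (va <= 0 || vb <= 0)
    stop("zero-variance block: pre-filter blocks before scoring")
  r <- sum((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
  if (similarity == "cr") r^2 else r
}

#' Select candidate blocks on a regular lattice
#'
#' Block centres lie on a lattice with \code{block_step} spacing, fully
#' inside the image. The source (pseudo-US) side keeps all blocks with
#' nonzero variance; the target side keeps blocks whose variance is at
#' least \code{variance_threshold_factor} times the image intensity range.
#'
#' @param img [scalar_volume()].
#' @param settings [match_settings()].
#' @param side \code{"source"} or \code{"target_threshold"}.
#' @param intensity_range range used for the target threshold (defaults to
#'   the range of \code{img}).
#' @return list: \code{centres} (n x 3, 0-based voxel indices),
#'   \code{variance}, \code{threshold}.
#' @export
select_source_blocks <- function(img, settings = match_settings(),
                                 side = c("source", "target_threshold"),
                                 intensity_range = NULL) {
  side <- match.arg(side)
  if (any(img$grid$shape < 2 * settings$block_radius + 1))
    stop("image smaller than one block")
  thr <- -1
  if (side == "target_threshold") {
    if (is.null(intensity_range)) intensity_range <- diff(range(img$values))
    thr <- settings$variance_threshold_factor * intensity_range
  }
  sel <- cpp_select_blocks(as.numeric(img$values), img$grid$shape,
                           settings$block_radius, settings$block_step, thr)
  if (nrow(sel$centres) == 0)
    stop("no blocks survive the variance rule (constant image?)")
  list(centres = sel$centres, variance = sel$variance, threshold = thr)
}

#' Match source blocks to their most similar target blocks
#'
#' The source volume is first warped through the current transform onto
#' the target grid, so block content is rotation/scale-compensated before
#' comparison. Blocks with nonzero variance are selected on the warped
#' source; for each, every integer-voxel offset within the search radius
#' around its (T-mapped) position is scored and the best-scoring target
#' block wins (ties: smaller Euclidean offset, then lexicographic).
#' Target candidates failing the variance threshold are skipped; source
#' blocks with no valid candidate are omitted. Displacements are reported
#' against the original (unwarped) source centroids, so
#' \code{C_i + d_i} is the matched target-space point used by the
#' least-trimmed-squares fit.
#'
#' @param source,target [scalar_volume()]s on a common resolution level.
#' @param current_T 4x4 affine (source world -> target world).
#' @param settings [match_settings()].
#' @param target_range intensity range for the target variance threshold.
#' @return \code{displacement_field}: data.frame with source centroids
#'   \code{cx, cy, cz}, displacements \code{dx, dy, dz} (matched target
#'   point minus source centroid, mm) and \code{similarity}.
#' @export
match_blocks <- function(source, target, current_T = affine_identity(),
                         settings = match_settings(), target_range = NULL) {
  check_affine(current_T)
  warped <- resample_volume(source, affine_invert(current_T), target$grid,
                            "linear")
  sel <- select_source_blocks(warped, settings, "source")
  if (is.null(target_range)) target_range <- diff(range(target$values))
  thr <- settings$variance_threshold_factor * target_range
  m <- cpp_match_blocks(as.numeric(warped$values), warped$grid$shape,
                        warped$grid$spacing, warped$grid$origin,
                        as.numeric(target$values), target$grid$shape,
                        target$grid$spacing, target$grid$origin,
                        sel$centres, affine_identity(),
                        settings$block_radius, settings$search_radius,
                        thr, settings$similarity == "cr")
  m <- m[m[, 1] == 1, , drop = FALSE]
  if (nrow(m) == 0) stop("empty displacement field")
  # map warped-space centroids back to original source coordinates
  p_src <- affine_apply(affine_invert(current_T), m[, 2:4, drop = FALSE])
  q_tgt <- m[, 2:4, drop = FALSE] + m[, 5:7, drop = FALSE]
  structure(data.frame(cx = p_src[, 1], cy = p_src[, 2], cz = p_src[, 3],
                       dx = q_tgt[, 1] - p_src[, 1],
                       dy = q_tgt[, 2] - p_src[, 2],
                       dz = q_tgt[, 3] - p_src[, 3],
                       similarity = m[, 8]),
            class = c("displacement_field", "data.frame"))
}

fit_affine_ls <- function(p, q) {
  # q ~ A p + t, least squares; requires >= 4 non-coplanar points
  X <- cbind(p, 1)
  if (qr(X)$rank < 4)
    stop("degenerate geometry: source points are coplanar (rank ",
         qr(X)$rank, " < 4)")
  B <- solve(crossprod(X), crossprod(X, q))   # 4 x 3
  rbind(cbind(t(B[1:3, ]), B[4, ]), c(0, 0, 0, 1))
}

fit_rigid_procrustes <- function(p, q) {
  if (nrow(p) < 3) stop("degenerate geometry: fewer than 3 points")
  pc <- colMeans(p); qc <- colMeans(q)
  H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
  if (qr(H)$rank < 2)
    stop("degenerate geometry: collinear points (rank ", qr(H)$rank, ")")
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qc - R %*% pc
  rbind(cbind(R, t), c(0, 0, 0, 1))
}

#' Least-trimmed-squares transform estimation from a displacement field
#'
#' Iterated concentration steps: fit the model on the current inlier set
#' (affine: linear least squares; rigid: Procrustes via the SVD of the
#' cross-covariance with determinant correction), rank the squared
#' residuals \code{||C_i + d_i - T(C_i)||^2}, keep the \code{ceil(h n)}
#' smallest (ties broken by index) and refit, until the inlier set repeats
#' or 100 iterations. \code{h = 1} reduces to ordinary least squares. The
#' trimmed objective is non-increasing across iterations.
#'
#' @param field [match_blocks()] output (or any data.frame with cx..dz).
#' @param model \code{"rigid"} or \code{"affine"}.
#' @param h trimming fraction in (0, 1].
#' @return 4x4 affine transform with attributes \code{inliers} (logical)
#'   and \code{trimmed_rms} (mm).
#' @export
lts_estimate <- function(field, model = c("rigid", "affine"), h = 0.75) {
  model <- match.arg(model)
  if (h <= 0 || h > 1) stop("h must lie in (0, 1]")
  p <- as.matrix(field[, c("cx", "cy", "cz")])
  q <- p + as.matrix(field[, c("dx", "dy", "dz")])
  n <- nrow(p)
  fit <- function(idx) {
    if (model == "affine") fit_affine_ls(p[idx, , drop = FALSE],
                                         q[idx, , drop = FALSE])
    else fit_rigid_procrustes(p[idx, , drop = FALSE], q[idx, , drop = FALSE])
  }
  keep <- max(ceiling(h * n), if (model == "affine") 4L else 3L)
  idx <- seq_len(n)
  T_cur <- fit(idx)
  if (keep >= n) {
    res2 <- rowSums((q - affine_apply(T_cur, p))^2)
    attr(T_cur, "inliers") <- rep(TRUE, n)
    attr(T_cur, "trimmed_rms") <- sqrt(mean(res2))
    return(T_cur)
  }
  prev_sets <- list()
  for (it in 1:100) {
    res2 <- rowSums((q - affine_apply(T_cur, p))^2)
    idx_new <- order(res2)[seq_len(keep)]          # index order breaks ties
    idx_new <- sort(idx_new)
    key <- paste(idx_new, collapse = ",")
    if (key %in% prev_sets) break
    prev_sets[[length(prev_sets) + 1]] <- key
    idx <- idx_new
    T_cur <- fit(idx)
  }
  res2 <- rowSums((q - affine_apply(T_cur, p))^2)
  inl <- logical(n); inl[idx] <- TRUE
  attr(T_cur, "inliers") <- inl
  attr(T_cur, "trimmed_rms") <- sqrt(mean(sort(res2)[seq_len(keep)]))
  T_cur
}

corner_displacement <- function(t_a, t_b, grid) {
  ext <- (grid$shape - 1) * grid$spacing
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  corners <- sweep(corners, 2, grid$origin, "+")
  max(sqrt(rowSums((affine_apply(t_a, corners) -
                    affine_apply(t_b, corners))^2)))
}

resample_isotropic <- function(vol, spacing_mm) {
  ext <- (vol$grid$shape - 1) * vol$grid$spacing
  shape <- pmax(2L, as.integer(floor(ext / spacing_mm)) + 1L)
  g <- volume_grid(shape, rep(spacing_mm, 3), vol$grid$origin)
  resample_volume(vol, affine_identity(), g, "linear")
}

#' Register a pseudo-ultrasound volume to an ultrasound volume
#'
#' Multi-resolution robust block matching. At each pyramid level both
#' volumes are resampled to the level's isotropic spacing; for each model
#' stage (rigid, then affine) the algorithm alternates block matching and
#' least-trimmed-squares estimation until the maximum corner displacement
#' between successive transforms falls below \code{tol_mm} or
#' \code{max_iter} iterations. The returned transform maps source world
#' coordinates (mm) to target world coordinates.
#'
#' @param source_pseudo pseudo-ultrasound [scalar_volume()] (source).
#' @param target_us preprocessed ultrasound \code{scalar_volume} (target).
#' @param init initial 4x4 affine (source -> target; default identity).
#' @param settings [match_settings()].
#' @return object of class \code{usreg}: \code{transform}, per-stage
#'   \code{stages} diagnostics (level, model, iterations, field size,
#'   trimmed RMS residual, similarity stats), \code{converged},
#'   \code{failed}, \code{settings}.
#' @export
register_us <- function(source_pseudo, target_us, init = affine_identity(),
                        settings = match_settings()) {
  check_affine(init)
  T_cur <- init
  stages <- list()
  failed <- FALSE
  for (lev in settings$levels) {
    src_l <- resample_isotropic(source_pseudo, lev)
    tgt_l <- resample_isotropic(target_us, lev)
    tgt_range <- diff(range(tgt_l$values))
    for (model in settings$models) {
      conv <- FALSE
      iters <- 0L
      fld <- NULL
      for (it in seq_len(settings$max_iter)) {
        iters <- it
        fld <- tryCatch(
          match_blocks(src_l, tgt_l, T_cur, settings, tgt_range),
          error = function(e) NULL)
        if (is.null(fld)) { failed <- TRUE; break }
        T_new <- tryCatch(
          lts_estimate(fld, model, settings$lts_fraction),
          error = function(e) NULL)
        if (is.null(T_new)) { failed <- TRUE; break }
        dc <- corner_displacement(T_new, T_cur, src_l$grid)
        T_cur <- T_new
        if (dc < settings$tol_mm) { conv <- TRUE; break }
      }
      stages[[length(stages) + 1]] <- list(
        level_mm = lev, model = model, iterations = iters,
        n_displacements = if (is.null(fld)) 0L else nrow(fld),
        trimmed_rms = if (is.null(fld)) NA_real_
                      else attr(T_cur, "trimmed_rms"),
        mean_similarity = if (is.null(fld)) NA_real_
                          else mean(fld$similarity),
        converged = conv)
      if (failed) break
    }
    if (failed) break
  }
  T_out <- T_cur
  attr(T_out, "inliers") <- NULL
  attr(T_out, "trimmed_rms") <- NULL
  structure(list(transform = T_out,
                 stages = stages, failed = failed,
                 converged = !failed && length(stages) > 0 &&
                   stages[[length(stages)]]$converged,
                 settings = settings, init = init),
            class = "usreg")
}

#' @export
print.usreg <- function(x, ...) {
  cat("Pseudo-US to US block-matching registration\n")
  rp <- rigid_params(x$transform)
  cat(sprintf("  translation (mm): %s\n",
              paste(sprintf("%.2f", rp$translation), collapse = ", ")))
  cat(sprintf("  Euler z-y-x (deg): %s\n",
              paste(sprintf("%.2f", rp$euler_deg), collapse = ", ")))
  cat(sprintf("  max Euler rotation: %.2f deg\n",
              max_euler_rotation(x$transform)))
  cat(sprintf("  stages: %d, converged: %s, failed: %s\n",
              length(x$stages), x$converged, x$failed))
  invisible(x)
}

#' @export
summary.usreg <- function(object, ...) {
  st <- do.call(rbind, lapply(object$stages, function(s)
    data.frame(level_mm = s$level_mm, model = s$model,
               iterations = s$iterations,
               n_displacements = s$n_displacements,
               trimmed_rms = s$trimmed_rms,
               mean_similarity = s$mean_similarity,
               converged = s$converged)))
  out <- list(stages = st, transform = object$transform,
              rigid = rigid_params(object$transform),
              converged = object$converged, failed = object$failed)
  class(out) <- "summary.usreg"
  out
}

#' @export
print.summary.usreg <- function(x, ...) {
  cat("Block-matching registration stages:\n")
  print(x$stages, row.names = FALSE)
  cat("\nFinal transform (source mm -> target mm):\n")
  print(round(x$transform, 5))
  invisible(x)
}

#' @export
coef.usreg <- function(object, ...) object$transform
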