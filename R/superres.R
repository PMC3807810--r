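#' Gaussian point-spread-function model of thick-slice MR acquisition
#'
#' The acquisition blur is approximated by an anisotropic 3D Gaussian with
#' through-plane FWHM equal to the slice thickness (slice selection
#' profile) and in-plane FWHM equal to 1.2 x the in-plane resolution
#' (sinc sampling). Discrete coupling coefficients are truncated at
#' 3 sigma and normalised to sum 1 per acquired voxel.
#'
#' @param slice_thickness mm.
#' @param in_plane_res mm.
#' @param recon_spacing reconstruction grid spacing, mm.
#' @return object of class \code{psf_model}: \code{sigma_mm} (x, y,
#'   through-plane z in the stack frame), \code{fwhm_mm},
#'   \code{support_radius} (recon voxels).
#' @export
make_psf <- function(slice_thickness, in_plane_res, recon_spacing) {
  if (slice_thickness <= 0 || in_plane_res <= 0 || recon_spacing <= 0)
    stop("all PSF arguments must be positive")
  f2s <- 1 / (2 * sqrt(2 * log(2)))
  fwhm <- c(1.2 * in_plane_res, 1.2 * in_plane_res, slice_thickness)
  sigma <- fwhm * f2s
  structure(list(sigma_mm = sigma, fwhm_mm = fwhm,
                 support_radius = as.integer(ceiling(3 * max(sigma) /
                                                       recon_spacing)),
                 recon_spacing = recon_spacing),
            class = "psf_model")
}

#' Discrete PSF kernel sampled on the reconstruction grid
#' @param psf [make_psf()] output.
#' @return 3D array of coefficients summing to 1.
#' @export
psf_kernel <- function(psf) {
  r <- psf$support_radius
  ax <- (-r:r) * psf$recon_spacing
  g <- function(d, s) exp(-0.5 * (d / s)^2) * (abs(d) <= 3 * s)
  k <- outer(outer(g(ax, psf$sigma_mm[1]), g(ax, psf$sigma_mm[2])),
             g(ax, psf$sigma_mm[3]))
  k / sum(k)
}

#' Thick-slice stack container
#'
#' @param values 3D array (in-plane x, in-plane y, slices) of acquired
#'   intensities.
#' @param in_plane_res,slice_thickness mm.
#' @param slice_spacing distance between slice centres, mm; defaults to
#'   the slice thickness (contiguous slices). Clinical fetal protocols
#'   often acquire with 50% overlap (spacing = thickness / 2).
#' @param poses either one 4x4 affine (stack frame -> reconstruction
#'   world, rigid) or a list of one pose per slice. In the stack frame,
#'   in-plane voxel (i, j) of slice s sits at
#'   (i * in_plane_res, j * in_plane_res, s * slice_spacing) mm
#'   (0-based), and per-slice poses see their own slice at z = 0.
#' @param scale per-stack positive intensity scale.
#' @param id stack identifier.
#' @return object of class \code{slice_stack}.
#' @export
slice_stack <- function(values, in_plane_res, slice_thickness,
                        poses = affine_identity(), scale = 1, id = "stack",
                        slice_spacing = slice_thickness) {
  stopifnot(length(dim(values)) == 3, in_plane_res > 0, slice_thickness > 0,
            slice_spacing > 0)
  if (any(!is.finite(values))) stop("stack values must be finite")
  if (scale <= 0) stop("scale must be positive")
  ns <- dim(values)[3]
  if (is.matrix(poses)) {
    base <- poses
    poses <- lapply(seq_len(ns) - 1, function(s) {
      off <- diag(4); off[3, 4] <- s * slice_spacing
      base %*% off
    })
  }
  if (length(poses) != ns) stop("need one pose per slice")
  lapply(poses, check_affine)
  structure(list(values = values, in_plane_res = in_plane_res,
                 slice_thickness = slice_thickness,
                 slice_spacing = slice_spacing, poses = poses,
                 scale = scale, id = id),
            class = "slice_stack")
}

psf_forward_slice <- function(vol, stack, psf, s) {
  pose <- stack$poses[[s]]
  Rinv <- solve(pose[1:3, 1:3])
  d <- dim(stack$values)
  cpp_psf_apply(as.numeric(vol$values), vol$grid$shape, vol$grid$spacing,
                vol$grid$origin, c(d[1], d[2], 1L),
                c(stack$in_plane_res, stack$in_plane_res,
                  stack$slice_thickness), c(0, 0, 0),
                pose, Rinv, psf$sigma_mm, 0L, numeric(0))
}

psf_adjoint_slice <- function(grid, stack, psf, s, slice_vals) {
  pose <- stack$poses[[s]]
  Rinv <- solve(pose[1:3, 1:3])
  d <- dim(stack$values)
  cpp_psf_apply(numeric(prod(grid$shape)), grid$shape, grid$spacing,
                grid$origin, c(d[1], d[2], 1L),
                c(stack$in_plane_res, stack$in_plane_res,
                  stack$slice_thickness), c(0, 0, 0),
                pose, Rinv, psf$sigma_mm, 1L, as.numeric(slice_vals))
}

#' Simulate acquired slices from a volume estimate
#'
#' Linear forward model \code{y_j = sum_i m_ij x_i} with the Gaussian PSF
#' coupling coefficients; constant volumes are reproduced exactly because
#' the coefficients sum to 1 per acquired voxel.
#'
#' @param volume [scalar_volume()] (current reconstruction estimate).
#' @param stack [slice_stack()].
#' @param psf [make_psf()].
#' @return array shaped like \code{stack$values}; voxels whose PSF support
#'   misses the volume are NA. A slice entirely outside the volume raises
#'   an error.
#' @export
simulate_slices <- function(volume, stack, psf) {
  d <- dim(stack$values)
  out <- array(NA_real_, d)
  for (s in seq_len(d[3])) {
    y <- psf_forward_slice(volume, stack, psf, s)
    if (all(is.na(y)))
      stop("slice ", s, " of ", stack$id, " lies entirely outside the volume")
    out[, , s] <- y
  }
  out
}

#' Robust inlier/outlier weights from reconstruction residuals
#'
#' Voxel level: EM on the pooled residuals with a zero-mean Gaussian
#' inlier density and a uniform outlier density over the residual range.
#' Slice level: EM with the same densities on the per-slice robust
#' residual scale (1.4826 x median absolute residual). The final weight of
#' an acquired voxel is the product of its voxel posterior and its slice's
#' posterior.
#'
#' @param residuals numeric vector of residuals \code{y* - y_sim}
#'   (NAs ignored).
#' @param slice_id integer vector grouping residuals into slices.
#' @param max_iter EM iterations (default 30).
#' @return list: \code{voxel} (posterior per residual), \code{slice}
#'   (posterior per slice, named by slice id), \code{w} (product weights),
#'   \code{sigma} (inlier sd).
#' @export
robust_weights <- function(residuals, slice_id, max_iter = 30) {
  if (length(unique(slice_id)) < 2) stop("need residuals from >= 2 slices")
  ok <- !is.na(residuals)
  e <- residuals[ok]
  if (all(e == 0) || sd(e) == 0) {
    slices <- sort(unique(slice_id))
    return(list(voxel = as.numeric(ok), w = as.numeric(ok),
                slice = setNames(rep(1, length(slices)), slices),
                sigma = 0))
  }
  em2 <- function(v) {
    # zero-mean Gaussian inlier + uniform outlier on [-R, R]
    R <- max(abs(v)) + 1e-12
    u <- 1 / (2 * R)
    sg <- max(sd(v), 1e-12)
    pi_in <- 0.9
    for (i in seq_len(max_iter)) {
      gin <- pi_in * dnorm(v, 0, sg)
      gout <- (1 - pi_in) * u
      post <- gin / (gin + gout)
      pi_new <- mean(post)
      sg_new <- sqrt(max(sum(post * v^2) / max(sum(post), 1e-12), 1e-16))
      if (abs(pi_new - pi_in) < 1e-8 && abs(sg_new - sg) < 1e-10 * sg) {
        pi_in <- pi_new; sg <- sg_new; break
      }
      pi_in <- min(max(pi_new, 1e-3), 1 - 1e-3)
      sg <- sg_new
    }
    gin <- pi_in * dnorm(v, 0, sg)
    list(post = gin / (gin + (1 - pi_in) * u), sigma = sg)
  }
  vox <- em2(e)
  voxel <- numeric(length(residuals))
  voxel[ok] <- vox$post
  slices <- sort(unique(slice_id))
  sstat <- vapply(slices, function(s) {
    es <- residuals[slice_id == s & ok]
    if (!length(es)) return(NA_real_)
    1.4826 * median(abs(es))
  }, numeric(1))
  med <- median(sstat, na.rm = TRUE)
  centred <- sstat - med
  centred[is.na(centred)] <- 0
  spost <- if (sd(centred) == 0) rep(1, length(slices))
           else em2(centred)$post
  slice <- setNames(pmin(pmax(spost, 0), 1), slices)
  w <- voxel * slice[as.character(slice_id)]
  w[!ok] <- 0
  list(voxel = voxel, slice = slice, w = as.numeric(w), sigma = vox$sigma)
}

charbonnier <- function(x, spacing, lambda, eps) {
  # value and gradient of lambda * sum sqrt(eps^2 + |grad x|^2)
  d <- dim(x)
  gx <- gy <- gz <- array(0, d)
  gx[-d[1], , ] <- (x[-1, , ] - x[-d[1], , ]) / spacing[1]
  gy[, -d[2], ] <- (x[, -1, ] - x[, -d[2], ]) / spacing[2]
  gz[, , -d[3]] <- (x[, , -1] - x[, , -d[3]]) / spacing[3]
  phi <- sqrt(eps^2 + gx^2 + gy^2 + gz^2)
  val <- lambda * sum(phi)
  # divergence of (grad x / phi)
  px <- gx / phi; py <- gy / phi; pz <- gz / phi
  div <- array(0, d)
  div[-1, , ] <- div[-1, , ] + px[-d[1], , ] / spacing[1]
  div <- div - px / spacing[1]
  div[, -1, ] <- div[, -1, ] + py[, -d[2], ] / spacing[2]
  div <- div - py / spacing[2]
  div[, , -1] <- div[, , -1] + pz[, , -d[3]] / spacing[3]
  div <- div - pz / spacing[3]
  list(value = val, grad = -lambda * div)
}

#' Super-resolution volume reconstruction from thick-slice stacks
#'
#' Minimises the robust weighted objective
#' \code{sum_j w_j (y_j* - y_j^s)^2} plus an isotropic Charbonnier
#' edge-preserving penalty by gradient descent with backtracking line
#' search. Each outer iteration re-estimates per-stack intensity scales by
#' weighted least squares, recomputes the EM inlier/outlier weights from
#' the current residuals, and runs a fixed number of descent steps on the
#' frozen weights (the objective is non-increasing across those steps).
#'
#' @param stacks list of [slice_stack()].
#' @param psf [make_psf()].
#' @param grid reconstruction [volume_grid()].
#' @param settings list; keys \code{outer_iter} (10), \code{inner_iter}
#'   (5), \code{lambda} (0.02 x range), \code{epsilon} (0.01 x range),
#'   \code{robust} (TRUE).
#' @return object of class \code{superres_recon}: \code{volume},
#'   \code{weights} (per stack, shaped like the stack), \code{scales},
#'   \code{objective} (history), \code{uncovered} (voxels with no slice
#'   coverage).
#' @export
reconstruct_volume <- function(stacks, psf, grid, settings = list()) {
  stopifnot(length(stacks) >= 1)
  s <- modifyList(list(outer_iter = 10, inner_iter = 5, lambda = NULL,
                       epsilon = NULL, robust = TRUE), settings)
  nslices <- vapply(stacks, function(st) dim(st$values)[3], integer(1))
  # initialisation: PSF-weighted scatter of the acquired data
  num <- den <- array(0, grid$shape)
  for (st in stacks)
    for (sl in seq_len(dim(st$values)[3])) {
      num <- num + array(psf_adjoint_slice(grid, st, psf, sl,
                                           st$values[, , sl]), grid$shape)
      den <- den + array(psf_adjoint_slice(grid, st, psf, sl,
                           array(1, dim(st$values)[1:2])), grid$shape)
    }
  uncovered <- den <= 1e-9
  if (any(uncovered))
    message(sum(uncovered), " voxels have no slice coverage; ",
            "kept at initialisation")
  x <- ifelse(uncovered, 0, num / pmax(den, 1e-9))
  vol <- scalar_volume(x, grid = grid)
  lambda <- s$lambda
  eps <- s$epsilon
  scales <- rep(1, length(stacks))
  obj_hist <- list()
  weights <- lapply(stacks, function(st) array(1, dim(st$values)))
  step <- 1e-3
  for (outer in seq_len(s$outer_iter)) {
    ysim <- lapply(seq_along(stacks), function(q)
      simulate_slices(vol, stacks[[q]], psf))
    # residuals at current scales, then robust weights
    res <- unlist(lapply(seq_along(stacks), function(q)
      as.numeric(scales[q] * stacks[[q]]$values - ysim[[q]])))
    sl_id <- unlist(lapply(seq_along(stacks), function(q)
      rep(seq_len(nslices[q]) + 1000 * q,
          each = prod(dim(stacks[[q]]$values)[1:2]))))
    if (s$robust && length(stacks) * min(nslices) >= 2) {
      rw <- robust_weights(res, sl_id)
      wflat <- rw$w
    } else wflat <- as.numeric(!is.na(res))
    off <- 0
    for (q in seq_along(stacks)) {
      nq <- prod(dim(stacks[[q]]$values))
      weights[[q]] <- array(wflat[off + seq_len(nq)],
                            dim(stacks[[q]]$values))
      off <- off + nq
    }
    # per-stack scale: fit scale * y_acq ~ y_sim by weighted least squares
    # (using the fresh weights so corrupted slices do not bias the fit)
    for (q in seq_along(stacks)) {
      ya <- as.numeric(stacks[[q]]$values)
      ys <- as.numeric(ysim[[q]])
      wq <- as.numeric(weights[[q]])
      ok <- !is.na(ys)
      den_s <- sum(wq[ok] * ya[ok]^2)
      if (den_s > 0) scales[q] <- sum(wq[ok] * ya[ok] * ys[ok]) / den_s
      if (!is.finite(scales[q]) || scales[q] <= 0) scales[q] <- 1
    }
    # gauge fixing: the objective is invariant to (x, s) -> (x/c, s/c);
    # anchor mean scale at 1 so intensities stay on the acquired scale
    cg <- mean(scales)
    if (is.finite(cg) && cg > 0 && abs(cg - 1) > 1e-12) {
      scales <- scales / cg
      vol <- scalar_volume(vol$values / cg, grid = grid)
      ysim <- lapply(ysim, function(y) y / cg)
    }
    if (outer == 1 && s$robust) {
      # re-initialise by weighted back-projection now that outliers are
      # identified: the unweighted start is contaminated by corrupted
      # slices that the weights have since down-weighted
      numw <- denw <- array(0, grid$shape)
      for (q in seq_along(stacks)) {
        wq <- weights[[q]]
        for (sl in seq_len(dim(wq)[3])) {
          numw <- numw + array(psf_adjoint_slice(grid, stacks[[q]], psf, sl,
                   wq[, , sl] * scales[q] * stacks[[q]]$values[, , sl]),
                   grid$shape)
          denw <- denw + array(psf_adjoint_slice(grid, stacks[[q]], psf, sl,
                   wq[, , sl]), grid$shape)
        }
      }
      # voxels whose inlier coverage is a small fraction of the typical
      # coverage would divide noise by noise; fill them from their
      # well-covered neighbourhood instead (the data term is silent
      # there, so only the initialisation speaks for them)
      keep <- !uncovered &
        denw > 0.1 * stats::median(denw[denw > 1e-9])
      xw <- array(0, grid$shape)
      xw[keep] <- (numw / pmax(denw, 1e-9))[keep]
      fill_num <- smooth_array(xw * keep, grid$spacing,
                               2 * max(grid$spacing))
      fill_den <- smooth_array(array(as.numeric(keep), grid$shape),
                               grid$spacing, 2 * max(grid$spacing))
      fill <- ifelse(fill_den > 1e-6, fill_num / pmax(fill_den, 1e-6), 0)
      xw[!keep] <- fill[!keep]
      vol <- scalar_volume(xw, grid = grid)
      ysim <- lapply(seq_along(stacks), function(q)
        simulate_slices(vol, stacks[[q]], psf))
    }
    if (outer == 1) {
      # size the edge-preserving penalty on the robustly initialised
      # volume, so corrupted slices cannot inflate the intensity range
      # and over-smooth the reconstruction
      rng <- max(diff(range(vol$values)), 1e-9)
      if (is.null(lambda)) lambda <- 0.02 * rng
      if (is.null(eps)) eps <- 0.01 * rng
    }
    # the forward model is linear, so the line search reuses the
    # simulated gradient: A(x - t g) = Ax - t Ag
    xv <- vol$values
    yx <- ysim
    data_term <- function(yx_list) {
      tot <- 0
      for (q in seq_along(stacks)) {
        e <- scales[q] * stacks[[q]]$values - yx_list[[q]]
        e[is.na(e)] <- 0
        tot <- tot + sum(weights[[q]] * e^2)
      }
      tot
    }
    f_cur <- data_term(yx) +
      charbonnier(xv, grid$spacing, lambda, eps)$value
    obj_outer <- f_cur
    for (inner in seq_len(s$inner_iter)) {
      ch <- charbonnier(xv, grid$spacing, lambda, eps)
      g <- ch$grad
      for (q in seq_along(stacks)) {
        e <- scales[q] * stacks[[q]]$values - yx[[q]]
        e[is.na(e)] <- 0
        we <- weights[[q]] * e
        for (sl in seq_len(dim(we)[3]))
          g <- g - 2 * array(psf_adjoint_slice(grid, stacks[[q]], psf, sl,
                                               we[, , sl]), grid$shape)
      }
      g[uncovered] <- 0
      gn2 <- sum(g^2)
      if (gn2 < 1e-18) break
      gvol <- scalar_volume(g, grid = grid)
      yg <- lapply(seq_along(stacks), function(q)
        simulate_slices(gvol, stacks[[q]], psf))
      step <- step * 2
      accepted <- FALSE
      repeat {
        x_try <- xv - step * g
        yx_try <- lapply(seq_along(stacks), function(q)
          yx[[q]] - step * yg[[q]])
        f_try <- data_term(yx_try) +
          charbonnier(x_try, grid$spacing, lambda, eps)$value
        if (f_try <= f_cur - 1e-4 * step * gn2) { accepted <- TRUE; break }
        if (step < 1e-12) break
        step <- step / 2
      }
      if (!accepted) break
      xv <- x_try
      yx <- yx_try
      f_cur <- f_try
      obj_outer <- c(obj_outer, f_cur)
    }
    obj_hist <- c(obj_hist, list(obj_outer))
    vol <- scalar_volume(xv, grid = grid)
  }
  structure(list(volume = vol, weights = weights, scales = scales,
                 objective = vapply(obj_hist, function(o) o[length(o)],
                                    numeric(1)),
                 objective_trace = obj_hist, uncovered = uncovered,
                 lambda = lambda, epsilon = eps),
            class = "superres_recon")
}

#' @export
print.superres_recon <- function(x, ...) {
  cat(sprintf("Super-resolution reconstruction: %d x %d x %d voxels\n",
              x$volume$grid$shape[1], x$volume$grid$shape[2],
              x$volume$grid$shape[3]))
  cat(sprintf("  objective: %s\n",
              paste(sprintf("%.4g", x$objective), collapse = " -> ")))
  invisible(x)
}
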