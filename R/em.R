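#' Probabilistic atlas priors
#'
#' Per-class prior probability volumes on the MR grid. The background class
#' must be present and is identified by name; its likelihood is modelled as
#' a two-component Gaussian mixture (amniotic fluid plus dark background).
#'
#' @param prob_list named list of 3D arrays (one per class, same dims),
#'   each voxelwise in [0, 1]; per-voxel sums must be 1 within 1e-3.
#' @param grid the shared [volume_grid()].
#' @param background name of the background class (default
#'   \code{"background"}).
#' @return object of class \code{atlas_priors} with a voxel x class
#'   probability matrix \code{p}, \code{classes} and \code{grid}.
#' @export
atlas_priors <- function(prob_list, grid, background = "background") {
  stopifnot(is.list(prob_list), length(prob_list) >= 2)
  if (is.null(names(prob_list)) || any(names(prob_list) == ""))
    stop("prob_list must be fully named")
  if (!background %in% names(prob_list))
    stop("background class '", background, "' missing from priors")
  # background last, tissues in given order
  ord <- c(setdiff(names(prob_list), background), background)
  p <- vapply(prob_list[ord], function(a) as.numeric(a),
              numeric(prod(grid$shape)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    stop("prior probabilities must lie in [0, 1]")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-3))
    stop("per-voxel prior sums must equal 1 within 1e-3")
  p <- p / rs
  structure(list(p = p, classes = ord, background = background, grid = grid),
            class = "atlas_priors")
}

#' Gaussian class parameters for EM segmentation
#'
#' @param mean,sd named numeric vectors over the tissue classes
#'   (background excluded); all \code{sd > 0}.
#' @param bg list with \code{mean}, \code{sd}, \code{w} (two components;
#'   mixing weights in (0,1) summing to 1) for the background mixture.
#' @return object of class \code{class_params}.
#' @export
class_params <- function(mean, sd, bg) {
  if (is.null(names(mean)) || !identical(names(mean), names(sd)))
    stop("mean and sd must be named identically")
  if (any(sd <= 0)) stop("all class sds must be positive")
  stopifnot(length(bg$mean) == 2, length(bg$sd) == 2, length(bg$w) == 2)
  if (any(bg$sd <= 0)) stop("background sds must be positive")
  if (any(bg$w <= 0) || abs(sum(bg$w) - 1) > 1e-9)
    stop("background mixing weights must be positive and sum to 1")
  structure(list(mean = mean, sd = sd, bg = bg), class = "class_params")
}

bg_likelihood <- function(x, bg) {
  bg$w[1] * dnorm(x, bg$mean[1], bg$sd[1]) +
    bg$w[2] * dnorm(x, bg$mean[2], bg$sd[2])
}

#' Posterior class probabilities (E step)
#'
#' Bayes combination of Gaussian class likelihoods with atlas priors:
#' \code{p_ik = N(x_i; mu_k, sigma_k) p_ik^atlas / sum_k'}. The background
#' class uses its two-component mixture likelihood. Voxels where every
#' prior-weighted likelihood vanishes are assigned to background.
#'
#' @param x_star bias-corrected intensities ([scalar_volume()]).
#' @param params [class_params()].
#' @param priors [atlas_priors()].
#' @return object of class \code{posterior_field}: matrix \code{p}
#'   (voxels x classes, rows summing to 1), \code{classes}, \code{grid}.
#' @export
em_posteriors <- function(x_star, params, priors) {
  tis <- setdiff(priors$classes, priors$background)
  if (!all(tis %in% names(params$mean)))
    stop("params missing classes: ",
         paste(setdiff(tis, names(params$mean)), collapse = ", "))
  x <- as.numeric(x_star$values)
  K <- length(priors$classes)
  lik <- matrix(0, length(x), K)
  for (k in seq_along(tis))
    lik[, k] <- dnorm(x, params$mean[[tis[k]]], params$sd[[tis[k]]])
  lik[, K] <- bg_likelihood(x, params$bg)
  num <- lik * priors$p
  rs <- rowSums(num)
  bad <- rs <= 0 | !is.finite(rs)
  if (any(bad)) {
    num[bad, ] <- 0
    num[bad, K] <- 1
    rs[bad] <- 1
  }
  structure(list(p = num / rs, classes = priors$classes,
                 background = priors$background, grid = priors$grid,
                 n_degenerate = sum(bad)),
            class = "posterior_field")
}

#' Update Gaussian class parameters (M step)
#'
#' Posterior-weighted means and variances per class; the background
#' sub-components are updated through their mixture responsibilities
#' within the background posterior. Classes with zero posterior mass are
#' frozen at their previous parameters with a warning.
#'
#' @param x_star bias-corrected intensities.
#' @param post [em_posteriors()] output.
#' @param prev previous [class_params()] (required to freeze empty classes
#'   and to split the background responsibilities).
#' @return updated [class_params()].
#' @export
update_class_params <- function(x_star, post, prev) {
  x <- as.numeric(x_star$values)
  tis <- setdiff(post$classes, post$background)
  K <- length(post$classes)
  mean_new <- prev$mean
  sd_new <- prev$sd
  for (k in seq_along(tis)) {
    w <- post$p[, k]
    sw <- sum(w)
    if (sw <= 0) {
      warning("class '", tis[k], "' has zero posterior mass; frozen")
      next
    }
    mu <- sum(w * x) / sw
    v <- sum(w * (x - mu)^2) / sw
    mean_new[[tis[k]]] <- mu
    sd_new[[tis[k]]] <- sqrt(max(v, 1e-12))
  }
  # background two-component mixture
  pb <- post$p[, K]
  bg <- prev$bg
  if (sum(pb) > 0) {
    comp <- cbind(bg$w[1] * dnorm(x, bg$mean[1], bg$sd[1]),
                  bg$w[2] * dnorm(x, bg$mean[2], bg$sd[2]))
    cs <- rowSums(comp)
    cs[cs <= 0] <- 1
    resp <- comp / cs
    for (c in 1:2) {
      w <- pb * resp[, c]
      sw <- sum(w)
      if (sw <= 0) next
      mu <- sum(w * x) / sw
      v <- sum(w * (x - mu)^2) / sw
      bg$mean[c] <- mu
      bg$sd[c] <- sqrt(max(v, 1e-12))
      bg$w[c] <- sw / sum(pb)
    }
    bg$w <- bg$w / sum(bg$w)
  }
  class_params(mean_new, sd_new, bg)
}

#' Multiplicative bias-field estimation step
#'
#' The bias-free image estimate uses inverse-variance posterior weighting,
#' \code{e_i = sum_k p_ik mu_k / sigma_k^2 / sum_k p_ik / sigma_k^2}; the
#' log residual \code{r_i = log(x_i* / e_i)} is smoothed with a weighted
#' Gaussian (weights \code{x_i* sum_k p_ik / sigma_k^2}) of standard
#' deviation \code{sigma_bias_mm}, re-centred to zero mean over the brain
#' mask, and removed multiplicatively: \code{x_i* <- x_i* exp(-b_i)}.
#'
#' @param x_star current bias-corrected intensities (positive inside the
#'   brain mask).
#' @param post posterior field.
#' @param params class parameters.
#' @param sigma_bias_mm smoothing standard deviation (default 20 mm).
#' @param mask optional logical array marking brain voxels; default is
#'   background posterior < 0.5.
#' @return list: \code{b} (log-bias [scalar_volume()]), \code{x_star}
#'   (updated volume), \code{r} (raw log residuals).
#' @export
estimate_bias <- function(x_star, post, params, sigma_bias_mm = 20,
                          mask = NULL) {
  x <- as.numeric(x_star$values)
  K <- length(post$classes)
  tis <- setdiff(post$classes, post$background)
  if (is.null(mask)) mask <- post$p[, K] < 0.5
  mask <- as.logical(mask)
  npos <- sum(mask & x <= 0)
  if (npos > 0)
    stop("estimate_bias: ", npos, " non-positive intensities inside mask")
  invvar <- 1 / params$sd[tis]^2
  num <- den <- numeric(length(x))
  for (k in seq_along(tis)) {
    num <- num + post$p[, k] * params$mean[[tis[k]]] * invvar[k]
    den <- den + post$p[, k] * invvar[k]
  }
  e <- ifelse(den > 0, num / den, 0)
  ok <- e > 0 & x > 0
  r <- numeric(length(x))
  r[ok] <- log(x[ok] / e[ok])
  w <- pmax(x, 0) * den
  w[!ok] <- 0
  sh <- x_star$grid$shape
  sp <- x_star$grid$spacing
  wr <- smooth_array(array(w * r, sh), sp, sigma_bias_mm)
  ws <- smooth_array(array(w, sh), sp, sigma_bias_mm)
  b <- ifelse(ws > 1e-12, wr / ws, 0)
  if (any(mask)) b <- b - mean(b[mask])
  xs <- x * exp(-as.numeric(b))
  list(b = scalar_volume(array(b, sh), grid = x_star$grid),
       x_star = scalar_volume(array(pmax(xs, 0), sh), grid = x_star$grid),
       r = array(r, sh))
}

init_class_params <- function(x, priors) {
  tis <- setdiff(priors$classes, priors$background)
  K <- length(priors$classes)
  mean0 <- sd0 <- setNames(numeric(length(tis)), tis)
  for (k in seq_along(tis)) {
    w <- priors$p[, k]
    sw <- sum(w)
    mu <- sum(w * x) / sw
    mean0[k] <- mu
    sd0[k] <- sqrt(max(sum(w * (x - mu)^2) / sw, 1e-12))
  }
  low <- x[priors$p[, K] > 0.5]
  if (length(low) < 10) low <- x
  q <- quantile(low, c(0.1, 0.6), names = FALSE)
  spread <- max(diff(range(x)) / 20, 1e-6)
  bg <- list(mean = q, sd = c(spread, spread), w = c(0.5, 0.5))
  class_params(mean0, sd0, bg)
}

#' EM tissue segmentation with interleaved bias correction
#'
#' Alternates [em_posteriors()], [update_class_params()] and
#' [estimate_bias()] until the largest class-mean change falls below
#' \code{tol} times the intensity range, or \code{max_iter} iterations.
#' Hard labels are the posterior argmax (background label 0).
#'
#' @param mri [scalar_volume()] on the atlas grid.
#' @param priors [atlas_priors()] on the same grid.
#' @param settings list; recognised keys \code{sigma_bias_mm} (20),
#'   \code{max_iter} (50), \code{tol} (0.001), \code{bias} (TRUE),
#'   \code{init} (optional [class_params()] to start from).
#' @return object of class \code{em_segmentation}: \code{labels}
#'   ([label_volume()]), \code{posterior}, \code{params}, \code{bias}
#'   (cumulative log-bias \code{scalar_volume}), \code{x_star},
#'   \code{converged}, \code{iterations}.
#' @export
segment_em <- function(mri, priors, settings = list()) {
  if (!grid_equal(mri$grid, priors$grid))
    stop("MR volume and atlas priors must share one grid")
  s <- modifyList(list(sigma_bias_mm = 20, max_iter = 50, tol = 0.001,
                       bias = TRUE), settings)
  x_star <- mri
  rng <- diff(range(mri$values))
  params <- if (!is.null(s$init)) s$init
            else init_class_params(as.numeric(mri$values), priors)
  tis <- setdiff(priors$classes, priors$background)
  b_total <- array(0, mri$grid$shape)
  converged <- FALSE
  it <- 0
  post <- NULL
  while (it < s$max_iter) {
    it <- it + 1
    post <- em_posteriors(x_star, params, priors)
    new_params <- update_class_params(x_star, post, params)
    dmu <- max(abs(unlist(new_params$mean[tis]) - unlist(params$mean[tis])))
    params <- new_params
    if (s$bias && all(x_star$values[post$p[, length(priors$classes)] < 0.5]
                      > 0)) {
      bs <- estimate_bias(x_star, post, params, s$sigma_bias_mm)
      x_star <- bs$x_star
      b_total <- b_total + bs$b$values
    }
    if (dmu < s$tol * rng) { converged <- TRUE; break }
  }
  post <- em_posteriors(x_star, params, priors)
  K <- length(priors$classes)
  hard <- max.col(post$p, ties.method = "first")
  lab <- integer(length(hard))
  for (k in seq_along(tis)) lab[hard == k] <- k
  scheme <- setNames(seq_along(tis), tis)
  labels <- label_volume(array(lab, mri$grid$shape), grid = mri$grid,
                         scheme = scheme)
  structure(list(labels = labels, posterior = post, params = params,
                 bias = scalar_volume(b_total, grid = mri$grid),
                 x_star = x_star, converged = converged, iterations = it),
            class = "em_segmentation")
}

#' @export
print.em_segmentation <- function(x, ...) {
  cat(sprintf("EM segmentation: %d classes, %d iterations, converged: %s\n",
              length(x$posterior$classes), x$iterations, x$converged))
  invisible(x)
}
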