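# run expr with a local RNG state derived from seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Fetal-head phantom specification
#'
#' Sizes are loosely modelled on a mid-gestation fetal head
#' (occipitofrontal > biparietal > height, biparietal diameter around
#' 55 mm at 22 weeks): the default head ellipsoid has semi-axes
#' (36, 28, 24) mm with a 2 mm skull shell, on a 96^3 grid at 1 mm
#' isotropic spacing. The nested shells (skull, CSF, echogenic brain
#' surface, hemispheres) carry a seeded random radial surface
#' irregularity (default 2 mm RMS, 5 mm correlation length, mirrored so
#' the phantom stays bilaterally symmetric) emulating the gyral and
#' skull-table irregularity of real anatomy, and large CSF-filled
#' indentations emulate the Sylvian fossae and major sulci; without such
#' block-scale surface structure the smooth analytic shells are
#' rotationally self-similar, which no feature-based matcher (and no
#' sonographer) could anchor a rotation to.
#'
#' @param grid phantom [volume_grid()].
#' @param head_semi_axes mm triple (x, y, z).
#' @param skull_thickness_mm skull shell thickness.
#' @param surface_irregularity_mm RMS amplitude of the radial surface
#'   perturbation (0 gives exact analytic ellipsoid shells).
#' @param irregularity_corr_mm correlation length of the perturbation.
#' @param seed integer; fixes the construction bitwise.
#' @param mirror flip the phantom left-right (for symmetry checks).
#' @return list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid = volume_grid(c(96, 96, 96), c(1, 1, 1)),
                         head_semi_axes = c(36, 28, 24),
                         skull_thickness_mm = 2,
                         surface_irregularity_mm = 2,
                         irregularity_corr_mm = 5,
                         seed = 1, mirror = FALSE) {
  if (any(head_semi_axes <= 0) || skull_thickness_mm <= 0)
    stop("head semi-axes and skull thickness must be positive")
  if (surface_irregularity_mm < 0 || irregularity_corr_mm <= 0)
    stop("irregularity parameters must be non-negative / positive")
  ext <- (grid$shape - 1) * grid$spacing
  if (any(2 * head_semi_axes >= ext))
    stop("head ellipsoid exceeds the grid")
  structure(list(grid = grid, head = head_semi_axes,
                 skull = skull_thickness_mm,
                 irregularity = surface_irregularity_mm,
                 irregularity_corr = irregularity_corr_mm,
                 seed = as.integer(seed), mirror = mirror),
            class = "phantom_spec")
}

# voxel-centre coordinate arrays relative to a centre point
coord_arrays <- function(grid, centre) {
  sh <- grid$shape
  x <- grid$origin[1] + (seq_len(sh[1]) - 1) * grid$spacing[1] - centre[1]
  y <- grid$origin[2] + (seq_len(sh[2]) - 1) * grid$spacing[2] - centre[2]
  z <- grid$origin[3] + (seq_len(sh[3]) - 1) * grid$spacing[3] - centre[3]
  list(x = array(rep(x, times = sh[2] * sh[3]), sh),
       y = array(rep(rep(y, each = sh[1]), times = sh[3]), sh),
       z = array(rep(z, each = sh[1] * sh[2]), sh))
}

ellipsoid_mask <- function(co, centre_off, semi) {
  ((co$x - centre_off[1]) / semi[1])^2 +
    ((co$y - centre_off[2]) / semi[2])^2 +
    ((co$z - centre_off[3]) / semi[3])^2 <= 1
}

#' Deterministic fetal-head label phantom
#'
#' Builds a [structure_scheme()] label volume: an irregular ellipsoidal
#' skull shell, a CSF layer, a thin echogenic brain surface draping
#' CSF-filled fossae/sulcal indentations (Sylvian-fossa-like lateral
#' wedges plus smaller sulci), two cortical hemispheres separated by a
#' one-voxel midline/falx gap, dark lateral-ventricle CSF lakes holding
#' elongated bright choroid plexus bodies, bilateral deep grey matter, a
#' brainstem, a cerebellum (with a darker cerebellar-WM core) and a
#' septum pellucidum slab. The same overlap precedence as
#' [build_structure_map()] applies; the construction is bitwise
#' reproducible per seed.
#'
#' @param spec [phantom_spec()].
#' @return list: \code{smap} ([label_volume()]), \code{brain_mask}
#'   (logical array: all labelled voxels except the skull), \code{wm_mask}
#'   (the two hemisphere interiors, for hemisphere-splitting tests),
#'   \code{centre} (head centre, world mm).
#' @export
make_label_phantom <- function(spec = phantom_spec()) {
  grid <- spec$grid
  centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  co <- coord_arrays(grid, centre)
  if (spec$mirror) co$x <- -co$x
  h <- spec$head
  sk <- spec$skull
  sch <- structure_scheme()
  lab <- array(0L, grid$shape)
  paint <- function(mask, name) lab[mask] <<- sch[[name]]
  # seeded, mirrored random radial perturbation of the nested shells
  rho <- 0
  if (spec$irregularity > 0) {
    rho <- with_seed(spec$seed, {
      r <- smooth_array(array(rnorm(prod(grid$shape)), grid$shape),
                        grid$spacing, spec$irregularity_corr)
      r <- (r + r[rev(seq_len(grid$shape[1])), , , drop = FALSE]) / 2
      r / sd(r) * spec$irregularity
    })
  }
  q <- sqrt((co$x / h[1])^2 + (co$y / h[2])^2 + (co$z / h[3])^2) -
    rho / mean(h)
  shell <- function(depth_mm) q <= 1 - depth_mm / mean(h)
  # CSF-filled fossae and sulci carved into the brain; the inner carve is
  # enlarged so the bright surface tier drapes each indentation
  wedges <- list(list(c(-30, 4, -2), c(10, 7, 6)),    # Sylvian fossae
                 list(c(30, 4, -2), c(10, 7, 6)),
                 list(c(-12, -24, 6), c(5, 8, 4)),    # parieto-occipital
                 list(c(12, -24, 6), c(5, 8, 4)),
                 list(c(-14, 16, 14), c(4, 6, 6)),    # frontal sulci
                 list(c(14, 16, 14), c(4, 6, 6)),
                 list(c(0, -10, 24), c(8, 5, 6)))     # superior midline
  carve <- function(grow)
    Reduce(`|`, lapply(wedges, function(w)
      ellipsoid_mask(co, w[[1]], w[[2]] + grow)))
  e_head <- shell(0)
  e_brainmask <- shell(sk)                             # brain + CSF
  e_brain <- shell(sk + 2) & !carve(0)                 # brain tissue
  e_inner <- shell(sk + 3.8) & !carve(1.8)             # below surface layer
  paint(e_brainmask & !e_brain, "csf")
  # hemispheres: inner brain split by a 1-voxel midline gap
  half_gap <- grid$spacing[1] / 2
  paint(e_inner & co$x < -half_gap, "cortical_hemisphere_L")
  paint(e_inner & co$x > half_gap, "cortical_hemisphere_R")
  # lateral ventricles: dark CSF lakes, elongated front-to-back
  vent <- ellipsoid_mask(co, c(-11, 2, 4), c(5, 12, 5)) |
    ellipsoid_mask(co, c(11, 2, 4), c(5, 12, 5))
  paint(vent & e_inner, "csf")
  # deep grey matter, bilateral
  dgm <- ellipsoid_mask(co, c(-8, 2, -2), c(8, 6, 6)) |
    ellipsoid_mask(co, c(8, 2, -2), c(8, 6, 6))
  paint(dgm & e_inner, "dgm")
  # brainstem, inferior midline
  paint(ellipsoid_mask(co, c(0, -4, -18), c(5, 5, 9)), "brainstem")
  # cerebellum, posterior-inferior, with darker WM core
  paint(ellipsoid_mask(co, c(0, -17, -13), c(11, 7, 6)), "cerebellum")
  paint(ellipsoid_mask(co, c(0, -17, -13), c(6, 3.5, 3)), "cerebellar_wm")
  # brain surface: thin echogenic shell draping the brain and fossae
  paint(e_brain & !e_inner, "brain_surface")
  # midline/falx gap between the hemispheres (outranks surface and deep
  # structures, like the real falx membrane tier)
  paint(e_inner & abs(co$x) <= half_gap, "midline_falx")
  # choroid plexus: elongated bright bodies inside the ventricles
  chor <- ellipsoid_mask(co, c(-11, 8, 4), c(4, 6, 3.5)) |
    ellipsoid_mask(co, c(-11, -2, 5), c(4, 5, 3.5)) |
    ellipsoid_mask(co, c(11, 8, 4), c(4, 6, 3.5)) |
    ellipsoid_mask(co, c(11, -2, 5), c(4, 5, 3.5))
  paint(chor & e_inner, "choroid_plexus")
  # septum pellucidum: thin anterior midline slab
  paint(abs(co$x) <= 1.2 & co$y >= 8 & co$y <= 18 &
          abs(co$z) <= 5 & e_inner, "septum_pellucidum")
  # skull shell, highest precedence
  paint(e_head & !e_brainmask, "skull")
  smap <- label_volume(lab, grid = grid, scheme = sch)
  wm <- array(lab %in% sch[c("cortical_hemisphere_L",
                             "cortical_hemisphere_R")], grid$shape)
  brain <- lab != 0L & lab != sch[["skull"]]
  list(smap = smap, brain_mask = brain, wm_mask = wm, centre = centre)
}

#' Nested-ellipsoid tissue phantom for segmentation tests
#'
#' K concentric ellipsoid shells labelled 1..K (innermost = K) inside a
#' zero background; a plain geometry for exercising the EM classifier.
#'
#' @param shape grid shape (default 64^3).
#' @param spacing mm (default 1).
#' @param n_classes number of tissue shells.
#' @return [label_volume()] with classes \code{class_1..class_K}.
#' @export
make_tissue_phantom <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                                n_classes = 3) {
  grid <- volume_grid(shape, spacing)
  centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  co <- coord_arrays(grid, centre)
  ext <- min((shape - 1) * spacing) / 2
  semi_max <- 0.85 * ext
  lab <- array(0L, grid$shape)
  for (k in seq_len(n_classes)) {
    semi <- semi_max * (n_classes - k + 1) / n_classes
    lab[ellipsoid_mask(co, c(0, 0, 0), rep(semi, 3))] <- k
  }
  label_volume(lab, grid = grid,
               scheme = setNames(seq_len(n_classes),
                                 paste0("class_", seq_len(n_classes))))
}

#' Atlas priors from a label volume
#'
#' One-hot class indicators blurred with a Gaussian, plus a background
#' class collecting the remaining probability; a stand-in for an aligned
#' probabilistic atlas in phantom experiments.
#'
#' @param labels [label_volume()] (0 = background).
#' @param sigma_mm blur (default 2 mm).
#' @param floor small probability floor keeping all classes possible
#'   everywhere (default 0.01).
#' @return [atlas_priors()].
#' @export
priors_from_labels <- function(labels, sigma_mm = 2, floor = 0.01) {
  cls <- names(labels$scheme)
  K <- length(cls)
  pl <- list()
  for (nm in cls) {
    ind <- array(as.numeric(labels$values == labels$scheme[[nm]]),
                 labels$grid$shape)
    pl[[nm]] <- smooth_array(ind, labels$grid$spacing, sigma_mm)
  }
  bg <- array(as.numeric(labels$values == 0L), labels$grid$shape)
  pl[["background"]] <- smooth_array(bg, labels$grid$spacing, sigma_mm)
  tot <- Reduce(`+`, pl)
  pl <- lapply(pl, function(a) (a / tot + floor) / (1 + (K + 1) * floor))
  atlas_priors(pl, labels$grid)
}

# smooth random multiplicative log-bias field: low-order 3D polynomial
random_bias_field <- function(grid, amplitude) {
  if (amplitude <= 0) return(array(0, grid$shape))
  centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  co <- coord_arrays(grid, centre)
  half <- (grid$shape - 1) * grid$spacing / 2
  u <- co$x / half[1]; v <- co$y / half[2]; w <- co$z / half[3]
  cf <- rnorm(9)
  g <- cf[1] * u + cf[2] * v + cf[3] * w + cf[4] * u * v + cf[5] * u * w +
    cf[6] * v * w + cf[7] * (u^2 - 1/3) + cf[8] * (v^2 - 1/3) +
    cf[9] * (w^2 - 1/3)
  g * (amplitude / max(abs(g)))
}

#' Simulate MR appearance from a label map
#'
#' Per-voxel Gaussian intensities by structure class multiplied by a
#' smooth random polynomial bias field \code{exp(g)} with
#' \code{max |g| = bias_amplitude}; the ground-truth log-bias is returned
#' for recovery tests.
#'
#' @param smap [label_volume()].
#' @param class_means,class_sds named vectors over structure names (a
#'   \code{background} entry covers label 0; missing names default to
#'   mean 0).
#' @param bias_amplitude max absolute log-bias (default 0).
#' @param seed RNG seed.
#' @return list: \code{volume} ([scalar_volume()]), \code{bias}
#'   (ground-truth log-bias array), \code{clean} (noise- and bias-free
#'   volume).
#' @export
simulate_mr <- function(smap, class_means, class_sds = 0 * class_means,
                        bias_amplitude = 0, seed = 1) {
  if (any(class_sds < 0)) stop("class sds must be non-negative")
  with_seed(seed, {
    lut_mean <- numeric(max(smap$scheme) + 1L)
    lut_sd <- numeric(max(smap$scheme) + 1L)
    if ("background" %in% names(class_means)) {
      lut_mean[1] <- class_means[["background"]]
      lut_sd[1] <- class_sds[["background"]]
    }
    for (nm in intersect(names(smap$scheme), names(class_means))) {
      lut_mean[smap$scheme[[nm]] + 1L] <- class_means[[nm]]
      lut_sd[smap$scheme[[nm]] + 1L] <- class_sds[[nm]]
    }
    sh <- smap$grid$shape
    clean <- array(lut_mean[smap$values + 1L], sh)
    noisy <- clean + array(rnorm(prod(sh)), sh) *
      array(lut_sd[smap$values + 1L], sh)
    g <- random_bias_field(smap$grid, bias_amplitude)
    if (bias_amplitude > 0 && any(smap$values > 0)) {
      # zero-mean log-bias over the labelled region: the conventional
      # gauge for multiplicative bias fields (estimators re-centre the
      # same way, so the ground truth is identifiable)
      g <- g - mean(g[smap$values > 0])
      g <- g * (bias_amplitude / max(abs(g[smap$values > 0])))
    }
    vals <- noisy * exp(g)
    list(volume = scalar_volume(vals, grid = smap$grid), bias = g,
         clean = scalar_volume(clean, grid = smap$grid))
  })
}

#' Ultrasound artefact specification
#'
#' @param transform ground-truth 4x4 affine (source pseudo world -> target
#'   ultrasound world).
#' @param speckle_sigma sd of the multiplicative log-normal speckle (0 =
#'   none).
#' @param attenuation_per_mm depth attenuation coefficient (1/mm).
#' @param probe_pos virtual probe apex, world mm (default above the +y
#'   face, set at simulation time when NULL).
#' @param shadow_halfangle_deg half-angle of the probe shadow cone (0 =
#'   no shadow).
#' @param shadow_axis unit direction of the cone axis (default -y:
#'   pointing from the probe into the head).
#' @param shadow_factor multiplicative attenuation inside the cone, in
#'   [0, 1].
#' @param noise_sd additive Gaussian noise sd (on the unit echogenicity
#'   scale, before output scaling).
#' @param seed RNG seed.
#' @param pad_voxels padding of the output grid on every side.
#' @param output_scale final intensity gain; the default 255 puts the
#'   simulated volume on the byte scale of reconstructed B-mode volumes,
#'   the scale on which the block-variance threshold (a fraction of the
#'   intensity range) is conventionally calibrated.
#' @return list of class \code{us_artifact_spec}.
#' @export
us_artifact_spec <- function(transform = affine_identity(),
                             speckle_sigma = 0.2,
                             attenuation_per_mm = 0.008,
                             probe_pos = NULL,
                             shadow_halfangle_deg = 0,
                             shadow_axis = c(0, -1, 0),
                             shadow_factor = 0.1,
                             noise_sd = 0.02, seed = 1,
                             pad_voxels = 8L, output_scale = 255) {
  check_affine(transform)
  if (shadow_factor < 0 || shadow_factor > 1)
    stop("shadow_factor must lie in [0, 1]")
  if (speckle_sigma < 0 || attenuation_per_mm < 0 || noise_sd < 0)
    stop("artefact magnitudes must be non-negative")
  structure(list(transform = transform, speckle_sigma = speckle_sigma,
                 attenuation_per_mm = attenuation_per_mm,
                 probe_pos = probe_pos,
                 shadow_halfangle_deg = shadow_halfangle_deg,
                 shadow_axis = shadow_axis / sqrt(sum(shadow_axis^2)),
                 shadow_factor = shadow_factor, noise_sd = noise_sd,
                 seed = as.integer(seed), pad_voxels = as.integer(pad_voxels),
                 output_scale = output_scale),
            class = "us_artifact_spec")
}

#' Simulate a 3D ultrasound volume from a pseudo-ultrasound image
#'
#' The pseudo image is resampled through the ground-truth transform onto a
#' padded target grid, then degraded: depth attenuation
#' \code{exp(-alpha * depth)} from the virtual probe apex, multiplicative
#' log-normal speckle, a probe shadow cone multiplied by the shadow
#' factor, and additive Gaussian noise. Deterministic per seed.
#'
#' @param pseudo [scalar_volume()] pseudo-ultrasound image.
#' @param art [us_artifact_spec()].
#' @return list: \code{us} (degraded volume), \code{transform}
#'   (ground-truth source -> target map), \code{shadow_mask} (logical),
#'   \code{clean} (resampled pseudo image before artefacts),
#'   \code{probe_pos}.
#' @export
simulate_us <- function(pseudo, art = us_artifact_spec()) {
  pad <- art$pad_voxels
  g0 <- pseudo$grid
  grid <- volume_grid(g0$shape + 2L * pad, g0$spacing,
                      g0$origin - pad * g0$spacing)
  clean <- resample_volume(pseudo, affine_invert(art$transform), grid,
                           "linear")
  probe <- art$probe_pos
  if (is.null(probe)) {
    centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
    probe <- centre - art$shadow_axis *
      (max((grid$shape - 1) * grid$spacing) * 0.75)
  }
  co <- coord_arrays(grid, probe)
  depth <- sqrt(co$x^2 + co$y^2 + co$z^2)
  out <- clean$values * exp(-art$attenuation_per_mm *
                              pmax(depth - min(depth), 0))
  # shadow cone: angle between (voxel - probe) and the cone axis
  shadow <- array(FALSE, grid$shape)
  if (art$shadow_halfangle_deg > 0 && art$shadow_factor < 1) {
    cosang <- (co$x * art$shadow_axis[1] + co$y * art$shadow_axis[2] +
                 co$z * art$shadow_axis[3]) / pmax(depth, 1e-9)
    shadow <- cosang >= cos(art$shadow_halfangle_deg * pi / 180)
    out[shadow] <- out[shadow] * art$shadow_factor
  }
  out <- with_seed(art$seed, {
    if (art$speckle_sigma > 0)
      out <- out * exp(array(rnorm(prod(grid$shape), 0, art$speckle_sigma),
                             grid$shape) - art$speckle_sigma^2 / 2)
    if (art$noise_sd > 0)
      out <- out + array(rnorm(prod(grid$shape), 0, art$noise_sd),
                         grid$shape)
    out
  })
  out <- out * art$output_scale
  list(us = scalar_volume(pmax(out, 0), grid = grid),
       transform = art$transform, shadow_mask = shadow, clean = clean,
       probe_pos = probe)
}

#' Shadow-cone half-angle occluding a given fraction of a mask
#'
#' Pure geometry: bisects the half-angle until the cone from the probe
#' apex covers the requested fraction of the mask voxels (used to set up
#' phantom studies with a stated occlusion level).
#'
#' @param mask logical array (e.g. brain mask).
#' @param grid its [volume_grid()].
#' @param probe_pos cone apex, world mm.
#' @param axis cone axis direction.
#' @param fraction target occluded fraction of the mask.
#' @return half-angle in degrees.
#' @export
shadow_halfangle_for_fraction <- function(mask, grid, probe_pos,
                                          axis = c(0, -1, 0),
                                          fraction = 0.2) {
  axis <- axis / sqrt(sum(axis^2))
  co <- coord_arrays(grid, probe_pos)
  depth <- sqrt(co$x^2 + co$y^2 + co$z^2)
  cosang <- (co$x * axis[1] + co$y * axis[2] + co$z * axis[3]) /
    pmax(depth, 1e-9)
  ang <- acos(pmin(pmax(cosang[mask], -1), 1)) * 180 / pi
  as.numeric(quantile(ang, fraction, names = FALSE))
}

#' Simulate thick-slice stacks from a volume
#'
#' Axis-aligned orthogonal stacks (slice axes cycling x, y, z) sampled
#' with [simulate_slices()]; optionally a fraction of slices is corrupted
#' by scrambling their intensities (random permutation plus a gain), the
#' classic motion artefact surrogate. The corruption mask is returned.
#'
#' @param volume [scalar_volume()] ground truth.
#' @param psf [make_psf()].
#' @param n_stacks number of stacks (>= 1).
#' @param corrupt_fraction fraction of slices to corrupt, in [0, 1).
#' @param seed RNG seed.
#' @param in_plane_res,slice_thickness stack geometry (defaults: recon
#'   spacing and PSF through-plane FWHM).
#' @param slice_spacing distance between slice centres (default
#'   thickness / 2: the 50% slice overlap of clinical fetal protocols).
#' @return list: \code{stacks} (list of [slice_stack()]), \code{corrupted}
#'   (list of logical per-slice masks), \code{clean} (uncorrupted value
#'   arrays).
#' @export
simulate_stacks <- function(volume, psf, n_stacks = 3, corrupt_fraction = 0,
                            seed = 1, in_plane_res = NULL,
                            slice_thickness = NULL, slice_spacing = NULL) {
  if (n_stacks < 1) stop("n_stacks must be >= 1")
  if (corrupt_fraction < 0 || corrupt_fraction >= 1)
    stop("corrupt_fraction must lie in [0, 1)")
  if (is.null(in_plane_res)) in_plane_res <- psf$recon_spacing
  if (is.null(slice_thickness)) slice_thickness <- psf$fwhm_mm[3]
  if (is.null(slice_spacing)) slice_spacing <- slice_thickness / 2
  g <- volume$grid
  ext <- (g$shape - 1) * g$spacing
  axes <- rep(1:3, length.out = n_stacks)
  with_seed(seed, {
    stacks <- list(); corrupted <- list(); clean <- list()
    for (q in seq_len(n_stacks)) {
      ax <- axes[q]
      inpl <- setdiff(1:3, ax)
      n1 <- max(2L, floor(ext[inpl[1]] / in_plane_res) + 1L)
      n2 <- max(2L, floor(ext[inpl[2]] / in_plane_res) + 1L)
      ns <- max(2L, floor(ext[ax] / slice_spacing) + 1L)
      # pose: stack axes (u, v, slice) -> world axes (inpl1, inpl2, ax)
      P <- matrix(0, 4, 4); P[4, 4] <- 1
      P[inpl[1], 1] <- 1; P[inpl[2], 2] <- 1; P[ax, 3] <- 1
      P[1:3, 4] <- g$origin
      vals <- array(0, c(n1, n2, ns))
      st <- slice_stack(vals, in_plane_res, slice_thickness, P,
                        id = paste0("stack", q),
                        slice_spacing = slice_spacing)
      st$values <- simulate_slices(volume, st, psf)
      st$values[is.na(st$values)] <- 0
      clean[[q]] <- st$values
      corr <- rep(FALSE, ns)
      ncor <- round(corrupt_fraction * ns)
      if (ncor > 0) {
        corr[sample.int(ns, ncor)] <- TRUE
        for (s in which(corr)) {
          v <- st$values[, , s]
          st$values[, , s] <- array(sample(as.numeric(v)) * 1.5 +
                                      0.2 * max(abs(v)), dim(v))
        }
      }
      corrupted[[q]] <- corr
      stacks[[q]] <- st
    }
    list(stacks = stacks, corrupted = corrupted, clean = clean)
  })
}

#' Tissue-class view of a structure-map phantom
#'
#' Collapses a [structure_scheme()] label volume into the six EM tissue
#' classes (WM, cortex, DGM, brainstem, cerebellum, CSF): hemispheres
#' become WM, the echogenic surface ribbon plays the cortex, cerebellar
#' WM joins the cerebellum, and the fluid-filled structures (CSF, midline
#' gap, septum region, choroid-bearing ventricles) join CSF. The skull is
#' left as background (dark on T2-weighted MR).
#'
#' @param smap [label_volume()] using [structure_scheme()].
#' @return [label_volume()] with classes wm, cortex, dgm, brainstem,
#'   cerebellum, csf.
#' @export
phantom_tissue_labels <- function(smap) {
  sch <- structure_scheme()
  v <- smap$values
  tis <- array(0L, smap$grid$shape)
  tis[v %in% sch[c("cortical_hemisphere_L", "cortical_hemisphere_R")]] <- 1L
  tis[v == sch[["brain_surface"]]] <- 2L
  tis[v == sch[["dgm"]]] <- 3L
  tis[v == sch[["brainstem"]]] <- 4L
  tis[v %in% sch[c("cerebellum", "cerebellar_wm")]] <- 5L
  tis[v %in% sch[c("csf", "midline_falx", "septum_pellucidum",
                   "choroid_plexus")]] <- 6L
  label_volume(tis, grid = smap$grid,
               scheme = c(wm = 1L, cortex = 2L, dgm = 3L, brainstem = 4L,
                          cerebellum = 5L, csf = 6L))
}

#' T2-weighted-like MR appearance defaults for the phantom
#'
#' Per-structure mean intensities (arbitrary units, CSF brightest, skull
#' and background dark) and a common noise standard deviation, for use
#' with [simulate_mr()].
#'
#' @param noise_sd per-class Gaussian noise sd (default 25).
#' @return list with \code{means} and \code{sds} named vectors.
#' @export
phantom_mr_appearance <- function(noise_sd = 25) {
  means <- c(cortical_hemisphere_L = 600, cortical_hemisphere_R = 600,
             brain_surface = 450, dgm = 500, brainstem = 480,
             cerebellum = 470, cerebellar_wm = 520, csf = 900,
             midline_falx = 900, septum_pellucidum = 460,
             choroid_plexus = 420, skull = 170, background = 120)
  list(means = means, sds = setNames(rep(noise_sd, length(means)),
                                     names(means)))
}
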