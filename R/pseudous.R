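#' Echogenicity table for pseudo-ultrasound synthesis
#'
#' Tissue brightness tiers ordered brightest to darkest. Only the ordering
#' carries information for the registration (block-wise NCC is invariant
#' to monotone intensity remapping within a tier pair); the default values
#' are a convenient strictly decreasing set. Background is always 0.
#'
#' @param tiers named numeric vector, structure name -> intensity in
#'   [0, 1], strictly decreasing in the given order. The default implements
#'   the six-tier ordering skull > choroid plexus / septi pellucidi /
#'   midline > brain surface > cerebellum > DGM / brainstem > cerebral
#'   hemispheres, with cerebellar WM sharing the darkest tier.
#' @return named numeric vector of class \code{echogenicity_table}.
#' @export
echogenicity_table <- function(tiers = NULL) {
  if (is.null(tiers)) {
    tiers <- c(skull = 1.00,
               choroid_plexus = 0.80, septum_pellucidum = 0.80,
               midline_falx = 0.80,
               brain_surface = 0.65,
               cerebellum = 0.50,
               dgm = 0.35, brainstem = 0.35,
               cortical_hemisphere_L = 0.20, cortical_hemisphere_R = 0.20,
               cerebellar_wm = 0.20,
               csf = 0.05)
  }
  if (is.null(names(tiers)) || any(names(tiers) == ""))
    stop("tiers must be fully named")
  if (any(tiers < 0) || any(tiers > 1))
    stop("tier intensities must lie in [0, 1]")
  u <- unique(as.numeric(tiers))
  if (any(diff(u) >= 0))
    stop("tier intensities must be strictly decreasing down the order")
  structure(tiers, class = "echogenicity_table")
}

#' Convert a structure map into an artefact-free pseudo-ultrasound image
#'
#' Every structure receives the uniform intensity of its echogenicity
#' tier; background voxels are 0. No speckle, attenuation or shadows are
#' modelled: the pseudo image is the idealised echogenicity pattern.
#'
#' @param smap [label_volume()] using [structure_scheme()] names.
#' @param table an [echogenicity_table()].
#' @return piecewise-constant [scalar_volume()].
#' @export
assign_pseudo_intensities <- function(smap, table = echogenicity_table()) {
  present <- names(smap$scheme)[smap$scheme %in% unique(as.vector(smap$values))]
  missing <- setdiff(present, names(table))
  if (length(missing))
    stop("structures missing from echogenicity table: ",
         paste(missing, collapse = ", "))
  lut <- numeric(max(smap$scheme) + 1L)          # index = label + 1
  for (nm in intersect(names(smap$scheme), names(table)))
    lut[smap$scheme[[nm]] + 1L] <- table[[nm]]
  vals <- array(lut[smap$values + 1L], dim = smap$grid$shape)
  scalar_volume(vals, grid = smap$grid)
}

#' Preprocess a real ultrasound volume for block matching
#'
#' Gaussian smoothing with a small kernel (speckle cannot guide the
#' registration, so it is suppressed) plus the intensity range used for
#' the block-variance threshold.
#'
#' @param us [scalar_volume()].
#' @param sigma_mm smoothing kernel (default 0.5 mm).
#' @return list: \code{us} (smoothed volume), \code{range} (max - min).
#' @export
preprocess_us <- function(us, sigma_mm = 0.5) {
  sm <- gaussian_smooth(us, sigma_mm)
  rng <- diff(range(sm$values))
  if (rng == 0)
    warning("constant ultrasound volume: intensity range 0, ",
            "all blocks will be rejected")
  list(us = sm, range = rng)
}
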