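#' End-to-end pipeline configuration
#'
#' Validates paths and settings for [run_pipeline()]. Inputs may be given
#' as file paths (NIfTI / transform text) or as in-memory objects.
#'
#' @param mri MR volume (path or [scalar_volume()]).
#' @param atlas atlas priors (path to a 4D NIfTI whose last class is
#'   background, or an [atlas_priors()] object).
#' @param us ultrasound volume (path or \code{scalar_volume}).
#' @param aux_labels named list of label masks (\code{choroid_plexus},
#'   \code{septum_pellucidum}, optional \code{cerebellar_wm}); paths or
#'   arrays.
#' @param init initial transform (path or 4x4 matrix).
#' @param ga_mode \code{"young"} or \code{"old"}.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param em_settings,match_settings,us_sigma_mm stage settings.
#' @param reference_labels optional reference [label_volume()] for the
#'   evaluation stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mri, atlas, us, aux_labels = list(),
                            init = affine_identity(),
                            ga_mode = c("young", "old"),
                            out_dir = tempfile("fetalreg_"),
                            seed = 1, em_settings = list(),
                            match_settings = fetalreg::match_settings(),
                            us_sigma_mm = 0.5,
                            reference_labels = NULL) {
  ga_mode <- match.arg(ga_mode)
  for (p in list(mri = mri, atlas = atlas, us = us)) {
    if (is.character(p) && !file.exists(p))
      stop("input file does not exist: ", p)
  }
  if (is.character(init)) init <- read_transform(init) else check_affine(init)
  structure(list(mri = mri, atlas = atlas, us = us,
                 aux_labels = aux_labels, init = init, ga_mode = ga_mode,
                 out_dir = out_dir, seed = as.integer(seed),
                 em_settings = em_settings,
                 match_settings = match_settings,
                 us_sigma_mm = us_sigma_mm,
                 reference_labels = reference_labels),
            class = "pipeline_config")
}

load_input <- function(x, kind = c("scalar", "label", "mask")) {
  kind <- match.arg(kind)
  if (is.character(x)) {
    v <- read_volume(x, label = kind != "scalar")
    if (kind == "mask") return(v$values != 0L)
    return(v)
  }
  if (kind == "mask") return(as_binary_mask(x))
  x
}

#' Run the full alignment pipeline
#'
#' Stages: EM segmentation of the MR volume, structure-map construction
#' (hemisphere split, skull shell, brain surface, midline), pseudo-US
#' synthesis, ultrasound preprocessing, block-matching registration, and
#' (when reference labels are supplied) metric evaluation. Every stage
#' output is written under \code{cfg$out_dir} together with a JSON
#' manifest (inputs, settings, content hashes, seed); a rerun with an
#' identical configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class \code{pipeline_result}: \code{registration}
#'   ([register_us()] object), \code{smap}, \code{pseudo},
#'   \code{segmentation}, \code{metrics} (or NULL), \code{manifest}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_done <- character(0)
  manifest <- list(seed = cfg$seed, ga_mode = cfg$ga_mode,
                   settings = list(em = cfg$em_settings,
                                   match = unclass(cfg$match_settings),
                                   us_sigma_mm = cfg$us_sigma_mm),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages_done <<- c(stages_done, name)
    res
  }

  mri <- load_input(cfg$mri, "scalar")
  us <- load_input(cfg$us, "scalar")
  priors <- if (is.character(cfg$atlas)) read_priors(cfg$atlas)
            else cfg$atlas
  aux <- lapply(cfg$aux_labels, load_input, kind = "mask")

  seg <- stage("segment_em", segment_em(mri, priors, cfg$em_settings))
  write_volume(seg$labels, file.path(cfg$out_dir, "em_labels.nii.gz"))
  write_volume(seg$bias, file.path(cfg$out_dir, "log_bias.nii.gz"))

  smap <- stage("structures", {
    wm <- label_mask(seg$labels, "wm")
    split <- split_hemispheres(array(wm, mri$grid$shape), seg$labels)
    brain <- seg$labels$values != 0L
    skull <- estimate_skull_shell(brain, grid = mri$grid)
    surface <- extract_brain_surface(brain, grid = mri$grid)
    build_structure_map(seg$labels, skull, surface, split$midline,
                        split$side, aux, cfg$ga_mode)
  })
  write_volume(smap, file.path(cfg$out_dir, "structure_map.nii.gz"))

  pseudo <- stage("pseudous", assign_pseudo_intensities(smap))
  write_volume(pseudo, file.path(cfg$out_dir, "pseudo_us.nii.gz"))

  reg <- stage("register", {
    pre <- preprocess_us(us, cfg$us_sigma_mm)
    register_us(pseudo, pre$us, cfg$init, cfg$match_settings)
  })
  write_transform(reg$transform, file.path(cfg$out_dir, "transform.mat"))

  metrics <- NULL
  if (!is.null(cfg$reference_labels))
    metrics <- stage("evaluate",
                     metric_report(smap, cfg$reference_labels,
                                   reg$transform))

  manifest$stages <- stages_done
  manifest$outputs <- list.files(cfg$out_dir)
  manifest$hashes <- as.list(tools::md5sum(
    file.path(cfg$out_dir, setdiff(manifest$outputs, "manifest.json"))))
  names(manifest$hashes) <- setdiff(manifest$outputs, "manifest.json")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(registration = reg, smap = smap, pseudo = pseudo,
                 segmentation = seg, metrics = metrics,
                 manifest = manifest, out_dir = cfg$out_dir),
            class = "pipeline_result")
}

#' Read atlas priors from a 4D NIfTI (last class = background)
#' @param path 4D NIfTI file.
#' @param classes optional class names (background last).
#' @return [atlas_priors()].
#' @export
read_priors <- function(path, classes = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("atlas priors must be a 4D NIfTI")
  X <- RNifti::xform(img)
  spacing <- sqrt(colSums(X[1:3, 1:3]^2))
  grid <- volume_grid(d[1:3], spacing, X[1:3, 4])
  if (is.null(classes))
    classes <- c(paste0("class_", seq_len(d[4] - 1)), "background")
  pl <- setNames(lapply(seq_len(d[4]), function(k)
    array(as.numeric(img[, , , k]), d[1:3])), classes)
  atlas_priors(pl, grid)
}
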