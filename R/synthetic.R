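#' Specify a synthetic thermal leaf scene
#'
#' Describes one simulated leaf-against-backdrop thermal image: a leaf-shaped
#' warm or cool region on a uniform paper backdrop, optics blur, and additive
#' sensor noise. The generator gives every downstream stage a ground truth:
#' the pre-blur leaf support is recorded as the true mask.
#'
#' Leaf pixels are drawn as `leaf_temp_mean` plus a smooth within-leaf ramp
#' of amplitude `leaf_temp_sd` plus iid Gaussian jitter with sd
#' `leaf_temp_sd`; with `leaf_temp_sd = 0` every leaf pixel equals
#' `leaf_temp_mean` exactly. The whole frame is then Gaussian-blurred
#' (`blur_sigma` pixels) and perturbed with iid sensor noise (`noise_sd`
#' degrees Celsius).
#'
#' @param shape Integer length-2, frame rows and columns (pixels).
#' @param background_temp Backdrop temperature, degrees Celsius.
#' @param leaf_temp_mean Mean leaf temperature, degrees Celsius.
#' @param leaf_temp_sd Within-leaf temperature spread, degrees Celsius.
#' @param noise_sd Sensor noise sd applied to the whole frame, degrees Celsius.
#' @param blur_sigma Gaussian optics blur, pixels; 0 disables.
#' @param leaf_geometry One of `"ellipse"`, `"lobed"`, `"okra"`. The lobed and
#'   okra shapes are unions of rotated ellipses; they exercise mask topology
#'   (concavities), with no botanical fidelity claimed.
#' @param size_frac Leaf major semi-axis as a fraction of the shorter frame
#'   side.
#' @param rotation Leaf rotation, radians.
#' @param center Leaf center `(row, col)`; default frame center.
#' @param seed Integer seed; the scene is a pure function of the spec.
#'
#' @return A `leaf_scene_spec` list.
#' @export
leaf_scene_spec <- function(shape = c(96L, 128L), background_temp = 22,
                            leaf_temp_mean = 24.5, leaf_temp_sd = 0.3,
                            noise_sd = 0.2, blur_sigma = 1,
                            leaf_geometry = c("ellipse", "lobed", "okra"),
                            size_frac = 0.32, rotation = 0,
                            center = NULL, seed = 1L) {
  leaf_geometry <- rlang::arg_match(leaf_geometry)
  stopifnot(length(shape) == 2L, shape[1] >= 8, shape[2] >= 8,
            noise_sd >= 0, blur_sigma >= 0, leaf_temp_sd >= 0,
            size_frac > 0)
  if (is.null(center)) center <- (shape + 1) / 2
  structure(
    list(shape = as.integer(shape), background_temp = background_temp,
         leaf_temp_mean = leaf_temp_mean, leaf_temp_sd = leaf_temp_sd,
         noise_sd = noise_sd, blur_sigma = blur_sigma,
         leaf_geometry = leaf_geometry, size_frac = size_frac,
         rotation = rotation, center = center, seed = as.integer(seed)),
    class = "leaf_scene_spec"
  )
}

# membership + analytic bounding half-extents of a union of rotated ellipses;
# each component: (dr, dc) offset from center, semi-axes (a, b), angle theta
leaf_support <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  s <- spec$size_frac * min(H, W)
  comps <- switch(spec$leaf_geometry,
    ellipse = list(c(0, 0, s, 0.68 * s, 0)),
    lobed = lapply(c(-0.9, 0, 0.9), function(th)
      c(0, 0, s, 0.38 * s, th)),
    okra = lapply(seq(0, pi * 4 / 5, length.out = 5), function(th)
      c(0, 0, s, 0.22 * s, th))
  )
  cy <- spec$center[1]; cx <- spec$center[2]
  ex <- 0; ey <- 0
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- matrix(FALSE, H, W)
  for (cc in comps) {
    a <- cc[3]; b <- cc[4]; th <- cc[5] + spec$rotation
    # half-extents of the rotated ellipse bounding box
    ey <- max(ey, sqrt((a * sin(th))^2 + (b * cos(th))^2))
    ex <- max(ex, sqrt((a * cos(th))^2 + (b * sin(th))^2))
    dy <- r - (cy + cc[1]); dx <- c_ - (cx + cc[2])
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  if (cy - ey < 1 || cy + ey > H || cx - ex < 1 || cx + ex > W) {
    rlang::abort("leaf geometry exceeds frame bounds", class = "thermoleaf_spec_error")
  }
  frac <- mean(mask)
  if (frac < 0.05 || frac > 0.70) {
    rlang::abort(
      sprintf("leaf area is %.1f%% of the frame; must be within 5%%-70%%", 100 * frac),
      class = "thermoleaf_spec_error"
    )
  }
  mask
}

#' Generate one synthetic thermal leaf scene
#'
#' @param spec A [leaf_scene_spec()].
#' @param sample_id,treatment Metadata stored on the generated frame.
#' @return A `synthetic_sample` list with elements `frame` (a
#'   [thermal_frame()]), `truth_mask` (a [leaf_mask()] recording the pre-blur
#'   leaf support), and `treatment`.
#' @export
generate_leaf_scene <- function(spec, sample_id = "synthetic", treatment = "unknown") {
  stopifnot(inherits(spec, "leaf_scene_spec"))
  support <- leaf_support(spec)
  H <- spec$shape[1]; W <- spec$shape[2]
  img <- withr::with_seed(spec$seed, {
    m <- matrix(spec$background_temp, H, W)
    n_leaf <- sum(support)
    # smooth within-leaf ramp along the image diagonal, amplitude leaf_temp_sd
    ramp <- (matrix(seq_len(H), H, W) / H + matrix(seq_len(W), H, W, byrow = TRUE) / W - 1)
    rampv <- ramp[support]
    if (n_leaf > 0 && diff(range(rampv)) > 0) {
      rampv <- 2 * (rampv - min(rampv)) / diff(range(rampv)) - 1
    } else {
      rampv <- rep(0, n_leaf)
    }
    m[support] <- spec$leaf_temp_mean + spec$leaf_temp_sd * rampv +
      stats::rnorm(n_leaf, 0, spec$leaf_temp_sd)
    if (spec$blur_sigma > 0) {
      m <- EBImage::gblur(m, sigma = spec$blur_sigma, boundary = "replicate")
    }
    if (spec$noise_sd > 0) m <- m + stats::rnorm(H * W, 0, spec$noise_sd)
    m
  })
  structure(
    list(
      frame = thermal_frame(img, sample_id = sample_id, treatment = treatment),
      truth_mask = leaf_mask(support),
      treatment = treatment
    ),
    class = "synthetic_sample"
  )
}

#' Generate a labeled synthetic cohort of leaf scenes
#'
#' Emulates a balanced two-treatment imaging campaign: well-watered (WW)
#' leaves stay cooler through transpiration, while dry-down (DD) leaves warm
#' as stomata close, modeled as a mean temperature offset (`dd_offset`,
#' default +2 degrees Celsius) of the DD class over WW. Per-sample leaf
#' temperature, size, rotation and geometry are jittered to mimic genotype
#' diversity.
#'
#' @param n_per_class Scenes per treatment class.
#' @param ww_params A [leaf_scene_spec()] template for the WW class.
#' @param dd_offset DD minus WW mean leaf temperature, degrees Celsius.
#' @param genotype_sd Between-sample sd of mean leaf temperature, degrees
#'   Celsius (genotype diversity).
#' @param seed Integer master seed; per-sample seeds derive from it.
#' @return A tibble with columns `sample_id`, `treatment`, `frame`
#'   (list of [thermal_frame()]), `truth_mask` (list of [leaf_mask()]).
#' @export
generate_cohort <- function(n_per_class, ww_params = leaf_scene_spec(),
                            dd_offset = 2.0, genotype_sd = 0.8, seed = 1L) {
  stopifnot(n_per_class >= 1)
  geoms <- c("ellipse", "lobed", "okra")
  draws <- withr::with_seed(seed, tibble::tibble(
    treatment = rep(c("WW", "DD"), each = n_per_class),
    temp_jit = stats::rnorm(2 * n_per_class, 0, genotype_sd),
    size_jit = stats::runif(2 * n_per_class, 0.85, 1.1),
    rot = stats::runif(2 * n_per_class, 0, pi),
    geom = sample(geoms, 2 * n_per_class, replace = TRUE),
    sub_seed = sample.int(.Machine$integer.max, 2 * n_per_class)
  ))
  samples <- purrr::pmap(draws, function(treatment, temp_jit, size_jit, rot, geom, sub_seed) {
    sp <- ww_params
    sp$leaf_temp_mean <- ww_params$leaf_temp_mean + temp_jit +
      if (treatment == "DD") dd_offset else 0
    sp$size_frac <- ww_params$size_frac * size_jit
    sp$rotation <- rot
    sp$leaf_geometry <- geom
    sp$seed <- sub_seed
    sp
  })
  ids <- sprintf("%s_%03d", tolower(draws$treatment),
                 stats::ave(seq_len(nrow(draws)), draws$treatment, FUN = seq_along))
  out <- purrr::map2(samples, seq_along(samples), function(sp, i) {
    generate_leaf_scene(sp, sample_id = ids[i], treatment = draws$treatment[i])
  })
  tibble::tibble(
    sample_id = ids,
    treatment = draws$treatment,
    frame = purrr::map(out, "frame"),
    truth_mask = purrr::map(out, "truth_mask")
  )
}

#' Write a synthetic cohort to disk as thermal CSVs plus manifest
#'
#' Writes one thermal CSV per scene, ground-truth masks as 0/255 PNG, and a
#' sample manifest readable by [load_manifest()].
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  paths <- purrr::map2_chr(cohort$frame, cohort$sample_id, function(fr, id) {
    p <- file.path(dir, paste0(id, ".csv"))
    write_thermal_csv(fr, p)
    p
  })
  purrr::walk2(cohort$truth_mask, cohort$sample_id, function(mk, id) {
    EBImage::writeImage(
      EBImage::Image(t(mk$values)),
      file.path(mask_dir, paste0(id, "_truth.png"))
    )
  })
  manifest <- tibble::tibble(
    sample_id = cohort$sample_id, path = paths, genotype = "synthetic",
    treatment = cohort$treatment, timepoint = "unknown",
    drought_stage = ifelse(cohort$treatment == "DD", "mild", "none"),
    replicate = 1L
  )
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath, progress = FALSE)
  invisible(mpath)
}
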