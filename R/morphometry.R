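#' Mineral-density threshold ladder
#'
#' The ladder of binarization thresholds for dynamic morphometry: 200 to
#' 920 mg HA/cm^3 in 120 mg HA/cm^3 steps. Thresholds above `trabecular_max`
#' (680) are ignored in the trabecular compartment; 320 is the standardized
#' analysis threshold.
#'
#' @param thresholds Strictly increasing densities (mg HA/cm^3).
#' @param trabecular_max Largest threshold applied to trabecular bone.
#' @param standardized The standardized analysis threshold.
#' @return An object of class `threshold_ladder`.
#' @export
threshold_ladder <- function(thresholds = seq(200, 920, by = 120),
                             trabecular_max = 680, standardized = 320) {
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (!standardized %in% thresholds)
    stop("the standardized threshold must be in the ladder", call. = FALSE)
  if (!trabecular_max %in% thresholds)
    stop("trabecular_max must be in the ladder", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 trabecular_max = trabecular_max, standardized = standardized),
            class = "threshold_ladder")
}

#' Binarize a density image
#'
#' A voxel is bone iff its density is greater than or equal to the threshold.
#'
#' @param image A [density_image()].
#' @param threshold Density threshold (mg HA/cm^3), non-negative.
#' @return 3D logical array.
#' @export
binarize <- function(image, threshold) {
  stopifnot(is_density_image(image))
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  image$values >= threshold
}

new_remodeling_labels <- function(labels, threshold, region) {
  structure(list(labels = labels, threshold = threshold, region = region),
            class = "remodeling_labels")
}

#' @export
print.remodeling_labels <- function(x, ...) {
  cat(sprintf(
    "<remodeling_labels> threshold %.0f: %d formed, %d resorbed, %d quiescent (region %d voxels)\n",
    x$threshold, sum(x$labels == 1L), sum(x$labels == 2L),
    sum(x$labels == 3L), sum(x$region)))
  invisible(x)
}

#' Classify voxels as formed, resorbed or quiescent
#'
#' Compares baseline and follow-up bone sets inside a common analysis region:
#' formed = follow-up only, resorbed = baseline only, quiescent = both,
#' background otherwise. Voxels outside the region are background.
#'
#' @param baseline_bone,followup_bone Congruent logical arrays (e.g. from
#'   [binarize()] of registered, resampled images).
#' @param region Logical array restricting the analysis (e.g. from
#'   [common_region()]); must be non-empty.
#' @param threshold The density threshold the bone sets were produced with
#'   (metadata only).
#' @param min_cluster Minimum 6-connected cluster size for formed/resorbed
#'   events; smaller clusters are reverted (formed to background, resorbed to
#'   quiescent). Off by default (`1`), exposed because some time-lapse
#'   protocols remove single-voxel islands as noise.
#' @return A `remodeling_labels` object: integer label array
#'   (0 background, 1 formed, 2 resorbed, 3 quiescent), threshold, region.
#' @export
classify_remodeling <- function(baseline_bone, followup_bone, region,
                                threshold = NA_real_, min_cluster = 1L) {
  stopifnot_congruent(baseline_bone, followup_bone)
  stopifnot_congruent(baseline_bone, region)
  if (!any(region)) stop("analysis region is empty", call. = FALSE)
  labels <- array(0L, dim(baseline_bone))
  labels[region & followup_bone & !baseline_bone] <- 1L
  labels[region & baseline_bone & !followup_bone] <- 2L
  labels[region & baseline_bone & followup_bone] <- 3L
  if (min_cluster > 1L) {
    for (code in c(1L, 2L)) {
      m <- labels == code
      if (!any(m)) next
      cl <- array(cpp_label6(m, dim(m)), dim(m))
      small <- which(tabulate(cl) < min_cluster)
      drop <- m & array(cl %in% small, dim(m))
      labels[drop] <- if (code == 1L) 0L else 3L
    }
  }
  new_remodeling_labels(labels, threshold, region)
}

#' Remodeling volume fractions per compartment
#'
#' Formation and resorption volume fractions relative to the baseline bone
#' volume at the classification threshold, per compartment. A compartment
#' with no baseline bone yields `NA` fractions with a warning.
#'
#' @param labels A [classify_remodeling()] result.
#' @param masks A [bone_masks()].
#' @param voxel_size Voxel edge (mm) for absolute volumes.
#' @return A tibble with one row per compartment: `compartment`, `threshold`,
#'   `n_baseline`, `baseline_volume_mm3`, `formation_vf`, `resorption_vf`.
#' @export
remodeling_fractions <- function(labels, masks, voxel_size) {
  stopifnot(inherits(labels, "remodeling_labels"),
            inherits(masks, "bone_masks"))
  stopifnot_congruent(labels$labels, masks$whole)
  vv <- voxel_size^3
  one <- function(comp) {
    m <- masks[[comp]]
    baseline <- sum((labels$labels == 2L | labels$labels == 3L) & m)
    formed <- sum(labels$labels == 1L & m)
    resorbed <- sum(labels$labels == 2L & m)
    if (baseline == 0) {
      warning(sprintf("no baseline bone in the %s compartment; fractions undefined",
                      comp), call. = FALSE)
      fvf <- NA_real_; rvf <- NA_real_
    } else {
      fvf <- formed / baseline
      rvf <- resorbed / baseline
    }
    tibble::tibble(compartment = comp, threshold = labels$threshold,
                   n_baseline = baseline,
                   baseline_volume_mm3 = baseline * vv,
                   formation_vf = fvf, resorption_vf = rvf)
  }
  rbind(one("cortical"), one("trabecular"))
}

#' Remodeling fractions across the threshold ladder
#'
#' Runs the full dynamic-morphometry chain for every threshold in the ladder:
#' optional constrained Gaussian denoising of both images, binarization,
#' voxel classification within the common region, and per-compartment volume
#' fractions. Trabecular rows are reported only for thresholds up to the
#' ladder's `trabecular_max`.
#'
#' @param baseline,followup_aligned Registered, congruent [density_image()]s
#'   (follow-up already resampled into the baseline frame).
#' @param masks Baseline [bone_masks()].
#' @param ladder A [threshold_ladder()].
#' @param region Analysis region (logical array); the whole mask by default.
#' @param denoise Apply the constrained Gaussian filter first (default TRUE).
#' @param sigma,truncate,support Filter parameters, see [denoise()].
#' @return A tibble (one row per threshold x compartment) as in
#'   [remodeling_fractions()].
#' @export
threshold_sweep <- function(baseline, followup_aligned, masks,
                            ladder = threshold_ladder(), region = NULL,
                            denoise = TRUE, sigma = 1.2, truncate = 0.8,
                            support = 1.0) {
  stopifnot_congruent(baseline, followup_aligned)
  region <- region %||% masks$whole
  if (denoise) {
    baseline <- denoise(baseline, sigma, truncate, support)
    followup_aligned <- denoise(followup_aligned, sigma, truncate, support)
  }
  rows <- lapply(ladder$thresholds, function(thr) {
    lab <- classify_remodeling(binarize(baseline, thr),
                               binarize(followup_aligned, thr),
                               region, threshold = thr)
    fr <- remodeling_fractions(lab, masks, baseline$voxel_size)
    if (thr > ladder$trabecular_max)
      fr <- fr[fr$compartment != "trabecular", , drop = FALSE]
    fr
  })
  do.call(rbind, rows)
}

#' Static densitometric summaries
#'
#' Plumbing-level static measures: bone volume fraction (BV/TV) at a given
#' threshold and mean density, per region (whole bone and compartments).
#'
#' @param image A [density_image()].
#' @param masks A [bone_masks()].
#' @param threshold Bone threshold for BV/TV (default the standardized 320).
#' @return A tibble with `region`, `n_voxels`, `bvtv`, `mean_density`.
#' @export
static_summaries <- function(image, masks, threshold = 320) {
  stopifnot(is_density_image(image), inherits(masks, "bone_masks"))
  stopifnot_congruent(image$values, masks$whole)
  bone <- binarize(image, threshold)
  one <- function(region) {
    m <- masks[[region]]
    n <- sum(m)
    if (n == 0) stop(sprintf("the %s mask is empty", region), call. = FALSE)
    tibble::tibble(region = region, n_voxels = n, bvtv = sum(bone & m) / n,
                   mean_density = mean(image$values[m]))
  }
  rbind(one("whole"), one("cortical"), one("trabecular"))
}
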