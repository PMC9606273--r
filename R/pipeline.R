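#' Configuration of an end-to-end subject run
#'
#' Collects every stage's parameters exactly once. By default the run is a
#' self-contained phantom study: a synthetic baseline/follow-up pair with a
#' known misalignment and a known mechanoregulation rule, pushed through
#' registration, dynamic morphometry, micro-FE and mechanoregulation.
#' Supplying `baseline_path`/`followup_path` analyses images from disk
#' instead.
#'
#' @param phantom A [phantom_params()] (ignored when image paths are given).
#'   The default grid is kept modest (52 x 52 x 64 voxels) so a full run
#'   completes in minutes on one CPU.
#' @param rule A [mechanoreg_rule()] driving the simulated remodeling. The
#'   config default uses `event_rate = 0.25`: a realistic per-interval
#'   turnover, at which surface remodeling does not masquerade as a rigid
#'   motion of the tapered shaft (bulk single-interval growth of most of the
#'   cortical surface genuinely confounds rigid registration).
#' @param misalignment `"random"` (rotations up to `misalign_rot_deg`,
#'   translation magnitude up to `misalign_trans_vox` voxels, drawn from the
#'   seed) or a fixed [rigid_transform()].
#' @param misalign_rot_deg,misalign_trans_vox Sampling bounds for the random
#'   misalignment.
#' @param baseline_path,followup_path Optional image files (see
#'   [read_image()]).
#' @param ladder A [threshold_ladder()].
#' @param filter List of constrained-Gaussian parameters
#'   (`sigma`, `truncate`, `support`).
#' @param denoise Apply the filter in dynamic morphometry (default TRUE).
#' @param law A [material_law()].
#' @param applied_strain Compression level for the micro-FE stage.
#' @param fe_tolerance Relative residual for the FE solver.
#' @param strain_source `"fe"` (micro-FE effective strain, the default) or
#'   `"depth_ramp"` (surrogate ramp; useful for fast validation runs).
#' @param truth_strain Strain field driving the simulated remodeling: `"fe"`
#'   (the phantom's own micro-FE field, the default) or `"depth_ramp"`. A
#'   ramp at a high event rate makes remodeling a systematic axial drift of
#'   the bone surface, which genuinely confounds rigid registration; the FE
#'   field has no such drift.
#' @param bin_width,min_count CP binning parameters, see [cp_curves()].
#' @param cp_type_weights CP conditioning convention, see [cp_curves()];
#'   the pipeline default `"equal"` equalizes event-type priors, which is
#'   what makes remodeling thresholds identifiable at physiological event
#'   rates where quiescence dominates every bin in raw counts.
#' @param normalization `"subject"` (the subject's own 99th-percentile
#'   effective strain) or a positive number (microstrain), e.g. a
#'   cohort-average constant.
#' @param registration_levels Pyramid levels for [register_rigid()].
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for report and tables.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_params(grid = c(52, 52, 64),
                                                outer_radius = 0.95,
                                                inner_radius = 0.68,
                                                taper = 0.3),
                       rule = mechanoreg_rule(event_rate = 0.25),
                       misalignment = "random",
                       misalign_rot_deg = 5, misalign_trans_vox = 5,
                       baseline_path = NULL, followup_path = NULL,
                       ladder = threshold_ladder(),
                       filter = list(sigma = 1.2, truncate = 0.8,
                                     support = 1.0),
                       denoise = TRUE,
                       law = material_law(), applied_strain = 0.01,
                       fe_tolerance = 1e-6,
                       strain_source = c("fe", "depth_ramp"),
                       truth_strain = c("fe", "depth_ramp"),
                       bin_width = 0.01, min_count = 10L,
                       cp_type_weights = c("equal", "counts"),
                       normalization = "subject",
                       registration_levels = 3L,
                       seed = 1L, out_dir = NULL) {
  strain_source <- match.arg(strain_source)
  truth_strain <- match.arg(truth_strain)
  cp_type_weights <- match.arg(cp_type_weights)
  structure(list(phantom = phantom, rule = rule, misalignment = misalignment,
                 misalign_rot_deg = misalign_rot_deg,
                 misalign_trans_vox = misalign_trans_vox,
                 baseline_path = baseline_path, followup_path = followup_path,
                 ladder = ladder, filter = filter, denoise = denoise,
                 law = law, applied_strain = applied_strain,
                 fe_tolerance = fe_tolerance, strain_source = strain_source,
                 truth_strain = truth_strain,
                 bin_width = bin_width, min_count = as.integer(min_count),
                 cp_type_weights = cp_type_weights,
                 normalization = normalization,
                 registration_levels = as.integer(registration_levels),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

sample_misalignment <- function(config, center, seed) {
  if (inherits(config$misalignment, "rigid_transform"))
    return(config$misalignment)
  set.seed(seed)
  rot <- runif(3, -1, 1) * config$misalign_rot_deg * pi / 180
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  mag <- runif(1, 0, config$misalign_trans_vox) * config$phantom$voxel_size
  rigid_transform(rotation = rot, translation = dir * mag, center = center)
}

#' Run the full pipeline for one subject
#'
#' Executes, in order: phantom generation (or image loading), rigid
#' registration of the follow-up onto the baseline, cubic resampling, mask
#' generation, common-region restriction, the dynamic-morphometry threshold
#' sweep, the micro-FE compression analysis, and the mechanoregulation
#' analysis at the standardized threshold. Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @return An object of class `subject_report`; when `config$out_dir` is set,
#'   also writes `report.json`, `fractions.csv`, `cp.csv` and
#'   `strain_percentiles.csv` there.
#' @export
run_subject <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 4L)
  truth <- NULL
  if (is.null(config$baseline_path)) {
    pp <- config$phantom
    pp$seed <- seeds[1]
    ph <- make_phantom(pp)
    strain_true <- if (config$truth_strain == "fe") {
      surrogate_strain(ph$masks, "fe", image = ph$geometry,
                       law = config$law,
                       applied_strain = config$applied_strain)
    } else {
      surrogate_strain(ph$masks, "depth_ramp")
    }
    mis <- sample_misalignment(config, grid_center(ph$image), seeds[2])
    fu <- simulate_followup(ph, strain_true, config$rule,
                            misalignment = mis, seed = seeds[3],
                            bone_threshold = config$ladder$standardized)
    baseline <- ph$image
    followup <- fu$image
    truth <- fu$truth
  } else {
    baseline <- read_image(config$baseline_path)
    followup <- read_image(config$followup_path)
  }

  reg <- register_rigid(baseline, followup,
                        levels = config$registration_levels)
  fu_aligned <- resample(followup, reg$transform, "cubic", fill = 0)

  masks <- generate_masks(baseline, apply_filter = config$denoise)
  masks_mov <- generate_masks(followup, apply_filter = config$denoise)
  region <- common_region(masks, masks_mov, reg$transform, like = baseline)

  fractions <- threshold_sweep(baseline, fu_aligned, masks,
                               ladder = config$ladder, region = region,
                               denoise = config$denoise,
                               sigma = config$filter$sigma,
                               truncate = config$filter$truncate,
                               support = config$filter$support)

  fl <- config$filter
  base_d <- if (config$denoise)
    denoise(baseline, fl$sigma, fl$truncate, fl$support) else baseline
  fu_d <- if (config$denoise)
    denoise(fu_aligned, fl$sigma, fl$truncate, fl$support) else fu_aligned

  mesh <- build_mesh(base_d, masks, config$law)
  fe <- solve_compression(mesh, applied_strain = config$applied_strain,
                          tolerance = config$fe_tolerance)
  percentiles <- strain_percentiles(fe, masks)
  p99 <- quantile(fe$eps_eff_ue, 0.99, names = FALSE)

  thr <- config$ladder$standardized
  baseline_bone <- binarize(base_d, thr)
  labels <- classify_remodeling(baseline_bone, binarize(fu_d, thr), region,
                                threshold = thr)
  strain_grid <- if (config$strain_source == "fe") {
    fe_strain_grid(fe)
  } else {
    surrogate_strain(masks, "depth_ramp") * p99
  }
  events <- extract_surface_events(labels, baseline_bone, strain_grid)
  norm_const <- if (identical(config$normalization, "subject")) p99
                else as.numeric(config$normalization)
  events <- normalize_strains(events, norm_const)
  cp <- cp_curves(events, bin_width = config$bin_width,
                  min_count = config$min_count,
                  type_weights = config$cp_type_weights)
  thresholds <- derive_thresholds(cp)
  rate <- if (anyNA(thresholds)) NA_real_ else ccr(events, thresholds)

  report <- structure(list(
    fractions = fractions,
    stiffness_kN_mm = fe$stiffness_kN_mm,
    strain_percentiles = percentiles,
    p99_ue = p99,
    normalization_constant = norm_const,
    thresholds = thresholds,
    ccr = rate,
    cp = cp,
    events = events,
    registration = list(transform = reg$transform,
                        final_mse = reg$final_mse,
                        initial_mse = reg$initial_mse,
                        converged = reg$converged),
    truth = truth,
    n_region = sum(region),
    n_elements = length(mesh$elements),
    config_hash = config_hash(config),
    seed = config$seed), class = "subject_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> stiffness %.3f kN/mm; p99 %.0f ue; Tr %.2f Tf %.2f; CCR %.3f\n",
              x$stiffness_kN_mm, x$p99_ue, x$thresholds[["Tr"]],
              x$thresholds[["Tf"]], x$ccr))
  invisible(x)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(report$fractions, file.path(out_dir, "fractions.csv"),
            row.names = FALSE)
  write.csv(report$strain_percentiles,
            file.path(out_dir, "strain_percentiles.csv"), row.names = FALSE)
  write.csv(report$cp$bins, file.path(out_dir, "cp.csv"), row.names = FALSE)
  tfm <- report$registration$transform
  jsonlite::write_json(list(
    stiffness_kN_mm = report$stiffness_kN_mm,
    p99_ue = report$p99_ue,
    normalization_constant = report$normalization_constant,
    Tr = report$thresholds[["Tr"]],
    Tf = report$thresholds[["Tf"]],
    ccr = report$ccr,
    n_region = report$n_region,
    registration = list(rotation = tfm$rotation,
                        translation = tfm$translation,
                        center = tfm$center,
                        final_mse = report$registration$final_mse,
                        converged = report$registration$converged),
    config_hash = report$config_hash,
    seed = report$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  invisible(out_dir)
}

#' Run a cohort of subjects with cohort-wide strain normalization
#'
#' Runs each subject, computes the cohort normalization constant as the mean
#' of the subjects' 99th-percentile effective strains, re-normalizes every
#' subject's events with it, and derives pooled (group-wise) CP curves,
#' thresholds and CCR per group.
#'
#' @param configs List of [run_config()]s (one per subject).
#' @param groups Character vector assigning each subject to a group
#'   (default: one group `"all"`).
#' @return An object of class `cohort_report`: `normalization_constant_ue`,
#'   per-subject tibble `subjects`, per-group tibble `groups`, the per-group
#'   [cp_curves()] objects, and the subject reports.
#' @export
run_cohort <- function(configs, groups = NULL) {
  if (length(configs) == 0) stop("empty cohort", call. = FALSE)
  groups <- groups %||% rep("all", length(configs))
  stopifnot(length(groups) == length(configs))
  reports <- lapply(configs, run_subject)
  const <- mean(vapply(reports, function(r) r$p99_ue, numeric(1)))
  subj_rows <- list()
  group_cp <- list()
  group_rows <- list()
  for (g in unique(groups)) {
    ev <- do.call(rbind, lapply(reports[groups == g], function(r) r$events))
    ev <- normalize_strains(ev, const)
    cpg <- cp_curves(ev, bin_width = configs[[1]]$bin_width,
                     min_count = configs[[1]]$min_count,
                     type_weights = configs[[1]]$cp_type_weights)
    th <- derive_thresholds(cpg)
    rate <- if (anyNA(th)) NA_real_ else ccr(ev, th)
    group_cp[[g]] <- cpg
    group_rows[[g]] <- tibble::tibble(group = g, n_subjects = sum(groups == g),
                                      n_events = nrow(ev),
                                      Tr = th[["Tr"]], Tf = th[["Tf"]],
                                      ccr = rate)
  }
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    ev <- normalize_strains(r$events, const)
    cps <- cp_curves(ev, bin_width = configs[[i]]$bin_width,
                     min_count = configs[[i]]$min_count,
                     type_weights = configs[[i]]$cp_type_weights)
    th <- derive_thresholds(cps)
    subj_rows[[i]] <- tibble::tibble(
      subject = i, group = groups[i], p99_ue = r$p99_ue,
      stiffness_kN_mm = r$stiffness_kN_mm,
      Tr = th[["Tr"]], Tf = th[["Tf"]],
      ccr = if (anyNA(th)) NA_real_ else ccr(ev, th))
  }
  structure(list(normalization_constant_ue = const,
                 subjects = do.call(rbind, subj_rows),
                 groups = do.call(rbind, group_rows),
                 group_cp = group_cp, reports = reports),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, normalization %.0f ue\n",
              nrow(x$subjects), x$normalization_constant_ue))
  print(x$groups)
  invisible(x)
}
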