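#' Extract surface remodeling events with their mechanical environment
#'
#' The bone surface is the set of baseline bone voxels with at least one face
#' neighbour outside the bone (6-connectivity; voxels beyond the grid count
#' as bone, so the cut faces where the scan stack truncates the shaft are not
#' treated as biological surfaces). Events are: resorbed surface voxels; formed voxels
#' face-adjacent to the surface, which inherit the effective strain of the
#' adjacent baseline bone voxel (lowest linear index when several); and
#' quiescent surface voxels. A quiescent surface voxel that is face-adjacent
#' to a formed voxel is, by default, not emitted as a quiescent event — the
#' site visibly formed and is represented by the formed voxel — which is what
#' lets formation dominate high-strain bins (set
#' `include_covered_quiescent = TRUE` for the literal all-surface variant).
#'
#' @param labels A [classify_remodeling()] result.
#' @param baseline_bone Logical array: the baseline bone set at the same
#'   threshold.
#' @param strain 3D numeric array of per-voxel effective strain (microstrain
#'   or any consistent unit); `NA` where undefined (e.g. unmeshed voxels).
#' @param include_covered_quiescent Emit quiescent events for surface voxels
#'   covered by formation (default FALSE).
#' @return A tibble of events: `voxel` (linear index), `type` (factor
#'   formed/quiescent/resorbed), `eps_eff`, `strain_norm` (NA until
#'   [normalize_strains()]).
#' @export
extract_surface_events <- function(labels, baseline_bone, strain,
                                   include_covered_quiescent = FALSE) {
  stopifnot(inherits(labels, "remodeling_labels"))
  stopifnot_congruent(labels$labels, baseline_bone)
  stopifnot_congruent(labels$labels, strain)
  if (!any(!is.na(strain)))
    stop("strain field carries no defined values", call. = FALSE)
  surf <- surface_voxels(baseline_bone)
  formed <- labels$labels == 1L & adjacent_to(surf)
  resorbed_idx <- which(surf & labels$labels == 2L)
  quiescent <- surf & labels$labels == 3L
  if (!include_covered_quiescent)
    quiescent <- quiescent & !adjacent_to(formed)
  quiescent_idx <- which(quiescent)
  formed_idx <- which(formed)
  # formed voxels inherit strain from the lowest-index adjacent bone voxel
  formed_eps <- rep(NA_real_, length(formed_idx))
  if (length(formed_idx)) {
    d <- dim(baseline_bone)
    strides <- c(1L, d[1], d[1] * d[2])
    donor_ok <- baseline_bone & !is.na(strain)
    f0 <- formed_idx - 1L
    fx <- f0 %% d[1]; fy <- (f0 %/% d[1]) %% d[2]; fz <- f0 %/% (d[1] * d[2])
    best <- rep(NA_integer_, length(formed_idx))
    for (k in seq_len(6)) {
      off <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))[[k]]
      jx <- fx + off[1]; jy <- fy + off[2]; jz <- fz + off[3]
      inb <- jx >= 0L & jx < d[1] & jy >= 0L & jy < d[2] & jz >= 0L & jz < d[3]
      nb <- jx + strides[2] * jy + strides[3] * jz + 1L
      ok <- inb
      ok[inb] <- donor_ok[nb[inb]]
      cand <- ifelse(ok, nb, NA_integer_)
      best <- pmin(best, cand, na.rm = TRUE)
    }
    formed_eps <- ifelse(is.na(best), NA_real_, strain[best])
  }
  ev <- tibble::tibble(
    voxel = c(formed_idx, quiescent_idx, resorbed_idx),
    type = factor(c(rep("formed", length(formed_idx)),
                    rep("quiescent", length(quiescent_idx)),
                    rep("resorbed", length(resorbed_idx))),
                  levels = c("formed", "quiescent", "resorbed")),
    eps_eff = c(formed_eps, strain[quiescent_idx], strain[resorbed_idx]),
    strain_norm = NA_real_)
  dropped <- sum(is.na(ev$eps_eff))
  if (dropped > 0) {
    warning(sprintf("%d events without a defined strain value were dropped",
                    dropped), call. = FALSE)
    ev <- ev[!is.na(ev$eps_eff), , drop = FALSE]
  }
  ev
}

#' Normalize event strains by a reference constant
#'
#' Divides each event's effective strain by a normalization constant — by
#' default the cohort-average 99th-percentile effective strain — and records
#' the constant as an attribute for downstream binning.
#'
#' @param events An [extract_surface_events()] tibble.
#' @param normalization_constant Positive scalar in the units of `eps_eff`.
#' @return The events tibble with `strain_norm` filled in.
#' @export
normalize_strains <- function(events, normalization_constant) {
  if (!is.numeric(normalization_constant) ||
      length(normalization_constant) != 1L ||
      !is.finite(normalization_constant) || normalization_constant <= 0)
    stop("normalization constant must be a positive number", call. = FALSE)
  events$strain_norm <- events$eps_eff / normalization_constant
  attr(events, "normalization_constant") <- normalization_constant
  events
}

#' Conditional probability curves of remodeling vs normalized strain
#'
#' Bins events at `bin_width` steps of normalized strain and computes, per
#' bin, the conditional probability of each event type given the bin
#' (bin-wise normalization): `p_t(b) = w_t n_t(b) / sum_t w_t n_t(b)`.
#' With `type_weights = "counts"` (`w_t = 1`) the probabilities are raw
#' per-bin type frequencies. With `type_weights = "equal"` each event type's
#' strain histogram is first normalized to unit mass (`w_t = 1/N_t`), i.e.
#' the types enter with equal priors; since quiescence vastly outnumbers the
#' remodeling events at physiological rates, this prior equalization is what
#' allows formation or resorption to become the dominant outcome of a bin at
#' all, and is the convention the curves' threshold/CCR summaries (with CCR
#' near 1/3 chance level) refer to in the HR-pQCT mechanoregulation
#' literature. Probabilities of the three types sum to one in every occupied
#' bin either way. Bins with fewer than `min_count` events are flagged and
#' excluded from threshold derivation.
#'
#' @param events A [normalize_strains()]'d events tibble (events from several
#'   subjects may be pooled first for group-wise curves).
#' @param bin_width Bin width in normalized strain (default 0.01, i.e. 1%).
#' @param min_count Minimum events for a bin to enter the threshold search.
#' @param type_weights `"counts"` or `"equal"` (see above).
#' @return An object of class `cp_analysis`: tibble `bins` with `bin_lower`,
#'   `bin_upper`, `n_F`, `n_Q`, `n_R`, `p_F`, `p_Q`, `p_R`, `occupied`, plus
#'   `bin_width`, `min_count`, `n_events`, `type_weights`,
#'   `normalization_constant`.
#' @export
cp_curves <- function(events, bin_width = 0.01, min_count = 10L,
                      type_weights = c("counts", "equal")) {
  type_weights <- match.arg(type_weights)
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  if (anyNA(events$strain_norm))
    stop("events must be normalized first (see normalize_strains)",
         call. = FALSE)
  nb <- max(1L, ceiling(max(events$strain_norm) / bin_width + 1e-12))
  bin <- pmin(pmax(floor(events$strain_norm / bin_width), 0) + 1L, nb)
  cnt <- function(tp) tabulate(bin[events$type == tp], nbins = nb)
  n_F <- cnt("formed"); n_Q <- cnt("quiescent"); n_R <- cnt("resorbed")
  tot <- n_F + n_Q + n_R
  w <- c(1, 1, 1)
  if (type_weights == "equal")
    w <- 1 / pmax(c(sum(n_F), sum(n_Q), sum(n_R)), 1)
  wtot <- w[1] * n_F + w[2] * n_Q + w[3] * n_R
  p <- function(n, wi) ifelse(tot > 0, wi * n / wtot, NA_real_)
  bins <- tibble::tibble(
    bin_lower = (seq_len(nb) - 1) * bin_width,
    bin_upper = seq_len(nb) * bin_width,
    n_F = n_F, n_Q = n_Q, n_R = n_R,
    p_F = p(n_F, w[1]), p_Q = p(n_Q, w[2]), p_R = p(n_R, w[3]),
    occupied = tot >= min_count)
  psum <- bins$p_F + bins$p_Q + bins$p_R
  stopifnot(all(abs(psum[tot > 0] - 1) < 1e-12))
  structure(list(bins = bins, bin_width = bin_width,
                 min_count = as.integer(min_count),
                 n_events = nrow(events), type_weights = type_weights,
                 normalization_constant =
                   attr(events, "normalization_constant")),
            class = "cp_analysis")
}

#' @export
print.cp_analysis <- function(x, ...) {
  cat(sprintf("<cp_analysis> %d events in %d bins (width %.2f), %d occupied\n",
              x$n_events, nrow(x$bins), x$bin_width, sum(x$bins$occupied)))
  invisible(x)
}

#' Derive resorption and formation thresholds from CP curves
#'
#' Scanning the occupied bins, the formation threshold `Tf` is the lower edge
#' of the first bin from which formation is strictly the most probable event
#' type in that bin and every later occupied bin (persistence rule, guarding
#' against single-bin noise); the resorption threshold `Tr` is the upper edge
#' of the last bin up to which resorption dominance persists from zero. A
#' missing dominance region yields `NA` (undefined), not an error.
#'
#' @param cp A [cp_curves()] result.
#' @return Named numeric `c(Tr = ..., Tf = ...)` in normalized strain.
#' @export
derive_thresholds <- function(cp) {
  stopifnot(inherits(cp, "cp_analysis"))
  b <- cp$bins[cp$bins$occupied, , drop = FALSE]
  if (nrow(b) == 0) return(c(Tr = NA_real_, Tf = NA_real_))
  f_dom <- b$p_F > b$p_Q & b$p_F > b$p_R
  r_dom <- b$p_R > b$p_Q & b$p_R > b$p_F
  Tf <- NA_real_
  # last FALSE before an all-TRUE tail
  tail_true <- rev(cumprod(rev(f_dom))) == 1
  if (any(tail_true)) Tf <- b$bin_lower[which(tail_true)[1]]
  Tr <- NA_real_
  head_true <- cumprod(r_dom) == 1
  if (any(head_true)) Tr <- b$bin_upper[max(which(head_true))]
  if (!is.na(Tr) && !is.na(Tf) && Tr > Tf) {
    warning("resorption threshold exceeds formation threshold; both undefined",
            call. = FALSE)
    return(c(Tr = NA_real_, Tf = NA_real_))
  }
  c(Tr = Tr, Tf = Tf)
}

#' Correct classification rate of remodeling events
#'
#' Predicts each event's type from its normalized strain (resorbed below
#' `Tr`, formed above `Tf`, quiescent between) and reports the fraction of
#' events whose observed type matches the prediction.
#'
#' @param events A [normalize_strains()]'d events tibble.
#' @param thresholds Named numeric `c(Tr, Tf)` from [derive_thresholds()];
#'   both must be defined.
#' @return CCR in `[0, 1]`.
#' @export
ccr <- function(events, thresholds) {
  Tr <- thresholds[["Tr"]]; Tf <- thresholds[["Tf"]]
  if (is.na(Tr) || is.na(Tf))
    stop("thresholds are undefined; provide more events or wider strain coverage",
         call. = FALSE)
  if (anyNA(events$strain_norm))
    stop("events must be normalized first", call. = FALSE)
  pred <- ifelse(events$strain_norm < Tr, "resorbed",
                 ifelse(events$strain_norm > Tf, "formed", "quiescent"))
  mean(pred == as.character(events$type))
}

#' Plot conditional probability curves
#'
#' @param object A [cp_curves()] result.
#' @param thresholds Optional `c(Tr, Tf)` to draw as vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cp_analysis <- function(object, thresholds = NULL, ...) {
  b <- object$bins[object$bins$n_F + object$bins$n_Q + object$bins$n_R > 0, ]
  mid <- (b$bin_lower + b$bin_upper) / 2
  df <- data.frame(
    strain = rep(mid, 3),
    p = c(b$p_F, b$p_Q, b$p_R),
    event = rep(c("formation", "quiescence", "resorption"), each = nrow(b)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$p,
                                         colour = .data$event)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized effective strain",
                  y = "conditional probability", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds) && !anyNA(thresholds))
    gg <- gg + ggplot2::geom_vline(xintercept = unname(thresholds),
                                   linetype = "dashed")
  gg
}

#' Plot remodeling fractions across the threshold ladder
#'
#' @param sweep A [threshold_sweep()] tibble.
#' @return A ggplot object with formation and resorption volume fractions per
#'   compartment.
#' @export
plot_threshold_sweep <- function(sweep) {
  df <- rbind(
    data.frame(threshold = sweep$threshold, compartment = sweep$compartment,
               fraction = sweep$formation_vf, kind = "formation"),
    data.frame(threshold = sweep$threshold, compartment = sweep$compartment,
               fraction = sweep$resorption_vf, kind = "resorption"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$fraction,
                                   colour = .data$kind,
                                   linetype = .data$compartment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "density threshold (mg HA/cm^3)",
                  y = "volume fraction (mm^3/mm^3)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
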