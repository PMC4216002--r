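# Whole-lung composition: voxel subtrees in parallel beneath a series
# upper-airway resistance, and the aggregation of per-voxel states to
# spirometry.

#' Whole-lung model: upper airways plus parallel voxel subtrees
#'
#' The lung is composed of `n_voxels` identical voxel subtrees (each a
#' [voxel_tree()]) combined in parallel beneath a series "upper airway"
#' resistance contributed by the generations above the voxel roots
#' (mucus-free by default, since imaging attributes mucus to voxels). For
#' the full-scale lung, `n_voxels = 2^13` subtrees of 11 generation levels
#' (13..23); reduced lungs (fewer, shallower voxels) are first-class for
#' fast experimentation.
#'
#' @param n_voxels Number of voxel subtrees; must be a power of two, so the
#'   voxel roots sit at generation `log2(n_voxels)`.
#' @param voxel_levels Number of generation levels per voxel subtree (11 for
#'   generations 13..23).
#' @param trachea_diameter_cm,trachea_length_cm Generation-0 geometry.
#' @param scale_factor Per-generation fractal scaling.
#' @param viscosity Air viscosity, Pa s.
#' @return An object of class `lung_model` with the voxel tree, upper-airway
#'   and healthy whole-lung resistances.
#' @examples
#' lung_model(n_voxels = 64, voxel_levels = 5)
#' @export
lung_model <- function(n_voxels = 2^13, voxel_levels = 11L,
                       trachea_diameter_cm = 1.8, trachea_length_cm = 12,
                       scale_factor = 2^(-1 / 3), viscosity = 1.81e-5) {
  vr <- log2(n_voxels)
  if (vr != round(vr) || n_voxels < 1) {
    rlang::abort("`n_voxels` must be a power of two",
                 class = "lungtrack_input_error")
  }
  vr <- as.integer(round(vr))
  vt <- airway_tree(
    vr, vr + as.integer(voxel_levels) - 1L,
    root_diameter_cm = trachea_diameter_cm * scale_factor^vr,
    root_length_cm = trachea_length_cm * scale_factor^vr,
    scale_factor = scale_factor, viscosity = viscosity
  )
  upper_resistance <- if (vr == 0L) 0 else {
    g <- 0:(vr - 1L)
    sum(segment_resistance(trachea_diameter_cm * scale_factor^g,
                           trachea_length_cm * scale_factor^g, 0,
                           viscosity = viscosity) / 2^g)
  }
  structure(
    list(
      n_voxels = as.integer(n_voxels),
      voxel_root_generation = vr,
      voxel_tree = vt,
      upper_resistance = upper_resistance,
      voxel_resistance_healthy = vt$resistance_empty,
      healthy_resistance = upper_resistance + vt$resistance_empty / n_voxels,
      voxel_capacity_mm3 = vt$total_capacity_units * vt$unit_volume_mm3,
      trachea_diameter_cm = trachea_diameter_cm,
      trachea_length_cm = trachea_length_cm,
      scale_factor = scale_factor, viscosity = viscosity
    ),
    class = "lung_model"
  )
}

#' @export
print.lung_model <- function(x, ...) {
  cat("<lung_model> ", x$n_voxels, " voxel subtrees (generations ",
      x$voxel_tree$g_min, "..", x$voxel_tree$g_max, ")\n",
      "  healthy resistance ", signif(x$healthy_resistance, 4),
      " Pa s/m^3, voxel lumen capacity ", signif(x$voxel_capacity_mm3, 4),
      " mm^3\n", sep = "")
  invisible(x)
}

# Aggregate per-voxel (ratio, aa) states to whole-lung quantities.
# Voxels not listed are healthy (ratio 1, aa 100). Vector inputs are one
# lung state; matrix inputs (voxels in columns) are vectorized over rows.
.lung_aggregate <- function(lung, ratio, aa, fvc_healthy, healthy_ratio = 0.8) {
  r0 <- lung$voxel_resistance_healthy
  if (is.matrix(ratio)) {
    n_listed <- ncol(ratio)
    cond <- rowSums(ifelse(is.finite(ratio), 1 / (ratio * r0), 0))
    aa_sum <- rowSums(aa)
  } else {
    n_listed <- length(ratio)
    cond <- sum(ifelse(is.finite(ratio), 1 / (ratio * r0), 0))
    aa_sum <- sum(aa)
  }
  n_healthy <- lung$n_voxels - n_listed
  cond <- cond + n_healthy / r0
  resistance <- ifelse(cond > 0, lung$upper_resistance + 1 / cond, Inf)
  ratio_lung <- resistance / lung$healthy_resistance
  aa_lung <- (aa_sum + 100 * n_healthy) / lung$n_voxels
  sp <- .spiro_from_ratio(ratio_lung, aa_lung, fvc_healthy, healthy_ratio)
  list(resistance = resistance, resistance_ratio = ratio_lung,
       aa_percent = aa_lung, fev1 = sp$fev1, fvc = sp$fvc)
}

#' Whole-lung spirometry from per-voxel states
#'
#' Combines per-voxel (resistance ratio, AA%) pairs into whole-lung
#' resistance (voxel subtrees in parallel beneath the upper-airway series
#' resistance), whole-lung AA% (equal-weight mean over all voxels, listed or
#' healthy), and the resulting FEV1/FVC via [spirometry_from_lung()]'s
#' single-compartment emptying model.
#'
#' @param lung A [lung_model()].
#' @param ratio,aa Per-voxel resistance ratios (possibly `Inf`) and AA
#'   percentages for the listed voxels; unlisted voxels (up to
#'   `lung$n_voxels`) are healthy.
#' @param patient A [patient_spirometry()] (demographics anchor FVC).
#' @return A one-row tibble: `resistance`, `resistance_ratio`, `aa_percent`,
#'   `fev1`, `fvc`.
#' @export
lung_spirometry <- function(lung, ratio, aa, patient) {
  if (length(ratio) != length(aa)) {
    rlang::abort("`ratio` and `aa` must have the same length",
                 class = "lungtrack_input_error")
  }
  if (length(ratio) > lung$n_voxels) {
    rlang::abort("more voxel states than voxels in the lung model",
                 class = "lungtrack_input_error")
  }
  fvc_h <- fvc_reference(patient$age, patient$height, patient$sex)
  agg <- .lung_aggregate(lung, ratio, aa, fvc_h)
  tibble::as_tibble(agg[c("resistance", "resistance_ratio", "aa_percent",
                          "fev1", "fvc")])
}
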