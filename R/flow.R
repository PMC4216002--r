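# Airflow physics: Poiseuille segment resistance, recursive tree resistance,
# accessible alveoli, and the mapping from whole-lung aggregates to FEV1/FVC.

#' Poiseuille resistance of a mucus-lined airway segment
#'
#' Laminar flow through a cylindrical segment whose lumen is narrowed by a
#' uniform annular mucus lining: with fill fraction `f = mucus / lumen`, the
#' effective radius is `r * sqrt(1 - f)` and the resistance is
#' `8 mu L / (pi r_eff^4)`, i.e. the mucus-free resistance divided by
#' `(1 - f)^2`. A completely filled segment (`f = 1`) has infinite
#' resistance; infinities propagate as zero conductance through the tree
#' recursion in [tree_flow()].
#'
#' @param diameter_cm,length_cm Segment geometry in cm (vectorized).
#' @param mucus_volume_mm3 Mucus volume in the segment, in mm^3.
#' @param lumen_volume_mm3 Lumen volume; defaults to the cylinder volume of
#'   the given geometry.
#' @param viscosity Dynamic viscosity of air in Pa s (default 1.81e-5,
#'   ~20 degrees C).
#' @return Resistance in Pa s/m^3 (possibly `Inf`).
#' @examples
#' segment_resistance(1.8, 12, 0) # mucus-free trachea, ~8.4e2 Pa s/m^3
#' @export
segment_resistance <- function(diameter_cm, length_cm, mucus_volume_mm3,
                               lumen_volume_mm3 = pi * (diameter_cm / 2)^2 * length_cm * 1000,
                               viscosity = 1.81e-5) {
  if (any(mucus_volume_mm3 < 0) || any(mucus_volume_mm3 > lumen_volume_mm3 * (1 + 1e-12))) {
    rlang::abort("`mucus_volume_mm3` must lie in [0, lumen volume]",
                 class = "lungtrack_input_error")
  }
  f <- pmin(mucus_volume_mm3 / lumen_volume_mm3, 1)
  r_m <- diameter_cm / 200         # radius in meters
  l_m <- length_cm / 100
  base <- 8 * viscosity * l_m / (pi * r_m^4)
  ifelse(f >= 1, Inf, base / (1 - f)^2)
}

# Fast path: resistance ratio and AA% for a unit-quantized configuration.
# Returns c(resistance, resistance_ratio, aa_percent). Fill fractions are
# computed on the quantized capacity so that a segment holding its full
# integer capacity counts as blocked.
.flow_units <- function(tree, units) {
  caps <- tree$cap_units
  nlev <- tree$n_levels
  blocked <- units == caps
  f <- units / caps
  rseg <- tree$r0_node / (1 - f)^2  # Inf where f == 1; superseded by `blocked`

  # bottom-up conductance recursion
  lo <- 2^(nlev - 1L)
  idx <- lo:(2L * lo - 1L)
  G <- ifelse(blocked[idx], 0, 1 / rseg[idx])
  for (l in (nlev - 2L):0L) {
    lo <- 2^l
    idx <- lo:(2L * lo - 1L)
    gc_sum <- G[c(TRUE, FALSE)] + G[c(FALSE, TRUE)]
    G <- ifelse(blocked[idx] | gc_sum <= 0, 0, 1 / (rseg[idx] + 1 / gc_sum))
  }
  resistance <- if (G > 0) 1 / G else Inf

  # top-down reachability for accessible alveoli
  reach <- !blocked[1L]
  for (l in 1L:(nlev - 1L)) {
    lo <- 2^l
    idx <- lo:(2L * lo - 1L)
    reach <- rep(reach, each = 2L) & !blocked[idx]
  }
  aa <- 100 * sum(reach) / tree$terminal_count
  c(resistance, resistance / tree$resistance_empty, aa)
}

#' Airflow resistance and accessible alveoli of a mucus configuration
#'
#' Computes the total resistance of the tree by the series/parallel
#' recursion `R(node) = R_segment + 1 / sum(1 / R(children))`, with fully
#' blocked segments contributing zero conductance, together with the percent
#' of terminal (alveolar-level) segments reachable through no fully blocked
#' segment (AA%) and the resistance ratio relative to the same tree free of
#' mucus.
#'
#' @param tree An [airway_tree()].
#' @param config A [mucus_config()] on that tree.
#' @return A one-row tibble: `resistance` (Pa s/m^3, possibly `Inf`),
#'   `resistance_ratio` (>= 1), `aa_percent` (0..100).
#' @export
tree_flow <- function(tree, config) {
  .check_materialized(tree)
  if (length(config$units) != tree$n_nodes) {
    rlang::abort("configuration does not match the tree",
                 class = "lungtrack_input_error")
  }
  res <- .flow_units(tree, config$units)
  tibble::tibble(resistance = res[1], resistance_ratio = res[2],
                 aa_percent = res[3])
}

# ---- spirometry -------------------------------------------------------------

#' Patient spirometry record
#'
#' Bundles the two standard spirometric indicators with the demographics
#' that anchor reference values: FEV1 (forced expiratory volume in one
#' second) and FVC (forced vital capacity), both in liters.
#'
#' @param age Years. @param height cm. @param sex `"male"` or `"female"`.
#' @param fev1,fvc Measured values in liters (optional when only
#'   demographics are needed, e.g. for forecasting); must satisfy
#'   `0 < fev1 <= fvc` when given.
#' @return A one-row tibble of class `patient_spirometry`.
#' @export
patient_spirometry <- function(age, height, sex, fev1 = NA_real_, fvc = NA_real_) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(age) || age <= 0 || !is.finite(height) || height <= 0) {
    rlang::abort("`age` and `height` must be positive",
                 class = "lungtrack_input_error")
  }
  if (!is.na(fev1) || !is.na(fvc)) {
    if (!(fev1 > 0 && fev1 <= fvc)) {
      rlang::abort("spirometry must satisfy 0 < fev1 <= fvc",
                   class = "lungtrack_input_error")
    }
  }
  structure(
    tibble::tibble(age = age, height = height, sex = sex,
                   fev1 = fev1, fvc = fvc),
    class = c("patient_spirometry", "tbl_df", "tbl", "data.frame")
  )
}

.hankinson_env <- new.env(parent = emptyenv())

.hankinson_table <- function() {
  if (is.null(.hankinson_env$tab)) {
    path <- system.file("extdata", "fvc_reference_coefficients.csv",
                        package = "lungtrack", mustWork = TRUE)
    .hankinson_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .hankinson_env$tab
}

#' Predicted healthy FVC from demographics
#'
#' Evaluates the NHANES III (Hankinson) adult reference regression
#' `FVC = b0 + b1 age + b2 age^2 + b3 height^2` (height in cm, FVC in
#' liters), with the published coefficient table shipped as package data.
#' Demographics outside the table's validity range are clamped with a
#' warning; non-positive values are an error.
#'
#' @param age Years. @param height cm. @param sex `"male"` or `"female"`.
#' @return Predicted FVC in liters.
#' @examples
#' fvc_reference(25, 175, "male")
#' @export
fvc_reference <- function(age, height, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(age) || age <= 0 || !is.finite(height) || height <= 0) {
    rlang::abort("`age` and `height` must be positive",
                 class = "lungtrack_input_error")
  }
  row <- .hankinson_table()
  row <- row[row$sex == sex, ]
  if (age < row$age_min || age > row$age_max) {
    rlang::warn(paste0("age ", age, " outside reference range [", row$age_min,
                       ", ", row$age_max, "]; clamped"))
    age <- min(max(age, row$age_min), row$age_max)
  }
  if (height < row$height_min || height > row$height_max) {
    rlang::warn(paste0("height ", height, " outside reference range [",
                       row$height_min, ", ", row$height_max, "]; clamped"))
    height <- min(max(height, row$height_min), row$height_max)
  }
  row$b0 + row$b_age * age + row$b_age2 * age^2 + row$b_height2 * height^2
}

#' Map whole-lung resistance and accessible alveoli to FEV1 and FVC
#'
#' FVC scales linearly with the fraction of accessible alveoli,
#' `fvc = fvc_reference * aa / 100`; FEV1 follows a single-compartment RC
#' emptying over one second, `fev1 = fvc * (1 - exp(-1 / (R C)))`, with the
#' compliance constant `C` calibrated once so that a healthy lung
#' (`R = healthy_resistance`, `aa = 100`) yields the textbook normal ratio
#' FEV1/FVC = 0.8. Equivalently `fev1/fvc = 1 - 5^(-R_healthy/R)`: FEV1 is
#' non-increasing in resistance and tends to 0 as the lung blocks up.
#'
#' @param total_resistance Whole-lung resistance in Pa s/m^3 (may be `Inf`).
#' @param aa_percent Whole-lung percent accessible alveoli, 0..100.
#' @param patient A [patient_spirometry()] (demographics are used).
#' @param healthy_resistance Resistance of the same lung free of mucus.
#' @param healthy_ratio FEV1/FVC calibration point for the healthy lung.
#' @return A one-row tibble with `fev1` and `fvc` in liters.
#' @export
spirometry_from_lung <- function(total_resistance, aa_percent, patient,
                                 healthy_resistance, healthy_ratio = 0.8) {
  if (any(aa_percent < 0 | aa_percent > 100)) {
    rlang::abort("`aa_percent` must lie in [0, 100]",
                 class = "lungtrack_input_error")
  }
  stopifnot(healthy_resistance > 0, healthy_ratio > 0, healthy_ratio < 1)
  fvc_h <- fvc_reference(patient$age, patient$height, patient$sex)
  res <- .spiro_from_ratio(total_resistance / healthy_resistance,
                           aa_percent, fvc_h, healthy_ratio)
  tibble::tibble(fev1 = res[[1]], fvc = res[[2]])
}

# vectorized core: resistance ratio + aa -> (fev1, fvc)
.spiro_from_ratio <- function(resistance_ratio, aa_percent, fvc_healthy,
                              healthy_ratio = 0.8) {
  fvc <- fvc_healthy * aa_percent / 100
  frac <- 1 - exp(log(1 - healthy_ratio) / resistance_ratio)
  frac[!is.finite(resistance_ratio)] <- 0
  list(fev1 = fvc * frac, fvc = fvc)
}
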