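# Forward propagation of voxel mucus under growth rates and the predicted
# joint FEV1/FVC distribution.

#' Propagate voxel mucus volumes forward in time
#'
#' Linear extrapolation per voxel: `mucus' = mucus + rate * horizon`,
#' clamped to `[0, voxel lumen capacity]`. Rates may be a single global mean
#' (mm^3 per year, applied to every voxel) or per-voxel via a `rate_mm3_yr`
#' column in the table; negative rates model treatment response (shrinking
#' pockets) and clamp at zero. Deterministic: no randomness is involved.
#'
#' @param voxels Voxel table with `mucus_mm3` (and optionally
#'   `rate_mm3_yr`).
#' @param lung A [lung_model()] (supplies the capacity clamp).
#' @param rate_mm3_yr Global growth rate, ignored when the table carries a
#'   `rate_mm3_yr` column. There is no default: the between-exacerbation
#'   population mean is an external input.
#' @param horizon_yr Forecast horizon in years (>= 0).
#' @return The voxel tibble with `mucus_mm3` updated.
#' @export
grow_mucus <- function(voxels, lung, rate_mm3_yr = NULL, horizon_yr) {
  voxels <- tibble::as_tibble(voxels)
  if (horizon_yr < 0) {
    rlang::abort("`horizon_yr` must be non-negative",
                 class = "lungtrack_input_error")
  }
  rates <- if ("rate_mm3_yr" %in% names(voxels)) {
    voxels$rate_mm3_yr
  } else if (!is.null(rate_mm3_yr)) {
    rate_mm3_yr
  } else {
    rlang::abort("supply `rate_mm3_yr` or a rate_mm3_yr column",
                 class = "lungtrack_input_error")
  }
  if (any(!is.finite(rates))) {
    rlang::abort("growth rates must be finite", class = "lungtrack_input_error")
  }
  dplyr::mutate(
    voxels,
    mucus_mm3 = pmin(pmax(.data$mucus_mm3 + rates * horizon_yr, 0),
                     lung$voxel_capacity_mm3)
  )
}

#' Predicted joint distribution of FEV1 and FVC
#'
#' Simple Monte Carlo through the offline tables: for each of `n_draws`
#' iterations, one (resistance ratio, AA%) pair is drawn independently per
#' voxel from its fraction-interpolated PDFE-2D slice, aggregated to
#' whole-lung FEV1/FVC, and the draws are histogrammed. Draws are
#' independent across iterations (not a chain).
#'
#' @param voxels Voxel table (typically after [grow_mucus()]).
#' @param pdfe A [build_pdfe_table()] for this lung's voxel tree.
#' @param lung A [lung_model()].
#' @param patient A [patient_spirometry()] (demographics anchor FVC).
#' @param n_draws Number of Monte Carlo draws; below 100 a warning is
#'   issued (the density estimate is unstable).
#' @param n_bins Bins per axis of the joint histogram.
#' @param seed Optional integer seed.
#' @return An object of class `spiro_forecast`: the draws (tibble), a
#'   normalized 2D histogram over (fev1, fvc) with its bin edges, and point
#'   summaries (mean and mode).
#' @export
predict_spirometry <- function(voxels, pdfe, lung, patient, n_draws = 1000L,
                               n_bins = 50L, seed = NULL) {
  voxels <- tibble::as_tibble(voxels)
  .check_pdfe_matches(pdfe, lung)
  if (n_draws < 100) {
    rlang::warn("fewer than 100 draws gives an unstable density estimate")
  }
  if (!is.null(seed)) set.seed(seed)
  fractions <- .voxel_fractions(voxels, lung)
  densities <- .voxel_densities(pdfe, fractions)
  bins <- pdfe$bins
  n_vox <- nrow(voxels)

  ratio <- matrix(NA_real_, n_draws, n_vox)
  aa <- matrix(NA_real_, n_draws, n_vox)
  for (q in seq_len(n_vox)) {
    p <- pdfe_sample_pair(densities[[q]], bins, n_draws)
    ratio[, q] <- p$resistance_ratio
    aa[, q] <- p$aa_percent
  }
  fvc_h <- fvc_reference(patient$age, patient$height, patient$sex)
  agg <- .lung_aggregate(lung, ratio, aa, fvc_h)
  draws <- tibble::tibble(fev1 = agg$fev1, fvc = agg$fvc)

  edges <- seq(0, fvc_h, length.out = n_bins + 1L)
  bx <- pmin(pmax(findInterval(draws$fev1, edges, rightmost.closed = TRUE), 1L),
             n_bins)
  by <- pmin(pmax(findInterval(draws$fvc, edges, rightmost.closed = TRUE), 1L),
             n_bins)
  hist2d <- matrix(
    tabulate((by - 1L) * n_bins + bx, nbins = n_bins * n_bins),
    nrow = n_bins
  ) / n_draws
  mode_cell <- which(hist2d == max(hist2d), arr.ind = TRUE)[1, ]
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  structure(
    list(
      draws = draws,
      histogram = hist2d,
      edges = edges,
      fvc_healthy = fvc_h,
      mean = c(fev1 = mean(draws$fev1), fvc = mean(draws$fvc)),
      mode = c(fev1 = mids[mode_cell[1]], fvc = mids[mode_cell[2]]),
      n_draws = as.integer(n_draws)
    ),
    class = "spiro_forecast"
  )
}

#' @export
print.spiro_forecast <- function(x, ...) {
  cat("<spiro_forecast> ", x$n_draws, " draws\n",
      "  mean FEV1 ", round(x$mean["fev1"], 2), " L, mean FVC ",
      round(x$mean["fvc"], 2), " L (healthy FVC ",
      round(x$fvc_healthy, 2), " L)\n", sep = "")
  invisible(x)
}

#' @export
tidy.spiro_forecast <- function(x, ...) x$draws

#' @export
glance.spiro_forecast <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws,
    fev1_mean = unname(x$mean["fev1"]), fvc_mean = unname(x$mean["fvc"]),
    fev1_mode = unname(x$mode["fev1"]), fvc_mode = unname(x$mode["fvc"]),
    fev1_sd = stats::sd(x$draws$fev1), fvc_sd = stats::sd(x$draws$fvc),
    fvc_healthy = x$fvc_healthy
  )
}

#' @export
autoplot.spiro_forecast <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$fev1, y = .data$fvc)) +
    ggplot2::geom_bin2d(bins = 40) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted FEV1 (L)", y = "predicted FVC (L)",
                  title = "Forecast joint density of FEV1 and FVC")
}
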