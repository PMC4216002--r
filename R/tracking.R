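# The inverse problem: fit per-voxel (resistance ratio, AA%) states to a
# patient's spirometry (with or without imaging voxels), and drill down into
# a voxel to estimate its per-generation mucus distribution.

#' Read / write a voxel mucus table
#'
#' The imaging interchange format: delimited text with header
#' `i,j,k,mucus_mm3` -- integer voxel coordinates on a 1 cm grid and the
#' mucus volume per voxel in mm^3. An optional `rate_mm3_yr` column carries
#' per-voxel growth rates for forecasting.
#'
#' @param path File path.
#' @param voxels A data frame with at least `i`, `j`, `k`, `mucus_mm3`.
#' @return `read_voxel_table` returns a tibble; `write_voxel_table` the path,
#'   invisibly.
#' @export
read_voxel_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("voxel table not found: ", path),
                 class = "lungtrack_input_error")
  }
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("i", "j", "k", "mucus_mm3")
  if (!all(need %in% names(df))) {
    rlang::abort("voxel table must have columns i, j, k, mucus_mm3",
                 class = "lungtrack_input_error")
  }
  df
}

#' @rdname read_voxel_table
#' @export
write_voxel_table <- function(voxels, path) {
  utils::write.csv(as.data.frame(voxels), path, row.names = FALSE)
  invisible(path)
}

.check_pdfe_matches <- function(pdfe, lung) {
  vt <- lung$voxel_tree
  m <- pdfe$meta
  ok <- isTRUE(all.equal(m$unit_volume_mm3, vt$unit_volume_mm3)) &&
    m$total_capacity_units == vt$total_capacity_units &&
    (m$g_max - m$g_min) == (vt$g_max - vt$g_min)
  if (!ok) {
    rlang::abort("PDFE table was built for a different voxel tree than this lung model",
                 class = "lungtrack_input_error")
  }
}

.voxel_fractions <- function(voxels, lung) {
  fr <- voxels$mucus_mm3 / lung$voxel_capacity_mm3
  if (any(fr < 0) || any(fr > 1 + 1e-9)) {
    rlang::abort("voxel mucus must lie in [0, voxel lumen capacity]",
                 class = "lungtrack_input_error")
  }
  pmin(fr, 1)
}

# Per-voxel interpolated densities, with one warning if any fraction falls
# outside the tabulated span.
.voxel_densities <- function(pdfe, fractions) {
  span <- range(pdfe$fractions)
  out <- fractions < span[1] | fractions > span[2]
  if (any(out)) {
    rlang::warn(paste0(sum(out), " voxel fraction(s) outside the tabulated span [",
                       span[1], ", ", span[2], "]; clamped"))
  }
  lapply(fractions, function(f) interpolate_pdfe(pdfe, f, warn = FALSE))
}

# O(log cells) draw from a fixed density: precomputed CDF + findInterval
.make_pair_sampler <- function(density, bins) {
  cdf <- cumsum(as.vector(density))
  cdf <- cdf / cdf[length(cdf)]
  nr <- nrow(density)
  n_cells <- length(cdf)
  function() {
    idx <- findInterval(stats::runif(1), cdf) + 1L
    if (idx > n_cells) idx <- n_cells
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    .pdfe_cell_values(bins, row, col)
  }
}

.sample_pairs_from <- function(samplers, idx = seq_along(samplers)) {
  ratio <- numeric(length(idx))
  aa <- numeric(length(idx))
  for (q in seq_along(idx)) {
    p <- samplers[[idx[q]]]()
    ratio[q] <- p$resistance_ratio
    aa[q] <- p$aa_percent
  }
  list(ratio = ratio, aa = aa)
}

.new_lung_fit <- function(chain, voxels, lung, targets, settings, mode,
                          fvc_h, extra = list()) {
  ns <- length(chain$samples)
  n_vox <- nrow(voxels)
  ratio_m <- do.call(rbind, lapply(chain$samples, function(s) s$ratio))
  aa_m <- do.call(rbind, lapply(chain$samples, function(s) s$aa))
  agg <- .lung_aggregate(lung, ratio_m, aa_m, fvc_h)
  samples <- tibble::tibble(
    step = chain$trace$step,
    energy = chain$trace$energy,
    fev1 = agg$fev1, fvc = agg$fvc,
    resistance_ratio = agg$resistance_ratio,
    aa_percent = agg$aa_percent
  )
  if (mode == "spirometry_only") {
    samples$total_mucus_mm3 <-
      vapply(chain$samples, function(s) s$total_mucus_mm3, numeric(1))
  }
  best <- which.min(samples$energy)
  structure(
    c(list(
      samples = samples,
      ratio_samples = ratio_m, aa_samples = aa_m,
      voxels = voxels, lung = lung, targets = targets, settings = settings,
      mode = mode,
      acceptance_rate = chain$acceptance_rate,
      best_index = best,
      min_energy = samples$energy[best],
      fvc_healthy = fvc_h
    ), extra),
    class = "lung_fit"
  )
}

#' Fit per-voxel obstruction states to spirometry and imaging voxels
#'
#' Solves the inverse problem with imaging: each listed voxel carries a
#' known mucus volume, and the chain samples one (resistance ratio, AA%)
#' pair per voxel consistent with the patient's measured FEV1 and FVC. The
#' Metropolis proposal resamples one uniformly chosen voxel's pair from its
#' (fraction-interpolated) PDFE-2D slice; because this independence proposal
#' draws from the prior, the Hastings ratio reduces to `exp(-dE/T)` for the
#' target `prior x exp(-E/T)`, with `E` the spirometric energy
#' ([energy_spirometric()]).
#'
#' @param voxels Voxel table (see [read_voxel_table()]): `i`, `j`, `k`,
#'   `mucus_mm3`. Voxels not listed are treated as healthy.
#' @param targets A [patient_spirometry()] with measured `fev1` and `fvc`.
#' @param pdfe A [build_pdfe_table()] (or [read_pdfe()]) built for this
#'   lung's voxel tree.
#' @param lung A [lung_model()].
#' @param settings A [chain_settings()].
#' @param feasible_energy Threshold on the minimum retained energy above
#'   which the fit is flagged infeasible (e.g. targets no lung state can
#'   reach). The default corresponds to ~2% relative mismatch per term.
#' @return An object of class `lung_fit`; see [tidy.lung_fit()],
#'   [glance.lung_fit()], [drilldown()].
#' @export
fit_lung <- function(voxels, targets, pdfe, lung,
                     settings = chain_settings(), feasible_energy = 1e-3) {
  voxels <- tibble::as_tibble(voxels)
  .check_pdfe_matches(pdfe, lung)
  if (is.na(targets$fev1) || is.na(targets$fvc)) {
    rlang::abort("`targets` must carry measured fev1 and fvc",
                 class = "lungtrack_input_error")
  }
  voxels <- assign_voxels(voxels, lung$n_voxels)
  voxels$fraction <- .voxel_fractions(voxels, lung)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  densities <- .voxel_densities(pdfe, voxels$fraction)
  bins <- pdfe$bins
  samplers <- lapply(densities, .make_pair_sampler, bins = bins)
  n_vox <- nrow(voxels)
  fvc_h <- fvc_reference(targets$age, targets$height, targets$sex)

  init <- .sample_pairs_from(samplers)
  energy_fn <- function(state) {
    agg <- .lung_aggregate(lung, state$ratio, state$aa, fvc_h)
    energy_spirometric(agg$fev1, agg$fvc, targets, settings$w1, settings$w2)
  }
  proposal_fn <- function(state) {
    q <- sample.int(n_vox, 1L)
    p <- samplers[[q]]()
    state$ratio[q] <- p$resistance_ratio
    state$aa[q] <- p$aa_percent
    state
  }
  chain_set <- settings
  chain_set$seed <- NULL
  chain <- run_chain(init, energy_fn, proposal_fn, chain_set)
  fit <- .new_lung_fit(chain, voxels, lung, targets, settings, "imaging", fvc_h,
                       extra = list(feasible_energy = feasible_energy,
                                    pdfe_bins = bins))
  fit$feasible <- fit$min_energy <= feasible_energy
  if (!fit$feasible) {
    rlang::warn(paste0("minimum retained energy ", signif(fit$min_energy, 3),
                       " exceeds the feasibility threshold; targets may be unreachable"))
  }
  fit
}

#' Fit obstruction states from spirometry alone
#'
#' The imaging-free mode: per-voxel mucus volumes are themselves state
#' variables. In addition to resampling a voxel's (ratio, AA%) pair from its
#' PDFE slice, the chain rearranges mucus between voxels (transfer of one
#' quantum between a uniformly drawn ordered pair) and lets the total vary
#' (add/remove one quantum in a uniformly drawn voxel, each direction with
#' probability 1/2); a voxel whose mucus changes gets its pair redrawn from
#' the slice at its new fraction. All three move types are symmetric over the
#' quantized allocation space, and the pair redraws come from their prior,
#' so the acceptance rule remains `exp(-dE/T)`.
#'
#' @inheritParams fit_lung
#' @param n_active Number of voxels carrying state (all of `lung$n_voxels`
#'   by default for reduced lungs; may be fewer to confine mucus to a
#'   region).
#' @param total_mucus_init_mm3 Initial total mucus volume, randomly
#'   allocated across the active voxels. By default it is moment-matched
#'   from the targets: the whole-lung AA needed for the FVC target
#'   (`100 fvc / fvc_healthy`) is inverted through the table's mode curve
#'   to an initial per-voxel fraction. This only positions the chain's
#'   start; the posterior is determined by the energy and the priors.
#' @param step_fraction Inter-voxel move quantum, as a fraction of one
#'   voxel's lumen capacity. The default 0.02 matches the production PDFE
#'   fraction-grid step.
#' @return A `lung_fit` whose samples include the inferred
#'   `total_mucus_mm3` and whose `alloc_samples` matrix carries per-voxel
#'   mucus volumes (mm^3) for each retained sample.
#' @export
fit_lung_spirometry <- function(targets, pdfe, lung,
                                settings = chain_settings(),
                                n_active = lung$n_voxels,
                                total_mucus_init_mm3 = NULL,
                                step_fraction = 0.02,
                                feasible_energy = 1e-3) {
  .check_pdfe_matches(pdfe, lung)
  stopifnot(n_active >= 1, n_active <= lung$n_voxels)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  bins <- pdfe$bins
  fvc_h <- fvc_reference(targets$age, targets$height, targets$sex)

  cap_units <- lung$voxel_tree$total_capacity_units
  v_mm3 <- lung$voxel_tree$unit_volume_mm3
  q_units <- max(1L, as.integer(round(step_fraction * cap_units)))
  q_mm3 <- q_units * v_mm3
  n_q_max <- as.integer(cap_units %/% q_units)

  # cache one interpolated slice sampler per attainable quantum level
  samplers_at <- lapply(0:n_q_max, function(qq) {
    .make_pair_sampler(
      interpolate_pdfe(pdfe, min(qq * q_units / cap_units, 1), warn = FALSE),
      bins
    )
  })

  if (is.null(total_mucus_init_mm3)) {
    aa_needed <- min(max(100 * targets$fvc / fvc_h, 0), 100)
    mc <- pdfe_mode_curve(pdfe)
    f_init <- mc$fraction[which.min(abs(mc$aa_percent - aa_needed))]
    total_mucus_init_mm3 <- n_active * f_init * lung$voxel_capacity_mm3
  }
  init_q <- .random_quanta(n_active, n_q_max,
                           as.integer(round(total_mucus_init_mm3 / q_mm3)))
  init <- .sample_pairs_from(samplers_at, idx = init_q + 1L)
  init$alloc <- init_q
  init$total_mucus_mm3 <- sum(init_q) * q_mm3

  energy_fn <- function(state) {
    agg <- .lung_aggregate(lung, state$ratio, state$aa, fvc_h)
    energy_spirometric(agg$fev1, agg$fvc, targets, settings$w1, settings$w2)
  }
  redraw <- function(state, q) {
    p <- samplers_at[[state$alloc[q] + 1L]]()
    state$ratio[q] <- p$resistance_ratio
    state$aa[q] <- p$aa_percent
    state
  }
  proposal_fn <- function(state) {
    move <- sample.int(3L, 1L)
    if (move == 1L) {
      # pair resample
      q <- sample.int(n_active, 1L)
      state <- redraw(state, q)
    } else if (move == 2L && n_active > 1L) {
      # quantum transfer between an ordered pair of voxels
      a <- sample.int(n_active, 1L)
      b <- sample.int(n_active - 1L, 1L)
      if (b >= a) b <- b + 1L
      if (state$alloc[a] >= 1L && state$alloc[b] < n_q_max) {
        state$alloc[a] <- state$alloc[a] - 1L
        state$alloc[b] <- state$alloc[b] + 1L
        state <- redraw(redraw(state, a), b)
      }
    } else if (move == 3L) {
      # birth/death of one quantum
      q <- sample.int(n_active, 1L)
      delta <- if (stats::runif(1) < 0.5) 1L else -1L
      new_q <- state$alloc[q] + delta
      if (new_q >= 0L && new_q <= n_q_max) {
        state$alloc[q] <- new_q
        state <- redraw(state, q)
      }
    }
    state$total_mucus_mm3 <- sum(state$alloc) * q_mm3
    state
  }
  chain_set <- settings
  chain_set$seed <- NULL
  chain <- run_chain(init, energy_fn, proposal_fn, chain_set)

  voxels <- tibble::tibble(i = seq_len(n_active), j = 0L, k = 0L,
                           mucus_mm3 = NA_real_, subtree = seq_len(n_active),
                           fraction = NA_real_)
  alloc_m <- do.call(rbind, lapply(chain$samples, function(s) s$alloc))
  fit <- .new_lung_fit(
    chain, voxels, lung, targets, settings, "spirometry_only", fvc_h,
    extra = list(feasible_energy = feasible_energy, pdfe_bins = bins,
                 alloc_samples = alloc_m * q_mm3, quantum_mm3 = q_mm3)
  )
  fit$feasible <- fit$min_energy <= feasible_energy
  fit
}

# random allocation of `total` quanta over n voxels with per-voxel cap
.random_quanta <- function(n, cap, total) {
  total <- min(total, n * cap)
  if (total <= 0L) return(integer(n))
  .random_fill_units(rep(cap, n), total)
}

#' @export
print.lung_fit <- function(x, ...) {
  cat("<lung_fit> (", x$mode, ") ", nrow(x$samples), " retained samples, ",
      nrow(x$voxels), " voxels\n",
      "  min energy ", signif(x$min_energy, 3),
      ", acceptance ", round(x$acceptance_rate, 3),
      ", feasible: ", x$feasible, "\n", sep = "")
  invisible(x)
}

#' Tidy and summarize fitted lung states
#'
#' `tidy()` returns one row per retained sample (step, energy, whole-lung
#' FEV1/FVC, resistance ratio, AA%, and the inferred total mucus volume in
#' spirometry-only mode). `glance()` returns a one-row model summary.
#'
#' @param x A `lung_fit`.
#' @param ... Unused.
#' @export
tidy.lung_fit <- function(x, ...) x$samples

#' @rdname tidy.lung_fit
#' @export
glance.lung_fit <- function(x, ...) {
  best <- x$best_index
  tibble::tibble(
    mode = x$mode,
    n_retained = nrow(x$samples),
    acceptance_rate = x$acceptance_rate,
    min_energy = x$min_energy,
    fev1_best = x$samples$fev1[best],
    fvc_best = x$samples$fvc[best],
    fev1_target = x$targets$fev1,
    fvc_target = x$targets$fvc,
    feasible = x$feasible
  )
}

#' @export
autoplot.lung_fit <- function(object, ...) {
  df <- object$samples
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$energy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Metropolis step", y = "energy (log scale)",
                  title = "Retained-sample energy trace")
}

#' Posterior summary per voxel
#'
#' Means of the sampled resistance ratio (finite draws) and AA% per voxel
#' across retained samples, plus the probability of the blocked state.
#'
#' @param fit A `lung_fit`.
#' @return A tibble with one row per voxel.
#' @export
voxel_posterior <- function(fit) {
  ratio <- fit$ratio_samples
  aa <- fit$aa_samples
  fin <- is.finite(ratio)
  mean_ratio <- colSums(ifelse(fin, ratio, 0)) / pmax(colSums(fin), 1L)
  mean_ratio[colSums(fin) == 0L] <- Inf
  dplyr::mutate(
    fit$voxels,
    mean_ratio = mean_ratio,
    mean_aa = colMeans(aa),
    p_blocked = colMeans(!fin)
  )
}

# ---- drill-down -------------------------------------------------------------

#' Normalized per-generation mucus
#'
#' The share of a voxel's mucus held by a generation, divided by that
#' generation's share of the voxel's air (lumen) volume:
#' `(mucus_g / V_mucus) / (airvol_g / V_voxel)`. A value of 1 everywhere
#' means mucus proportional to available airway volume; a voxel with no
#' mucus has an all-zero profile by convention. The profile is invariant to
#' scaling all mucus amounts by a common factor.
#'
#' @param mucus_g Mucus volume per generation (mm^3, vectorized).
#' @param total_mucus Total mucus in the voxel (mm^3).
#' @param air_g Lumen (air) volume per generation (mm^3).
#' @param total_air Total lumen volume of the voxel (mm^3).
#' @return Dimensionless non-negative ratios.
#' @export
normalized_mucus <- function(mucus_g, total_mucus, air_g, total_air) {
  if (any(air_g <= 0) || total_air <= 0) {
    rlang::abort("air volumes must be positive", class = "lungtrack_input_error")
  }
  if (total_mucus == 0) return(rep(0, length(mucus_g)))
  (mucus_g / total_mucus) / (air_g / total_air)
}

#' Estimate the per-generation mucus distribution inside one voxel
#'
#' Given a voxel's mucus volume and its sampled (resistance ratio, AA%)
#' pair, runs a Metropolis chain over mucus configurations of the voxel
#' subtree at fixed total volume, with [energy_voxel()] steering the chain
#' toward configurations whose flow matches the pair. Per-generation mucus
#' is averaged over the retained samples and normalized by
#' [normalized_mucus()].
#'
#' If no configuration comes within `feasible_tol` relative residual of the
#' target pair (per component), the profile is flagged infeasible and the
#' best-found profile returned with its residual energy.
#'
#' @param tree The voxel [airway_tree()].
#' @param mucus_mm3 Total mucus volume in the voxel.
#' @param ratio_target,aa_target The voxel's sampled pair (ratio may be
#'   `Inf` for a blocked voxel).
#' @param settings A [chain_settings()].
#' @param feasible_tol Per-component relative residual below which the
#'   target counts as met.
#' @return A tibble of class `generation_profile` (one row per generation:
#'   mean and sd of mucus volume, air volume, normalized mucus) with
#'   attributes `feasible`, `residual_energy`, `residual_ratio`,
#'   `residual_aa`, `targets`, `total_mucus_mm3`.
#' @export
drilldown_voxel <- function(tree, mucus_mm3, ratio_target, aa_target,
                            settings = chain_settings(), feasible_tol = 0.05) {
  .check_materialized(tree)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  caps <- tree$cap_units
  v_units <- as.integer(round(mucus_mm3 / tree$unit_volume_mm3))
  if (v_units > tree$total_capacity_units) {
    rlang::abort("voxel mucus exceeds the subtree's lumen capacity",
                 class = "lungtrack_input_error")
  }
  air_g <- tree$geometry$n_segments * tree$geometry$lumen_volume_mm3
  total_air <- tree$total_lumen_mm3
  lev <- tree$node_level
  nlev <- tree$n_levels

  per_gen <- function(units) as.numeric(rowsum(units * tree$unit_volume_mm3, lev))

  if (v_units == 0L || v_units == tree$total_capacity_units) {
    # unique configuration; no chain needed
    units <- if (v_units == 0L) integer(length(caps)) else caps
    fl <- .flow_units(tree, units)
    gen_mm3 <- per_gen(units)
    res <- .pair_residuals(fl[2], fl[3], ratio_target, aa_target)
    profile <- tibble::tibble(
      generation = tree$geometry$generation,
      mucus_mm3 = gen_mm3, sd_mm3 = 0, air_mm3 = air_g,
      normalized = normalized_mucus(gen_mm3, sum(gen_mm3), air_g, total_air)
    )
    return(.as_generation_profile(profile, res, feasible_tol,
                                  ratio_target, aa_target, mucus_mm3,
                                  energy_voxel(fl[2], fl[3], ratio_target,
                                               aa_target, settings$w1,
                                               settings$w2)))
  }

  units0 <- .random_fill_units(caps, v_units)
  energy_fn <- function(u) {
    fl <- .flow_units(tree, u)
    energy_voxel(fl[2], fl[3], ratio_target, aa_target,
                 settings$w1, settings$w2)
  }
  chain_set <- settings
  chain_set$seed <- NULL
  chain <- run_chain(
    units0, energy_fn, function(u) .propose_units(u, caps), chain_set,
    sample_fn = function(u) {
      fl <- .flow_units(tree, u)
      list(gen = per_gen(u), ratio = fl[2], aa = fl[3])
    }
  )
  gen_m <- t(vapply(chain$samples, `[[`, numeric(nlev), "gen"))
  ratios <- vapply(chain$samples, `[[`, numeric(1), "ratio")
  aas <- vapply(chain$samples, `[[`, numeric(1), "aa")
  best <- which.min(chain$trace$energy)
  res <- .pair_residuals(ratios[best], aas[best], ratio_target, aa_target)

  mean_gen <- colMeans(gen_m)
  profile <- tibble::tibble(
    generation = tree$geometry$generation,
    mucus_mm3 = mean_gen,
    sd_mm3 = apply(gen_m, 2, stats::sd),
    air_mm3 = air_g,
    normalized = normalized_mucus(mean_gen, sum(mean_gen), air_g, total_air)
  )
  .as_generation_profile(profile, res, feasible_tol, ratio_target, aa_target,
                         mucus_mm3, chain$trace$energy[best])
}

# relative residuals of a (ratio, aa) pair against possibly degenerate targets
.pair_residuals <- function(ratio, aa, ratio_target, aa_target) {
  r_res <- if (!is.finite(ratio_target)) {
    if (is.finite(ratio)) 1 / ratio else 0
  } else if (!is.finite(ratio)) Inf else {
    abs(ratio - ratio_target) / ratio_target
  }
  a_res <- if (aa_target == 0) aa / 100 else abs(aa - aa_target) / aa_target
  c(ratio = r_res, aa = a_res)
}

.as_generation_profile <- function(profile, residuals, tol, ratio_target,
                                   aa_target, mucus_mm3, energy) {
  structure(
    profile,
    class = c("generation_profile", class(profile)),
    feasible = all(residuals <= tol),
    residual_ratio = unname(residuals["ratio"]),
    residual_aa = unname(residuals["aa"]),
    residual_energy = energy,
    target_ratio = ratio_target,
    target_aa = aa_target,
    total_mucus_mm3 = mucus_mm3
  )
}

#' @export
autoplot.generation_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$generation), y = .data$normalized)) +
    ggplot2::geom_col(fill = "indianred3") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "airway generation", y = "normalized mucus",
                  title = "Per-generation mucus distribution (voxel drill-down)")
}

#' Drill into one voxel of a fitted lung
#'
#' Convenience wrapper: takes the voxel's mucus volume and its sampled
#' (ratio, AA%) pair from the minimum-energy retained sample of a
#' [fit_lung()] result and calls [drilldown_voxel()].
#'
#' @param fit A `lung_fit` in imaging mode.
#' @param voxel Row index of the voxel in `fit$voxels`.
#' @inheritParams drilldown_voxel
#' @export
drilldown <- function(fit, voxel, settings = chain_settings(),
                      feasible_tol = 0.05) {
  stopifnot(inherits(fit, "lung_fit"))
  if (fit$mode != "imaging") {
    rlang::abort("drill-down needs an imaging-mode fit with per-voxel mucus volumes",
                 class = "lungtrack_input_error")
  }
  b <- fit$best_index
  drilldown_voxel(
    fit$lung$voxel_tree,
    mucus_mm3 = fit$voxels$mucus_mm3[voxel],
    ratio_target = fit$ratio_samples[b, voxel],
    aa_target = fit$aa_samples[b, voxel],
    settings = settings, feasible_tol = feasible_tol
  )
}
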