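# Offline 2D probability tables of (airflow resistance ratio, percent
# accessible alveoli) per voxel mucus fraction, built by flat-energy
# Metropolis sampling of mucus configurations at fixed total volume, plus
# real-time interpolation between tabulated fractions.

#' Binning scheme for PDFE-2D histograms
#'
#' Resistance ratios span several orders of magnitude (up to ~1e6 just
#' before a subtree blocks completely), so they are binned on a log10 scale
#' over `[0, log_ratio_max]` with one extra overflow row for fully blocked
#' states (infinite resistance). AA% is binned linearly over `[0, 100]`.
#' Finite ratios beyond the last edge are clamped into the last finite bin.
#'
#' @param n_ratio,n_aa Number of finite resistance-ratio bins and AA bins.
#' @param log_ratio_max Upper edge of the log10 resistance-ratio axis.
#' @return A list of class `pdfe_bins` with the bin edges.
#' @export
pdfe_bins <- function(n_ratio = 100L, n_aa = 100L, log_ratio_max = 6) {
  stopifnot(n_ratio >= 2, n_aa >= 2, log_ratio_max > 0)
  structure(
    list(n_ratio = as.integer(n_ratio), n_aa = as.integer(n_aa),
         log_ratio_max = as.numeric(log_ratio_max),
         breaks_logr = seq(0, log_ratio_max, length.out = n_ratio + 1L),
         breaks_aa = seq(0, 100, length.out = n_aa + 1L)),
    class = "pdfe_bins"
  )
}

# (row, col) cell indices for (ratio, aa) pairs; row n_ratio+1 is "blocked".
.pdfe_cell <- function(bins, ratio, aa) {
  row <- ifelse(
    is.finite(ratio),
    pmin(pmax(findInterval(log10(pmax(ratio, 1)), bins$breaks_logr,
                           rightmost.closed = TRUE), 1L), bins$n_ratio),
    bins$n_ratio + 1L
  )
  col <- pmin(pmax(findInterval(aa, bins$breaks_aa, rightmost.closed = TRUE),
                   1L), bins$n_aa)
  cbind(row, col)
}

# Representative (ratio, aa) values of cells. Boundary cells snap to the
# attainable extremes so that degenerate states stay exact: the first ratio
# bin maps to ratio 1 (healthy), the blocked row to Inf; the last AA bin to
# 100, the first to 0. Interior cells use midpoints.
.pdfe_cell_values <- function(bins, row, col) {
  mid_r <- (bins$breaks_logr[row] + bins$breaks_logr[row + 1L]) / 2
  ratio <- ifelse(row > bins$n_ratio, Inf,
                  ifelse(row == 1L, 1, 10^mid_r))
  aa <- ifelse(col == bins$n_aa, 100,
               ifelse(col == 1L, 0,
                      (bins$breaks_aa[col] + bins$breaks_aa[col + 1L]) / 2))
  list(resistance_ratio = unname(ratio), aa_percent = unname(aa))
}

# Equilibrate a configuration under the flat-energy kernel: `sweeps` full
# sweeps of accepted-by-construction unit moves. Used to draw (approximately)
# uniform configurations at fixed total volume.
.equilibrate_units <- function(units, caps, sweeps = 20L) {
  n <- length(units)
  for (s in seq_len(sweeps * n)) {
    i <- sample.int(n, 1L)
    j <- sample.int(n - 1L, 1L)
    if (j >= i) j <- j + 1L
    if (units[i] >= 1L && units[j] < caps[j]) {
      units[i] <- units[i] - 1L
      units[j] <- units[j] + 1L
    }
  }
  units
}

# fast internal proposal on raw unit vectors (frozenness pre-checked)
.propose_units <- function(units, caps) {
  n <- length(units)
  i <- sample.int(n, 1L)
  j <- sample.int(n - 1L, 1L)
  if (j >= i) j <- j + 1L
  if (units[i] >= 1L && units[j] < caps[j]) {
    units[i] <- units[i] - 1L
    units[j] <- units[j] + 1L
  }
  units
}

#' Build one PDFE-2D slice: the (ratio, AA%) histogram at a mucus fraction
#'
#' Fills the voxel subtree with `fraction` of its total lumen capacity
#' (rounded to whole unit volumes), then explores mucus configurations at
#' that fixed total with a flat-energy (unbiased) Metropolis chain -- every
#' legal unit move is accepted -- recording the resistance ratio and AA% of
#' each retained configuration. The two degenerate fractions need no chain:
#' fraction 0 is a point mass at (ratio 1, AA 100) and fraction 1 (a single,
#' saturated configuration) a point mass in the (blocked, AA 0) cell.
#'
#' @param tree A voxel [airway_tree()] (or any reduced tree).
#' @param fraction Mucus fraction of total lumen capacity, in `[0, 1]`.
#' @param settings A [chain_settings()]; `n_steps`, `burn_in`, `thin` and
#'   `seed` are used (the energy is flat, so `temperature` is irrelevant).
#' @param bins A [pdfe_bins()].
#' @return A list with `fraction`, integer `counts` (matrix, rows = ratio
#'   bins + blocked, cols = AA bins), `n_samples`, and the normalized
#'   `density`.
#' @export
build_pdfe_slice <- function(tree, fraction, settings, bins = pdfe_bins()) {
  stopifnot(fraction >= 0, fraction <= 1)
  .check_materialized(tree)
  if (!is.null(settings$seed)) set.seed(settings$seed)

  caps <- tree$cap_units
  total <- tree$total_capacity_units
  v_units <- as.integer(round(fraction * total))
  if (v_units == 0L && fraction > 0) {
    rlang::warn(paste0("fraction ", signif(fraction, 3),
                       " rounds to zero unit volumes; treated as 0"))
  }
  n_nominal <- (settings$n_steps - settings$burn_in) %/% settings$thin

  counts <- matrix(0L, nrow = bins$n_ratio + 1L, ncol = bins$n_aa)
  if (v_units == 0L || v_units == total) {
    units <- if (v_units == 0L) integer(length(caps)) else caps
    fl <- .flow_units(tree, units)
    cell <- .pdfe_cell(bins, fl[2], fl[3])
    counts[cell] <- n_nominal
    n_samples <- n_nominal
  } else {
    units0 <- .random_fill_units(caps, v_units)
    chain <- run_chain(
      initial_state = units0,
      energy_fn = function(u) 0,
      proposal_fn = function(u) .propose_units(u, caps),
      settings = chain_settings(
        n_steps = settings$n_steps, burn_in = settings$burn_in,
        thin = settings$thin, temperature = settings$temperature,
        w1 = settings$w1, w2 = settings$w2, seed = NULL
      ),
      sample_fn = function(u) .flow_units(tree, u)
    )
    pairs <- do.call(rbind, chain$samples)
    cells <- .pdfe_cell(bins, pairs[, 2], pairs[, 3])
    nr <- bins$n_ratio + 1L
    counts <- matrix(
      tabulate((cells[, 2] - 1L) * nr + cells[, 1], nbins = nr * bins$n_aa),
      nrow = nr
    )
    storage.mode(counts) <- "integer"
    n_samples <- nrow(cells)
  }
  list(fraction = fraction, counts = counts, n_samples = n_samples,
       density = counts / sum(counts))
}

#' Build a full PDFE-2D table over a grid of mucus fractions
#'
#' Maps [build_pdfe_slice()] over `fractions`, deriving one sub-seed per
#' fraction from `settings$seed` so the build is reproducible and slices are
#' independent.
#'
#' @param tree A voxel [airway_tree()].
#' @param fractions Increasing vector of mucus fractions in `[0, 1]`. The
#'   production default steps by 0.02; tests and examples use coarser grids.
#' @param settings A [chain_settings()] (per-slice chain length).
#' @param bins A [pdfe_bins()].
#' @return An object of class `pdfe2d_table`: fractions, bins, per-fraction
#'   integer count matrices, sample counts and metadata (tree parameters,
#'   chain settings, seed).
#' @export
build_pdfe_table <- function(tree, fractions = seq(0, 1, by = 0.02),
                             settings = chain_settings(), bins = pdfe_bins()) {
  stopifnot(!is.unsorted(fractions), all(fractions >= 0), all(fractions <= 1))
  slices <- vector("list", length(fractions))
  for (idx in seq_along(fractions)) {
    s_i <- settings
    if (!is.null(settings$seed)) s_i$seed <- settings$seed + idx - 1L
    slices[[idx]] <- build_pdfe_slice(tree, fractions[idx], s_i, bins)
  }
  structure(
    list(
      fractions = as.numeric(fractions),
      bins = bins,
      counts = lapply(slices, `[[`, "counts"),
      n_samples = vapply(slices, `[[`, integer(1), "n_samples"),
      meta = list(
        g_min = tree$g_min, g_max = tree$g_max,
        root_diameter_cm = tree$root_diameter_cm,
        root_length_cm = tree$root_length_cm,
        scale_factor = tree$scale_factor, viscosity = tree$viscosity,
        unit_volume_mm3 = tree$unit_volume_mm3,
        total_capacity_units = as.integer(tree$total_capacity_units),
        n_steps = settings$n_steps, burn_in = settings$burn_in,
        thin = settings$thin, temperature = settings$temperature,
        seed = if (is.null(settings$seed)) NA_integer_ else
          as.integer(settings$seed)
      )
    ),
    class = "pdfe2d_table"
  )
}

#' @export
print.pdfe2d_table <- function(x, ...) {
  cat("<pdfe2d_table> ", length(x$fractions), " mucus fractions in [",
      min(x$fractions), ", ", max(x$fractions), "], ",
      x$bins$n_ratio, "x", x$bins$n_aa,
      " bins (+ blocked row), ", sum(x$n_samples), " samples total\n", sep = "")
  invisible(x)
}

#' Normalized density of one tabulated slice
#' @param table A [build_pdfe_table()] result.
#' @param index Slice index along the fraction grid.
#' @return A density matrix summing to 1.
#' @export
pdfe_density <- function(table, index) {
  m <- table$counts[[index]]
  m / sum(m)
}

#' Interpolate the PDFE-2D density at an arbitrary mucus fraction
#'
#' Linear interpolation of the two bracketing tabulated densities, followed
#' by renormalization; at a grid point the stored slice is returned exactly.
#' Fractions outside the tabulated span are clamped (with a warning).
#'
#' @inheritParams pdfe_density
#' @param fraction Mucus fraction.
#' @param warn Warn when clamping out-of-span fractions.
#' @return A density matrix summing to 1.
#' @export
interpolate_pdfe <- function(table, fraction, warn = TRUE) {
  fr <- table$fractions
  if (fraction < fr[1] || fraction > fr[length(fr)]) {
    if (warn) {
      rlang::warn(paste0("fraction ", signif(fraction, 4),
                         " outside the tabulated span [", fr[1], ", ",
                         fr[length(fr)], "]; clamped"))
    }
    fraction <- min(max(fraction, fr[1]), fr[length(fr)])
  }
  hi <- findInterval(fraction, fr, rightmost.closed = TRUE)
  if (fraction == fr[hi]) return(pdfe_density(table, hi))
  w <- (fraction - fr[hi]) / (fr[hi + 1L] - fr[hi])
  d <- (1 - w) * pdfe_density(table, hi) + w * pdfe_density(table, hi + 1L)
  d / sum(d)
}

#' Draw (resistance ratio, AA%) pairs from a PDFE-2D density
#'
#' Samples cells with probability equal to their density and returns each
#' cell's representative values: midpoints of the log-ratio and AA bins,
#' with boundary cells snapped to the attainable extremes (first ratio bin
#' to 1, blocked row to `Inf`, last AA bin to 100, first AA bin to 0).
#'
#' @param density A normalized density matrix (from [pdfe_density()] or
#'   [interpolate_pdfe()]).
#' @param bins The [pdfe_bins()] the density was built with.
#' @param n Number of draws.
#' @return A tibble with `resistance_ratio` and `aa_percent`.
#' @export
pdfe_sample_pair <- function(density, bins, n = 1L) {
  tot <- sum(density)
  if (!(tot > 0)) {
    rlang::abort("density has no mass to sample from",
                 class = "lungtrack_input_error")
  }
  idx <- sample.int(length(density), n, replace = TRUE, prob = as.vector(density))
  row <- ((idx - 1L) %% nrow(density)) + 1L
  col <- ((idx - 1L) %/% nrow(density)) + 1L
  vals <- .pdfe_cell_values(bins, row, col)
  tibble::tibble(resistance_ratio = vals$resistance_ratio,
                 aa_percent = vals$aa_percent)
}

#' Maximum-likelihood (mode) curve of a PDFE-2D table
#'
#' For each tabulated mucus fraction, the cell of maximum density; ties are
#' broken toward lower resistance, then higher AA. Along the physical
#' degradation path the AA mode is non-increasing and the resistance-ratio
#' mode non-decreasing in the mucus fraction (up to one-bin sampling noise).
#'
#' @inheritParams pdfe_density
#' @return A tibble with one row per fraction: `fraction`, `blocked`,
#'   `resistance_ratio` (`Inf` when blocked), `log10_ratio`, `aa_percent`
#'   and the mode's `density`.
#' @export
pdfe_mode_curve <- function(table) {
  rows <- lapply(seq_along(table$fractions), function(idx) {
    d <- pdfe_density(table, idx)
    mx <- max(d)
    hits <- which(d == mx, arr.ind = TRUE)
    # lower resistance first, then higher aa
    hits <- hits[order(hits[, 1], -hits[, 2]), , drop = FALSE]
    row <- hits[1, 1]; col <- hits[1, 2]
    vals <- .pdfe_cell_values(table$bins, row, col)
    tibble::tibble(
      fraction = table$fractions[idx],
      blocked = row > table$bins$n_ratio,
      resistance_ratio = vals$resistance_ratio,
      log10_ratio = ifelse(is.finite(vals$resistance_ratio),
                           log10(vals$resistance_ratio), NA_real_),
      aa_percent = vals$aa_percent,
      density = mx
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pdfe2d_mode", class(out))
  out
}

#' @export
tidy.pdfe2d_table <- function(x, ...) {
  bins <- x$bins
  purrr::map_dfr(seq_along(x$fractions), function(idx) {
    d <- pdfe_density(x, idx)
    nz <- which(d > 0, arr.ind = TRUE)
    vals <- .pdfe_cell_values(bins, nz[, 1], nz[, 2])
    tibble::tibble(
      fraction = x$fractions[idx],
      blocked = nz[, 1] > bins$n_ratio,
      resistance_ratio = vals$resistance_ratio,
      aa_percent = vals$aa_percent,
      density = d[nz]
    )
  })
}

#' @export
autoplot.pdfe2d_table <- function(object, ...) {
  df <- tidy(object)
  df$log10_ratio <- ifelse(df$blocked, object$bins$log_ratio_max * 1.05,
                           log10(pmax(df$resistance_ratio, 1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_ratio, y = .data$aa_percent)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$density)) +
    ggplot2::facet_wrap(~fraction, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = "log10 airflow resistance ratio (blocked at right edge)",
                  y = "accessible alveoli (%)",
                  title = "PDFE-2D by voxel mucus fraction")
}

#' @rdname pdfe_mode_curve
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.pdfe2d_mode <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$aa_percent), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$aa_percent), colour = "steelblue") +
    ggplot2::labs(x = "voxel mucus fraction", y = "mode AA (%)",
                  title = "Most likely accessible alveoli vs mucus fraction")
}

# ---- persistence ------------------------------------------------------------

#' Save / load a PDFE-2D table
#'
#' Tables persist as a structured JSON container with one record per mucus
#' fraction (integer sample counts per cell, number of samples) plus the
#' binning parameters and build metadata (tree parameters, chain settings,
#' seed). Counts are stored as integers and densities recomputed on load,
#' so a save/load round trip reproduces the table bit-exactly.
#'
#' @param table A `pdfe2d_table`.
#' @param path File path (conventionally `.json`).
#' @return `write_pdfe` returns `path` invisibly; `read_pdfe` the table.
#' @export
write_pdfe <- function(table, path) {
  stopifnot(inherits(table, "pdfe2d_table"))
  payload <- list(
    format = "lungtrack-pdfe2d",
    version = 1L,
    n_ratio = table$bins$n_ratio,
    n_aa = table$bins$n_aa,
    log_ratio_max = table$bins$log_ratio_max,
    fractions = table$fractions,
    n_samples = table$n_samples,
    counts = table$counts,
    meta = table$meta
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}

#' @rdname write_pdfe
#' @export
read_pdfe <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("PDFE table file not found: ", path),
                 class = "lungtrack_input_error")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "lungtrack-pdfe2d")) {
    rlang::abort("not a lungtrack PDFE-2D container",
                 class = "lungtrack_input_error")
  }
  counts <- p$counts
  if (is.array(counts) && length(dim(counts)) == 3L) {
    counts <- lapply(seq_len(dim(counts)[1]), function(s) {
      m <- counts[s, , ]
      storage.mode(m) <- "integer"
      m
    })
  } else {
    counts <- lapply(counts, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "integer"
      m
    })
  }
  meta <- p$meta
  meta$seed <- if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_ else
    as.integer(meta$seed)
  for (f in c("g_min", "g_max", "n_steps", "burn_in", "thin",
              "total_capacity_units")) {
    meta[[f]] <- as.integer(meta[[f]])
  }
  for (f in c("root_diameter_cm", "root_length_cm", "scale_factor",
              "viscosity", "unit_volume_mm3", "temperature", "w1", "w2")) {
    if (!is.null(meta[[f]])) meta[[f]] <- as.numeric(meta[[f]])
  }
  structure(
    list(
      fractions = as.numeric(p$fractions),
      bins = pdfe_bins(p$n_ratio, p$n_aa, as.numeric(p$log_ratio_max)),
      counts = counts,
      n_samples = as.integer(p$n_samples),
      meta = meta
    ),
    class = "pdfe2d_table"
  )
}
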