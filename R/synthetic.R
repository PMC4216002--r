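# Synthetic patients: a lung-shaped voxel grid with contiguous pockets of
# infection, ground-truth per-voxel mucus micro-configurations, and the
# forward-computed spirometry they imply. Everything downstream is testable
# against these without any clinical data.

# Two ellipsoidal voxel masks (left/right lung) on the 1 cm grid, scaled so
# at least n voxels fall inside; the n with smallest ellipsoid radius are
# kept (deterministic).
.lung_shape <- function(n_voxels) {
  s <- 1
  repeat {
    a <- 2.2 * s; b <- 3.2 * s; c2 <- 4.5 * s
    r <- ceiling(c(a + 2.6 * s, b, c2))
    grid <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
    d_left <- ((grid$i + 1.3 * s) / a)^2 + (grid$j / b)^2 + (grid$k / c2)^2
    d_right <- ((grid$i - 1.3 * s) / a)^2 + (grid$j / b)^2 + (grid$k / c2)^2
    d <- pmin(d_left, d_right)
    inside <- d <= 1
    if (sum(inside) >= n_voxels) {
      g <- grid[inside, ]
      g$d <- d[inside]
      g <- g[order(g$d, g$i, g$j, g$k), ]
      return(tibble::as_tibble(g[seq_len(n_voxels), c("i", "j", "k")]))
    }
    s <- s * 1.2
  }
}

#' Generate a synthetic patient
#'
#' Emulates the imaging summary the tracking pipeline consumes: a
#' lung-shaped set of voxels (two ellipsoidal masks on the 1 cm grid) with
#' `n_pockets` contiguous pockets of infection, each a cluster of voxels
#' around a random center carrying a mucus fraction drawn uniformly from
#' `fraction_range`. Every pocket voxel receives a concrete ground-truth
#' mucus micro-configuration, drawn from the uniform configuration ensemble
#' at the pocket fraction (random fill plus flat-energy Metropolis
#' equilibration -- the same ensemble the offline PDFE tables describe),
#' whose exact airflow resistance ratio and AA% are
#' computed with [tree_flow()] and aggregated to the ground-truth FEV1/FVC.
#' Deterministic under `seed`.
#'
#' @param lung A [lung_model()]; `lung$n_voxels` voxels are generated.
#' @param n_pockets Number of infection pockets (0 gives a healthy patient).
#' @param pocket_radius Pocket radius in voxels (Euclidean, on the grid).
#' @param fraction_range Range the pocket mucus fractions are drawn from.
#' @param age,height,sex Demographics of the synthetic patient.
#' @param seed Integer seed.
#' @return An object of class `synthetic_patient`: `voxels` (the standard
#'   `i,j,k,mucus_mm3` table), `truth` (per-voxel fraction, exact ratio,
#'   AA%), `pockets`, `patient` (a [patient_spirometry()] whose `fev1`/`fvc`
#'   are the ground-truth forward values), `fev1`, `fvc`, and the seed.
#' @export
generate_patient <- function(lung, n_pockets = 3L, pocket_radius = 1.5,
                             fraction_range = c(0.3, 0.8),
                             age = 22, height = 170, sex = "male",
                             seed = 1L) {
  stopifnot(n_pockets >= 0, all(fraction_range >= 0), all(fraction_range <= 1))
  set.seed(seed)
  shape <- .lung_shape(lung$n_voxels)
  n <- nrow(shape)
  fraction <- rep(0, n)

  pockets <- tibble::tibble(pocket = integer(), center_i = integer(),
                            center_j = integer(), center_k = integer(),
                            radius = numeric(), fraction = numeric(),
                            n_voxels = integer())
  if (n_pockets > 0) {
    centers <- sample.int(n, n_pockets, replace = FALSE)
    for (p in seq_len(n_pockets)) {
      ctr <- shape[centers[p], ]
      fr <- stats::runif(1, fraction_range[1], fraction_range[2])
      d2 <- (shape$i - ctr$i)^2 + (shape$j - ctr$j)^2 + (shape$k - ctr$k)^2
      members <- d2 <= pocket_radius^2
      if (!any(members)) {
        rlang::abort("pocket does not fit inside the lung shape",
                     class = "lungtrack_input_error")
      }
      fraction[members] <- pmax(fraction[members], fr)
      pockets <- dplyr::bind_rows(pockets, tibble::tibble(
        pocket = p, center_i = ctr$i, center_j = ctr$j, center_k = ctr$k,
        radius = pocket_radius, fraction = fr, n_voxels = sum(members)
      ))
    }
  }

  vt <- lung$voxel_tree
  units <- as.integer(round(fraction * vt$total_capacity_units))
  mucus_mm3 <- units * vt$unit_volume_mm3
  ratio <- rep(1, n); aa <- rep(100, n)
  for (q in which(units > 0L)) {
    # draw the ground-truth micro-configuration from the flat (uniform)
    # configuration ensemble: random fill plus Metropolis equilibration,
    # the same ensemble the offline tables are built from
    cfg_units <- .equilibrate_units(
      .random_fill_units(vt$cap_units, units[q]), vt$cap_units
    )
    fl <- .flow_units(vt, cfg_units)
    ratio[q] <- fl[2]; aa[q] <- fl[3]
  }

  fvc_h <- fvc_reference(age, height, sex)
  agg <- .lung_aggregate(lung, ratio, aa, fvc_h)
  patient <- patient_spirometry(age, height, sex,
                                fev1 = agg$fev1, fvc = agg$fvc)
  structure(
    list(
      voxels = dplyr::bind_cols(shape, tibble::tibble(mucus_mm3 = mucus_mm3)),
      truth = dplyr::bind_cols(
        shape,
        tibble::tibble(mucus_mm3 = mucus_mm3, fraction = units /
                         vt$total_capacity_units,
                       resistance_ratio = ratio, aa_percent = aa)
      ),
      pockets = pockets,
      patient = patient,
      fev1 = agg$fev1, fvc = agg$fvc,
      aa_percent = agg$aa_percent, resistance_ratio = agg$resistance_ratio,
      lung = lung, seed = as.integer(seed)
    ),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient> ", nrow(x$voxels), " voxels, ",
      nrow(x$pockets), " pockets, total mucus ",
      round(sum(x$voxels$mucus_mm3), 1), " mm^3\n",
      "  ground truth FEV1 ", round(x$fev1, 2), " L, FVC ",
      round(x$fvc, 2), " L\n", sep = "")
  invisible(x)
}

#' Write a synthetic patient to delimited text
#'
#' Emits the standard voxel table (`<stem>_voxels.csv`), the ground-truth
#' sidecar (`<stem>_truth.csv`: per-voxel fraction and exact flow pair) and
#' the patient record (`<stem>_patient.csv` with demographics and the
#' forward-computed FEV1/FVC). The sidecar is meant for tests and
#' validation only -- a real pipeline never sees it.
#'
#' @param sp A [generate_patient()] result.
#' @param stem Path stem for the three files.
#' @return The three paths, invisibly.
#' @export
write_patient <- function(sp, stem) {
  stopifnot(inherits(sp, "synthetic_patient"))
  paths <- paste0(stem, c("_voxels.csv", "_truth.csv", "_patient.csv"))
  utils::write.csv(as.data.frame(sp$voxels), paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(sp$truth), paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(sp$patient), paths[3], row.names = FALSE)
  invisible(paths)
}
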