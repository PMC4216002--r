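test_that("a healthy patient with zero-mucus voxels fits at energy zero immediately", {
  lung <- test_lung()
  tab <- test_pdfe()
  p <- patient_spirometry(25, 175, "male")
  healthy <- lung_spirometry(lung, rep(1, 64), rep(100, 64), p)
  targets <- patient_spirometry(25, 175, "male",
                                fev1 = healthy$fev1, fvc = healthy$fvc)
  voxels <- tibble::tibble(i = 1:8, j = rep(1:4, 2), k = rep(1:2, 4),
                           mucus_mm3 = 0)
  fit <- fit_lung(voxels, targets, tab, lung, fit_settings(n_steps = 2000))
  expect_identical(fit$min_energy, 0)
  expect_true(fit$feasible)
  expect_equal(max(tidy(fit)$energy), 0)
})

test_that("fit_lung recovers forward-simulated spirometry (single voxel)", {
  # single-voxel lung: the voxel subtree is the whole tree
  lung <- lung_model(n_voxels = 1, voxel_levels = 6)
  # fine ratio bins so a single voxel can match targets within the cell width
  bins <- pdfe_bins(400, 200, 3)
  tab <- build_pdfe_table(lung$voxel_tree, seq(0, 0.6, by = 0.1),
                          chain_settings(n_steps = 20000, thin = 10, seed = 42),
                          bins)
  set.seed(3)
  truth <- random_config(lung$voxel_tree, fraction = 0.3)
  # equilibrate into the uniform ensemble the tables describe
  truth$units <- lungtrack:::.equilibrate_units(truth$units,
                                                lung$voxel_tree$cap_units)
  fl <- tree_flow(lung$voxel_tree, truth)
  p <- patient_spirometry(25, 175, "male")
  fwd <- lung_spirometry(lung, fl$resistance_ratio, fl$aa_percent, p)
  targets <- patient_spirometry(25, 175, "male", fev1 = fwd$fev1, fvc = fwd$fvc)
  voxels <- tibble::tibble(i = 1, j = 1, k = 1, mucus_mm3 = mucus_volume(truth))
  fit <- fit_lung(voxels, targets, tab, lung, fit_settings(n_steps = 20000))
  g <- glance(fit)
  expect_lt(abs(g$fev1_best - targets$fev1) / targets$fev1, 0.02)
  expect_lt(abs(g$fvc_best - targets$fvc) / targets$fvc, 0.02)
})

test_that("fits are deterministic under a seed and flag unreachable targets", {
  lung <- test_lung()
  tab <- test_pdfe()
  targets <- patient_spirometry(25, 175, "male", fev1 = 2.2, fvc = 3.1)
  voxels <- tibble::tibble(i = 1:4, j = 1, k = 1,
                           mucus_mm3 = 0.3 * lung$voxel_capacity_mm3)
  f1 <- suppressWarnings(fit_lung(voxels, targets, tab, lung, fit_settings()))
  f2 <- suppressWarnings(fit_lung(voxels, targets, tab, lung, fit_settings()))
  expect_identical(tidy(f1), tidy(f2))

  # 4 diseased voxels out of 8192-equivalent cannot drag fvc to 3.1 L
  expect_warning(
    fit_lung(voxels, targets, tab, lung, fit_settings(n_steps = 3000)),
    "threshold"
  )
})

test_that("voxel mucus exceeding lumen capacity is rejected", {
  lung <- test_lung()
  tab <- test_pdfe()
  targets <- patient_spirometry(25, 175, "male", fev1 = 2, fvc = 3)
  voxels <- tibble::tibble(i = 1, j = 1, k = 1,
                           mucus_mm3 = lung$voxel_capacity_mm3 * 1.2)
  expect_error(fit_lung(voxels, targets, tab, lung, fit_settings()),
               class = "lungtrack_input_error")
})

test_that("spirometry-only fit of healthy targets keeps mucus near zero", {
  lung <- test_lung()
  tab <- test_pdfe()
  p <- patient_spirometry(25, 175, "male")
  healthy <- lung_spirometry(lung, rep(1, 64), rep(100, 64), p)
  targets <- patient_spirometry(25, 175, "male",
                                fev1 = healthy$fev1, fvc = healthy$fvc)
  # low temperature: this is a concentration check, not an exploration run
  fit <- fit_lung_spirometry(
    targets, tab, lung,
    chain_settings(n_steps = 20000, thin = 10, temperature = 1e-4, seed = 5)
  )
  total_cap <- 64 * lung$voxel_capacity_mm3
  expect_lt(mean(tidy(fit)$total_mucus_mm3) / total_cap, 0.05)
  expect_lt(fit$min_energy, 1e-3)
})

test_that("spirometry-only posterior is calibrated for the total mucus volume", {
  # simulation-based calibration: draw the truth from the sampler's own
  # generative prior (uniform quantized allocation, pairs from the slices),
  # so the central 90% interval must cover the true total
  lung <- test_lung()
  tab <- test_pdfe()
  truth <- draw_prior_lung(lung, tab, seed = 501)
  fit <- fit_lung_spirometry(truth$targets, tab, lung,
                             fit_settings(n_steps = 80000, seed = 601))
  ci <- stats::quantile(tidy(fit)$total_mucus_mm3, c(0.05, 0.95))
  expect_gte(truth$total_mm3, ci[[1]])
  expect_lte(truth$total_mm3, ci[[2]])
  # mucus conservation within fixed-total proposals: totals move in quanta
  steps <- diff(tidy(fit)$total_mucus_mm3)
  expect_true(all(abs(steps / fit$quantum_mm3 -
                        round(steps / fit$quantum_mm3)) < 1e-9))
})

test_that("normalized mucus satisfies its identities", {
  air <- c(10, 20, 30)
  # proportional to air volume -> flat profile of 1
  expect_equal(normalized_mucus(air * 0.2, sum(air) * 0.2, air, sum(air)),
               rep(1, 3))
  # all mucus in one generation
  expect_equal(normalized_mucus(c(0, 5, 0), 5, air, sum(air)),
               c(0, sum(air) / 20, 0))
  # scale invariance
  expect_equal(normalized_mucus(c(1, 2, 3), 6, air, sum(air)),
               normalized_mucus(2 * c(1, 2, 3), 12, air, sum(air)))
  # no mucus -> zero profile by convention
  expect_equal(normalized_mucus(c(0, 0, 0), 0, air, sum(air)), rep(0, 3))
  expect_error(normalized_mucus(1, 1, 0, 1), class = "lungtrack_input_error")
})

test_that("drill-down handles the degenerate voxels exactly", {
  vt <- test_lung()$voxel_tree
  empty <- drilldown_voxel(vt, 0, 1, 100, fit_settings(n_steps = 1000))
  expect_equal(empty$mucus_mm3, rep(0, 5))
  expect_equal(empty$normalized, rep(0, 5))
  expect_true(attr(empty, "feasible"))

  cap <- vt$total_capacity_units * vt$unit_volume_mm3
  full <- drilldown_voxel(vt, cap, Inf, 0, fit_settings(n_steps = 1000))
  expect_equal(full$normalized, rep(1, 5), tolerance = 1e-12)
  expect_equal(sum(full$mucus_mm3), cap)
  expect_true(attr(full, "feasible"))
})

test_that("drill-down conserves mucus and reports residuals", {
  vt <- test_lung()$voxel_tree
  v <- 0.3 * vt$total_capacity_units * vt$unit_volume_mm3
  v_exact <- round(v / vt$unit_volume_mm3) * vt$unit_volume_mm3
  pr <- drilldown_voxel(vt, v, 2, 37.5, fit_settings(n_steps = 5000))
  expect_equal(sum(pr$mucus_mm3), v_exact, tolerance = 1e-12)
  expect_true(is.finite(attr(pr, "residual_energy")))
  expect_s3_class(pr, "generation_profile")

  # an unattainable pair is flagged, best-found profile still returned
  bad <- drilldown_voxel(vt, v, 1, 100, fit_settings(n_steps = 2000))
  expect_false(attr(bad, "feasible"))
  expect_equal(sum(bad$mucus_mm3), v_exact, tolerance = 1e-12)
})

test_that("drilldown() pulls the voxel state from a fitted lung", {
  lung <- test_lung()
  tab <- test_pdfe()
  sp <- generate_patient(lung, n_pockets = 2, seed = 31)
  fit <- suppressWarnings(
    fit_lung(sp$voxels, sp$patient, tab, lung, fit_settings(n_steps = 10000))
  )
  target_voxel <- which(sp$voxels$mucus_mm3 > 0)[1]
  pr <- drilldown(fit, target_voxel, fit_settings(n_steps = 3000))
  expect_s3_class(pr, "generation_profile")
  expect_equal(attr(pr, "total_mucus_mm3"), sp$voxels$mucus_mm3[target_voxel])
})
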