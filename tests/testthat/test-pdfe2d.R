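small_tree <- function() airway_tree(0, 2)   # 7 nodes, caps (4,2,2,1,1,1,1)

test_that("degenerate fractions give the exact point masses", {
  tr <- small_tree()
  bins <- pdfe_bins(20, 20, 6)
  st <- chain_settings(n_steps = 1000, thin = 10, seed = 1)

  s0 <- build_pdfe_slice(tr, 0, st, bins)
  expect_equal(sum(s0$density), 1)
  # all mass in the cell holding (ratio 1, aa 100): first ratio row, last aa col
  expect_equal(s0$density[1, 20], 1)

  s1 <- build_pdfe_slice(tr, 1, st, bins)
  expect_equal(s1$density[21, 1], 1)   # blocked overflow row, aa = 0 column
})

test_that("a fraction rounding to zero units warns and degrades to empty", {
  tr <- small_tree()
  st <- chain_settings(n_steps = 1000, thin = 10, seed = 1)
  expect_warning(s <- build_pdfe_slice(tr, 1e-4, st, pdfe_bins(10, 10, 6)),
                 "zero unit")
  expect_equal(s$density[1, 10], 1)
})

test_that("flat-energy slice matches exhaustive enumeration of configurations", {
  tr <- small_tree()
  bins <- pdfe_bins(30, 30, 6)
  v_units <- 2L
  states <- enumerate_configs(tr$cap_units, v_units)
  # expected cell probabilities: uniform over configurations
  expected <- matrix(0, bins$n_ratio + 1L, bins$n_aa)
  for (s in seq_len(nrow(states))) {
    fl <- tree_flow(tr, mucus_config(tr, states[s, ]))
    cell <- lungtrack:::.pdfe_cell(bins, fl$resistance_ratio, fl$aa_percent)
    expected[cell] <- expected[cell] + 1 / nrow(states)
  }
  fraction <- v_units / tr$total_capacity_units
  # thinned so retained samples are nearly independent for the chi-square
  st <- chain_settings(n_steps = 100000, burn_in = 10000, thin = 20, seed = 21)
  slice <- build_pdfe_slice(tr, fraction, st, bins)
  expect_equal(slice$fraction, fraction)

  nz <- expected > 0
  expect_true(all(slice$counts[!nz] == 0))
  obs <- slice$counts[nz]
  test <- suppressWarnings(stats::chisq.test(obs, p = expected[nz]))
  expect_gt(test$p.value, 0.01)
})

test_that("table builds are deterministic under a fixed seed", {
  tr <- small_tree()
  st <- chain_settings(n_steps = 2000, thin = 5, seed = 13)
  bins <- pdfe_bins(15, 15, 6)
  t1 <- build_pdfe_table(tr, c(0, 0.25, 1), st, bins)
  t2 <- build_pdfe_table(tr, c(0, 0.25, 1), st, bins)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$n_samples, t2$n_samples)
})

test_that("interpolation is exact at grid points and renormalized between", {
  tr <- small_tree()
  st <- chain_settings(n_steps = 3000, thin = 5, seed = 17)
  tab <- build_pdfe_table(tr, c(0, 0.5, 1), st, pdfe_bins(15, 15, 6))

  expect_identical(interpolate_pdfe(tab, 0.5), pdfe_density(tab, 2))
  mid <- interpolate_pdfe(tab, 0.25)
  expect_equal(sum(mid), 1)
  expect_equal(mid, (pdfe_density(tab, 1) + pdfe_density(tab, 2)) / 2)
  expect_warning(clamped <- interpolate_pdfe(tab, 1.5), "clamped")
  expect_identical(clamped, pdfe_density(tab, 3))
})

test_that("pair sampling reproduces the density and snaps boundary cells", {
  bins <- pdfe_bins(10, 10, 2)
  dens <- matrix(0, 11, 10)
  dens[1, 10] <- 0.5   # (ratio 1, aa 100)
  dens[11, 1] <- 0.3   # (blocked, aa 0)
  dens[5, 5] <- 0.2
  set.seed(31)
  draws <- pdfe_sample_pair(dens, bins, 5000)
  expect_setequal(unique(draws$aa_percent[draws$resistance_ratio == 1]), 100)
  blocked <- !is.finite(draws$resistance_ratio)
  expect_setequal(unique(draws$aa_percent[blocked]), 0)
  freq <- c(mean(draws$resistance_ratio == 1), mean(blocked))
  expect_lt(abs(freq[1] - 0.5), 3 * sqrt(0.25 / 5000))
  expect_lt(abs(freq[2] - 0.3), 3 * sqrt(0.21 / 5000))
  # interior cell uses midpoints
  mid <- draws[is.finite(draws$resistance_ratio) & draws$resistance_ratio > 1, ]
  expect_equal(unique(mid$aa_percent), 45)
  expect_equal(unique(mid$resistance_ratio), 10^0.9)

  expect_error(pdfe_sample_pair(matrix(0, 11, 10), bins),
               class = "lungtrack_input_error")
})

test_that("pair sampling is deterministic under a seed", {
  bins <- pdfe_bins(10, 10, 2)
  dens <- matrix(1 / 110, 11, 10)
  set.seed(5); d1 <- pdfe_sample_pair(dens, bins, 50)
  set.seed(5); d2 <- pdfe_sample_pair(dens, bins, 50)
  expect_identical(d1, d2)
})

test_that("the mode curve breaks ties toward lower resistance then higher aa", {
  bins <- pdfe_bins(5, 5, 2)
  counts <- matrix(0L, 6, 5)
  counts[2, 2] <- 5L; counts[2, 4] <- 5L; counts[4, 5] <- 5L  # three-way tie
  tab <- structure(
    list(fractions = 0.5, bins = bins, counts = list(counts),
         n_samples = 15L, meta = list()),
    class = "pdfe2d_table"
  )
  mode <- pdfe_mode_curve(tab)
  # row 2 beats row 4 (lower resistance); col 4 beats col 2 (higher aa);
  # 5 log-ratio bins over [0, 2]: row 2 spans [0.4, 0.8], midpoint 0.6
  expect_equal(mode$aa_percent, (60 + 80) / 2)
  expect_equal(mode$resistance_ratio, 10^((0.4 + 0.8) / 2))
})

test_that("mode curves of point-mass endpoint slices are the exact extremes", {
  tr <- small_tree()
  st <- chain_settings(n_steps = 1000, thin = 10, seed = 2)
  tab <- build_pdfe_table(tr, c(0, 1), st, pdfe_bins(10, 10, 6))
  mode <- pdfe_mode_curve(tab)
  expect_equal(mode$resistance_ratio[1], 1)
  expect_equal(mode$aa_percent[1], 100)
  expect_true(mode$blocked[2])
  expect_equal(mode$aa_percent[2], 0)
})

test_that("persistence round-trips the table bit-exactly", {
  tr <- small_tree()
  st <- chain_settings(n_steps = 3000, thin = 5, seed = 19)
  tab <- build_pdfe_table(tr, c(0, 0.3, 0.7, 1), st, pdfe_bins(25, 25, 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_pdfe(tab, path)
  back <- read_pdfe(path)
  expect_identical(unclass(tab), unclass(back))
  expect_error(read_pdfe(withr::local_tempfile(fileext = ".json")),
               class = "lungtrack_input_error")
})

test_that("every stored and interpolated histogram is normalized", {
  tab <- test_pdfe()
  for (i in seq_along(tab$fractions)) {
    expect_equal(sum(pdfe_density(tab, i)), 1, tolerance = 1e-12)
  }
  for (f in c(0.05, 0.33, 0.91)) {
    expect_equal(sum(interpolate_pdfe(tab, f)), 1, tolerance = 1e-12)
  }
})

test_that("the mode curve degrades monotonically with mucus fraction", {
  tab <- test_pdfe()
  mode <- pdfe_mode_curve(tab)
  bins <- tab$bins
  aa_bin <- findInterval(mode$aa_percent, bins$breaks_aa, rightmost.closed = TRUE)
  r_bin <- ifelse(mode$blocked, bins$n_ratio + 1L,
                  findInterval(mode$log10_ratio, bins$breaks_logr,
                               rightmost.closed = TRUE))
  # non-increasing aa / non-decreasing ratio, up to one-bin sampling noise
  expect_true(all(diff(aa_bin) <= 1))
  expect_true(all(diff(r_bin) >= -1))
})
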