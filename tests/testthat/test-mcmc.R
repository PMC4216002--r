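test_that("spirometric energy is a squared relative error", {
  targets <- patient_spirometry(25, 175, "male", fev1 = 2, fvc = 3)
  expect_identical(energy_spirometric(2, 3, targets), 0)
  expect_equal(energy_spirometric(2.2, 3, targets), 0.01)       # +10% fev1
  expect_equal(energy_spirometric(1.8, 3, targets), 0.01)       # sign-symmetric
  e1 <- energy_spirometric(2.2, 3, targets, w1 = 1)
  expect_equal(energy_spirometric(2.2, 3, targets, w1 = 2), 2 * e1)
  bad <- patient_spirometry(25, 175, "male")
  expect_error(energy_spirometric(2, 3, bad), class = "lungtrack_input_error")
})

test_that("voxel energy handles degenerate targets", {
  expect_identical(energy_voxel(2, 40, 2, 40), 0)
  expect_equal(energy_voxel(2.4, 40, 2, 40), 0.04)              # +20% ratio
  expect_equal(energy_voxel(1.6, 40, 2, 40), 0.04)
  # aa target 0 -> absolute term on the aa fraction
  expect_equal(energy_voxel(2, 30, 2, 0), 0.09)
  # blocked target -> absolute term on the conductance ratio
  expect_equal(energy_voxel(4, 0, Inf, 0), 1 / 16)
  expect_identical(energy_voxel(Inf, 0, Inf, 0), 0)
  # blocked model against a finite target is infinitely bad
  expect_identical(energy_voxel(Inf, 10, 2, 10), Inf)
})

test_that("the acceptance rule is Metropolis with one uniform draw", {
  expect_true(mh_accept(1, 1, 0.01))
  expect_true(mh_accept(1, 0.5, 0.01, u = 0.999999))
  # dE = T ln 2 -> acceptance threshold exactly 1/2
  T <- 0.01
  expect_true(mh_accept(0, T * log(2), T, u = 0.4))
  expect_false(mh_accept(0, T * log(2), T, u = 0.6))
  expect_error(mh_accept(0, 1, 0), class = "lungtrack_input_error")
})

test_that("empirical acceptance frequency matches the Boltzmann factor", {
  T <- 0.01
  de <- 0.005
  p <- exp(-de / T)
  set.seed(99)
  n <- 20000
  acc <- sum(vapply(seq_len(n), function(i) mh_accept(0, de, T), logical(1)))
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("chain settings are validated", {
  expect_error(chain_settings(temperature = 0), class = "lungtrack_input_error")
  expect_error(chain_settings(n_steps = 10, burn_in = 10),
               class = "lungtrack_input_error")
  expect_error(chain_settings(thin = 0), class = "lungtrack_input_error")
  expect_identical(chain_settings(1000)$burn_in, 100L)  # 10% default
})

test_that("chains are bit-for-bit reproducible under a seed", {
  tr <- airway_tree(0, 2)
  set.seed(1)
  init <- random_config(tr, fraction = 0.3)$units
  st <- chain_settings(n_steps = 2000, thin = 5, seed = 123)
  run <- function() run_chain(
    init, function(u) 0,
    function(u) lungtrack:::.propose_units(u, tr$cap_units), st
  )
  c1 <- run(); c2 <- run()
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$trace, c2$trace)
})

test_that("flat-energy sampling is uniform over legal configurations", {
  tr <- airway_tree(0, 1)            # caps (2, 1, 1)
  states <- enumerate_configs(tr$cap_units, 2L)
  key <- apply(states, 1, paste, collapse = ",")
  st <- chain_settings(n_steps = 30000, burn_in = 3000, thin = 5, seed = 7)
  chain <- run_chain(
    c(2L, 0L, 0L), function(u) 0,
    function(u) lungtrack:::.propose_units(u, tr$cap_units), st,
    sample_fn = function(u) paste(u, collapse = ",")
  )
  obs <- table(factor(unlist(chain$samples), levels = key))
  test <- suppressWarnings(stats::chisq.test(obs, p = rep(1 / 4, 4)))
  expect_gt(test$p.value, 0.01)
})

test_that("long-run state frequencies follow Boltzmann weights", {
  tr <- airway_tree(0, 1)
  states <- enumerate_configs(tr$cap_units, 2L)
  key <- apply(states, 1, paste, collapse = ",")
  T <- 0.7
  energy <- function(u) u[1]        # units in the root
  w <- exp(-states[, 1] / T)
  probs <- w / sum(w)
  st <- chain_settings(n_steps = 60000, burn_in = 5000, thin = 5,
                       temperature = T, seed = 11)
  chain <- run_chain(
    c(2L, 0L, 0L), energy,
    function(u) lungtrack:::.propose_units(u, tr$cap_units), st,
    sample_fn = function(u) paste(u, collapse = ",")
  )
  obs <- table(factor(unlist(chain$samples), levels = key))
  test <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(test$p.value, 0.01)
})

test_that("a tiny temperature concentrates the chain on the energy minimum", {
  tr <- airway_tree(0, 1)
  # unique minimum: both units in the terminal nodes, none in the root
  energy <- function(u) u[1]
  st <- chain_settings(n_steps = 20000, burn_in = 5000, thin = 5,
                       temperature = 1e-4, seed = 3)
  chain <- run_chain(
    c(2L, 0L, 0L), energy,
    function(u) lungtrack:::.propose_units(u, tr$cap_units), st,
    sample_fn = function(u) u[1]
  )
  expect_lt(mean(unlist(chain$samples)), 0.01)
})

test_that("a frozen start terminates the chain gracefully", {
  tr <- airway_tree(0, 1)
  st <- chain_settings(n_steps = 100, burn_in = 0, thin = 1, seed = 5)
  chain <- run_chain(
    integer(3), function(u) 0,
    function(u) propose_move(mucus_config(tr, u), tr), st
  )
  expect_true(chain$frozen)
  expect_identical(length(chain$samples), 0L)
})
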