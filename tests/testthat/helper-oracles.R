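# Independent oracles and shared fixtures, built in code at test time.

# All mucus configurations (rows) with per-node capacities `caps` summing to
# exactly `v_units`, by direct recursive enumeration.
enumerate_configs <- function(caps, v_units) {
  if (length(caps) == 1L) {
    if (v_units <= caps) return(matrix(v_units, 1, 1))
    return(NULL)
  }
  out <- list()
  for (v in 0:min(caps[1], v_units)) {
    rest <- enumerate_configs(caps[-1], v_units - v)
    if (!is.null(rest)) out[[length(out) + 1L]] <- cbind(v, rest)
  }
  do.call(rbind, out)
}

# Brute-force Kirchhoff nodal analysis of the equivalent conductance network:
# pressure 1 at the inlet, 0 at the alveoli, one junction per internal
# segment's distal end; returns total resistance (Inf if no flow).
kirchhoff_resistance <- function(tree, units) {
  caps <- tree$cap_units
  blocked <- units == caps
  f <- units / caps
  g_seg <- ifelse(blocked, 0, (1 - f)^2 / tree$r0_node)
  n_int <- 2^(tree$n_levels - 1L) - 1L
  if (g_seg[1] == 0) return(Inf)
  # restrict to junctions reachable from the inlet through open segments
  # (floating subnetworks behind blocked segments carry no current and
  # would make the full system singular)
  reach <- logical(n_int)
  queue <- 1L
  reach[1L] <- TRUE
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    for (ch in c(2L * k, 2L * k + 1L)) {
      if (ch <= n_int && !reach[ch] && g_seg[ch] > 0) {
        reach[ch] <- TRUE
        queue <- c(queue, ch)
      }
    }
  }
  idx <- which(reach)
  m <- length(idx)
  pos <- integer(n_int); pos[idx] <- seq_len(m)
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (k in idx) {
    r <- pos[k]
    gk <- g_seg[k]
    A[r, r] <- A[r, r] + gk
    if (k == 1L) b[r] <- b[r] + gk else A[r, pos[k %/% 2L]] <- A[r, pos[k %/% 2L]] - gk
    for (ch in c(2L * k, 2L * k + 1L)) {
      gc <- g_seg[ch]
      A[r, r] <- A[r, r] + gc
      if (ch <= n_int && gc > 0) A[r, pos[ch]] <- A[r, pos[ch]] - gc
      # terminal children drain to pressure 0: no rhs term
    }
  }
  pressures <- solve(A, b)
  flow <- g_seg[1] * (1 - pressures[1])
  if (flow <= 0) Inf else 1 / flow
}

# memoized shared fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a reduced lung (64 voxels of 5-level subtrees) with a matching PDFE table
test_lung <- function() fixture("lung64", function() {
  lung_model(n_voxels = 64, voxel_levels = 5)
})

test_pdfe <- function() fixture("pdfe64", function() {
  build_pdfe_table(
    test_lung()$voxel_tree, fractions = seq(0, 1, by = 0.1),
    chain_settings(n_steps = 10000, thin = 10, seed = 42),
    pdfe_bins(100, 100, 6)
  )
})

fit_settings <- function(n_steps = 30000, seed = 5) {
  chain_settings(n_steps = n_steps, thin = 10, temperature = 5e-4, seed = seed)
}

# One whole-lung state drawn from the spirometry-only sampler's generative
# prior: per-voxel allocations uniform on the quantized lattice, (ratio, aa)
# pairs from the interpolated slices. Returns the implied targets and total.
draw_prior_lung <- function(lung, tab, seed, step_fraction = 0.02) {
  set.seed(seed)
  vt <- lung$voxel_tree
  cap_units <- vt$total_capacity_units
  q_units <- max(1L, as.integer(round(step_fraction * cap_units)))
  n_q_max <- cap_units %/% q_units
  n <- lung$n_voxels
  alloc <- sample(0:n_q_max, n, replace = TRUE)
  frac <- alloc * q_units / cap_units
  ratio <- numeric(n); aa <- numeric(n)
  for (v in seq_len(n)) {
    pr <- pdfe_sample_pair(interpolate_pdfe(tab, frac[v], warn = FALSE),
                           tab$bins, 1)
    ratio[v] <- pr$resistance_ratio
    aa[v] <- pr$aa_percent
  }
  p <- patient_spirometry(25, 175, "male")
  agg <- lung_spirometry(lung, ratio, aa, p)
  list(
    targets = patient_spirometry(25, 175, "male",
                                 fev1 = agg$fev1, fvc = agg$fvc),
    total_mm3 = sum(alloc) * q_units * vt$unit_volume_mm3
  )
}
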