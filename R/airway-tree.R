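# Fractal binary airway tree: geometry, node indexing, mucus configurations.
#
# Nodes are stored in breadth-first "heap" order: node 1 is the root segment,
# the children of node i are 2i and 2i+1, and level l (0-based, counted from
# g_min) occupies indices 2^l .. 2^(l+1)-1. Per-node vectors are materialized
# only for trees small enough to simulate on; the whole-lung tree (24 levels,
# ~1.7e7 segments) keeps per-generation geometry only.

.MAX_MATERIALIZED_LEVELS <- 18L

#' Construct a fractal binary airway tree
#'
#' Builds a complete symmetric binary tree of airway segments between two
#' generation bounds, in the spirit of the Weibel symmetric lung model. The
#' segment at generation `g` has diameter and length equal to the root
#' geometry scaled by `scale_factor^(g - g_min)`; with the default factor
#' `2^(-1/3)` every daughter generation preserves total cross-sectional
#' scaling a la Murray's law and the lumen volume halves per generation.
#'
#' The lumen volume of the deepest (narrowest) generation is the tree's
#' *unit volume*: the quantum in which mucus is moved by the Metropolis
#' proposals (see [mucus_config()], [propose_move()]).
#'
#' @param g_min,g_max Integer generation bounds, `0 <= g_min < g_max <= 23`.
#'   The whole lung spans 0 to 23; one imaging voxel corresponds to the
#'   subtree spanning generations 13 to 23 (10 bifurcations).
#' @param root_diameter_cm,root_length_cm Geometry of the generation-`g_min`
#'   segment, in cm. Defaults are standard tracheal values and are meant to
#'   be used with `g_min = 0`; for subtrees pass the already-scaled values
#'   or use [voxel_tree()].
#' @param scale_factor Per-generation scaling of both diameter and length,
#'   in (0, 1).
#' @param viscosity Dynamic viscosity of air in Pa s, used for per-segment
#'   Poiseuille resistances.
#' @return An object of class `airway_tree`: a list with generation-level
#'   geometry (`geometry`, a tibble), node counts, the unit volume, per-node
#'   capacity and resistance vectors for trees of at most
#'   2^18 - 1 segments, and the mucus-free tree resistance.
#' @examples
#' tr <- airway_tree(13, 23, root_diameter_cm = 0.09, root_length_cm = 0.6)
#' tr$terminal_count # 1024 alveolar-level segments
#' @export
airway_tree <- function(g_min = 0L, g_max = 23L,
                        root_diameter_cm = 1.8, root_length_cm = 12,
                        scale_factor = 2^(-1 / 3),
                        viscosity = 1.81e-5) {
  if (!rlang::is_scalar_double(as.double(g_min)) || g_min < 0 || g_min != round(g_min)) {
    rlang::abort(paste0("`g_min` must be an integer in [0, 23], got ", g_min),
                 class = "lungtrack_input_error")
  }
  if (g_max != round(g_max) || g_max > 23) {
    rlang::abort(paste0("`g_max` must be an integer in [0, 23], got ", g_max),
                 class = "lungtrack_input_error")
  }
  if (g_min >= g_max) {
    rlang::abort(
      paste0("`g_min` (", g_min, ") must be strictly below `g_max` (", g_max, ")"),
      class = "lungtrack_input_error"
    )
  }
  stopifnot(scale_factor > 0, scale_factor < 1,
            root_diameter_cm > 0, root_length_cm > 0, viscosity > 0)
  g_min <- as.integer(g_min); g_max <- as.integer(g_max)

  n_levels <- g_max - g_min + 1L
  levels <- seq_len(n_levels) - 1L
  diameter <- root_diameter_cm * scale_factor^levels
  length_cm <- root_length_cm * scale_factor^levels
  # lumen volume in mm^3: pi (d/2)^2 L with d, L in cm gives cm^3
  lumen <- pi * (diameter / 2)^2 * length_cm * 1000
  r0 <- segment_resistance(diameter, length_cm, 0, lumen, viscosity)

  unit_volume <- lumen[n_levels]
  cap_units <- as.integer(floor(lumen / unit_volume + 1e-9))

  geometry <- tibble::tibble(
    generation = g_min + levels,
    level = levels,
    n_segments = 2^levels,
    diameter_cm = diameter,
    length_cm = length_cm,
    lumen_volume_mm3 = lumen,
    capacity_units = cap_units,
    segment_resistance = r0
  )

  n_nodes <- 2^n_levels - 1
  tree <- structure(
    list(
      g_min = g_min, g_max = g_max, n_levels = n_levels,
      n_nodes = n_nodes, terminal_count = 2^(n_levels - 1L),
      geometry = geometry,
      scale_factor = scale_factor, viscosity = viscosity,
      root_diameter_cm = root_diameter_cm, root_length_cm = root_length_cm,
      unit_volume_mm3 = unit_volume,
      total_lumen_mm3 = sum(geometry$n_segments * lumen),
      total_capacity_units = sum(geometry$n_segments * cap_units),
      # symmetric mucus-free tree: level resistances halve in parallel
      resistance_empty = sum(r0 / 2^levels),
      materialized = n_levels <= .MAX_MATERIALIZED_LEVELS
    ),
    class = "airway_tree"
  )
  if (tree$materialized) {
    node_level <- rep(levels, times = 2^levels)
    tree$node_level <- node_level
    tree$cap_units <- cap_units[node_level + 1L]
    tree$r0_node <- r0[node_level + 1L]
  }
  tree
}

#' @export
print.airway_tree <- function(x, ...) {
  cat("<airway_tree> generations ", x$g_min, "..", x$g_max,
      " (", x$n_nodes, " segments, ", x$terminal_count, " terminals)\n",
      "  unit volume ", signif(x$unit_volume_mm3, 4), " mm^3, total lumen ",
      signif(x$total_lumen_mm3, 4), " mm^3\n", sep = "")
  invisible(x)
}

#' @export
tidy.airway_tree <- function(x, ...) x$geometry

#' Voxel subtree with geometry inherited from a whole-lung tree
#'
#' Convenience constructor: the subtree rooted at generation `g_min` of a
#' whole lung whose trachea has the given geometry, i.e. the root segment is
#' the tracheal geometry scaled by `scale_factor^g_min`.
#'
#' @inheritParams airway_tree
#' @param trachea_diameter_cm,trachea_length_cm Generation-0 geometry.
#' @return An [airway_tree()].
#' @export
voxel_tree <- function(g_min = 13L, g_max = 23L,
                       trachea_diameter_cm = 1.8, trachea_length_cm = 12,
                       scale_factor = 2^(-1 / 3), viscosity = 1.81e-5) {
  airway_tree(
    g_min, g_max,
    root_diameter_cm = trachea_diameter_cm * scale_factor^g_min,
    root_length_cm = trachea_length_cm * scale_factor^g_min,
    scale_factor = scale_factor, viscosity = viscosity
  )
}

.check_materialized <- function(tree) {
  if (!isTRUE(tree$materialized)) {
    rlang::abort(
      "per-node operations need a tree with at most 2^18 - 1 segments; use a reduced tree or a voxel subtree",
      class = "lungtrack_input_error"
    )
  }
}

# ---- mucus configurations ---------------------------------------------------

#' Create a mucus configuration on an airway tree
#'
#' A mucus configuration assigns each airway segment a mucus volume that is
#' an integer multiple of the tree's unit volume (the lumen volume of the
#' deepest generation), never exceeding the segment's lumen. Configurations
#' are the state of the Metropolis chains; the total volume is conserved by
#' [propose_move()].
#'
#' @param tree An [airway_tree()].
#' @param units Integer vector of per-node mucus amounts in unit volumes, in
#'   heap order (length `tree$n_nodes`), or a single number recycled.
#' @return An object of class `mucus_config`.
#' @export
mucus_config <- function(tree, units = 0L) {
  .check_materialized(tree)
  units <- as.integer(round(units))
  if (length(units) == 1L) units <- rep(units, tree$n_nodes)
  if (length(units) != tree$n_nodes) {
    rlang::abort(paste0("`units` must have length ", tree$n_nodes),
                 class = "lungtrack_input_error")
  }
  if (any(units < 0L) || any(units > tree$cap_units)) {
    rlang::abort("mucus must lie in [0, lumen capacity] for every segment",
                 class = "lungtrack_input_error")
  }
  structure(
    list(units = units,
         unit_volume_mm3 = tree$unit_volume_mm3,
         total_units = sum(units)),
    class = "mucus_config"
  )
}

#' @export
print.mucus_config <- function(x, ...) {
  cat("<mucus_config> ", x$total_units, " unit volumes (",
      signif(x$total_units * x$unit_volume_mm3, 4), " mm^3) over ",
      length(x$units), " segments\n", sep = "")
  invisible(x)
}

#' Total mucus volume of a configuration in mm^3
#' @param config A [mucus_config()].
#' @return Scalar volume in mm^3.
#' @export
mucus_volume <- function(config) config$total_units * config$unit_volume_mm3

#' Randomly fill a tree with a given amount of mucus
#'
#' Distributes a total mucus volume over the segments uniformly at random
#' (respecting lumen capacities), the "randomly filling up the voxel's airway
#' tree" initialization of the sampling chains. The volume is first rounded
#' to a whole number of unit volumes.
#'
#' @param tree An [airway_tree()].
#' @param total_mm3 Total mucus volume in mm^3 (rounded to unit volumes).
#'   Give either this or `fraction`.
#' @param fraction Alternatively, the mucus fraction of the tree's total
#'   lumen capacity, in `[0, 1]`.
#' @return A [mucus_config()].
#' @export
random_config <- function(tree, total_mm3 = NULL, fraction = NULL) {
  .check_materialized(tree)
  if (is.null(total_mm3) == is.null(fraction)) {
    rlang::abort("give exactly one of `total_mm3` or `fraction`",
                 class = "lungtrack_input_error")
  }
  v_units <- if (!is.null(fraction)) {
    stopifnot(fraction >= 0, fraction <= 1)
    as.integer(round(fraction * tree$total_capacity_units))
  } else {
    as.integer(round(total_mm3 / tree$unit_volume_mm3))
  }
  if (v_units > tree$total_capacity_units) {
    rlang::abort("requested mucus exceeds the tree's total lumen capacity",
                 class = "lungtrack_input_error")
  }
  units <- .random_fill_units(tree$cap_units, v_units)
  mucus_config(tree, units)
}

# Capped multinomial fill: allocate V units over nodes with capacities `caps`
# proportionally at random, then redistribute any overflow.
.random_fill_units <- function(caps, v_units) {
  n <- length(caps)
  units <- integer(n)
  remaining <- v_units
  free <- caps
  while (remaining > 0L) {
    idx <- free > 0L
    add <- as.integer(stats::rmultinom(1, remaining, prob = free[idx] / sum(free[idx])))
    add <- pmin(add, free[idx])
    units[idx] <- units[idx] + add
    free <- caps - units
    remaining <- v_units - sum(units)
  }
  units
}

#' Propose a unit-volume mucus move (Metropolis neighbor)
#'
#' Draws one ordered pair of distinct segments uniformly at random and, if
#' legal, moves one unit volume of mucus from the first (donor) to the second
#' (acceptor). If the drawn move is illegal (empty donor or full acceptor)
#' the proposal is a *null move* and the configuration is returned unchanged;
#' this keeps the proposal kernel exactly symmetric, so the Metropolis
#' acceptance rule needs no Hastings correction. Total mucus is conserved by
#' construction.
#'
#' @param config A [mucus_config()].
#' @param tree The [airway_tree()] the configuration lives on.
#' @return A `mucus_config` with attribute `"moved"` (`TRUE` if a unit was
#'   actually displaced) and, when moved, attributes `"donor"`/`"acceptor"`.
#'   Signals a condition of class `lungtrack_frozen` when no legal move
#'   exists anywhere (no mucus, or a saturated tree).
#' @export
propose_move <- function(config, tree) {
  units <- config$units
  caps <- tree$cap_units
  if (.is_frozen_units(units, caps)) {
    rlang::abort("frozen configuration: no legal unit-volume move exists",
                 class = "lungtrack_frozen")
  }
  n <- length(units)
  i <- sample.int(n, 1L)
  j <- sample.int(n - 1L, 1L)
  if (j >= i) j <- j + 1L
  if (units[i] >= 1L && units[j] < caps[j]) {
    units[i] <- units[i] - 1L
    units[j] <- units[j] + 1L
    config$units <- units
    attr(config, "moved") <- TRUE
    attr(config, "donor") <- i
    attr(config, "acceptor") <- j
  } else {
    attr(config, "moved") <- FALSE
  }
  config
}

.is_frozen_units <- function(units, caps) {
  donors <- which(units > 0L)
  acceptors <- which(units < caps)
  if (length(donors) == 0L || length(acceptors) == 0L) return(TRUE)
  if (length(donors) == 1L && length(acceptors) == 1L && donors == acceptors) {
    return(TRUE)
  }
  FALSE
}

# Deterministic single move, used by tests to enumerate the proposal kernel.
.move_unit <- function(config, tree, donor, acceptor) {
  units <- config$units
  if (units[donor] < 1L || units[acceptor] >= tree$cap_units[acceptor] ||
      donor == acceptor) {
    return(NULL)
  }
  units[donor] <- units[donor] - 1L
  units[acceptor] <- units[acceptor] + 1L
  config$units <- units
  config
}

#' Per-generation summary of a mucus configuration
#'
#' @param config A [mucus_config()].
#' @param tree Its [airway_tree()].
#' @return A tibble with one row per generation: total mucus volume, total
#'   lumen volume and the filled fraction.
#' @export
mucus_by_generation <- function(config, tree) {
  lev <- tree$node_level
  mucus_units <- as.numeric(rowsum(as.numeric(config$units), lev))
  tibble::tibble(
    generation = tree$geometry$generation,
    mucus_mm3 = mucus_units * tree$unit_volume_mm3,
    lumen_mm3 = tree$geometry$n_segments * tree$geometry$lumen_volume_mm3,
    fill_fraction = mucus_units * tree$unit_volume_mm3 /
      (tree$geometry$n_segments * tree$geometry$lumen_volume_mm3)
  )
}

# ---- voxel <-> subtree assignment -------------------------------------------

#' Assign imaging voxels to airway subtrees
#'
#' Deterministically maps a set of voxel coordinates (1 cm grid) onto the
#' generation-`g` subtrees of the lung by recursive bisection: the coordinate
#' bounding box is split along its longest axis into two halves whose sizes
#' match the two halves of the subtree id range, mirroring the tree's
#' bifurcations. The same input always yields the same assignment. This is a
#' reproducibility-first stand-in for anatomical (e.g. Kitaoka-style)
#' space-filling airway models.
#'
#' @param voxels A data frame with integer coordinate columns `i`, `j`, `k`.
#' @param n_subtrees Number of available subtrees (e.g. `2^13` for voxels at
#'   generation 13); must be at least `nrow(voxels)`.
#' @return The input tibble with a `subtree` id column (1-based, unique).
#' @export
assign_voxels <- function(voxels, n_subtrees) {
  voxels <- tibble::as_tibble(voxels)
  stopifnot(all(c("i", "j", "k") %in% names(voxels)))
  n <- nrow(voxels)
  if (n > n_subtrees) {
    rlang::abort(paste0("more voxels (", n, ") than subtrees (", n_subtrees, ")"),
                 class = "lungtrack_input_error")
  }
  if (anyDuplicated(voxels[c("i", "j", "k")]) > 0) {
    rlang::abort("voxel coordinates must be unique", class = "lungtrack_input_error")
  }
  ids <- integer(n)
  recurse <- function(rows, id_lo, id_hi) {
    if (length(rows) == 0L) return()
    if (length(rows) == 1L) {
      ids[rows] <<- id_lo
      return()
    }
    coords <- voxels[rows, c("i", "j", "k")]
    spans <- vapply(coords, function(x) diff(range(x)), numeric(1))
    axis <- c("i", "j", "k")[which.max(spans)]
    ord <- rows[order(voxels[[axis]][rows], voxels$i[rows], voxels$j[rows],
                      voxels$k[rows])]
    half_ids <- (id_hi - id_lo + 1L) %/% 2L
    n_left <- max(length(ord) - half_ids, length(ord) %/% 2L)
    n_left <- min(n_left, half_ids)
    recurse(ord[seq_len(n_left)], id_lo, id_lo + half_ids - 1L)
    recurse(ord[-seq_len(n_left)], id_lo + half_ids, id_hi)
  }
  recurse(seq_len(n), 1L, as.integer(n_subtrees))
  dplyr::mutate(voxels, subtree = ids)
}
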