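# Constant-temperature Metropolis-Hastings driver and the two energy
# functions used throughout: a spirometric energy (whole-lung fit) and a
# voxel energy (resistance ratio / accessible alveoli fit).

#' Settings for a Metropolis chain
#'
#' @param n_steps Total number of Metropolis steps.
#' @param burn_in Steps discarded before recording; defaults to 10% of
#'   `n_steps`.
#' @param thin Record every `thin`-th post-burn-in state.
#' @param temperature Constant sampling temperature `T` (> 0). The default
#'   0.01 makes a 1% relative spirometric mismatch cost about one `k T`
#'   under the squared-relative-error energies with unit weights.
#' @param w1,w2 Non-negative weights of the two energy terms (FEV1/FVC, or
#'   resistance/AA). Defaults are equal weights.
#' @param seed Integer seed; every stochastic operation of the chain draws
#'   from the global RNG seeded once with this value, so runs are exactly
#'   reproducible.
#' @return A list of class `chain_settings`.
#' @export
chain_settings <- function(n_steps = 10000L, burn_in = NULL, thin = 10L,
                           temperature = 0.01, w1 = 1, w2 = 1, seed = NULL) {
  if (is.null(burn_in)) burn_in <- floor(n_steps / 10)
  n_steps <- as.integer(n_steps); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (!(temperature > 0)) {
    rlang::abort("`temperature` must be > 0", class = "lungtrack_input_error")
  }
  if (!(n_steps > burn_in && burn_in >= 0L)) {
    rlang::abort("need n_steps > burn_in >= 0", class = "lungtrack_input_error")
  }
  if (thin < 1L || w1 < 0 || w2 < 0) {
    rlang::abort("need thin >= 1 and non-negative weights",
                 class = "lungtrack_input_error")
  }
  structure(list(n_steps = n_steps, burn_in = burn_in, thin = thin,
                 temperature = temperature, w1 = w1, w2 = w2, seed = seed),
            class = "chain_settings")
}

#' Spirometric state energy
#'
#' Squared relative mismatch between modeled and target spirometry,
#' `E = w1 ((fev1 - fev1*)/fev1*)^2 + w2 ((fvc - fvc*)/fvc*)^2`. Zero if and
#' only if both match exactly. Used as the soft constraint that keeps the
#' whole-lung chain near configurations with approximately correct
#' spirometric readings.
#'
#' @param fev1_model,fvc_model Modeled values, liters (vectorized).
#' @param targets A [patient_spirometry()] with measured `fev1`, `fvc`.
#' @param w1,w2 Term weights.
#' @return Non-negative energy.
#' @export
energy_spirometric <- function(fev1_model, fvc_model, targets, w1 = 1, w2 = 1) {
  if (is.na(targets$fev1) || is.na(targets$fvc) ||
      targets$fev1 <= 0 || targets$fvc <= 0) {
    rlang::abort("spirometry targets must be positive",
                 class = "lungtrack_input_error")
  }
  w1 * ((fev1_model - targets$fev1) / targets$fev1)^2 +
    w2 * ((fvc_model - targets$fvc) / targets$fvc)^2
}

#' Voxel state energy
#'
#' The same squared-relative-error form applied to a voxel's airflow
#' resistance ratio and percent accessible alveoli. Degenerate targets are
#' handled so the drill-down chain stays defined over the whole state space:
#' a zero AA target uses an absolute term on the AA fraction
#' (`(aa/100)^2`), and an infinite (blocked) resistance-ratio target uses an
#' absolute term on the conductance ratio (`(1/ratio)^2`, target 0).
#'
#' @param ratio_model,aa_model Modeled resistance ratio and AA% (vectorized).
#' @param ratio_target,aa_target Target values (ratio may be `Inf`,
#'   aa may be 0).
#' @param w1,w2 Term weights (resistance term, AA term).
#' @return Non-negative energy.
#' @export
energy_voxel <- function(ratio_model, aa_model, ratio_target, aa_target,
                         w1 = 1, w2 = 1) {
  r_term <- if (!is.finite(ratio_target)) {
    (1 / ratio_model)^2
  } else {
    ((ratio_model - ratio_target) / ratio_target)^2
  }
  r_term[!is.finite(ratio_model) & !is.finite(ratio_target)] <- 0
  r_term[!is.finite(ratio_model) & is.finite(ratio_target)] <-
    Inf
  a_term <- if (aa_target == 0) {
    (aa_model / 100)^2
  } else {
    ((aa_model - aa_target) / aa_target)^2
  }
  w1 * r_term + w2 * a_term
}

#' Metropolis acceptance rule
#'
#' Accept a proposed state with energy `e_new` when `e_new <= e_old`;
#' otherwise accept with probability `exp(-(e_new - e_old) / temperature)`,
#' using a single uniform draw (supplied via `u` for deterministic testing,
#' otherwise drawn from the RNG only when needed).
#'
#' @param e_old,e_new Energies of the current and proposed state.
#' @param temperature Sampling temperature (> 0).
#' @param u Optional uniform(0,1) draw to compare against.
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
mh_accept <- function(e_old, e_new, temperature, u = NULL) {
  if (!(temperature > 0)) {
    rlang::abort("`temperature` must be > 0", class = "lungtrack_input_error")
  }
  if (e_new <= e_old) return(TRUE)
  if (is.null(u)) u <- stats::runif(1)
  u < exp(-(e_new - e_old) / temperature)
}

#' Run a constant-temperature Metropolis chain
#'
#' Generic driver: starting from `initial_state`, repeatedly calls
#' `proposal_fn(state)` and accepts or rejects by [mh_accept()] on
#' `energy_fn(state)`. States after burn-in are recorded every `thin` steps,
#' passed through `sample_fn` (so large states can be summarized on the
#' fly). A `lungtrack_frozen` condition signaled by the proposal terminates
#' the chain gracefully with the samples collected so far.
#'
#' @param initial_state Any object accepted by `proposal_fn`/`energy_fn`.
#' @param energy_fn Function `state ->` non-negative scalar energy.
#' @param proposal_fn Function `state -> state` implementing a symmetric
#'   proposal kernel (null moves allowed).
#' @param settings A [chain_settings()]; if its `seed` is non-`NULL` the
#'   global RNG is seeded once at chain start, making the sample sequence
#'   bit-for-bit reproducible.
#' @param sample_fn Applied to each retained state before storage.
#' @return An object of class `mh_chain`: list with `samples` (list of
#'   retained `sample_fn` values), `trace` (tibble of retained step index
#'   and energy), `final_state`, `acceptance_rate`, `frozen` flag, and the
#'   settings.
#' @export
run_chain <- function(initial_state, energy_fn, proposal_fn, settings,
                      sample_fn = identity) {
  stopifnot(inherits(settings, "chain_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)

  state <- initial_state
  e <- energy_fn(state)
  if (is.na(e) || e < 0) {
    rlang::abort("energy of the initial state must be non-negative",
                 class = "lungtrack_input_error")
  }
  n_keep <- (settings$n_steps - settings$burn_in) %/% settings$thin + 1L
  samples <- vector("list", n_keep)
  kept_step <- integer(n_keep)
  kept_energy <- numeric(n_keep)
  k <- 0L
  n_acc <- 0L
  frozen <- FALSE

  for (step in seq_len(settings$n_steps)) {
    prop <- tryCatch(proposal_fn(state), lungtrack_frozen = function(cnd) cnd)
    if (inherits(prop, "condition")) {
      frozen <- TRUE
      break
    }
    e_new <- tryCatch(energy_fn(prop), error = function(cnd) {
      rlang::abort("energy evaluation failed for a proposed state",
                   parent = cnd, class = "lungtrack_energy_error")
    })
    if (mh_accept(e, e_new, settings$temperature)) {
      state <- prop
      e <- e_new
      n_acc <- n_acc + 1L
    }
    if (step > settings$burn_in &&
        (step - settings$burn_in) %% settings$thin == 0L) {
      k <- k + 1L
      samples[[k]] <- sample_fn(state)
      kept_step[k] <- step
      kept_energy[k] <- e
    }
  }

  structure(
    list(
      samples = samples[seq_len(k)],
      trace = tibble::tibble(step = kept_step[seq_len(k)],
                             energy = kept_energy[seq_len(k)]),
      final_state = state,
      final_energy = e,
      acceptance_rate = n_acc / max(step, 1L),
      n_steps_run = step,
      frozen = frozen,
      settings = settings
    ),
    class = "mh_chain"
  )
}

#' @export
print.mh_chain <- function(x, ...) {
  cat("<mh_chain> ", length(x$samples), " retained samples from ",
      x$n_steps_run, " steps (acceptance ", round(x$acceptance_rate, 3),
      if (x$frozen) ", frozen" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.mh_chain <- function(x, ...) x$trace

#' @export
glance.mh_chain <- function(x, ...) {
  tibble::tibble(
    n_retained = length(x$samples),
    n_steps = x$n_steps_run,
    acceptance_rate = x$acceptance_rate,
    min_energy = if (nrow(x$trace)) min(x$trace$energy) else NA_real_,
    final_energy = x$final_energy,
    frozen = x$frozen
  )
}
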