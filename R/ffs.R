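#' Pluggable stochastic model for Forward Flux Sampling
#'
#' A model is a discrete-time Markov process with a `step` function and an
#' integer-valued reaction coordinate `Q`. The FFS engine is model-agnostic:
#' any state representation works as long as `step` propagates it and `Q`
#' maps every reachable state to an integer.
#'
#' @param step Function `state -> state` advancing one time step (uses the
#'   R RNG stream).
#' @param Q Function `state -> integer` reaction coordinate.
#' @param init_state A state in the initial basin.
#' @return An object of class `stochastic_model`.
#' @export
stochastic_model <- function(step, Q, init_state) {
  stopifnot(is.function(step), is.function(Q))
  structure(list(step = step, Q = Q, init_state = init_state),
            class = "stochastic_model")
}

#' Interface scheme on the reaction coordinate
#'
#' Non-intersecting interfaces sit between consecutive integer values of Q.
#' The flux is measured from the initial basin (`Q <= q_min`) to the first
#' interface (`Q >= q0`); stages then advance one Q level at a time up to the
#' absorbing target `q_max`, with failure defined as return to the basin.
#'
#' @param q_min Basin Q value.
#' @param q0 First interface Q value (flux target).
#' @param q_max Target (absorbing) Q value.
#' @return An object of class `interface_scheme`.
#' @export
interface_scheme <- function(q_min, q0, q_max) {
  stopifnot(q_min < q0, q0 <= q_max)
  structure(list(q_min = as.integer(q_min), q0 = as.integer(q0),
                 q_max = as.integer(q_max),
                 stages = if (q0 < q_max) (q0 + 1L):q_max else integer(0)),
            class = "interface_scheme")
}

#' Estimate the initial flux by free dynamics
#'
#' Runs unbiased dynamics and counts successful transitions: one transition
#' is recorded each time the system first reaches `Q >= q0` after having
#' occupied the basin (`Q <= q_min`). The crossing configurations are stored
#' as starting points for the first stage. Dwell in the absorbing target
#' basin is excluded from the sampling time by construction: whenever the
#' trajectory completes a transition (`Q >= q_max`) it is reinstated in the
#' initial basin, so the flux is measured per unit reactant-side time — the
#' convention under which `flux * prod(p)` equals the inverse mean
#' first-passage time of a rare transition.
#'
#' @param model A [stochastic_model()].
#' @param scheme An [interface_scheme()].
#' @param sampling_steps Number of dynamics steps to sample.
#' @param equilibration_steps Steps discarded before sampling starts.
#' @param seed Optional RNG seed.
#' @return An object of class `flux_estimate`: list with `n_transitions`,
#'   `sampling_time` (steps counted), `flux` (transitions per step),
#'   `configs` (states at crossing), `flagged` (`TRUE` when no transition
#'   was observed).
#' @export
estimate_flux <- function(model, scheme, sampling_steps = 1e5,
                          equilibration_steps = 1e3, seed = NULL) {
  stopifnot(inherits(model, "stochastic_model"),
            inherits(scheme, "interface_scheme"))
  if (!is.null(seed)) set.seed(seed)
  state <- model$init_state
  for (i in seq_len(equilibration_steps)) state <- model$step(state)
  armed <- model$Q(state) <= scheme$q_min
  n_trans <- 0L
  t_sampled <- 0
  configs <- list()
  for (i in seq_len(sampling_steps)) {
    t_sampled <- t_sampled + 1
    state <- model$step(state)
    q_new <- model$Q(state)
    if (q_new >= scheme$q_max) {
      # completed transition: restart from the initial basin so time spent
      # in the bound/target state never enters the sampling time
      state <- model$init_state
      armed <- TRUE
      next
    }
    if (q_new <= scheme$q_min) armed <- TRUE
    if (armed && q_new >= scheme$q0) {
      n_trans <- n_trans + 1L
      configs[[n_trans]] <- state
      armed <- FALSE
    }
  }
  structure(list(n_transitions = n_trans, sampling_time = t_sampled,
                 flux = if (t_sampled > 0) n_trans / t_sampled else NA_real_,
                 configs = configs, flagged = n_trans == 0L),
            class = "flux_estimate")
}

#' Run one FFS stage
#'
#' Trials start from states drawn uniformly with replacement from the stored
#' crossing configurations of the previous interface and are propagated until
#' they either cross the next interface (`Q >= target_q`, success — the
#' crossing state is stored) or fall back to the basin (`Q <= q_min`,
#' failure).
#'
#' @param model A [stochastic_model()].
#' @param configs Stored configurations at the previous interface.
#' @param target_q Q value of the interface to reach.
#' @param scheme An [interface_scheme()] (supplies the failure interface).
#' @param n_trials Number of trials.
#' @param seed Optional RNG seed.
#' @param classify Optional function `state -> label` applied to each success
#'   state (e.g. to identify which binding site was reached in the terminal
#'   basin); labels are tabulated in the result.
#' @param max_steps Safety cap on steps per trial.
#' @return An object of class `stage_result`: list with `target_q`,
#'   `n_trials`, `n_successes`, `p` (success probability), `se` (binomial),
#'   `configs` (success states), optional `labels` table.
#' @export
run_stage <- function(model, configs, target_q, scheme, n_trials = 1000L,
                      seed = NULL, classify = NULL, max_steps = 1e6) {
  stopifnot(inherits(model, "stochastic_model"),
            inherits(scheme, "interface_scheme"))
  if (length(configs) == 0L) stop("no stored configurations to start from")
  if (!is.null(seed)) set.seed(seed)
  succ <- list()
  labels <- character(0)
  n_s <- 0L
  for (tr in seq_len(n_trials)) {
    state <- configs[[sample.int(length(configs), 1L)]]
    if (model$Q(state) >= target_q) {       # already beyond: trivial success
      n_s <- n_s + 1L
      succ[[n_s]] <- state
      if (!is.null(classify)) labels <- c(labels, classify(state))
      next
    }
    for (st in seq_len(max_steps)) {
      state <- model$step(state)
      q <- model$Q(state)
      if (q >= target_q) {
        n_s <- n_s + 1L
        succ[[n_s]] <- state
        if (!is.null(classify)) labels <- c(labels, classify(state))
        break
      }
      if (q <= scheme$q_min) break
    }
  }
  p <- n_s / n_trials
  structure(list(target_q = target_q, n_trials = n_trials, n_successes = n_s,
                 p = p, se = sqrt(p * (1 - p) / n_trials), configs = succ,
                 labels = if (is.null(classify)) NULL else table(labels)),
            class = "stage_result")
}

#' Assemble the FFS rate estimate
#'
#' The transition rate is the initial flux times the product of the
#' conditional interface-crossing probabilities,
#' `r = flux * prod_i p(i | i-1)`. The relative uncertainty combines the
#' per-stage binomial errors in quadrature.
#'
#' @param flux A [estimate_flux()] result.
#' @param stages List of [run_stage()] results, in interface order.
#' @return An object of class `rate_estimate`: list with `rate`, `flux`,
#'   `stage_p`, `stage_se`, `rel_se`, `flagged`.
#' @export
ffs_rate <- function(flux, stages) {
  stopifnot(inherits(flux, "flux_estimate"))
  p <- vapply(stages, function(s) s$p, numeric(1))
  se <- vapply(stages, function(s) s$se, numeric(1))
  rate <- flux$flux * prod(p)
  rel <- if (all(p > 0) && flux$n_transitions > 0)
    sqrt(sum((se / p)^2) + 1 / flux$n_transitions) else NA_real_
  structure(list(rate = if (flux$flagged) NA_real_ else rate,
                 flux = flux$flux, stage_p = p, stage_se = se,
                 rel_se = rel,
                 flagged = flux$flagged || any(p == 0)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> rate = %.4g /step (flux %.4g, stages: %s)\n",
              x$rate, x$flux, paste(sprintf("%.3f", x$stage_p), collapse = " ")))
  invisible(x)
}

#' Full Direct FFS pipeline
#'
#' Chains [estimate_flux()] and [run_stage()] over all interfaces of the
#' scheme and returns the [ffs_rate()] together with the per-stage records,
#' as a JSON-serializable run record.
#'
#' @inheritParams estimate_flux
#' @param n_trials Trials per stage.
#' @param classify Optional terminal-state classifier applied at the last
#'   stage only.
#' @return List with `rate` (a `rate_estimate`), `flux`, `stages`, `scheme`,
#'   `seed`.
#' @export
run_ffs <- function(model, scheme, sampling_steps = 1e5,
                    equilibration_steps = 1e3, n_trials = 1000L, seed = NULL,
                    classify = NULL) {
  if (!is.null(seed)) set.seed(seed)
  flux <- estimate_flux(model, scheme, sampling_steps, equilibration_steps)
  stages <- list()
  configs <- flux$configs
  if (!flux$flagged) {
    for (tq in scheme$stages) {
      last <- tq == scheme$q_max
      st <- run_stage(model, configs, tq, scheme, n_trials,
                      classify = if (last) classify else NULL)
      stages[[length(stages) + 1L]] <- st
      if (st$n_successes == 0L) break
      configs <- st$configs
    }
  }
  list(rate = ffs_rate(flux, stages), flux = flux, stages = stages,
       scheme = scheme, seed = seed)
}

#' Write an FFS run record as JSON
#'
#' @param run A [run_ffs()] result.
#' @param path Output path.
#' @export
write_ffs_json <- function(run, path) {
  rec <- list(
    scheme = unclass(run$scheme),
    seed = run$seed,
    flux = list(n_transitions = run$flux$n_transitions,
                sampling_time = run$flux$sampling_time,
                flux = run$flux$flux),
    stages = lapply(run$stages, function(s)
      list(target_q = s$target_q, n_trials = s$n_trials,
           n_successes = s$n_successes, p = s$p)),
    rate = run$rate$rate, rel_se = run$rate$rel_se)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Toy birth-death chain with Metropolis dynamics
#'
#' A 1D chain on states `1..n_states` with an energy profile (in kT):
#' proposals move +/-1 with equal probability (rejected at the ends) and are
#' accepted with the Metropolis rule, so the chain satisfies detailed balance
#' with respect to `exp(-energy)`. Serves as an exactly solvable stand-in
#' for a molecular system with a rare barrier crossing.
#'
#' @param energy Numeric vector of state energies in kT.
#' @param Q Optional reaction-coordinate function (default: identity on the
#'   state index).
#' @return A [stochastic_model()] whose state is the integer position, with
#'   the transition matrix in attribute `transition_matrix`.
#' @export
bd_model <- function(energy, Q = NULL) {
  n <- length(energy)
  stopifnot(n >= 3)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) P[i, i - 1] <- 0.5 * min(1, exp(energy[i] - energy[i - 1]))
    if (i < n) P[i, i + 1] <- 0.5 * min(1, exp(energy[i] - energy[i + 1]))
    P[i, i] <- 1 - sum(P[i, ])
  }
  step <- function(state) {
    prop <- state + (if (stats::runif(1) < 0.5) -1L else 1L)
    if (prop < 1L || prop > n) return(state)
    if (stats::runif(1) < min(1, exp(energy[state] - energy[prop]))) prop
    else state
  }
  Qf <- if (is.null(Q)) function(state) state else Q
  m <- stochastic_model(step, Qf, init_state = which.min(energy[1:max(1, n %/% 2)]))
  attr(m, "transition_matrix") <- P
  attr(m, "energy") <- energy
  m
}

#' Exact rate of a birth-death chain from mean first passage
#'
#' Solves the linear system for the mean first-passage time (MFPT) from
#' `start` to the absorbing `target` and returns `1 / MFPT`, the exact rate
#' the FFS estimate is validated against.
#'
#' @param model A [bd_model()].
#' @param start Starting state.
#' @param target Absorbing state.
#' @return List with `rate`, `mfpt`.
#' @export
exact_rate_bd <- function(model, start, target) {
  P <- attr(model, "transition_matrix")
  stopifnot(!is.null(P))
  n <- nrow(P)
  keep <- setdiff(seq_len(n), target)
  A <- diag(length(keep)) - P[keep, keep, drop = FALSE]
  tau <- solve(A, rep(1, length(keep)))
  mfpt <- tau[match(start, keep)]
  list(rate = 1 / mfpt, mfpt = mfpt)
}

#' Exact committor of a birth-death chain
#'
#' Probability of reaching state `b` before state `a`, for every state, by
#' linear solve on the transition matrix — the oracle for per-stage crossing
#' probabilities.
#'
#' @param model A [bd_model()].
#' @param a Failure (basin) state.
#' @param b Success state.
#' @return Numeric vector of committor values, one per state.
#' @export
committor_bd <- function(model, a, b) {
  P <- attr(model, "transition_matrix")
  n <- nrow(P)
  q <- rep(NA_real_, n)
  inner <- setdiff(seq_len(n), c(a, b))
  A <- diag(length(inner)) - P[inner, inner, drop = FALSE]
  rhs <- P[inner, b, drop = FALSE]
  q[inner] <- solve(A, rhs)
  q[a] <- 0; q[b] <- 1
  q
}
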