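#' Neuronal gain function
#'
#' Rate gain applied to the membrane potential of every pyramidal cell and
#' interneuron: zero for non-positive potentials, otherwise
#' `min(1, sinh(x) * h + 0.008)`. The `min` clamps activations at 1; the
#' small 0.008 offset keeps a just-supra-threshold neuron faintly active.
#'
#' @param x membrane potential(s).
#' @param h gain slope.
#' @return activations in `[0, 1]`, same shape as `x`.
#' @export
gain <- function(x, h) {
  a <- pmin(1, sinh(x) * h + 0.008)
  a[x <= 0] <- 0
  a
}

#' Fresh network state
#'
#' All membrane potentials start at zero (so all activations are zero, the
#' Subiculum is silent, and dopamine is on). The state also carries the
#' per-neuron exponential moving average of activation used by the
#' stable-activation gate, the input synaptic-flux accumulator that drives
#' the activity-dependent noise, and the cached sensory drive.
#'
#' @param params a [ca1_params()] record.
#' @return an object of class `ca1_state`.
#' @export
new_network_state <- function(params) {
  P <- params$pyr_rows * params$pyr_cols
  I <- params$int_rows * params$int_cols
  s <- list(
    u_p = numeric(P), a_p = numeric(P),
    u_i = numeric(I), a_i = numeric(I),
    a_s = integer(P), a_ap = 0L, da = 1L,
    ema_a = numeric(P),
    flux = numeric(P),          # |d(syn potential)/dt| summed per neuron
    flux_pending = numeric(P),  # contribution of weight updates, next step
    a_inp = numeric(P),         # current input activations
    si = numeric(P),            # cached sensory drive w_inp %*% a_inp
    age = 0L                    # total pyramidal steps taken
  )
  class(s) <- "ca1_state"
  s
}

#' Per-neuron input synaptic flux
#'
#' The noise term of the membrane equation scales with the summed absolute
#' change, over one step, of a neuron's excitatory input synaptic
#' potentials (each potential being `w * a_pre`). Given the per-synapse
#' potentials at two consecutive steps this returns that sum per
#' post-synaptic neuron; noise therefore vanishes once the sensory drive
#' stabilises.
#'
#' @param syn_now,syn_prev per-synapse potentials: either matrices
#'   (rows = post-synaptic neurons) or vectors (one neuron).
#' @return flux per post-synaptic neuron (vector, or scalar for vector
#'   input).
#' @export
compute_flux <- function(syn_now, syn_prev) {
  stopifnot(length(syn_now) == length(syn_prev))
  if (is.matrix(syn_now)) rowSums(abs(syn_now - syn_prev))
  else sum(abs(syn_now - syn_prev))
}

#' One Euler step of the pyramidal layer
#'
#' Integrates `tau * du = -u + SI + LE + LI + Noise` with forward Euler:
#' sensory input `SI = w_inp %*% a_inp`, lateral excitation
#' `LE = w_pp %*% a_p`, lateral inhibition `LI = w_ip %*% a_i` (with
#' `w_ip <= 0`), and `Noise = lambda * runif * flux` per neuron. The flux
#' is updated from the change of input synaptic potentials (stimulus
#' switches and any weight updates registered in `flux_pending`), then
#' activations are refreshed through [gain()] and the moving average used
#' by the stable-activation gate is advanced.
#'
#' @param state a `ca1_state`.
#' @param weights a `ca1_weights`.
#' @param input_act input-layer activations (length = pyramidal count).
#' @param params a [ca1_params()].
#' @return the updated state.
#' @export
step_pyramidal <- function(state, weights, input_act, params) {
  if (length(input_act) != ncol(weights$w_inp)) {
    stop("stimulus length does not match the input layer size",
         call. = FALSE)
  }
  flux_now <- state$flux_pending
  if (!identical(input_act, state$a_inp)) {
    # w_inp is non-negative, so |delta(w * a)| = w * |delta a| per synapse
    flux_now <- flux_now +
      as.vector(weights$w_inp %*% abs(input_act - state$a_inp))
    state$si <- as.vector(weights$w_inp %*% input_act)
    state$a_inp <- input_act
  }
  P <- length(state$u_p)
  noise <- if (params$lambda_noise > 0) {
    params$lambda_noise * stats::runif(P) * flux_now
  } else 0
  drive <- state$si +
    as.vector(weights$w_pp %*% state$a_p) +
    as.vector(weights$w_ip %*% state$a_i) +
    noise
  state$u_p <- state$u_p + (params$dt / params$tau) * (-state$u_p + drive)
  state$a_p <- gain(state$u_p, params$h)
  alpha <- 1 / (params$delta1 * params$tau)
  state$ema_a <- state$ema_a + alpha * (state$a_p - state$ema_a)
  state$flux <- flux_now
  state$flux_pending <- numeric(P)
  state$age <- state$age + 1L
  state
}

#' One Euler step of the interneuron layer
#'
#' Interneurons integrate the excitatory drive from the pyramidal layer
#' with a 1.5 times slower time constant:
#' `1.5 * tau * du = -u + w_pi %*% a_p`.
#'
#' @inheritParams step_pyramidal
#' @return the updated state.
#' @export
step_interneuron <- function(state, weights, params) {
  drive <- as.vector(weights$w_pi %*% state$a_p)
  state$u_i <- state$u_i +
    (params$dt / (1.5 * params$tau)) * (-state$u_i + drive)
  state$a_i <- gain(state$u_i, params$h)
  state
}

#' Novelty-detection circuit
#'
#' Pure threshold chain from pyramidal activations to phasic dopamine:
#' a Subiculum neuron fires iff its pyramidal counterpart reaches the
#' familiarity threshold; the Accumbens/Pallidum unit fires iff any
#' Subiculum neuron fires; the VTA dopamine unit fires iff the
#' Accumbens/Pallidum unit is silent. Dopamine is therefore on exactly
#' while no pyramidal neuron signals familiarity.
#'
#' @param a_p pyramidal activations in `[0, 1]`.
#' @param theta_plus Subiculum threshold.
#' @return a list with binary `a_s` (per neuron), `a_ap` and `da`.
#' @export
novelty_circuit <- function(a_p, theta_plus) {
  a_s <- as.integer(a_p >= theta_plus)
  a_ap <- as.integer(sum(a_s) > 0)
  list(a_s = a_s, a_ap = a_ap, da = as.integer(a_ap == 0))
}

apply_novelty <- function(state, params) {
  nov <- novelty_circuit(state$a_p, params$theta_plus)
  state$a_s <- nov$a_s
  state$a_ap <- nov$a_ap
  state$da <- nov$da
  state
}

# dopamine actually seen by the plasticity rules, after lesions
effective_da <- function(state, params) {
  if (params$lesion_no_learning) return(0L)
  if (params$lesion_no_da_modulation) return(1L)
  state$da
}

#' Settle the network on a stimulus
#'
#' Iterates pyramidal and interneuron steps (weights frozen) until the
#' largest per-step change of pyramidal activation falls below
#' `settle_eps`, or `t_settle_max` steps have elapsed. The state is not
#' reset beforehand: residual activity from previous stimuli carries over,
#' as in the animal.
#'
#' @inheritParams step_pyramidal
#' @param stimulus input activations.
#' @param trace_file optional CSV path; one row per step (`step`,
#'   `peak_activation`, `da`) is appended for offline inspection.
#' @return a list with the updated `state` and a `report` (class
#'   `settle_report`) holding `peak_neuron`, `peak_activation`, `da`,
#'   `steps` and `converged`. The peak neuron is the most active cell;
#'   because the gain clamps rates at 1, ties among saturated cells are
#'   resolved by the membrane potential (the latent activity), and any
#'   remaining exact tie takes the lowest row-major index.
#' @export
settle <- function(state, weights, stimulus, params, trace_file = NULL) {
  steps <- 0L
  converged <- FALSE
  trace <- if (is.null(trace_file)) NULL else vector("list", 64L)
  while (steps < params$t_settle_max) {
    prev <- state$a_p
    state <- step_pyramidal(state, weights, stimulus, params)
    state <- step_interneuron(state, weights, params)
    state <- apply_novelty(state, params)
    steps <- steps + 1L
    if (!is.null(trace)) {
      trace[[steps]] <- c(steps, max(state$a_p), state$da)
    }
    if (max(abs(state$a_p - prev)) < params$settle_eps) {
      converged <- TRUE
      break
    }
  }
  if (!is.null(trace_file)) {
    df <- as.data.frame(do.call(rbind, trace[seq_len(steps)]))
    names(df) <- c("step", "peak_activation", "da")
    data.table::fwrite(df, trace_file, append = file.exists(trace_file))
  }
  report <- list(
    # rates clamp at 1; the membrane potential breaks ties among
    # saturated cells (gain is strictly increasing below the clamp)
    peak_neuron = which.max(state$u_p),
    peak_activation = max(state$a_p),
    da = state$da,
    steps = steps,
    converged = converged
  )
  class(report) <- "settle_report"
  list(state = state, report = report)
}

#' @export
print.settle_report <- function(x, ...) {
  cat(sprintf(
    "<settle_report> peak neuron %d (a = %.3f), DA = %d, %d steps%s\n",
    x$peak_neuron, x$peak_activation, x$da, x$steps,
    if (x$converged) "" else " (truncated)"))
  invisible(x)
}

#' Serialize a settle report to a JSON line
#'
#' @param report a `settle_report`.
#' @return a single-line JSON string.
#' @export
settle_report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}
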