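#' Plasticity gates
#'
#' Three per-neuron boolean gates condition every weight update:
#'
#' * `gate_LT()` — learning threshold: the post-synaptic activation must be
#'   strictly above `theta_minus`, so weights are never updated from
#'   noise-level activity.
#' * `gate_SA()` — stable activation: the activation must exceed its
#'   exponential moving average (effective window `delta1 * tau` steps) by
#'   more than `delta2`, and the input synaptic flux must be below
#'   `sa_flux_max`. Learning therefore happens only once the sensory drive
#'   has stabilised, while the neuron's activation still stands above its
#'   recent history -- not during the onset transient, and not on residual,
#'   decaying activity from a previous image. With fewer than
#'   `delta1 * tau` steps of history the gate is closed (treated as
#'   transient).
#' * `gate_ELL()` — excitatory learning level (inhibitory rule only): the
#'   mean absolute mismatch between a neuron's input weights and the
#'   current stimulus must be strictly above `ell_min`; as the excitatory
#'   synapses converge on the stimulus this gate closes and inhibitory
#'   plasticity stops.
#'
#' All boundary comparisons are strict.
#'
#' @param a_post post-synaptic activation(s) in `[0, 1]`.
#' @param theta_minus learning threshold.
#' @return logical vector(s), `TRUE` where learning is permitted.
#' @export
gate_LT <- function(a_post, theta_minus) {
  a_post > theta_minus
}

#' @rdname gate_LT
#' @param ema exponential moving average of the activation(s).
#' @param flux input synaptic flux per neuron.
#' @param params a [ca1_params()].
#' @param age number of steps of history accumulated (gate closed below
#'   `delta1 * tau`).
#' @export
gate_SA <- function(a_post, ema, flux, params, age = Inf) {
  if (age < params$delta1 * params$tau) {
    return(rep(FALSE, length(a_post)))
  }
  dev <- a_post - ema
  if (params$sa_mode == "absolute") dev <- abs(dev)
  (dev > params$delta2) & (flux < params$sa_flux_max)
}

#' @rdname gate_LT
#' @param w_inp input-weight matrix (rows = neurons) or a single neuron's
#'   weight vector.
#' @param a_inp input activations.
#' @param ell_min mismatch threshold.
#' @export
gate_ELL <- function(w_inp, a_inp, ell_min = 0.004) {
  if (is.matrix(w_inp)) {
    dev <- rowMeans(abs(sweep(w_inp, 2, a_inp, "-")))
  } else {
    dev <- mean(abs(a_inp - w_inp))
  }
  dev > ell_min
}

#' Dopamine-gated excitatory weight update
#'
#' Oja-like Hebbian factor gated by dopamine and by the learning-threshold
#' and stable-activation gates: per synapse
#' `dw = lr_exc * DA * a_post * (a_pre - w)`, applied only on rows where
#' both gates hold. The `(a_pre - w)` term makes the stimulus itself the
#' fixed point of the update, bounding growth without any renormalisation.
#'
#' @param w_inp input-weight matrix (rows = post-synaptic neurons).
#' @param a_inp input activations.
#' @param a_p pyramidal activations.
#' @param da binary dopamine signal.
#' @param gates logical per-neuron vector (`LT & SA`).
#' @param lr_exc learning-step scale.
#' @return the weight-delta matrix (zero outside gated rows).
#' @export
update_excitatory <- function(w_inp, a_inp, a_p, da, gates, lr_exc = 0.05) {
  delta <- matrix(0, nrow(w_inp), ncol(w_inp))
  if (da == 0) return(delta)
  rows <- which(gates)
  if (length(rows) == 0) return(delta)
  target <- matrix(a_inp, length(rows), length(a_inp), byrow = TRUE)
  delta[rows, ] <- lr_exc * a_p[rows] *
    (target - w_inp[rows, , drop = FALSE])
  delta
}

#' Homeostatic inhibitory weight update
#'
#' In the presence of dopamine, the inhibitory weights converging on a
#' learning pyramidal neuron are driven more negative in proportion to its
#' activation: per synapse
#' `dw = -(L / tau) * DA * a_post * (a_pre_I + 0.3 * w)`, applied on rows
#' where `LT & SA & ELL` hold. Since `w <= 0`, the update relaxes each
#' weight toward the equilibrium `-a_pre_I / 0.3`: the more active the
#' surrounding interneurons, the stronger the inhibition a winning neuron
#' accrues, handicapping it in future competitions.
#'
#' @param w_ip inhibitory weight matrix (non-positive; rows = pyramidal
#'   neurons, columns = interneurons).
#' @param a_i interneuron activations.
#' @param a_p pyramidal activations.
#' @param da binary dopamine signal.
#' @param gates logical per-neuron vector (`LT & SA & ELL`).
#' @param params a [ca1_params()] (uses `L` and `tau`).
#' @return the weight-delta matrix (zero outside gated rows).
#' @export
update_inhibitory <- function(w_ip, a_i, a_p, da, gates, params) {
  delta <- matrix(0, nrow(w_ip), ncol(w_ip))
  if (da == 0 || params$lesion_no_inhibitory_plasticity) return(delta)
  rows <- which(gates)
  if (length(rows) == 0) return(delta)
  ai <- matrix(a_i, length(rows), length(a_i), byrow = TRUE)
  delta[rows, ] <- -(params$L / params$tau) * a_p[rows] *
    (ai + 0.3 * w_ip[rows, , drop = FALSE])
  delta
}

new_trace <- function(P) {
  list(
    labels = rep(NA_character_, P),
    update_mass = numeric(P),
    label_mass = list(),   # per-label cumulative |dw| per neuron
    episode_log = list()
  )
}

#' Observe and learn one image
#'
#' The per-image learning episode: the network first settles on the
#' stimulus (dynamics only), then runs joint dynamics + plasticity steps
#' until dopamine switches off (the stimulus has become familiar) or the
#' forced-advance budget `t_max_episode` expires. Every neuron whose input
#' weights receive a non-zero update is labelled with the image's task id
#' (last write wins, with per-label update mass retained). The network
#' state is never reset between images.
#'
#' Lesions: with `lesion_no_da_modulation` dopamine is pinned to 1, so the
#' episode always runs the full budget; with `lesion_no_learning` dopamine
#' is pinned to 0 and no plasticity occurs;
#' `lesion_no_inhibitory_plasticity` freezes only the inhibitory rule.
#'
#' @param model a [ca1_model()].
#' @param stimulus input activations (length = input-layer size), or an
#'   `image_stimulus`.
#' @param task_id label assigned to updated neurons.
#' @param image_id identifier recorded in the episode log.
#' @return a list with the updated `model` and an `episode` record
#'   (`learned`, `steps`, `updated_neurons`, `da_onset`, `da_end`,
#'   `counted`).
#' @export
learn_image <- function(model, stimulus, task_id, image_id = NA_character_) {
  if (inherits(stimulus, "image_stimulus")) {
    if (is.na(image_id)) image_id <- stimulus$id
    if (missing(task_id)) task_id <- stimulus$task_id
    stimulus <- stimulus$values
  }
  params <- model$params
  state <- model$state
  weights <- model$weights
  trace <- model$trace

  res <- settle(state, weights, stimulus, params)
  state <- res$state
  da_onset <- effective_da(state, params)

  updated <- logical(length(state$a_p))
  steps <- 0L
  eda <- da_onset
  task_key <- as.character(task_id)
  while (eda == 1L && steps < params$t_max_episode) {
    state <- step_pyramidal(state, weights, stimulus, params)
    state <- step_interneuron(state, weights, params)
    state <- apply_novelty(state, params)
    steps <- steps + 1L
    eda <- effective_da(state, params)
    if (eda == 0L) break
    gates <- gate_LT(state$a_p, params$theta_minus) &
      gate_SA(state$a_p, state$ema_a, state$flux, params, state$age)
    rows <- which(gates)
    if (length(rows) > 0) {
      wr <- weights$w_inp[rows, , drop = FALSE]
      if (!params$lesion_no_inhibitory_plasticity) {
        # ELL uses the pre-update excitatory weights
        ell <- gate_ELL(wr, stimulus, params$ell_min)
        rows_i <- rows[ell]
        if (length(rows_i) > 0) {
          wi <- weights$w_ip[rows_i, , drop = FALSE]
          ai <- matrix(state$a_i, length(rows_i), length(state$a_i),
                       byrow = TRUE)
          dwi <- -(params$L / params$tau) * state$a_p[rows_i] *
            (ai + 0.3 * wi)
          weights$w_ip[rows_i, ] <- wi + dwi
        }
      }
      target <- matrix(stimulus, length(rows), length(stimulus),
                       byrow = TRUE)
      dw <- params$lr_exc * state$a_p[rows] * (target - wr)
      weights$w_inp[rows, ] <- wr + dw
      state$si[rows] <- as.vector(weights$w_inp[rows, , drop = FALSE]
                                  %*% stimulus)
      state$flux_pending[rows] <- state$flux_pending[rows] +
        as.vector(abs(dw) %*% stimulus)
      mass <- rowSums(abs(dw))
      nz <- rows[mass > 0]
      if (length(nz) > 0) {
        trace$labels[nz] <- task_key
        trace$update_mass[nz] <- trace$update_mass[nz] + mass[mass > 0]
        if (is.null(trace$label_mass[[task_key]])) {
          trace$label_mass[[task_key]] <- numeric(length(state$a_p))
        }
        trace$label_mass[[task_key]][nz] <-
          trace$label_mass[[task_key]][nz] + mass[mass > 0]
        updated[nz] <- TRUE
      }
    }
  }

  episode <- list(
    image_id = image_id,
    task_id = task_id,
    learned = eda == 0L,
    steps = steps,
    updated_neurons = sum(updated),
    da_onset = da_onset,
    da_end = state$da,
    counted = da_onset == 1L || any(updated)
  )
  trace$episode_log[[length(trace$episode_log) + 1L]] <- episode

  model$state <- state
  model$weights <- weights
  model$trace <- trace
  list(model = model, episode = episode)
}

#' Append an episode record to a JSON-lines log
#'
#' @param episode an episode record from [learn_image()].
#' @param path log file (appended to).
#' @param lesions optional named lesion flags to record.
#' @return `path`, invisibly.
#' @export
log_episode <- function(episode, path, lesions = NULL) {
  rec <- episode
  if (!is.null(lesions)) rec$lesions <- lesions
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}
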