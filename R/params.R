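#' Model parameters
#'
#' Builds the full, validated parameter record of the CA1 continual-learning
#' model: layer geometry, connectivity-kernel decays, rate-dynamics constants,
#' plasticity constants and lesion switches. Every value can be overridden;
#' the defaults define the reference model (40x40 pyramidal grid, 13x13
#' interneuron grid, i.e. the ~9:1 pyramidal:interneuron ratio of CA1).
#'
#' Units: distances are measured in pyramidal-grid units (the spacing between
#' two neighbouring pyramidal neurons); time constants are expressed in
#' integration steps (forward Euler with step `dt`).
#'
#' @param pyr_rows,pyr_cols pyramidal (and input) grid dimensions.
#' @param int_rows,int_cols interneuron grid dimensions.
#' @param s1_pp Gaussian decay of the pyramidal-to-pyramidal kernel
#'   (narrow local excitation).
#' @param s1_pi Gaussian decay of the pyramidal-to-interneuron kernel.
#'   Deliberately wide by default: interneurons pool the activity of a
#'   large neighbourhood, providing the excitation-inhibition balance
#'   that gives the map its competitive contrast.
#' @param s1_ip,s2_ip decays of the Mexican-hat interneuron-to-pyramidal
#'   kernel; must satisfy `s1_ip < s2_ip` so the difference of Gaussians is
#'   non-negative with a ring maximum.
#' @param tau membrane time constant of pyramidal cells, in steps
#'   (interneurons use `1.5 * tau`).
#' @param dt Euler integration step.
#' @param h slope of the `min(1, sinh(x) * h + 0.008)` gain function.
#' @param lambda_noise noise level; per-step noise is
#'   `lambda_noise * runif(1) * flux` per neuron, where flux is the summed
#'   absolute change of that neuron's input synaptic potentials, so noise
#'   vanishes once the sensory drive stabilises.
#' @param theta_plus Subiculum familiarity threshold on pyramidal activation.
#' @param settle_eps per-step activation-change tolerance declaring the
#'   network settled.
#' @param t_settle_max maximum settling steps (defaults to `15 * tau`).
#' @param theta_minus learning threshold: plasticity needs activation
#'   strictly above it.
#' @param delta1 moving-average window factor; the stable-activation gate
#'   compares activation against an exponential moving average with
#'   effective window `delta1 * tau` steps.
#' @param delta2 deviation threshold of the stable-activation gate.
#' @param sa_flux_max input-flux ceiling of the stable-activation gate.
#' @param ell_min mean absolute input-weight mismatch above which inhibitory
#'   plasticity stays enabled (excitatory-learning-level gate).
#' @param L inhibitory learning constant (per-step rate is `L / tau`).
#' @param lr_exc excitatory learning-step scale applied to the Oja-like
#'   update.
#' @param sa_mode `"signed"` compares `activation - moving average` against
#'   `delta2` (learning only while activation rises above its recent
#'   history); `"absolute"` uses the absolute deviation.
#' @param t_max_episode forced-advance budget: maximum plasticity-active
#'   steps spent on one image before moving on.
#' @param max_epochs lifelong-protocol safety cap on epochs.
#' @param max_passes lifelong-protocol cap on corridor traversals within one
#'   epoch (relevant under lesions that never silence novelty).
#' @param lesion_no_da_modulation pin dopamine to 1: novelty never stops
#'   learning.
#' @param lesion_no_inhibitory_plasticity disable the homeostatic inhibitory
#'   rule.
#' @param lesion_no_learning pin dopamine to 0: no plasticity at all.
#'
#' @return an object of class `ca1_params` (a validated named list).
#' @seealso [ca1_lesions()] for the named lesion conditions,
#'   [ca1_model()] to instantiate a model.
#' @export
ca1_params <- function(pyr_rows = 40L, pyr_cols = 40L,
                       int_rows = 13L, int_cols = 13L,
                       s1_pp = 0.5, s1_pi = 0.02,
                       s1_ip = 0.05, s2_ip = 0.5,
                       tau = 10, dt = 1, h = 0.15,
                       lambda_noise = 0.1,
                       theta_plus = 0.9,
                       settle_eps = 1e-4,
                       t_settle_max = NULL,
                       theta_minus = 0.1,
                       delta1 = 5, delta2 = 0.001,
                       sa_flux_max = 0.012,
                       ell_min = 0.004,
                       L = 0.1,
                       lr_exc = 0.1,
                       sa_mode = c("signed", "absolute"),
                       t_max_episode = 300L,
                       max_epochs = 20L,
                       max_passes = 5L,
                       lesion_no_da_modulation = FALSE,
                       lesion_no_inhibitory_plasticity = FALSE,
                       lesion_no_learning = FALSE) {
  sa_mode <- match.arg(sa_mode)
  if (is.null(t_settle_max)) t_settle_max <- ceiling(15 * tau)
  p <- list(
    pyr_rows = as.integer(pyr_rows), pyr_cols = as.integer(pyr_cols),
    int_rows = as.integer(int_rows), int_cols = as.integer(int_cols),
    s1_pp = s1_pp, s1_pi = s1_pi, s1_ip = s1_ip, s2_ip = s2_ip,
    tau = tau, dt = dt, h = h,
    lambda_noise = lambda_noise,
    theta_plus = theta_plus,
    settle_eps = settle_eps,
    t_settle_max = as.integer(t_settle_max),
    theta_minus = theta_minus,
    delta1 = delta1, delta2 = delta2,
    sa_flux_max = sa_flux_max,
    ell_min = ell_min,
    L = L, lr_exc = lr_exc,
    sa_mode = sa_mode,
    t_max_episode = as.integer(t_max_episode),
    max_epochs = as.integer(max_epochs),
    max_passes = as.integer(max_passes),
    lesion_no_da_modulation = isTRUE(lesion_no_da_modulation),
    lesion_no_inhibitory_plasticity = isTRUE(lesion_no_inhibitory_plasticity),
    lesion_no_learning = isTRUE(lesion_no_learning)
  )
  class(p) <- "ca1_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    p$pyr_rows >= 1, p$pyr_cols >= 1, p$int_rows >= 1, p$int_cols >= 1,
    p$s1_pp > 0, p$s1_pi > 0, p$s1_ip > 0, p$s2_ip > 0,
    p$tau > 0, p$dt > 0, p$h > 0,
    p$lambda_noise >= 0,
    p$theta_plus > 0, p$theta_plus <= 1,
    p$settle_eps > 0,
    p$t_settle_max >= 1,
    p$theta_minus > 0, p$delta1 > 0, p$delta2 > 0,
    p$sa_flux_max > 0, p$ell_min > 0,
    p$L > 0, p$lr_exc > 0,
    p$t_max_episode >= 1, p$max_epochs >= 1, p$max_passes >= 1
  )
  if (p$s1_ip >= p$s2_ip) {
    stop("Mexican-hat kernel requires s1_ip < s2_ip ",
         "(otherwise the difference of Gaussians is non-positive)",
         call. = FALSE)
  }
  invisible(p)
}

#' Named lesion conditions
#'
#' Translates the experimental lesion conditions into parameter overrides:
#' `"none"` (intact), `"no-da"` (dopamine pinned on, novelty never stops
#' learning), `"no-inh"` (no homeostatic inhibitory plasticity), `"both"`
#' (the double lesion), `"no-learning"` (dopamine pinned off, all plasticity
#' frozen).
#'
#' @param condition one of `"none"`, `"no-da"`, `"no-inh"`, `"both"`,
#'   `"no-learning"`.
#' @return a named list of the three lesion flags.
#' @export
ca1_lesions <- function(condition = c("none", "no-da", "no-inh", "both",
                                      "no-learning")) {
  condition <- match.arg(condition)
  list(
    lesion_no_da_modulation = condition %in% c("no-da", "both"),
    lesion_no_inhibitory_plasticity = condition %in% c("no-inh", "both"),
    lesion_no_learning = condition == "no-learning"
  )
}

#' @export
print.ca1_params <- function(x, ...) {
  cat("<ca1_params>\n")
  cat(sprintf("  pyramidal grid : %d x %d (%d neurons)\n",
              x$pyr_rows, x$pyr_cols, x$pyr_rows * x$pyr_cols))
  cat(sprintf("  interneurons   : %d x %d (%d neurons)\n",
              x$int_rows, x$int_cols, x$int_rows * x$int_cols))
  cat(sprintf("  kernels        : s1_pp=%g s1_pi=%g s1_ip=%g s2_ip=%g\n",
              x$s1_pp, x$s1_pi, x$s1_ip, x$s2_ip))
  cat(sprintf("  dynamics       : tau=%g dt=%g h=%g lambda=%g theta+=%g\n",
              x$tau, x$dt, x$h, x$lambda_noise, x$theta_plus))
  cat(sprintf("  plasticity     : theta-=%g delta1=%g delta2=%g L=%g lr=%g\n",
              x$theta_minus, x$delta1, x$delta2, x$L, x$lr_exc))
  les <- c("no-da-modulation", "no-inhibitory-plasticity", "no-learning")[
    c(x$lesion_no_da_modulation, x$lesion_no_inhibitory_plasticity,
      x$lesion_no_learning)]
  cat("  lesions        :", if (length(les)) paste(les, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Derive a reproducible sub-seed
#'
#' Every source of randomness in the package (weight blocks, stimulus
#' generators, protocol permutations, dynamics noise) draws from its own
#' named stream derived from a single top-level seed, so that runs are
#' reproducible and streams do not interfere.
#'
#' @param seed top-level integer seed.
#' @param label stream name.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(label) == 1)
  codes <- utf8ToInt(as.character(label))
  hash <- sum(codes * seq_along(codes) * 131)
  x <- ((abs(seed) %% 2147483647) * 1009 + hash * 97) %% 2147483646
  as.integer(x) + 1L
}
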