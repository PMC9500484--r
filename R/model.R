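#' Instantiate a CA1 model
#'
#' Bundles parameters, freshly generated weights, a zeroed network state
#' and an empty learning trace into one object. All weight blocks draw
#' from named sub-streams of `seed`.
#'
#' @param params a [ca1_params()] record.
#' @param seed top-level integer seed for the weight blocks.
#' @return an object of class `ca1_model`.
#' @export
ca1_model <- function(params = ca1_params(), seed = 1L) {
  weights <- build_weights(params, seed)
  model <- list(
    params = params,
    weights = weights,
    state = new_network_state(params),
    trace = new_trace(params$pyr_rows * params$pyr_cols),
    seed = as.integer(seed)
  )
  class(model) <- "ca1_model"
  model
}

#' @export
print.ca1_model <- function(x, ...) {
  P <- x$params$pyr_rows * x$params$pyr_cols
  I <- x$params$int_rows * x$params$int_cols
  cat(sprintf(
    "<ca1_model> %d input + %d pyramidal + %d interneurons (seed %d)\n",
    P, P, I, x$seed))
  n_lab <- sum(!is.na(x$trace$labels))
  cat(sprintf("  labelled neurons: %d | episodes logged: %d\n",
              n_lab, length(x$trace$episode_log)))
  invisible(x)
}

#' Present a stimulus with plasticity off
#'
#' Settles the network on the stimulus without any weight change (the test
#' condition of the recognition protocols). The network state is carried
#' over, not reset.
#'
#' @param model a [ca1_model()].
#' @param stimulus input activations or an `image_stimulus`.
#' @return a list with the updated `model` and the `settle` `report`.
#' @export
present_stimulus <- function(model, stimulus) {
  if (inherits(stimulus, "image_stimulus")) stimulus <- stimulus$values
  res <- settle(model$state, model$weights, stimulus, model$params)
  model$state <- res$state
  list(model = model, report = res$report)
}
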