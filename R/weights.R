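#' Distance kernels
#'
#' `kernel_gaussian()` is the narrow Gaussian used for both excitatory
#' lateral projections; `kernel_mexican_hat()` is the difference of
#' Gaussians `0.5 * (exp(-d^2 s1) - exp(-d^2 s2))` used for the inhibitory
#' interneuron-to-pyramidal projection. With `s1 < s2` the latter is
#' non-negative, zero at distance 0 and maximal on a ring around the
#' post-synaptic neuron, so inhibition spares the immediate neighbourhood of
#' a winning cell and suppresses the surround.
#'
#' @param d distance (pyramidal-grid units); vector or matrix.
#' @param s1,s2 positive decay parameters; `kernel_mexican_hat()` requires
#'   `s1 < s2`.
#' @return kernel values, same shape as `d`.
#' @export
kernel_gaussian <- function(d, s1) {
  stopifnot(s1 > 0)
  exp(-d^2 * s1)
}

#' @rdname kernel_gaussian
#' @export
kernel_mexican_hat <- function(d, s1, s2) {
  if (s1 >= s2) {
    stop("Mexican-hat kernel requires s1 < s2", call. = FALSE)
  }
  0.5 * (exp(-d^2 * s1) - exp(-d^2 * s2))
}

# shared machinery: weight = kernel(distance) * U[0,1), then the vector of
# weights converging on each post-synaptic neuron is L2-normalised.
build_kernel_block <- function(coords_post, coords_pre, period,
                               kernel_values, seed, zero_self = FALSE) {
  w <- withr::with_seed(seed, {
    matrix(stats::runif(length(kernel_values)), nrow = nrow(kernel_values))
  }) * kernel_values
  if (zero_self) diag(w) <- 0
  l2_normalise_rows(w)
}

l2_normalise_rows <- function(w) {
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w / nrm
}

#' Initial input-to-pyramidal weights
#'
#' Each pyramidal neuron receives an all-to-all projection from the input
#' layer; its converging weight vector is drawn uniformly from `[0, 1)` and
#' L2-normalised, so every neuron starts with a unit-norm random receptive
#' field.
#'
#' @param n_post,n_pre number of post-synaptic (pyramidal) and pre-synaptic
#'   (input) neurons.
#' @param seed integer seed for this weight block.
#' @return an `n_post x n_pre` matrix with unit-L2-norm rows.
#' @export
init_input_weights <- function(n_post, n_pre, seed) {
  stopifnot(n_post > 0, n_pre > 0)
  w <- withr::with_seed(seed, matrix(stats::runif(n_post * n_pre), n_post))
  l2_normalise_rows(w)
}

#' Lateral excitatory weights within a layer
#'
#' Pyramidal-to-pyramidal connectivity: each weight is the product of a
#' narrow Gaussian of the toroidal distance and a uniform random factor;
#' the converging vector of each neuron is L2-normalised. Self-connections
#' are forced to zero.
#'
#' @param geom [layer_geometry()] of the layer.
#' @param s1 Gaussian decay.
#' @param seed integer seed for this weight block.
#' @return an `n x n` weight matrix (rows = post-synaptic) with zero
#'   diagonal and unit-L2-norm rows.
#' @export
build_lateral_excitatory <- function(geom, s1, seed) {
  coords <- grid_coords(geom)
  d <- torus_distance_matrix(coords, coords, geom$period)
  build_kernel_block(coords, coords, geom$period,
                     kernel_gaussian(d, s1), seed, zero_self = TRUE)
}

#' Excitatory projection between two layers
#'
#' Same stochastic Gaussian kernel as [build_lateral_excitatory()] but
#' between two layers sharing the pyramidal sheet (used for the
#' pyramidal-to-interneuron projection, with interneuron coordinates from
#' [place_interneurons()]).
#'
#' @param coords_post,coords_pre coordinate matrices in pyramidal-grid
#'   units.
#' @param period wrap period of the pyramidal map.
#' @param s1 Gaussian decay.
#' @param seed integer seed.
#' @return an `n_post x n_pre` weight matrix with unit-L2-norm rows.
#' @export
build_projection_excitatory <- function(coords_post, coords_pre, period,
                                        s1, seed) {
  d <- torus_distance_matrix(coords_post, coords_pre, period)
  build_kernel_block(coords_post, coords_pre, period,
                     kernel_gaussian(d, s1), seed)
}

#' Inhibitory interneuron-to-pyramidal weights
#'
#' The magnitude of each weight follows the Mexican-hat kernel times a
#' uniform random factor; converging magnitude vectors are L2-normalised
#' and the result is stored with a negative sign. Storing inhibition as
#' non-positive weights lets the membrane equation simply add the lateral
#' inhibition term, and lets the homeostatic rule strengthen inhibition by
#' driving weights more negative.
#'
#' @param geom_i interneuron [layer_geometry()].
#' @param geom_p pyramidal [layer_geometry()].
#' @param s1,s2 Mexican-hat decays, `s1 < s2`.
#' @param seed integer seed.
#' @return an `n_pyr x n_int` non-positive weight matrix whose rows have
#'   unit L2 norm in magnitude.
#' @export
build_inhibitory_weights <- function(geom_i, geom_p, s1, s2, seed) {
  coords_p <- grid_coords(geom_p)
  coords_i <- place_interneurons(geom_p, geom_i)
  d <- torus_distance_matrix(coords_p, coords_i, geom_p$period)
  -build_kernel_block(coords_p, coords_i, geom_p$period,
                      kernel_mexican_hat(d, s1, s2), seed)
}

#' Build all weight blocks of a model
#'
#' Generates the four CA1 weight blocks (input-to-pyramidal, lateral
#' pyramidal-to-pyramidal, pyramidal-to-interneuron,
#' interneuron-to-pyramidal) plus the fixed downstream gains: one-to-one
#' Subiculum afferents (weight 1) and the inhibitory Accumbens/Pallidum to
#' VTA connection (weight -1). Each block draws from its own sub-stream of
#' `seed` (see [derive_seed()]).
#'
#' @param params a [ca1_params()] record.
#' @param seed top-level integer seed.
#' @return an object of class `ca1_weights` with elements `w_inp`, `w_pp`,
#'   `w_pi`, `w_ip`, `w_sub`, `w_ap_vta`, and the geometries used.
#' @export
build_weights <- function(params, seed) {
  geom_p <- layer_geometry(params$pyr_rows, params$pyr_cols, unit = 1)
  geom_i <- layer_geometry(params$int_rows, params$int_cols,
                           unit = geom_p$period[1] / params$int_rows)
  coords_p <- grid_coords(geom_p)
  coords_i <- place_interneurons(geom_p, geom_i)
  w <- list(
    w_inp = init_input_weights(geom_p$n, geom_p$n,
                               derive_seed(seed, "w_inp")),
    w_pp = build_lateral_excitatory(geom_p, params$s1_pp,
                                    derive_seed(seed, "w_pp")),
    w_pi = build_projection_excitatory(coords_i, coords_p, geom_p$period,
                                       params$s1_pi,
                                       derive_seed(seed, "w_pi")),
    w_ip = build_inhibitory_weights(geom_i, geom_p, params$s1_ip,
                                    params$s2_ip,
                                    derive_seed(seed, "w_ip")),
    w_sub = 1,
    w_ap_vta = -1,
    geom_p = geom_p,
    geom_i = geom_i,
    seed = as.integer(seed),
    kernel = list(s1_pp = params$s1_pp, s1_pi = params$s1_pi,
                  s1_ip = params$s1_ip, s2_ip = params$s2_ip)
  )
  class(w) <- "ca1_weights"
  w
}

#' @export
print.ca1_weights <- function(x, ...) {
  cat("<ca1_weights>\n")
  cat(sprintf("  w_inp %d x %d | w_pp %d x %d | w_pi %d x %d | w_ip %d x %d\n",
              nrow(x$w_inp), ncol(x$w_inp), nrow(x$w_pp), ncol(x$w_pp),
              nrow(x$w_pi), ncol(x$w_pi), nrow(x$w_ip), ncol(x$w_ip)))
  cat(sprintf("  w_sub = %g, w_ap_vta = %g, seed = %d\n",
              x$w_sub, x$w_ap_vta, x$seed))
  invisible(x)
}

#' Serialize weight blocks to disk
#'
#' Writes each plastic/static block as a gzip-compressed CSV plus a JSON
#' sidecar (`meta.json`) recording the seed, geometry and kernel
#' parameters, so a network can be archived and restored exactly.
#'
#' @param weights a `ca1_weights` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_weights <- function(weights, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (block in c("w_inp", "w_pp", "w_pi", "w_ip")) {
    data.table::fwrite(data.table::as.data.table(weights[[block]]),
                       file.path(dir, paste0(block, ".csv.gz")),
                       col.names = FALSE)
  }
  meta <- list(
    seed = weights$seed,
    w_sub = weights$w_sub, w_ap_vta = weights$w_ap_vta,
    geom_p = list(rows = weights$geom_p$rows, cols = weights$geom_p$cols,
                  unit = weights$geom_p$unit),
    geom_i = list(rows = weights$geom_i$rows, cols = weights$geom_i$cols,
                  unit = weights$geom_i$unit),
    kernel = weights$kernel
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_weights
#' @export
read_weights <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  w <- lapply(c(w_inp = "w_inp", w_pp = "w_pp", w_pi = "w_pi",
                w_ip = "w_ip"), function(block) {
    con <- gzfile(file.path(dir, paste0(block, ".csv.gz")))
    as.matrix(utils::read.csv(con, header = FALSE,
                              colClasses = "numeric"))
  })
  w <- lapply(w, unname)
  w$w_sub <- meta$w_sub
  w$w_ap_vta <- meta$w_ap_vta
  w$geom_p <- layer_geometry(meta$geom_p$rows, meta$geom_p$cols,
                             meta$geom_p$unit)
  w$geom_i <- layer_geometry(meta$geom_i$rows, meta$geom_i$cols,
                             meta$geom_i$unit)
  w$seed <- as.integer(meta$seed)
  w$kernel <- meta$kernel
  class(w) <- "ca1_weights"
  w
}
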