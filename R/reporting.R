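#' Per-position recognition bar chart
#'
#' Bars (with standard-deviation whiskers) of the mean recognition
#' percentage at each learning position, averaged over task-order
#' permutations.
#'
#' @param x a `cf_result`.
#' @param generalization plot the held-out generalization scores instead?
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_recognition <- function(x, generalization = FALSE, ...) {
  m <- if (generalization) x$gen_recognition else x$recognition
  s <- if (generalization) x$gen_sd else x$sd
  if (is.null(m)) stop("no generalization scores in this result",
                       call. = FALSE)
  mid <- graphics::barplot(m, ylim = c(0, 105),
                           names.arg = seq_along(m),
                           xlab = "task (learning position)",
                           ylab = "recognition (%)", ...)
  up <- pmin(105, m + s)
  keep <- s > 0
  if (any(keep)) {
    graphics::arrows(mid[keep], pmax(0, (m - s)[keep]), mid[keep],
                     up[keep], angle = 90, code = 3, length = 0.04)
  }
  invisible(mid)
}

#' Mosaic of input receptive fields
#'
#' Renders the input weights of every pyramidal neuron as a tile at the
#' neuron's position on the CA1 map: a grid of `pyr_rows x pyr_cols`
#' tiles, each tile the neuron's `rows x cols` input-weight vector in
#' grayscale (white = strongest). After learning, tiles reproduce the
#' learned images at the winning populations.
#'
#' @param model a [ca1_model()].
#' @param ... passed to [graphics::image()].
#' @return the assembled mosaic matrix, invisibly.
#' @export
plot_weight_mosaic <- function(model, ...) {
  pr <- model$params$pyr_rows
  pc <- model$params$pyr_cols
  big <- matrix(0, pr * pr, pc * pc)
  for (k in seq_len(pr * pc)) {
    r <- (k - 1L) %/% pc
    c_ <- (k - 1L) %% pc
    tile <- matrix(model$weights$w_inp[k, ], pr, pc, byrow = TRUE)
    big[(r * pr + 1):(r * pr + pr), (c_ * pc + 1):(c_ * pc + pc)] <- tile
  }
  graphics::image(t(big[nrow(big):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, ...)
  invisible(big)
}

#' Label map of the pyramidal layer
#'
#' Shows which task each pyramidal neuron learned (dominant label by
#' cumulative update mass), one coloured cell per neuron on the CA1 map;
#' unlabelled neurons are left dark.
#'
#' @param model a [ca1_model()].
#' @param dominant use the label with the largest cumulative update mass
#'   (otherwise the last-written label).
#' @param ... passed to [graphics::image()].
#' @return the integer label matrix, invisibly.
#' @export
plot_label_map <- function(model, dominant = TRUE, ...) {
  pr <- model$params$pyr_rows
  pc <- model$params$pyr_cols
  labs <- if (dominant) trace_dominant_labels(model$trace)
          else model$trace$labels
  lev <- sort(unique(labs[!is.na(labs)]))
  code <- match(labs, lev)
  m <- matrix(code, pr, pc, byrow = TRUE)
  pal <- c("black", grDevices::hcl.colors(max(1, length(lev)), "Spectral"))
  m0 <- m
  m0[is.na(m0)] <- 0
  graphics::image(t(m0[pr:1, ]), col = pal[seq_len(max(m0) + 1)],
                  axes = FALSE, ...)
  invisible(m)
}

#' Activation heatmap of a layer
#'
#' @param model a [ca1_model()].
#' @param layer `"pyramidal"` or `"interneuron"`.
#' @param ... passed to [graphics::image()].
#' @return the activation matrix, invisibly.
#' @export
plot_activation <- function(model, layer = c("pyramidal", "interneuron"),
                            ...) {
  layer <- match.arg(layer)
  if (layer == "pyramidal") {
    a <- model$state$a_p
    nr <- model$params$pyr_rows
    nc <- model$params$pyr_cols
    pal <- grDevices::hcl.colors(256, "Reds", rev = TRUE)
  } else {
    a <- model$state$a_i
    nr <- model$params$int_rows
    nc <- model$params$int_cols
    pal <- grDevices::hcl.colors(256, "Blues", rev = TRUE)
  }
  m <- matrix(a, nr, nc, byrow = TRUE)
  graphics::image(t(m[nr:1, ]), zlim = c(0, 1), col = pal, axes = FALSE,
                  ...)
  invisible(m)
}

#' Peak-position scatter of a lifelong run
#'
#' Positions of the winning neurons on the CA1 map for every image:
#' squares for the first corridor, circles for the second; winners shared
#' by two images are drawn red, by three or more green.
#'
#' @param x a `lifelong_result`.
#' @param epoch epoch whose peak map to draw (default: the final combined
#'   map).
#' @param ... passed to [graphics::plot()].
#' @return the plotted peak map, invisibly.
#' @export
plot_peak_map <- function(x, epoch = NULL, ...) {
  map <- if (is.null(epoch)) x$final_map else x$peak_maps[[epoch]]
  tasks <- unique(map$task_id)
  pch <- ifelse(map$task_id == tasks[1], 22, 21)
  n_shared <- table(map$winner)[as.character(map$winner)]
  col <- ifelse(n_shared >= 3, "green3", ifelse(n_shared == 2, "red",
                                                "black"))
  pr <- x$model$params$pyr_rows
  pc <- x$model$params$pyr_cols
  graphics::plot(map$col, pr - 1 - map$row, pch = pch, col = col,
                 bg = "white", xlim = c(0, pc - 1), ylim = c(0, pr - 1),
                 xlab = "column", ylab = "row", ...)
  invisible(map)
}

#' Write protocol results to disk
#'
#' `write_cf_result()` writes one CSV row per learning position (mean and
#' sd over permutations) plus a JSON file with the full per-run matrices
#' and metadata. `write_lifelong_result()` writes an epochs CSV (episodes
#' per epoch), a peak-map coordinate CSV (`image_id`, `row`, `col`) and a
#' JSON summary. Lesion flags are recorded verbatim.
#'
#' @param x a `cf_result` or `lifelong_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cf_result <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(position = seq_along(x$recognition),
                   mean = x$recognition, sd = x$sd)
  utils::write.csv(df, file.path(dir, "recognition.csv"),
                   row.names = FALSE)
  payload <- list(runs = unclass(x$runs),
                  runs_by_task = unclass(x$runs_by_task),
                  permutations = x$permutations, seed = x$seed,
                  lesions = x$lesions)
  if (!is.null(x$gen_recognition)) {
    payload$gen_recognition <- x$gen_recognition
    payload$gen_runs <- unclass(x$gen_runs)
    gdf <- data.frame(position = seq_along(x$gen_recognition),
                      mean = x$gen_recognition, sd = x$gen_sd)
    utils::write.csv(gdf, file.path(dir, "generalization.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(payload, file.path(dir, "cf_result.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cf_result
#' @export
write_lifelong_result <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(epoch = seq_along(x$episodes_per_epoch),
               corridor = x$epoch_corridor,
               episodes = x$episodes_per_epoch),
    file.path(dir, "epochs.csv"), row.names = FALSE)
  utils::write.csv(x$final_map[, c("image_id", "task_id", "winner",
                                   "row", "col")],
                   file.path(dir, "peak_map.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(epochs_total = x$epochs_total, terminal = x$terminal,
         distinct_peaks = x$distinct_peaks,
         stability_count = x$stability_count, seed = x$seed,
         lesions = x$lesions),
    file.path(dir, "lifelong_result.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
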