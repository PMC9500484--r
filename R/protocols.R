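#' Recognition of a single presentation
#'
#' The recognition rule of the catastrophic-forgetting test: a stimulus is
#' correctly recognized iff the most active pyramidal neuron after
#' settling was labelled, during learning, with the stimulus's own task.
#' A neuron updated by several tasks carries the label into which it put
#' the most cumulative weight change (its dominant label); an unlabelled
#' winner counts as a misclassification.
#'
#' @param report a `settle_report` from [present_stimulus()].
#' @param trace the model's learning trace.
#' @param true_task the stimulus's task id.
#' @return `TRUE`/`FALSE`.
#' @export
classify_peak <- function(report, trace, true_task) {
  lab <- trace_dominant_labels(trace)[report$peak_neuron]
  !is.na(lab) && lab == as.character(true_task)
}

# label of each neuron by largest cumulative |dw|; falls back to the
# last-write label when no mass was recorded
trace_dominant_labels <- function(trace) {
  labs <- trace$labels
  if (length(trace$label_mass) > 1) {
    mass <- do.call(cbind, trace$label_mass)
    has <- rowSums(mass) > 0
    labs[has] <- colnames(mass)[max.col(mass[has, , drop = FALSE],
                                        ties.method = "first")]
  }
  labs
}

#' Catastrophic-forgetting experiment
#'
#' Learns the tasks of `train_set` one after the other (each image seen
#' once), in a random task order; then presents all images again, in the
#' same order, with plasticity off, scoring each via [classify_peak()].
#' The whole experiment is repeated over `permutations` random task
#' orders, each with freshly generated weights, and results are averaged
#' by position in the learned sequence (position 1 = first-learned task),
#' which is what exposes interference: the more forgetting, the lower the
#' recognition of early positions. With 4 images per task every per-task
#' score is one of 0, 25, 50, 75, 100%.
#'
#' If `test_set` is given (held-out images of the same classes) a
#' generalization score is computed the same way.
#'
#' @param params a [ca1_params()] (including lesion flags).
#' @param train_set a [stimulus_set()] of tasks (default protocol: 10
#'   tasks of 4 images).
#' @param test_set optional held-out [stimulus_set()] with matching task
#'   labels.
#' @param permutations number of task-order permutations.
#' @param seed top-level seed (weights, permutations and dynamics noise
#'   derive named sub-streams from it).
#' @return an object of class `cf_result`: `recognition`/`sd` (% per
#'   learning position), the per-run matrix `runs`, a by-task-identity
#'   matrix `runs_by_task`, optional `gen_*` counterparts, and the final
#'   model of the last run.
#' @export
run_catastrophic_forgetting <- function(params, train_set, test_set = NULL,
                                        permutations = 10L, seed = 1L) {
  tasks <- train_set$tasks
  T_ <- length(tasks)
  if (T_ == 0 || any(vapply(tasks, length, 1L) == 0)) {
    stop("every task must contain at least one image", call. = FALSE)
  }
  task_ids <- names(tasks)
  runs <- matrix(NA_real_, permutations, T_,
                 dimnames = list(NULL, paste0("pos", seq_len(T_))))
  runs_by_task <- matrix(NA_real_, permutations, T_,
                         dimnames = list(NULL, task_ids))
  gen_runs <- if (!is.null(test_set)) runs else NULL
  last_model <- NULL

  for (r in seq_len(permutations)) {
    run_out <- withr::with_seed(derive_seed(seed, paste0("cf-run-", r)), {
      perm <- sample(T_)
      model <- ca1_model(params,
                         seed = derive_seed(seed, paste0("cf-weights-", r)))
      for (p in seq_len(T_)) {
        for (img in tasks[[perm[p]]]) {
          model <- learn_image(model, img)$model
        }
      }
      # test phase: plasticity off, same presentation order
      score <- numeric(T_)
      for (p in seq_len(T_)) {
        task <- tasks[[perm[p]]]
        ok <- 0L
        for (img in task) {
          pres <- present_stimulus(model, img)
          model <- pres$model
          ok <- ok + classify_peak(pres$report, model$trace, img$task_id)
        }
        score[p] <- 100 * ok / length(task)
      }
      gen_score <- NULL
      if (!is.null(test_set)) {
        gen_score <- numeric(T_)
        for (p in seq_len(T_)) {
          task <- test_set$tasks[[task_ids[perm[p]]]]
          ok <- 0L
          for (img in task) {
            pres <- present_stimulus(model, img)
            model <- pres$model
            ok <- ok + classify_peak(pres$report, model$trace, img$task_id)
          }
          gen_score[p] <- 100 * ok / length(task)
        }
      }
      list(perm = perm, score = score, gen_score = gen_score, model = model)
    })
    runs[r, ] <- run_out$score
    runs_by_task[r, run_out$perm] <- run_out$score
    if (!is.null(gen_runs)) gen_runs[r, ] <- run_out$gen_score
    last_model <- run_out$model
  }

  res <- list(
    recognition = colMeans(runs),
    sd = apply(runs, 2, stats::sd),
    runs = runs,
    runs_by_task = runs_by_task,
    permutations = permutations,
    seed = as.integer(seed),
    lesions = params[c("lesion_no_da_modulation",
                       "lesion_no_inhibitory_plasticity",
                       "lesion_no_learning")],
    model = last_model
  )
  if (!is.null(gen_runs)) {
    res$gen_recognition <- colMeans(gen_runs)
    res$gen_sd <- apply(gen_runs, 2, stats::sd)
    res$gen_runs <- gen_runs
  }
  class(res) <- "cf_result"
  res
}

#' @export
print.cf_result <- function(x, ...) {
  cat(sprintf("<cf_result> %d permutations, %d task positions\n",
              x$permutations, length(x$recognition)))
  cat("  recognition (% by learning position):\n")
  print(round(x$recognition, 1))
  invisible(x)
}

# frozen-plasticity evaluation of a list of stimuli -> peak-map data frame
eval_peak_map <- function(model, images) {
  rows <- lapply(images, function(img) {
    pres <- present_stimulus(model, img)
    model <<- pres$model
    k <- pres$report$peak_neuron
    data.frame(image_id = img$id, task_id = img$task_id,
               winner = k,
               row = (k - 1L) %/% model$params$pyr_cols,
               col = (k - 1L) %% model$params$pyr_cols,
               peak_activation = pres$report$peak_activation,
               stringsAsFactors = FALSE)
  })
  list(map = do.call(rbind, rows), model = model)
}

#' Lifelong two-corridor experiment
#'
#' Simulates an agent alternating between two corridors of images. Within
#' an epoch the current corridor is traversed repeatedly, learning each
#' image ([learn_image()]), until one full pass raises no novelty signal
#' (or `max_passes` traversals elapse, which only matters under lesions
#' that never silence novelty). The agent then switches corridor and the
#' epoch counter increments. The experiment ends when two consecutive
#' epochs require no learning episode, or at `max_epochs`.
#'
#' At the end of each epoch the winner (peak) neuron of every image of the
#' traversed corridor is recorded with plasticity off; after termination
#' all images of both corridors are evaluated once more (`final_map`).
#'
#' @param params a [ca1_params()] (including lesion flags).
#' @param corridor_a,corridor_b lists of [image_stimulus()] or single-task
#'   [stimulus_set()]s (default protocol: 20 images each).
#' @param seed top-level seed.
#' @param max_epochs,max_passes overrides of the parameter-record caps.
#' @return an object of class `lifelong_result`: `episodes_per_epoch`,
#'   `epoch_corridor`, `peak_maps` (one data frame per epoch),
#'   `final_map`, `distinct_peaks`, `stability_count`, `terminal`, and the
#'   final model.
#' @export
run_lifelong <- function(params, corridor_a, corridor_b, seed = 1L,
                         max_epochs = NULL, max_passes = NULL) {
  as_images <- function(x) {
    if (inherits(x, "stimulus_set")) {
      stopifnot(length(x$tasks) == 1)
      x$tasks[[1]]
    } else x
  }
  corr <- list(A = as_images(corridor_a), B = as_images(corridor_b))
  stopifnot(length(corr$A) >= 1, length(corr$B) >= 1)
  if (is.null(max_epochs)) max_epochs <- params$max_epochs
  if (is.null(max_passes)) max_passes <- params$max_passes

  withr::with_seed(derive_seed(seed, "lifelong"), {
    model <- ca1_model(params, seed = derive_seed(seed, "ll-weights"))
    episodes_per_epoch <- integer(0)
    epoch_corridor <- character(0)
    peak_maps <- list()
    epoch <- 0L
    side <- "A"
    terminal <- FALSE
    while (epoch < max_epochs) {
      epoch <- epoch + 1L
      episodes <- 0L
      passes <- 0L
      repeat {
        passes <- passes + 1L
        pass_novel <- FALSE
        for (img in corr[[side]]) {
          out <- learn_image(model, img)
          model <- out$model
          if (out$episode$counted) {
            episodes <- episodes + 1L
            pass_novel <- TRUE
          }
        }
        if (!pass_novel || passes >= max_passes) break
      }
      ev <- eval_peak_map(model, corr[[side]])
      model <- ev$model
      peak_maps[[epoch]] <- ev$map
      episodes_per_epoch[epoch] <- episodes
      epoch_corridor[epoch] <- side
      if (epoch >= 2L && episodes_per_epoch[epoch] == 0L &&
            episodes_per_epoch[epoch - 1L] == 0L) {
        terminal <- TRUE
        break
      }
      side <- if (side == "A") "B" else "A"
    }

    ev <- eval_peak_map(model, c(corr$A, corr$B))
    final_map <- ev$map
    model <- ev$model

    # stability of corridor A: first epoch vs first revisit
    map_first <- peak_maps[[1]]
    revisit_idx <- which(epoch_corridor == "A")[2]
    map_revisit <- if (!is.na(revisit_idx)) peak_maps[[revisit_idx]]
                   else final_map[final_map$task_id ==
                                    corr$A[[1]]$task_id, ]
    stability <- peak_stability(map_first, map_revisit)

    res <- list(
      episodes_per_epoch = episodes_per_epoch,
      epoch_corridor = epoch_corridor,
      epochs_total = epoch,
      peak_maps = peak_maps,
      final_map = final_map,
      distinct_peaks = distinct_peak_count(final_map),
      stability_count = stability,
      terminal = terminal,
      seed = as.integer(seed),
      lesions = params[c("lesion_no_da_modulation",
                         "lesion_no_inhibitory_plasticity",
                         "lesion_no_learning")],
      model = model
    )
    class(res) <- "lifelong_result"
    res
  })
}

#' @export
print.lifelong_result <- function(x, ...) {
  cat(sprintf("<lifelong_result> %d epochs%s\n", x$epochs_total,
              if (x$terminal) " (terminal, novelty-free)" else ""))
  cat("  episodes per epoch:",
      paste(sprintf("%s:%d", x$epoch_corridor, x$episodes_per_epoch),
            collapse = " "), "\n")
  cat(sprintf("  distinct peaks: %d | corridor-A stable peaks: %d\n",
              x$distinct_peaks, x$stability_count))
  invisible(x)
}

#' Number of distinct winning neurons
#'
#' Counts the unique peak-neuron indices over all images of a peak map. A
#' count close to the number of images means each image has its own
#' neural representation; a low count means several images share winners.
#'
#' @param peak_map a data frame with a `winner` column (as produced by the
#'   protocols) or a vector of winner indices.
#' @return the number of distinct winners.
#' @export
distinct_peak_count <- function(peak_map) {
  w <- if (is.data.frame(peak_map)) peak_map$winner else peak_map
  length(unique(w[!is.na(w)]))
}

#' Peak-position stability between two visits
#'
#' Counts how many images keep the same winning neuron between two peak
#' maps of the same images (typically a corridor's first epoch and its
#' first revisit after the other corridor was learned).
#'
#' @param map_epoch1,map_revisit peak maps (data frames with `image_id`
#'   and `winner`) covering the same image ids.
#' @return the number of images with an unchanged winner.
#' @export
peak_stability <- function(map_epoch1, map_revisit) {
  ids1 <- map_epoch1$image_id
  ids2 <- map_revisit$image_id
  if (!setequal(ids1, ids2)) {
    stop("peak maps cover different image ids", call. = FALSE)
  }
  w2 <- map_revisit$winner[match(ids1, ids2)]
  sum(map_epoch1$winner == w2)
}
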