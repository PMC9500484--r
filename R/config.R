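#' Run configuration
#'
#' A flat key-value record from which a whole experiment is reproducible:
#' every model parameter (the defaults stand in for the original tuned
#' constants and can be tuned against the package's acceptance
#' properties), the protocol, the lesion condition, the stimulus source
#' and all seeds. Configurations round-trip through YAML:
#' `read_run_config(write_run_config(cfg))` is identical to `cfg`.
#'
#' @return `default_run_config()`: the default configuration (named
#'   list of class `run_config`).
#' @export
default_run_config <- function() {
  cfg <- c(
    list(
      protocol = "cf",            # "cf" or "lifelong"
      lesion = "none",            # none | no-da | no-inh | both | no-learning
      stimuli = "synthetic",      # synthetic | mnist | dir
      seed = 1L,
      stimulus_seed = 1L,
      out_dir = "ca1som-out",
      permutations = 10L,
      classes = 10L,
      per_class = 4L,
      corridor_n = 20L,
      mnist_images = "",
      mnist_labels = "",
      images_dir = "",
      stimulus_gain = 1,
      stimulus_offset = 0
    ),
    # every ca1_params() argument, under its own name
    unclass(ca1_params())
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname default_run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config()`: `path`, invisibly;
#'   `read_run_config()`: the validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname default_run_config
#' @export
validate_run_config <- function(cfg) {
  ref <- default_run_config()
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- ref
  for (k in names(cfg)) merged[[k]] <- cfg[[k]]
  stopifnot(merged$protocol %in% c("cf", "lifelong"),
            merged$stimuli %in% c("synthetic", "mnist", "dir"))
  ca1_lesions(merged$lesion)  # errors on unknown condition
  class(merged) <- "run_config"
  merged
}

config_params <- function(cfg) {
  les <- ca1_lesions(cfg$lesion)
  args <- cfg[intersect(names(cfg), names(formals(ca1_params)))]
  args[names(les)] <- les
  do.call(ca1_params, args)
}

#' Load grayscale images from a directory
#'
#' Reads all PNG/TIFF/JPEG files of a directory (sorted by name),
#' converts them to grayscale and groups them, in order, into tasks of
#' `images_per_task` images labelled `"0"`, `"1"`, ...
#'
#' @param dir image directory.
#' @param images_per_task task size.
#' @param target,gain,offset passed to [preprocess_image()].
#' @return a [stimulus_set()].
#' @export
load_image_dir <- function(dir, images_per_task = 4L,
                           target = c(40L, 40L), gain = 1, offset = 0) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no image files in ", dir, call. = FALSE)
  stims <- lapply(files, function(f) {
    img <- EBImage::readImage(f)
    m <- if (length(dim(img)) == 3) rowMeans(EBImage::imageData(img),
                                             dims = 2)
         else EBImage::imageData(img)
    t(m) * 255  # EBImage is (x, y); transpose to (row, col)
  })
  n_task <- ceiling(length(stims) / images_per_task)
  tasks <- lapply(seq_len(n_task), function(ti) {
    idx <- ((ti - 1L) * images_per_task + 1L):
      min(ti * images_per_task, length(stims))
    lapply(seq_along(idx), function(j) {
      preprocess_image(stims[[idx[j]]], target = target, gain = gain,
                       offset = offset,
                       id = basename(files[idx[j]]),
                       task_id = as.character(ti - 1L), position = j)
    })
  })
  names(tasks) <- as.character(seq_len(n_task) - 1L)
  stimulus_set(tasks, kind = "mnist-like", size = target,
               meta = list(source = dir))
}

config_stimuli <- function(cfg, params) {
  size <- params$pyr_rows
  target <- c(params$pyr_rows, params$pyr_cols)
  if (cfg$protocol == "lifelong") {
    set <- switch(cfg$stimuli,
      synthetic = gen_corridor_pair(cfg$stimulus_seed, n = cfg$corridor_n,
                                    size = size),
      dir = load_image_dir(cfg$images_dir,
                           images_per_task = cfg$corridor_n,
                           target = target, gain = cfg$stimulus_gain,
                           offset = cfg$stimulus_offset),
      stop("lifelong protocol supports synthetic or dir stimuli",
           call. = FALSE))
    if (length(set$tasks) < 2) {
      stop("lifelong protocol needs two corridors", call. = FALSE)
    }
    list(corridor_a = set$tasks[[1]], corridor_b = set$tasks[[2]],
         set = set)
  } else {
    switch(cfg$stimuli,
      synthetic = {
        # draw twice the variants per class; the second half is the
        # held-out generalization set of the same prototypes
        full <- gen_digit_like(cfg$stimulus_seed, classes = cfg$classes,
                               per_class = 2L * cfg$per_class,
                               size = size)
        split_stimulus_set(full, seq_len(cfg$per_class),
                           cfg$per_class + seq_len(cfg$per_class))
      },
      mnist = load_mnist_subsets(cfg$mnist_images, cfg$mnist_labels,
                                 per_class = cfg$per_class,
                                 classes = 0:(cfg$classes - 1),
                                 target = target,
                                 gain = cfg$stimulus_gain,
                                 offset = cfg$stimulus_offset),
      dir = list(train = load_image_dir(cfg$images_dir,
                                        images_per_task = cfg$per_class,
                                        target = target,
                                        gain = cfg$stimulus_gain,
                                        offset = cfg$stimulus_offset),
                 test = NULL))
  }
}

#' Execute a configured experiment
#'
#' Resolves a [default_run_config()]-style configuration, builds the
#' stimuli, runs the selected protocol and writes results (CSV + JSON),
#' episode logs and an echo of the fully resolved configuration to
#' `out_dir`.
#'
#' @param cfg a `run_config` (or a named list of overrides).
#' @return the protocol result, invisibly.
#' @export
run_from_config <- function(cfg) {
  cfg <- validate_run_config(cfg)
  params <- config_params(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  stim <- config_stimuli(cfg, params)
  if (cfg$protocol == "cf") {
    res <- run_catastrophic_forgetting(params, stim$train, stim$test,
                                       permutations = cfg$permutations,
                                       seed = cfg$seed)
    write_cf_result(res, cfg$out_dir)
  } else {
    res <- run_lifelong(params, stim$corridor_a, stim$corridor_b,
                        seed = cfg$seed)
    write_lifelong_result(res, cfg$out_dir)
  }
  log_path <- file.path(cfg$out_dir, "episodes.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  for (ep in res$model$trace$episode_log) {
    log_episode(ep, log_path, lesions = res$lesions)
  }
  invisible(res)
}
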