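#' Image stimulus
#'
#' A single preprocessed stimulus: activations in `[0, 1]`, stored
#' row-major so that element `k` drives input neuron `k` of the grid.
#'
#' @param values numeric vector of activations in `[0, 1]` (length
#'   `rows * cols`).
#' @param id stimulus identifier.
#' @param task_id task / corridor label.
#' @param position index within its task.
#' @param size grid dimensions, `c(rows, cols)`.
#' @return an object of class `image_stimulus`.
#' @export
image_stimulus <- function(values, id, task_id, position = NA_integer_,
                           size = c(40L, 40L)) {
  values <- as.numeric(values)
  if (length(values) != prod(size)) {
    stop("stimulus length ", length(values), " does not match ",
         size[1], "x", size[2], call. = FALSE)
  }
  if (any(values < 0) || any(values > 1)) {
    stop("stimulus values must lie in [0, 1]", call. = FALSE)
  }
  s <- list(values = values, id = as.character(id),
            task_id = as.character(task_id),
            position = as.integer(position), size = as.integer(size))
  class(s) <- "image_stimulus"
  s
}

#' Ordered stimulus set
#'
#' An ordered list of tasks, each an ordered list of stimuli. The
#' catastrophic-forgetting protocol uses 10 tasks of 4 images; the
#' lifelong protocol uses 2 corridors of 20 images.
#'
#' @param tasks named list; each element is a list of [image_stimulus()].
#' @param kind `"mnist-like"` or `"corridor-like"`.
#' @param size stimulus grid dimensions.
#' @param meta optional named list (generator seed and parameters).
#' @return an object of class `stimulus_set`.
#' @export
stimulus_set <- function(tasks, kind = c("mnist-like", "corridor-like"),
                         size = c(40L, 40L), meta = list()) {
  kind <- match.arg(kind)
  s <- list(tasks = tasks, kind = kind, size = as.integer(size),
            meta = meta)
  class(s) <- "stimulus_set"
  s
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %s: %d task(s) x %s images, %dx%d\n",
              x$kind, length(x$tasks),
              paste(unique(vapply(x$tasks, length, 1L)), collapse = "/"),
              x$size[1], x$size[2]))
  invisible(x)
}

#' Flatten a stimulus set in task order
#'
#' @param set a [stimulus_set()].
#' @return a list of `image_stimulus` in presentation order.
#' @export
set_stimuli <- function(set) {
  unlist(unname(set$tasks), recursive = FALSE)
}

#' Preprocess a raw grayscale image
#'
#' Converts a 2D matrix of gray levels (0-255) into input activations:
#' bilinear resize to the target grid (skipped when dimensions already
#' match), linear mapping `(v / 255) * gain + offset`, clamped to
#' `[0, 1]`. Gain and offset absorb dataset-level brightness/contrast
#' differences that in an animal would be compensated upstream of the
#' hippocampus.
#'
#' @param raw numeric matrix of gray levels in `[0, 255]`.
#' @param target output dimensions `c(rows, cols)`.
#' @param gain,offset linear intensity mapping.
#' @param id,task_id,position passed to [image_stimulus()].
#' @return an [image_stimulus()].
#' @export
preprocess_image <- function(raw, target = c(40L, 40L), gain = 1,
                             offset = 0, id = "img", task_id = "0",
                             position = NA_integer_) {
  if (is.null(dim(raw)) || any(dim(raw) == 0) || length(raw) == 0) {
    stop("empty image", call. = FALSE)
  }
  m <- as.matrix(raw)
  if (!all(dim(m) == target)) {
    m <- EBImage::resize(EBImage::Image(m), w = target[1], h = target[2],
                         filter = "bilinear")
    m <- matrix(as.numeric(m), target[1], target[2])
  }
  v <- (m / 255) * gain + offset
  v <- pmin(pmax(v, 0), 1)
  image_stimulus(as.vector(t(v)), id = id, task_id = task_id,
                 position = position, size = target)
}

# ---- MNIST IDX format ----------------------------------------------------

#' Read MNIST IDX files
#'
#' Minimal reader for the IDX format used by MNIST: magic 0x00000803
#' (2051) for image files, 0x00000801 (2049) for label files, big-endian
#' headers, one unsigned byte per pixel/label. Images are returned as a
#' raw-byte payload with an accessor to avoid materialising the full
#' dataset as doubles.
#'
#' @param path IDX file path.
#' @return `read_idx_images()`: a list with `n`, `nrow`, `ncol` and the
#'   raw `data`; `read_idx_labels()`: an integer vector.
#' @export
read_idx_images <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) {
    stop("malformed IDX image file (magic ", magic, ", expected 2051)",
         call. = FALSE)
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  nr <- readBin(con, "integer", 1, size = 4, endian = "big")
  nc <- readBin(con, "integer", 1, size = 4, endian = "big")
  data <- readBin(con, "raw", n * nr * nc)
  if (length(data) != n * nr * nc) {
    stop("malformed IDX image file: truncated payload", call. = FALSE)
  }
  list(n = n, nrow = nr, ncol = nc, data = data)
}

#' @rdname read_idx_images
#' @export
read_idx_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2049L)) {
    stop("malformed IDX label file (magic ", magic, ", expected 2049)",
         call. = FALSE)
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  labels <- as.integer(readBin(con, "raw", n))
  if (length(labels) != n) {
    stop("malformed IDX label file: truncated payload", call. = FALSE)
  }
  labels
}

#' @rdname read_idx_images
#' @param idx a list from `read_idx_images()`.
#' @param i image index (1-based).
#' @export
idx_image <- function(idx, i) {
  stopifnot(i >= 1, i <= idx$n)
  px <- as.integer(idx$data[((i - 1) * idx$nrow * idx$ncol + 1):
                              (i * idx$nrow * idx$ncol)])
  # IDX stores pixels row-major
  matrix(px, idx$nrow, idx$ncol, byrow = TRUE)
}

#' Build the digit learning tasks from MNIST files
#'
#' Takes, in dataset order, the first `per_class` images of each digit as
#' the training tasks (10 tasks x 4 images by default) and, disjointly,
#' the next `per_class` of each digit as the generalization test set.
#'
#' @param images_path,labels_path IDX files.
#' @param per_class images per digit.
#' @param classes digits to use.
#' @param test also build the held-out test set?
#' @param target,gain,offset passed to [preprocess_image()].
#' @return a list with `train` and (optionally) `test`
#'   [stimulus_set()]s.
#' @export
load_mnist_subsets <- function(images_path, labels_path, per_class = 4L,
                               classes = 0:9, test = TRUE,
                               target = c(40L, 40L), gain = 1, offset = 0) {
  idx <- read_idx_images(images_path)
  labels <- read_idx_labels(labels_path)
  if (length(labels) != idx$n) {
    stop("IDX image/label counts differ", call. = FALSE)
  }
  need <- per_class * (1L + as.integer(test))
  pick <- lapply(classes, function(cl) {
    w <- which(labels == cl)
    if (length(w) < need) {
      stop("not enough images of digit ", cl, call. = FALSE)
    }
    w[seq_len(need)]
  })
  build <- function(offset_idx) {
    tasks <- lapply(seq_along(classes), function(ci) {
      lapply(seq_len(per_class), function(v) {
        i <- pick[[ci]][offset_idx + v]
        preprocess_image(idx_image(idx, i), target = target, gain = gain,
                         offset = offset,
                         id = sprintf("mnist_%d", i),
                         task_id = as.character(classes[ci]), position = v)
      })
    })
    names(tasks) <- as.character(classes)
    stimulus_set(tasks, kind = "mnist-like", size = target,
                 meta = list(source = images_path, per_class = per_class))
  }
  out <- list(train = build(0L))
  if (test) out$test <- build(per_class)
  out
}

# ---- synthetic generators ------------------------------------------------

# accumulate Gaussian-profile strokes along a polyline onto a size x size
# canvas; anchors are (row, col) in pixel units
draw_stroke_image <- function(anchors, size, sigma, intensity = 0.9) {
  px <- matrix(rep(seq_len(size) - 1, size), size, size)          # rows
  py <- t(px)                                                     # cols
  img <- matrix(0, size, size)
  for (s in seq_len(nrow(anchors) - 1)) {
    a <- anchors[s, ]
    b <- anchors[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t_ <- pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    d2 <- (px - (a[1] + t_ * ab[1]))^2 + (py - (a[2] + t_ * ab[2]))^2
    img <- img + intensity * exp(-d2 / (2 * sigma^2))
  }
  pmin(img, 1)  # matrix first: pmin(1, img) would drop dim
}

#' Synthetic digit-like stimulus set
#'
#' Generates a labelled set emulating the structure of handwritten-digit
#' data: each class has a random stroke (polyline) prototype; variants are
#' small affine perturbations (global shift plus per-anchor jitter) with
#' additive pixel noise. Strokes cover a small fraction of the canvas, so
#' images are sparse and mostly dark like real digit data, and variants of
#' one class correlate far more with each other than with other classes.
#' A pure function of its seed and parameters.
#'
#' @param seed integer seed.
#' @param classes number of classes.
#' @param per_class variants per class.
#' @param size canvas side (stimuli are `size x size`).
#' @param jitter translation scale of the variants, in pixels.
#' @param noise_sd additive pixel-noise standard deviation.
#' @param target_norm L2 norm each image is scaled to. Fixing the norm
#'   (rather than the mean) keeps the total sensory drive a stimulus
#'   delivers to the network independent of canvas size, which is what
#'   the familiarity threshold operates on.
#' @return a [stimulus_set()] of `classes` tasks (labelled `"0"`,
#'   `"1"`, ...) with `per_class` images each.
#' @export
gen_digit_like <- function(seed, classes = 10L, per_class = 4L,
                           size = 40L, jitter = 1.5, noise_sd = 0.03,
                           target_norm = 2.2) {
  sigma <- max(1, size / 16)
  withr::with_seed(derive_seed(seed, "digit-like"), {
    tasks <- lapply(seq_len(classes) - 1L, function(cl) {
      # anchors alternate between the upper and lower half of the canvas,
      # so every stroke spans it and covers a digit-like pixel fraction
      n_anchor <- sample(4:6, 1)
      cols <- stats::runif(n_anchor, 0.15 * size, 0.85 * size)
      side <- (seq_len(n_anchor) + sample(0:1, 1)) %% 2
      rows <- stats::runif(n_anchor, 0.15 * size, 0.5 * size) +
        side * 0.35 * size
      proto <- cbind(rows, cols)
      lapply(seq_len(per_class), function(v) {
        shift <- stats::runif(2, -jitter, jitter)
        anchors <- proto +
          matrix(shift, nrow(proto), 2, byrow = TRUE) +
          matrix(stats::rnorm(length(proto), 0, jitter / 3), nrow(proto))
        img <- draw_stroke_image(anchors, size, sigma)
        img <- img + matrix(stats::rnorm(size * size, 0, noise_sd),
                            size, size)
        img <- pmax(img, 0)
        img <- img * (target_norm / sqrt(sum(img^2)))
        image_stimulus(pmin(as.vector(t(img)), 1),
                       id = sprintf("d%d.%d", cl, v),
                       task_id = as.character(cl), position = v,
                       size = c(size, size))
      })
    })
    names(tasks) <- as.character(seq_len(classes) - 1L)
    stimulus_set(tasks, kind = "mnist-like", size = c(size, size),
                 meta = list(seed = seed, classes = classes,
                             per_class = per_class, jitter = jitter,
                             noise_sd = noise_sd,
                             target_norm = target_norm))
  })
}

#' Synthetic corridor of contiguous textured images
#'
#' Emulates a sequence of naturalistic views along a corridor. The
#' corridor is a chain of `n + 1` independent 1/f-filtered sparse
#' texture chunks (scene segments, rich in detail at all scales); view
#' `i` blends chunk `i` with, at weight `overlap`, chunk `i + 1`, so
#' consecutive views share a stretch of scene content and correlate,
#' while non-adjacent views are nearly orthogonal. Only the bright
#' upper tail of each chunk is kept (pixels above the `sparsity`
#' quantile) -- without this, every non-negative dense texture shares
#' its mean and all views cross-correlate strongly. Each view is scaled
#' to the L2 norm `contrast * target_norm` and the corridor-specific
#' `luminance` floor is added, so the two corridors of a pair differ in
#' overall brightness the way two landscapes do. A pure function of its
#' seed and parameters.
#'
#' @param seed integer seed.
#' @param n number of images.
#' @param size image side.
#' @param luminance base brightness added to every pixel (per-corridor).
#' @param contrast multiplier on the detail amplitude.
#' @param overlap blend weight of the scene chunk shared with the next
#'   view (0 = unrelated views, values near 1 = near-duplicates).
#' @param corridor_id task label.
#' @param alpha spectral exponent of the 1/f filter.
#' @param sparsity quantile below which texture is cut to black.
#' @param target_norm L2 norm of the detail component at `contrast = 1`;
#'   fixing the norm keeps the sensory drive independent of image size.
#' @return a [stimulus_set()] with a single task of `n` images.
#' @export
gen_corridor <- function(seed, n = 20L, size = 40L, luminance = 0.01,
                         contrast = 1, overlap = 0.25,
                         corridor_id = "A", alpha = 1, sparsity = 0.85,
                         target_norm = 2.2) {
  stopifnot(n >= 1, overlap >= 0, overlap < 1)
  fr <- fft_freq(size)
  amp <- outer(fr^2, fr^2, "+")^(-alpha / 2)
  amp[1, 1] <- 0
  chunks <- withr::with_seed(
    derive_seed(seed, paste0("corridor-", corridor_id)),
    lapply(seq_len(n + 1L), function(i) {
      f <- matrix(stats::rnorm(size * size), size, size)
      f <- Re(stats::fft(stats::fft(f) * amp, inverse = TRUE)) / size^2
      f <- (f - mean(f)) / stats::sd(as.vector(f))
      pmax(f - stats::quantile(as.vector(f), sparsity), 0)
    }))
  imgs <- lapply(seq_len(n), function(i) {
    win <- chunks[[i]] + overlap * chunks[[i + 1L]]
    # norm-match under the [0, 1] ceiling: rescale/clamp until stable
    for (k in 1:3) {
      win <- win * (contrast * target_norm / sqrt(sum(win^2)))
      win <- pmin(win, 1 - luminance)
    }
    win <- win + luminance
    image_stimulus(as.vector(t(win)),
                   id = sprintf("%s%02d", corridor_id, i),
                   task_id = corridor_id, position = i,
                   size = c(size, size))
  })
  tasks <- stats::setNames(list(imgs), corridor_id)
  stimulus_set(tasks, kind = "corridor-like", size = c(size, size),
               meta = list(seed = seed, n = n, luminance = luminance,
                           contrast = contrast, overlap = overlap,
                           alpha = alpha, sparsity = sparsity,
                           target_norm = target_norm))
}

fft_freq <- function(n) {
  k <- c(0:floor(n / 2), if (n > 2) -(ceiling(n / 2) - 1):-1)
  k / n
}

#' Two-corridor stimulus set
#'
#' Convenience wrapper building the lifelong-learning input: two corridors
#' of `n` contiguous images each, with different luminance/contrast
#' (different landscapes).
#'
#' @param seed integer seed.
#' @param n images per corridor.
#' @param size image side.
#' @param luminances length-2 brightness floors of the two corridors.
#' @param overlap within-corridor window overlap.
#' @return a [stimulus_set()] with tasks `"A"` and `"B"`.
#' @export
gen_corridor_pair <- function(seed, n = 20L, size = 40L,
                              luminances = c(0.01, 0.03),
                              overlap = 0.25) {
  a <- gen_corridor(seed, n = n, size = size, luminance = luminances[1],
                    overlap = overlap, corridor_id = "A")
  b <- gen_corridor(seed, n = n, size = size, luminance = luminances[2],
                    overlap = overlap, corridor_id = "B")
  stimulus_set(c(a$tasks, b$tasks), kind = "corridor-like",
               size = c(size, size),
               meta = list(seed = seed, n = n, luminances = luminances,
                           overlap = overlap))
}

#' Split a stimulus set by within-task position
#'
#' Partitions every task of a set into two disjoint sets by image
#' position — e.g. the first four variants of each digit for learning and
#' the next four, of the same prototypes, for the generalization test.
#'
#' @param set a [stimulus_set()].
#' @param idx_train,idx_test within-task positions for each part.
#' @return a list with `train` and `test` [stimulus_set()]s.
#' @export
split_stimulus_set <- function(set, idx_train, idx_test) {
  stopifnot(length(intersect(idx_train, idx_test)) == 0)
  pick <- function(idx) {
    tasks <- lapply(set$tasks, function(task) task[idx])
    stimulus_set(tasks, kind = set$kind, size = set$size, meta = set$meta)
  }
  list(train = pick(idx_train), test = pick(idx_test))
}

#' Nearest-prototype classification accuracy
#'
#' Sanity baseline for synthetic digit-like sets: classify each held-out
#' image by the highest Pearson correlation with the per-class mean of the
#' training set. A meaningful class structure yields accuracy well above
#' chance.
#'
#' @param train_set,test_set [stimulus_set()]s with matching task labels.
#' @return fraction of test images assigned to their true class.
#' @export
nearest_prototype_accuracy <- function(train_set, test_set) {
  protos <- vapply(train_set$tasks, function(task) {
    rowMeans(vapply(task, function(s) s$values,
                    numeric(length(task[[1]]$values))))
  }, numeric(length(train_set$tasks[[1]][[1]]$values)))
  labs <- names(train_set$tasks)
  test <- set_stimuli(test_set)
  hits <- vapply(test, function(s) {
    r <- apply(protos, 2, function(p) stats::cor(p, s$values))
    labs[which.max(r)] == s$task_id
  }, logical(1))
  mean(hits)
}

#' Write a stimulus set to disk
#'
#' Writes one PNG montage per task (images side by side, separated by a
#' one-pixel white gap) plus a JSON manifest recording kind, size, task
#' ids, image ids and generator metadata. Re-running with the same set
#' produces byte-identical output.
#'
#' @param set a [stimulus_set()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_stimulus_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (task_id in names(set$tasks)) {
    task <- set$tasks[[task_id]]
    sz <- set$size
    W <- length(task) * (sz[2] + 1L) - 1L
    canvas <- matrix(1, sz[1], W)
    for (i in seq_along(task)) {
      m <- matrix(task[[i]]$values, sz[1], sz[2], byrow = TRUE)
      canvas[, ((i - 1L) * (sz[2] + 1L) + 1L):
                 ((i - 1L) * (sz[2] + 1L) + sz[2])] <- m
    }
    f <- file.path(dir, sprintf("task_%s.png", task_id))
    # EBImage images are (x, y) = (col, row)
    EBImage::writeImage(EBImage::Image(t(canvas)), f)
    files[[task_id]] <- basename(f)
  }
  manifest <- list(
    kind = set$kind,
    size = set$size,
    tasks = lapply(names(set$tasks), function(task_id) {
      list(task_id = task_id,
           ids = vapply(set$tasks[[task_id]], function(s) s$id, ""),
           file = files[[task_id]])
    }),
    meta = set$meta
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
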