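test_that("preprocessing maps gray levels linearly and clamps", {
  raw <- matrix(255, 40, 40)
  s <- preprocess_image(raw, gain = 1, offset = 0)
  expect_equal(s$values, rep(1, 1600))
  expect_length(s$values, 1600)
  # gain/offset act after the /255 scaling
  s2 <- preprocess_image(matrix(100, 40, 40), gain = 0.5, offset = 0.1)
  expect_equal(s2$values, rep(100 / 255 * 0.5 + 0.1, 1600))
  # offset pushes out of range: clamped
  s3 <- preprocess_image(matrix(250, 40, 40), gain = 1, offset = 0.5)
  expect_equal(s3$values, rep(1, 1600))
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("preprocessing is identity on already-sized input, else resizes", {
  set.seed(4)
  raw <- matrix(runif(1600, 0, 255), 40, 40)
  s <- preprocess_image(raw, target = c(40, 40))
  expect_equal(s$values, as.vector(t(raw / 255)))   # row-major, no resize
  # idempotence on 40x40 inputs
  s2 <- preprocess_image(matrix(s$values * 255, 40, 40, byrow = TRUE))
  expect_equal(s2$values, s$values)
  # resize path: output size contract holds
  big <- matrix(runif(28 * 28, 0, 255), 28, 28)
  r <- preprocess_image(big, target = c(40, 40))
  expect_length(r$values, 1600)
  expect_true(all(r$values >= 0 & r$values <= 1))
  # a constant image stays constant under bilinear resampling
  rc <- preprocess_image(matrix(128, 28, 28), target = c(40, 40))
  expect_equal(rc$values, rep(128 / 255, 1600), tolerance = 1e-6)
})

write_idx_fixture <- function(dir, images, labels) {
  # images: list of byte matrices (0..255); big-endian IDX encoding
  img_path <- file.path(dir, "images.idx")
  lab_path <- file.path(dir, "labels.idx")
  con <- file(img_path, "wb")
  writeBin(c(2051L, length(images), nrow(images[[1]]), ncol(images[[1]])),
           con, size = 4, endian = "big")
  for (m in images) writeBin(as.raw(as.vector(t(m))), con)
  close(con)
  con <- file(lab_path, "wb")
  writeBin(c(2049L, length(labels)), con, size = 4, endian = "big")
  writeBin(as.raw(labels), con)
  close(con)
  list(images = img_path, labels = lab_path)
}

test_that("MNIST IDX reading and subset construction", {
  dir <- withr::local_tempdir()
  set.seed(2)
  # 3 digits x 9 images each, in interleaved dataset order
  labels <- rep(0:2, times = 9)
  images <- lapply(seq_along(labels), function(i) {
    m <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
    m[1, 1] <- as.integer(labels[i] * 10 + 7)   # fingerprint pixel
    m
  })
  fx <- write_idx_fixture(dir, images, labels)

  idx <- read_idx_images(fx$images)
  expect_equal(idx$n, 27)
  expect_equal(idx$nrow, 7)
  expect_identical(idx_image(idx, 5), images[[5]])
  expect_identical(read_idx_labels(fx$labels), labels)

  sets <- load_mnist_subsets(fx$images, fx$labels, per_class = 4,
                             classes = 0:2, target = c(7, 7))
  expect_length(sets$train$tasks, 3)
  expect_true(all(vapply(sets$train$tasks, length, 1L) == 4))
  expect_length(set_stimuli(sets$train), 12)
  # train and test are disjoint by image index
  ids_train <- vapply(set_stimuli(sets$train), function(s) s$id, "")
  ids_test <- vapply(set_stimuli(sets$test), function(s) s$id, "")
  expect_length(intersect(ids_train, ids_test), 0)
  # first training image of digit 1 is the first "1" in dataset order
  expect_equal(sets$train$tasks[["1"]][[1]]$values[1],
               preprocess_image(images[[2]], target = c(7, 7))$values[1])

  # malformed files are rejected
  bad <- file.path(dir, "bad.idx")
  con <- file(bad, "wb")
  writeBin(c(1234L, 1L), con, size = 4, endian = "big")
  close(con)
  expect_error(read_idx_images(bad), "malformed")
  expect_error(read_idx_labels(fx$images), "malformed")
})

test_that("digit-like sets are reproducible with class structure", {
  a <- gen_digit_like(5, classes = 6, per_class = 4, size = 20)
  b <- gen_digit_like(5, classes = 6, per_class = 4, size = 20)
  expect_equal(a, b)                            # pure function of the seed
  c_ <- gen_digit_like(6, classes = 6, per_class = 4, size = 20)
  expect_false(identical(a$tasks[[1]][[1]]$values,
                         c_$tasks[[1]][[1]]$values))
  vals <- vapply(set_stimuli(a), function(s) range(s$values),
                 numeric(2))
  expect_true(all(vals >= 0 & vals <= 1))

  # intra-class correlation exceeds inter-class correlation
  M <- vapply(set_stimuli(a), function(s) s$values, numeric(400))
  cls <- vapply(set_stimuli(a), function(s) s$task_id, "")
  cc <- cor(M)
  same <- outer(cls, cls, "==") & upper.tri(cc)
  diff_ <- outer(cls, cls, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff_]))
})

test_that("digit-like sets support above-chance prototype classification", {
  full <- gen_digit_like(5, classes = 10, per_class = 8, size = 20)
  parts <- split_stimulus_set(full, 1:4, 5:8)
  expect_length(set_stimuli(parts$train), 40)
  expect_length(set_stimuli(parts$test), 40)
  acc <- nearest_prototype_accuracy(parts$train, parts$test)
  expect_gt(acc, 0.3)      # chance is 0.1
})

test_that("corridors are contiguous textures with set luminance", {
  co <- gen_corridor(3, n = 20, size = 20)
  expect_length(co$tasks[[1]], 20)
  expect_equal(co, gen_corridor(3, n = 20, size = 20))
  vals <- vapply(co$tasks[[1]], function(s) s$values, numeric(400))
  expect_true(all(vals >= 0 & vals <= 1))

  # luminance parameter controls mean pixel value
  dark <- gen_corridor(3, n = 6, size = 20, luminance = 0.08)
  bright <- gen_corridor(3, n = 6, size = 20, luminance = 0.2)
  expect_lt(mean(vapply(dark$tasks[[1]], function(s) mean(s$values), 1)),
            mean(vapply(bright$tasks[[1]], function(s) mean(s$values), 1)))

  # consecutive images correlate more than non-adjacent ones
  cc <- cor(vals)
  adj <- mean(cc[cbind(1:19, 2:20)])
  far <- mean(cc[cbind(1:14, 7:20)])
  expect_gt(adj, far)

  pair <- gen_corridor_pair(4, n = 5, size = 20)
  expect_length(pair$tasks, 2)
  expect_false(mean(vapply(pair$tasks$A, function(s) mean(s$values), 1)) ==
                 mean(vapply(pair$tasks$B, function(s) mean(s$values), 1)))
})

test_that("stimulus sets serialize to PNG montages with a manifest", {
  set <- gen_digit_like(2, classes = 2, per_class = 3, size = 12)
  dir <- withr::local_tempdir()
  write_stimulus_set(set, dir)
  expect_true(file.exists(file.path(dir, "task_0.png")))
  expect_true(file.exists(file.path(dir, "task_1.png")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$kind, "mnist-like")
  expect_equal(man$tasks$ids[[1]], c("d0.1", "d0.2", "d0.3"))
  # byte-identical on re-write
  md5 <- tools::md5sum(file.path(dir, "manifest.json"))
  write_stimulus_set(set, dir)
  expect_identical(tools::md5sum(file.path(dir, "manifest.json")), md5)
})

test_that("stimulus containers validate their invariants", {
  expect_error(image_stimulus(rep(0.5, 10), "x", "0", size = c(40, 40)),
               "does not match")
  expect_error(image_stimulus(c(rep(0.5, 1599), 1.2), "x", "0"),
               "\\[0, 1\\]")
})
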