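test_that("learning-threshold gate uses a strict inequality", {
  expect_false(gate_LT(0, 0.1))
  expect_false(gate_LT(0.1, 0.1))          # boundary excluded
  expect_true(gate_LT(0.2, 0.1))
  expect_identical(gate_LT(c(0.05, 0.1, 0.15), 0.1),
                   c(FALSE, FALSE, TRUE))
})

test_that("stable-activation gate needs low flux, history and a rise", {
  p <- tiny_params()
  # high flux blocks learning regardless of activation
  expect_false(any(gate_SA(0.9, 0.1, flux = 0.02, p)))
  expect_true(any(gate_SA(0.9, 0.1, flux = 0.011, p)))
  # flat activation (zero deviation from its average) blocks learning
  expect_false(any(gate_SA(0.5, 0.5, flux = 0, p)))
  # decaying activation (below its average) blocks learning
  expect_false(any(gate_SA(0.3, 0.5, flux = 0, p)))
  # rising activation with quiet input enables learning
  expect_true(all(gate_SA(0.5, 0.3, flux = 0, p)))
  # insufficient history is treated as transient
  expect_false(any(gate_SA(0.5, 0.3, flux = 0, p,
                           age = p$delta1 * p$tau - 1)))
  # absolute mode also fires on a fall
  p2 <- tiny_params(sa_mode = "absolute")
  expect_true(all(gate_SA(0.3, 0.5, flux = 0, p2)))
})

test_that("excitatory-learning-level gate closes as weights converge", {
  a <- c(0.2, 0.8, 0.4, 0.0)
  expect_false(gate_ELL(a, a))                       # converged neuron
  expect_true(gate_ELL(rep(0, 4), a))                # mean dev 0.35
  # strict boundary at exactly the threshold (dyadic values, so the
  # mean deviation is exact in floating point)
  b <- c(0.5, 0.75, 0.25, 0)
  wb <- b
  wb[1] <- b[1] - 1 / 64
  expect_false(gate_ELL(wb, b, ell_min = 1 / 256))
  expect_true(gate_ELL(wb, b, ell_min = 1 / 512))
  # matrix form gates per row
  W <- rbind(a, rep(0, 4))
  expect_identical(unname(gate_ELL(W, a)), c(FALSE, TRUE))
})

test_that("excitatory update has the stimulus as its fixed point", {
  a_inp <- c(0.9, 0.1, 0.5)
  w <- rbind(a_inp, c(0, 0, 0))
  gates <- c(TRUE, TRUE)
  # dopamine off: no update anywhere
  expect_equal(update_excitatory(w, a_inp, c(0.8, 0.8), da = 0, gates),
               matrix(0, 2, 3))
  d <- update_excitatory(w, a_inp, c(0.8, 0.8), da = 1, gates,
                         lr_exc = 0.05)
  expect_equal(d[1, ], c(0, 0, 0))          # w = a_pre: fixed point
  expect_true(all(d[2, ] >= 0))
  # gated-off rows receive nothing
  d2 <- update_excitatory(w, a_inp, c(0.8, 0.8), da = 1, c(FALSE, TRUE))
  expect_equal(d2[1, ], c(0, 0, 0))
})

test_that("repeated gated updates converge monotonically to the input", {
  set.seed(7)
  a_inp <- runif(25)
  w <- matrix(runif(25), 1)
  w <- w / sqrt(sum(w^2))
  cos_prev <- sum(w * a_inp) / sqrt(sum(w^2) * sum(a_inp^2))
  err_prev <- max(abs(w - a_inp))
  for (i in 1:400) {
    w <- w + update_excitatory(w, a_inp, 0.9, da = 1, TRUE, lr_exc = 0.05)
    err <- max(abs(w - a_inp))
    expect_lte(err, err_prev + 1e-12)        # monotone contraction
    err_prev <- err
  }
  cosine <- sum(w * a_inp) / sqrt(sum(w^2) * sum(a_inp^2))
  expect_gt(cosine, 0.99)
  expect_gt(cosine, cos_prev)
})

test_that("excitatory weights stay bounded over long random stimulation", {
  set.seed(11)
  w <- matrix(runif(20), 1)
  w <- w / sqrt(sum(w^2))
  for (i in 1:10000) {
    a_inp <- runif(20)
    w <- w + update_excitatory(w, a_inp, runif(1), da = 1, TRUE,
                               lr_exc = 0.05)
    if (i %% 500 == 0) expect_true(all(w >= 0 & w <= 1))
  }
  expect_true(all(is.finite(w)))
})

test_that("inhibitory update relaxes toward its homeostatic equilibrium", {
  p <- tiny_params()
  a_i <- c(0.3, 0.1)
  w <- rbind(-a_i / 0.3, c(-0.5, -0.2))
  # dopamine off or lesion: nothing happens
  expect_equal(update_inhibitory(w, a_i, c(0.9, 0.9), 0, c(TRUE, TRUE), p),
               matrix(0, 2, 2))
  p_les <- tiny_params(lesion_no_inhibitory_plasticity = TRUE)
  expect_equal(update_inhibitory(w, a_i, c(0.9, 0.9), 1, c(TRUE, TRUE),
                                 p_les), matrix(0, 2, 2))
  d <- update_inhibitory(w, a_i, c(0.9, 0.9), 1, c(TRUE, TRUE), p)
  expect_equal(d[1, ], c(0, 0))             # equilibrium w = -a_i / 0.3
  # a_i = 0.3, w = -0.5: (a_i + 0.3 w) = 0.15 > 0, inhibition strengthens
  expect_lt(d[2, 1], 0)
})

test_that("inhibition approaches equilibrium without overshooting", {
  p <- tiny_params(L = 0.5)
  a_i <- 0.4
  eq <- -a_i / 0.3
  w <- matrix(0, 1, 1)
  prev <- 0
  for (i in 1:2000) {
    w <- w + update_inhibitory(w, a_i, 1, 1, TRUE, p)
    expect_lte(w[1], prev + 1e-12)          # non-increasing ...
    expect_gte(w[1], eq)                    # ... never past equilibrium
    prev <- w[1]
  }
  expect_equal(w[1], eq, tolerance = 1e-3)
})

test_that("an episode learns a novel image and then recognises it", {
  par <- small_params()
  stim <- gen_digit_like(21, classes = 1, per_class = 1, size = 20)
  stim <- stim$tasks[[1]][[1]]
  m <- ca1_model(par, seed = 5)
  set.seed(5)
  out <- learn_image(m, stim)
  expect_equal(out$episode$da_onset, 1L)     # novel at first sight
  expect_true(out$episode$learned)
  expect_gt(out$episode$updated_neurons, 0)
  expect_lt(out$episode$updated_neurons, 200)  # localized population
  expect_true(out$episode$counted)
  # neurons that updated carry the task label; others do not
  labs <- out$model$trace$labels
  expect_equal(sum(!is.na(labs)), sum(out$model$trace$update_mass > 0))
  # familiarity: an immediate re-presentation triggers no learning
  w_before <- out$model$weights$w_inp
  out2 <- learn_image(out$model, stim)
  expect_equal(out2$episode$da_onset, 0L)
  expect_equal(out2$episode$updated_neurons, 0L)
  expect_false(out2$episode$counted)
  expect_identical(out2$model$weights$w_inp, w_before)
})

test_that("winner weights converge to the stimulus during an episode", {
  par <- small_params()
  stim <- gen_digit_like(33, classes = 1, per_class = 1, size = 20)
  stim <- stim$tasks[[1]][[1]]
  m <- ca1_model(par, seed = 8)
  set.seed(8)
  out <- learn_image(m, stim)
  # repeat the episode loop by re-presenting after erasing familiarity:
  # instead, drive the winner directly to convergence with the rule
  k <- which.max(out$model$trace$update_mass)
  w <- out$model$weights$w_inp[k, , drop = FALSE]
  for (i in 1:300) {
    w <- w + update_excitatory(w, stim$values, 0.95, 1, TRUE, 0.05)
  }
  cosine <- sum(w * stim$values) /
    sqrt(sum(w^2) * sum(stim$values^2))
  expect_gt(cosine, 0.99)
})

test_that("lesion switches reproduce the experimental conditions", {
  stim <- gen_digit_like(9, classes = 1, per_class = 1, size = 20)
  stim <- stim$tasks[[1]][[1]]
  # dopamine pinned off: no labels, no updates, episodes not counted
  par0 <- small_params(lesion_no_learning = TRUE)
  m0 <- ca1_model(par0, seed = 3)
  set.seed(3)
  out0 <- learn_image(m0, stim)
  expect_equal(out0$episode$updated_neurons, 0L)
  expect_false(out0$episode$counted)
  expect_true(all(is.na(out0$model$trace$labels)))
  # dopamine pinned on: the episode always runs the full budget
  par1 <- small_params(lesion_no_da_modulation = TRUE,
                       t_max_episode = 40L)
  m1 <- ca1_model(par1, seed = 3)
  set.seed(3)
  out1 <- learn_image(m1, stim)
  expect_equal(out1$episode$steps, 40L)
  expect_false(out1$episode$learned)
  # inhibitory lesion: excitatory learning proceeds, w_ip frozen
  par2 <- small_params(lesion_no_inhibitory_plasticity = TRUE)
  m2 <- ca1_model(par2, seed = 3)
  w_ip_before <- m2$weights$w_ip
  set.seed(3)
  out2 <- learn_image(m2, stim)
  expect_gt(out2$episode$updated_neurons, 0)
  expect_identical(out2$model$weights$w_ip, w_ip_before)
})
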