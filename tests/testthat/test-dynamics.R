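# hand-built weight container for toy networks (bypasses build_weights)
toy_weights <- function(w_inp, w_pp, w_pi, w_ip) {
  w <- list(w_inp = w_inp, w_pp = w_pp, w_pi = w_pi, w_ip = w_ip,
            w_sub = 1, w_ap_vta = -1)
  class(w) <- "ca1_weights"
  w
}

toy_state <- function(P, I) {
  p <- ca1_params(pyr_rows = P, pyr_cols = 1, int_rows = I, int_cols = 1)
  new_network_state(p)
}

test_that("gain is zero for non-positive input and clamps at one", {
  expect_equal(gain(0, 0.15), 0)
  expect_equal(gain(-3, 0.15), 0)
  expect_equal(gain(c(-1, 0, -1e-9), 0.5), c(0, 0, 0))
  expect_equal(gain(10, 0.15), 1)       # sinh(10) * h >> 1
  expect_equal(gain(1e6, 1), 1)         # no overflow past the clamp
  # smooth branch: sinh(x) * h + 0.008
  expect_equal(gain(0.5, 0.1), sinh(0.5) * 0.1 + 0.008)
  expect_true(all(gain(rnorm(100, 0, 3), 0.15) >= 0))
  expect_true(all(gain(rnorm(100, 0, 3), 0.15) <= 1))
})

test_that("pyramidal potential leaks and tracks a constant drive", {
  P <- 4
  par <- ca1_params(pyr_rows = P, pyr_cols = 1, int_rows = 1, int_cols = 1,
                    lambda_noise = 0, tau = 10)
  w <- toy_weights(diag(P), matrix(0, P, P), matrix(0, 1, P),
                   matrix(0, P, 1))
  st <- new_network_state(par)
  st$u_p <- rep(1, P)
  st$a_inp <- rep(0, P)
  # zero drive: homogeneous leak by (1 - dt/tau) per step
  st2 <- step_pyramidal(st, w, rep(0, P), par)
  expect_equal(st2$u_p, rep(1 - 1 / 10, P))
  st3 <- step_pyramidal(st2, w, rep(0, P), par)
  expect_equal(st3$u_p, rep((1 - 1 / 10)^2, P))
  # constant drive D: u converges to D (identity input weights)
  D <- c(0.3, 0.7, 0.2, 0.5)
  st <- new_network_state(par)
  for (i in 1:400) st <- step_pyramidal(st, w, D, par)
  expect_equal(st$u_p, D, tolerance = 1e-8)
})

test_that("interneurons integrate 1.5x slower than pyramidal cells", {
  par <- ca1_params(pyr_rows = 1, pyr_cols = 1, int_rows = 1, int_cols = 1,
                    lambda_noise = 0, tau = 10)
  w <- toy_weights(matrix(1, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1),
                   matrix(0, 1, 1))
  st <- new_network_state(par)
  st$a_p <- 1                       # unit drive to the interneuron
  st$si <- 1                        # pretend unit sensory drive
  st$a_inp <- 1                     # keep the cache consistent
  u_p_track <- u_i_track <- numeric(30)
  for (i in 1:30) {
    st$a_p <- 1                     # hold the drive fixed
    st <- step_interneuron(st, w, par)
    u_i_track[i] <- st$u_i
    # analytic pyramidal reference under the same unit drive
    u_p_track[i] <- 1 - (1 - 1 / 10)^i
  }
  expect_equal(u_i_track[30], 1 - (1 - 1 / 15)^30, tolerance = 1e-10)
  expect_true(all(u_i_track < u_p_track))
  # zero drive decays toward zero
  st$a_p <- 0
  u_prev <- st$u_i
  st <- step_interneuron(st, w, par)
  expect_lt(st$u_i, u_prev)
})

test_that("flux sums absolute changes of synaptic potentials", {
  expect_equal(compute_flux(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(compute_flux(0.5, 0.2), 0.3)
  expect_equal(compute_flux(c(0.3, 0.1), c(0.2, 0.2)), 0.2)
  m_now <- rbind(c(0.3, 0.1), c(0.0, 0.0))
  m_prev <- rbind(c(0.2, 0.2), c(0.0, 0.1))
  expect_equal(compute_flux(m_now, m_prev), c(0.2, 0.1))
})

test_that("noise vanishes once the sensory drive stabilises", {
  P <- 4
  par <- ca1_params(pyr_rows = P, pyr_cols = 1, int_rows = 1, int_cols = 1,
                    lambda_noise = 5, tau = 10)
  w <- toy_weights(init_input_weights(P, P, 1), matrix(0, P, P),
                   matrix(0, 1, P), matrix(0, P, 1))
  st <- new_network_state(par)
  stim <- c(0.5, 0.1, 0.9, 0.3)
  st <- step_pyramidal(st, w, stim, par)   # onset: flux pulse
  expect_true(all(st$flux > 0))
  st <- step_pyramidal(st, w, stim, par)   # held stimulus: flux zero
  expect_equal(st$flux, rep(0, P))
  # with zero flux the update is deterministic despite lambda > 0
  st_a <- step_pyramidal(st, w, stim, par)
  st_b <- step_pyramidal(st, w, stim, par)
  expect_identical(st_a$u_p, st_b$u_p)
})

test_that("novelty circuit matches its truth table on random vectors", {
  theta <- 0.95
  set.seed(42)
  for (i in 1:200) {
    a <- runif(20)
    if (i %% 7 == 0) a[sample(20, 1)] <- theta        # exact boundary
    nov <- novelty_circuit(a, theta)
    expect_identical(nov$a_s, as.integer(a >= theta))
    expect_identical(nov$a_ap, as.integer(any(a >= theta)))
    expect_identical(nov$da, as.integer(!any(a >= theta)))
  }
  # monotonicity: raising an activation never turns dopamine on
  a <- runif(20, 0, 0.9)
  base <- novelty_circuit(a, theta)$da
  a[3] <- 0.99
  expect_lte(novelty_circuit(a, theta)$da, base)
})

test_that("settled potentials match the algebraic fixed point", {
  # 3 pyramidal neurons + 1 interneuron with hand-set weights; the
  # independent oracle solves the steady-state system with pracma::fsolve
  par <- ca1_params(pyr_rows = 3, pyr_cols = 1, int_rows = 1, int_cols = 1,
                    lambda_noise = 0, h = 0.15,
                    settle_eps = 1e-13, t_settle_max = 20000L)
  w_inp <- l2n(rbind(c(0.9, 0.1, 0.2), c(0.2, 0.8, 0.3), c(0.1, 0.3, 0.9)))
  w_pp <- rbind(c(0, 0.4, 0.1), c(0.4, 0, 0.2), c(0.1, 0.2, 0))
  w_pi <- matrix(c(0.5, 0.6, 0.4), 1, 3)
  w_ip <- matrix(c(-0.4, -0.5, -0.3), 3, 1)
  w <- toy_weights(w_inp, w_pp, w_pi, w_ip)
  stim <- c(0.8, 0.5, 0.9)
  st <- new_network_state(par)
  res <- settle(st, w, stim, par)
  expect_true(res$report$converged)

  g <- function(x) gain(x, par$h)
  fp <- function(u) {
    up <- u[1:3]; ui <- u[4]
    c(-up + as.vector(w_inp %*% stim) + as.vector(w_pp %*% g(up)) +
        as.vector(w_ip %*% g(ui)),
      -ui + sum(w_pi * g(up)))
  }
  sol <- pracma::fsolve(fp, rep(0.5, 4))$x
  expect_equal(res$state$u_p, sol[1:3], tolerance = 1e-6)
  expect_equal(res$state$u_i, sol[4], tolerance = 1e-6)
})

test_that("settling is deterministic and repeatable without noise", {
  par <- tiny_params(lambda_noise = 0)
  w <- build_weights(par, seed = 9)
  stim <- gen_digit_like(5, classes = 1, per_class = 1, size = 12)
  stim <- stim$tasks[[1]][[1]]$values
  r1 <- settle(new_network_state(par), w, stim, par)
  r2 <- settle(new_network_state(par), w, stim, par)
  expect_identical(r1$state$u_p, r2$state$u_p)
  expect_identical(r1$report, r2$report)
  # the same stimulus presented again settles on the same peak neuron
  r3 <- settle(r1$state, w, stim, par)
  expect_equal(r3$report$peak_neuron, r1$report$peak_neuron)
})

test_that("activations stay in [0,1] through arbitrary stimulation", {
  par <- tiny_params(lambda_noise = 2)   # exaggerated noise
  w <- build_weights(par, seed = 2)
  st <- new_network_state(par)
  set.seed(1)
  for (i in 1:60) {
    stim <- runif(144, 0, 1)
    st <- step_pyramidal(st, w, stim, par)
    st <- step_interneuron(st, w, par)
    expect_true(all(st$a_p >= 0 & st$a_p <= 1))
    expect_true(all(st$a_i >= 0 & st$a_i <= 1))
  }
})

test_that("a blank stimulus leaves every neuron below threshold", {
  par <- tiny_params()
  w <- build_weights(par, seed = 6)
  set.seed(3)
  res <- settle(new_network_state(par), w, rep(0, 144), par)
  expect_true(all(res$state$a_p < par$theta_minus))
  expect_equal(res$report$da, 1L)
})
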