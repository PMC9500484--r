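# small model configurations used across tests; geometry keeps the ~9:1
# pyramidal:interneuron ratio of the full-size model
tiny_params <- function(...) {
  ca1_params(pyr_rows = 12L, pyr_cols = 12L, int_rows = 4L, int_cols = 4L,
             h = 0.15, s1_pi = 0.02, ...)
}

small_params <- function(...) {
  ca1_params(pyr_rows = 20L, pyr_cols = 20L, int_rows = 7L, int_cols = 7L,
             h = 0.15, s1_pi = 0.02, ...)
}

l2n <- function(m) m / sqrt(rowSums(m^2))

# brute-force toroidal distance: minimum over the 9 periodic images
brute_torus_distance <- function(p, q, period) {
  best <- Inf
  for (dr in c(-period[1], 0, period[1])) {
    for (dc in c(-period[2], 0, period[2])) {
      best <- min(best, sqrt(sum((p - (q + c(dr, dc)))^2)))
    }
  }
  best
}
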