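# Shared fixtures: all built in code at test time.

noiseless_config <- function(preset = "default", seed = 1) {
  generator_config(preset, seed = seed, raman_noise_sd = 0, image_noise_sd = 0)
}

# a flat-color pattern (every pixel of every channel at `value`)
uniform_pattern <- function(value = 77, size = 128) {
  arr <- array(value, dim = c(size, size, 3))
  list(ambient = arr, uv = arr,
       geometry = list(size = size, center = c(size / 2, size / 2),
                       radius = 40, ring_width = 6))
}

# small deterministic regression problem: one informative predictor
informative_toy <- function() {
  X <- cbind(v1 = c(0.1, -0.2, 0.05, -0.1, 0.15, -0.05),
             v2 = c(1, 2, 3, 4, 5, 6),
             v3 = c(-0.12, 0.08, 0.02, -0.06, 0.1, -0.02),
             v4 = c(0.07, -0.11, 0.04, 0.09, -0.03, -0.06))
  y <- 2 * X[, "v2"] + c(0.01, -0.02, 0.015, -0.005, 0.02, -0.01)
  list(X = X, y = y)
}

# subset a feature block's rows without reaching into package internals
block_rows_public <- function(block, idx) {
  block$x <- block$x[idx, , drop = FALSE]
  block
}

# direct (brute-force) evaluation of the VIP formula from a model's
# stored matrices, independent of compute_vip()'s vectorized path
vip_by_hand <- function(model) {
  W <- model$weights
  ssy <- model$ssy
  p <- nrow(W)
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(ncol(W))) {
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    }
    out[j] <- sqrt(p * acc / sum(ssy))
  }
  out
}
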