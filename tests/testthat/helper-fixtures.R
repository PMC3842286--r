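# fixture builders shared across test files; everything is generated in code

# analytic Gaussian blob frame, quantized to 8 bits like the renderer
blob_frame <- function(cx, cy, sigma = 1.8, amp = 200, h = 64, w = 64) {
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  img <- amp * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma^2))
  matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
}

# textured random frame (reproducible)
noise_frame <- function(h = 64, w = 64, seed = 1, sd = 60, mean = 120) {
  set.seed(seed)
  matrix(as.integer(pmin(255, pmax(0, round(rnorm(h * w, mean, sd))))), h, w)
}

# shift a frame by integer (dx, dy) px, zero-filling the uncovered strip;
# positive dx moves content rightward (+x), positive dy downward
shift_frame <- function(f, dx, dy) {
  h <- nrow(f); w <- ncol(f)
  g <- matrix(0L, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  g[which(ok_r), which(ok_c)] <- f[src_r[ok_r], src_c[ok_c]]
  g
}

# quiet, small sneeze-like config for fast tests
small_sneeze_config <- function(noise_sd = 0, ...) {
  synth_config(frame_width = 320, frame_height = 160, duration = 0.2,
               n_particles = 25, n_large_droplets = 0, noise_sd = noise_sd,
               mouth_position = c(15, 80), seed = 11, ...)
}

# full study-conditions sneeze (the conditions the pipeline targets)
study_sneeze_config <- function(seed = 42, ...) {
  synth_config(seed = seed, ...)
}

study_cough_config <- function(seed = 43, ...) {
  synth_config(A = 1100, k = 32, c = 27, convection_velocity = 27,
               seed = seed, ...)
}
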