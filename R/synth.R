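#' Configuration for the synthetic expiratory-plume generator
#'
#' Defines the study conditions for a simulated particle cloud expelled
#' horizontally from the mouth, whose front-line velocity follows
#' \eqn{V_h(t) = A e^{-kt} + c}. Defaults reproduce the recording geometry of
#' the high-speed setup the pipeline targets: 300 frames/s, 640x400 px,
#' 21 px = 4.4 cm (pixel_size 4.4/21 cm), 0.4 s of footage (120 frames).
#'
#' Interior particles travel slower than the front: each receives a velocity
#' scale factor drawn uniformly from \[0.5, 1\], the front particle forced to
#' 1. Once a particle's decaying velocity term falls below
#' `momentum_floor` it stops advancing ballistically and performs a random
#' walk (Gaussian steps of sd `diffusion_sd * sqrt(dt)`) plus a uniform
#' `convection_velocity` drift — the diffusion regime seen after momentum
#' loss. Large droplets additionally fall at their Stokes settling velocity
#' and model the fast-falling fraction excluded from front-line analysis.
#'
#' @param A,k,c decay-model coefficients (cm/s, 1/s, cm/s); sneeze defaults
#'   A = 1500, k = 22, c = 0.
#' @param frame_rate frames per second.
#' @param frame_width,frame_height frame size in px.
#' @param pixel_size calibration, cm per px (default 4.4/21).
#' @param duration clip length, s; `duration * frame_rate` must be an
#'   integer frame count within rounding.
#' @param n_particles number of fine particles (including the front one).
#' @param particle_radius_range Gaussian blob sigma range, px (min 1).
#' @param intensity_range peak blob intensity range, 0-255.
#' @param noise_sd additive Gaussian sensor noise sd, intensity units.
#' @param convection_velocity uniform ambient drift applied in the diffusion
#'   regime, cm/s (positive = along the expectoration direction).
#' @param n_large_droplets number of large fast-falling droplets.
#' @param large_droplet_diameter their aerodynamic diameter, µm.
#' @param diffusion_sd random-walk scale after momentum loss, cm/sqrt(s).
#' @param momentum_floor velocity (cm/s) below which the decaying term hands
#'   the particle over to the diffusion regime.
#' @param mouth_position (x, y) of the mouth in px (0-based).
#' @param seed integer seed; the single source of randomness.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(A = 1500, k = 22, c = 0,
                         frame_rate = 300,
                         frame_width = 640, frame_height = 400,
                         pixel_size = 4.4 / 21,
                         duration = 0.4,
                         n_particles = 80,
                         particle_radius_range = c(1.2, 2.2),
                         intensity_range = c(120, 220),
                         noise_sd = 2,
                         convection_velocity = 0,
                         n_large_droplets = 3,
                         large_droplet_diameter = 400,
                         diffusion_sd = 5,
                         momentum_floor = 15,
                         mouth_position = c(30, 200),
                         seed = 1L) {
  cfg <- list(A = A, k = k, c = c, frame_rate = frame_rate,
              frame_width = as.integer(frame_width),
              frame_height = as.integer(frame_height),
              pixel_size = pixel_size, duration = duration,
              n_particles = as.integer(n_particles),
              particle_radius_range = particle_radius_range,
              intensity_range = intensity_range,
              noise_sd = noise_sd,
              convection_velocity = convection_velocity,
              n_large_droplets = as.integer(n_large_droplets),
              large_droplet_diameter = large_droplet_diameter,
              diffusion_sd = diffusion_sd,
              momentum_floor = momentum_floor,
              mouth_position = mouth_position,
              seed = as.integer(seed))
  if (cfg$A <= 0 || cfg$k <= 0 || cfg$c < 0)
    stop("synth_config: require A > 0, k > 0, c >= 0")
  if (cfg$frame_rate <= 0 || cfg$pixel_size <= 0)
    stop("synth_config: frame_rate and pixel_size must be > 0")
  if (cfg$duration <= 0)
    stop("synth_config: duration must be > 0")
  nf <- cfg$duration * cfg$frame_rate
  if (abs(nf - round(nf)) > 1e-6)
    stop("synth_config: duration * frame_rate must be an integer frame count")
  if (cfg$n_particles < 1L)
    stop("synth_config: n_particles must be >= 1")
  if (min(cfg$particle_radius_range) < 1)
    stop("synth_config: particle radii must be >= 1 px")
  if (length(cfg$mouth_position) != 2L)
    stop("synth_config: mouth_position must be (x, y)")
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate particle trajectories of an expelled cloud
#'
#' Generates ground-truth trajectories sampled exactly at the frame
#' timestamps. The front (maximal-x) particle moves with horizontal velocity
#' \eqn{A e^{-kt} + c}; interior particles move with per-particle scaled
#' velocities \eqn{s_i (A e^{-kt} + c)}, \eqn{s_i \in (0, 1]}. While a
#' particle's decaying term \eqn{s_i A e^{-kt}} stays above `momentum_floor`
#' its position is the analytic integral of its velocity; afterwards it
#' switches to diffusion (Gaussian increments plus convection drift). Large
#' droplets also fall at their Stokes settling velocity throughout.
#'
#' Random draws, in order, from one stream seeded with `config$seed`:
#' velocity scales, initial x offsets, initial y offsets (fine particles,
#' then droplets), then per-frame diffusion increments (x then y, particle
#' order) for particles in the diffusion regime.
#'
#' @param config a [synth_config()].
#' @return A `ground_truth` list: `trajectories` (data frame with columns
#'   `particle_id`, `class`, `t_s`, `x_cm`, `y_cm`; coordinates are cm from
#'   the mouth, x along the expectoration direction, y downward),
#'   `front_position` and `front_velocity` (per-frame, cm and cm/s),
#'   `timestamps`, `scales`, and the config echo.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$duration <= 0 || config$n_particles == 0L)
    stop("simulate_trajectories: invalid configuration")
  n_frames <- round(config$duration * config$frame_rate)
  dt <- 1 / config$frame_rate
  ts <- (seq_len(n_frames) - 1L) * dt
  n_fine <- config$n_particles
  n_drop <- config$n_large_droplets
  n <- n_fine + n_drop

  set.seed(config$seed)
  scales <- runif(n, 0.5, 1.0)
  scales[1L] <- 1.0                      # the front particle
  if (n_drop > 0)                        # droplets lag the front
    scales[n_fine + seq_len(n_drop)] <- runif(n_drop, 0.3, 0.6)
  x0 <- runif(n, 0, 1.5)
  x0[1L] <- 1.6                          # front particle starts ahead
  y0 <- c(rnorm(n_fine, 0, 2.5),
          if (n_drop > 0) rnorm(n_drop, 8, 1.5) else numeric(0))
  y0[1L] <- 0

  v_settle <- if (n_drop > 0)
    as.numeric(settling_velocity(config$large_droplet_diameter)) else 0
  cls <- c(rep("fine", n_fine), rep("large-droplet", n_drop))

  # analytic ballistic position: x0 + s*[(A/k)(1 - e^{-kt}) + c t]
  ballistic_x <- function(i, t)
    x0[i] + scales[i] * ((config$A / config$k) * (1 - exp(-config$k * t)) +
                           config$c * t)
  # switch time: s*A*e^{-kt} = floor (never, if the floor is 0 or below)
  t_switch <- if (config$momentum_floor <= 0) rep(Inf, n) else
    ifelse(scales * config$A > config$momentum_floor,
           log(scales * config$A / config$momentum_floor) / config$k,
           0)

  x <- matrix(0, n_frames, n)
  y <- matrix(rep(y0, each = n_frames), n_frames, n)
  for (i in seq_len(n)) x[, i] <- ballistic_x(i, ts)
  if (n_drop > 0)
    y[, n_fine + seq_len(n_drop)] <- y[, n_fine + seq_len(n_drop)] +
      outer(ts, rep(v_settle, n_drop))

  # diffusion regime: overwrite frames past each particle's switch time
  sd_step <- config$diffusion_sd * sqrt(dt)
  for (j in 2:n_frames) {
    in_diff <- ts[j] > t_switch
    if (!any(in_diff)) next
    idx <- which(in_diff)
    stepx <- rnorm(length(idx), config$convection_velocity * dt, sd_step)
    stepy <- rnorm(length(idx), 0, sd_step)
    for (m in seq_along(idx)) {
      i <- idx[m]
      base_x <- if (ts[j - 1L] <= t_switch[i]) ballistic_x(i, t_switch[i])
                else x[j - 1L, i]
      x[j, i] <- base_x + stepx[m] +
        if (ts[j - 1L] <= t_switch[i])
          config$convection_velocity * (ts[j] - t_switch[i] - dt) else 0
      y[j, i] <- y[j - 1L, i] + stepy[m] +
        (if (cls[i] == "large-droplet") v_settle * dt else 0)
    }
  }

  traj <- data.frame(
    particle_id = rep(seq_len(n), each = n_frames),
    class = rep(cls, each = n_frames),
    t_s = rep(ts, n),
    x_cm = as.vector(x),
    y_cm = as.vector(y))

  front_v <- config$A * exp(-config$k * ts) + config$c
  front_v[ts > t_switch[1L]] <- NA_real_   # diffusion-dominated afterwards
  structure(list(trajectories = traj,
                 front_position = x[, 1L],
                 front_velocity = front_v,
                 timestamps = ts,
                 scales = scales,
                 t_switch = t_switch,
                 config = config),
            class = "ground_truth")
}

#' Render a trajectory set to a grayscale frame sequence
#'
#' Each particle becomes an isotropic Gaussian intensity blob at its (x, y)
#' position converted to pixel coordinates relative to `mouth_position`.
#' Additive Gaussian sensor noise (sd `noise_sd`) is applied, then values
#' are clipped to \[0, 255\] and quantized to 8 bits. Particles outside the
#' frame are simply not rendered. Blob sizes and peak intensities are drawn
#' once per particle from a stream seeded with `seed + 1` (independent of
#' the trajectory stream so re-rendering is reproducible on its own).
#'
#' @param truth a `ground_truth` from [simulate_trajectories()].
#' @param config the same [synth_config()].
#' @return A [frame_sequence()] of `round(duration * frame_rate)` frames.
#' @export
render_frames <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  n_frames <- length(truth$timestamps)
  W <- config$frame_width; H <- config$frame_height
  n <- if (nrow(truth$trajectories) == 0) 0L else
    max(truth$trajectories$particle_id)
  cls <- truth$trajectories$class[match(seq_len(n),
                                        truth$trajectories$particle_id)]

  set.seed(config$seed + 1L)
  sigma <- runif(n, config$particle_radius_range[1],
                 config$particle_radius_range[2])
  sigma[cls == "large-droplet"] <- sigma[cls == "large-droplet"] + 1.5
  amp <- runif(n, config$intensity_range[1], config$intensity_range[2])

  xs <- matrix(truth$trajectories$x_cm, nrow = n_frames)
  ys <- matrix(truth$trajectories$y_cm, nrow = n_frames)
  frames <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    img <- matrix(0, H, W)
    px <- config$mouth_position[1] + xs[j, ] / config$pixel_size
    py <- config$mouth_position[2] + ys[j, ] / config$pixel_size
    for (i in seq_len(n)) {
      r <- ceiling(4 * sigma[i])
      c0 <- floor(px[i]) - r; c1 <- floor(px[i]) + r + 1L
      r0 <- floor(py[i]) - r; r1 <- floor(py[i]) + r + 1L
      if (c1 < 0 || c0 > W - 1L || r1 < 0 || r0 > H - 1L) next
      cc <- max(c0, 0L):min(c1, W - 1L)
      rr <- max(r0, 0L):min(r1, H - 1L)
      blob <- amp[i] * exp(-(outer((rr - py[i])^2, (cc - px[i])^2, "+")) /
                             (2 * sigma[i]^2))
      img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] + blob
    }
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
    frames[[j]] <- matrix(as.integer(pmin(255, pmax(0, round(img)))), H, W)
  }
  frame_sequence(frames, dt = 1 / config$frame_rate,
                 pixel_size = config$pixel_size,
                 mouth_position = config$mouth_position)
}

#' Write ground truth to CSV with a JSON config sidecar
#'
#' @param truth a `ground_truth`.
#' @param path output CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(truth$trajectories, path, row.names = FALSE)
  cfg <- unclass(truth$config)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
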