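# a hand-built vector field row, defaulting to a valid horizontal vector
vf_row <- function(t = 0.1, cx = 100, cy = 50, vx = 100, vy = 0,
                   valid = TRUE) {
  data.frame(frame_index = 1L, t_s = t, cx_px = cx, cy_px = cy,
             dx_px = vx / (4.4 / 21) / 300, dy_px = vy / (4.4 / 21) / 300,
             vx_cms = vx, vy_cms = vy, peak = 0.95, valid = valid,
             excluded = FALSE, abandonment_count = 0L,
             reduced_precision = FALSE)
}

as_field <- function(df, mouth = c(0, 50), px = 4.4 / 21) {
  attr(df, "pixel_size") <- px
  attr(df, "mouth_position") <- mouth
  attr(df, "dt") <- 1 / 300
  df
}

test_that("Stokes settling velocity follows the d-squared law", {
  v10 <- settling_velocity(10)
  expect_equal(as.numeric(v10), 0.303, tolerance = 1e-3)
  expect_true(attr(v10, "stokes_ok"))

  # vanishing diameter: velocity vanishes quadratically
  expect_lt(as.numeric(settling_velocity(1e-3)), 1e-8)

  # 300 um droplet: fast-falling, outside the Stokes regime
  v300 <- settling_velocity(300)
  expect_gt(as.numeric(v300), 200)
  expect_false(attr(v300, "stokes_ok"))
  expect_gt(attr(v300, "reynolds"), 1)

  expect_error(settling_velocity(0), "> 0")
  expect_error(settling_velocity(10, density = -1), "> 0")
})

test_that("droplet exclusion filters on fall speed and nothing else", {
  field <- as_field(rbind(vf_row(cx = 50), vf_row(cx = 100),
                          vf_row(cx = 150, vy = 400)))
  # all-horizontal field: nothing excluded
  horiz <- exclude_fast_falling(as_field(rbind(vf_row(), vf_row(cx = 80))),
                                300)
  expect_false(any(horiz$excluded))

  out <- exclude_fast_falling(field, 300)
  expect_equal(which(out$excluded), 3L)
  # retained vectors are untouched (pure filtering)
  expect_identical(out[1:2, setdiff(names(out), "excluded")],
                   field[1:2, setdiff(names(field), "excluded")])
})

test_that("droplet-dominated windows are excluded on synthetic ground truth", {
  cfg <- synth_config(frame_width = 360, frame_height = 260,
                      n_particles = 30, n_large_droplets = 3, noise_sd = 0,
                      duration = 0.2, mouth_position = c(15, 60), seed = 17)
  truth <- simulate_trajectories(cfg)
  seq <- render_frames(truth, cfg)
  i <- 16L   # t ~ 0.05 s: droplets still in frame and falling fast
  vf <- compute_vector_field(seq$frames[[i]], seq$frames[[i + 1]],
                             dt = seq$dt, pixel_size = seq$pixel_size,
                             t_mid = (i - 0.5) * seq$dt)
  vf <- exclude_fast_falling(vf, 300)

  tr <- truth$trajectories
  drop_now <- tr[tr$class == "large-droplet" & tr$t_s == truth$timestamps[i], ]
  drop_px <- cbind(cfg$mouth_position[1] + drop_now$x_cm / cfg$pixel_size,
                   cfg$mouth_position[2] + drop_now$y_cm / cfg$pixel_size)
  in_frame <- drop_px[, 1] >= 0 & drop_px[, 1] < cfg$frame_width &
    drop_px[, 2] >= 0 & drop_px[, 2] < cfg$frame_height
  expect_gt(sum(in_frame), 0)
  for (d in which(in_frame)) {
    win <- which(abs(vf$cx_px - drop_px[d, 1]) <= 10.5 &
                   abs(vf$cy_px - drop_px[d, 2]) <= 10.5 & vf$valid)
    if (length(win)) expect_true(all(vf$excluded[win]))
  }
  # fine-particle windows are not excluded
  expect_false(all(vf$excluded[vf$valid]))
})

test_that("front-line extraction picks the distal margin inside the window", {
  single <- as_field(vf_row(t = 0.1, cx = 120, vx = 250))
  fl <- extract_frontline(single, window = c(0.04, 0.20))
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$vh_cms, 250)
  expect_equal(fl$h_cm, 120 * 4.4 / 21)

  # several vectors per instant: the farthest wins; window bounds respected
  field <- as_field(rbind(
    vf_row(t = 0.05, cx = 100, vx = 300), vf_row(t = 0.05, cx = 140, vx = 280),
    vf_row(t = 0.10, cx = 150, vx = 150), vf_row(t = 0.10, cx = 80, vx = 200),
    vf_row(t = 0.30, cx = 400, vx = 999)))  # outside the window
  fl2 <- extract_frontline(field, window = c(0.04, 0.20))
  expect_equal(nrow(fl2), 2L)
  expect_true(all(fl2$t_s >= 0.04 & fl2$t_s <= 0.20))
  expect_equal(fl2$vh_cms, c(280, 150))

  # invalid-only input: informative failure
  empty <- as_field(vf_row(valid = FALSE))
  expect_error(extract_frontline(empty, window = c(0.04, 0.20)),
               "no qualifying vectors")
})

test_that("extracted front velocity follows the decay law on clean footage", {
  cfg <- synth_config(n_particles = 60, n_large_droplets = 0, noise_sd = 0,
                      duration = 0.25, seed = 23)
  truth <- simulate_trajectories(cfg)
  seq <- render_frames(truth, cfg)
  mid <- (seq_len(length(seq) - 1) - 0.5) * seq$dt
  pairs <- which(mid >= 0.04 - seq$dt & mid <= 0.20 + seq$dt)
  field <- track_sequence(seq, pairs = pairs)
  fl <- extract_frontline(field, window = c(0.04, 0.20))

  v_true <- cfg$A * exp(-cfg$k * fl$t_s) + cfg$c
  expect_true(all(abs(fl$vh_cms - v_true) / v_true < 0.10))
  # the distal margin advances monotonically on noiseless input
  expect_true(all(diff(fl$h_cm) >= 0))

  # the selected window tracks the true front to within one window width
  h_true <- approx(truth$timestamps, truth$front_position, xout = fl$t_s)$y
  expect_true(all(abs(fl$h_cm - h_true) <= 1.5 * 21 * cfg$pixel_size))
})

test_that("the velocity map conserves vector counts", {
  field <- as_field(rbind(vf_row(t = 0.05, cx = 100), vf_row(t = 0.05, cx = 60),
                          vf_row(t = 0.06, cx = 110),
                          vf_row(t = 0.06, valid = FALSE)))
  vm <- export_velocity_map(field)
  expect_equal(nrow(vm), 3L)

  none <- as_field(vf_row(valid = FALSE))
  expect_equal(nrow(export_velocity_map(none)), 0L)
})

test_that("early in the cloud the fastest vectors sit at the front", {
  cfg <- synth_config(n_particles = 60, n_large_droplets = 0, noise_sd = 0,
                      duration = 0.15, seed = 29)
  seq <- render_frames(simulate_trajectories(cfg), cfg)
  i <- 15L   # ~0.05 s
  vf <- compute_vector_field(seq$frames[[i]], seq$frames[[i + 1]],
                             dt = seq$dt, pixel_size = seq$pixel_size,
                             t_mid = (i - 0.5) * seq$dt)
  attr(vf, "mouth_position") <- cfg$mouth_position
  vm <- export_velocity_map(vf)
  vm <- vm[vm$h_cm > 0, ]
  expect_equal(which.max(vm$vh_cms), which.max(vm$h_cm))
})
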