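#!/usr/bin/env Rscript
# Stage 2: PIV tracking and front-line extraction.
#
# Loads the frames written by 01_simulate.R, tracks consecutive pairs with
# 21x21 px interrogation windows (ZNCC + subpixel Gaussian interpolation +
# successive abandonment), excludes fast-falling large droplets (> 300 µm
# by settling velocity) and reduces each frame to its distal-margin point.
# Analysis windows: 0.04-0.20 s (sneeze; the first 0.04 s are too dense to
# track single particles) and 0.03-0.20 s (cough).

library(plumekin)

runs <- list(
  sneeze = list(window = c(0.04, 0.20), mouth = c(30, 200)),
  cough  = list(window = c(0.03, 0.20), mouth = c(30, 200)))

for (label in names(runs)) {
  run <- runs[[label]]
  seq <- load_frames(file.path("scratch", "frames", label, "frame_*.png"),
                     dt = 1 / 300, pixel_size = 4.4 / 21,
                     mouth_position = run$mouth)
  mid <- (seq_len(length(seq) - 1) - 0.5) * seq$dt
  pairs <- which(mid >= run$window[1] - seq$dt & mid <= run$window[2] + seq$dt)
  field <- track_sequence(seq, interrogation_grid(), pairs = pairs)
  field <- exclude_fast_falling(field, diameter_cutoff_um = 300)
  fl <- extract_frontline(field, window = run$window, label = label)
  vm <- export_velocity_map(field)

  write.csv(as.data.frame(field),
            file.path("results", paste0("vector_field_", label, ".csv")),
            row.names = FALSE)
  write_frontline(fl, file.path("results", paste0("frontline_", label, ".csv")))
  write.csv(vm, file.path("results", paste0("velocity_map_", label, ".csv")),
            row.names = FALSE)
  cat(sprintf(
    "%s: %d pairs tracked, %d/%d vectors valid, %d excluded as droplets, %d front points\n",
    label, length(pairs), sum(field$valid), nrow(field),
    sum(field$excluded), nrow(fl)))
  cat(sprintf("  front Vh spans %.0f -> %.0f cm/s over %.2f-%.2f s\n",
              fl$vh_cms[1], fl$vh_cms[nrow(fl)], min(fl$t_s), max(fl$t_s)))
}
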