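#!/usr/bin/env Rscript
# Stage 1: generate the study footage.
#
# Two synthetic recordings at the target acquisition geometry (300 frames/s,
# 640x400 px, 21 px = 4.4 cm, 0.4 s = 120 frames):
#   - a sneeze-like event: front velocity 1500*exp(-22 t) cm/s, still room;
#   - a cough-like event:  front velocity 1100*exp(-32 t) + 27 cm/s, in a
#     room with a ~27 cm/s draught along the expectoration direction.
# Ground-truth trajectories go to results/, the 8-bit frames to scratch/.

library(plumekin)

configs <- list(
  sneeze = synth_config(A = 1500, k = 22, c = 0, seed = 42),
  cough  = synth_config(A = 1100, k = 32, c = 27,
                        convection_velocity = 27, seed = 43))

dir.create("results", showWarnings = FALSE)
for (label in names(configs)) {
  cfg <- configs[[label]]
  truth <- simulate_trajectories(cfg)
  seq <- render_frames(truth, cfg)
  write_ground_truth(truth, file.path("results",
                                      paste0("ground_truth_", label, ".csv")))
  frame_dir <- file.path("scratch", "frames", label)
  write_frames(seq, frame_dir)
  cat(sprintf(
    "%s: %d frames (%.2f s at %g fps), %d fine particles + %d droplets -> %s\n",
    label, length(seq), cfg$duration, cfg$frame_rate, cfg$n_particles,
    cfg$n_large_droplets, frame_dir))
  cat(sprintf("  front reaches %.1f cm; momentum-loss switch at %.3f s\n",
              max(truth$front_position), truth$t_switch[1]))
}
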