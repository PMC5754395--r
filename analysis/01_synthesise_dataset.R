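#!/usr/bin/env Rscript
# Build the reduced lip model and a small labelled synthetic dataset
# (2 instructions x 2 repetitions, cross-talk 0.1, noise floor on), with
# reference trajectories simulated by the model itself, and persist
# everything under results/dataset/.

suppressPackageStartupMessages(library(lipmaps))

out_dir <- "results/dataset"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

model <- build_lip_mesh(mesh_config(nx = 8, ny = 2))
print(model)
write_lip_mesh(model, file.path(out_dir, "lip_mesh.vtk"))

ds <- make_dataset(instructions_used = c("A", "B"), repetitions = 2,
                   seed = 1, model = model, xtalk = crosstalk_model(0.1, 0.5))
cat(sprintf("generated %d records; adapted sigma_max = %.1f kPa\n",
            length(ds), attr(ds, "sigma_max_kpa")))

for (i in seq_along(ds)) {
  rec <- ds[[i]]
  tag <- sprintf("%s_r%d", rec$recording$instruction,
                 rec$recording$repetition)
  write_recording(rec$recording, file.path(out_dir,
                                           sprintf("semg_%s.csv", tag)))
  write_trajectories(rec$trajectories,
                     file.path(out_dir, sprintf("markers_%s.csv", tag)))
  peak <- max(abs(rec$truth$model))
  cat(sprintf("  %s: peak truth activation %.2f, %d sEMG samples\n",
              tag, peak, ncol(rec$recording$samples)))
}
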