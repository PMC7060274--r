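#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analysis scripts consume,
# through the validated stage runner so each dataset lands next to its
# ground-truth sidecar and a run manifest. Run from the repository root:
#   Rscript analysis/01_simulate.R

suppressPackageStartupMessages(library(cmquant))

data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

# striated images across the dispersion sweep used by 02_structure.R
for (disp in c(0, 10, 20, 40, 60)) {
  run_stage(list(stage = "generate_striated", spacing_um = 2,
                 pixel_size_um = 0.1, dispersion_deg = disp,
                 seed = 100L + disp,
                 out_dir = file.path(data_dir, sprintf("striated_d%02d", disp))))
}

# a paced calcium trace at SNR 10 (noise_sd 15 on a baseline-100,
# amplitude-1.5 transient) and a noise-free reference
run_stage(list(stage = "generate_calcium", seed = 201L, noise_sd = 15,
               out_dir = file.path(data_dir, "calcium_snr10")))
run_stage(list(stage = "generate_calcium", seed = 202L,
               out_dir = file.path(data_dir, "calcium_clean")))

# one noise-free OCR well plus three replicate noisy wells
run_stage(list(stage = "generate_ocr", basal = 100, atp_linked = 60,
               proton_leak = 30, maximal = 150, nonmito = 10, seed = 301L,
               out_dir = file.path(data_dir, "ocr_clean")))
for (w in 1:3) {
  run_stage(list(stage = "generate_ocr", basal = 100, atp_linked = 60,
                 proton_leak = 30, maximal = 150, nonmito = 10,
                 noise_sd = 5, seed = 310L + w,
                 out_dir = file.path(data_dir, sprintf("ocr_well%d", w))))
}

# cytometry: a day-28-like 70%-positive sample, a day-10-like mostly
# negative sample, and an unstained control
run_stage(list(stage = "generate_cytometry", n_events = 10000,
               positive_fraction = 0.7, pos_location = 3.5,
               pos_scale = 0.25, seed = 401L,
               out_dir = file.path(data_dir, "cytometry_day28")))
run_stage(list(stage = "generate_cytometry", n_events = 10000,
               positive_fraction = 0.005, pos_location = 3.5,
               pos_scale = 0.25, seed = 402L,
               out_dir = file.path(data_dir, "cytometry_day10")))
run_stage(list(stage = "generate_cytometry", n_events = 10000,
               positive_fraction = 0, seed = 403L,
               out_dir = file.path(data_dir, "cytometry_control")))

# contraction movie and labelled cell populations are generated in their
# analysis scripts (the movie array and label masks are intermediate data;
# only their derived tables are kept under results/)
message("simulation inputs written under ", data_dir)
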