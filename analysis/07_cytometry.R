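#!/usr/bin/env Rscript
# Fluorescence gating of the stored cytometry samples against the
# unstained control. Requires 01_simulate.R. Run:
#   Rscript analysis/07_cytometry.R

suppressPackageStartupMessages(library(cmquant))
data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

control <- file.path(data_dir, "cytometry_control", "events.csv")
rows <- do.call(rbind, lapply(c("cytometry_day10", "cytometry_day28"),
                              function(d) {
  outs <- run_stage(list(stage = "cytometry",
                         sample = file.path(data_dir, d, "events.csv"),
                         control = control,
                         out_dir = file.path(data_dir, d, "gate")))
  g <- read_numeric_csv(outs[["gate"]])
  cbind(data.frame(sample = d), g)
}))
write_table(rows, "results/cytometry_gates.csv")
message(sprintf("percent positive: %s",
                paste(sprintf("%s %.2f%%", rows$sample,
                              100 * rows$fraction_positive),
                      collapse = ", ")))
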