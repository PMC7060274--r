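#!/usr/bin/env Rscript
# Calcium-transient kinetics: stage-runner pass over the stored traces and
# a 100-trace recovery experiment at SNR 10. Requires 01_simulate.R. Run:
#   Rscript analysis/04_calcium.R

suppressPackageStartupMessages(library(cmquant))
data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

for (d in c("calcium_clean", "calcium_snr10")) {
  run_stage(list(stage = "calcium",
                 trace = file.path(data_dir, d, "calcium_trace.csv"),
                 pacing_hz = 1,
                 out_dir = file.path(data_dir, d, "metrics")))
}
clean <- read_numeric_csv(
  file.path(data_dir, "calcium_clean", "metrics", "calcium_summary.csv"),
  "mean")

# recovery of time to peak, amplitude and decay time over 100 seeded
# traces at SNR 10 (noise sd 15 on a peak signal of 150)
recovery <- do.call(rbind, lapply(1:100, function(s) {
  g <- gen_calcium_trace(trace_spec(noise_sd = 15, seed = 5000L + s))
  tm <- transient_metrics(compute_dff(g$trace, pacing_hz = 1))
  sm <- tm$summary
  est <- sm$mean[match(c("time_to_peak", "peak_amplitude", "decay_time"),
                       sm$metric)]
  truth <- c(g$truth$rise_time, g$truth$amplitude,
             g$truth$decay_tau * log(10))
  data.frame(seed = 5000L + s,
             metric = c("time_to_peak", "peak_amplitude", "decay_time"),
             estimate = est, truth = truth,
             rel_err = abs(est - truth) / truth)
}))
write_table(recovery, "results/calcium_recovery.csv")

med <- aggregate(rel_err ~ metric, recovery, median)
write_table(med, "results/calcium_recovery_medians.csv")
message(sprintf(
  "noise-free decay time %.4f s; median rel errors: %s",
  clean$mean[clean$metric == "decay_time"],
  paste(sprintf("%s %.1f%%", med$metric, 100 * med$rel_err),
        collapse = ", ")))
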