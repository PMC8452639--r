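#!/usr/bin/env Rscript

# Step 1: generate the synthetic recordings the rest of the analysis
# consumes -- patch-clamp EPSC/IPSC traces under control and NMDAR-antibody
# conditions, and a field recording with interictal transients and one
# ictal epoch. Traces and ground truth go to results/recordings/.

suppressPackageStartupMessages(library(epicmc))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[1] else 1)

out <- "results/recordings"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat("== synthetic recordings (seed", seed, ") ==\n")

base <- synaptic_trace_config(duration = 120, seed = seed)
conditions <- list(
  epsc_control = condition_effects("control", "EPSC"),
  epsc_nmdar_48h = condition_effects("nmdar_48h", "EPSC"),
  epsc_nmdar_7d = condition_effects("nmdar_7d", "EPSC"),
  ipsc_control = condition_effects("control", "IPSC"),
  ipsc_nmdar_48h = condition_effects("nmdar_48h", "IPSC"))

for (nm in names(conditions)) {
  cfg <- make_condition_config(base, conditions[[nm]])
  cfg$seed <- seed + match(nm, names(conditions))
  r <- render_synaptic_trace(cfg)
  write_trace(r$trace, file.path(out, paste0(nm, ".txt")))
  write_ground_truth(r$truth, file.path(out, paste0(nm, "_truth.json")))
  cat(sprintf("  %-16s %4d events, rate %.2f/s\n", nm,
              length(r$truth$event_times),
              length(r$truth$event_times) / cfg$duration))
}

field_cfg <- field_trace_config(
  duration = 300, spike_rate = 0.4, spike_amp_factor = 8,
  ictal_epochs = data.frame(start = 180, end = 220, beta_amp = 40,
                            spike_rate_mult = 4),
  seed = seed)
fr <- render_field_trace(field_cfg)
write_trace(fr$trace, file.path(out, "field.txt"))
write_ground_truth(fr$truth, file.path(out, "field_truth.json"))
cat(sprintf("  field recording: %d transients, 1 ictal epoch (180-220 s)\n",
            length(fr$truth$event_times)))
cat("wrote", out, "\n")
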