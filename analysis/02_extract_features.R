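#!/usr/bin/env Rscript

# Step 2: operational metrics on the step-1 recordings. Patch traces yield
# synaptic feature sets and the NMDAR/control contrast that seeds the
# microcircuit priors; the field trace yields event counts, interevent
# intervals, coastline and band power, plus a segment-library
# classification of the ictal epoch.

suppressPackageStartupMessages(library(epicmc))
rec <- "results/recordings"
out <- "results/features"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
stopifnot(file.exists(file.path(rec, "epsc_control.txt")))

cat("== feature extraction ==\n")

## patch-clamp features per condition
feature_row <- function(name) {
  f <- extract_synaptic_features(read_trace(file.path(rec,
                                                      paste0(name, ".txt"))),
                                 polarity = "inward")
  data.frame(condition = name, n_events = f$n_events,
             mean_amplitude_pA = f$mean_amplitude,
             mean_iei_ms = mean(f$ieis), decay_tau_ms = f$decay_tau,
             half_life_ms = f$half_life,
             sigmoid_slope_per_pA = f$sigmoid_midpoint_slope)
}
conds <- c("epsc_control", "epsc_nmdar_48h", "epsc_nmdar_7d",
           "ipsc_control", "ipsc_nmdar_48h")
tab <- do.call(rbind, lapply(conds, feature_row))
write.csv(tab, file.path(out, "synaptic_features.csv"), row.names = FALSE)
print(tab, digits = 3)

## contrast and prior shifts (NMDAR 48 h vs control, EPSC only)
fc <- extract_synaptic_features(read_trace(file.path(rec, "epsc_control.txt")),
                                "inward")
fn <- extract_synaptic_features(
  read_trace(file.path(rec, "epsc_nmdar_48h.txt")), "inward")
ct <- contrast_from_features(fc, fn)
shifts <- shifts_from_contrast(ct)
cat(sprintf("contrast: amplitude %.2f, half-life %.2f, slope %.2f\n",
            ct$amplitude_ratio, ct$half_life_ratio, ct$slope_ratio))
cat(sprintf("log shifts: gamma %.3f, tau %.3f, sigma %.3f\n",
            shifts["gamma"], shifts["tau"], shifts["sigma"]))
jsonlite::write_json(as.list(shifts), file.path(out, "microscale_shifts.json"),
                     auto_unbox = TRUE, digits = NA)

## field-trace metrics
field <- read_trace(file.path(rec, "field.txt"))
ev <- detect_events(field)
cl <- coastline(field)
bp <- band_power(field)
write.csv(data.frame(time_s = ev$times, peak = ev$peak_amplitudes),
          file.path(out, "field_events.csv"), row.names = FALSE)
write.csv(data.frame(second = seq_along(cl) - 1, coastline = cl),
          file.path(out, "field_coastline.csv"), row.names = FALSE)
write.csv(bp, file.path(out, "field_band_power.csv"), row.names = FALSE)
cat(sprintf("field: %d events (%.2f/s), median IEI %.0f ms\n",
            length(ev$times), length(ev$times) / 300,
            median(interevent_intervals(ev))))
cat(sprintf("band power 12-30 Hz: %.3g (largest band share %.0f%%)\n",
            bp$power[4], 100 * max(bp$power) / sum(bp$power)))

## segment library classification: ictal epoch vs background
truth <- read_ground_truth(file.path(rec, "field_truth.json"))
metrics <- segment_metric_table(field)
in_ictal <- metrics$start >= truth$epochs$start[1] &
  metrics$start < truth$epochs$end[1]
lib_idx <- c(head(which(!in_ictal), 20), head(which(in_ictal), 20))
library_df <- cbind(metrics[lib_idx, -1],
                    label = ifelse(in_ictal[lib_idx], "ictal", "background"))
held <- setdiff(seq_len(nrow(metrics)), lib_idx)
pred <- vapply(held, function(k)
  classify_segment(as.list(metrics[k, -1]), library_df), character(1))
acc <- mean(pred == ifelse(in_ictal[held], "ictal", "background"))
cat(sprintf("segment classifier held-out accuracy: %.1f%%\n", 100 * acc))
write.csv(data.frame(second = metrics$start[held], label = pred),
          file.path(out, "segment_labels.csv"), row.names = FALSE)
cat("wrote", out, "\n")
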