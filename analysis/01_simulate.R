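#!/usr/bin/env Rscript
# Build every synthetic dataset the analysis rests on: continuous and
# 3-cluster ripple sets in the 127D waveform space, geometric ground-truth
# objects, and a laminar LFP session with programmed feature-CSD couplings.
# Writes event/feature tables and cloud containers under results/.

library(ripplemap)
seed <- 20260919
dir.create("results", showWarnings = FALSE)

message("Continuous ripple set (n = 2000, 80-240 Hz)")
cont <- generate_ripple_set(2000, seed = seed)
write_cloud(cont$cloud, "results/cloud_continuous.tsv")
write_event_table(cont$features, "results/features_continuous.tsv")

message("Clustered ripple set (80-100 / 130-150 / 190-210 Hz)")
clus <- generate_ripple_set(2000, mode = "clustered", seed = seed + 1)
write_cloud(clus$cloud, "results/cloud_clustered.tsv")
write_event_table(clus$features, "results/features_clustered.tsv")

message("Geometric ground-truth objects in 127D")
for (kind in c("line", "plane", "torus", "hyperball")) {
  obj <- generate_geometric_object(kind, n_points = 2000, seed = seed + 2)
  message(sprintf("  %s: intrinsic dim %d, %d points", kind,
                  obj$intrinsic_dim, nrow(obj$X)))
}

message("Laminar session (200 events, default couplings)")
sess <- generate_laminar_session(n_events = 200, seed = seed + 3)
write_event_table(sess$events, "results/laminar_ground_truth.tsv")
utils::write.table(cbind(event = seq_len(nrow(sess$csd_true)), sess$csd_true),
                   "results/laminar_csd_true.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("  recording: %d channels x %d samples",
                nrow(sess$recording$signal), ncol(sess$recording$signal)))
message("done; artifacts in results/")
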