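#!/usr/bin/env Rscript
# Generate the synthetic study: signaling histories with ground truth, fate
# markers, a micropattern colony, a tracking fixture and RNA-seq counts.
# Everything downstream (02-07) reads from results/data/.

library(signalfate)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Signaling histories: 500 cells, 0-42 h at 10-min resolution, ",
        "noise SD 0.1")
hs <- gen_histories(history_gen_params(n_cells = 500, noise_sd = 0.1,
                                       seed = substream_seed(seed, "hist")))
write_histories_csv(hs$histories, file.path(out, "histories.csv"))
write.csv(hs$truth, file.path(out, "histories_truth.csv"), row.names = FALSE)

message("Fate markers: logistic threshold on the integral at 26 ratio*h")
ft <- gen_fates(hs$truth, fate_gen_params(seed = substream_seed(seed, "fate")))
write.csv(ft, file.path(out, "markers.csv"), row.names = FALSE)
message("  ", sum(ft$true_fate == "amnion"), " amnion / ",
        sum(ft$true_fate == "pluripotent"), " pluripotent cells")

message("Micropattern colony: 900 cells, three radial signaling classes")
col <- gen_colony(colony_gen_params(seed = substream_seed(seed, "colony")))
write_histories_csv(col$histories, file.path(out, "colony_histories.csv"))
write.csv(col$positions, file.path(out, "colony_positions.csv"),
          row.names = FALSE)
write.csv(col$fates, file.path(out, "colony_markers.csv"), row.names = FALSE)

message("Tracking fixture: 100 labeled nuclei, 50 frames, divisions")
fx <- gen_tracking_fixture(100, 50, step_sd = 3, division_prob = 0.002,
                           seed = substream_seed(seed, "track"))
write_detections_tsv(fx$detections, file.path(out, "detections.tsv"))
jsonlite::write_json(fx$truth, file.path(out, "tracking_truth.json"),
                     dataframe = "columns", na = "null")
write.table(fx$true_links, file.path(out, "true_links.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

message("RNA-seq counts: 1000 genes, 8 timepoints + 8-dose series at 5 h")
cs <- gen_counts(n_genes = 1000, seed = substream_seed(seed, "rna"))
write.table(cs$time_counts, file.path(out, "counts_timeseries.tsv"),
            sep = "\t", quote = FALSE)
write.table(cs$dose_counts, file.path(out, "counts_dose.tsv"),
            sep = "\t", quote = FALSE)
write.csv(cs$truth, file.path(out, "gene_truth.csv"), row.names = FALSE)
jsonlite::write_json(list(timepoints = cs$timepoints,
                          dose_levels = cs$dose_levels, seed = seed),
                     file.path(out, "design.json"), auto_unbox = TRUE)

message("done: synthetic inputs under ", out)
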