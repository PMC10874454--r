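#!/usr/bin/env Rscript
# Division-aware tracking of the synthetic detections and comparison to the
# known lineage: frame-to-frame linking accuracy, division recall, purity.

library(signalfate)

det <- read_detections_tsv("results/data/detections.tsv")
truth <- jsonlite::read_json("results/data/tracking_truth.json",
                             simplifyVector = TRUE)
links <- read.delim("results/data/true_links.tsv")
fx <- list(detections = det, truth = truth, true_links = links)

ts <- link_frames(det, max_disp = 15, max_gap = 1)
ts <- resolve_divisions(ts, det, division_radius = 15)
m <- track_metrics(ts, fx)

message(sprintf("link accuracy   %.2f%% of %d true links",
                100 * m$link_accuracy, nrow(links)))
message(sprintf("division recall %.0f%% of %d divisions",
                100 * m$division_recall,
                sum(!is.na(truth$tracks$parent)) / 2))
message(sprintf("track purity    %.2f%%", 100 * m$track_purity))

dir.create("results", showWarnings = FALSE)
write_lineage_json(ts, "results/lineage.json")
jsonlite::write_json(m, "results/tracking_metrics.json", auto_unbox = TRUE,
                     digits = NA)
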