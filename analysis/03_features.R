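#!/usr/bin/env Rscript
# Sigmoid feature extraction and PCA of the signaling histories; recovery of
# the generating features, and what each principal component represents.

library(signalfate)

h <- read_histories_csv("results/data/histories.csv")
truth <- read.csv("results/data/histories_truth.csv")

feat <- extract_features(h$histories, h$time, baseline = 1)
write.csv(feat, "results/features.csv", row.names = FALSE)

message(sprintf("median |duration error|   %.2f h",
                median(abs(feat$d - truth$d), na.rm = TRUE)))
message(sprintf("median |high-level error| %.3f",
                median(abs(feat$H - truth$H), na.rm = TRUE)))
message(sprintf("integral vs truth         r = %.3f",
                cor(feat$integral, truth$integral)))

ve <- attr(feat, "variance_explained")
message(sprintf("PC1-3 explain %.0f%% of variance (raw histories)",
                100 * sum(ve[1:3])))

cm <- feature_pc_correlation(feat, as.matrix(feat[, c("pc1", "pc2", "pc3")]))
write.csv(round(cm, 3), "results/feature_pc_correlation.csv")
message("feature-PC correlations (integral row should dominate PC1):")
print(round(cm, 2))
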