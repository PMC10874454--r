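#!/usr/bin/env Rscript
# The integrator-gene screen: CPM filtering, temporal Ward clustering into
# three classes, the 5 h dose-response filter, and the TF candidate sets.

library(signalfate)

tc <- as.matrix(read.delim("results/data/counts_timeseries.tsv"))
dc <- as.matrix(read.delim("results/data/counts_dose.tsv"))
truth <- read.csv("results/data/gene_truth.csv")
design <- jsonlite::read_json("results/data/design.json",
                              simplifyVector = TRUE)

cp <- cpm_normalize(tc)
expressed <- filter_expressed(cp, min_mean = 2.5)
message(length(expressed), " of ", nrow(cp), " genes pass the 2.5 CPM filter")

dyn <- filter_dynamic(cp[expressed, ], design$timepoints)
message(length(dyn$genes), " genes pass the dynamic-change filter ",
        sprintf("(cumulative |log2FC| > %.2f = mean + 1 SD)", dyn$threshold))

cls <- cluster_timecourses(cp[dyn$genes, ], design$timepoints)
message("temporal classes: ",
        paste(names(table(cls$class)), table(cls$class),
              sep = "=", collapse = " "))
truth_cls <- truth$class[match(cls$gene, truth$gene)]
message(sprintf("Ward clustering vs planted classes: ARI %.3f",
                mclust::adjustedRandIndex(cls$class, truth_cls)))

scr <- dose_response_screen(cpm_normalize(dc)[dyn$genes, ],
                            design$dose_levels, apply(cp, 1, max))
cand <- integrator_candidates(cls, scr,
                              stats::setNames(truth$is_tf, truth$gene))
message(length(cand$immediate_down), " immediately decreasing and ",
        length(cand$immediate_up),
        " immediately increasing TF candidate integrators")

f1 <- function(pred, tru) 2 * length(intersect(pred, tru)) /
  (length(pred) + length(tru))
dn_tru <- truth$gene[truth$class == "decreasing" & truth$is_tf]
up_tru <- truth$gene[truth$class == "immediate" & truth$is_tf]
message(sprintf("candidate recovery: F1 down %.2f, F1 up %.2f",
                f1(cand$immediate_down, dn_tru), f1(cand$immediate_up, up_tru)))

write.csv(merge(cls, scr, by = "gene", all.x = TRUE),
          "results/gene_screen.csv", row.names = FALSE)
jsonlite::write_json(cand, "results/candidates.json")
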