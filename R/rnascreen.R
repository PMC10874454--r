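#' Counts per million
#'
#' @param counts genes x samples matrix of raw counts.
#' @return CPM matrix (columns sum to 1e6).
#' @export
cpm_normalize <- function(counts) {
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("zero library size")
  sweep(counts, 2, libs, "/") * 1e6
}

#' Filter out low-expressed genes
#'
#' Keeps genes with mean CPM across all samples at or above `min_mean`
#' (default 2.5 counts per million).
#'
#' @param cpm CPM matrix.
#' @param min_mean threshold on the per-gene mean CPM.
#' @return Character vector of retained gene names.
#' @export
filter_expressed <- function(cpm, min_mean = 2.5) {
  keep <- rowMeans(cpm) >= min_mean
  if (!any(keep)) warning("no genes pass the expression filter")
  rownames(cpm)[keep]
}

#' Filter out genes with little temporal change
#'
#' Per gene, the cumulative absolute log2 fold change relative to t = 0,
#' summed over the post-treatment timepoints (pseudocount 0.5 guards zeros).
#' Genes below the threshold -- by default the mean plus `sd_multiplier`
#' standard deviations of the statistic across genes (~1.55 at one SD on the
#' study's data) -- are dropped. A fixed threshold can be supplied instead.
#'
#' @param cpm CPM matrix of the time series (genes x timepoints).
#' @param timepoints sampling times (hours), must include 0; >= 3 points.
#' @param sd_multiplier multiplier on the across-gene SD (default 1).
#' @param threshold optional fixed threshold overriding the automatic one.
#' @return list: `genes` (retained), `statistic` (per gene), `threshold`
#'   (realized).
#' @export
filter_dynamic <- function(cpm, timepoints, sd_multiplier = 1,
                           threshold = NULL) {
  if (length(timepoints) < 3) stop("need at least 3 timepoints")
  t0 <- which(timepoints == 0)
  if (!length(t0)) stop("timepoints must include t = 0")
  lg <- log2(cpm + 0.5)
  fc <- lg[, -t0, drop = FALSE] - lg[, t0]
  stat <- rowSums(abs(fc))
  thr <- threshold %||% (mean(stat) + sd_multiplier * stats::sd(stat))
  list(genes = rownames(cpm)[stat > thr], statistic = stat, threshold = thr)
}

timecourse_templates <- function(timepoints) {
  tmax <- max(timepoints)
  list(decreasing = 0.15 + 0.85 * exp(-timepoints / (tmax / 4)),
       immediate_up = 0.15 + 0.85 * (1 - exp(-timepoints / (tmax / 12))),
       delayed_up = 0.15 + 0.85 * stats::plogis((timepoints - 0.45 * tmax) /
                                                  (tmax / 10)))
}

#' Cluster filtered time courses into three temporal classes
#'
#' Each gene is normalized to its maximum over the time series, clustered by
#' agglomerative hierarchical clustering (Euclidean distance, Ward linkage)
#' and cut into three clusters, which are auto-labeled `decreasing`,
#' `immediate_up` or `delayed_up` by correlation of the cluster centroid with
#' canonical temporal templates.
#'
#' @param cpm CPM matrix of the filtered genes (genes x timepoints).
#' @param timepoints sampling times (hours).
#' @param k number of clusters (default 3).
#' @return data.frame: `gene`, `cluster` (integer), `class` (label);
#'   attribute `"normalized"` holds the max-normalized matrix.
#' @export
cluster_timecourses <- function(cpm, timepoints, k = 3) {
  if (nrow(cpm) < 3) stop("need at least 3 genes")
  norm <- cpm / apply(cpm, 1, max)
  hc <- stats::hclust(stats::dist(norm), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  tmpl <- timecourse_templates(timepoints)
  cent <- t(vapply(seq_len(k), function(g)
    colMeans(norm[cl == g, , drop = FALSE]), numeric(ncol(norm))))
  cors <- vapply(tmpl, function(tm)
    apply(cent, 1, stats::cor, y = tm), numeric(k))
  # greedy unique assignment of templates to clusters, best correlation first
  lab <- rep(NA_character_, k)
  cm <- cors
  for (i in seq_len(min(k, length(tmpl)))) {
    best <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    lab[best[1]] <- colnames(cors)[best[2]]
    cm[best[1], ] <- NA
    cm[, best[2]] <- NA
  }
  out <- data.frame(gene = rownames(cpm), cluster = unname(cl),
                    class = lab[cl], stringsAsFactors = FALSE)
  attr(out, "normalized") <- norm
  out
}

#' Dose-response screen at the 5-hour timepoint
#'
#' Per gene: Pearson correlation of expression with the SMAD4 signaling level
#' across doses, and the OLS slope of expression (normalized to the gene's
#' time-series maximum) on the level. Hits require `|correlation| > corr_min`
#' and `|normalized slope| > slope_min`.
#'
#' @param dose_cpm CPM matrix of the dose series (genes x doses).
#' @param smad4_levels SMAD4 level per dose sample (normalized units), >= 4.
#' @param ts_max per-gene maximum CPM over the time series (normalization).
#' @param corr_min,slope_min screen thresholds (defaults 0.9 and 0.1).
#' @return data.frame: `gene`, `correlation`, `slope_norm`, `hit`,
#'   `direction` (+1/-1); zero-variance genes are skipped.
#' @export
dose_response_screen <- function(dose_cpm, smad4_levels, ts_max,
                                 corr_min = 0.9, slope_min = 0.1) {
  if (length(smad4_levels) < 4) stop("need at least 4 dose levels")
  genes <- rownames(dose_cpm)
  keep <- apply(dose_cpm, 1, stats::sd) > 0
  res <- lapply(which(keep), function(i) {
    y <- dose_cpm[i, ] / ts_max[[genes[i]]]
    r <- stats::cor(dose_cpm[i, ], smad4_levels)
    b <- stats::coef(stats::lm(y ~ smad4_levels))[2]
    data.frame(gene = genes[i], correlation = r, slope_norm = unname(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$hit <- abs(out$correlation) > corr_min & abs(out$slope_norm) > slope_min
  out$direction <- sign(out$slope_norm)
  out
}

#' Candidate integrator genes
#'
#' Intersects the temporal classes with the dose-response screen, restricted
#' to transcription factors: immediately responding decreasing TFs (candidate
#' pluripotency-side integrators, the SOX2-like set) and immediately
#' increasing TFs.
#'
#' @param classes output of [cluster_timecourses()].
#' @param screen output of [dose_response_screen()].
#' @param tf_flags named logical vector: is the gene a transcription factor?
#' @return list: `immediate_down` and `immediate_up` gene sets.
#' @export
integrator_candidates <- function(classes, screen, tf_flags) {
  tf_genes <- names(tf_flags)[tf_flags]
  hits_dn <- screen$gene[screen$hit & screen$direction < 0]
  hits_up <- screen$gene[screen$hit & screen$direction > 0]
  dn <- intersect(intersect(classes$gene[classes$class == "decreasing"],
                            hits_dn), tf_genes)
  up <- intersect(intersect(classes$gene[classes$class == "immediate_up"],
                            hits_up), tf_genes)
  list(immediate_down = dn, immediate_up = up)
}
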