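#' Radial binning of a colony by edge distance
#'
#' Subdivides the colony into `n_bins` bins with equal numbers of cells, by
#' quantiles of distance to the colony edge. Bin 1 is the outermost (closest
#' to the edge). Per-bin summaries use the median, the convention for
#' radially averaged expression and signaling.
#'
#' @param positions data.frame with `x`, `y` (um, colony centered at the
#'   origin) or an `edge_dist` column.
#' @param colony_radius colony radius (um).
#' @param n_bins number of bins (default 30).
#' @return list of class `radial_binning`: `bin` (per cell, 1 = edge),
#'   `ranges` (per-bin edge-distance min/max), `n_bins`.
#' @export
radial_bin <- function(positions, colony_radius, n_bins = 30) {
  edge <- positions$edge_dist %||%
    (colony_radius - sqrt(positions$x^2 + positions$y^2))
  n <- length(edge)
  if (n < n_bins) stop("fewer cells than bins")
  if (any(edge < -1e-6)) stop("positions outside the colony")
  rk <- rank(edge, ties.method = "first")
  bin <- as.integer(floor((rk - 1) * n_bins / n) + 1)
  ranges <- t(vapply(seq_len(n_bins), function(b)
    range(edge[bin == b]), numeric(2)))
  colnames(ranges) <- c("min_edge_dist", "max_edge_dist")
  if (any(ranges[, 2] - ranges[, 1] < 1e-9) && stats::sd(edge) < 1e-9)
    warning("degenerate bins: all cells at one radius")
  structure(list(bin = bin, ranges = as.data.frame(ranges), n_bins = n_bins),
            class = "radial_binning")
}

#' Kymograph: radially averaged signaling over time
#'
#' Per-bin, per-timepoint median of the signaling histories; bins are rows
#' ordered edge to center. With replicate colony ids, replicates are binned
#' and medianed separately, then averaged.
#'
#' @param histories cells x timepoints matrix.
#' @param binning a `radial_binning` aligned with the history rows.
#' @param replicate optional per-cell replicate (colony) ids.
#' @return bins x timepoints matrix.
#' @export
kymograph <- function(histories, binning, replicate = NULL) {
  stopifnot(inherits(binning, "radial_binning"))
  one <- function(rows) {
    t(vapply(seq_len(binning$n_bins), function(b) {
      sel <- rows & binning$bin == b
      apply(histories[sel, , drop = FALSE], 2, stats::median)
    }, numeric(ncol(histories))))
  }
  if (is.null(replicate)) return(one(rep(TRUE, nrow(histories))))
  mats <- lapply(unique(replicate), function(r) one(replicate == r))
  Reduce(`+`, mats) / length(mats)
}

#' Soft k-means clustering of radially averaged signaling histories
#'
#' Fuzzy c-means (fuzzifier `m = 2`) on the rows of a kymograph, with
#' restarts keeping the best objective. Clusters are relabeled in a stable
#' order (descending mean signaling, so the sustained edge class is cluster
#' 1). A designated bin's cluster can be manually reassigned --- the "elbow"
#' correction for the one position whose assignment is not objectively
#' determined.
#'
#' @param radial bins x timepoints matrix (e.g. a [kymograph()]).
#' @param k number of clusters (default 3).
#' @param m fuzzifier (default 2).
#' @param restarts random restarts (default 10).
#' @param seed integer seed.
#' @param reassign optional named integer vector `c(bin = cluster)` applied
#'   after clustering.
#' @return list of class `radial_clusters`: `membership` (bins x k),
#'   `cluster` (dominant per bin), `centers`, `duplicated_clusters` (TRUE
#'   when two centroids nearly coincide, e.g. k exceeds the true class
#'   count).
#' @export
cluster_radial_histories <- function(radial, k = 3, m = 2, restarts = 10,
                                     seed = 1L, reassign = NULL) {
  radial <- as.matrix(radial)
  if (nrow(unique(radial)) < k) stop("need at least k distinct histories")
  set.seed(substream_seed(seed, "cluster_radial"))
  best <- NULL
  if (k == 1) {
    memb <- matrix(1, nrow(radial), 1)
    best <- list(membership = memb, centers = matrix(colMeans(radial), 1),
                 withinerror = 0)
  } else {
    for (r in seq_len(restarts)) {
      fit <- e1071::cmeans(radial, centers = k, m = m, method = "cmeans",
                           iter.max = 200)
      if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
    }
  }
  ord <- order(rowMeans(best$centers), decreasing = TRUE)
  memb <- best$membership[, ord, drop = FALSE]
  centers <- best$centers[ord, , drop = FALSE]
  cluster <- max.col(memb, ties.method = "first")
  if (!is.null(reassign)) {
    cluster[as.integer(names(reassign))] <- as.integer(reassign)
  }
  cd <- as.matrix(stats::dist(centers))
  diag(cd) <- Inf
  scale <- max(stats::dist(radial))
  dup <- min(cd) < 0.05 * scale
  if (any(!seq_len(k) %in% cluster))
    warning("empty cluster after hardening")
  structure(list(membership = memb, cluster = cluster, centers = centers,
                 duplicated_clusters = dup),
            class = "radial_clusters")
}

#' Discretized fate map over radial bins
#'
#' The dominant (modal) fate per bin. Ties fall to the label of the adjacent
#' bin nearer the edge (outermost bin: "amnion", the edge fate). With
#' replicate colonies each is discretized first, then per-bin majority wins.
#'
#' @param fate_labels per-cell labels (factor or character).
#' @param binning a `radial_binning` aligned with the labels.
#' @param replicate optional per-cell replicate ids.
#' @return character vector, one fate per bin (edge to center).
#' @export
fate_map <- function(fate_labels, binning, replicate = NULL) {
  stopifnot(inherits(binning, "radial_binning"))
  lab <- as.character(fate_labels)
  one <- function(rows) {
    out <- character(binning$n_bins)
    for (b in seq_len(binning$n_bins)) {
      tb <- table(lab[rows & binning$bin == b])
      if (!length(tb)) { out[b] <- NA_character_; next }
      top <- names(tb)[tb == max(tb)]
      out[b] <- if (length(top) == 1) top
                else if (b == 1) "amnion"
                else out[b - 1]
    }
    out
  }
  if (is.null(replicate)) return(one(rep(TRUE, length(lab))))
  maps <- vapply(unique(replicate), function(r) one(replicate == r),
                 character(binning$n_bins))
  apply(maps, 1, function(x) names(which.max(table(x))))
}

#' Agreement between two per-bin maps
#'
#' Fraction of bins with matching labels after aligning label alphabets:
#' with equally many labels the best one-to-one permutation is used (cluster
#' numberings are arbitrary); with more labels in `a` than `b` (e.g. three
#' signaling clusters against two fates) each `a` label maps to its dominant
#' `b` label.
#'
#' @param a,b vectors of bin labels of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
map_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  ua <- unique(a); ub <- unique(b)
  if (length(ua) == length(ub)) {
    best <- mean(a == b)
    for (p in permutations_of(ub)) {
      m <- stats::setNames(p, ua)
      best <- max(best, mean(m[a] == b))
    }
    return(best)
  }
  # many-to-one: each a-label takes its modal b-label
  m <- vapply(ua, function(l) names(which.max(table(b[a == l]))), character(1))
  mean(m[a] == b)
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  out
}

#' Feature threshold at 50% differentiation from a dose-response curve
#'
#' Least-squares logistic fit `fraction = 1 / (1 + exp(-(x - x0) / w))`;
#' the threshold is the fitted midpoint `x0`, with a standard error from the
#' fit covariance. Refuses to extrapolate: the curve must cross 50%.
#'
#' @param feature condition feature values (level, duration, or integral).
#' @param fraction differentiated fractions in `[0, 1]`.
#' @return list: `threshold`, `se`, `width`, `fit`.
#' @export
threshold_from_dose_response <- function(feature, fraction) {
  if (any(fraction < 0 | fraction > 1)) stop("fractions must be in [0, 1]")
  if (all(fraction < 0.5) || all(fraction > 0.5))
    stop("curve does not cross 50%; refusing to extrapolate")
  ord <- order(feature)
  x <- feature[ord]; y <- fraction[ord]
  # crossing-interpolated start for the midpoint; several width starts since
  # near-step curves have a very narrow basin
  cross <- which(diff(sign(y - 0.5)) != 0)[1]
  x0_start <- if (!is.na(cross)) {
    stats::approx(y[cross + 0:1], x[cross + 0:1], 0.5, ties = "ordered")$y
  } else x[which.min(abs(y - 0.5))]
  if (is.na(x0_start)) x0_start <- x[which.min(abs(y - 0.5))]
  fit <- NULL
  for (w_start in diff(range(x)) / c(5, 20, 100)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + exp(-(x - x0) / w)),
                        start = list(x0 = x0_start, w = max(w_start, 1e-3)),
                        lower = c(x0 = -Inf, w = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit)))
      fit <- cand
  }
  if (is.null(fit)) {
    # degenerate near-step curves: interpolate the 50% crossing directly
    if (!is.na(cross)) {
      return(list(threshold = x0_start, se = NA_real_, width = NA_real_,
                  fit = NULL))
    }
    stop("logistic threshold fit failed")
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["x0"], error = function(e) NA_real_)
  list(threshold = unname(cf["x0"]), se = unname(se),
       width = unname(cf["w"]), fit = fit)
}

#' Integral-collapse test across signaling conditions
#'
#' Conditions that differ in signaling level (or pulse structure) each trace a
#' differentiation curve; under integral control these curves collapse onto a
#' single threshold on the signaling-integral axis, while their thresholds in
#' the native feature (e.g. duration) shift between levels. Reports the
#' per-group integral thresholds and their coefficient of variation, plus the
#' native-feature thresholds. A CV of a few percent indicates collapse; the
#' level+duration alternative model fails with a CV tracking the level ratio.
#'
#' @param dose_response data.frame with columns `sigma` (integral),
#'   `fraction`, a grouping column, and optionally the native feature.
#' @param group_col name of the grouping column (default `"level"`).
#' @param feature_col native feature for per-group thresholds (default
#'   `"duration"`; skipped if absent).
#' @return list: `sigma_thresholds` (per group), `sigma_cv`,
#'   `feature_thresholds`, `feature_shift` (max relative difference).
#' @export
collapse_test <- function(dose_response, group_col = "level",
                          feature_col = "duration") {
  groups <- split(dose_response, dose_response[[group_col]])
  if (length(groups) < 2) stop("need at least 2 conditions")
  sig_thr <- vapply(groups, function(g)
    threshold_from_dose_response(g$sigma, g$fraction)$threshold, numeric(1))
  cv <- stats::sd(sig_thr) / mean(sig_thr)
  feat_thr <- NULL; shift <- NA_real_
  if (feature_col %in% names(dose_response)) {
    feat_thr <- vapply(groups, function(g)
      threshold_from_dose_response(g[[feature_col]], g$fraction)$threshold,
      numeric(1))
    shift <- (max(feat_thr) - min(feat_thr)) / min(feat_thr)
  }
  list(sigma_thresholds = sig_thr, sigma_cv = cv,
       feature_thresholds = feat_thr, feature_shift = shift)
}

#' Dose-response table from a shutdown-style micropattern experiment
#'
#' Builds per-bin conditions the way the signaling-shutdown analysis does:
#' each radial bin at each shutdown time is one condition whose level is the
#' bin's mean signaling before shutdown, duration is the shutdown time, and
#' integral is the bin's integrated signaling; differentiation is the bin's
#' fraction of amnion cells (fate score > 0).
#'
#' @param kymo bins x timepoints kymograph (baseline-subtracted signal).
#' @param time time grid (hours).
#' @param shutdown_time shutdown time (hours).
#' @param fate_scores per-cell fate scores.
#' @param binning the `radial_binning` used for `kymo`.
#' @return data.frame: bin, level, duration, sigma, fraction.
#' @export
shutdown_dose_response <- function(kymo, time, shutdown_time, fate_scores,
                                   binning) {
  keep <- time <= shutdown_time
  level <- rowMeans(kymo[, keep, drop = FALSE])
  sigma <- apply(kymo[, keep, drop = FALSE], 1, function(r)
    pracma::trapz(time[keep], r))
  frac <- vapply(seq_len(binning$n_bins), function(b)
    mean(fate_scores[binning$bin == b] > 0), numeric(1))
  data.frame(bin = seq_len(binning$n_bins), level = level,
             duration = shutdown_time, sigma = sigma, fraction = frac)
}
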