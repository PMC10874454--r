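#' @importFrom mclust Mclust mclustBIC priorControl
NULL

#' Log-transform and z-score normalize marker intensities
#'
#' Natural-log transform (with a pseudo-offset guarding zeros) followed by a
#' per-marker z-score. The raw log values are retained for ratio-based scores,
#' which must stay invariant to global intensity scaling.
#'
#' @param raw cells x markers matrix or data.frame of positive intensities.
#' @param pseudo offset added before the log when zeros are present.
#' @return list: `log` (log intensities), `z` (z-scored log intensities).
#' @export
normalize_markers <- function(raw, pseudo = 1e-6) {
  if (is.data.frame(raw)) {
    num <- raw[, vapply(raw, is.numeric, logical(1)), drop = FALSE]
    X <- as.matrix(num)
    rownames(X) <- raw$cell_id %||% rownames(raw)
  } else X <- as.matrix(raw)
  if (any(X < 0)) stop("marker intensities must be non-negative")
  if (any(colSums(X) == 0)) stop("all-zero marker column")
  lg <- log(X + ifelse(any(X == 0), pseudo, 0))
  z <- scale(lg)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant marker: z-scores all 0
  list(log = lg, z = z[, , drop = FALSE])
}

#' Cluster cells into two fates with a Gaussian mixture model
#'
#' Two-component full-covariance GMM on the log-normalized 7-marker data. The
#' component with the higher mean ISL1 is labeled amnion. When component
#' separation is below 1 for every marker the clustering is flagged ambiguous.
#'
#' @param markers FateTable data.frame (raw intensities) or numeric matrix.
#' @param seed seed controlling the (deterministic) mclust initialization
#'   subsample when n is large.
#' @return factor of labels ("amnion"/"pluripotent") with attributes
#'   `ambiguous` (logical) and `fit` (the mclust model).
#' @export
cluster_fates <- function(markers, seed = 1L) {
  nm <- normalize_markers(markers)
  Z <- nm$z
  if (nrow(Z) < 20) stop("need at least 20 cells")
  set.seed(substream_seed(seed, "cluster_fates"))
  fit <- tryCatch(
    mclust::Mclust(Z, G = 2, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular covariance; refitting with a regularizing prior")
    fit <- mclust::Mclust(Z, G = 2, modelNames = "VVV", verbose = FALSE,
                          prior = mclust::priorControl())
  }
  cl <- fit$classification
  isl1 <- if ("ISL1" %in% colnames(Z)) Z[, "ISL1"] else Z[, 1]
  m1 <- mean(isl1[cl == 1]); m2 <- mean(isl1[cl == 2])
  amnion_comp <- if (m1 >= m2) 1L else 2L
  labels <- factor(ifelse(cl == amnion_comp, "amnion", "pluripotent"),
                   levels = c("amnion", "pluripotent"))
  seps <- vapply(seq_len(ncol(Z)), function(j)
    separation_statistic(Z[, j], cl), numeric(1))
  attr(labels, "ambiguous") <- all(seps < 1, na.rm = TRUE)
  attr(labels, "fit") <- fit
  labels
}

#' Cluster separation statistic
#'
#' Difference of the class means over the sum of the class standard
#' deviations: `|mu1 - mu2| / (sd1 + sd2)`. Used to rank which markers best
#' separate the two fates.
#'
#' @param values numeric vector.
#' @param labels two-class labels, both classes nonempty.
#' @return Numeric score; `Inf` (with a warning) when both SDs are zero.
#' @export
separation_statistic <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("need exactly two nonempty classes")
  g <- split(values, droplevels(labels))
  s <- stats::sd(g[[1]]) + stats::sd(g[[2]])
  if (is.na(s) || s == 0) {
    warning("zero total SD; separation is infinite")
    return(Inf)
  }
  abs(mean(g[[1]]) - mean(g[[2]])) / s
}

#' Continuous fate score and threshold label
#'
#' The fate score is the log expression ratio of two markers on raw
#' intensities -- by default `log(ISL1/NANOG)`, the pair that best separates
#' amnion-like from pluripotent cells. A cell is labeled amnion iff its score
#' is strictly positive (a boundary score of 0 is assigned pluripotent).
#' Under TGF-beta inhibition `c("ISL1", "SOX2")` is the appropriate pair.
#'
#' @param markers FateTable data.frame or matrix with raw intensities.
#' @param pair character(2): numerator and denominator markers.
#' @return data.frame: `cell_id`, `score`, `label`.
#' @export
fate_score <- function(markers, pair = c("ISL1", "NANOG")) {
  if (is.data.frame(markers)) {
    if (!all(pair %in% names(markers))) stop("missing marker: ", paste(setdiff(pair, names(markers)), collapse = ", "))
    num <- markers[[pair[1]]]; den <- markers[[pair[2]]]
    ids <- markers$cell_id %||% sprintf("cell_%04d", seq_along(num))
  } else {
    if (!all(pair %in% colnames(markers))) stop("missing marker")
    num <- markers[, pair[1]]; den <- markers[, pair[2]]
    ids <- rownames(markers) %||% sprintf("cell_%04d", seq_along(num))
  }
  score <- log(num) - log(den)
  data.frame(cell_id = ids, score = score,
             label = factor(ifelse(score > 0, "amnion", "pluripotent"),
                            levels = c("amnion", "pluripotent")),
             stringsAsFactors = FALSE)
}
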