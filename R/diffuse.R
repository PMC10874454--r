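#' Build a MAGIC-style diffusion operator over cells
#'
#' Adaptive Gaussian kernel with per-cell bandwidth equal to the distance to
#' the `knn`-th nearest neighbor, restricted to the symmetrized kNN support
#' (each cell keeps kernel weights only to its `knn` nearest neighbors and to
#' cells that count it among theirs, plus itself), symmetrized as `(K + K')/2`
#' and row-normalized to a row-stochastic Markov matrix. The support
#' restriction keeps diffusion local, which is what lets a small `knn` average
#' away measurement noise without blurring distinct cells together. Duplicate
#' points are handled by flooring the bandwidth at a machine-epsilon scale of
#' the data spread.
#'
#' @param X cells x dims numeric matrix (the space the affinity graph is
#'   built on: histories for history-based denoising, log-normalized markers
#'   for fate-based denoising).
#' @param knn number of nearest neighbors setting the kernel bandwidth and
#'   support (default 3).
#' @param n_pca optionally project `X` onto its leading `n_pca` principal
#'   components before computing distances (the usual preprocessing when `X`
#'   is a high-dimensional noisy matrix such as raw histories); `NULL` uses
#'   `X` as is.
#' @return list of class `diffusion_operator`: `M` (row-stochastic matrix),
#'   `knn`.
#' @export
build_operator <- function(X, knn = 3, n_pca = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < knn + 1) stop("need at least knn + 1 cells")
  if (!is.null(n_pca) && n_pca < min(dim(X))) {
    X <- stats::prcomp(X, center = TRUE)$x[, seq_len(n_pca), drop = FALSE]
  }
  D <- as.matrix(stats::dist(X))
  scale <- max(D)
  floor_bw <- max(scale, 1) * sqrt(.Machine$double.eps)
  sigma <- apply(D, 1, function(row) sort(row)[knn + 1L])  # k-th non-self
  sigma <- pmax(sigma, floor_bw)
  K <- exp(-(D / sigma)^2)      # rows scaled by own bandwidth
  supp <- matrix(FALSE, n, n)
  for (i in seq_len(n)) supp[i, order(D[i, ])[seq_len(knn + 1L)]] <- TRUE
  K[!(supp | t(supp))] <- 0
  K <- (K + t(K)) / 2
  M <- K / rowSums(K)
  structure(list(M = M, knn = knn), class = "diffusion_operator")
}

#' Denoise data by graph diffusion
#'
#' Returns `M^t %*% Y`: each cell's values are replaced by a convex
#' combination of similar cells' values. `t = 0` returns `Y` unchanged.
#'
#' @param Y cells x features matrix (e.g. histories), rows aligned with the
#'   operator.
#' @param operator a `diffusion_operator` from [build_operator()].
#' @param t diffusion time (power of the operator), non-negative integer;
#'   default 3.
#' @return Denoised matrix of the same shape.
#' @export
denoise <- function(Y, operator, t = 3) {
  stopifnot(inherits(operator, "diffusion_operator"))
  if (t < 0) stop("t must be non-negative")
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(operator$M)) stop("operator and data are not row-aligned")
  out <- Y
  for (i in seq_len(t)) out <- operator$M %*% out
  dimnames(out) <- dimnames(Y)
  out
}

#' Fate-based denoising of signaling histories
#'
#' Builds the diffusion operator on log-normalized fate-marker space and
#' applies it to the signaling histories, so each history is averaged with the
#' histories of the cells most similar in fate --- a fine-grained extension of
#' averaging histories within discrete fates.
#'
#' @param histories cells x timepoints matrix (rownames = cell ids).
#' @param markers FateTable (data.frame with `cell_id` and raw marker
#'   intensity columns) or a numeric marker matrix; cells must match
#'   `histories`.
#' @param knn,t diffusion parameters (defaults 3 and 3).
#' @return Denoised history matrix.
#' @export
fate_based_denoise <- function(histories, markers, knn = 3, t = 3) {
  Z <- marker_space(markers, rownames(histories))
  denoise(histories, build_operator(Z, knn), t)
}

marker_space <- function(markers, cell_ids = NULL) {
  if (is.data.frame(markers)) {
    num <- markers[, intersect(names(markers),
                               c(AMNION_MARKERS, PLURI_MARKERS)), drop = FALSE]
    if (!ncol(num))
      num <- markers[, vapply(markers, is.numeric, logical(1)), drop = FALSE]
    Z <- as.matrix(num)
    rownames(Z) <- markers$cell_id %||% rownames(markers)
  } else {
    Z <- as.matrix(markers)
  }
  if (!is.null(cell_ids) && !is.null(rownames(Z))) {
    if (!setequal(rownames(Z), cell_ids))
      stop("histories and markers cover different cells")
    Z <- Z[cell_ids, , drop = FALSE]
  } else if (!is.null(cell_ids) && nrow(Z) != length(cell_ids)) {
    stop("histories and markers cover different cells")
  }
  normalize_markers(Z)$z
}

#' Correlation between signaling integral and fate score
#'
#' Helper reporting `cor(integral, log(ISL1/NANOG))`, optionally after
#' fate-based denoising of the histories.
#'
#' @param histories cells x timepoints matrix.
#' @param markers FateTable aligned with `histories`.
#' @param time time grid (hours).
#' @param baseline baseline for the integral.
#' @param denoise_histories apply [fate_based_denoise()] first?
#' @param knn,t diffusion parameters.
#' @param score_pair marker pair for the fate score.
#' @return list: `correlation`, `integral`, `score`.
#' @export
fate_signal_correlation <- function(histories, markers, time, baseline = 0,
                                    denoise_histories = TRUE, knn = 3, t = 3,
                                    score_pair = c("ISL1", "NANOG")) {
  H <- if (denoise_histories) fate_based_denoise(histories, markers, knn, t)
       else histories
  sigma <- signal_integral(H, time, baseline)
  sc <- fate_score(markers, pair = score_pair)
  list(correlation = stats::cor(sigma, sc$score), integral = sigma,
       score = sc$score)
}

#' Randomized-pairing control for fate-based denoising
#'
#' Guards against denoising-created artifacts: signaling histories are
#' randomly re-assigned to marker expression before fate-based denoising, and
#' the correlation between the denoised integral and the fate score of the
#' (shuffled) pairing is reported. Any real pipeline must give a near-zero
#' correlation here; a large value would mean the denoiser manufactures the
#' signal-fate relationship.
#'
#' @inheritParams fate_signal_correlation
#' @param seed seed for the permutation.
#' @param permutation optional explicit permutation (overrides `seed`); the
#'   identity permutation reproduces the non-control result.
#' @return list: `correlation`, `permutation`.
#' @export
randomized_control <- function(histories, markers, time, baseline = 0,
                               knn = 3, t = 3, seed = 1L,
                               score_pair = c("ISL1", "NANOG"),
                               permutation = NULL) {
  n <- nrow(histories)
  if (n < 50) stop("need at least 50 cells for the randomized control")
  set.seed(substream_seed(seed, "randomized_control"))
  perm <- permutation %||% sample.int(n)
  mperm <- if (is.data.frame(markers)) markers[perm, , drop = FALSE]
           else markers[perm, , drop = FALSE]
  if (is.data.frame(mperm) && "cell_id" %in% names(mperm))
    mperm$cell_id <- markers$cell_id  # pairing permuted, ids re-aligned
  if (!is.null(rownames(mperm))) rownames(mperm) <- rownames(markers)
  res <- fate_signal_correlation(histories, mperm, time, baseline,
                                 denoise_histories = TRUE, knn = knn, t = t,
                                 score_pair = score_pair)
  list(correlation = res$correlation, permutation = perm)
}
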