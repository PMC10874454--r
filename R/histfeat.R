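#' Nuclear-to-cytoplasmic signaling ratio
#'
#' The SMAD4 signaling readout: background-subtracted nuclear intensity
#' divided by background-subtracted cytoplasmic intensity. With
#' `subtract_background = FALSE` the plain nuclear/cytoplasmic ratio is
#' returned (used for SMAD1-style data where background subtraction is
#' skipped). A non-positive denominator yields `NA` (flagged missing value),
#' not an error.
#'
#' @param nuclear,cytoplasmic,background intensity vectors (arbitrary units).
#' @param subtract_background subtract `background` from both intensities?
#' @return Numeric vector of N:C ratios.
#' @export
nc_ratio <- function(nuclear, cytoplasmic, background = 0,
                     subtract_background = TRUE) {
  if (subtract_background) {
    num <- nuclear - background
    den <- cytoplasmic - background
  } else {
    num <- nuclear
    den <- cytoplasmic
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(out)) warning("non-positive denominator: ratio set to NA")
  out
}

#' Fit a descending sigmoid to one signaling history
#'
#' Least-squares fit of `s(t) = L + (H - L) / (1 + exp((t - d) / tau))`
#' (see [sigmoid_response()]) by Levenberg-Marquardt. Initial values default
#' from the data: `H` = mean over the first quartile of timepoints, `L` =
#' mean over the last quartile, `d` = time of half-crossing, `tau` = 2 h.
#' Near-constant histories are degenerate (the duration is unidentifiable)
#' and return a flagged fit with `H = L =` the mean and `d`, `tau` missing.
#'
#' @param history numeric vector of signaling values.
#' @param time time grid (hours), >= 8 points.
#' @param init optional named list/vector with `H`, `L`, `d`, `tau` starts.
#' @return list of class `sigmoid_fit`: `H`, `L`, `d`, `tau`, `rmse`,
#'   `converged`, `degenerate`.
#' @export
fit_sigmoid <- function(history, time, init = NULL) {
  if (length(history) != length(time)) stop("history/time length mismatch")
  if (length(time) < 8) stop("need at least 8 timepoints")
  amp <- diff(range(history))
  if (amp < 1e-9 || stats::sd(history) < 1e-9) {
    return(structure(list(H = mean(history), L = mean(history), d = NA_real_,
                          tau = NA_real_, rmse = stats::sd(history) %||% 0,
                          converged = FALSE, degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  q <- length(time) %/% 4
  H0 <- mean(history[seq_len(max(q, 2))])
  L0 <- mean(history[seq(length(history) - max(q, 2) + 1, length(history))])
  half <- (H0 + L0) / 2
  below <- which(history <= half)
  d0 <- if (length(below)) time[below[1]] else stats::median(time)
  st <- list(H = H0, L = L0, d = d0, tau = 2)
  if (!is.null(init)) st[names(init)] <- as.list(init)[names(init)]
  df <- data.frame(t = time, y = history)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L + (H - L) / (1 + exp((t - d) / tau)),
                      data = df, start = st,
                      lower = c(H = -Inf, L = -Inf, d = min(time) - 50,
                                tau = 1e-2),
                      upper = c(H = Inf, L = Inf, d = max(time) + 50,
                                tau = 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(H = NA_real_, L = NA_real_, d = NA_real_,
                          tau = NA_real_, rmse = NA_real_, converged = FALSE,
                          degenerate = FALSE),
                     class = "sigmoid_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(H = unname(cf["H"]), L = unname(cf["L"]),
                 d = unname(cf["d"]), tau = unname(cf["tau"]),
                 rmse = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE, degenerate = FALSE),
            class = "sigmoid_fit")
}

#' Fit sigmoids to every history in a matrix
#'
#' @param histories cells x timepoints matrix.
#' @param time time grid (hours).
#' @return data.frame with cell_id, H, L, d, tau, rmse, converged.
#' @export
fit_sigmoids <- function(histories, time) {
  ids <- rownames(histories) %||% sprintf("cell_%04d", seq_len(nrow(histories)))
  rows <- lapply(seq_len(nrow(histories)), function(i) {
    f <- fit_sigmoid(histories[i, ], time)
    data.frame(cell_id = ids[i], H = f$H, L = f$L, d = f$d, tau = f$tau,
               rmse = f$rmse, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time integral of signaling above a baseline
#'
#' Trapezoid-rule integral of `s(t) - baseline` over the observation window;
#' the total amount of signaling a cell experienced.
#'
#' @param history numeric vector, or cells x timepoints matrix.
#' @param time strictly increasing time grid (hours).
#' @param baseline reference level (default 0); typically the population
#'   pre-treatment median.
#' @return Numeric scalar (or vector for a matrix input), ratio x hours.
#' @export
signal_integral <- function(history, time, baseline = 0) {
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  if (is.matrix(history)) {
    if (ncol(history) != length(time)) stop("history/time length mismatch")
    return(apply(history, 1, function(h)
      pracma::trapz(time, h - baseline)))
  }
  if (length(history) != length(time)) stop("history/time length mismatch")
  pracma::trapz(time, history - baseline)
}

#' PCA of signaling histories
#'
#' Column-mean-centered principal components of the history matrix. Each
#' component's sign is fixed so its correlation with the per-cell signaling
#' integral is non-negative, making scores comparable across runs.
#'
#' @param histories cells x timepoints matrix, no missing values.
#' @param n_components number of components to return.
#' @param time optional time grid for the integral used by the sign
#'   convention; defaults to equal spacing.
#' @return list: `scores` (cells x k), `components` (timepoints x k),
#'   `variance_explained` (per component, all components).
#' @export
pca_histories <- function(histories, n_components = 3, time = NULL) {
  if (anyNA(histories)) stop("histories must not contain missing values")
  if (nrow(histories) < n_components)
    stop("fewer cells than requested components")
  time <- time %||% seq_len(ncol(histories))
  pc <- stats::prcomp(histories, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  comps <- pc$rotation[, seq_len(k), drop = FALSE]
  sigma <- signal_integral(histories, time)
  for (j in seq_len(k)) {
    r <- suppressWarnings(stats::cor(scores[, j], sigma))
    if (!is.na(r) && r < 0) {
      scores[, j] <- -scores[, j]
      comps[, j] <- -comps[, j]
    }
  }
  list(scores = scores, components = comps,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Correlation between sigmoid features and principal components
#'
#' @param features data.frame with columns `H`, `L`, `d`, `integral`.
#' @param scores PC score matrix (cells x k), rows aligned with `features`.
#' @return matrix of Pearson correlations, features x PCs; zero-variance
#'   features give `NA`.
#' @export
feature_pc_correlation <- function(features, scores) {
  if (nrow(features) < 3) stop("need at least 3 cells")
  feat <- as.matrix(features[, c("H", "L", "d", "integral")])
  out <- matrix(NA_real_, 4, ncol(scores),
                dimnames = list(c("H", "L", "d", "integral"),
                                colnames(scores) %||%
                                  paste0("PC", seq_len(ncol(scores)))))
  for (i in seq_len(4)) {
    if (stats::sd(feat[, i], na.rm = TRUE) == 0) next
    ok <- !is.na(feat[, i])
    out[i, ] <- stats::cor(feat[ok, i], scores[ok, , drop = FALSE])
  }
  out
}

#' Full feature extraction from a history matrix
#'
#' Convenience wrapper: sigmoid fits, baseline-subtracted integrals and PC
#' scores in one table.
#'
#' @param histories cells x timepoints matrix.
#' @param time time grid (hours).
#' @param baseline baseline for the integral; `"auto"` (default) uses the
#'   population median of the final quartile of timepoints as the reference
#'   level, or supply a constant.
#' @param n_components PCs to append.
#' @return data.frame: cell_id, H, L, d, tau, rmse, converged, integral,
#'   pc1..pcK; attribute `"baseline"` records the level used.
#' @export
extract_features <- function(histories, time, baseline = "auto",
                             n_components = 3) {
  if (identical(baseline, "auto")) {
    q <- max(ncol(histories) %/% 4, 1)
    baseline <- stats::median(histories[, seq(ncol(histories) - q + 1,
                                              ncol(histories))])
  }
  feat <- fit_sigmoids(histories, time)
  feat$integral <- signal_integral(histories, time, baseline)
  pc <- pca_histories(histories, n_components, time)
  for (j in seq_len(ncol(pc$scores))) feat[[paste0("pc", j)]] <- pc$scores[, j]
  attr(feat, "baseline") <- baseline
  attr(feat, "variance_explained") <- pc$variance_explained
  feat
}
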